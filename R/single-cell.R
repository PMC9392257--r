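#' Average matched diploid cells per window
#'
#' Computes the per-window mean and unbiased (n-1) variance of read depth
#' across matched diploid cells. The mean vector is the diploid baseline
#' `mu` of the emission model; the (mean, variance) pairs are the input to
#' [fit_dispersion].
#'
#' @param cells list of at least two [binned_depth] objects on one grid.
#' @return An object of class `diploid_profile` with fields `windows`,
#'   `mean`, `variance`, `n_cells`.
#' @export
average_diploid <- function(cells) {
  if (length(cells) < 2L)
    stop("need >= 2 diploid cells to estimate per-window variance")
  w <- cells[[1L]]$windows
  for (c in cells[-1L]) assert_same_grid(w, c$windows)
  X <- do.call(cbind, lapply(cells, `[[`, "counts"))
  structure(list(windows = w,
                 mean = rowMeans(X),
                 variance = apply(X, 1L, stats::var),
                 n_cells = length(cells)),
            class = "diploid_profile")
}

#' @export
print.diploid_profile <- function(x, ...) {
  cat("<diploid_profile>", length(x$mean), "windows averaged over",
      x$n_cells, "diploid cells; mean depth",
      sprintf("%.1f", mean(x$mean)), "\n")
  invisible(x)
}

#' Fit the variance-mean dispersion model on diploid data
#'
#' Least-squares fit of `variance = a*mean^2 + b*mean + c` to the per-window
#' (mean, variance) pairs of the diploid baseline, constrained to
#' `a >= 0`, `c >= 0`. An unconstrained quadratic regression provides the
#' starting point; the constrained solution is found with L-BFGS-B.
#'
#' @param diploid a `diploid_profile` from [average_diploid]; needs at
#'   least 50 windows with positive mean and non-constant means.
#' @param epsilon sequencing-error constant to carry into the model
#'   (default 0.01 reads).
#' @return A [dispersion_model] with attribute `residual_rmse`.
#' @export
fit_dispersion <- function(diploid, epsilon = 0.01) {
  stopifnot(inherits(diploid, "diploid_profile"))
  ok <- diploid$mean > 0
  if (sum(ok) < 50L)
    stop("need >= 50 windows with positive diploid mean")
  m <- diploid$mean[ok]
  v <- diploid$variance[ok]
  if (stats::sd(m) == 0)
    stop("degenerate design: diploid means are constant across windows")
  ls <- stats::lm(v ~ I(m^2) + m)
  start <- c(a = max(unname(stats::coef(ls)[2L]), 0),
             b = unname(stats::coef(ls)[3L]),
             c = max(unname(stats::coef(ls)[1L]), 0))
  obj <- function(p) sum((p[1L] * m^2 + p[2L] * m + p[3L] - v)^2)
  fit <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(0, -Inf, 0), upper = rep(Inf, 3L))
  out <- dispersion_model(unname(fit$par[1L]), unname(fit$par[2L]),
                          unname(fit$par[3L]), epsilon)
  attr(out, "residual_rmse") <- sqrt(fit$value / length(m))
  out
}

# structured single-cell genome chain for rates (alpha,beta,gamma) and time t
single_cell_chain <- function(alpha, beta, gamma, t, k) {
  Q <- build_rate_matrix(cna_rates(alpha, beta, gamma), k)
  P <- transition_matrix(Q, t)
  single_cell_genome_transition(P, k)
}

# moment-match {alpha,gamma,t} (beta fixed at 1, the rate-scale
# normalisation) to an unconstrained BW chain: grid of candidate t values,
# Nelder-Mead refinement of log(alpha), log(gamma) at each, smallest
# Frobenius distance wins
match_rates_to_chain <- function(M_bw, k, t_grid = c(0.02, 0.05, 0.1, 0.2,
                                                     0.5, 1, 2)) {
  best <- NULL
  for (t0 in t_grid) {
    obj <- function(lp) {
      p <- exp(lp)
      Ms <- tryCatch(single_cell_chain(p[1L], 1, p[2L], t0, k),
                     error = function(e) NULL)
      if (is.null(Ms)) return(1e10)
      sum((Ms - M_bw)^2)
    }
    o <- stats::optim(log(c(0.5, 0.1)), obj, control = list(maxit = 150L))
    if (is.null(best) || o$value < best$value)
      best <- list(value = o$value, par = exp(o$par), t = t0)
  }
  list(alpha = best$par[1L], beta = 1, gamma = best$par[2L], t = best$t)
}

#' Fit the single-cell copy-number model to one cell
#'
#' Stage-1 fit of the evolutionary copy-number model to one tumor cell,
#' analysed independently of all others:
#' 1. an unconstrained Baum-Welch pass ([baum_welch_init]) estimates a free
#'    (k+1)-state chain and refines the library-size scaling factor `s`;
#' 2. rates `{alpha, beta, gamma}` and total branch length `t` are
#'    initialised by least-squares matching of the structured genome chain
#'    to the Baum-Welch chain;
#' 3. `{s, alpha, beta, gamma, t}` are jointly refined by BFGS on the
#'    forward log-likelihood, parameterised on the log scale to enforce
#'    positivity (up to 3 seeded random restarts on failure);
#' 4. the Viterbi path gives the cell's integer copy-number profile.
#'
#' The event-rate scale and branch lengths are confounded (only the
#' products rate x time enter the transition chain), so `beta` is fixed at
#' 1 during this stage: `alpha` and `gamma` are then rate ratios and `t`
#' is measured in expected any-magnitude events per bin pair.
#'
#' @param cell a [binned_depth] for the tumor cell.
#' @param diploid a `diploid_profile` from [average_diploid].
#' @param dispersion a [dispersion_model] from [fit_dispersion].
#' @param k maximum copy number (default 10).
#' @param bw_max_iter maximum Baum-Welch sweeps (default 25).
#' @return An object of class `cn_fit` with components `cell_id`, `s`,
#'   `rates` ([cna_rates]), `t`, `loglik`, `cnp` ([cn_profile]), `model`
#'   (the fitted [cn_hmm]), and `convergence`.
#' @export
fit_cell <- function(cell, diploid, dispersion, k = 10L,
                     bw_max_iter = 25L) {
  stopifnot(inherits(cell, "binned_depth"))
  assert_same_grid(cell$windows, diploid$windows)
  mu <- diploid$mean
  s0 <- sum(cell$counts) / sum(mu)
  ctx0 <- emission_context(s0, mu, dispersion)
  bw <- baum_welch_init(cell, ctx0, k, max_iter = bw_max_iter)
  init <- match_rates_to_chain(bw$transition, k)
  starts <- chromosome_starts(cell$windows)

  # lp = log(s, alpha, gamma, t); beta = 1 (identifiability normalisation)
  negll <- function(lp) {
    p <- exp(lp)
    val <- tryCatch({
      M <- single_cell_chain(p[2L], 1, p[3L], p[4L], k)
      pi <- steady_state(M)
      ctx <- emission_context(p[1L], mu, dispersion)
      -hmm_forward_cpp(emission_logmat(cell$counts, ctx, k), M, pi, starts)
    }, error = function(e) Inf)
    if (!is.finite(val)) 1e12 else val
  }

  lower <- log(c(1e-2, 1e-6, 1e-6, 1e-4))
  upper <- log(c(1e2, 1e3, 1e3, 50))
  lp0 <- pmin(pmax(log(c(bw$s, init$alpha, init$gamma, init$t)), lower),
              upper)
  opt <- stats::optim(lp0, negll, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(maxit = 200L, factr = 1e7))
  for (r in seq_len(3L)) {
    if (is.finite(opt$value) && opt$value < 1e11) break
    jitter <- stats::rnorm(length(lp0), 0, 0.3)
    opt2 <- stats::optim(pmin(pmax(lp0 + jitter, lower), upper), negll,
                         method = "L-BFGS-B", lower = lower, upper = upper,
                         control = list(maxit = 200L, factr = 1e7))
    if (opt2$value < opt$value) opt <- opt2
  }
  if (!is.finite(opt$value) || opt$value >= 1e11)
    stop("single-cell optimisation failed for cell ", cell$cell_id)
  p <- exp(opt$par)
  # canonicalise the rate/time scale: (c*alpha, c*beta, t/c) is likelihood
  # invariant, so rescale to alpha + beta = 1; t is then the expected
  # number of single-bin events per bin over the cell's history
  sc <- p[2L] + 1
  s <- p[1L]; rates <- cna_rates(p[2L] / sc, 1 / sc, p[3L])
  t_hat <- p[4L] * sc
  M <- single_cell_chain(rates$alpha, rates$beta, rates$gamma, t_hat, k)
  pi <- steady_state(M)
  ctx <- emission_context(s, mu, dispersion)
  model <- cn_hmm(M, pi, list(ctx), cell$windows, k)
  cnp <- viterbi(model, cell)
  structure(list(cell_id = cell$cell_id, s = s, rates = rates, t = t_hat,
                 loglik = -opt$value, cnp = cnp, model = model,
                 convergence = opt$convergence,
                 init_loglik = -negll(lp0)),
            class = "cn_fit")
}

#' @export
print.cn_fit <- function(x, ...) {
  cat(sprintf(
    "<cn_fit> cell '%s': s=%.3f alpha=%.3g beta=%.3g gamma=%.3g t=%.3g\n",
    x$cell_id, x$s, x$rates$alpha, x$rates$beta, x$rates$gamma, x$t))
  cat(sprintf("  log-likelihood %.2f over %d windows\n", x$loglik,
              length(x$cnp$cn)))
  invisible(x)
}

#' @export
coef.cn_fit <- function(object, ...) {
  c(s = object$s, alpha = object$rates$alpha, beta = object$rates$beta,
    gamma = object$rates$gamma, t = object$t)
}

#' @export
logLik.cn_fit <- function(object, ...) {
  structure(object$loglik, df = 5L, class = "logLik")
}

#' @export
summary.cn_fit <- function(object, ...) {
  tab <- table(factor(object$cnp$cn, levels = 0:object$model$k))
  out <- list(coef = coef(object), loglik = object$loglik,
              cn_table = tab, cell_id = object$cell_id)
  class(out) <- "summary.cn_fit"
  out
}

#' @export
print.summary.cn_fit <- function(x, ...) {
  cat("Single-cell copy-number model fit, cell '", x$cell_id, "'\n",
      sep = "")
  print(round(x$coef, 5L))
  cat("log-likelihood:", format(x$loglik), "\n")
  cat("decoded copy-number distribution:\n")
  print(x$cn_table)
  invisible(x)
}

#' @export
plot.cn_fit <- function(x, ...) {
  n <- length(x$cnp$cn)
  graphics::plot(seq_len(n), x$cnp$cn, type = "s", xlab = "window index",
                 ylab = "copy number",
                 main = paste0("Decoded profile: ", x$cell_id),
                 ylim = c(0, max(x$cnp$cn) + 0.5), ...)
  graphics::abline(h = 2, lty = 3, col = "grey50")
  invisible(x)
}
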