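#' Hidden Markov model over binned read depth
#'
#' Container tying together a genome-wide transition chain, its stationary
#' initial distribution (used to re-initialise the chain at the start of
#' every chromosome, enforcing chromosomal independence), per-cell emission
#' contexts, and the window grid.
#'
#' For a single cell the hidden states are copy numbers 0..k; for a pair of
#' cells they are paired copy numbers (CN_A, CN_B), indexed row-major.
#'
#' @param transition row-stochastic transition matrix.
#' @param initial initial/stationary probability vector.
#' @param contexts list of one or two [emission_context]s.
#' @param windows the shared [genomic_windows] grid.
#' @param k maximum copy number.
#' @return An object of class `cn_hmm`.
#' @export
cn_hmm <- function(transition, initial, contexts, windows, k) {
  stopifnot(is.matrix(transition), nrow(transition) == ncol(transition))
  if (abs(sum(initial) - 1) > 1e-6) stop("initial distribution must sum to 1")
  if (max(abs(rowSums(transition) - 1)) > 1e-6)
    stop("transition matrix must be row-stochastic")
  n_cells <- length(contexts)
  if (!n_cells %in% 1:2) stop("contexts must hold one or two cells")
  S <- nrow(transition)
  expect <- if (n_cells == 1L) k + 1L else (k + 1L)^2
  if (S != expect) stop("transition dimension does not match k and cell count")
  structure(list(transition = transition, initial = as.numeric(initial),
                 contexts = contexts, windows = windows, k = as.integer(k),
                 n_cells = n_cells),
            class = "cn_hmm")
}

hmm_logemissions <- function(model, obs) {
  if (inherits(obs, "binned_depth")) obs <- list(obs)
  if (length(obs) != model$n_cells)
    stop("number of observation cells does not match model")
  for (o in obs) {
    if (length(o$counts) != nrow(model$windows))
      stop("observations not aligned to the model window grid")
  }
  if (model$n_cells == 1L) {
    emission_logmat(obs[[1L]]$counts, model$contexts[[1L]], model$k)
  } else {
    pair_emission_logmat(obs[[1L]]$counts, obs[[2L]]$counts,
                         model$contexts[[1L]], model$contexts[[2L]], model$k)
  }
}

#' Forward log-likelihood
#'
#' Scaled forward recursion over the window grid. At the first window of
#' each chromosome the state distribution is reset to the model's initial
#' (stationary) vector; the returned value is the sum of per-chromosome
#' log-likelihoods.
#'
#' @param model a [cn_hmm].
#' @param obs a [binned_depth] (single-cell model) or list of two
#'   (pair model), aligned to the model's window grid.
#' @return Total log-likelihood.
#' @export
forward_loglik <- function(model, obs) {
  logE <- hmm_logemissions(model, obs)
  hmm_forward_cpp(logE, model$transition, model$initial,
                  chromosome_starts(model$windows))
}

#' Viterbi decoding
#'
#' Most likely state path, decoded independently per chromosome with
#' stationary initialisation. Ties are broken toward the smaller state
#' index. Windows with diploid mean 0 are uninformative; their decoded
#' value follows the chain.
#'
#' @inheritParams forward_loglik
#' @return For a single-cell model, a [cn_profile]. For a pair model, a
#'   list of two [cn_profile]s (`A`, `B`).
#' @export
viterbi <- function(model, obs) {
  logE <- hmm_logemissions(model, obs)
  path <- hmm_viterbi_cpp(logE, model$transition, model$initial,
                          chromosome_starts(model$windows))
  if (inherits(obs, "binned_depth")) obs <- list(obs)
  if (model$n_cells == 1L) {
    cn_profile(model$windows, path - 1L, integer_valued = TRUE,
               cell_id = obs[[1L]]$cell_id)
  } else {
    k <- model$k
    cnA <- (path - 1L) %/% (k + 1L)
    cnB <- (path - 1L) %% (k + 1L)
    list(A = cn_profile(model$windows, cnA, TRUE, obs[[1L]]$cell_id),
         B = cn_profile(model$windows, cnB, TRUE, obs[[2L]]$cell_id))
  }
}

#' Unconstrained Baum-Welch initialisation for one cell
#'
#' Fits an unconstrained (k+1)-state transition matrix to a single cell's
#' binned depth by expectation-maximisation, with emissions fixed by the
#' copy-number structure except for the library-size scaling factor `s`,
#' which is refined by one golden-section search per EM sweep. Used to
#' produce starting points for the structured model fit.
#'
#' @param obs a [binned_depth].
#' @param ctx an [emission_context] (its `s` is the starting value).
#' @param k maximum copy number.
#' @param max_iter maximum EM sweeps (default 100).
#' @param tol relative log-likelihood improvement for convergence
#'   (default 1e-6).
#' @return List with `transition` (the fitted chain), `s` (refined scaling
#'   factor), `initial`, and `loglik_trace` (non-decreasing within 1e-8).
#' @export
baum_welch_init <- function(obs, ctx, k, max_iter = 100L, tol = 1e-6) {
  stopifnot(inherits(obs, "binned_depth"))
  starts <- chromosome_starts(obs$windows)
  S <- k + 1L
  # diagonal-heavy start: copy number tracks along the genome
  M <- matrix(0.05 / (S - 1L), S, S)
  diag(M) <- 0.95
  pi <- rep(1 / S, S)
  s <- ctx$s
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    ctx_it <- emission_context(s, ctx$mu, ctx$dispersion)
    logE <- emission_logmat(obs$counts, ctx_it, k)
    es <- hmm_bw_estep_cpp(logE, M, pi, starts)
    if (!is.finite(es$loglik)) stop("non-finite likelihood in Baum-Welch")
    trace <- c(trace, es$loglik)
    if (it > 1L) {
      rel <- (trace[it] - trace[it - 1L]) / abs(trace[it - 1L])
      if (rel < tol) break
    }
    xi <- es$xi
    rs <- rowSums(xi)
    keep <- rs > 0
    M[keep, ] <- xi[keep, , drop = FALSE] / rs[keep]
    M[!keep, ] <- 1 / S
    gs <- es$gamma_start
    if (sum(gs) > 0) pi <- gs / sum(gs)
    # refine s against the current chain
    f <- function(sv) {
      ctx_s <- emission_context(sv, ctx$mu, ctx$dispersion)
      -hmm_forward_cpp(emission_logmat(obs$counts, ctx_s, k), M, pi, starts)
    }
    s <- stats::optimize(f, interval = c(s / 2, s * 2), tol = s * 1e-3)$minimum
  }
  list(transition = M, s = s, initial = pi, loglik_trace = trace)
}
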