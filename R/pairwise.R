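#' Combine per-cell rate estimates into shared rates
#'
#' The event rates `{alpha, beta, gamma}` are assumed shared across all
#' cells of a tumor; the per-cell estimates from [fit_cell] are combined by
#' the component-wise median (for an even number of cells, the average of
#' the two middle values).
#'
#' @param fits list of `cn_fit` objects (at least one).
#' @return A [cna_rates] object.
#' @export
combine_rates <- function(fits) {
  if (length(fits) == 0L) stop("no fits to combine")
  cna_rates(stats::median(vapply(fits, function(f) f$rates$alpha, 0)),
            stats::median(vapply(fits, function(f) f$rates$beta, 0)),
            stats::median(vapply(fits, function(f) f$rates$gamma, 0)))
}

#' Pair tree container
#'
#' Branch lengths of the two-cell tree: `t1` from the diploid ancestor to
#' the divergence point, `t2` and `t3` from divergence to cells A and B.
#' `t2 + t3` is the pairwise evolutionary distance between the cells.
#'
#' @param t1,t2,t3 non-negative branch lengths.
#' @return An object of class `pair_tree`.
#' @export
pair_tree <- function(t1, t2, t3) {
  if (any(c(t1, t2, t3) < 0)) stop("branch lengths must be >= 0")
  structure(list(t1 = t1, t2 = t2, t3 = t3), class = "pair_tree")
}

#' @export
print.pair_tree <- function(x, ...) {
  cat(sprintf("<pair_tree> t1=%.4g t2=%.4g t3=%.4g (t2+t3=%.4g)\n",
              x$t1, x$t2, x$t3, x$t2 + x$t3))
  invisible(x)
}

#' Initial pair-tree branch lengths from single-cell fits
#'
#' Given the total branch lengths `tA`, `tB` estimated for each cell
#' independently, the starting point for the pair optimisation places the
#' divergence at half the smaller total:
#' `t1 = min(tA, tB)/2`, `t2 = tA - t1`, `t3 = tB - t1`.
#'
#' @param tA,tB positive total branch lengths for cells A and B.
#' @return A [pair_tree].
#' @export
init_tree <- function(tA, tB) {
  if (tA <= 0 || tB <= 0) stop("total branch lengths must be > 0")
  t1 <- min(tA, tB) / 2
  pair_tree(t1, tA - t1, tB - t1)
}

# build the pair HMM ingredients for given rates/tree; branch lengths
# floored at 1e-6 to keep the chain irreducible
pair_chain <- function(rates, tree, k, cache = NULL) {
  t1 <- max(tree$t1, 1e-6); t2 <- max(tree$t2, 1e-6); t3 <- max(tree$t3, 1e-6)
  key <- paste(round(c(t1, t2, t3), 9L), collapse = "_")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  Q <- build_rate_matrix(rates, k)
  P1 <- transition_matrix(Q, t1)
  P2 <- if (t2 == t1) P1 else transition_matrix(Q, t2)
  P3 <- if (t3 == t2) P2 else if (t3 == t1) P1 else transition_matrix(Q, t3)
  Fm <- pair_joint_adjacent(P1, P2, P3, k)
  M <- genome_transition(Fm)
  pi <- steady_state(M)
  out <- list(M = M, pi = pi)
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' Fit the two-cell tree for one pair of cells
#'
#' Maximises the two-cell forward log-likelihood over the branch lengths
#' `(t1, t2, t3)` of the pair tree by BFGS on the log scale, starting from
#' [init_tree] of the cells' independent total branch lengths. The
#' library-size factors, dispersion model and shared rates are held fixed
#' from stage 1-2; the genome-wide transition matrix and its stationary
#' (chromosome-reset) distribution are rebuilt at every evaluation. The
#' fitted tree is then used for a joint Viterbi decoding of both cells.
#'
#' @param cellA,cellB [binned_depth] objects on one grid.
#' @param ctxA,ctxB [emission_context]s for the two cells (fixed `s`).
#' @param shared shared [cna_rates] from [combine_rates].
#' @param k maximum copy number.
#' @param init a [pair_tree] starting point (e.g. from [init_tree]).
#' @param maxit BFGS iteration cap (default 100).
#' @return An object of class `cn_pair_fit`: `cells`, `tree`, `loglik`,
#'   `cnpA`, `cnpB`, `init_loglik`, `convergence`.
#' @export
fit_cell_pair <- function(cellA, cellB, ctxA, ctxB, shared, k,
                          init = pair_tree(0.1, 0.1, 0.1), maxit = 100L) {
  assert_same_grid(cellA$windows, cellB$windows)
  starts <- chromosome_starts(cellA$windows)
  logE <- pair_emission_logmat(cellA$counts, cellB$counts, ctxA, ctxB, k)
  cache <- new.env(parent = emptyenv())
  negll <- function(lp) {
    tr <- pair_tree(exp(lp[1L]), exp(lp[2L]), exp(lp[3L]))
    val <- tryCatch({
      ch <- pair_chain(shared, tr, k, cache)
      -hmm_forward_cpp(logE, ch$M, ch$pi, starts)
    }, error = function(e) Inf)
    if (!is.finite(val)) 1e12 else val
  }
  m0 <- mean(c(init$t1, init$t2, init$t3))
  starts_lp <- list(log(pmax(c(init$t1, init$t2, init$t3), 1e-4)),
                    log(rep(max(m0, 1e-3), 3L)))
  opt <- NULL
  for (lp0 in starts_lp) {
    o <- stats::optim(lp0, negll, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-7))
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  lp0 <- starts_lp[[1L]]
  for (r in seq_len(3L)) {
    if (is.finite(opt$value) && opt$value < 1e11) break
    opt2 <- stats::optim(lp0 + stats::rnorm(3L, 0, 0.3), negll,
                         method = "BFGS",
                         control = list(maxit = maxit, reltol = 1e-7))
    if (opt2$value < opt$value) opt <- opt2
  }
  if (!is.finite(opt$value) || opt$value >= 1e11)
    stop("pair optimisation failed for (", cellA$cell_id, ", ",
         cellB$cell_id, ")")
  tree <- pair_tree(exp(opt$par[1L]), exp(opt$par[2L]), exp(opt$par[3L]))
  ch <- pair_chain(shared, tree, k, cache)
  model <- cn_hmm(ch$M, ch$pi, list(ctxA, ctxB), cellA$windows, k)
  dec <- viterbi(model, list(cellA, cellB))
  structure(list(cells = c(cellA$cell_id, cellB$cell_id), tree = tree,
                 loglik = -opt$value, cnpA = dec$A, cnpB = dec$B,
                 init_loglik = -negll(lp0), convergence = opt$convergence),
            class = "cn_pair_fit")
}

#' @export
print.cn_pair_fit <- function(x, ...) {
  cat(sprintf("<cn_pair_fit> (%s, %s): t1=%.4g t2=%.4g t3=%.4g  logLik %.2f\n",
              x$cells[1L], x$cells[2L], x$tree$t1, x$tree$t2, x$tree$t3,
              x$loglik))
  invisible(x)
}

#' @export
coef.cn_pair_fit <- function(object, ...) {
  c(t1 = object$tree$t1, t2 = object$tree$t2, t3 = object$tree$t3)
}

#' @export
logLik.cn_pair_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, class = "logLik")
}

#' Fit all requested pairs of cells
#'
#' Runs [fit_cell_pair] for every pair in `pair_list` (by default all
#' unordered pairs). Each pair is independent; results are keyed
#' `"A|B"` with the two ids in lexicographic order.
#'
#' @param cells named list of [binned_depth] objects.
#' @param fits named list of `cn_fit` objects (same names), providing the
#'   fixed `s` and the initial branch lengths.
#' @param shared shared [cna_rates].
#' @param diploid a `diploid_profile` (for `mu`).
#' @param dispersion a [dispersion_model].
#' @param k maximum copy number.
#' @param pair_list optional 2-column character matrix of pairs to fit;
#'   default all pairs.
#' @param maxit per-pair BFGS iteration cap.
#' @return Named list of `cn_pair_fit` objects.
#' @export
fit_all_pairs <- function(cells, fits, shared, diploid, dispersion, k,
                          pair_list = NULL, maxit = 100L) {
  ids <- names(cells)
  if (is.null(ids)) stop("cells must be a named list")
  if (is.null(pair_list)) {
    if (length(ids) < 2L) stop("need >= 2 cells")
    pair_list <- t(utils::combn(sort(ids), 2L))
  }
  if (length(pair_list) == 0L) {
    warning("empty pair list; nothing to fit")
    return(list())
  }
  unknown <- setdiff(unique(as.vector(pair_list)), ids)
  if (length(unknown)) stop("unknown cell id: ", unknown[1L])
  out <- list()
  for (r in seq_len(nrow(pair_list))) {
    ab <- sort(pair_list[r, ])
    A <- ab[1L]; B <- ab[2L]
    ctxA <- emission_context(fits[[A]]$s, diploid$mean, dispersion)
    ctxB <- emission_context(fits[[B]]$s, diploid$mean, dispersion)
    out[[paste(A, B, sep = "|")]] <- fit_cell_pair(
      cells[[A]], cells[[B]], ctxA, ctxB, shared, k,
      init = init_tree(fits[[A]]$t, fits[[B]]$t), maxit = maxit)
  }
  out
}
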