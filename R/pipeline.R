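#' Joint copy-number inference across a set of tumor cells
#'
#' End-to-end pipeline:
#' 1. average matched diploid cells and fit the variance-mean dispersion
#'    model ([average_diploid], [fit_dispersion]);
#' 2. fit each tumor cell independently ([fit_cell]);
#' 3. combine rate estimates by the median ([combine_rates]) and fit the
#'    two-cell tree for every pair — or, with finite `kappa`, only the
#'    pairs involving each cell's `kappa` nearest neighbours
#'    ([fit_cell_pair]);
#' 4. summarise each cell's paired decodings into a consensus profile
#'    ([consensus_profile]).
#'
#' With `kappa < n - 1` the distance matrix is incomplete and tree
#' estimation on `t2 + t3` is unavailable (all pairs are required).
#'
#' @param tumor named list of [binned_depth]s for tumor cells.
#' @param diploid list of [binned_depth]s for matched diploid cells.
#' @param k maximum copy number (default 10).
#' @param kappa number of nearest-neighbour pairs per cell, or `"all"`
#'   (default) for every pair.
#' @param summary consensus summary: "mean" (default), "median", "mode".
#' @param bw_max_iter Baum-Welch sweep cap passed to [fit_cell].
#' @param pair_maxit BFGS cap passed to [fit_cell_pair].
#' @param verbose print progress (default FALSE).
#' @return An object of class `paircn_fit`: `fits`, `shared_rates`,
#'   `pair_fits`, `consensus`, `diploid`, `dispersion`, `k`, `kappa`,
#'   `summary`.
#' @export
paircn <- function(tumor, diploid, k = 10L, kappa = "all",
                   summary = "mean", bw_max_iter = 25L, pair_maxit = 100L,
                   verbose = FALSE) {
  if (is.null(names(tumor)) || any(!nzchar(names(tumor))))
    names(tumor) <- vapply(tumor, `[[`, "", "cell_id")
  dip <- average_diploid(diploid)
  disp <- fit_dispersion(dip)
  fits <- list()
  for (id in names(tumor)) {
    if (verbose) message("fitting cell ", id)
    fits[[id]] <- fit_cell(tumor[[id]], dip, disp, k,
                           bw_max_iter = bw_max_iter)
  }
  shared <- combine_rates(fits)
  ids <- names(tumor)
  pair_list <- NULL
  if (!identical(kappa, "all")) {
    cnps <- lapply(fits, `[[`, "cnp")
    sel <- unique(do.call(rbind, lapply(ids, function(id) {
      nb <- nearest_neighbors(id, cnps, as.integer(kappa))
      t(vapply(nb, function(b) sort(c(id, b)), c("", "")))
    })))
    pair_list <- sel
  }
  if (verbose) message("fitting pairs")
  pair_fits <- fit_all_pairs(tumor, fits, shared, dip, disp, k,
                             pair_list = pair_list, maxit = pair_maxit)
  consensus <- list()
  for (id in ids) {
    pp <- paired_profiles_for(id, pair_fits)
    consensus[[id]] <- consensus_profile(pp, summary = summary,
                                         cell_id = id)
  }
  structure(list(fits = fits, shared_rates = shared,
                 pair_fits = pair_fits, consensus = consensus,
                 diploid = dip, dispersion = disp, k = k, kappa = kappa,
                 summary = summary),
            class = "paircn_fit")
}

#' @export
print.paircn_fit <- function(x, ...) {
  cat("<paircn_fit>", length(x$fits), "cells,", length(x$pair_fits),
      "pair fits, consensus =", x$summary, "\n")
  print(x$shared_rates)
  invisible(x)
}

#' @export
summary.paircn_fit <- function(object, ...) {
  t23 <- vapply(object$pair_fits, function(p) p$tree$t2 + p$tree$t3, 0)
  out <- list(n_cells = length(object$fits),
              n_pairs = length(object$pair_fits),
              shared = object$shared_rates,
              t_hat = vapply(object$fits, `[[`, 0, "t"),
              t2t3 = t23, summary = object$summary)
  class(out) <- "summary.paircn_fit"
  out
}

#' @export
print.summary.paircn_fit <- function(x, ...) {
  cat("Joint copy-number fit:", x$n_cells, "cells,", x$n_pairs, "pairs\n")
  cat("shared rates: "); print(x$shared)
  cat("per-cell total branch lengths:\n"); print(round(x$t_hat, 4L))
  cat("pairwise t2+t3 distances (summary):\n")
  print(summary(x$t2t3))
  invisible(x)
}

#' Distance matrix from a fitted pipeline
#'
#' @param fit a `paircn_fit` run with `kappa = "all"`.
#' @param metric "t2t3" (pairwise branch-length distance) or "euclidean"
#'   (over the independent single-cell profiles).
#' @return Symmetric distance matrix.
#' @export
distance_matrix <- function(fit, metric = c("t2t3", "euclidean")) {
  metric <- match.arg(metric)
  if (metric == "t2t3") t2t3_matrix(fit$pair_fits)
  else euclidean_matrix(lapply(fit$fits, `[[`, "cnp"))
}
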