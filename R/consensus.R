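#' Nearest neighbours of a cell by profile distance
#'
#' Orders the other cells by Euclidean distance between their independent
#' (single-cell) copy-number profiles and the target's, ascending; ties are
#' broken lexicographically by cell id. Used to restrict the pairwise stage
#' to the `kappa` most similar cells.
#'
#' @param target_cell id of the cell of interest.
#' @param cnps named list of [cn_profile]s (one per cell, shared grid).
#' @param kappa number of neighbours to return; if it is not smaller than
#'   the number of other cells, all are returned with a warning.
#' @return Character vector of cell ids, nearest first.
#' @export
nearest_neighbors <- function(target_cell, cnps, kappa) {
  if (!target_cell %in% names(cnps)) stop("unknown target cell")
  others <- setdiff(names(cnps), target_cell)
  tgt <- cnps[[target_cell]]
  d <- vapply(others, function(id) {
    assert_same_grid(tgt$windows, cnps[[id]]$windows)
    sqrt(sum((tgt$cn - cnps[[id]]$cn)^2))
  }, 0)
  ord <- order(d, others)
  if (kappa >= length(others)) {
    if (kappa > length(others))
      warning("kappa >= number of other cells; returning all")
    return(others[ord])
  }
  others[ord][seq_len(kappa)]
}

#' Consensus copy-number profile across paired decodings
#'
#' A cell analysed in m pairs receives m paired Viterbi profiles; the
#' consensus summarises them per window with the mean (default), median or
#' mode. Mean and median may be fractional; the mode is integer, with ties
#' broken toward the smaller copy number.
#'
#' @param paired_cnps non-empty list of integer [cn_profile]s for one cell.
#' @param summary one of "mean", "median", "mode".
#' @param cell_id optional id for the output profile.
#' @return A [cn_profile]; `integer_valued` reflects the summary used.
#' @export
consensus_profile <- function(paired_cnps, summary = c("mean", "median",
                                                       "mode"),
                              cell_id = NULL) {
  summary <- match.arg(summary)
  if (length(paired_cnps) == 0L) stop("no paired profiles to summarise")
  w <- paired_cnps[[1L]]$windows
  for (p in paired_cnps[-1L]) assert_same_grid(w, p$windows)
  X <- do.call(cbind, lapply(paired_cnps, `[[`, "cn"))
  cn <- switch(summary,
    mean = rowMeans(X),
    median = apply(X, 1L, stats::median),
    mode = apply(X, 1L, function(v) {
      tb <- table(v)
      as.numeric(names(tb)[which.max(tb)])  # which.max: first = smallest CN
    }))
  cn_profile(w, cn, integer_valued = all(cn == round(cn)), cell_id = cell_id)
}

#' Extract a cell's paired profiles from a set of pair fits
#'
#' @param cell_id the cell whose profiles to collect.
#' @param pair_fits named list of `cn_pair_fit`s keyed `"A|B"`.
#' @return List of [cn_profile]s for `cell_id`, one per pair it appears in.
#' @export
paired_profiles_for <- function(cell_id, pair_fits) {
  out <- list()
  for (pf in pair_fits) {
    if (pf$cells[1L] == cell_id) out[[length(out) + 1L]] <- pf$cnpA
    else if (pf$cells[2L] == cell_id) out[[length(out) + 1L]] <- pf$cnpB
  }
  out
}
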