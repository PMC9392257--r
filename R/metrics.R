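#' Sum of squared errors between two copy-number profiles
#'
#' @param inferred,truth [cn_profile]s on one grid.
#' @return `sum((inferred - truth)^2)` over windows.
#' @export
sse <- function(inferred, truth) {
  assert_same_grid(inferred$windows, truth$windows)
  sum((inferred$cn - truth$cn)^2)
}

profile_breakpoints <- function(profile) {
  cn <- profile$cn
  chrom <- as.character(profile$windows$chrom)
  n <- length(cn)
  if (n < 2L) return(data.frame(chrom = character(0), pos = integer(0)))
  i <- seq_len(n - 1L)
  hit <- cn[i] != cn[i + 1L] & chrom[i] == chrom[i + 1L]
  data.frame(chrom = chrom[i][hit], pos = i[hit])
}

#' Breakpoint distance and inflation ratio
#'
#' A breakpoint is a boundary between adjacent windows of one chromosome
#' where the profile value changes. `total_distance` sums, over true
#' breakpoints, the distance (in windows) to the nearest inferred
#' breakpoint on the same chromosome; chromosomes with true breakpoints
#' but no inferred ones contribute the chromosome length (in windows) per
#' true breakpoint. `omega` is the ratio of inferred to true breakpoint
#' counts (1 is ideal); it is `NA` when there are no true breakpoints.
#'
#' @param inferred,truth [cn_profile]s on one grid.
#' @return List with `total_distance`, `omega`, `n_inferred`, `n_true`.
#' @export
breakpoint_stats <- function(inferred, truth) {
  assert_same_grid(inferred$windows, truth$windows)
  bp_inf <- profile_breakpoints(inferred)
  bp_tru <- profile_breakpoints(truth)
  chrom_len <- table(as.character(truth$windows$chrom))
  total <- 0
  for (r in seq_len(nrow(bp_tru))) {
    ch <- bp_tru$chrom[r]
    cand <- bp_inf$pos[bp_inf$chrom == ch]
    total <- total + if (length(cand)) min(abs(cand - bp_tru$pos[r]))
                     else as.numeric(chrom_len[[ch]])
  }
  omega <- if (nrow(bp_tru) == 0L) NA_real_
           else nrow(bp_inf) / nrow(bp_tru)
  list(total_distance = total, omega = omega,
       n_inferred = nrow(bp_inf), n_true = nrow(bp_tru))
}
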