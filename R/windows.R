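#' Genomic window grids and binned depth containers
#'
#' A `genomic_windows` object is an ordered grid of fixed genomic intervals
#' (0-based, half-open, BED convention) shared by every cell in one analysis.
#' Windows are kept in file order; chromosome boundaries are derived from
#' changes in the `chrom` field and drive the per-chromosome resets of the
#' hidden Markov chain.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors of 0-based half-open interval bounds.
#' @return An object of class `genomic_windows`: a data frame with columns
#'   `chrom`, `start`, `end`.
#' @export
genomic_windows <- function(chrom, start, end) {
  if (length(chrom) == 0L) stop("empty window grid")
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start, end must have equal length")
  start <- as.integer(start)
  end <- as.integer(end)
  if (anyNA(start) || anyNA(end)) stop("non-integer start/end in window grid")
  if (any(end <= start)) stop("windows must satisfy start < end")
  # within each chromosome run, windows must be sorted and non-overlapping
  runs <- rle(as.character(chrom))$lengths
  idx_end <- cumsum(runs)
  idx_start <- idx_end - runs + 1L
  for (r in seq_along(runs)) {
    i <- idx_start[r]:idx_end[r]
    if (length(i) > 1L) {
      s <- start[i]; e <- end[i]
      if (any(diff(s) <= 0) || any(s[-1L] < e[-length(e)]))
        stop("windows on chromosome '", chrom[idx_start[r]],
             "' are unsorted or overlapping")
    }
  }
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_windows", "data.frame")
  out
}

#' @export
print.genomic_windows <- function(x, ...) {
  cat("Genomic window grid:", nrow(x), "windows on",
      length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Indices at which a new chromosome starts
#'
#' @param windows a `genomic_windows` object.
#' @return Integer vector of 1-based indices of the first window of each
#'   chromosome block, in grid order.
#' @export
chromosome_starts <- function(windows) {
  runs <- rle(as.character(windows$chrom))$lengths
  cumsum(c(1L, runs[-length(runs)]))
}

#' Check that two window grids are identical
#' @param a,b `genomic_windows` objects.
#' @return TRUE invisibly; errors describing the first mismatch otherwise.
#' @export
assert_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b))
    stop("window grids differ in length (", nrow(a), " vs ", nrow(b), ")")
  bad <- which(a$chrom != b$chrom | a$start != b$start | a$end != b$end)
  if (length(bad))
    stop("window grids differ at index ", bad[1L])
  invisible(TRUE)
}

#' Construct a binned read-depth object
#'
#' Per-cell vector of read counts over a shared window grid; the observation
#' sequence of the copy-number HMM.
#'
#' @param windows a `genomic_windows` grid.
#' @param counts non-negative integer vector, one count per window.
#' @param cell_id cell identifier string.
#' @return An object of class `binned_depth` with fields `windows`, `counts`,
#'   `cell_id`.
#' @export
binned_depth <- function(windows, counts, cell_id = "cell") {
  stopifnot(inherits(windows, "genomic_windows"))
  if (length(counts) != nrow(windows))
    stop("length(counts) != number of windows")
  if (any(counts < 0)) stop("negative read counts")
  if (any(counts != floor(counts))) stop("non-integer read counts")
  structure(list(windows = windows, counts = as.numeric(counts),
                 cell_id = as.character(cell_id)),
            class = "binned_depth")
}

#' @export
print.binned_depth <- function(x, ...) {
  cat("<binned_depth> cell '", x$cell_id, "': ", length(x$counts),
      " windows, total reads ", format(sum(x$counts), big.mark = ","),
      "\n", sep = "")
  invisible(x)
}

#' Construct a copy-number profile
#'
#' @param windows a `genomic_windows` grid.
#' @param cn non-negative numeric vector of per-window copy numbers.
#' @param integer_valued logical; TRUE for decoded (integer) profiles, FALSE
#'   for fractional consensus profiles.
#' @param cell_id optional cell identifier.
#' @return An object of class `cn_profile`.
#' @export
cn_profile <- function(windows, cn, integer_valued = all(cn == round(cn)),
                       cell_id = NULL) {
  stopifnot(inherits(windows, "genomic_windows"))
  if (length(cn) != nrow(windows)) stop("length(cn) != number of windows")
  if (any(cn < 0)) stop("negative copy numbers")
  if (integer_valued && any(cn != round(cn)))
    stop("integer_valued profile contains fractional values")
  structure(list(windows = windows, cn = as.numeric(cn),
                 integer_valued = isTRUE(integer_valued),
                 cell_id = cell_id),
            class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat("<cn_profile>", if (!is.null(x$cell_id)) paste0("cell '", x$cell_id, "'"),
      length(x$cn), "windows,",
      if (x$integer_valued) "integer" else "fractional", "values\n")
  invisible(x)
}
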