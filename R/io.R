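#' Read a binned read-depth file
#'
#' Parses the 4-column tab-separated layout produced by `bedtools coverage`
#' on fixed genomic windows: chrom, start, end, count. Coordinates are
#' 0-based half-open. Extra columns beyond the fourth are ignored with a
#' warning.
#'
#' @param path path to the depth file.
#' @param cell_id cell identifier; defaults to the file name without
#'   extension.
#' @return A [binned_depth] object with windows in file order.
#' @export
read_depth_file <- function(path, cell_id = NULL) {
  if (is.null(cell_id))
    cell_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty depth file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("malformed depth line ", which(nf < 4L)[1L], " in ", path,
         ": fewer than 4 tab-separated columns")
  if (any(nf > 4L))
    warning("depth file ", path, " has extra columns; ignoring columns > 4")
  chrom <- vapply(fields, `[[`, "", 1L)
  parse_int <- function(col, what) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", col)))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad))
      stop("non-integer ", what, " on line ", bad[1L], " in ", path)
    v
  }
  start <- parse_int(2L, "start")
  end <- parse_int(3L, "end")
  count <- parse_int(4L, "count")
  neg <- which(count < 0)
  if (length(neg))
    stop("negative count on line ", neg[1L], " in ", path)
  binned_depth(genomic_windows(chrom, start, end), count, cell_id)
}

#' Write a binned read-depth file
#' @param x a [binned_depth] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_file <- function(x, path) {
  stopifnot(inherits(x, "binned_depth"))
  df <- data.frame(x$windows$chrom, x$windows$start, x$windows$end,
                   format(x$counts, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a copy-number profile as 4-column TSV
#'
#' Columns: chrom, start, end, copy number. With `round_to_int`, values are
#' rounded half-up to the nearest integer (1.5 becomes 2).
#'
#' @param profile a [cn_profile].
#' @param path output path.
#' @param round_to_int round fractional copy numbers half-up before writing.
#' @return `path`, invisibly.
#' @export
write_cnp <- function(profile, path, round_to_int = FALSE) {
  stopifnot(inherits(profile, "cn_profile"))
  cn <- profile$cn
  if (round_to_int) cn <- floor(cn + 0.5)
  df <- data.frame(profile$windows$chrom, profile$windows$start,
                   profile$windows$end,
                   format(cn, scientific = FALSE, trim = TRUE, digits = 15))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a copy-number profile written by [write_cnp]
#' @param path input path.
#' @param cell_id optional cell identifier.
#' @return A [cn_profile].
#' @export
read_cnp <- function(path, cell_id = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("expected 4 columns in CNP file ", path)
  cn_profile(genomic_windows(df[[1L]], df[[2L]], df[[3L]]), df[[4L]],
             integer_valued = all(df[[4L]] == round(df[[4L]])),
             cell_id = cell_id)
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree] and [ape::write.tree] that validate
#' the parse and preserve leaf labels and branch lengths.
#'
#' @param path file path.
#' @return `read_newick` returns an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e)
    stop("failed to parse Newick file ", path, ": ", conditionMessage(e)))
  if (is.null(tr)) stop("failed to parse Newick file ", path)
  tr
}

#' @param tree an [ape::phylo] object.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read / write labelled square distance matrices
#'
#' TSV layout with a header row of cell ids and a leading label column.
#' Symmetry is enforced on read to 1e-9; the diagonal must be zero.
#'
#' @param path file path.
#' @return `read_dist_matrix` returns a symmetric numeric matrix with
#'   dimnames.
#' @export
read_dist_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("distance matrix is not square")
  if (max(abs(m - t(m))) > 1e-9)
    stop("distance matrix is asymmetric beyond 1e-9 tolerance")
  if (any(abs(diag(m)) > 1e-9)) stop("distance matrix has nonzero diagonal")
  if (any(m < 0)) stop("negative distances")
  dimnames(m) <- list(rownames(df), colnames(df))
  m
}

#' @param m symmetric numeric matrix with dimnames.
#' @rdname read_dist_matrix
#' @export
write_dist_matrix <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-9) stop("refusing to write asymmetric matrix")
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
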