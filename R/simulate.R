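#' Simulation window template
#'
#' Generates an equal-width window grid tiling a simulated reference
#' genome, partitioned into synthetic chromosome blocks. Defaults mimic the
#' 250 kb tiling of a human-scale genome: 12,397 windows over 22
#' chromosomes.
#'
#' @param n_windows number of windows (default 12397).
#' @param n_chrom number of chromosome blocks (default 22).
#' @param bp_per_window nominal window width in bp for the coordinate
#'   columns (default 250000).
#' @return A [genomic_windows] grid.
#' @export
sim_windows <- function(n_windows = 12397L, n_chrom = 22L,
                        bp_per_window = 250000L) {
  n_windows <- as.integer(n_windows)
  n_chrom <- as.integer(min(n_chrom, n_windows))
  base <- n_windows %/% n_chrom
  sizes <- rep(base, n_chrom)
  extra <- n_windows %% n_chrom
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  chrom <- rep(paste0("chr", seq_len(n_chrom)), sizes)
  idx <- unlist(lapply(sizes, seq_len)) - 1L
  genomic_windows(chrom, idx * bp_per_window, (idx + 1L) * bp_per_window)
}

#' Simulation parameters for the line-segment tumor model
#'
#' @param genome_length simulated reference length, arbitrary units
#'   (default 100).
#' @param amp_rate,del_rate amplification/deletion rates, events per unit
#'   evolutionary time per unit genome (default 0.1 each).
#' @param amp_mean_len,del_mean_len expected event length as a fraction of
#'   the genome (default 0.02).
#' @param n_windows windows in the depth grid (default 12397).
#' @param n_chrom synthetic chromosome blocks (default 22).
#' @param total_reads expected total reads per cell (default 4e6).
#' @param nb_size negative-binomial size parameter r of the read simulator
#'   (default 50).
#' @param n_diploid number of matched diploid cells (default 100).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(genome_length = 100, amp_rate = 0.1, del_rate = 0.1,
                       amp_mean_len = 0.02, del_mean_len = 0.02,
                       n_windows = 12397L, n_chrom = 22L,
                       total_reads = 4e6, nb_size = 50, n_diploid = 100L) {
  stopifnot(genome_length > 0, amp_rate >= 0, del_rate >= 0,
            amp_mean_len > 0, amp_mean_len < 1,
            del_mean_len > 0, del_mean_len < 1,
            total_reads > 0, nb_size > 0)
  structure(list(genome_length = genome_length, amp_rate = amp_rate,
                 del_rate = del_rate, amp_mean_len = amp_mean_len,
                 del_mean_len = del_mean_len,
                 n_windows = as.integer(n_windows),
                 n_chrom = as.integer(n_chrom),
                 total_reads = total_reads, nb_size = nb_size,
                 n_diploid = as.integer(n_diploid)),
            class = "sim_params")
}

# pectinate newick with per-leaf terminal branch lengths; leaf j=1,2 are the
# cherry (deepest), j increasing toward the root; internal branches ibl
pectinate_newick <- function(n, ibl, term) {
  s <- sprintf("(t1:%.10g,t2:%.10g)", term[1L], term[2L])
  if (n > 2L) for (j in 3:n)
    s <- sprintf("(%s:%.10g,t%d:%.10g)", s, ibl, j, term[j])
  paste0(s, ";")
}

balanced_newick <- function(n, bl) {
  build <- function(lo, hi) {
    if (lo == hi) return(sprintf("t%d:%.10g", lo, bl))
    mid <- (lo + hi) %/% 2L
    sprintf("(%s,%s):%.10g", build(lo, mid), build(mid + 1L, hi), bl)
  }
  mid <- n %/% 2L
  paste0("(", build(1L, mid), ",", build(mid + 1L, n), ");")
}

#' Build a simulation tree (structures A-D)
#'
#' Four tree shapes spanning extremes of balance and clock-likeness:
#' * `"A"` pectinate (maximally imbalanced) and ultrametric: internal
#'   branches `1/n`, terminal branches stretched so all leaf depths are
#'   equal (branching evolution);
#' * `"B"` perfectly balanced and ultrametric, all branches `1/n`
#'   (`n` must be a power of 2; neutral evolution);
#' * `"C"` pectinate with all internal and terminal branches `1/n`
#'   (linear evolution, non-ultrametric);
#' * `"D"` pectinate, internal branches `1/n`, terminal branch of the j-th
#'   leaf (cherry first) proportional to `1/log(j+1)` (linear evolution
#'   with logarithmically decaying terminals).
#'
#' The tree is rescaled so the root-to-farthest-leaf height equals
#' `height_scale`, and a root branch of length `root_branch` is prepended
#' (CNAs on it are shared by every cell).
#'
#' @param structure one of "A", "B", "C", "D".
#' @param n_leaves number of leaves (default 128; power of 2 for "B").
#' @param root_branch length of the branch leading to the root (default 1).
#' @param height_scale target tree height (default 1).
#' @return An [ape::phylo] with `root.edge` set.
#' @export
build_sim_tree <- function(structure = c("A", "B", "C", "D"),
                           n_leaves = 128L, root_branch = 1,
                           height_scale = 1) {
  structure <- match.arg(structure)
  n <- as.integer(n_leaves)
  if (n < 2L) stop("need >= 2 leaves")
  ibl <- 1 / n
  if (structure == "B") {
    if (bitwAnd(n, n - 1L) != 0L)
      stop("balanced tree needs n_leaves to be a power of 2")
    tr <- ape::read.tree(text = balanced_newick(n, ibl))
  } else {
    # internal-edge depth of leaf j: cherry leaves sit below n-2 internal
    # edges, leaf n below none
    int_depth <- c(rep((n - 2L) * ibl, 2L),
                   if (n > 2L) ((n - 3L):0L) * ibl)
    term <- switch(structure,
      A = max(int_depth) + ibl - int_depth,
      C = rep(ibl, n),
      D = ibl * log(2) / log(seq_len(n) + 1))
    tr <- ape::read.tree(text = pectinate_newick(n, ibl, term))
  }
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * height_scale / h
  tr$root.edge <- root_branch
  tr
}

new_segment_genome <- function(L) {
  structure(list(segments = matrix(c(0, L, 0, L), 2L, 2L, byrow = TRUE,
                                   dimnames = list(NULL, c("start", "end"))),
                 genome_length = L),
            class = "segment_genome")
}

#' @export
print.segment_genome <- function(x, ...) {
  cat("<segment_genome>", nrow(x$segments), "segments on [0,",
      x$genome_length, ")\n")
  invisible(x)
}

apply_event <- function(g, type, ev_start, ev_end) {
  segs <- g$segments
  ov <- which(segs[, 1L] < ev_end & segs[, 2L] > ev_start)
  if (length(ov) == 0L) return(g)  # ploidy-0 region: nothing to copy/delete
  pick <- ov[sample.int(length(ov), 1L)]
  a <- max(segs[pick, 1L], ev_start)
  b <- min(segs[pick, 2L], ev_end)
  if (type == "amp") {
    segs <- rbind(segs, c(a, b))
  } else {
    left <- if (segs[pick, 1L] < a) c(segs[pick, 1L], a) else NULL
    right <- if (segs[pick, 2L] > b) c(b, segs[pick, 2L]) else NULL
    segs <- rbind(segs[-pick, , drop = FALSE], left, right)
  }
  g$segments <- segs
  g
}

branch_events <- function(g, branch_length, p) {
  L <- p$genome_length
  total_rate <- (p$amp_rate + p$del_rate) * L
  n_ev <- stats::rpois(1L, total_rate * branch_length)
  log <- if (n_ev > 0L)
    data.frame(type = character(n_ev), start = numeric(n_ev),
               end = numeric(n_ev))
  else data.frame(type = character(0), start = numeric(0), end = numeric(0))
  for (e in seq_len(n_ev)) {
    amp <- stats::runif(1L) < p$amp_rate / (p$amp_rate + p$del_rate)
    type <- if (amp) "amp" else "del"
    mean_len <- (if (amp) p$amp_mean_len else p$del_mean_len) * L
    s <- stats::runif(1L, 0, L)
    len <- stats::rexp(1L, 1 / mean_len)
    e_end <- min(s + len, L)  # truncated at the reference end
    g <- apply_event(g, type, s, e_end)
    log$type[e] <- type; log$start[e] <- s; log$end[e] <- e_end
  }
  list(genome = g, log = log)
}

#' Simulate copy-number alterations down a tree
#'
#' The line-segment model: a genome is a multiset of segments over the
#' fixed reference `[0, genome_length)`; ploidy at a point is the number of
#' segments covering it. Along each branch, the number of events is
#' Poisson with rate `(amp_rate + del_rate) * genome_length * branch
#' length`; each event picks its type by the rate ratio, a uniform start,
#' and an exponential length truncated at the reference end, then
#' duplicates (amplification) or removes (deletion) the overlapped portion
#' of one uniformly chosen covering segment. Ancestral events are inherited
#' by all descendants; events on the root branch are shared by every cell.
#'
#' @param tree [ape::phylo] with branch lengths and optionally `root.edge`.
#' @param p a [sim_params].
#' @return List with `genomes` (named by leaf label, plus `".root"`),
#'   and `event_log` (named per-branch event tables).
#' @export
simulate_cnas <- function(tree, p) {
  stopifnot(inherits(tree, "phylo"), inherits(p, "sim_params"))
  L <- p$genome_length
  root <- length(tree$tip.label) + 1L
  root_g <- new_segment_genome(L)
  event_log <- list()
  if (!is.null(tree$root.edge) && tree$root.edge > 0) {
    be <- branch_events(root_g, tree$root.edge, p)
    root_g <- be$genome
    event_log[[".root"]] <- be$log
  }
  n_nodes <- max(tree$edge)
  genomes <- vector("list", n_nodes)
  genomes[[root]] <- root_g
  # preorder: parents appear before children in ape's cladewise edge order
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (r in seq_len(nrow(ord$edge))) {
    par <- ord$edge[r, 1L]; child <- ord$edge[r, 2L]
    be <- branch_events(genomes[[par]], ord$edge.length[r], p)
    genomes[[child]] <- be$genome
    nm <- if (child <= length(tree$tip.label)) tree$tip.label[child]
          else paste0("node", child)
    event_log[[nm]] <- be$log
  }
  leaf_genomes <- genomes[seq_along(tree$tip.label)]
  names(leaf_genomes) <- tree$tip.label
  leaf_genomes[[".root"]] <- root_g
  list(genomes = leaf_genomes, event_log = event_log)
}

#' True fractional copy number per window
#'
#' Windows tile the simulated reference proportionally, in grid order; the
#' true copy number of a window is the average ploidy over it, which is
#' fractional when an event boundary falls inside the window.
#'
#' @param g a `segment_genome`.
#' @param windows a [genomic_windows] grid.
#' @return A fractional [cn_profile].
#' @export
true_window_cnp <- function(g, windows) {
  stopifnot(inherits(g, "segment_genome"))
  n <- nrow(windows)
  w0 <- g$genome_length / n
  cov <- numeric(n)
  segs <- g$segments
  for (r in seq_len(nrow(segs))) {
    a <- segs[r, 1L]; b <- segs[r, 2L]
    if (b <= a) next
    ia <- floor(a / w0) + 1L
    ib <- min(ceiling(b / w0), n)
    i <- ia:ib
    cov[i] <- cov[i] + pmin(i * w0, b) - pmax((i - 1L) * w0, a)
  }
  cn_profile(windows, cov / w0, integer_valued = FALSE)
}

#' Simulate binned read depth from a true copy-number profile
#'
#' Expected reads in window i are proportional to its copy-number mass:
#' `lambda_i = total_reads * cn_i * |w_i| / sum_j cn_j * |w_j|`; observed
#' counts are independent negative binomials with size `nb_size`.
#'
#' @param true_cnp a [cn_profile] (fractional allowed).
#' @param p a [sim_params].
#' @param cell_id id for the simulated cell.
#' @return A [binned_depth].
#' @export
simulate_reads <- function(true_cnp, p, cell_id = "sim") {
  stopifnot(inherits(true_cnp, "cn_profile"), inherits(p, "sim_params"))
  cn <- true_cnp$cn
  if (all(cn == 0)) stop("all-zero genome: no reads to simulate")
  wlen <- true_cnp$windows$end - true_cnp$windows$start
  lambda <- p$total_reads * (cn * wlen) / sum(cn * wlen)
  counts <- stats::rnbinom(length(lambda), size = p$nb_size, mu = lambda)
  binned_depth(true_cnp$windows, counts, cell_id)
}

#' Simulate a complete dataset: tumor cells, diploid cells, truth
#'
#' Runs the line-segment simulator down `tree`, converts each leaf genome
#' to a true fractional profile, and draws read depth for every tumor cell
#' and for `p$n_diploid` diploid cells (true copy number exactly 2
#' everywhere).
#'
#' @param tree [ape::phylo] from [build_sim_tree].
#' @param p a [sim_params].
#' @param leaves leaf labels to emit as tumor cells (default all).
#' @return List with `tumor` (named [binned_depth] list), `diploid`
#'   ([binned_depth] list), `truth` (named fractional [cn_profile] list),
#'   `windows`, `tree`, `event_log`.
#' @export
simulate_dataset <- function(tree, p, leaves = NULL) {
  windows <- sim_windows(p$n_windows, p$n_chrom)
  sim <- simulate_cnas(tree, p)
  if (is.null(leaves)) leaves <- tree$tip.label
  truth <- list(); tumor <- list()
  for (lf in leaves) {
    truth[[lf]] <- true_window_cnp(sim$genomes[[lf]], windows)
    tumor[[lf]] <- simulate_reads(truth[[lf]], p, cell_id = lf)
  }
  dip_truth <- cn_profile(windows, rep(2, nrow(windows)),
                          integer_valued = TRUE)
  diploid <- lapply(seq_len(p$n_diploid), function(i)
    simulate_reads(dip_truth, p, cell_id = paste0("diploid", i)))
  list(tumor = tumor, diploid = diploid, truth = truth, windows = windows,
       tree = tree, event_log = sim$event_log)
}

# mean/variance-parameterised NB sampler used by the HMM self-simulator
rnb_mv <- function(n, lambda, sigma2) {
  sigma2 <- pmax(sigma2, lambda * (1 + 1e-6))
  stats::rnbinom(n, size = lambda^2 / (sigma2 - lambda), mu = lambda)
}

#' Simulate observations directly from a fitted HMM
#'
#' Samples a hidden state path from the genome-wide chain (reset to the
#' stationary distribution at each chromosome start) and negative-binomial
#' read counts from the emission model. For a pair model, returns two
#' cells. Used for self-consistency checks of the estimation machinery.
#'
#' @param model a [cn_hmm].
#' @param cell_ids ids for the simulated cell(s).
#' @return List with `obs` (list of [binned_depth]) and `path`
#'   (integer state indices), plus `cn` (per-cell integer profiles).
#' @export
simulate_from_hmm <- function(model, cell_ids = c("simA", "simB")) {
  stopifnot(inherits(model, "cn_hmm"))
  N <- nrow(model$windows)
  S <- nrow(model$transition)
  starts <- chromosome_starts(model$windows)
  path <- integer(N)
  for (i in seq_len(N)) {
    prob <- if (i %in% starts) model$initial
            else model$transition[path[i - 1L], ]
    path[i] <- sample.int(S, 1L, prob = prob)
  }
  k <- model$k
  cn_list <- if (model$n_cells == 1L) list(path - 1L)
             else list((path - 1L) %/% (k + 1L), (path - 1L) %% (k + 1L))
  obs <- vector("list", model$n_cells)
  for (ci in seq_len(model$n_cells)) {
    ctx <- model$contexts[[ci]]
    d <- ctx$dispersion
    lambda <- (cn_list[[ci]] * ctx$mu / 2) * ctx$s + d$epsilon
    sigma2 <- d$a * lambda^2 + d$b * lambda + d$c
    obs[[ci]] <- binned_depth(model$windows, rnb_mv(N, lambda, sigma2),
                              cell_ids[ci])
  }
  list(obs = obs, path = path,
       cn = lapply(cn_list, function(v)
         cn_profile(model$windows, v, integer_valued = TRUE)))
}
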