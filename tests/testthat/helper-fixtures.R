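# shared in-code fixtures; everything is generated, nothing read from disk

toy_windows <- function(n = 4L, chrom = rep("chr1", n)) {
  genomic_windows(chrom, (seq_len(n) - 1L) * 100L, seq_len(n) * 100L)
}

toy_dispersion <- function() dispersion_model(0.02, 1, 0, epsilon = 0.01)

toy_context <- function(n, s = 1, mu = 300) {
  emission_context(s, rep(mu, n), toy_dispersion())
}

# a small two-cell HMM at max copy number k with given branch lengths
toy_pair_model <- function(k = 2L, t1 = 0.8, t2 = 0.4, t3 = 0.6,
                           rates = cna_rates(0.5, 1, 0.3),
                           windows = toy_windows()) {
  Q <- build_rate_matrix(rates, k)
  F <- pair_joint_adjacent(transition_matrix(Q, t1),
                           transition_matrix(Q, t2),
                           transition_matrix(Q, t3), k)
  M <- genome_transition(F)
  pi <- steady_state(M)
  n <- nrow(windows)
  cn_hmm(M, pi, list(toy_context(n), toy_context(n)), windows, k)
}

# brute-force forward log-likelihood / best path by path enumeration
enumerate_hmm <- function(logE, M, pi, chrom_starts) {
  S <- nrow(logE); N <- ncol(logE)
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(S)), N)))
  lp <- numeric(nrow(paths))
  logM <- log(M); logPi <- log(pi)
  for (i in seq_len(N)) {
    reset <- i %in% chrom_starts
    lp <- lp + logE[cbind(paths[, i], i)] +
      if (reset) logPi[paths[, i]]
      else logM[cbind(paths[, i - 1L], paths[, i])]
  }
  list(loglik = max(lp) + log(sum(exp(lp - max(lp)))),
       best = unname(paths[which.max(lp), ]))
}

# brute-force non-trivial bipartitions of an unrooted binary tree
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  n <- length(tips)
  out <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    if (child <= n) next  # trivial split
    below <- ape::extract.clade(tree, child)$tip.label
    side <- sort(below)
    if (length(side) <= 1L || length(side) >= n - 1L) next
    other <- setdiff(tips, side)
    key <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      paste(side, collapse = ",") else paste(other, collapse = ",")
    out <- c(out, key)
  }
  unique(out)
}

rf_bruteforce <- function(T1, T2) {
  b1 <- tree_bipartitions(T1)
  b2 <- tree_bipartitions(T2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# mean/variance-parameterised NB draws (test-side twin of the emission law)
rnb_mv_test <- function(n, lambda, sigma2) {
  sigma2 <- pmax(sigma2, lambda * (1 + 1e-6))
  stats::rnbinom(n, size = lambda^2 / (sigma2 - lambda), mu = lambda)
}

# random binary tree with branch lengths, for additivity checks
random_binary_tree <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.5, 2)
  tr
}
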