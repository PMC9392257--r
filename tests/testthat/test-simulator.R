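test_that("window template tiles the requested counts", {
  w <- sim_windows(12397L, 22L)
  expect_equal(nrow(w), 12397L)
  expect_equal(length(unique(w$chrom)), 22L)
  expect_equal(unname(w$end - w$start), rep(250000L, 12397L))
  expect_length(chromosome_starts(w), 22L)
})

test_that("simulation trees have the stated shapes", {
  trA <- build_sim_tree("A", 8L)
  # pectinate: exactly one cherry; ultrametric after scaling
  depths <- ape::node.depth.edgelength(trA)[seq_len(8L)]
  expect_equal(max(abs(depths - 1)), 0, tolerance = 1e-9)
  cherries <- sum(tabulate(trA$edge[trA$edge[, 2L] <= 8L, 1L]) == 2L)
  expect_equal(cherries, 1L)
  expect_equal(trA$root.edge, 1)

  trB <- build_sim_tree("B", 8L)
  depthsB <- ape::node.depth.edgelength(trB)[seq_len(8L)]
  expect_equal(max(abs(depthsB - 1)), 0, tolerance = 1e-9)
  # perfectly balanced: every internal node has two leaf-balanced sides
  expect_equal(ape::balance(ape::multi2di(trB))[1L, ], c(4, 4),
               ignore_attr = TRUE)
  expect_error(build_sim_tree("B", 6L), "power of 2")

  trC <- build_sim_tree("C", 8L)
  expect_gt(stats::sd(ape::node.depth.edgelength(trC)[1:8]), 0)

  trD <- build_sim_tree("D", 8L)
  term <- trD$edge.length[trD$edge[, 2L] <= 8L]
  ord <- trD$edge[trD$edge[, 2L] <= 8L, 2L]
  term <- term[order(ord)]  # leaf t1..t8 in ladder order
  expect_true(all(diff(term) < 0))
})

test_that("line-segment events edit ploidy as described", {
  p <- sim_params(n_windows = 100L, n_chrom = 2L)
  g <- paircn:::new_segment_genome(100)
  # deletion of [20,40) on one of the two segments
  g1 <- paircn:::apply_event(g, "del", 20, 40)
  w <- sim_windows(100L, 2L)
  cn <- true_window_cnp(g1, w)$cn
  expect_equal(cn[25], 1)
  expect_equal(cn[10], 2)
  expect_equal(cn[90], 2)
  # amplification adds a copy of the overlapped portion
  g2 <- paircn:::apply_event(g, "amp", 50, 60)
  cn2 <- true_window_cnp(g2, w)$cn
  expect_equal(cn2[55], 3)
  expect_equal(cn2[10], 2)
  # half-window deletion gives fractional CN 1.5
  g3 <- paircn:::apply_event(g, "del", 0, 0.5)
  expect_equal(true_window_cnp(g3, w)$cn[1L], 1.5)
  # conservation: sum cn * width equals total segment length
  segs <- g2$segments
  expect_equal(sum(cn2) * 1, sum(segs[, 2L] - segs[, 1L]))
})

test_that("zero event rates leave every node diploid", {
  p <- sim_params(amp_rate = 0, del_rate = 0, n_windows = 50L,
                  n_chrom = 2L, n_diploid = 2L)
  tr <- build_sim_tree("A", 4L)
  sim <- simulate_cnas(tr, p)
  for (g in sim$genomes)
    expect_equal(true_window_cnp(g, sim_windows(50L, 2L))$cn, rep(2, 50L))
})

test_that("events are heritable down the tree", {
  set.seed(91)
  p <- sim_params(n_windows = 200L, n_chrom = 4L)
  tr <- build_sim_tree("A", 8L)
  sim <- simulate_cnas(tr, p)
  # replay audit: events on the cherry pair's shared path are identical,
  # so the two cherry profiles differ only via branch-private events
  w <- sim_windows(200L, 4L)
  cn1 <- true_window_cnp(sim$genomes[["t1"]], w)$cn
  cn2 <- true_window_cnp(sim$genomes[["t2"]], w)$cn
  priv <- rbind(sim$event_log[["t1"]], sim$event_log[["t2"]])
  changed <- which(cn1 != cn2)
  if (length(changed)) {
    # every differing window overlaps some private event interval
    w0 <- p$genome_length / 200L
    covered <- vapply(changed, function(i) {
      any(priv$start < i * w0 & priv$end > (i - 1L) * w0)
    }, TRUE)
    expect_true(all(covered))
  } else succeed()
})

test_that("read simulation has the stated expectations", {
  set.seed(92)
  p <- sim_params(n_windows = 12397L, n_chrom = 22L)
  w <- sim_windows(p$n_windows, p$n_chrom)
  dip <- cn_profile(w, rep(2, nrow(w)), integer_valued = TRUE)
  bd <- simulate_reads(dip, p, "d")
  lambda <- p$total_reads / p$n_windows
  expect_equal(lambda, 322.7, tolerance = 1e-3)
  sd_total <- sqrt(nrow(w) * (lambda + lambda^2 / p$nb_size))
  expect_lt(abs(sum(bd$counts) - p$total_reads), 4 * sd_total)
  # a CN-4 window doubles the expectation of a CN-2 window
  cn <- rep(2, nrow(w)); cn[100] <- 4
  pr <- cn_profile(w, cn, integer_valued = TRUE)
  reps <- sapply(1:200, function(i) simulate_reads(pr, p, "x")$counts[100])
  lam4 <- p$total_reads * 4 / (sum(cn))
  expect_lt(abs(mean(reps) - lam4) / lam4, 0.05)
  expect_error(simulate_reads(cn_profile(w, rep(0, nrow(w))), p),
               "all-zero")
})

test_that("accuracy metrics follow their definitions", {
  w <- sim_windows(100L, 1L)
  a <- cn_profile(w, rep(2, 100L), integer_valued = TRUE)
  expect_equal(sse(a, a), 0)
  b <- a; b$cn[c(3, 50, 97)] <- 3
  expect_equal(sse(b, a), 3)
  d <- a; d$cn[1:4] <- 2.5
  expect_equal(sse(d, a), 1.0)

  # breakpoints: truth at {10, 50}, inferred at {12}
  tru <- a; tru$cn[11:50] <- 3
  inf <- a; inf$cn[13:100] <- 3
  bs <- breakpoint_stats(inf, tru)
  expect_equal(bs$total_distance, abs(10 - 12) + abs(50 - 12))
  expect_equal(bs$omega, 0.5)
  ident <- breakpoint_stats(tru, tru)
  expect_equal(ident$total_distance, 0)
  expect_equal(ident$omega, 1)
  # no inferred breakpoints: chromosome-length cap per true breakpoint
  none <- breakpoint_stats(a, tru)
  expect_equal(none$omega, 0)
  expect_equal(none$total_distance, 200)
  # no true breakpoints: omega undefined
  expect_true(is.na(breakpoint_stats(tru, a)$omega))
})
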