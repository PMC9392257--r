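test_that("rate matrix entries follow the event-rate rules", {
  Q <- build_rate_matrix(cna_rates(1, 2, 0.5), 1L)
  i <- function(U, V) U * 2L + V + 1L
  expect_equal(Q[i(0, 0), i(1, 1)], 0.5 * (1 + 2))  # joint +1
  expect_equal(Q[i(0, 0), i(1, 0)], 1 + 2)          # single-bin +1
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-9)

  Q2 <- build_rate_matrix(cna_rates(0.3, 0.7, 2), 3L)
  j <- function(U, V) U * 4L + V + 1L
  expect_equal(Q2[j(0, 0), j(1, 2)], 0)        # bins changed differently
  expect_equal(Q2[j(0, 0), j(2, 2)], 2 * 0.7)  # joint +2: gamma*beta
  expect_equal(Q2[j(1, 1), j(3, 1)], 0.7)      # single +2: beta
  expect_equal(max(abs(rowSums(Q2))), 0, tolerance = 1e-12)
  expect_error(build_rate_matrix(cna_rates(1, 1, 1), 0L), "k")
})

test_that("transition matrix is a proper CTMC solution", {
  Q <- build_rate_matrix(cna_rates(0.5, 1, 0.3), 2L)
  expect_equal(transition_matrix(Q, 0), diag(9L), ignore_attr = TRUE)
  # Chapman-Kolmogorov
  expect_equal(transition_matrix(Q, 0.3) %*% transition_matrix(Q, 0.7),
               transition_matrix(Q, 1.0), tolerance = 1e-8,
               ignore_attr = TRUE)
  # Taylor series at small t
  Q1 <- build_rate_matrix(cna_rates(1, 2, 0.5), 1L)
  t <- 1e-4
  taylor <- diag(4L) + Q1 * t + Q1 %*% Q1 * t^2 / 2
  expect_lt(max(abs(transition_matrix(Q1, t) - taylor)), 1e-9)
  expect_equal(max(abs(rowSums(transition_matrix(Q, 2.5)) - 1)), 0,
               tolerance = 1e-9)
  expect_error(transition_matrix(Q, -1), "t must be")
})

test_that("pair joint matrix marginalises to 1 and matches a triple loop", {
  k <- 2L
  Q <- build_rate_matrix(cna_rates(0.4, 0.8, 0.6), k)
  P1 <- transition_matrix(Q, 0.7)
  P2 <- transition_matrix(Q, 0.3)
  P3 <- transition_matrix(Q, 0.9)
  F <- pair_joint_adjacent(P1, P2, P3, k)
  expect_equal(sum(F), 1, tolerance = 1e-9)

  # brute-force oracle: explicit loop over (W,Y) and all index pairs
  S <- (k + 1L)^2
  idx <- function(U, V) U * (k + 1L) + V + 1L
  Fb <- matrix(0, S, S)
  for (W in 0:k) for (Y in 0:k)
    for (ciA in 0:k) for (ciB in 0:k) for (cjA in 0:k) for (cjB in 0:k)
      Fb[idx(ciA, ciB), idx(cjA, cjB)] <-
        Fb[idx(ciA, ciB), idx(cjA, cjB)] +
        P1[idx(2, 2), idx(W, Y)] * P2[idx(W, Y), idx(ciA, cjA)] *
        P3[idx(W, Y), idx(ciB, cjB)]
  expect_equal(F, Fb, tolerance = 1e-12, ignore_attr = TRUE)

  # swap symmetry: exchanging the two cells swaps t2/t3
  Fswap <- pair_joint_adjacent(P1, P3, P2, k)
  st <- expand.grid(V = 0:k, U = 0:k)  # V fastest matches state indexing
  perm <- st$V * (k + 1L) + st$U + 1L  # (U,V) -> index of (V,U)
  expect_equal(F, Fswap[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)

  # t2 = t3 = 0 forces both cells into the same state
  P0 <- transition_matrix(Q, 0)
  F0 <- pair_joint_adjacent(P1, P0, P0, k)
  diag_states <- vapply(0:k, function(c) idx(c, c), 0L)
  expect_equal(sum(F0[-diag_states, ]), 0)
  expect_equal(sum(F0[, -diag_states]), 0)
  expect_error(pair_joint_adjacent(P1, P2, P3, 1L), "k must be >= 2")
})

test_that("genome transition is the row-normalised joint matrix", {
  toy <- matrix(c(0.1, 0.3, 0.2, 0.4), 2L, byrow = TRUE)
  expect_equal(genome_transition(toy),
               matrix(c(0.25, 0.75, 1 / 3, 2 / 3), 2L, byrow = TRUE))
  k <- 2L
  Q <- build_rate_matrix(cna_rates(0.4, 0.8, 0.6), k)
  F <- pair_joint_adjacent(transition_matrix(Q, 0.7),
                           transition_matrix(Q, 0.3),
                           transition_matrix(Q, 0.9), k)
  M <- genome_transition(F)
  expect_equal(rowSums(M), rep(1, 9L), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(genome_transition(rbind(c(0, 0), c(1, 1))), "zero row")
})

test_that("single-cell chain is consistent with the two-cell chain", {
  k <- 2L
  Q <- build_rate_matrix(cna_rates(0.5, 1, 0.3), k)
  Msc <- single_cell_genome_transition(transition_matrix(Q, 0.6), k)
  expect_equal(rowSums(Msc), rep(1, k + 1L), ignore_attr = TRUE)
  # near t=0 the diploid row concentrates on staying diploid
  M0 <- single_cell_genome_transition(transition_matrix(Q, 1e-6), k)
  expect_gt(M0["2", "2"], 0.999)
  # two-cell chain at t1=t, t2=t3=0, restricted to diagonal states and
  # renormalised, reduces to the single-cell chain
  P0 <- transition_matrix(Q, 0)
  F <- pair_joint_adjacent(transition_matrix(Q, 0.6), P0, P0, k)
  idx <- function(U, V) U * (k + 1L) + V + 1L
  dg <- vapply(0:k, function(c) idx(c, c), 0L)
  sub <- F[dg, dg]
  sub <- sub / rowSums(sub)
  expect_equal(sub, Msc, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("steady state is the chain's fixed point", {
  M <- matrix(c(0.9, 0.1, 0.1, 0.9), 2L)
  expect_equal(steady_state(M), c(0.5, 0.5), ignore_attr = TRUE)
  set.seed(42)
  for (rep in 1:5) {
    S <- sample(3:8, 1L)
    M <- matrix(stats::rexp(S * S), S)
    M <- M / rowSums(M)
    pi <- steady_state(M)
    expect_lt(max(abs(as.vector(pi %*% M) - pi)), 1e-10)
    # power-iteration oracle
    Mp <- M
    for (i in 1:12) Mp <- Mp %*% Mp  # M^(2^12)
    expect_equal(pi, Mp[1L, ], tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("pair-cell self-transition mass shrinks with divergence time", {
  k <- 2L
  rates <- cna_rates(0.5, 1, 0.3)
  Q <- build_rate_matrix(rates, k)
  P1 <- transition_matrix(Q, 0.5)
  idx <- function(U, V) U * (k + 1L) + V + 1L
  dg <- vapply(0:k, function(c) idx(c, c), 0L)
  same_mass <- vapply(c(0.01, 0.05, 0.2, 0.5), function(t23) {
    P23 <- transition_matrix(Q, t23)
    M <- genome_transition(pair_joint_adjacent(P1, P23, P23, k))
    sum(diag(M)[dg])
  }, 0)
  expect_true(all(diff(same_mass) < 0))
})
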