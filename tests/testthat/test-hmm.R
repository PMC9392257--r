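test_that("forward and Viterbi match exhaustive enumeration", {
  set.seed(20)
  # random generic instances: up to 4 states, up to 5 windows, with and
  # without an internal chromosome break
  for (rep in 1:12) {
    S <- sample(2:4, 1L)
    N <- sample(2:5, 1L)
    M <- matrix(stats::rexp(S * S) + 0.05, S)
    M <- M / rowSums(M)
    pi <- stats::rexp(S) + 0.05
    pi <- pi / sum(pi)
    logE <- matrix(stats::rnorm(S * N, sd = 2), S, N)
    breaks <- if (rep %% 2L == 0L && N >= 3L) c(1L, 3L) else 1L
    oracle <- enumerate_hmm(logE, M, pi, breaks)
    expect_equal(paircn:::hmm_forward_cpp(logE, M, pi, breaks), oracle$loglik,
                 tolerance = 1e-8)
    vit <- paircn:::hmm_viterbi_cpp(logE, M, pi, breaks)
    # compare achieved log-probability (ties may differ in path)
    lp_path <- function(p) {
      lp <- 0
      for (i in seq_len(N)) {
        lp <- lp + logE[p[i], i] +
          if (i %in% breaks) log(pi)[p[i]] else log(M)[p[i - 1L], p[i]]
      }
      lp
    }
    expect_equal(lp_path(vit), lp_path(oracle$best), tolerance = 1e-9)
  }
})

test_that("pair model forward/Viterbi agree with enumeration end to end", {
  model <- toy_pair_model(k = 2L, windows = toy_windows(4L))
  obs <- list(binned_depth(model$windows, c(300L, 150L, 450L, 300L), "A"),
              binned_depth(model$windows, c(300L, 300L, 480L, 270L), "B"))
  logE <- paircn:::pair_emission_logmat(obs[[1L]]$counts, obs[[2L]]$counts,
                                        model$contexts[[1L]],
                                        model$contexts[[2L]], model$k)
  oracle <- enumerate_hmm(logE, model$transition, model$initial, 1L)
  expect_equal(forward_loglik(model, obs), oracle$loglik, tolerance = 1e-8)
  dec <- viterbi(model, obs)
  k <- model$k
  expect_equal(dec$A$cn, (oracle$best - 1L) %/% (k + 1L))
  expect_equal(dec$B$cn, (oracle$best - 1L) %% (k + 1L))
})

test_that("forward likelihood over two chromosomes splits additively", {
  k <- 2L
  w2 <- genomic_windows(c("chr1", "chr1", "chr2", "chr2"),
                        c(0L, 100L, 0L, 100L), c(100L, 200L, 100L, 200L))
  model <- toy_pair_model(k = k, windows = w2)
  obs <- list(binned_depth(w2, c(300L, 150L, 450L, 300L), "A"),
              binned_depth(w2, c(300L, 300L, 480L, 270L), "B"))
  ll <- forward_loglik(model, obs)
  w1 <- genomic_windows(rep("chr1", 2L), c(0L, 100L), c(100L, 200L))
  m1 <- toy_pair_model(k = k, windows = w1)
  llA <- forward_loglik(m1, list(binned_depth(w1, c(300L, 150L), "A"),
                                 binned_depth(w1, c(300L, 300L), "B")))
  llB <- forward_loglik(m1, list(binned_depth(w1, c(450L, 300L), "A"),
                                 binned_depth(w1, c(480L, 270L), "B")))
  expect_equal(ll, llA + llB, tolerance = 1e-10)
})

test_that("single-window forward equals the direct mixture likelihood", {
  w <- toy_windows(1L)
  model <- toy_pair_model(k = 2L, windows = w)
  obs <- list(binned_depth(w, 310L, "A"), binned_depth(w, 290L, "B"))
  logE <- paircn:::pair_emission_logmat(310, 290, model$contexts[[1L]],
                                        model$contexts[[2L]], 2L)
  expect_equal(forward_loglik(model, obs),
               log(sum(model$initial * exp(logE[, 1L]))))
})

test_that("Viterbi on strong constant-diploid signal decodes (2,2)", {
  set.seed(5)
  N <- 200L
  w <- toy_windows(N)
  model <- toy_pair_model(k = 2L, t1 = 0.05, t2 = 0.02, t3 = 0.02,
                          windows = w)
  ctx <- model$contexts[[1L]]
  d <- ctx$dispersion
  lambda <- 300
  sigma2 <- d$a * lambda^2 + d$b * lambda + d$c
  mk <- function(id) binned_depth(w, stats::rnbinom(
    N, size = lambda^2 / (sigma2 - lambda), mu = lambda), id)
  dec <- viterbi(model, list(mk("A"), mk("B")))
  expect_gte(mean(dec$A$cn == 2 & dec$B$cn == 2), 0.99)
})

test_that("Baum-Welch increases likelihood and recovers a planted chain", {
  set.seed(9)
  N <- 6000L
  k <- 3L
  w <- sim_windows(N, 4L)
  # planted sticky 3-state chain over CN {1,2,3}
  states <- c(2L, 3L, 1L)  # CN+1 indices never used; plant on CN directly
  M_true <- matrix(0.01, 3L, 3L)
  diag(M_true) <- 0.98
  cn_path <- integer(N)
  cn_lvls <- c(1L, 2L, 3L)
  starts <- chromosome_starts(w)
  for (i in seq_len(N)) {
    cn_path[i] <- if (i %in% starts) sample(1:3, 1L)
                  else sample(1:3, 1L, prob = M_true[cn_path[i - 1L], ])
  }
  mu <- rep(300, N)
  disp <- toy_dispersion()
  lambda <- cn_lvls[cn_path] * 300 / 2 + disp$epsilon
  sigma2 <- disp$a * lambda^2 + disp$b * lambda + disp$c
  counts <- stats::rnbinom(N, size = lambda^2 / (sigma2 - lambda),
                           mu = lambda)
  obs <- binned_depth(w, counts, "bw")
  ctx <- emission_context(1, mu, disp)
  bw <- baum_welch_init(obs, ctx, k, max_iter = 40L)
  expect_true(all(diff(bw$loglik_trace) > -1e-8))
  # CN 0 never occurs: compare the planted chain on the CN {1,2,3} block
  est <- bw$transition[2:4, 2:4]
  est <- est / rowSums(est)
  expect_lt(max(abs(est - M_true)), 0.05)
  expect_equal(bw$s, 1, tolerance = 0.05)
})
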