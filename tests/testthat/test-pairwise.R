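test_that("rate combination is the component-wise median", {
  mk <- function(a, b, g) structure(list(rates = cna_rates(a, b, g)),
                                    class = "cn_fit")
  expect_equal(combine_rates(list(mk(1, 1, 1), mk(2, 5, 3),
                                  mk(10, 2, 9)))$alpha, 2)
  even <- combine_rates(list(mk(1, 1, 1), mk(3, 2, 5)))
  expect_equal(even$alpha, 2)
  expect_equal(even$gamma, 3)
  single <- combine_rates(list(mk(4, 2, 7)))
  expect_equal(unlist(single[c("alpha", "beta", "gamma")]),
               c(alpha = 4, beta = 2, gamma = 7))
  expect_error(combine_rates(list()), "no fits")
})

test_that("initial pair tree halves the smaller total branch length", {
  tr <- init_tree(0.8, 0.6)
  expect_equal(c(tr$t1, tr$t2, tr$t3), c(0.3, 0.5, 0.3))
  tr2 <- init_tree(1, 1)
  expect_equal(c(tr2$t1, tr2$t2, tr2$t3), c(0.5, 0.5, 0.5))
  expect_equal(tr$t1 + tr$t2, 0.8)
  expect_equal(tr$t1 + tr$t3, 0.6)
  expect_error(init_tree(0, 1), "> 0")
})

# one shared self-simulated pair dataset for the optimisation tests
pair_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(81)
    k <- 3L
    N <- 3000L
    w <- sim_windows(N, 8L)
    rates <- cna_rates(0.1, 0.05, 1)
    disp <- toy_dispersion()
    mu <- rep(322.7, N)
    ctx <- emission_context(1, mu, disp)
    ch <- paircn:::pair_chain(rates, pair_tree(0.8, 0.4, 0.4), k)
    model <- cn_hmm(ch$M, ch$pi, list(ctx, ctx), w, k)
    sim <- simulate_from_hmm(model, c("A", "B"))
    cache <<- list(k = k, w = w, rates = rates, ctx = ctx, sim = sim,
                   model = model)
    cache
  }
})

test_that("pair fit improves on its starting point and is symmetric", {
  fx <- pair_fixture()
  pf <- fit_cell_pair(fx$sim$obs[[1L]], fx$sim$obs[[2L]], fx$ctx, fx$ctx,
                      fx$rates, fx$k, init = pair_tree(0.2, 0.2, 0.2),
                      maxit = 60L)
  expect_gte(pf$loglik, pf$init_loglik - 1e-6)
  # swapping the cells mirrors t2/t3 and keeps the likelihood
  pf_swap <- fit_cell_pair(fx$sim$obs[[2L]], fx$sim$obs[[1L]], fx$ctx,
                           fx$ctx, fx$rates, fx$k,
                           init = pair_tree(0.2, 0.2, 0.2), maxit = 60L)
  expect_equal(pf_swap$loglik, pf$loglik, tolerance = 1e-4)
  expect_equal(pf_swap$tree$t2 + pf_swap$tree$t3,
               pf$tree$t2 + pf$tree$t3, tolerance = 0.05)
  # likelihood at the simulated truth beats a doubled-divergence tree
  ll <- function(tr) {
    ch <- paircn:::pair_chain(fx$rates, tr, fx$k)
    m <- cn_hmm(ch$M, ch$pi, list(fx$ctx, fx$ctx), fx$w, fx$k)
    forward_loglik(m, fx$sim$obs)
  }
  expect_gt(ll(pair_tree(0.8, 0.4, 0.4)), ll(pair_tree(0.8, 0.8, 0.8)))
})

test_that("a cell paired with itself shows near-zero divergence", {
  fx <- pair_fixture()
  same <- fit_cell_pair(fx$sim$obs[[1L]], fx$sim$obs[[1L]], fx$ctx, fx$ctx,
                        fx$rates, fx$k, init = pair_tree(0.2, 0.2, 0.2),
                        maxit = 60L)
  diff <- fit_cell_pair(fx$sim$obs[[1L]], fx$sim$obs[[2L]], fx$ctx, fx$ctx,
                        fx$rates, fx$k, init = pair_tree(0.2, 0.2, 0.2),
                        maxit = 60L)
  expect_lt(same$tree$t2 + same$tree$t3,
            0.2 * (diff$tree$t2 + diff$tree$t3))
})

test_that("fit_all_pairs covers requested pairs deterministically", {
  fx <- pair_fixture()
  cells <- list(a = fx$sim$obs[[1L]], b = fx$sim$obs[[2L]])
  cells$a$cell_id <- "a"; cells$b$cell_id <- "b"
  mkfit <- function() structure(list(s = 1, t = 0.5,
                                     rates = fx$rates),
                                class = "cn_fit")
  fits <- list(a = mkfit(), b = mkfit())
  dp <- structure(list(windows = fx$w, mean = fx$ctx$mu,
                       variance = rep(400, nrow(fx$w)), n_cells = 5L),
                  class = "diploid_profile")
  res <- fit_all_pairs(cells, fits, fx$rates, dp, toy_dispersion(), fx$k,
                       maxit = 30L)
  expect_named(res, "a|b")
  expect_s3_class(res[["a|b"]], "cn_pair_fit")
  expect_error(fit_all_pairs(cells, fits, fx$rates, dp, toy_dispersion(),
                             fx$k, pair_list = rbind(c("a", "zz"))),
               "unknown cell id")
  expect_warning(
    empty <- fit_all_pairs(cells, fits, fx$rates, dp, toy_dispersion(),
                           fx$k, pair_list = matrix(character(0), 0L, 2L)),
    "empty pair list")
  expect_length(empty, 0L)
})
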