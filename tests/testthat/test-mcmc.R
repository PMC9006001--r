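make_fixture_fit <- function() {
  g <- epoch_grid(numeric(0))
  r <- rate_set(lambda0 = 0.25, lambda1 = 0.25, mu0 = 0.05, q01 = 0.05,
                grid = g)
  cfg <- sim_config(r, grid = g, origin_age = 16, root_state = 0,
                    tip_window = c(40, 120), max_attempts = 100)
  s <- simulate_bisse_tree(cfg, seed = 19)
  spec <- model_spec(grid = g)
  fit <- fit_ml(spec, s$phy, s$tip_states, n_restarts = 2, seed = 1)
  list(sim = s, fit = fit)
}

test_that("with a flat likelihood the chain samples the prior", {
  fx <- make_fixture_fit()
  pm <- 0.4
  ps <- sample_posterior(fx$fit, fx$sim$phy, fx$sim$tip_states, n_gen = 5000,
                         prior = exp_prior(pm), seed = 3,
                         flat_likelihood = TRUE)
  draws <- ps$draws[seq(501, 5000, by = 5), 1]   # thin for the KS test
  ks <- suppressWarnings(stats::ks.test(draws, stats::pexp, 1 / pm))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(ps$draws[, 2]), pm, tolerance = 0.1)
})

test_that("chains are bit-identical under the same seed", {
  fx <- make_fixture_fit()
  a <- sample_posterior(fx$fit, fx$sim$phy, fx$sim$tip_states, n_gen = 50,
                        seed = 11)
  b <- sample_posterior(fx$fit, fx$sim$phy, fx$sim$tip_states, n_gen = 50,
                        seed = 11)
  expect_identical(a$draws, b$draws)
  expect_identical(a$logLik, b$logLik)
  c <- sample_posterior(fx$fit, fx$sim$phy, fx$sim$tip_states, n_gen = 50,
                        seed = 12)
  expect_false(identical(a$draws, c$draws))
})

test_that("posterior means match a dense-grid quadrature on a small fixture", {
  # 4-tip tree, single epoch, fully constrained 3-parameter model
  phy <- read_newick("((A:2,B:2):3,(C:4,D:4):1):0;")
  st <- c(A = 0, B = 1, C = 0, D = 0)
  g <- epoch_grid(numeric(0))
  spec <- model_spec(grid = g)
  fit <- fit_ml(spec, phy, st, n_restarts = 3, seed = 2)
  pm <- 0.5
  ps <- sample_posterior(fit, phy, st, n_gen = 4000, prior = exp_prior(pm),
                         seed = 7)
  keep <- ps$draws[401:4000, ]
  # quadrature over a log-spaced grid (posterior = L x exp prior)
  gr <- exp(seq(log(2e-4), log(3), length.out = 33))
  wts <- c(diff(gr)[1], diff(gr))          # trapezoid-flavoured weights
  cells <- as.matrix(expand.grid(l = gr, m = gr, q = gr))
  wcell <- as.numeric(expand.grid(wts, wts, wts) |> apply(1, prod))
  lp <- vapply(seq_len(nrow(cells)), function(i) {
    r <- expand_rates(spec, cells[i, ])
    tree_loglik(phy, st, r) +
      sum(stats::dexp(cells[i, ], 1 / pm, log = TRUE))
  }, numeric(1))
  w <- exp(lp - max(lp)) * wcell
  w <- w / sum(w)
  post_mean <- colSums(cells * w)
  for (j in 1:3) {
    mcse <- mcse_batch(keep[, j])
    # quadrature discretization adds error of its own; allow 4 MCSE + 5%
    expect_lt(abs(mean(keep[, j]) - post_mean[j]),
              4 * mcse + 0.05 * post_mean[j])
  }
})

test_that("pooling is idempotent, order-invariant, and counts draws", {
  fx <- make_fixture_fit()
  a <- sample_posterior(fx$fit, fx$sim$phy, fx$sim$tip_states, n_gen = 200,
                        seed = 21, tree_id = 1)
  b <- sample_posterior(fx$fit, fx$sim$phy, fx$sim$tip_states, n_gen = 200,
                        seed = 22, tree_id = 2)
  s1 <- pool_and_summarize(list(a, a))
  s0 <- pool_and_summarize(a)
  expect_equal(s1$summary$median, s0$summary$median)
  expect_equal(s1$summary$lo, s0$summary$lo)
  s_ab <- pool_and_summarize(list(a, b))
  s_ba <- pool_and_summarize(list(b, a))
  expect_equal(s_ab$summary, s_ba$summary)
  expect_equal(s_ab$n_draws, 2 * 180)       # 10% burn-in dropped per chain
  # a single epoch has no epoch contrasts
  expect_equal(nrow(s_ab$contrasts), 0L)

  # complementary contrasts sum to one on a multi-epoch parameterization
  g3 <- epoch_grid(c(12, 6))
  spec3 <- model_spec(lambda = c("tied", "free"), grid = g3)
  set.seed(1)
  ps3 <- structure(list(
    draws = matrix(stats::rexp(50 * spec3$k, 5), 50, spec3$k),
    logLik = numeric(50), logPrior = numeric(50), spec = spec3,
    tree_id = 1L, seed = 1L), class = "posterior_sample")
  cns <- pool_and_summarize(ps3, burn_in_frac = 0)$contrasts
  expect_gt(nrow(cns), 0L)
  # complementarity holds wherever the cells are genuinely distinct draws
  # (epoch-tied parameters tie exactly by construction)
  free <- cns[cns$rate %in% c("lambda0", "lambda1"), ]
  for (i in seq_len(nrow(free))) {
    mirror <- free[free$rate == free$rate[i] & free$epoch_a == free$epoch_b[i] &
                   free$epoch_b == free$epoch_a[i], ]
    expect_equal(free$p_less[i] + mirror$p_less, 1)
  }
})

test_that("effective sample size tracks chain autocorrelation", {
  set.seed(4)
  iid <- stats::rnorm(2000)
  expect_gt(ess(iid), 1200)
  # AR(1) with strong positive correlation has far fewer effective draws
  ar <- as.numeric(stats::arima.sim(list(ar = 0.9), 2000))
  expect_lt(ess(ar), 500)
  expect_equal(ess(rep(1, 100)), 100)
})

test_that("net diversification is computed per draw", {
  g <- epoch_grid(numeric(0))
  spec <- model_spec(lambda = c("free", "tied"), mu = c("free", "tied"),
                     q = c("tied", "tied"), grid = g)
  draws <- matrix(c(0.2, 0.3, 0.05, 0.1, 0.01,
                    0.4, 0.5, 0.15, 0.2, 0.02), 2, 5, byrow = TRUE)
  ps <- structure(list(draws = draws, logLik = c(0, 0), logPrior = c(0, 0),
                       spec = spec, tree_id = 1L, seed = 1L),
                  class = "posterior_sample")
  s <- pool_and_summarize(ps, burn_in_frac = 0)
  nd0 <- s$summary[s$summary$rate == "netdiv0" & s$summary$epoch == 1, ]
  expect_equal(nd0$median, stats::median(c(0.2 - 0.05, 0.4 - 0.15)))
  nd1 <- s$summary[s$summary$rate == "netdiv1" & s$summary$epoch == 1, ]
  expect_equal(nd1$median, stats::median(c(0.3 - 0.1, 0.5 - 0.2)))
  expect_error(pool_and_summarize(list(ps, structure(list(
    draws = draws[, 1:3], spec = model_spec(grid = g), tree_id = 2L),
    class = "posterior_sample"))), "parameterization")
})

test_that("a simulated mid-epoch speciation drop is detected by contrast
           probabilities", {
  # three epochs with lambda halved in the middle one; moderately sized
  # trees keep the check brisk while the drop stays recoverable
  g <- epoch_grid(c(12, 6))
  r <- rate_set(lambda0 = c(0.35, 0.175, 0.35), lambda1 = c(0.35, 0.175, 0.35),
                mu0 = 0.03, q01 = 0.05, grid = g)
  cfg <- sim_config(r, grid = g, origin_age = 18, root_state = 0,
                    tip_window = c(250, 700), max_attempts = 300)
  spec <- model_spec(lambda = c("tied", "shift"), grid = g)
  ok <- 0L; n <- 0L
  for (i in 1:3) {
    s <- tryCatch(simulate_bisse_tree(cfg, seed = 400 + i),
                  error = function(e) NULL)
    if (is.null(s)) next
    ft <- fit_ml(spec, s$phy, s$tip_states, n_restarts = 2, seed = i)
    ps <- sample_posterior(ft, s$phy, s$tip_states, n_gen = 250,
                           n_adapt = 80, seed = 50 + i)
    su <- pool_and_summarize(ps)
    n <- n + 1L
    ok <- ok + (contrast_prob(su, "lambda0", 1, 2) > 0.9)
  }
  expect_gte(n, 2L)
  expect_gte(ok / n, 2 / 3)
})
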