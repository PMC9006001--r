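test_that("the programmatic ladder has the documented shape", {
  lad <- enumerate_models()
  expect_lte(length(lad), 18L)
  k <- vapply(lad, `[[`, 0, "k")
  # fully constrained: one lambda, one mu, one q
  expect_equal(min(k), 3L)
  expect_equal(lad[[which.min(k)]]$name, "fully_constrained")
  # fully free: 6 rates x 3 epochs
  expect_equal(max(k), 18L)
  full <- lad[[which.max(k)]]
  # every model nested in the fully free model; free-parameter count equals
  # the number of distinct map indices
  for (m in lad) {
    expect_true(is_nested(m, full))
    expect_equal(m$k, length(unique(as.integer(m$map))))
  }
  # the state-free/time-constant model is present
  expect_true(any(k == 6 & vapply(lad, function(m)
    all(vapply(m$modes, function(md) md[1] == "free" && md[2] == "tied",
               TRUE)), TRUE)))
  expect_equal(anyDuplicated(vapply(lad, `[[`, "", "name")), 0L)
})

test_that("expand_rates honours the constraint map", {
  g <- epoch_grid(c(66, 40))
  spec <- model_spec(lambda = c("free", "shift"), mu = c("tied", "tied"),
                     q = c("tied", "tied"), grid = g)
  expect_equal(spec$k, 6L)
  th <- c(0.1, 0.2, 0.3, 0.4, 0.05, 0.01)
  r <- expand_rates(spec, th)
  # lambda0 epochs (pre, gap, post) = (th1, th2, th1); lambda1 = (th3, th4, th3)
  expect_equal(unname(r[, "lambda0"]), th[c(1, 2, 1)])
  expect_equal(unname(r[, "lambda1"]), th[c(3, 4, 3)])
  expect_equal(unname(r[, "mu0"]), rep(th[5], 3))
  expect_equal(unname(r[, "mu1"]), rep(th[5], 3))
  expect_equal(unname(r[, "q01"]), rep(th[6], 3))
})

test_that("nesting detection follows partition refinement", {
  g <- epoch_grid(c(66, 40))
  m3 <- model_spec(grid = g)
  m4 <- model_spec(lambda = c("free", "tied"), grid = g)
  m8 <- model_spec(lambda = c("free", "shift"), mu = c("free", "tied"),
                   q = c("free", "tied"), grid = g)
  expect_true(is_nested(m3, m4))
  expect_true(is_nested(m4, m8))
  expect_false(is_nested(m4, m3))
  # mu-state model is not nested in the lambda-state model
  mmu <- model_spec(mu = c("free", "tied"), grid = g)
  expect_false(is_nested(mmu, m4))
})

test_that("LRT identities: self-comparison, degrees of freedom, monotone logL", {
  g <- epoch_grid(numeric(0))
  r <- rate_set(lambda0 = 0.25, lambda1 = 0.35, mu0 = 0.05, q01 = 0.05,
                grid = g)
  cfg <- sim_config(r, grid = g, origin_age = 20, root_state = 0,
                    tip_window = c(60, 200), max_attempts = 100)
  s <- simulate_bisse_tree(cfg, seed = 31)
  m3 <- model_spec(grid = g)
  m4 <- model_spec(lambda = c("free", "tied"), grid = g)
  m6 <- model_spec(lambda = c("free", "tied"), mu = c("free", "tied"),
                   q = c("free", "tied"), grid = g)
  f3 <- fit_ml(m3, s$phy, s$tip_states, n_restarts = 2, seed = 1)
  f4 <- fit_ml(m4, s$phy, s$tip_states, n_restarts = 2, seed = 2)
  f6 <- fit_ml(m6, s$phy, s$tip_states, n_restarts = 2, seed = 3)
  self <- lrt(f3, f3)
  expect_equal(self$statistic, 0)
  expect_equal(self$p, 1)
  expect_equal(lrt(f3, f4)$df, 1L)
  expect_equal(lrt(f4, f6)$df, 2L)
  # nested ML logL never exceeds the richer model's
  expect_lte(f3$logLik, f4$logLik + 1e-6)
  expect_lte(f4$logLik, f6$logLik + 1e-6)
  expect_error(lrt(f4, f3), "not nested")
  # df arithmetic for the full ladder endpoints
  lad <- enumerate_models()
  expect_equal(lad[[length(lad)]]$k - lad[[1]]$k, 15L)
})

test_that("LRT statistics are invariant to rate reparameterization", {
  # the statistic depends on maximized log-likelihoods only; refitting with
  # a rescaled tree (rates in different units) shifts both logLs equally
  g <- epoch_grid(numeric(0))
  r <- rate_set(lambda0 = 0.3, lambda1 = 0.3, mu0 = 0.05, q01 = 0.05,
                grid = g)
  cfg <- sim_config(r, grid = g, origin_age = 15, root_state = 0,
                    tip_window = c(50, 150), max_attempts = 100)
  s <- simulate_bisse_tree(cfg, seed = 8)
  m3 <- model_spec(grid = g)
  m4 <- model_spec(lambda = c("free", "tied"), grid = g)
  f3 <- fit_ml(m3, s$phy, s$tip_states, n_restarts = 2, seed = 1)
  f4 <- fit_ml(m4, s$phy, s$tip_states, n_restarts = 2, seed = 2)
  stat <- lrt(f3, f4)$statistic
  phy2 <- s$phy
  phy2$edge.length <- phy2$edge.length * 10    # Myr -> 10^5 yr units
  f3b <- fit_ml(m3, phy2, s$tip_states, n_restarts = 2, seed = 1, upper = 1)
  f4b <- fit_ml(m4, phy2, s$tip_states, n_restarts = 2, seed = 2, upper = 1)
  expect_equal(lrt(f3b, f4b)$statistic, stat, tolerance = 0.02)
})

test_that("restart count barely moves the maximized likelihood", {
  g <- epoch_grid(numeric(0))
  r <- rate_set(lambda0 = 0.25, lambda1 = 0.35, mu0 = 0.05, q01 = 0.05,
                grid = g)
  cfg <- sim_config(r, grid = g, origin_age = 18, root_state = 0,
                    tip_window = c(80, 140), max_attempts = 200)
  s <- simulate_bisse_tree(cfg, seed = 77)
  m4 <- model_spec(lambda = c("free", "tied"), grid = g)
  f5 <- fit_ml(m4, s$phy, s$tip_states, n_restarts = 5, seed = 4)
  f10 <- fit_ml(m4, s$phy, s$tip_states, n_restarts = 10, seed = 9)
  expect_lt(abs(f5$logLik - f10$logLik), 1e-3)
})

test_that("stepwise selection is deterministic and respects alpha limits", {
  g <- epoch_grid(numeric(0))
  r <- rate_set(lambda0 = 0.2, lambda1 = 0.45, mu0 = 0.05, q01 = 0.08,
                grid = g)
  cfg <- sim_config(r, grid = g, origin_age = 16, root_state = 0,
                    tip_window = c(80, 250), max_attempts = 100)
  s <- simulate_bisse_tree(cfg, seed = 5)
  lad <- list(model_spec(grid = g),
              model_spec(lambda = c("free", "tied"), grid = g),
              model_spec(lambda = c("free", "tied"), mu = c("free", "tied"),
                         q = c("free", "tied"), grid = g))
  fits <- lapply(seq_along(lad), function(i)
    fit_ml(lad[[i]], s$phy, s$tip_states, n_restarts = 2, seed = i))
  s1 <- stepwise_select(lad, fits = fits, alpha = 0.05)
  s2 <- stepwise_select(lad, fits = fits, alpha = 0.05)
  expect_identical(s1$selected, s2$selected)
  # alpha -> 0: nothing rejects, the simplest model stands
  expect_equal(stepwise_select(lad, fits = fits, alpha = 1e-12)$selected,
               lad[[1]]$name)
  # alpha = 1: everything rejects, the search walks to the richest model
  expect_equal(stepwise_select(lad, fits = fits, alpha = 1)$selected,
               lad[[3]]$name)
  expect_named(s1$table, c("model", "k", "logLik", "AIC", "df_vs_full",
                           "LRT_stat", "p"))
})

test_that("selection keeps the simple model on data it generated", {
  # q gives an even state mix at the tips: the chi-square null of the LRT
  # needs both state-specific rates well identified
  g <- epoch_grid(numeric(0))
  r <- rate_set(lambda0 = 0.25, lambda1 = 0.25, mu0 = 0.05, q01 = 0.1,
                grid = g)
  cfg <- sim_config(r, grid = g, origin_age = 16, root_state = 0,
                    tip_window = c(60, 250), max_attempts = 100)
  lad <- list(model_spec(grid = g),
              model_spec(lambda = c("free", "tied"), grid = g),
              model_spec(mu = c("free", "tied"), grid = g))
  hits <- 0L
  n_rep <- 30L
  for (i in seq_len(n_rep)) {
    s <- tryCatch(simulate_bisse_tree(cfg, seed = 900 + i),
                  error = function(e) NULL)
    if (is.null(s)) { n_rep <- n_rep - 1L; next }
    sl <- stepwise_select(lad, s$phy, s$tip_states, alpha = 0.05,
                          n_restarts = 2, seed = i)
    hits <- hits + (sl$selected == lad[[1]]$name)
  }
  # per-comparison type-I error 0.05; two (correlated) comparisons
  expect_gte(hits / n_rep, 0.85)
})
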