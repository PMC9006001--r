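test_that("branch integration matches closed forms in degenerate limits", {
  g <- epoch_grid(numeric(0))
  # pure loss of D0 at rate lambda0: D0(t) = e^(-lambda0 t)
  r <- rate_set(lambda0 = 0.1, lambda1 = 0, mu0 = 0, q01 = 0, grid = g)
  out <- bisse_integrate_branch(c(0, 0, 1, 0), 0, 1, r)
  expect_equal(out$y[3] * exp(out$log_scale), exp(-0.1), tolerance = 1e-8)
  # pure extinction: E0(t) = 1 - e^(-mu0 t)
  r2 <- rate_set(lambda0 = 0, mu0 = 0.25, q01 = 0, grid = g)
  out2 <- bisse_integrate_branch(c(0, 0, 1, 0), 0, 3, r2)
  expect_equal(out2$y[1], 1 - exp(-0.25 * 3), tolerance = 1e-8)
})

test_that("adaptive integration matches a fine-step RK4 oracle", {
  g <- epoch_grid(numeric(0))
  pars <- c(0.2, 0.1, 0.05, 0.05, 0.02, 0.01)
  r <- rate_set(pars[1], pars[2], pars[3], pars[4], pars[5], pars[6], grid = g)
  y0 <- c(0, 0, 1, 0.5)
  mine <- bisse_integrate_branch(y0, 0, 10, r)
  y_mine <- mine$y * c(1, 1, exp(mine$log_scale), exp(mine$log_scale))
  y_rk4 <- bisse_rk4(y0, 0, 10, pars, h = 1e-3)
  expect_lt(max(abs(y_mine - y_rk4) / pmax(abs(y_rk4), 1e-10)), 1e-6)
})

test_that("identical rates in every epoch equal single-segment integration", {
  g3 <- epoch_grid(c(6, 3))
  g1 <- epoch_grid(numeric(0))
  r3 <- rate_set(lambda0 = 0.2, lambda1 = 0.1, mu0 = 0.05, q01 = 0.03,
                 q10 = 0.01, grid = g3)
  r1 <- rate_set(lambda0 = 0.2, lambda1 = 0.1, mu0 = 0.05, q01 = 0.03,
                 q10 = 0.01, grid = g1)
  y0 <- c(0, 0, 0.3, 0.7)
  a <- bisse_integrate_branch(y0, 0, 10, r3)
  b <- bisse_integrate_branch(y0, 0, 10, r1)
  expect_lt(max(abs(a$y - b$y)), 1e-8)
})

test_that("the two-tip likelihood matches the hand-integrated case", {
  # both tips state 0, q = 0, mu = 0, single epoch: one speciation density
  # at the root times two surviving-lineage factors,
  # logL = log(lambda) - 2 lambda t
  g <- epoch_grid(numeric(0))
  phy <- read_newick("(A:1.5,B:1.5):0;")
  ll <- tree_loglik(phy, c(A = 0, B = 0), rate_set(0.2, grid = g),
                    condition_surv = FALSE)
  expect_equal(ll, log(0.2) - 2 * 0.2 * 1.5, tolerance = 1e-9)
})

test_that("state-independent rates factorize into birth-death x Markov", {
  g <- epoch_grid(numeric(0))
  lambda <- 0.15; mu <- 0.04; q <- 0.04
  r <- rate_set(lambda0 = lambda, lambda1 = lambda, mu0 = mu, mu1 = mu,
                q01 = q, q10 = q, grid = g)
  for (seed in 1:3) {
    phy <- fixture_tree(50, age = 40, seed = seed)
    st <- fixture_states(phy, 0.4, seed = seed + 10)
    ll <- tree_loglik(phy, st, r, root_mode = "flat", condition_surv = FALSE)
    ll_bd <- bd_loglik_closed(phy, lambda, mu)
    ll_mk <- mk_loglik_expm(phy, st, q, q, prior = c(0.5, 0.5))
    expect_equal(ll, ll_bd + ll_mk, tolerance = 1e-6)
  }
})

test_that("likelihood is invariant to label swaps within a state", {
  g <- epoch_grid(c(20, 10))
  r <- rate_set(lambda0 = c(0.2, 0.1, 0.25), lambda1 = 0.15, mu0 = 0.03,
                q01 = 0.02, grid = g)
  phy <- fixture_tree(30, age = 30, seed = 5)
  st <- fixture_states(phy, 0.5, seed = 2)
  ll1 <- tree_loglik(phy, st, r)
  zeros <- names(st)[st == 0][1:2]
  st2 <- st
  names(st2)[match(zeros, names(st2))] <- rev(zeros)
  expect_equal(tree_loglik(phy, st2, r), ll1, tolerance = 1e-10)
})

test_that("refining the epoch grid with duplicated rates leaves logL fixed", {
  phy <- fixture_tree(50, age = 90, seed = 7)
  st <- fixture_states(phy, 0.35, seed = 3)
  g2 <- epoch_grid(c(66, 40))
  r2 <- rate_set(lambda0 = c(0.12, 0.08, 0.15), lambda1 = c(0.2, 0.12, 0.22),
                 mu0 = 0.05, mu1 = 0.04, q01 = 0.02, q10 = 0.01, grid = g2)
  ll2 <- tree_loglik(phy, st, r2)
  # insert a boundary at 25 Ma with identical rates on both sides
  g3 <- epoch_grid(c(66, 40, 25))
  r3 <- rate_set(lambda0 = c(0.12, 0.08, 0.15, 0.15),
                 lambda1 = c(0.2, 0.12, 0.22, 0.22),
                 mu0 = 0.05, mu1 = 0.04, q01 = 0.02, q10 = 0.01, grid = g3)
  expect_lt(abs(tree_loglik(phy, st, r3) - ll2), 1e-8)
})

test_that("E stays in [0,1] and grows with age under positive extinction", {
  g <- epoch_grid(numeric(0))
  r <- rate_set(lambda0 = 0.1, lambda1 = 0.2, mu0 = 0.06, mu1 = 0.03,
                q01 = 0.02, q10 = 0.02, grid = g)
  y <- c(0, 0, 1, 1)
  prev <- c(0, 0)
  for (a in seq(2, 40, by = 2)) {
    out <- bisse_integrate_branch(c(0, 0, 1, 1), 0, a, r)
    expect_true(all(out$y[1:2] >= 0 & out$y[1:2] <= 1))
    expect_true(all(out$y[1:2] >= prev - 1e-12))
    prev <- out$y[1:2]
  }
})

test_that("logL is finite and continuous in the rates on fixtures", {
  phy <- fixture_tree(30, age = 30, seed = 9)
  st <- fixture_states(phy, 0.5, seed = 4)
  g <- epoch_grid(c(20, 10))
  base <- c(lambda0 = 0.15, lambda1 = 0.2, mu0 = 0.02, mu1 = 0.03,
            q01 = 0.03, q10 = 0.02)
  mk <- function(v) rate_set(v[1], v[2], v[3], v[4], v[5], v[6], grid = g)
  ll0 <- tree_loglik(phy, st, mk(base))
  expect_true(is.finite(ll0))
  for (j in seq_along(base)) {
    for (eps in c(1e-5, -1e-5)) {
      v <- base
      v[j] <- v[j] * (1 + eps)
      expect_lt(abs(tree_loglik(phy, st, mk(v)) - ll0), 0.05)
    }
  }
})

test_that("unknown tip states integrate over both states", {
  g <- epoch_grid(numeric(0))
  r <- rate_set(lambda0 = 0.2, lambda1 = 0.1, mu0 = 0.03, q01 = 0.05,
                grid = g)
  phy <- fixture_tree(12, age = 15, seed = 11)
  st <- fixture_states(phy, 0.5, seed = 6)
  st_na <- st
  st_na[1] <- NA
  ll_na <- tree_loglik(phy, st_na, r, condition_surv = FALSE,
                       root_mode = "flat")
  # marginalization: the NA-tip likelihood is the sum over its two states
  st0 <- st; st0[1] <- 0
  st1 <- st; st1[1] <- 1
  l0 <- tree_loglik(phy, st0, r, condition_surv = FALSE, root_mode = "flat")
  l1 <- tree_loglik(phy, st1, r, condition_surv = FALSE, root_mode = "flat")
  expect_equal(ll_na, log(exp(l0) + exp(l1)), tolerance = 1e-7)
})

test_that("likelihood prefers the generating rates over perturbed ones", {
  # Monte-Carlo consistency at modest scale: mean logL at truth beats the
  # mean at x2 / half rates across simulated trees.
  g <- epoch_grid(numeric(0))
  r_true <- rate_set(lambda0 = 0.15, lambda1 = 0.3, mu0 = 0.05, q01 = 0.05,
                     grid = g)
  r_hi <- rate_set(lambda0 = 0.3, lambda1 = 0.6, mu0 = 0.1, q01 = 0.1,
                   grid = g)
  r_lo <- rate_set(lambda0 = 0.075, lambda1 = 0.15, mu0 = 0.025, q01 = 0.025,
                   grid = g)
  cfg <- sim_config(r_true, grid = g, origin_age = 18, root_state = 0,
                    tip_window = c(10, 200), max_attempts = 50)
  d_hi <- d_lo <- numeric(0)
  for (i in 1:60) {
    s <- tryCatch(simulate_bisse_tree(cfg, seed = 500 + i),
                  error = function(e) NULL)
    if (is.null(s)) next
    llt <- tree_loglik(s$phy, s$tip_states, r_true)
    d_hi <- c(d_hi, llt - tree_loglik(s$phy, s$tip_states, r_hi))
    d_lo <- c(d_lo, llt - tree_loglik(s$phy, s$tip_states, r_lo))
  }
  expect_gt(length(d_hi), 40)
  expect_gt(mean(d_hi), 0)
  expect_gt(mean(d_lo), 0)
})
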