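test_that("character histories enforce their invariants at construction", {
  phy <- read_newick("((A:1,B:1):1,C:2):0;")
  ok <- list(stats::setNames(1, "0"), stats::setNames(c(0.4, 0.6), c("0", "1")),
             stats::setNames(1, "1"), stats::setNames(2, "0"))
  # order maps to match phy$edge rows
  maps <- vector("list", 4)
  for (i in 1:4) maps[[i]] <- NULL
  e <- phy$edge
  build <- function(m_root_int, m_a, m_b, m_c) {
    maps <- vector("list", 4)
    for (i in seq_len(4)) {
      par <- e[i, 1]; ch <- e[i, 2]
      maps[[i]] <- if (par == 4 && ch == 5) m_root_int
        else if (ch == 1) m_a else if (ch == 2) m_b else m_c
    }
    maps
  }
  h <- character_history(phy, build(stats::setNames(1, "0"),
                                    stats::setNames(c(0.4, 0.6), c("0", "1")),
                                    stats::setNames(1, "0"),
                                    stats::setNames(2, "0")))
  expect_equal(unname(history_transitions(h)), c(1L, 0L))
  expect_equal(unname(history_dwell_times(h)), c(4.4, 0.6))
  expect_equal(count_origins(h), 1L)
  # dwell sum violated
  expect_error(character_history(phy, build(stats::setNames(0.9, "0"),
    stats::setNames(c(0.4, 0.6), c("0", "1")), stats::setNames(1, "0"),
    stats::setNames(2, "0"))), "sum")
  # junction inconsistency: internal edge ends in 1, daughter starts in 0
  expect_error(character_history(phy, build(stats::setNames(1, "1"),
    stats::setNames(1, "0"), stats::setNames(1, "0"),
    stats::setNames(2, "0"))), "parent")
  # non-alternating run labels
  expect_error(character_history(phy, build(stats::setNames(1, "0"),
    stats::setNames(c(0.4, 0.6), c("0", "0")), stats::setNames(1, "0"),
    stats::setNames(2, "0"))), "alternate")
})

test_that("origin counting follows the change points, not the root state", {
  phy <- read_newick("((A:1,B:1):1,C:2):0;")
  e <- phy$edge
  maps <- vector("list", 4)
  for (i in seq_len(4)) {
    par <- e[i, 1]; ch <- e[i, 2]
    maps[[i]] <- if (par == 4 && ch == 5) stats::setNames(1, "1")
      else if (ch == 1) stats::setNames(1, "1")
      else if (ch == 2) stats::setNames(c(0.5, 0.5), c("1", "0"))
      else stats::setNames(2, "1")
  }
  h <- character_history(phy, maps)
  # root state 1, no gains anywhere: zero origins
  expect_equal(count_origins(h), 0L)
  # hand-built history with two gains and one loss
  maps2 <- maps
  for (i in seq_len(4)) {
    par <- e[i, 1]; ch <- e[i, 2]
    if (par == 4 && ch == 5) maps2[[i]] <- stats::setNames(1, "0")
    if (ch == 1) maps2[[i]] <- stats::setNames(c(0.3, 0.7), c("0", "1"))
    if (ch == 2) maps2[[i]] <- stats::setNames(c(0.2, 0.5, 0.3),
                                               c("0", "1", "0"))
    if (ch == 3) maps2[[i]] <- stats::setNames(2, "0")
  }
  h2 <- character_history(phy, maps2)
  expect_equal(count_origins(h2), 2L)
  expect_equal(unname(history_transitions(h2)), c(2L, 1L))
  s <- summarize_origins(c(2, 2, 3, 2, 4))
  expect_equal(s$min, 2)
  expect_equal(s$mode, 2L)
})

test_that("histories serialize to per-branch change-point JSON", {
  phy <- read_newick("((A:1,B:1):1,C:2):0;")
  e <- phy$edge
  maps <- vector("list", 4)
  for (i in seq_len(4)) {
    par <- e[i, 1]; ch <- e[i, 2]
    maps[[i]] <- if (par == 4 && ch == 5) stats::setNames(1, "0")
      else if (ch == 1) stats::setNames(c(0.4, 0.6), c("0", "1"))
      else if (ch == 2) stats::setNames(1, "0")
      else stats::setNames(2, "0")
  }
  h <- character_history(phy, maps)
  js <- jsonlite::fromJSON(history_to_json(h), simplifyDataFrame = FALSE)
  expect_length(js, 4L)
  iA <- which(vapply(js, function(r) r$child == 1, TRUE))
  rec <- js[[iA]]
  expect_equal(rec$start_state, 0L)
  expect_equal(rec$end_state, 1L)
  # edge to tip A spans ages 1..0; the switch happens 0.4 into it
  expect_equal(rec$change_points[[1]]$age, 0.6)
  expect_equal(rec$change_points[[1]]$to_state, 1L)
  f <- tempfile(fileext = ".json")
  history_to_json(h, f)
  expect_true(file.exists(f))
  unlink(f)
})

test_that("the Mk likelihood matches a matrix-exponential pruning oracle", {
  phy <- fixture_tree(25, age = 20, seed = 12)
  st <- fixture_states(phy, 0.4, seed = 5)
  for (q in list(c(0.05, 0.02), c(0.3, 0.3), c(0.01, 0.2))) {
    pi0 <- c(q[2], q[1]) / sum(q)
    expect_equal(mk_loglik(phy, st, q[1], q[2], root_prior = "stationary"),
                 mk_loglik_expm(phy, st, q[1], q[2], prior = pi0),
                 tolerance = 1e-8)
  }
})

test_that("monomorphic tips drive the rate MLEs to the boundary", {
  phy <- fixture_tree(15, age = 10, seed = 3)
  st <- stats::setNames(rep(0L, 15), phy$tip.label)
  expect_warning(ft <- fit_mk(phy, st), "one state")
  expect_lt(ft$q01, 1e-6)
  expect_gt(ft$logLik, -1e-6)   # no-change likelihood tends to 1
})

test_that("Mk rates are recovered on simulated data", {
  phy <- fixture_tree(300, age = 60, seed = 21)
  q01 <- 0.05; q10 <- 0.02
  est <- vapply(1:30, function(i) {
    nt <- simulate_neutral_trait(phy, q01, q10, root_state = 0, seed = 600 + i)
    ft <- fit_mk(phy, nt$tip_states)
    c(ft$q01, ft$q10)
  }, numeric(2))
  expect_lt(abs(stats::median(est[1, ]) - q01) / q01, 0.3)
  expect_lt(abs(stats::median(est[2, ]) - q10) / q10, 0.3)
})

test_that("sampled histories reproduce tips and conserve dwell time", {
  phy <- fixture_tree(30, age = 25, seed = 14)
  nt <- simulate_neutral_trait(phy, 0.08, 0.04, 0, seed = 4)
  sm <- sample_histories(phy, nt$tip_states, list(q01 = 0.08, q10 = 0.04),
                         n_maps = 40, seed = 9)
  tl <- sum(phy$edge.length)
  for (h in sm$histories) {
    expect_equal(unname(h$node_states[seq_len(30)]), unname(nt$tip_states))
    expect_equal(sum(history_dwell_times(h)), tl, tolerance = 1e-8)
  }
  expect_true(all(abs(sm$node_posterior$pp_state0 +
                      sm$node_posterior$pp_state1 - 1) < 1e-12))
  # determinism under the seed
  sm2 <- sample_histories(phy, nt$tip_states, list(q01 = 0.08, q10 = 0.04),
                          n_maps = 40, seed = 9)
  expect_identical(sm$origin_counts, sm2$origin_counts)
  expect_identical(sm$node_posterior, sm2$node_posterior)
})

test_that("with no losses and root state 0 paths are nondecreasing", {
  phy <- fixture_tree(25, age = 20, seed = 16)
  nt <- simulate_neutral_trait(phy, 0.1, 0, root_state = 0, seed = 11)
  sm <- sample_histories(phy, nt$tip_states, list(q01 = 0.1, q10 = 0),
                         n_maps = 25, root_prior = "equal", seed = 2)
  for (h in sm$histories) {
    expect_equal(unname(history_transitions(h)["n10"]), 0L)
    for (m in h$maps) {
      sts <- as.integer(names(m))
      expect_true(all(diff(sts) >= 0))
    }
  }
})

test_that("mean transition count approaches tree length times flux", {
  phy <- fixture_tree(40, age = 30, seed = 18)
  q01 <- 0.07; q10 <- 0.05
  nt <- simulate_neutral_trait(phy, q01, q10, 0, seed = 3)
  sm <- sample_histories(phy, nt$tip_states, list(q01 = q01, q10 = q10),
                         n_maps = 2000, seed = 8)
  ntrans <- vapply(sm$histories, function(h) sum(history_transitions(h)),
                   numeric(1))
  dwell <- vapply(sm$histories, history_dwell_times, numeric(2))
  expected_flux <- q01 * mean(dwell[1, ]) + q10 * mean(dwell[2, ])
  expect_lt(abs(mean(ntrans) - expected_flux) / expected_flux, 0.1)
})
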