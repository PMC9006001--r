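#' Exponential prior on model rates
#'
#' Independent exponential priors on each free rate, with a common mean
#' (typically 2x the ML rate under the fully constrained model, mirroring
#' the usual construction for diversification MCMC).
#'
#' @param mean Prior mean (scalar, or one per free parameter).
#' @export
exp_prior <- function(mean = 1) {
  stopifnot(all(mean > 0))
  structure(list(mean = mean), class = "rate_prior")
}

log_prior <- function(prior, theta) {
  m <- rep_len(prior$mean, length(theta))
  if (any(theta <= 0)) return(-Inf)
  sum(stats::dexp(theta, rate = 1 / m, log = TRUE))
}

#' Prior mean heuristic from the fully constrained fit
#'
#' @param phy,states,f,seed As in [fit_ml()].
#' @param grid Epoch grid.
#' @return An [exp_prior()] with mean `2 x` the constrained ML rates
#'   (lambda-mean for every parameter, a single scale).
#' @export
default_prior <- function(phy, states, f = c(1, 1), grid = epoch_grid(),
                          seed = 1L) {
  base <- model_spec(grid = grid)
  ft <- fit_ml(base, phy, states, f = f, n_restarts = 3, seed = seed)
  exp_prior(mean = 2 * max(ft$par))
}

#' Posterior sampling of a model's rates by slice sampling
#'
#' Univariate slice sampling (stepping-out and shrinkage) over log-rates,
#' one parameter at a time, starting at the ML point. Step widths are tuned
#' during an adaptation phase whose draws are kept in the output (burn-in is
#' discarded at summary time only). Same seed, same chain.
#'
#' @param fit A `fit_result` from [fit_ml()] (the chain starts at its ML
#'   point).
#' @param phy,states,f As in [tree_loglik()].
#' @param n_gen Number of generations (one full parameter sweep each).
#' @param prior An [exp_prior()].
#' @param seed Integer seed.
#' @param n_adapt Adaptation generations (step-width tuning), `<= n_gen`.
#' @param tree_id Identifier recorded with the draws.
#' @param root_mode,condition_surv,rtol,atol Likelihood conventions.
#' @param flat_likelihood If `TRUE` the likelihood is held constant so the
#'   chain targets the prior (a sampler validity check).
#' @return A `posterior_sample`: `draws` (n_gen x k matrix of rates),
#'   `logLik`, `logPrior`, `spec`, `tree_id`, `seed`, `n_adapt`.
#' @export
sample_posterior <- function(fit, phy, states, f = c(1, 1), n_gen = 1000,
                             prior = exp_prior(mean = 2 * max(fit$par)),
                             seed = 1L, n_adapt = min(500, n_gen %/% 5),
                             tree_id = 1L, root_mode = "obs",
                             condition_surv = TRUE, rtol = 1e-7, atol = 1e-9,
                             flat_likelihood = FALSE) {
  spec <- fit$spec
  td <- bisse_tree_data(phy, states)
  k <- spec$k
  loglik <- function(lth) {
    if (flat_likelihood) return(0)
    r <- expand_rates(spec, exp(lth))
    tree_loglik_td(td, r, spec$grid, f, root_mode, condition_surv, rtol, atol)
  }
  # posterior over log-rates: log L + log prior(rate) + log |Jacobian| (= sum lth)
  lpost_from <- function(ll, lth) ll + log_prior(prior, exp(lth)) + sum(lth)
  lth <- log(as.numeric(fit$par))
  ll <- loglik(lth)
  if (!is.finite(ll) && !flat_likelihood)
    stop("non-finite likelihood at the chain start")
  lp <- lpost_from(ll, lth)
  if (!is.finite(lp)) stop("non-finite posterior at the chain start")
  w <- rep(1, k)
  draws <- matrix(NA_real_, n_gen, k)
  ll_out <- numeric(n_gen); lpri_out <- numeric(n_gen)
  with_seed(seed, {
    for (g in seq_len(n_gen)) {
      for (j in seq_len(k)) {
        z <- lp - stats::rexp(1)            # log slice level
        u <- stats::runif(1)
        L <- lth[j] - u * w[j]
        R <- L + w[j]
        # stepping out
        lthL <- lth; lthR <- lth
        steps <- 0L
        repeat {
          lthL[j] <- L
          if (lpost_from(loglik(lthL), lthL) <= z || steps > 50L) break
          L <- L - w[j]; steps <- steps + 1L
        }
        steps <- 0L
        repeat {
          lthR[j] <- R
          if (lpost_from(loglik(lthR), lthR) <= z || steps > 50L) break
          R <- R + w[j]; steps <- steps + 1L
        }
        # shrinkage
        moved <- 0
        repeat {
          prop <- lth
          prop[j] <- stats::runif(1, L, R)
          ll_p <- loglik(prop)
          lp_p <- lpost_from(ll_p, prop)
          if (lp_p > z) { moved <- abs(prop[j] - lth[j])
                          lth <- prop; ll <- ll_p; lp <- lp_p; break }
          if (prop[j] < lth[j]) L <- prop[j] else R <- prop[j]
          if (R - L < 1e-12) break
        }
        if (g <= n_adapt)
          w[j] <- max(0.05, 0.9 * w[j] + 0.1 * 4 * moved)
      }
      draws[g, ] <- exp(lth)
      ll_out[g] <- ll
      lpri_out[g] <- log_prior(prior, exp(lth))
    }
  })
  structure(list(draws = draws, logLik = ll_out, logPrior = lpri_out,
                 spec = spec, prior = prior, tree_id = tree_id, seed = seed,
                 n_adapt = n_adapt, burn_in_frac = 0.1),
            class = "posterior_sample")
}

#' Pool posterior samples across trees and summarize epoch rates
#'
#' Discards the burn-in fraction of each chain, pools the remaining draws
#' with equal weight per tree, expands each draw into the full per-epoch,
#' per-state rate grid, and reports the posterior median and 95% interval
#' of every rate cell and of net diversification `r = lambda - mu`
#' (computed per draw), together with epoch contrast probabilities
#' `P(rate in epoch b < rate in epoch a)` for every epoch pair and rate.
#'
#' @param samples A `posterior_sample` or list of them (equal
#'   parameterization, equal draws per tree).
#' @param burn_in_frac Fraction of each chain discarded before pooling.
#' @return An `epoch_summary`: `summary` (long data frame
#'   `rate, state, epoch, median, lo, hi`), `contrasts`
#'   (`rate, state, epoch_a, epoch_b, p_less`), `n_draws`, `spec`.
#' @export
pool_and_summarize <- function(samples, burn_in_frac = 0.1) {
  if (inherits(samples, "posterior_sample")) samples <- list(samples)
  if (!length(samples)) stop("need at least one posterior sample")
  spec <- samples[[1]]$spec
  for (s in samples)
    if (!identical(unclass(s$spec$map), unclass(spec$map)))
      stop("samples use different model parameterizations")
  nd <- vapply(samples, function(s) nrow(s$draws), 0)
  if (length(unique(nd)) != 1)
    stop("samples hold different numbers of draws per tree")
  pooled <- do.call(rbind, lapply(samples, function(s) {
    drop_n <- floor(burn_in_frac * nrow(s$draws))
    s$draws[(drop_n + 1):nrow(s$draws), , drop = FALSE]
  }))
  ne <- nrow(spec$map)
  # ECDF-based quantiles: pooling identical chains leaves them unchanged
  qs <- function(v) stats::quantile(v, c(0.5, 0.025, 0.975), names = FALSE,
                                    type = 2)
  rows <- list(); cons <- list()
  rate_class <- c("lambda", "lambda", "mu", "mu", "q", "q")
  state_of <- c(0L, 1L, 0L, 1L, 0L, 1L)
  cell_draws <- function(e, cc) pooled[, spec$map[e, cc]]
  for (cc in seq_len(6)) {
    for (e in seq_len(ne)) {
      q3 <- qs(cell_draws(e, cc))
      rows[[length(rows) + 1L]] <- data.frame(
        rate = rate_names[cc], class = rate_class[cc], state = state_of[cc],
        epoch = e, median = q3[1], lo = q3[2], hi = q3[3])
    }
    for (a in seq_len(ne)) for (b in seq_len(ne)) if (a != b)
      cons[[length(cons) + 1L]] <- data.frame(
        rate = rate_names[cc], state = state_of[cc], epoch_a = a, epoch_b = b,
        p_less = mean(cell_draws(b, cc) < cell_draws(a, cc)))
  }
  # net diversification per draw
  for (st in 0:1) {
    lam_c <- if (st == 0) 1L else 2L
    mu_c <- if (st == 0) 3L else 4L
    for (e in seq_len(ne)) {
      r_draw <- cell_draws(e, lam_c) - cell_draws(e, mu_c)
      q3 <- qs(r_draw)
      rows[[length(rows) + 1L]] <- data.frame(
        rate = paste0("netdiv", st), class = "netdiv", state = st, epoch = e,
        median = q3[1], lo = q3[2], hi = q3[3])
    }
    for (a in seq_len(ne)) for (b in seq_len(ne)) if (a != b)
      cons[[length(cons) + 1L]] <- data.frame(
        rate = paste0("netdiv", st), state = st, epoch_a = a, epoch_b = b,
        p_less = mean((cell_draws(b, lam_c) - cell_draws(b, mu_c)) <
                      (cell_draws(a, lam_c) - cell_draws(a, mu_c))))
  }
  empty_contrasts <- data.frame(rate = character(0), state = integer(0),
                                epoch_a = integer(0), epoch_b = integer(0),
                                p_less = numeric(0))
  structure(list(summary = do.call(rbind, rows),
                 contrasts = if (length(cons)) do.call(rbind, cons)
                             else empty_contrasts,
                 n_draws = nrow(pooled), n_trees = length(samples),
                 spec = spec, burn_in_frac = burn_in_frac),
            class = "epoch_summary")
}

#' Pooled 95% interval of one rate cell
#'
#' Convenience accessor on an `epoch_summary`.
#'
#' @param summary An `epoch_summary`.
#' @param rate Rate cell name (one of `lambda0, ..., q10`, `netdiv0`,
#'   `netdiv1`).
#' @param epoch Epoch index (1 = oldest).
#' @export
epoch_interval <- function(summary, rate, epoch) {
  s <- summary$summary
  row <- s[s$rate == rate & s$epoch == epoch, ]
  if (nrow(row) != 1) stop("no such rate cell")
  c(lo = row$lo, median = row$median, hi = row$hi)
}

#' Contrast probability between two epochs
#'
#' `P(rate in epoch_b < rate in epoch_a)` from the pooled draws.
#'
#' @inheritParams epoch_interval
#' @param epoch_a,epoch_b Epoch indices (1 = oldest).
#' @export
contrast_prob <- function(summary, rate, epoch_a, epoch_b) {
  cns <- summary$contrasts
  row <- cns[cns$rate == rate & cns$epoch_a == epoch_a &
             cns$epoch_b == epoch_b, ]
  if (nrow(row) != 1) stop("no such contrast")
  row$p_less
}

#' Effective sample size of a chain
#'
#' Initial-positive-sequence autocovariance estimator: the sample size
#' divided by the integrated autocorrelation time, truncating the lag sum
#' where consecutive autocorrelations stop being positive.
#'
#' @param x Numeric chain (one parameter's draws).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4 || stats::var(x) == 0) return(as.numeric(n))
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  tau <- 1
  for (k in seq_along(ac)) {
    if (ac[k] <= 0) break
    tau <- tau + 2 * ac[k]
  }
  min(n, n / tau)
}
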