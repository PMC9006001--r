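#' A constrained epoch-sliced BiSSE model
#'
#' A `model_spec` ties each of the `6 x n_epochs` rate cells (rows = epochs,
#' oldest first; columns `lambda0, lambda1, mu0, mu1, q01, q10`) to a free
#' parameter index. Cells sharing an index are constrained equal; the number
#' of free parameters is the number of distinct indices.
#'
#' The constructor builds the map from one mode pair per rate class
#' (`lambda`, `mu`, `q`):
#' * state mode `"tied"` (both states share a value) or `"free"`;
#' * time mode `"tied"` (constant through time), `"shift"` (the middle-epoch
#'   value differs while the flanking epochs share one value — the
#'   megaherbivore-gap shift with boundaries at 66 and 40 Ma), or `"free"`
#'   (one value per epoch). `"shift"` requires exactly 3 epochs.
#'
#' @param lambda,mu,q Length-2 character vectors `c(state_mode, time_mode)`.
#' @param grid An [epoch_grid()].
#' @param name Optional model name.
#' @return A `model_spec` with elements `name`, `map` (integer matrix
#'   `n_epochs x 6`), `k` (free parameters), `modes`, `grid`.
#' @export
model_spec <- function(lambda = c("tied", "tied"), mu = c("tied", "tied"),
                       q = c("tied", "tied"), grid = epoch_grid(),
                       name = NULL) {
  modes <- list(lambda = lambda, mu = mu, q = q)
  ne <- n_epochs(grid)
  map <- matrix(0L, ne, 6, dimnames = list(NULL, rate_names))
  nxt <- 0L
  for (cl in c("lambda", "mu", "q")) {
    sm <- match.arg(modes[[cl]][1], c("tied", "free"))
    tm <- match.arg(modes[[cl]][2], c("tied", "shift", "free"))
    if (tm == "shift" && ne != 3L)
      stop("time mode 'shift' needs exactly 3 epochs")
    n_state <- if (sm == "tied") 1L else 2L
    epoch_grp <- switch(tm, tied = rep(1L, ne), shift = c(1L, 2L, 1L),
                        free = seq_len(ne))
    n_time <- max(epoch_grp)
    cols <- switch(cl, lambda = c("lambda0", "lambda1"),
                   mu = c("mu0", "mu1"), q = c("q01", "q10"))
    for (s in 1:2) {
      sg <- if (sm == "tied") 1L else s
      map[, cols[s]] <- nxt + (sg - 1L) * n_time + epoch_grp
    }
    nxt <- nxt + n_state * n_time
  }
  if (is.null(name))
    name <- paste0("L", substr(lambda[1], 1, 1), substr(lambda[2], 1, 1),
                   "_M", substr(mu[1], 1, 1), substr(mu[2], 1, 1),
                   "_Q", substr(q[1], 1, 1), substr(q[2], 1, 1))
  structure(list(name = name, map = map, k = max(map), modes = modes,
                 grid = grid), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec `", x$name, "`: ", x$k, " free parameters, ",
      nrow(x$map), " epochs\n", sep = "")
  invisible(x)
}

#' Expand a free-parameter vector into a full rate set
#'
#' @param spec A [model_spec()].
#' @param theta Numeric vector of free parameters (rates/Myr).
#' @export
expand_rates <- function(spec, theta) {
  if (length(theta) != spec$k) stop("theta must have length ", spec$k)
  m <- matrix(theta[spec$map], nrow(spec$map), 6,
              dimnames = list(NULL, rate_names))
  structure(m, grid = spec$grid, class = c("rate_set", "matrix"))
}

#' Is one model nested in another?
#'
#' `nested` is a constrained version of `full` when the partition of rate
#' cells induced by `full` refines the one induced by `nested`: every pair of
#' cells equal under `full` is also equal under `nested`, and `nested` has
#' no more free parameters.
#'
#' @param nested,full [model_spec()] objects on the same grid.
#' @export
is_nested <- function(nested, full) {
  a <- as.integer(nested$map); b <- as.integer(full$map)
  if (length(a) != length(b)) return(FALSE)
  if (nested$k > full$k) return(FALSE)
  # every class of `full` maps into one class of `nested`
  all(tapply(a, b, function(v) length(unique(v)) == 1L))
}

#' The stepwise model ladder
#'
#' Builds the nested model space searched during selection: all eight
#' combinations of state-tied/state-free rates with time held constant, then
#' time-dependent extensions of the state-free model in which each rate class
#' (and combinations of classes) gains either a middle-epoch shift or full
#' epoch-dependence, ending with the fully free model (`6 x n_epochs`
#' parameters). With the default 3-epoch grid the ladder holds exactly 18
#' models, every one nested in the fully free model.
#'
#' @param grid An [epoch_grid()] with 3 epochs.
#' @return List of [model_spec()]s ordered by parameter count.
#' @export
enumerate_models <- function(grid = epoch_grid()) {
  if (n_epochs(grid) != 3L)
    stop("the default ladder is defined for 3 epochs")
  sf <- expand.grid(l = c("tied", "free"), m = c("tied", "free"),
                    q = c("tied", "free"), stringsAsFactors = FALSE)
  ladder <- lapply(seq_len(nrow(sf)), function(i)
    model_spec(c(sf$l[i], "tied"), c(sf$m[i], "tied"), c(sf$q[i], "tied"),
               grid))
  time_ext <- list(
    list(l = "shift", m = "tied",  q = "tied"),
    list(l = "free",  m = "tied",  q = "tied"),
    list(l = "tied",  m = "shift", q = "tied"),
    list(l = "tied",  m = "free",  q = "tied"),
    list(l = "tied",  m = "tied",  q = "shift"),
    list(l = "tied",  m = "tied",  q = "free"),
    list(l = "shift", m = "tied",  q = "shift"),
    list(l = "shift", m = "shift", q = "tied"),
    list(l = "shift", m = "shift", q = "shift"))
  ladder <- c(ladder, lapply(time_ext, function(e)
    model_spec(c("free", e$l), c("free", e$m), c("free", e$q), grid)))
  ladder <- c(ladder, list(model_spec(c("free", "free"), c("free", "free"),
                                      c("free", "free"), grid,
                                      name = "fully_free")))
  ladder[[1]]$name <- "fully_constrained"
  ladder[order(vapply(ladder, `[[`, 0, "k"))]
}

#' Maximum-likelihood fit of a constrained model
#'
#' Bounded optimization over log-rates from `n_restarts` jittered starts
#' around a Yule-rate heuristic; deterministic given `seed`.
#'
#' @param spec A [model_spec()].
#' @param phy,states,f As in [tree_loglik()] (states may be a named vector).
#' @param n_restarts Independent jittered starts.
#' @param seed Integer seed for the jitter.
#' @param lower,upper Rate bounds (events/lineage/Myr).
#' @param root_mode,condition_surv Root conventions, see [tree_loglik()].
#' @param rtol,atol Integrator tolerances used during optimization.
#' @return A `fit_result`: `spec`, `par` (named rates), `logLik`,
#'   `rates` (full [rate_set()]), `restart_logLik`, `convergence_gap`.
#' @export
fit_ml <- function(spec, phy, states, f = c(1, 1), n_restarts = 5, seed = 1L,
                   lower = 1e-8, upper = 10, root_mode = "obs",
                   condition_surv = TRUE, rtol = 1e-7, atol = 1e-9) {
  td <- bisse_tree_data(phy, states)
  if (td$ntip < 4) stop("need at least 4 tips")
  if (length(unique(stats::na.omit(td$tip_state))) < 2)
    warning("only one tip state present; state-specific rates are weakly identified")
  grid <- spec$grid
  nll <- function(lth) {
    r <- expand_rates(spec, exp(lth))
    ll <- tryCatch(
      tree_loglik_td(td, r, grid, f, root_mode, condition_surv, rtol, atol),
      error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  # heuristic centre: Yule speciation rate from tip count and crown age,
  # modest extinction, slow transitions
  T0 <- max(td$ages)
  lam0 <- max(lower * 10, log(max(td$ntip, 3) / 2) / T0)
  centre <- log(pmin(upper / 2, pmax(lower * 10, ifelse(
    grepl("lambda", rate_names), lam0,
    ifelse(grepl("mu", rate_names), lam0 / 4, 0.1 * lam0)))))
  centre_free <- vapply(seq_len(spec$k), function(j) {
    cells <- which(spec$map == j)
    mean(centre[(cells - 1) %/% nrow(spec$map) + 1])
  }, numeric(1))
  fits <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(r) {
      start <- centre_free + if (r == 1) 0 else stats::rnorm(spec$k, 0, 0.75)
      start <- pmin(log(upper), pmax(log(lower), start))
      try(stats::optim(start, nll, method = "L-BFGS-B",
                       lower = rep(log(lower), spec$k),
                       upper = rep(log(upper), spec$k),
                       control = list(maxit = 500)), silent = TRUE)
    })
  })
  ok <- !vapply(fits, inherits, TRUE, "try-error")
  fits <- fits[ok]
  if (!length(fits)) stop("all restarts failed to converge for ", spec$name)
  vals <- vapply(fits, `[[`, 0, "value")
  best <- fits[[which.min(vals)]]
  sorted <- sort(vals)
  structure(list(
    spec = spec, par = stats::setNames(exp(best$par), paste0("p", seq_len(spec$k))),
    logLik = -best$value,
    rates = expand_rates(spec, exp(best$par)),
    restart_logLik = -vals,
    convergence_gap = if (length(sorted) > 1) sorted[2] - sorted[1] else NA_real_),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result `", x$spec$name, "`: k = ", x$spec$k,
      ", logLik = ", format(x$logLik, digits = 8), "\n", sep = "")
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' @param nested,full `fit_result`s; `nested$spec` must be nested in
#'   `full$spec`.
#' @return List with `statistic` (clamped at 0), `df`, `p`.
#' @export
lrt <- function(nested, full) {
  if (!is_nested(nested$spec, full$spec))
    stop("`", nested$spec$name, "` is not nested in `", full$spec$name, "`")
  stat <- max(0, 2 * (full$logLik - nested$logLik))
  df <- full$spec$k - nested$spec$k
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Stepwise model selection by likelihood-ratio testing
#'
#' Starts from the fewest-parameter model and repeatedly tests it against
#' every richer ladder model it is nested in; if any comparison rejects at
#' level `alpha`, the search moves to the rejecting model with the fewest
#' parameters (ties broken by higher log-likelihood, then ladder order) and
#' repeats. The result is the model with the fewest parameters that no
#' richer nested comparison rejects: extra parameters are kept only when
#' they significantly improve fit.
#'
#' @param ladder List of [model_spec()]s (see [enumerate_models()]).
#' @param phy,states,f,n_restarts,seed,... Passed to [fit_ml()].
#' @param alpha LRT significance level.
#' @param fits Optional precomputed list of `fit_result`s matching `ladder`.
#' @return List with `best` (`fit_result`), `fits`, and `table` (one row per
#'   model: `model, k, logLik, AIC, df_vs_full, LRT_stat, p`).
#' @export
stepwise_select <- function(ladder, phy, states, f = c(1, 1), alpha = 0.05,
                            n_restarts = 3, seed = 1L, fits = NULL, ...) {
  if (!length(ladder)) stop("empty ladder")
  if (is.null(fits))
    fits <- lapply(seq_along(ladder), function(i)
      fit_ml(ladder[[i]], phy, states, f = f, n_restarts = n_restarts,
             seed = seed + i, ...))
  k <- vapply(ladder, `[[`, 0, "k")
  ll <- vapply(fits, `[[`, 0, "logLik")
  cur <- order(k, -ll)[1]
  repeat {
    richer <- which(k > k[cur] &
                    vapply(seq_along(ladder), function(j)
                      is_nested(ladder[[cur]], ladder[[j]]), TRUE))
    if (!length(richer)) break
    ps <- vapply(richer, function(j) lrt(fits[[cur]], fits[[j]])$p, 0)
    sig <- richer[ps < alpha]
    if (!length(sig)) break
    cur <- sig[order(k[sig], -ll[sig])][1]
  }
  ifull <- which.max(k)
  tab <- data.frame(
    model = vapply(ladder, `[[`, "", "name"), k = k, logLik = ll,
    AIC = 2 * k - 2 * ll,
    df_vs_full = k[ifull] - k,
    LRT_stat = pmax(0, 2 * (ll[ifull] - ll)),
    p = vapply(seq_along(ladder), function(i)
      if (i == ifull) 1 else
        tryCatch(lrt(fits[[i]], fits[[ifull]])$p,
                 error = function(e) NA_real_), numeric(1)))
  list(best = fits[[cur]], fits = fits, table = tab, alpha = alpha,
       selected = ladder[[cur]]$name)
}
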