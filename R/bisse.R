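#' Epoch grid for piecewise-constant rates
#'
#' An ordered set of epoch boundary ages (Myr before present, strictly
#' decreasing). Boundaries `c(66, 40)` define the default three epochs
#' `(root..66]`, `(66..40]` (the Palaeocene megaherbivore gap) and `(40..0]`.
#' An age falling exactly on a boundary belongs to the older epoch. An empty
#' boundary vector gives a single, time-constant epoch.
#'
#' @param boundaries Numeric vector of boundary ages; may be empty.
#' @return An `epoch_grid` object.
#' @export
epoch_grid <- function(boundaries = c(66, 40)) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries)) {
    if (any(boundaries <= 0) || anyNA(boundaries))
      stop("epoch boundaries must be positive ages")
    if (is.unsorted(rev(boundaries), strictly = TRUE))
      stop("epoch boundaries must be strictly decreasing ages")
  }
  structure(list(boundaries = boundaries), class = "epoch_grid")
}

#' Number of epochs in a grid
#' @param grid An [epoch_grid()].
#' @export
n_epochs <- function(grid) length(grid$boundaries) + 1L

#' Epoch index of one or more ages
#'
#' @param grid An [epoch_grid()].
#' @param age Ages (Myr before present).
#' @return Integer epoch indices, 1 = oldest epoch.
#' @export
epoch_index <- function(grid, age) {
  vapply(age, function(a) 1L + sum(grid$boundaries > a), integer(1))
}

#' Per-state, per-epoch rate set
#'
#' Holds the six BiSSE rates (speciation `lambda0`, `lambda1`; extinction
#' `mu0`, `mu1`; transitions `q01`, `q10`; all events/lineage/Myr) for each
#' epoch of a grid, rows ordered oldest epoch first.
#'
#' @param lambda0,lambda1,mu0,mu1,q01,q10 Rate vectors, each of length 1
#'   (recycled) or `n_epochs(grid)`.
#' @param grid An [epoch_grid()].
#' @return A `rate_set`: numeric matrix `n_epochs x 6` with the grid attached.
#' @export
rate_set <- function(lambda0, lambda1 = lambda0, mu0 = 0, mu1 = mu0,
                     q01 = 0, q10 = q01, grid = epoch_grid(numeric(0))) {
  ne <- n_epochs(grid)
  cols <- list(lambda0 = lambda0, lambda1 = lambda1, mu0 = mu0, mu1 = mu1,
               q01 = q01, q10 = q10)
  m <- vapply(cols, function(v) {
    if (!length(v) %in% c(1L, ne)) stop("rate vectors must have length 1 or n_epochs")
    rep_len(as.numeric(v), ne)
  }, numeric(ne))
  m <- matrix(m, nrow = ne, dimnames = list(NULL, names(cols)))
  if (anyNA(m) || any(!is.finite(m)) || any(m < 0))
    stop("all rates must be finite and >= 0")
  structure(m, grid = grid, class = c("rate_set", "matrix"))
}

rate_names <- c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")

#' Integrate the BiSSE equations along one branch
#'
#' Integrates the state `(E0, E1, D0, D1)` backward in time from `age_lo` up
#' to `age_hi`, splitting the integration exactly at every epoch boundary
#' crossed. `D` is rescaled into a log accumulator when it threatens
#' under/overflow.
#'
#' @param y Numeric length-4 state `(E0, E1, D0, D1)`.
#' @param age_lo,age_hi Age interval, `age_lo < age_hi` (Myr before present).
#' @param rates A [rate_set()].
#' @param grid Epoch grid; defaults to the grid attached to `rates`.
#' @param rtol,atol Relative/absolute integrator tolerances.
#' @return List with `y` (state at `age_hi`) and `log_scale`.
#' @export
bisse_integrate_branch <- function(y, age_lo, age_hi, rates,
                                   grid = attr(rates, "grid"),
                                   rtol = 1e-10, atol = 1e-12) {
  bisse_branch_cpp(as.numeric(y), age_lo, age_hi, unclass(rates),
                   grid$boundaries, rtol, atol)
}

# Precompute the tree-shaped data reused by every likelihood evaluation on
# the same tree: postorder edge list, node ages, tip states in tip order.
bisse_tree_data <- function(phy, states) {
  phy <- validate_tree(phy)
  st <- match_states(phy, states, allow_na = TRUE)
  po <- ape::reorder.phylo(phy, "postorder")
  list(edge = po$edge, ages = node_ages(phy), tip_state = st,
       ntip = length(phy$tip.label))
}

match_states <- function(phy, states, allow_na = FALSE) {
  if (!is.null(names(states))) {
    miss <- setdiff(phy$tip.label, names(states))
    if (length(miss))
      stop("no state for tips: ", paste(utils::head(miss, 5), collapse = ", "))
    states <- states[phy$tip.label]
  } else if (length(states) != length(phy$tip.label)) {
    stop("states must be named or match the number of tips")
  }
  st <- as.integer(states)
  bad <- !(st %in% c(0L, 1L)) & !is.na(st)
  if (any(bad)) stop("tip states must be 0, 1 or NA")
  if (!allow_na && anyNA(st)) stop("unknown tip states are not allowed here")
  st
}

#' Epoch-sliced BiSSE log-likelihood of tip states on a tree
#'
#' Post-order pruning: a tip observed in state `i` starts with
#' `D_i = f_i`, `D_j = 0` and `E_i(0) = 1 - f_i`; a tip with `NA` state starts
#' with `D_i = f_i` for both states. At each internal node
#' `D_i <- D_i^left * D_i^right * lambda_i` (the speciation rate of the
#' epoch containing the node age; the root node included). At the root the
#' two states are combined according to `root_mode`, and when
#' `condition_surv` is on the likelihood is divided by
#' `sum_i w_i * lambda_i * (1 - E_i)^2`, conditioning on the survival of both
#' root lineages.
#'
#' @param phy Validated ultrametric tree.
#' @param states Tip states: 0/1/`NA` vector named by tip label (or in tip
#'   order).
#' @param rates A [rate_set()].
#' @param grid Epoch grid (defaults to the one attached to `rates`).
#' @param f Sampling fractions `c(f0, f1)` in `(0, 1]`.
#' @param root_mode How root states are weighted: `"obs"` weights by the
#'   relative `D` values at the root, `"flat"` uses equal weights,
#'   `"state0"`/`"state1"` fix the root state.
#' @param condition_surv Condition on survival of both root lineages.
#' @param rtol,atol Integrator tolerances.
#' @return The log-likelihood (scalar; `-Inf` for impossible data).
#' @export
tree_loglik <- function(phy, states, rates, grid = attr(rates, "grid"),
                        f = c(1, 1),
                        root_mode = c("obs", "flat", "state0", "state1"),
                        condition_surv = TRUE, rtol = 1e-10, atol = 1e-12) {
  td <- bisse_tree_data(phy, states)
  tree_loglik_td(td, rates, grid, f, match.arg(root_mode), condition_surv,
                 rtol, atol)
}

# Likelihood on precomputed tree data (the hot path for fitting and MCMC).
tree_loglik_td <- function(td, rates, grid = attr(rates, "grid"), f = c(1, 1),
                           root_mode = "obs", condition_surv = TRUE,
                           rtol = 1e-10, atol = 1e-12) {
  if (any(f <= 0) || any(f > 1)) stop("sampling fractions must be in (0, 1]")
  pars <- unclass(rates)
  if (anyNA(pars) || any(pars < 0)) stop("rates must be finite and >= 0")
  res <- bisse_prune_cpp(td$edge, td$ages, td$tip_state, pars,
                         grid$boundaries, f[1], f[2], rtol, atol)
  D <- res$D
  E <- res$E
  if (anyNA(c(D, E)) || any(!is.finite(c(D, E))) || sum(D) <= 0) return(-Inf)
  w <- switch(root_mode,
    obs = D / sum(D),
    flat = c(0.5, 0.5),
    state0 = c(1, 0),
    state1 = c(0, 1),
    stop("unknown root_mode"))
  ll <- log(sum(w * D)) + res$log_scale
  if (condition_surv) {
    e <- epoch_index(grid, res$root_age)
    lam <- pars[e, c("lambda0", "lambda1")]
    denom <- sum(w * lam * (1 - E)^2)
    if (denom <= 0) return(-Inf)
    ll <- ll - log(denom)
  }
  as.numeric(ll)
}
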