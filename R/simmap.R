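#' A realized binary-state history painted on a tree
#'
#' Stores, for every edge of `phy`, the run lengths of time spent in each
#' state from the rootward end to the tipward end (a named numeric vector
#' with names `"0"`/`"1"`, as in the `maps` element of a stochastic map).
#' Construction validates the invariants: dwell times on each edge sum to the
#' edge length, states alternate along an edge, and states are consistent
#' across parent/child junctions (all daughters of a node start in the state
#' their parent edge ended in).
#'
#' @param phy A `phylo` object.
#' @param maps List (one element per row of `phy$edge`) of named run-length
#'   vectors.
#' @return A `character_history` object.
#' @export
character_history <- function(phy, maps) {
  ne <- nrow(phy$edge)
  if (length(maps) != ne) stop("need one map per edge")
  ntip <- length(phy$tip.label)
  node_state <- rep(NA_integer_, ntip + phy$Nnode)
  for (i in seq_len(ne)) {
    m <- maps[[i]]
    sts <- as.integer(names(m))
    if (length(m) == 0 || anyNA(sts) || any(!sts %in% 0:1))
      stop("edge ", i, ": map states must be named 0/1")
    if (any(m < 0)) stop("edge ", i, ": negative dwell time")
    if (length(sts) > 1 && any(diff(sts) == 0))
      stop("edge ", i, ": consecutive states must alternate")
    if (abs(sum(m) - phy$edge.length[i]) >
        1e-8 * max(1, phy$edge.length[i]))
      stop("edge ", i, ": dwell times do not sum to the edge length")
    node_state[phy$edge[i, 2]] <- sts[length(sts)]
  }
  root <- ntip + 1L
  # root state and junction consistency
  for (i in seq_len(ne)) {
    par <- phy$edge[i, 1]
    start <- as.integer(names(maps[[i]])[1])
    if (par == root) {
      if (is.na(node_state[root])) node_state[root] <- start
      else if (node_state[root] != start)
        stop("root daughters start in different states")
    } else if (node_state[par] != start) {
      stop("edge ", i, ": starts in state ", start,
           " but its parent node is in state ", node_state[par])
    }
  }
  structure(list(phy = phy, maps = maps, node_states = node_state),
            class = "character_history")
}

#' @rdname character_history
#' @param x A `character_history`.
#' @return `history_dwell_times`: total time spent in each state.
#' @export
history_dwell_times <- function(x) {
  out <- c("0" = 0, "1" = 0)
  for (m in x$maps)
    for (k in seq_along(m)) out[names(m)[k]] <- out[names(m)[k]] + m[[k]]
  out
}

#' @rdname character_history
#' @return `history_transitions`: counts of 0->1 and 1->0 change points.
#' @export
history_transitions <- function(x) {
  n01 <- 0L; n10 <- 0L
  for (m in x$maps) {
    sts <- as.integer(names(m))
    if (length(sts) > 1) {
      d <- diff(sts)
      n01 <- n01 + sum(d == 1L)
      n10 <- n10 + sum(d == -1L)
    }
  }
  c(n01 = n01, n10 = n10)
}

#' @rdname character_history
#' @return `history_change_points`: data frame of change points with ages.
#' @export
history_change_points <- function(x) {
  ages <- node_ages(x$phy)
  out <- list()
  for (i in seq_along(x$maps)) {
    m <- x$maps[[i]]
    if (length(m) < 2) next
    sts <- as.integer(names(m))
    a0 <- ages[x$phy$edge[i, 1]]
    cum <- cumsum(m)
    for (k in seq_len(length(m) - 1L))
      out[[length(out) + 1L]] <- data.frame(
        edge = i, age = a0 - cum[[k]], from = sts[k], to = sts[k + 1L])
  }
  if (!length(out))
    return(data.frame(edge = integer(0), age = numeric(0),
                      from = integer(0), to = integer(0)))
  do.call(rbind, out)
}

#' @export
print.character_history <- function(x, ...) {
  tr <- history_transitions(x)
  cat("Binary character history on", length(x$phy$tip.label), "tips:",
      tr["n01"], "gains,", tr["n10"], "losses\n")
  invisible(x)
}

# Exact 2-state transition probability matrix for Q = [[-a, a], [b, -b]].
mk_pmat <- function(a, b, t) {
  s <- a + b
  if (s == 0) return(diag(2))
  e <- exp(-s * t)
  matrix(c(b + a * e, b - b * e,      # column 1: P(.->0)
           a - a * e, a + b * e), 2, 2) / s
}

# Post-order scaled partial likelihoods of a binary character.
# Returns L (nnode x 2, each internal row scaled to sum 1 at combination
# time), log scaling, and the postorder tree used.
mk_partials <- function(phy, states, a, b) {
  ntip <- length(phy$tip.label)
  st <- match_states(phy, states, allow_na = TRUE)
  nn <- ntip + phy$Nnode
  L <- matrix(1, nn, 2)
  for (i in seq_len(ntip)) {
    if (is.na(st[i])) next
    L[i, ] <- if (st[i] == 0) c(1, 0) else c(0, 1)
  }
  po <- ape::reorder.phylo(phy, "postorder")
  logcomp <- 0
  done <- rep(FALSE, nn)
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; ch <- po$edge[k, 2]
    P <- mk_pmat(a, b, po$edge.length[k])
    contrib <- as.numeric(P %*% L[ch, ])
    L[par, ] <- L[par, ] * contrib
    if (done[par]) {              # both children in: rescale
      sc <- sum(L[par, ])
      if (sc > 0) { L[par, ] <- L[par, ] / sc; logcomp <- logcomp + log(sc) }
    }
    done[par] <- TRUE
  }
  list(L = L, logcomp = logcomp, root = ntip + 1L)
}

mk_root_prior <- function(a, b, prior = c("stationary", "equal")) {
  prior <- match.arg(prior)
  if (prior == "equal" || a + b == 0) return(c(0.5, 0.5))
  c(b, a) / (a + b)
}

#' Log-likelihood of a binary trait under the 2-state Markov (Mk) model
#'
#' @param phy Validated tree.
#' @param states Tip states (0/1/`NA`), named by tip or in tip order.
#' @param q01,q10 Gain and loss rates.
#' @param root_prior `"stationary"` (of the rate matrix) or `"equal"`.
#' @export
mk_loglik <- function(phy, states, q01, q10,
                      root_prior = c("stationary", "equal")) {
  pl <- mk_partials(phy, states, q01, q10)
  pi0 <- mk_root_prior(q01, q10, match.arg(root_prior))
  val <- sum(pi0 * pl$L[pl$root, ])
  if (val <= 0) return(-Inf)
  log(val) + pl$logcomp
}

#' Fit a 2-state Markov model of binary trait evolution
#'
#' Maximum-likelihood transition rates by bounded optimization over log
#' rates. `"ARD"` (default) estimates gain and loss separately; `"ER"`
#' constrains them equal.
#'
#' @inheritParams mk_loglik
#' @param model `"ARD"` or `"ER"`.
#' @param lower,upper Rate bounds (events/lineage/Myr).
#' @return List with `q01`, `q10`, `logLik`, `model`, `root_prior`.
#' @export
fit_mk <- function(phy, states, model = c("ARD", "ER"),
                   root_prior = c("stationary", "equal"),
                   lower = 1e-8, upper = 100) {
  model <- match.arg(model)
  root_prior <- match.arg(root_prior)
  phy <- validate_tree(phy)
  st <- match_states(phy, states, allow_na = TRUE)
  if (length(unique(stats::na.omit(st))) < 2)
    warning("only one state present among tips; rate MLEs sit at the boundary")
  # start: parsimony-flavoured guess, changes per unit tree length
  tl <- sum(phy$edge.length)
  q0 <- max(lower * 10, min(upper / 10, 0.5 * length(st) / max(tl, 1e-8)))
  npar <- if (model == "ARD") 2L else 1L
  fn <- function(lp) {
    q <- exp(lp)
    if (model == "ER") q <- c(q, q)
    -mk_loglik(phy, st, q[1], q[2], root_prior)
  }
  best <- NULL
  for (start in list(rep(log(q0), npar), rep(log(q0 / 10), npar),
                     rep(log(q0 * 5), npar))) {
    o <- try(stats::optim(start, fn, method = "L-BFGS-B",
                          lower = rep(log(lower), npar),
                          upper = rep(log(upper), npar)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("Mk optimization failed")
  q <- exp(best$par)
  if (model == "ER") q <- c(q, q)
  list(q01 = q[1], q10 = q[2], logLik = -best$value, model = model,
       root_prior = root_prior)
}

#' Draw stochastic character maps of a binary trait
#'
#' Samples full character histories consistent with the tip data and an Mk
#' model: node states are drawn from their conditional distributions (root
#' from prior x partial likelihoods, then pre-order conditional draws), and
#' within-branch histories conditional on the branch endpoints are drawn by
#' uniformization. Node posterior probabilities are the frequencies of
#' sampled states across maps.
#'
#' @inheritParams mk_loglik
#' @param params List with `q01`, `q10` (e.g. from [fit_mk()]).
#' @param n_maps Number of maps (500 mirrors common practice).
#' @param seed Integer seed; same seed gives identical maps.
#' @return List with `histories` (list of [character_history()]),
#'   `node_posterior` (data frame `node_id, age_ma, pp_state0, pp_state1`),
#'   `origin_counts` (0->1 change points per map), and `params`.
#' @export
sample_histories <- function(phy, states, params, n_maps = 500,
                             root_prior = c("stationary", "equal"),
                             seed = 1L) {
  root_prior <- match.arg(root_prior)
  phy <- validate_tree(phy)
  st <- match_states(phy, states, allow_na = TRUE)
  a <- params$q01; b <- params$q10
  stopifnot(is.finite(a), is.finite(b), a >= 0, b >= 0)
  pl <- mk_partials(phy, st, a, b)
  pi0 <- mk_root_prior(a, b, root_prior)
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  pre <- ape::reorder.phylo(phy, "cladewise")
  key <- paste(phy$edge[, 1], phy$edge[, 2])
  pre_to_phy <- match(paste(pre$edge[, 1], pre$edge[, 2]), key)
  Pmats <- lapply(seq_len(nrow(pre$edge)),
                  function(i) mk_pmat(a, b, pre$edge.length[i]))
  with_seed(seed, {
    hists <- vector("list", n_maps)
    node_draws <- matrix(0L, n_maps, nn)
    for (m in seq_len(n_maps)) {
      ns <- integer(nn)
      pr <- pi0 * pl$L[pl$root, ]
      ns[pl$root] <- draw_state(pr)
      maps <- vector("list", nrow(phy$edge))
      for (i in seq_len(nrow(pre$edge))) {
        par <- pre$edge[i, 1]; ch <- pre$edge[i, 2]
        P <- Pmats[[i]]
        w <- P[ns[par] + 1L, ] * pl$L[ch, ]
        ns[ch] <- draw_state(w)
        maps[[pre_to_phy[i]]] <- mk_bridge(ns[par], ns[ch],
                                           pre$edge.length[i], a, b, P)
      }
      hists[[m]] <- character_history(phy, maps)
      node_draws[m, ] <- ns
    }
    pp1 <- colMeans(node_draws)
    ages <- node_ages(phy)
    internal <- (ntip + 1L):nn
    node_posterior <- data.frame(node_id = internal, age_ma = ages[internal],
                                 pp_state0 = 1 - pp1[internal],
                                 pp_state1 = pp1[internal])
    list(histories = hists,
         node_posterior = node_posterior,
         origin_counts = vapply(hists, function(h)
           unname(history_transitions(h)["n01"]), numeric(1)),
         params = list(q01 = a, q10 = b, root_prior = root_prior),
         seed = seed)
  })
}

draw_state <- function(w) {
  s <- sum(w)
  if (s <= 0) stop("conditional state distribution is degenerate")
  if (stats::runif(1) < w[1] / s) 0L else 1L
}

# Sample a 2-state path on a branch of length t conditional on endpoint
# states (i, j) by uniformization.  Returns a named run-length vector.
mk_bridge <- function(i, j, t, a, b, P = mk_pmat(a, b, t)) {
  if (a + b == 0 || t <= 0) {
    if (i != j) stop("impossible endpoint pair with zero rates")
    return(stats::setNames(t, as.character(i)))
  }
  om <- max(a, b)
  R <- diag(2) + matrix(c(-a, b, a, -b), 2, 2) / om   # uniformized chain
  pij <- P[i + 1L, j + 1L]
  # number of uniformized jumps: P(n) = dpois(n, om t) (R^n)_ij / pij
  u <- stats::runif(1)
  Rpow <- list(diag(2))               # R^0
  n <- 0L
  cum <- stats::dpois(0, om * t) * Rpow[[1]][i + 1L, j + 1L] / pij
  while (cum < u && n < 10000L) {
    n <- n + 1L
    Rpow[[n + 1L]] <- Rpow[[n]] %*% R
    cum <- cum + stats::dpois(n, om * t) * Rpow[[n + 1L]][i + 1L, j + 1L] / pij
  }
  if (n == 0L) return(stats::setNames(t, as.character(i)))
  # states at the n jumps (the n-th must be j)
  sts <- integer(n)
  cur <- i
  for (k in seq_len(n)) {
    rem <- n - k
    w <- R[cur + 1L, ] * Rpow[[rem + 1L]][, j + 1L]
    sts[k] <- draw_state(w)
    cur <- sts[k]
  }
  times <- sort(stats::runif(n, 0, t))
  # drop virtual (self) jumps
  keep <- c(sts[1] != i, diff(sts) != 0)
  times <- times[keep]; sts <- sts[keep]
  seg <- diff(c(0, times, t))
  names(seg) <- as.character(c(i, sts))
  seg
}

#' Count independent origins of a state in a character history
#'
#' @param history A [character_history()].
#' @param target State whose gains are counted (default 1): the number of
#'   change points into `target` across all branches. A root already in the
#'   target state contributes no origin.
#' @export
count_origins <- function(history, target = 1L) {
  tr <- history_transitions(history)
  if (target == 1L) unname(tr["n01"]) else unname(tr["n10"])
}

#' Summarize origin counts across stochastic maps
#'
#' @param counts Integer vector of per-map origin counts (e.g.
#'   `sample_histories()$origin_counts`).
#' @return List with `min`, `median`, `mode`, and the full `table`.
#' @export
summarize_origins <- function(counts) {
  tab <- table(counts)
  list(min = min(counts), median = stats::median(counts),
       mode = as.integer(names(tab)[which.max(tab)]), table = tab)
}

#' Serialize a character history to per-branch change-point JSON
#'
#' One record per edge: parent/child node ids, start state, and the ordered
#' change points (age, new state) on that branch.
#'
#' @param x A [character_history()].
#' @param file Optional path; if `NULL` the JSON string is returned.
#' @export
history_to_json <- function(x, file = NULL) {
  ages <- node_ages(x$phy)
  recs <- lapply(seq_along(x$maps), function(i) {
    m <- x$maps[[i]]
    sts <- as.integer(names(m))
    cum <- cumsum(m)
    n <- length(m)
    list(edge = i,
         parent = x$phy$edge[i, 1], child = x$phy$edge[i, 2],
         start_state = sts[1], end_state = sts[n],
         change_points = if (n > 1)
           data.frame(age = ages[x$phy$edge[i, 1]] - unname(cum[-n]),
                      to_state = sts[-1])
         else data.frame(age = numeric(0), to_state = integer(0)))
  })
  if (is.null(file))
    jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA)
  else {
    jsonlite::write_json(recs, file, auto_unbox = TRUE, digits = NA)
    invisible(file)
  }
}
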