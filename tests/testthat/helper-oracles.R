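# Shared fixtures and independent oracles for the test suite.

with_seed <- epochsse:::with_seed   # RNG-preserving seeding helper

# A reproducible pure-birth fixture tree of roughly `n` tips, rescaled to
# crown age `age`.
fixture_tree <- function(n, age = 30, seed = 1) {
  phy <- with_seed(seed, ape::rphylo(n, birth = 0.2, death = 0))
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * age / depth
  validate_tree(phy)
}

fixture_states <- function(phy, p1 = 0.4, seed = 1) {
  with_seed(seed, stats::setNames(
    stats::rbinom(length(phy$tip.label), 1, p1), phy$tip.label))
}

# --- constant-rate birth-death log-likelihood, closed form -----------------
# Pruning with exact per-branch propagation factors: with E(0) = 0,
#   E(a) = mu (e^{ra} - 1) / (lambda e^{ra} - mu),        r = lambda - mu,
#   D(a_p)/D(a_c) = e^{-r (a_p - a_c)} (1 - E(a_p))^2 / (1 - E(a_c))^2,
# one lambda factor per internal node (root included), no survival
# conditioning.  Independent of the package's ODE machinery.
bd_loglik_closed <- function(phy, lambda, mu) {
  r <- lambda - mu
  Efun <- function(a) {
    if (mu == 0) return(rep(0, length(a)))
    if (abs(r) < 1e-12) return(mu * a / (1 + mu * a))
    mu * (exp(r * a) - 1) / (lambda * exp(r * a) - mu)
  }
  ages <- node_ages(phy)
  ll <- 0
  for (k in seq_len(nrow(phy$edge))) {
    ap <- ages[phy$edge[k, 1]]; ac <- ages[phy$edge[k, 2]]
    ll <- ll + (-r * (ap - ac)) +
      2 * (log(1 - Efun(ap)) - log(1 - Efun(ac)))
  }
  ll + phy$Nnode * log(lambda)
}

# --- Mk log-likelihood via matrix exponentials -----------------------------
# Pruning with Matrix::expm on the 2x2 generator; independent of the
# package's closed-form transition probabilities.
mk_loglik_expm <- function(phy, states, q01, q10, prior = c(0.5, 0.5)) {
  Q <- matrix(c(-q01, q10, q01, -q10), 2, 2)
  st <- states[phy$tip.label]
  ntip <- length(phy$tip.label)
  L <- matrix(1, ntip + phy$Nnode, 2)
  for (i in seq_len(ntip))
    if (!is.na(st[i])) L[i, ] <- if (st[i] == 0) c(1, 0) else c(0, 1)
  po <- ape::reorder.phylo(phy, "postorder")
  logcomp <- 0
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; ch <- po$edge[k, 2]
    P <- as.matrix(Matrix::expm(Q * po$edge.length[k]))
    L[par, ] <- L[par, ] * as.numeric(P %*% L[ch, ])
    m <- max(L[par, ])
    if (m > 0) { L[par, ] <- L[par, ] / m; logcomp <- logcomp + log(m) }
  }
  log(sum(prior * L[ntip + 1L, ])) + logcomp
}

# --- fixed-step RK4 for the BiSSE equations --------------------------------
# Independent integrator used to check the adaptive solver; `pars` is one
# epoch row (lambda0, lambda1, mu0, mu1, q01, q10).
bisse_rk4 <- function(y, t0, t1, pars, h = 1e-3) {
  f <- function(y) {
    la0 <- pars[1]; la1 <- pars[2]; mu0 <- pars[3]; mu1 <- pars[4]
    q01 <- pars[5]; q10 <- pars[6]
    c(mu0 - (la0 + mu0 + q01) * y[1] + la0 * y[1]^2 + q01 * y[2],
      mu1 - (la1 + mu1 + q10) * y[2] + la1 * y[2]^2 + q10 * y[1],
      -(la0 + mu0 + q01) * y[3] + q01 * y[4] + 2 * la0 * y[1] * y[3],
      -(la1 + mu1 + q10) * y[4] + q10 * y[3] + 2 * la1 * y[2] * y[4])
  }
  n <- ceiling((t1 - t0) / h)
  h <- (t1 - t0) / n
  for (i in seq_len(n)) {
    k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# --- exact marginal ancestral posteriors for the Mk model ------------------
# Re-rooting oracle: the marginal posterior of an internal node's state is
# prior x partial likelihood at the root of the tree re-rooted at that node
# (valid because the 2-state chain is reversible w.r.t. its stationary
# distribution).
mk_marginals_reroot <- function(phy, states, q01, q10) {
  ntip <- length(phy$tip.label)
  pi0 <- if (q01 + q10 == 0) c(0.5, 0.5) else c(q10, q01) / (q01 + q10)
  internal <- ntip + seq_len(phy$Nnode)
  t(vapply(internal, function(nd) {
    rt <- if (nd == ntip + 1L) phy else ape::root(phy, node = nd)
    pl <- epochsse:::mk_partials(rt, states[rt$tip.label], q01, q10)
    w <- pi0 * pl$L[length(rt$tip.label) + 1L, ]
    w / sum(w)
  }, numeric(2)))
}

# --- exact joint-ML ancestral states under Brownian motion -----------------
# Minimizing sum over edges of (x_u - x_v)^2 / len is a sparse linear system
# in the internal values (the weighted tree Laplacian); solved directly,
# independent of the pruning/re-rooting implementation.
bm_joint_ml <- function(phy, x) {
  ntip <- length(phy$tip.label)
  nint <- phy$Nnode
  A <- matrix(0, nint, nint)
  b <- numeric(nint)
  xv <- x[phy$tip.label]
  for (k in seq_len(nrow(phy$edge))) {
    u <- phy$edge[k, 1]; v <- phy$edge[k, 2]
    w <- 1 / phy$edge.length[k]
    iu <- u - ntip
    if (v <= ntip) {
      A[iu, iu] <- A[iu, iu] + w
      b[iu] <- b[iu] + w * xv[v]
    } else {
      iv <- v - ntip
      A[iu, iu] <- A[iu, iu] + w
      A[iv, iv] <- A[iv, iv] + w
      A[iu, iv] <- A[iu, iv] - w
      A[iv, iu] <- A[iv, iu] - w
    }
  }
  as.numeric(solve(A, b))
}

# Batch-means Monte-Carlo standard error of a chain mean.
mcse_batch <- function(x, n_batch = 20) {
  bs <- floor(length(x) / n_batch)
  m <- vapply(seq_len(n_batch), function(i)
    mean(x[((i - 1) * bs + 1):(i * bs)]), numeric(1))
  stats::sd(m) / sqrt(n_batch)
}
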