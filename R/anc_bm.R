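#' Maximum-likelihood ancestral states of a continuous trait under Brownian
#' motion
#'
#' Each internal node's estimate is the Brownian-motion ML root state of the
#' tree re-rooted at that node (equivalently the generalized-least-squares
#' estimate given the tips). The diffusion rate `sigma2` is estimated by ML
#' on the original tree; each node's estimation variance is the re-rooted
#' root variance scaled by the ML `sigma2`, and the 95% CI is
#' `estimate +/- 1.96 * sqrt(variance)`.
#'
#' The tree need not be ultrametric (fossil pseudo-tips are allowed). Every
#' tip must carry a value; prune beforehand if not.
#'
#' @param phy A `phylo` object (>= 3 tips).
#' @param x Numeric tip values named by tip label (or in tip order).
#' @return An `anc_bm` object: data frame `nodes` with
#'   `node_id, age_ma, estimate, var, ci_lo, ci_hi`, plus `sigma2`,
#'   `tip_values`, and the tree.
#' @export
anc_bm_ml <- function(phy, x) {
  ntip <- length(phy$tip.label)
  if (ntip < 3) stop("need at least 3 tips with values")
  x <- match_tip_values(phy, x)
  pr <- bm_prune(phy, x)
  sigma2 <- pr$rss / ntip           # ML (not REML), conditional on ML root
  internal <- ntip + seq_len(phy$Nnode)
  est <- numeric(phy$Nnode); vfac <- numeric(phy$Nnode)
  for (k in seq_along(internal)) {
    nd <- internal[k]
    rt <- if (nd == ntip + 1L) phy else ape::root(phy, node = nd)
    p <- bm_prune(rt, x[rt$tip.label])
    est[k] <- p$root_est
    vfac[k] <- p$root_v
  }
  v <- sigma2 * vfac
  ages <- node_ages(phy)
  nodes <- data.frame(node_id = internal, age_ma = ages[internal],
                      estimate = est, var = v,
                      ci_lo = est - 1.96 * sqrt(v),
                      ci_hi = est + 1.96 * sqrt(v))
  structure(list(nodes = nodes, sigma2 = sigma2, tip_values = x, phy = phy),
            class = "anc_bm")
}

match_tip_values <- function(phy, x) {
  if (!is.null(names(x))) {
    miss <- setdiff(phy$tip.label, names(x))
    if (length(miss))
      stop("no value for tips: ", paste(utils::head(miss, 5), collapse = ", "))
    x <- x[phy$tip.label]
  } else if (length(x) != length(phy$tip.label)) {
    stop("tip values must be named or match the number of tips")
  }
  if (anyNA(x)) stop("tip values must not be missing; prune first")
  stats::setNames(as.numeric(x), phy$tip.label)
}

# Felsenstein pruning for BM: ML root state, root variance factor (in units
# of sigma2), and the GLS residual sum of squares (sum of squared
# standardized contrasts).  Handles multifurcations and degree-2 nodes
# (re-rooted trees) and zero-length pendants, which pin a node's value
# exactly (used for fossil constraints).
bm_prune <- function(phy, x) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  xh <- numeric(nn); v <- numeric(nn)
  xh[seq_len(ntip)] <- as.numeric(x)
  po <- ape::reorder.phylo(phy, "postorder")
  prec <- numeric(nn); wsum <- numeric(nn); ssq <- numeric(nn)
  pinned <- rep(FALSE, nn); pin_val <- numeric(nn)
  rss <- 0
  finalize <- function(nd) {
    if (pinned[nd]) {
      xh[nd] <<- pin_val[nd]; v[nd] <<- 0
    } else {
      if (prec[nd] <= 0) stop("internal node with no informative children")
      xh[nd] <<- wsum[nd] / prec[nd]
      v[nd] <<- 1 / prec[nd]
    }
    rss <<- rss + (ssq[nd] - 2 * xh[nd] * wsum[nd] + xh[nd]^2 * prec[nd])
  }
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; ch <- po$edge[k, 2]
    if (ch > ntip) finalize(ch)        # postorder: subtree of ch is complete
    V <- v[ch] + po$edge.length[k]
    if (V == 0) {
      if (pinned[par] && pin_val[par] != xh[ch])
        stop("conflicting zero-length pendants pin one node to two values; ",
             "sigma2 is unidentifiable")
      pinned[par] <- TRUE; pin_val[par] <- xh[ch]
    } else {
      prec[par] <- prec[par] + 1 / V
      wsum[par] <- wsum[par] + xh[ch] / V
      ssq[par] <- ssq[par] + xh[ch]^2 / V
    }
  }
  root <- po$edge[nrow(po$edge), 1]
  finalize(root)
  list(root_est = xh[root], root_v = v[root], rss = rss)
}

#' A fossil constraint on the ancestral path of an extant lineage
#'
#' @param tip Label of the extant tip whose root-to-tip path is constrained.
#' @param age Age (Myr before present) at which the path is pinned.
#' @param value Trait value (log cm) the reconstruction must pass through.
#' @export
fossil_constraint <- function(tip, age, value) {
  stopifnot(is.finite(age), age >= 0, is.finite(value))
  structure(list(tip = tip, age = age, value = value),
            class = "fossil_constraint")
}

#' Graft a fossil constraint onto a tree
#'
#' Implements a fixed ancestral value by grafting a zero-length pendant
#' pseudo-tip carrying the constraint value onto the constrained lineage at
#' the constraint age. The reconstruction then proceeds unchanged and is
#' forced through the value at that age exactly.
#'
#' @param phy Validated tree.
#' @param x Named tip values.
#' @param constraint A [fossil_constraint()].
#' @param label Label for the pseudo-tip.
#' @return List with the modified `phy` and `x`.
#' @export
apply_fossil_constraint <- function(phy, x, constraint,
                                    label = "fossil_constraint") {
  stopifnot(inherits(constraint, "fossil_constraint"))
  x <- match_tip_values(phy, x)
  tip_num <- match(constraint$tip, phy$tip.label)
  if (is.na(tip_num)) stop("tip `", constraint$tip, "` not in tree")
  ages <- node_ages(phy)
  # walk the path tip -> root, find the edge spanning the constraint age
  node <- tip_num
  edge_idx <- NA_integer_
  while (TRUE) {
    k <- which(phy$edge[, 2] == node)
    if (!length(k)) break
    par <- phy$edge[k, 1]
    if (constraint$age >= ages[node] && constraint$age <= ages[par]) {
      edge_idx <- k
      break
    }
    node <- par
  }
  if (is.na(edge_idx))
    stop("constraint age ", constraint$age,
         " does not lie on the root-to-tip path of `", constraint$tip, "`")
  new <- graft_zero_tip(phy, edge_idx, constraint$age, label)
  x2 <- c(x, stats::setNames(constraint$value, label))
  list(phy = new, x = x2[new$tip.label])
}

# Insert a node at `age` on edge `edge_idx` and hang a zero-length tip off it.
graft_zero_tip <- function(phy, edge_idx, age, label) {
  ntip <- length(phy$tip.label)
  ages <- node_ages(phy)
  par <- phy$edge[edge_idx, 1]; ch <- phy$edge[edge_idx, 2]
  # renumber: tips 1..ntip keep, new tip = ntip+1, old internals shift by +1
  shift <- function(n) ifelse(n > ntip, n + 1L, n)
  edge <- apply(phy$edge, 2, shift)
  len <- phy$edge.length
  new_tip <- ntip + 1L
  new_node <- ntip + 1L + phy$Nnode + 1L
  # split the edge
  upper <- ages[par] - age       # parent -> new node
  lower <- age - ages[ch]        # new node -> child
  edge[edge_idx, ] <- c(shift(par), new_node)
  len[edge_idx] <- upper
  edge <- rbind(edge, c(new_node, shift(ch)), c(new_node, new_tip))
  len <- c(len, lower, 0)
  out <- list(edge = edge, edge.length = len,
              tip.label = c(phy$tip.label, label),
              Nnode = phy$Nnode + 1L)
  class(out) <- "phylo"
  ape::reorder.phylo(out, "cladewise")
}

#' Traitgram coordinates with fossil overlay
#'
#' Projects the reconstruction into (age, trait) space: one row per tip
#' (age 0, observed value), per internal node (ML estimate with CI), per
#' edge sample (linear interpolation between the endpoint estimates), and
#' per fossil (plotted at the midpoint of its epoch, size log-transformed
#' consistently with the tips; seed measurements are flagged as minimum size
#' estimates and join the overlay only).
#'
#' @param recon An [anc_bm_ml()] result.
#' @param fossils Optional fossil table (see [read_fossil_table()]).
#' @param edge_samples Interpolation points per edge.
#' @return Data frame `age_ma, value, type, label, ci_lo, ci_hi, is_minimum`.
#' @export
traitgram_table <- function(recon, fossils = NULL, edge_samples = 20) {
  phy <- recon$phy
  ntip <- length(phy$tip.label)
  ages <- node_ages(phy)
  node_val <- numeric(ntip + phy$Nnode)
  node_val[seq_len(ntip)] <- recon$tip_values
  node_val[recon$nodes$node_id] <- recon$nodes$estimate
  rows <- list(
    data.frame(age_ma = 0, value = recon$tip_values, type = "tip",
               label = phy$tip.label, ci_lo = NA_real_, ci_hi = NA_real_,
               is_minimum = FALSE),
    data.frame(age_ma = recon$nodes$age_ma, value = recon$nodes$estimate,
               type = "node", label = as.character(recon$nodes$node_id),
               ci_lo = recon$nodes$ci_lo, ci_hi = recon$nodes$ci_hi,
               is_minimum = FALSE))
  if (edge_samples > 0) {
    sm <- lapply(seq_len(nrow(phy$edge)), function(i) {
      par <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
      s <- seq(0, 1, length.out = edge_samples + 2L)
      a <- ages[par] + s * (ages[ch] - ages[par])
      vl <- node_val[par] + s * (node_val[ch] - node_val[par])
      data.frame(age_ma = a[-c(1, length(a))], value = vl[-c(1, length(a))],
                 type = "edge_sample", label = as.character(i),
                 ci_lo = NA_real_, ci_hi = NA_real_, is_minimum = FALSE)
    })
    rows <- c(rows, sm)
  }
  if (!is.null(fossils) && nrow(fossils)) {
    fossils <- validate_fossil_table(fossils)
    size <- ifelse(is.na(fossils$length_cm), fossils$width_cm,
                   fossils$length_cm)
    rows <- c(rows, list(data.frame(
      age_ma = fossils$age_mid_ma, value = log(size), type = "fossil",
      label = fossils$taxon, ci_lo = NA_real_, ci_hi = NA_real_,
      is_minimum = fossils$organ == "seed")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
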