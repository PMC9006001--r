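#' Simulation configuration for state- and epoch-dependent birth-death trees
#'
#' @param rates A [rate_set()] (per-epoch BiSSE rates used forward in time).
#' @param grid Epoch grid; defaults to the grid attached to `rates`.
#' @param origin `"crown"` starts with two lineages at `origin_age` (both in
#'   the root state) and conditions on both crown lineages leaving surviving
#'   descendants, matching the likelihood's survival conditioning. `"stem"`
#'   starts with a single lineage and applies no such conditioning.
#' @param origin_age Age (Myr before present) of the crown/stem origin.
#' @param root_state Root state 0 or 1, or a probability of state 1 in
#'   `[0, 1]` from which the root state is drawn per attempt.
#' @param tip_window Acceptance window `c(min, max)` on the number of
#'   surviving tips; attempts outside the window are rejected and redrawn.
#' @param max_attempts Attempts before giving up.
#' @param max_lineages Hard cap on concurrently alive lineages (guards
#'   against supercritical blow-up).
#' @export
sim_config <- function(rates, grid = attr(rates, "grid"),
                       origin = c("crown", "stem"), origin_age = 100,
                       root_state = 0, tip_window = c(2, Inf),
                       max_attempts = 1000, max_lineages = 50000) {
  origin <- match.arg(origin)
  if (origin_age <= 0) stop("origin age must be > 0")
  if (length(tip_window) != 2 || tip_window[1] > tip_window[2] ||
      tip_window[1] < 2)
    stop("tip window must be c(min >= 2, max >= min)")
  structure(list(rates = rates, grid = grid, origin = origin,
                 origin_age = origin_age, root_state = root_state,
                 tip_window = tip_window, max_attempts = max_attempts,
                 max_lineages = max_lineages),
            class = "sim_config")
}

#' Simulate a tree under the epoch-sliced BiSSE model
#'
#' Forward-time Gillespie simulation: every lineage in state `i` waits an
#' exponential time at total rate `lambda_i + mu_i + q_ij` under the rates of
#' the current epoch, and the event type and lineage are chosen
#' proportionally to their rates. Rates switch exactly when the simulation
#' clock crosses an epoch boundary. Extinct subtrees are pruned; the
#' surviving, ultrametric tree is returned together with the full event log
#' (the true character history). Attempts are rejected and redrawn until the
#' surviving tip count falls inside the acceptance window (and, for crown
#' simulations, both crown lineages survive).
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; all randomness flows through it.
#' @return List with `phy` (ultrametric `phylo`), `tip_states` (named 0/1),
#'   `transitions` (event log of character changes on the surviving tree,
#'   with ages), `history` (a [character_history()] painted on `phy`),
#'   `root_state`, `n_attempts`, `seed`.
#' @export
simulate_bisse_tree <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    for (attempt in seq_len(cfg$max_attempts)) {
      rs <- cfg$root_state
      if (rs > 0 && rs < 1) rs <- stats::rbinom(1, 1, rs)
      sim <- sim_bisse_once(cfg, as.integer(rs))
      if (is.null(sim)) next
      ntip <- length(sim$phy$tip.label)
      if (ntip < cfg$tip_window[1] || ntip > cfg$tip_window[2]) next
      sim$n_attempts <- attempt
      sim$seed <- seed
      return(sim)
    }
    stop("tip-count acceptance window not reached in ", cfg$max_attempts,
         " attempts")
  })
}

# One forward simulation attempt; NULL on rejection (total extinction, a dead
# crown lineage, or the lineage cap).
sim_bisse_once <- function(cfg, root_state) {
  T0 <- cfg$origin_age
  pars <- unclass(cfg$rates)
  bounds <- cfg$grid$boundaries
  # forward times at which rates switch (ages below origin)
  cuts <- sort(T0 - bounds[bounds < T0])
  cuts <- c(cuts, Inf)

  cap <- 4096L
  parent <- integer(cap); start_s <- numeric(cap); end_s <- numeric(cap)
  fate <- character(cap); state0 <- integer(cap)
  tr_lin <- integer(0); tr_s <- numeric(0); tr_from <- integer(0)

  n_lin <- if (cfg$origin == "crown") 2L else 1L
  parent[seq_len(n_lin)] <- 0L
  start_s[seq_len(n_lin)] <- 0
  state0[seq_len(n_lin)] <- root_state

  grow <- function() {
    cap2 <- cap * 2L
    length(parent) <<- cap2; length(start_s) <<- cap2
    length(end_s) <<- cap2; length(fate) <<- cap2; length(state0) <<- cap2
    cap <<- cap2
  }

  # alive-lineage sets per state with O(1) swap-remove
  set0 <- integer(1024); set1 <- integer(1024); n0 <- 0L; n1 <- 0L
  add_lin <- function(id, grp) {
    if (grp == 0L) {
      n0 <<- n0 + 1L
      if (n0 > length(set0)) length(set0) <<- 2L * length(set0)
      set0[n0] <<- id
    } else {
      n1 <<- n1 + 1L
      if (n1 > length(set1)) length(set1) <<- 2L * length(set1)
      set1[n1] <<- id
    }
  }
  rm_at <- function(pos, grp) {
    if (grp == 0L) { set0[pos] <<- set0[n0]; n0 <<- n0 - 1L }
    else { set1[pos] <<- set1[n1]; n1 <<- n1 - 1L }
  }
  for (i in seq_len(n_lin)) add_lin(i, root_state)

  ntr <- 0L; tr_lin <- integer(256); tr_s <- numeric(256); tr_from <- integer(256)
  s <- 0; ci <- 1L
  e <- epoch_index(cfg$grid, T0 - 0)          # epoch at the origin
  repeat {
    R0 <- pars[e, 1L] + pars[e, 3L] + pars[e, 5L]   # lambda0 + mu0 + q01
    R1 <- pars[e, 2L] + pars[e, 4L] + pars[e, 6L]
    Rtot <- n0 * R0 + n1 * R1
    dt <- if (Rtot > 0) stats::rexp(1, Rtot) else Inf
    if (s + dt >= cuts[ci] && cuts[ci] < T0) {   # cross an epoch boundary
      s <- cuts[ci]; ci <- ci + 1L
      e <- epoch_index(cfg$grid, T0 - s - 1e-12)
      next
    }
    if (s + dt >= T0) break                      # reached the present
    s <- s + dt
    in1 <- stats::runif(1) < n1 * R1 / Rtot
    grp <- if (in1) 1L else 0L
    rts <- if (in1) pars[e, c(2L, 4L, 6L)] else pars[e, c(1L, 3L, 5L)]
    u <- stats::runif(1) * (rts[1] + rts[2] + rts[3])
    ev <- if (u < rts[1]) 1L else if (u < rts[1] + rts[2]) 2L else 3L
    pos <- sample.int(if (in1) n1 else n0, 1L)
    lin <- if (in1) set1[pos] else set0[pos]
    if (ev == 1L) {                              # speciation
      while (n_lin + 2L > cap) grow()
      kids <- n_lin + 1:2
      parent[kids] <- lin; start_s[kids] <- s; state0[kids] <- grp
      n_lin <- n_lin + 2L
      end_s[lin] <- s; fate[lin] <- "speciation"
      rm_at(pos, grp); add_lin(kids[1], grp); add_lin(kids[2], grp)
      if (n0 + n1 > cfg$max_lineages) return(NULL)
    } else if (ev == 2L) {                       # extinction
      end_s[lin] <- s; fate[lin] <- "extinct"
      rm_at(pos, grp)
      if (n0 + n1 == 0L) return(NULL)
    } else {                                     # state transition
      ntr <- ntr + 1L
      if (ntr > length(tr_lin)) {
        length(tr_lin) <- 2L * length(tr_lin)
        length(tr_s) <- 2L * length(tr_s)
        length(tr_from) <- 2L * length(tr_from)
      }
      tr_lin[ntr] <- lin; tr_s[ntr] <- s; tr_from[ntr] <- grp
      rm_at(pos, grp); add_lin(lin, 1L - grp)
    }
  }
  alive <- c(set0[seq_len(n0)], set1[seq_len(n1)])
  if (!length(alive)) return(NULL)
  end_s[alive] <- T0; fate[alive] <- "extant"
  tr_lin <- tr_lin[seq_len(ntr)]; tr_s <- tr_s[seq_len(ntr)]
  tr_from <- tr_from[seq_len(ntr)]
  n <- n_lin
  lin_tab <- data.frame(id = seq_len(n), parent = parent[seq_len(n)],
                        start_s = start_s[seq_len(n)], end_s = end_s[seq_len(n)],
                        fate = fate[seq_len(n)], state_start = state0[seq_len(n)])
  assemble_sim_tree(cfg, lin_tab,
                    data.frame(lineage = tr_lin, s = tr_s, from = tr_from),
                    alive)
}

# Prune extinct subtrees and build the ape tree plus the painted history.
assemble_sim_tree <- function(cfg, lin, trans, alive) {
  T0 <- cfg$origin_age
  n <- nrow(lin)
  contributes <- logical(n)
  contributes[alive] <- TRUE
  for (i in rev(seq_len(n)))            # children have larger ids than parents
    if (contributes[i] && lin$parent[i] > 0)
      contributes[lin$parent[i]] <- TRUE
  roots <- which(lin$parent == 0)
  if (cfg$origin == "crown" && !all(contributes[roots])) return(NULL)
  if (sum(contributes[roots]) == 0) return(NULL)

  kids <- split(lin$id[lin$parent > 0], lin$parent[lin$parent > 0])

  # Follow a chain of single-contributing-child lineages; return the chain of
  # lineage ids and the terminal kind ("tip" or "split").
  follow <- function(id) {
    chain <- integer(0)
    repeat {
      chain <- c(chain, id)
      if (lin$fate[id] == "extant") return(list(chain = chain, kind = "tip"))
      ch <- kids[[as.character(id)]]
      ch <- ch[contributes[ch]]
      if (length(ch) == 2L) return(list(chain = chain, kind = "split",
                                        children = ch))
      id <- ch
    }
  }

  edges <- list()
  n_tip <- 0L; n_int <- 0L
  # two passes: first count tips to number nodes, so walk twice
  # pass 1: discover structure
  walk <- function(id, parent_node) {
    fo <- follow(id)
    last <- fo$chain[length(fo$chain)]
    if (fo$kind == "tip") {
      n_tip <<- n_tip + 1L
      this <- list(type = "tip", num = n_tip)
    } else {
      n_int <<- n_int + 1L
      this <- list(type = "node", num = n_int, time = lin$end_s[last])
    }
    rec <- list(parent = parent_node, this = this, chain = fo$chain,
                start = lin$start_s[fo$chain[1]],
                end = lin$end_s[last])
    edges[[length(edges) + 1L]] <<- rec
    if (fo$kind == "split")
      for (ch in fo$children) walk(ch, this)
  }

  croots <- roots[contributes[roots]]
  if (cfg$origin == "crown") {
    root_node <- list(type = "node", num = { n_int <- n_int + 1L; n_int },
                      time = 0)
    for (ch in croots) walk(ch, root_node)
    root_time <- 0
  } else {
    # stem: walk the single chain from the stem lineage; its first split (or
    # tip) anchors the root.  A single surviving tip cannot form a tree.
    fo <- follow(croots)
    if (fo$kind == "tip") return(NULL)
    last <- fo$chain[length(fo$chain)]
    root_node <- list(type = "node", num = { n_int <- n_int + 1L; n_int },
                      time = lin$end_s[last])
    root_time <- lin$end_s[last]
    for (ch in fo$children) walk(ch, root_node)
  }

  ntip <- n_tip
  node_id <- function(x) if (x$type == "tip") x$num else ntip + x$num
  m <- length(edges)
  edge_mat <- matrix(0L, m, 2)
  edge_len <- numeric(m)
  chains <- vector("list", m)
  starts <- numeric(m); ends <- numeric(m)
  tip_chain_last <- integer(ntip)
  for (i in seq_len(m)) {
    r <- edges[[i]]
    edge_mat[i, ] <- c(node_id(r$parent), node_id(r$this))
    edge_len[i] <- r$end - r$start
    chains[[i]] <- r$chain
    starts[i] <- r$start; ends[i] <- r$end
    if (r$this$type == "tip") tip_chain_last[r$this$num] <- r$chain[length(r$chain)]
  }
  phy <- list(edge = edge_mat, edge.length = edge_len,
              tip.label = paste0("t", seq_len(ntip)), Nnode = n_int)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  if (cfg$origin == "stem") phy$root.edge <- root_time

  # per-edge state maps from the transition log (dwell run lengths, rootward
  # to tipward, named by state)
  maps <- vector("list", m)
  tr_by_lin <- split(seq_len(nrow(trans)), trans$lineage)
  for (i in seq_len(m)) {
    ch <- chains[[i]]
    s0 <- starts[i]
    state <- lin$state_start[ch[1]]
    pts <- numeric(0)
    for (id in ch) {
      ii <- tr_by_lin[[as.character(id)]]
      if (length(ii)) pts <- c(pts, trans$s[ii])
    }
    pts <- sort(pts)
    seg <- diff(c(s0, pts, ends[i]))
    st_seq <- state
    if (length(pts))
      for (k in seq_along(pts)) st_seq <- c(st_seq, 1L - st_seq[length(st_seq)])
    names(seg) <- as.character(st_seq)
    maps[[i]] <- seg
  }
  # reorder maps to match the cladewise edge order of phy
  key_new <- paste(phy$edge[, 1], phy$edge[, 2])
  key_old <- paste(edge_mat[, 1], edge_mat[, 2])
  maps <- maps[match(key_new, key_old)]

  tip_states <- integer(ntip)
  for (tp in seq_len(ntip)) {
    mp <- maps[[which(phy$edge[, 2] == tp)]]
    tip_states[tp] <- as.integer(names(mp)[length(mp)])
  }
  names(tip_states) <- phy$tip.label

  hist <- character_history(phy, maps)
  ages <- node_ages(phy)
  trans_out <- history_change_points(hist)
  list(phy = phy, tip_states = tip_states, history = hist,
       transitions = trans_out, root_state = lin$state_start[1],
       origin_age = T0)
}

#' Simulate a neutral binary trait on a fixed tree
#'
#' Evolves a 2-state Markov character (gain rate `q01`, loss rate `q10`)
#' along a fixed phylogeny, independent of diversification. Used for the
#' artefact check: a trait simulated this way carries no information about
#' speciation or extinction, so state-dependent diversification models should
#' be selected at no more than the nominal test level.
#'
#' @param phy Validated tree.
#' @param q01,q10 Transition rates (events/lineage/Myr).
#' @param root_state Root state (0/1).
#' @param seed Integer seed.
#' @return List with `tip_states` (named 0/1 vector) and `history`
#'   (a [character_history()]).
#' @export
simulate_neutral_trait <- function(phy, q01, q10, root_state = 0L, seed = 1L) {
  stopifnot(q01 >= 0, q10 >= 0)
  phy <- validate_tree(phy)
  with_seed(seed, {
    ntip <- length(phy$tip.label)
    nnode <- ntip + phy$Nnode
    node_state <- integer(nnode)
    root <- ntip + 1L
    node_state[root] <- as.integer(root_state)
    pre <- ape::reorder.phylo(phy, "cladewise")
    maps <- vector("list", nrow(pre$edge))
    rates <- c(q01, q10)
    for (i in seq_len(nrow(pre$edge))) {
      par <- pre$edge[i, 1]; ch <- pre$edge[i, 2]
      len <- pre$edge.length[i]
      st <- node_state[par]
      seg <- numeric(0)
      pos <- 0
      repeat {
        r <- rates[st + 1L]
        w <- if (r > 0) stats::rexp(1, r) else Inf
        if (pos + w >= len) { seg <- c(seg, stats::setNames(len - pos, st)); break }
        seg <- c(seg, stats::setNames(w, st))
        pos <- pos + w
        st <- 1L - st
      }
      maps[[i]] <- seg
      node_state[ch] <- st
    }
    key <- paste(phy$edge[, 1], phy$edge[, 2])
    maps <- maps[match(key, paste(pre$edge[, 1], pre$edge[, 2]))]
    hist <- character_history(phy, maps)
    tips <- node_state[seq_len(ntip)]
    names(tips) <- phy$tip.label
    list(tip_states = tips, history = hist, seed = seed)
  })
}

#' Simulate a Brownian-motion trait on a fixed tree
#'
#' @param phy Validated tree.
#' @param sigma2 Diffusion rate (trait^2/Myr), `>= 0`.
#' @param root_value Trait value at the root.
#' @param seed Integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm <- function(phy, sigma2, root_value = 0, seed = 1L) {
  stopifnot(sigma2 >= 0)
  with_seed(seed, {
    ntip <- length(phy$tip.label)
    val <- numeric(ntip + phy$Nnode)
    val[ntip + 1L] <- root_value
    pre <- ape::reorder.phylo(phy, "cladewise")
    for (i in seq_len(nrow(pre$edge)))
      val[pre$edge[i, 2]] <- val[pre$edge[i, 1]] +
        stats::rnorm(1, 0, sqrt(sigma2 * pre$edge.length[i]))
    stats::setNames(val[seq_len(ntip)], phy$tip.label)
  })
}

#' Generate a toy fossil fruit/seed table
#'
#' Emulates the structure of a literature-assembled fossil table: each record
#' gets an epoch with an age interval, an organ (fruit or seed), and a size
#' drawn log-uniformly from `size_range_cm`.
#'
#' @param n Number of records.
#' @param epochs Data frame with columns `epoch`, `age_lo_ma`, `age_hi_ma`;
#'   defaults to a coarse Late Cretaceous-to-Neogene scale.
#' @param size_range_cm Length-2 range of sizes (cm).
#' @param seed Integer seed.
#' @return A validated fossil table (see [read_fossil_table()]).
#' @export
generate_fossil_table <- function(n, epochs = default_epoch_table(),
                                  size_range_cm = c(0.3, 17), seed = 1L) {
  stopifnot(n >= 0)
  if (n == 0)
    return(validate_fossil_table(utils::read.csv(text =
      "taxon_rank,taxon,site,epoch,age_lo_ma,age_hi_ma,organ,length_cm,width_cm")))
  with_seed(seed, {
    i <- sample.int(nrow(epochs), n, replace = TRUE)
    organ <- sample(c("fruit", "seed"), n, replace = TRUE)
    len <- exp(stats::runif(n, log(size_range_cm[1]), log(size_range_cm[2])))
    tab <- data.frame(
      taxon_rank = "genus",
      taxon = paste0("fossiltaxon_", seq_len(n)),
      site = paste0("site_", sample.int(max(3L, n %/% 3L), n, replace = TRUE)),
      epoch = epochs$epoch[i],
      age_lo_ma = epochs$age_lo_ma[i],
      age_hi_ma = epochs$age_hi_ma[i],
      organ = organ,
      length_cm = ifelse(organ == "fruit", round(len, 2), NA),
      width_cm = ifelse(organ == "seed", round(len, 2), NA),
      stringsAsFactors = FALSE)
    validate_fossil_table(tab)
  })
}

#' @rdname generate_fossil_table
#' @export
default_epoch_table <- function() {
  data.frame(
    epoch = c("Late Cretaceous", "Palaeocene", "Eocene", "Oligocene",
              "Miocene", "Pliocene"),
    age_lo_ma = c(66, 56, 33.9, 23, 5.3, 2.6),
    age_hi_ma = c(100.5, 66, 56, 33.9, 23, 5.3),
    stringsAsFactors = FALSE)
}
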