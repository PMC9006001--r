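#' Read a time-calibrated tree from Newick text
#'
#' Parses a Newick string (or a file containing one tree) into an
#' [ape::phylo] object and validates it for downstream use: the tree must be
#' rooted, fully bifurcating (polytomies are rejected unless
#' `resolve_polytomies = TRUE`), carry branch lengths on every non-root edge,
#' and be ultrametric within a relative tolerance. Tip ages that deviate from
#' zero by at most `tol * root_age` are snapped to zero by extending terminal
#' branches; larger deviations are an error reporting the maximum deviation.
#'
#' Ages follow the geological convention: tips sit at age 0 and ages increase
#' toward the root (Myr before present), so epoch boundaries such as 66 Ma and
#' 40 Ma are ages, not elapsed times.
#'
#' @param text Newick string. Exactly one of `text`/`file` must be given.
#' @param file Path to a file whose first line holds one Newick tree.
#' @param tol Relative ultrametricity tolerance (fraction of root age).
#' @param resolve_polytomies If `TRUE`, polytomies are resolved into
#'   zero-length bifurcations in randomized order using `seed`.
#' @param seed Integer seed used only when resolving polytomies.
#' @return A validated `phylo` object with tip order preserved from input.
#' @export
read_newick <- function(text = NULL, file = NULL, tol = 1e-6,
                        resolve_polytomies = FALSE, seed = 1L) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) text <- readLines(file, warn = FALSE)[1]
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse Newick text")
  validate_tree(phy, tol = tol, resolve_polytomies = resolve_polytomies,
                seed = seed)
}

#' Read a sample of trees (one Newick per line)
#'
#' @param file Path to a file with one Newick tree per line (e.g. a posterior
#'   sample).
#' @inheritParams read_newick
#' @return List of validated `phylo` objects.
#' @export
read_tree_sample <- function(file, tol = 1e-6, resolve_polytomies = FALSE,
                             seed = 1L) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l)
    read_newick(text = l, tol = tol,
                resolve_polytomies = resolve_polytomies, seed = seed))
}

#' Write a tree (or trees) as Newick
#'
#' @param phy A `phylo` object or a list of them.
#' @param file Output path; if `NULL` the Newick string(s) are returned.
#' @param digits Significant digits for branch lengths.
#' @export
write_newick <- function(phy, file = NULL, digits = 12) {
  if (inherits(phy, "phylo")) phy <- list(phy)
  txt <- vapply(phy, function(p) ape::write.tree(p, digits = digits),
                character(1))
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}

#' Validate (and lightly repair) a phylogeny for epoch-sliced analyses
#'
#' @inheritParams read_newick
#' @param phy A `phylo` object.
#' @return The validated tree, with terminal branches extended so tips sit
#'   exactly at age 0 when the deviation is within tolerance.
#' @export
validate_tree <- function(phy, tol = 1e-6, resolve_polytomies = FALSE,
                          seed = 1L) {
  if (!inherits(phy, "phylo")) stop("`phy` must be a `phylo` object")
  if (is.null(phy$tip.label) || any(!nzchar(phy$tip.label)))
    stop("all tips must be labelled")
  if (anyDuplicated(phy$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(phy$edge.length) || any(phy$edge.length < 0))
    stop("branch lengths must all be present and >= 0")
  if (!ape::is.binary(phy)) {
    if (!resolve_polytomies)
      stop("tree contains polytomies; set resolve_polytomies = TRUE to ",
           "resolve them into zero-length bifurcations")
    phy <- with_seed(seed, ape::multi2di(phy, random = TRUE))
  }
  if (!ape::is.rooted(phy)) stop("tree must be rooted")

  depth <- ape::node.depth.edgelength(phy)
  ntip <- length(phy$tip.label)
  root_age <- max(depth[seq_len(ntip)])
  if (root_age <= 0) stop("root age must be > 0")
  dev <- root_age - depth[seq_len(ntip)]   # shortfall of each tip below age 0
  if (max(dev) > tol * root_age)
    stop(sprintf(
      "tree is not ultrametric: max tip-age deviation %.6g exceeds %.3g x root age (%.6g)",
      max(dev), tol, root_age))
  if (max(dev) > 0) {
    term <- match(seq_len(ntip), phy$edge[, 2])
    phy$edge.length[term] <- phy$edge.length[term] + dev
  }
  phy
}

#' Node ages of an ultrametric tree
#'
#' @param phy A validated `phylo` object.
#' @return Numeric vector of ages (Myr before present) indexed by node number
#'   (tips `1..ntip` first, then internal nodes); tips are at age 0.
#' @export
node_ages <- function(phy) {
  depth <- ape::node.depth.edgelength(phy)
  ages <- max(depth[seq_len(length(phy$tip.label))]) - depth
  ages[seq_len(length(phy$tip.label))] <- 0
  ages
}

#' Root age (crown age) of a tree
#' @param phy A validated `phylo` object.
#' @export
root_age <- function(phy) {
  node_ages(phy)[length(phy$tip.label) + 1L]
}

#' Trait-classification configuration
#'
#' @param megafaunal_threshold_cm Fruit length (cm) at and above which a
#'   species is classed as megafaunal-fruited. Default 4 cm, the dispersal
#'   ecology dichotomy used for megafauna-dispersed plants.
#' @param armature_channel Which armature indicator feeds the combined
#'   `armature` state: `"any"` (stem OR leaf), `"stem"`, or `"leaf"`.
#' @export
trait_config <- function(megafaunal_threshold_cm = 4.0,
                         armature_channel = c("any", "stem", "leaf")) {
  if (!is.numeric(megafaunal_threshold_cm) || megafaunal_threshold_cm <= 0)
    stop("megafaunal threshold must be > 0")
  structure(list(megafaunal_threshold_cm = megafaunal_threshold_cm,
                 armature_channel = match.arg(armature_channel)),
            class = "trait_config")
}

#' Read a species trait table
#'
#' Expects a CSV with header `species,fruit_length_cm,stem_armature,leaf_armature`;
#' armature coded 0/1, blanks = missing.
#'
#' @param file CSV path.
#' @return A validated data frame.
#' @export
read_trait_table <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_trait_table(tab)
}

#' @rdname read_trait_table
#' @param tab A data frame shaped like the trait CSV.
#' @export
validate_trait_table <- function(tab) {
  need <- c("species", "fruit_length_cm", "stem_armature", "leaf_armature")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("trait table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$species))
    stop("duplicated species in trait table")
  fl <- tab$fruit_length_cm
  if (any(!is.na(fl) & fl <= 0)) stop("fruit lengths must be > 0 when present")
  for (ch in c("stem_armature", "leaf_armature")) {
    v <- tab[[ch]]
    if (any(!is.na(v) & !v %in% c(0, 1)))
      stop("column ", ch, " must be 0/1/missing")
  }
  tab
}

#' Classify species traits into the binary states the analyses use
#'
#' Produces one 0/1/NA state vector per channel: `fruit_size` (1 =
#' megafaunal, i.e. fruit length >= threshold), `stem_armature`,
#' `leaf_armature`, and `armature` (the configured combination; `"any"` is the
#' OR of stem and leaf, treating a known 1 as decisive over a missing value).
#'
#' @param tab Trait table (see [read_trait_table()]).
#' @param cfg A [trait_config()].
#' @return Data frame `species` plus one integer column per channel.
#' @export
classify_traits <- function(tab, cfg = trait_config()) {
  tab <- validate_trait_table(tab)
  fruit <- ifelse(is.na(tab$fruit_length_cm), NA_integer_,
                  as.integer(tab$fruit_length_cm >= cfg$megafaunal_threshold_cm))
  stem <- as.integer(tab$stem_armature)
  leaf <- as.integer(tab$leaf_armature)
  any_arm <- ifelse(
    !is.na(stem) & stem == 1L | !is.na(leaf) & leaf == 1L, 1L,
    ifelse(is.na(stem) | is.na(leaf), NA_integer_, 0L))
  armature <- switch(cfg$armature_channel, any = any_arm, stem = stem,
                     leaf = leaf)
  out <- data.frame(species = tab$species, fruit_size = fruit,
                    stem_armature = stem, leaf_armature = leaf,
                    armature = armature, stringsAsFactors = FALSE)
  for (ch in c("fruit_size", "stem_armature", "leaf_armature", "armature"))
    if (all(is.na(out[[ch]])))
      stop("trait channel `", ch, "` has no observed values")
  out
}

#' Reconcile a tree with a focal binary trait
#'
#' Drops tips whose focal state is missing (or absent from the table) and
#' computes per-state sampling fractions. Under the default `"state"`
#' convention, `f_s` is the number of retained tips in state `s` divided by
#' the number of species known to be in state `s` in the full table (so
#' incomplete trait coverage, not incomplete tree coverage, drives the
#' correction). `"global"` uses a single fraction `retained / known` for both
#' states; `"complete"` sets both fractions to 1 and treats the pruned tree
#' as fully sampled.
#'
#' @param phy Validated tree.
#' @param states Data frame from [classify_traits()] (or any frame with
#'   `species` and the focal column).
#' @param channel Name of the focal state column.
#' @param sampling One of `"state"`, `"global"`, `"complete"`.
#' @return List with `phy` (pruned tree), `states` (named 0/1 vector in tip
#'   order), and `f` (length-2 sampling fractions for states 0 and 1).
#' @export
align_tree_and_traits <- function(phy, states, channel = "fruit_size",
                                  sampling = c("state", "global", "complete")) {
  sampling <- match.arg(sampling)
  if (!channel %in% names(states)) stop("no column `", channel, "` in states")
  st <- states[[channel]]
  names(st) <- states$species
  known <- st[!is.na(st)]
  keep <- intersect(phy$tip.label, names(known))
  if (length(keep) < 2)
    stop("fewer than 2 species shared between tree and trait table")
  drop <- setdiff(phy$tip.label, keep)
  pruned <- if (length(drop)) ape::drop.tip(phy, drop) else phy
  x <- known[pruned$tip.label]
  f <- switch(sampling,
    complete = c(1, 1),
    global = rep(min(1, length(x) / length(known)), 2),
    state = {
      n_tree <- c(sum(x == 0), sum(x == 1))
      n_known <- c(sum(known == 0), sum(known == 1))
      ifelse(n_known > 0, pmin(1, n_tree / n_known), 1)
    })
  f[f <= 0] <- 1e-8
  list(phy = pruned, states = x, f = as.numeric(f))
}

#' Read a fossil fruit/seed table
#'
#' Expects a CSV with header
#' `taxon_rank,taxon,site,epoch,age_lo_ma,age_hi_ma,organ,length_cm,width_cm`.
#' `age_lo_ma < age_hi_ma` (both Myr before present) and at least one of
#' length/width must be present per record. Seed measurements are minimum
#' estimates of fruit size and are flagged downstream.
#'
#' @param file CSV path.
#' @return Validated data frame with an added `age_mid_ma` column (the epoch
#'   midpoint used for plotting).
#' @export
read_fossil_table <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_fossil_table(tab)
}

#' @rdname read_fossil_table
#' @param tab Data frame shaped like the fossil CSV.
#' @export
validate_fossil_table <- function(tab) {
  need <- c("taxon_rank", "taxon", "site", "epoch", "age_lo_ma", "age_hi_ma",
            "organ", "length_cm", "width_cm")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("fossil table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(tab)) {
    if (any(!(tab$age_lo_ma < tab$age_hi_ma)))
      stop("each fossil needs age_lo_ma < age_hi_ma")
    if (any(!tab$organ %in% c("fruit", "seed")))
      stop("organ must be 'fruit' or 'seed'")
    if (any(is.na(tab$length_cm) & is.na(tab$width_cm)))
      stop("each fossil needs at least one size measurement")
    sz <- c(tab$length_cm, tab$width_cm)
    if (any(!is.na(sz) & sz <= 0)) stop("fossil sizes must be > 0")
  }
  tab$age_mid_ma <- (tab$age_lo_ma + tab$age_hi_ma) / 2
  tab
}

# Run `expr` with a temporary RNG state seeded at `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
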