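#' Configuration for a full epoch-sliced diversification analysis
#'
#' Collects every input and tuning knob of the pipeline. Trees, traits and
#' fossils may be given as in-memory objects or file paths (Newick, one tree
#' per line; trait and fossil CSVs as documented in [read_trait_table()] and
#' [read_fossil_table()]).
#'
#' @param trees A `phylo`, a list of `phylo` (posterior sample), or a path.
#' @param traits Trait table or path.
#' @param fossils Optional fossil table or path.
#' @param channel Focal binary channel: `"fruit_size"`, `"armature"`,
#'   `"stem_armature"` or `"leaf_armature"`.
#' @param boundaries Epoch boundary ages (Myr); default `c(66, 40)` brackets
#'   the Palaeocene megaherbivore gap.
#' @param megafaunal_threshold_cm Fruit-size dichotomy (cm).
#' @param sampling Sampling-fraction convention, see [align_tree_and_traits()].
#' @param ladder Optional list of [model_spec()]s overriding
#'   [enumerate_models()].
#' @param alpha LRT level for stepwise selection.
#' @param n_restarts Restarts per ML fit.
#' @param mcmc List: `n_gen`, `n_adapt`, `prior_mean` (`NULL` = heuristic
#'   from the constrained fit), `burn_in_frac`.
#' @param simmap List: `n_maps`, `model`, `root_prior`.
#' @param anc List: `edge_samples`, plus optional `constraint`
#'   (a [fossil_constraint()]).
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory (created if missing).
#' @export
run_config <- function(trees, traits, fossils = NULL, channel = "fruit_size",
                       boundaries = c(66, 40), megafaunal_threshold_cm = 4,
                       sampling = "state", ladder = NULL, alpha = 0.05,
                       n_restarts = 3,
                       mcmc = list(), simmap = list(), anc = list(),
                       seed = 1L, out_dir = tempfile("epochsse_run_")) {
  mcmc <- utils::modifyList(list(n_gen = 1000, n_adapt = 100,
                                 prior_mean = NULL, burn_in_frac = 0.1), mcmc)
  simmap <- utils::modifyList(list(n_maps = 500, model = "ARD",
                                   root_prior = "stationary"), simmap)
  anc <- utils::modifyList(list(edge_samples = 20, constraint = NULL), anc)
  if (!channel %in% c("fruit_size", "armature", "stem_armature",
                      "leaf_armature"))
    stop("unknown trait channel: ", channel)
  structure(list(trees = trees, traits = traits, fossils = fossils,
                 channel = channel, boundaries = boundaries,
                 megafaunal_threshold_cm = megafaunal_threshold_cm,
                 sampling = sampling, ladder = ladder, alpha = alpha,
                 n_restarts = n_restarts, mcmc = mcmc, simmap = simmap,
                 anc = anc, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

resolve_inputs <- function(config) {
  paths <- character(0)
  grab <- function(x, reader) {
    if (is.character(x) && length(x) == 1) {
      paths <<- c(paths, normalizePath(x))
      reader(x)
    } else x
  }
  trees <- grab(config$trees, read_tree_sample)
  if (inherits(trees, "phylo")) trees <- list(trees)
  traits <- grab(config$traits, read_trait_table)
  fossils <- if (!is.null(config$fossils))
    grab(config$fossils, read_fossil_table)
  if (length(paths) && dir.exists(config$out_dir)) {
    out <- normalizePath(config$out_dir)
    if (any(startsWith(paths, out)))
      stop("config error: inputs live inside the output directory; ",
           "refusing to re-consume the pipeline's own outputs")
  }
  list(trees = trees, traits = traits, fossils = fossils)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' classify -> align -> ladder fit/stepwise selection (on the first tree) ->
#' MCMC of the selected model over every tree -> pooled epoch summaries;
#' plus continuous ancestral reconstruction with a traitgram (fruit-size
#' channel, when fruit lengths are available) or stochastic character
#' mapping (armature channels). Writes all tables plus a manifest (inputs,
#' seeds, package version, per-file checksums) under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `selection`, `summary`, `samples`,
#'   `anc`/`simmap` results, and `manifest`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- stage("input", resolve_inputs(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- epoch_grid(config$boundaries)
  cfg_tc <- trait_config(config$megafaunal_threshold_cm,
                         if (config$channel == "armature") "any"
                         else if (config$channel == "stem_armature") "stem"
                         else if (config$channel == "leaf_armature") "leaf"
                         else "any")
  states <- stage("classify", classify_traits(inp$traits, cfg_tc))
  ch <- if (config$channel %in% c("stem_armature", "leaf_armature", "armature"))
    "armature" else config$channel
  aligned <- stage("align", lapply(inp$trees, align_tree_and_traits,
                                   states = states, channel = ch,
                                   sampling = config$sampling))
  a1 <- aligned[[1]]

  ladder <- if (is.null(config$ladder)) enumerate_models(grid)
            else config$ladder
  sel <- stage("select", stepwise_select(
    ladder, a1$phy, a1$states, f = a1$f, alpha = config$alpha,
    n_restarts = config$n_restarts, seed = config$seed))

  prior <- if (is.null(config$mcmc$prior_mean))
    stage("prior", default_prior(a1$phy, a1$states, f = a1$f, grid = grid,
                                 seed = config$seed))
  else exp_prior(config$mcmc$prior_mean)
  samples <- stage("mcmc", lapply(seq_along(aligned), function(i) {
    al <- aligned[[i]]
    ft <- if (i == 1) sel$best
          else fit_ml(sel$best$spec, al$phy, al$states, f = al$f,
                      n_restarts = 2, seed = config$seed + 1000L + i)
    sample_posterior(ft, al$phy, al$states, f = al$f,
                     n_gen = config$mcmc$n_gen, prior = prior,
                     n_adapt = config$mcmc$n_adapt,
                     seed = config$seed + 2000L + i, tree_id = i)
  }))
  summ <- stage("summarize",
                pool_and_summarize(samples, config$mcmc$burn_in_frac))

  anc <- NULL
  if (config$channel == "fruit_size" &&
      any(!is.na(inp$traits$fruit_length_cm))) {
    anc <- stage("ancrec", {
      tr <- inp$traits[!is.na(inp$traits$fruit_length_cm), ]
      phy1 <- inp$trees[[1]]
      keep <- intersect(phy1$tip.label, tr$species)
      phya <- ape::drop.tip(phy1, setdiff(phy1$tip.label, keep))
      x <- log(stats::setNames(tr$fruit_length_cm, tr$species)[phya$tip.label])
      if (!is.null(config$anc$constraint)) {
        mod <- apply_fossil_constraint(phya, x, config$anc$constraint)
        phya <- mod$phy; x <- mod$x
      }
      rec <- anc_bm_ml(phya, x)
      list(recon = rec,
           traitgram = traitgram_table(rec, inp$fossils,
                                       config$anc$edge_samples))
    })
  }
  simmap <- NULL
  if (ch == "armature") {
    simmap <- stage("simmap", {
      fmk <- fit_mk(a1$phy, a1$states, model = config$simmap$model,
                    root_prior = config$simmap$root_prior)
      sh <- sample_histories(a1$phy, a1$states, fmk,
                             n_maps = config$simmap$n_maps,
                             root_prior = config$simmap$root_prior,
                             seed = config$seed + 3000L)
      list(fit = fmk, maps = sh, origins = summarize_origins(sh$origin_counts))
    })
  }

  manifest <- stage("write", write_outputs(config, sel, samples, summ, anc,
                                           simmap))
  invisible(list(selection = sel, samples = samples, summary = summ,
                 anc = anc, simmap = simmap, manifest = manifest,
                 aligned = aligned))
}

write_outputs <- function(config, sel, samples, summ, anc, simmap) {
  out <- config$out_dir
  wcsv <- function(df, name) {
    p <- file.path(out, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  files <- c(
    wcsv(sel$table, "model_table.csv"),
    wcsv(do.call(rbind, lapply(samples, function(s) {
      d <- as.data.frame(s$draws)
      names(d) <- paste0("p", seq_len(ncol(d)))
      cbind(tree_id = s$tree_id, gen = seq_len(nrow(d)), d,
            logLik = s$logLik, logPrior = s$logPrior)
    })), "chains.csv"),
    wcsv(summ$summary, "epoch_summary.csv"),
    wcsv(summ$contrasts, "epoch_contrasts.csv"))
  if (!is.null(anc)) {
    nodes <- anc$recon$nodes
    names(nodes)[names(nodes) == "estimate"] <- "estimate_log_cm"
    files <- c(files,
               wcsv(nodes, "ancestral_states.csv"),
               wcsv(anc$traitgram, "traitgram.csv"))
  }
  if (!is.null(simmap)) {
    files <- c(files,
               wcsv(simmap$maps$node_posterior, "node_posterior.csv"),
               wcsv(data.frame(map = seq_along(simmap$maps$origin_counts),
                               origins = simmap$maps$origin_counts),
                    "origin_counts.csv"))
  }
  manifest <- list(
    package = "epochsse",
    version = as.character(utils::packageVersion("epochsse")),
    seed = config$seed,
    channel = config$channel,
    boundaries = config$boundaries,
    selected_model = sel$selected,
    n_trees = length(samples),
    files = basename(files),
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' Neutral-trait robustness check
#'
#' Simulates traits that evolve independently of diversification on the
#' provided tree(s), reruns the model ladder on each replicate, and reports
#' how often a state-dependent (or time-dependent) model is selected. On
#' trees whose shape carries no genuine state signal this fraction should
#' not exceed the nominal test level by much; larger values would indicate
#' that tree shape alone can masquerade as trait-dependent diversification.
#'
#' @param trees A `phylo` or list of them (replicates cycle over the list).
#' @param n_rep Number of neutral replicates (0 gives an empty report).
#' @param q01,q10 Neutral trait transition rates.
#' @param ladder Ladder to rerun (default [enumerate_models()]).
#' @param grid Epoch grid for the refits.
#' @param alpha,n_restarts,seed As in [stepwise_select()].
#' @return Data frame with one row per replicate: `rep, tree, selected, k,
#'   state_dep, time_dep`, with the selection fractions as attributes
#'   `frac_state_dep` / `frac_time_dep`.
#' @export
run_robustness <- function(trees, n_rep = 50, q01 = 0.05, q10 = 0.05,
                           ladder = NULL, grid = epoch_grid(), alpha = 0.05,
                           n_restarts = 2, seed = 1L) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(ladder)) ladder <- enumerate_models(grid)
  if (n_rep == 0) {
    warning("zero robustness replicates requested; returning an empty report")
    out <- data.frame(rep = integer(0), tree = integer(0),
                      selected = character(0), k = integer(0),
                      state_dep = logical(0), time_dep = logical(0))
    attr(out, "frac_state_dep") <- NA_real_
    attr(out, "frac_time_dep") <- NA_real_
    return(out)
  }
  rows <- lapply(seq_len(n_rep), function(r) {
    ti <- ((r - 1L) %% length(trees)) + 1L
    phy <- trees[[ti]]
    nt <- simulate_neutral_trait(phy, q01, q10,
                                 root_state = (r %% 2L), seed = seed + 7L * r)
    sl <- stepwise_select(ladder, phy, nt$tip_states, alpha = alpha,
                          n_restarts = n_restarts, seed = seed + 31L * r)
    modes <- sl$best$spec$modes
    data.frame(rep = r, tree = ti, selected = sl$selected,
               k = sl$best$spec$k,
               state_dep = any(vapply(modes, function(m) m[1] == "free", TRUE)),
               time_dep = any(vapply(modes, function(m) m[2] != "tied", TRUE)))
  })
  out <- do.call(rbind, rows)
  attr(out, "frac_state_dep") <- mean(out$state_dep)
  attr(out, "frac_time_dep") <- mean(out$time_dep)
  out
}
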