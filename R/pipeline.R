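# End-to-end orchestration: structure -> RIN -> centralities ->
# criticality -> features -> group comparison -> classifier training ->
# per-residue vote scores, with every stage's table written to the run
# directory and a JSON manifest recording parameters and seeds.

.config_keys <- c(
  "structure", "conservation", "labels", "sesa", "outdir", "chains",
  "probe_radius", "min_seq_separation", "heavy_atoms_only",
  "n_bins", "bootstrap_iterations", "ml_preset", "ml_k", "estimators",
  "combos", "sasa_probe", "sasa_points", "seed"
)

#' Build and validate a pipeline configuration
#'
#' @param structure path to the input PDB structure
#' @param conservation path to the conservation CSV (residue, conservation)
#' @param labels path to the label CSV (residue, label)
#' @param outdir run output directory
#' @param sesa optional path to an imported SESA CSV (residue, sesa);
#'   without it the probe-0 approximation is used and flagged
#' @param chains optional chain filter for the RIN
#' @param probe_radius,min_seq_separation,heavy_atoms_only contact rule
#' @param n_bins criticality bins per axis
#' @param bootstrap_iterations resampling iterations of the group test
#' @param ml_preset `"fast"` or `"paper"` hyperparameter grids
#' @param ml_k cross-validation folds
#' @param estimators estimator subset (default all five)
#' @param combos preprocessing combination subset (default all four)
#' @param sasa_probe,sasa_points surface-sampling parameters
#' @param seed master seed; per-stage seeds are `seed + 1000 * stage index`
#' @param ... rejected — unknown keys are an error
#' @return validated list of class `fv_run_config`
#' @export
run_config <- function(structure, conservation, labels, outdir,
                       sesa = NULL, chains = NULL,
                       probe_radius = 0.25, min_seq_separation = 1L,
                       heavy_atoms_only = TRUE, n_bins = 4L,
                       bootstrap_iterations = 10000L,
                       ml_preset = "fast", ml_k = 10L,
                       estimators = fvclass_estimators(),
                       combos = names(all_combos()),
                       sasa_probe = 1.4, sasa_points = 960L, seed = 1L, ...) {
  extra <- list(...)
  if (length(extra) > 0L) {
    stop("unknown config key(s): ", paste(names(extra), collapse = ", "))
  }
  cfg <- list(structure = structure, conservation = conservation,
              labels = labels, sesa = sesa, outdir = outdir, chains = chains,
              probe_radius = probe_radius,
              min_seq_separation = as.integer(min_seq_separation),
              heavy_atoms_only = heavy_atoms_only, n_bins = as.integer(n_bins),
              bootstrap_iterations = as.integer(bootstrap_iterations),
              ml_preset = match.arg(ml_preset, c("fast", "paper")),
              ml_k = as.integer(ml_k), estimators = estimators,
              combos = combos, sasa_probe = sasa_probe,
              sasa_points = as.integer(sasa_points), seed = as.integer(seed))
  for (p in c("structure", "conservation", "labels")) {
    if (!file.exists(cfg[[p]])) stop("input file not readable: ", cfg[[p]])
  }
  stopifnot(cfg$ml_preset %in% c("fast", "paper"),
            all(cfg$estimators %in% fvclass_estimators()),
            all(cfg$combos %in% names(all_combos())))
  structure(cfg, class = "fv_run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the [run_config()] arguments
#' @return an `fv_run_config`
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configurations")
  }
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — build-rin, centrality,
#' criticality, features, compare-groups, train, score — writing each
#' stage's CSV and a `manifest.json` into the configured output
#' directory. Idempotent per seed: a rerun with the same configuration
#' reproduces the same tables.
#'
#' @param config an `fv_run_config` (or path to a YAML file)
#' @return invisibly, the output directory; stage outputs are also
#'   returned as the attribute `stages`
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "fv_run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage_names <- c("build-rin", "centrality", "criticality", "features",
                   "compare-groups", "train", "score")
  stage_seed <- function(stage) config$seed + 1000L * match(stage, stage_names)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  out <- list()

  s <- run_stage("build-rin", parse_structure(config$structure))
  rule <- contact_rule(probe_radius = config$probe_radius,
                       min_seq_separation = config$min_seq_separation,
                       heavy_atoms_only = config$heavy_atoms_only)
  g <- run_stage("build-rin", build_rin(s, rule, chains = config$chains))
  out$rin <- g
  utils::write.csv(rin_edge_table(g),
                   file.path(config$outdir, "rin_edges.csv"), row.names = FALSE)
  write_sif(g, file.path(config$outdir, "rin.sif"))

  cent <- run_stage("centrality", compute_centralities(g))
  out$centralities <- cent
  utils::write.csv(cent, file.path(config$outdir, "centralities.csv"),
                   row.names = FALSE)
  sp <- run_stage("centrality", spearman_matrix(cent))
  utils::write.csv(as.data.frame(sp),
                   file.path(config$outdir, "centrality_spearman.csv"))

  crit <- run_stage("criticality", bin_criticality(cent, config$n_bins))
  super <- run_stage("criticality", pareto_supercritical(cent))
  crit_tab <- crit$labels
  crit_tab$supercritical <- crit_tab$residue %in% super
  out$criticality <- crit_tab
  out$bin_grid <- crit$grid
  utils::write.csv(crit_tab, file.path(config$outdir, "criticality.csv"),
                   row.names = FALSE)

  sesa_tab <- if (!is.null(config$sesa)) {
    utils::read.csv(config$sesa, stringsAsFactors = FALSE)
  } else NULL
  struct_feats <- run_stage("features", compute_structural_features(
    s, sesa = sesa_tab, probe = config$sasa_probe,
    n_points = config$sasa_points))
  cons <- utils::read.csv(config$conservation, stringsAsFactors = FALSE)
  labs <- utils::read.csv(config$labels, stringsAsFactors = FALSE)
  fm <- run_stage("features",
                  assemble_feature_matrix(cent, struct_feats, cons, labs))
  out$features <- fm
  utils::write.csv(fm, file.path(config$outdir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(attr(fm, "drop_log"),
                   file.path(config$outdir, "feature_drop_log.csv"),
                   row.names = FALSE)

  comp <- run_stage("compare-groups", compare_feature_groups(
    fm, n_iter = config$bootstrap_iterations,
    seed = stage_seed("compare-groups")))
  out$group_stats <- comp
  utils::write.csv(comp, file.path(config$outdir, "group_stats.csv"),
                   row.names = FALSE)

  lb <- run_stage("train", cv_leaderboard(
    fm, estimators = config$estimators,
    combos = all_combos()[config$combos], preset = config$ml_preset,
    k = config$ml_k, seed = stage_seed("train")))
  out$leaderboard <- lb
  utils::write.csv(lb, file.path(config$outdir, "cv_leaderboard.csv"),
                   row.names = FALSE)
  models <- run_stage("train", train_final_models(
    fm, select_best(lb), seed = stage_seed("train")))
  out$models <- models

  votes <- run_stage("score", ensemble_vote(models, fm))
  votes <- votes[order(-votes$vote, order_residue_keys(votes$residue)), ]
  out$votes <- votes
  utils::write.csv(votes, file.path(config$outdir, "votes.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("fvrin")),
    stages = stage_names,
    seed = config$seed,
    stage_seeds = stats::setNames(
      lapply(stage_names, stage_seed), stage_names),
    parameters = config[setdiff(names(config),
                                c("structure", "conservation", "labels",
                                  "sesa", "outdir"))],
    inputs = config[c("structure", "conservation", "labels")],
    n_residues = igraph::vcount(g), n_edges = igraph::ecount(g),
    n_instances = nrow(fm), n_dropped = nrow(attr(fm, "drop_log"))
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  attr(config$outdir, "stages") <- out
  invisible(config$outdir)
}
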