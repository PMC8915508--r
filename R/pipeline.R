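#' Pipeline configuration
#'
#' One structured configuration drives the end-to-end pipeline. The
#' defaults run a fully synthetic experiment: generate a cohort, filter it,
#' build the multimorbidity network on the construction era, engineer
#' features on the modeling era and run the ablation harness.
#'
#' @param records_path Path to an admissions CSV (`NULL` to simulate).
#' @param catalog_path Path to a one-column `code` CSV chronic catalog
#'   (`NULL` with simulation: the synthetic catalog is used).
#' @param eci_map_path Optional code-to-Elixhauser CSV; with simulation the
#'   synthetic map is generated when this is `NULL`.
#' @param simulate List of [cohort_params()] arguments for the synthetic
#'   cohort (used when `records_path` is `NULL`).
#' @param mn_era,modeling_era Length-2 date vectors; the network era must
#'   end before the modeling era begins.
#' @param inclusion List: `min_age`, `los_quantile`, `los_cutoff`.
#' @param mn List: `min_pair_count`, `edge_rule`, `sigma_mode`,
#'   `weight_mode`.
#' @param psn List: `k`, `exclude_same_patient`.
#' @param features List: `window_years`, `lda`, `lda_candidates`,
#'   `lda_components`.
#' @param plan List: `models` (names for [model_spec()]), `repeats`,
#'   `tune`.
#' @param seed Global seed, fanned out per stage via [stage_seed()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(records_path = NULL,
                            catalog_path = NULL,
                            eci_map_path = NULL,
                            simulate = list(n_patients = 2000L),
                            mn_era = c("2015-01-01", "2017-12-31"),
                            modeling_era = c("2018-01-01", "2019-12-31"),
                            inclusion = list(),
                            mn = list(),
                            psn = list(),
                            features = list(),
                            plan = list(),
                            seed = 42L) {
  cfg <- list(
    records_path = records_path, catalog_path = catalog_path,
    eci_map_path = eci_map_path, simulate = simulate,
    mn_era = as.character(mn_era), modeling_era = as.character(modeling_era),
    inclusion = modifyList(list(min_age = 65L, los_quantile = 0.99, los_cutoff = NULL),
      inclusion),
    mn = modifyList(list(min_pair_count = 1L, edge_rule = "ci_low_gt_1",
      sigma_mode = "sqrt", weight_mode = "rr"), mn),
    psn = modifyList(list(k = 100L, exclude_same_patient = TRUE), psn),
    features = modifyList(list(window_years = 3, lda = TRUE,
      lda_candidates = c(8L, 16L, 32L, 64L), lda_components = NULL), features),
    plan = modifyList(list(models = "xgboost", repeats = 10L, tune = TRUE), plan),
    seed = as.integer(seed)
  )
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error(paste0("no such config file: ", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    config_error(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

config_error <- function(msg) {
  abort(msg, class = "losnet_config_error")
}

validate_pipeline_config <- function(cfg) {
  problems <- character(0)
  mn_era <- try(as.Date(cfg$mn_era), silent = TRUE)
  mod_era <- try(as.Date(cfg$modeling_era), silent = TRUE)
  if (inherits(mn_era, "try-error") || anyNA(mn_era) || length(mn_era) != 2) {
    problems <- c(problems, "mn_era must be two parseable dates")
  }
  if (inherits(mod_era, "try-error") || anyNA(mod_era) || length(mod_era) != 2) {
    problems <- c(problems, "modeling_era must be two parseable dates")
  }
  if (length(problems) == 0 && !(mn_era[2] < mod_era[1])) {
    problems <- c(problems, "the network era must end before the modeling era begins")
  }
  q <- cfg$inclusion$los_quantile
  if (!is.numeric(q) || q <= 0 || q >= 1) {
    problems <- c(problems, "inclusion$los_quantile must be in (0, 1)")
  }
  for (pth in c(cfg$records_path, cfg$catalog_path, cfg$eci_map_path)) {
    if (!is.null(pth) && !file.exists(pth)) {
      problems <- c(problems, paste0("path does not resolve: ", pth))
    }
  }
  if (!cfg$mn$edge_rule %in% c("ci_low_gt_1", "rr_gt_1", "all")) {
    problems <- c(problems, "mn$edge_rule must be ci_low_gt_1, rr_gt_1 or all")
  }
  if (length(problems) > 0) {
    config_error(paste0("invalid configuration:\n  - ",
      paste(problems, collapse = "\n  - ")))
  }
  invisible(cfg)
}

config_hash <- function(cfg) {
  fnv1a32(as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null")))
}

pipeline_stages <- function() {
  c("simulate", "filter", "build-mn", "build-psn", "featurize", "reduce",
    "train", "evaluate", "report")
}

artifact <- function(out_dir, name) file.path(out_dir, name)

require_artifact <- function(out_dir, name, producer) {
  p <- artifact(out_dir, name)
  if (!file.exists(p)) {
    abort(paste0("missing artifact '", name, "': run the '", producer,
      "' stage first"), class = "losnet_stage_error")
  }
  p
}

write_manifest <- function(out_dir, stage, cfg, seed, counts, inputs = character(0)) {
  manifest <- list(
    stage = stage, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, config_hash = config_hash(cfg),
    inputs = as.list(inputs), counts = counts
  )
  jsonlite::write_json(manifest, artifact(out_dir, paste0("manifest_", gsub("-", "_", stage), ".json")),
    auto_unbox = TRUE, pretty = TRUE)
  log_stage(stage, paste0(
    "done (", paste(names(counts), unlist(counts), sep = "=", collapse = ", "), ")"
  ))
}

log_stage <- function(stage, msg, level = "INFO") {
  inform(sprintf("[%s] %s %-9s %s", format(Sys.time(), "%H:%M:%S"), level, stage, msg))
}

load_catalog <- function(cfg, out_dir) {
  path <- cfg$catalog_path %||% require_artifact(out_dir, "catalog.csv", "simulate")
  codes <- readr::read_csv(path, col_types = "c", progress = FALSE)$code
  chronic_catalog(codes, paste0("file: ", path))
}

load_eci_map <- function(cfg, catalog) {
  if (!is.null(cfg$eci_map_path)) return(read_eci_map(cfg$eci_map_path))
  if (is.null(cfg$records_path)) return(synthetic_eci_map(as.character(catalog)))
  NULL
}

#' Run pipeline stages
#'
#' Orchestrates the end-to-end flow: `simulate` (synthetic cohort),
#' `filter` (inclusion criteria), `build-mn` (construction-era network with
#' centrality), `featurize` (split-aware feature table; also writes the
#' `build-psn` neighbour lists and the `reduce` discriminant projection),
#' `train` (the ablation experiment), `evaluate` (summary tables and the
#' per-LOS error profile) and `report` (a plain-text summary). Each stage
#' writes versioned CSV/JSON artifacts plus a manifest with its seed,
#' configuration hash and row counts; `all` chains every stage. Reruns with
#' the same config and seed are bit-identical for the deterministic stages.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param stage One of `r paste0('\x60', pipeline_stages(), '\x60', collapse = ", ")`
#'   or `"all"`.
#' @param out_dir Artifact directory (created if needed).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config, stage = "all", out_dir = "losnet-run") {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  validate_pipeline_config(cfg)
  if (!stage %in% c(pipeline_stages(), "all")) {
    config_error(paste0("unknown stage '", stage, "'"))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (stage == "all") {
    c("simulate", "filter", "build-mn", "featurize", "train", "evaluate", "report")
  } else {
    stage
  }
  for (st in stages) run_stage(st, cfg, out_dir)
  invisible(out_dir)
}

run_stage <- function(st, cfg, out_dir) {
  seed <- stage_seed(cfg$seed, st)
  log_stage(st, "starting")
  switch(st,
    "simulate" = stage_simulate(cfg, out_dir, seed),
    "filter" = stage_filter(cfg, out_dir, seed),
    "build-mn" = stage_build_mn(cfg, out_dir, seed),
    "build-psn" = stage_psn_export(cfg, out_dir, seed),
    "featurize" = stage_featurize(cfg, out_dir, seed),
    "reduce" = stage_reduce_export(cfg, out_dir, seed),
    "train" = stage_train(cfg, out_dir, seed),
    "evaluate" = stage_evaluate(cfg, out_dir, seed),
    "report" = stage_report(cfg, out_dir, seed)
  )
}

stage_simulate <- function(cfg, out_dir, seed) {
  if (!is.null(cfg$records_path)) {
    file.copy(cfg$records_path, artifact(out_dir, "records.csv"), overwrite = TRUE)
    write_manifest(out_dir, "simulate", cfg, seed,
      list(copied = 1L), inputs = cfg$records_path)
    return(invisible())
  }
  sim_args <- cfg$simulate
  if (is.null(sim_args$seed)) sim_args$seed <- seed
  if (!is.null(sim_args$planted_pairs) && !is.data.frame(sim_args$planted_pairs)) {
    # YAML gives a list of {i, j, rr} maps
    sim_args$planted_pairs <- bind_rows(lapply(sim_args$planted_pairs, as_tibble))
  }
  cohort <- generate_cohort(do.call(cohort_params, sim_args))
  write_admissions(cohort$records, artifact(out_dir, "records.csv"))
  readr::write_csv(tibble(code = as.character(cohort$catalog)),
    artifact(out_dir, "catalog.csv"), progress = FALSE)
  jsonlite::write_json(
    list(
      planted_pairs = cohort$truth$planted_pairs,
      disease_effects = as.list(cohort$truth$disease_effects)
    ),
    artifact(out_dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE
  )
  write_manifest(out_dir, "simulate", cfg, seed,
    list(records = nrow(cohort$records), diseases = length(cohort$catalog)))
}

stage_filter <- function(cfg, out_dir, seed) {
  rec_path <- require_artifact(out_dir, "records.csv", "simulate")
  records <- read_admissions(rec_path)
  catalog <- load_catalog(cfg, out_dir)
  res <- apply_inclusion_criteria(records, catalog,
    min_age = cfg$inclusion$min_age,
    los_quantile = cfg$inclusion$los_quantile,
    los_cutoff = cfg$inclusion$los_cutoff,
    date_range = c(cfg$mn_era[1], cfg$modeling_era[2])
  )
  write_admissions(res$records, artifact(out_dir, "filtered.csv"))
  readr::write_csv(res$tally, artifact(out_dir, "inclusion_tally.csv"), progress = FALSE)
  write_manifest(out_dir, "filter", cfg, seed,
    list(kept = nrow(res$records), removed = sum(res$tally$removed),
      los_cutoff = res$cutoff), inputs = "records.csv")
}

stage_build_mn <- function(cfg, out_dir, seed) {
  rec_path <- require_artifact(out_dir, "filtered.csv", "filter")
  records <- read_admissions(rec_path)
  catalog <- load_catalog(cfg, out_dir)
  M <- build_disease_matrix(records, catalog, era = cfg$mn_era)
  mn <- build_mn(M,
    min_pair_count = cfg$mn$min_pair_count,
    edge_rule = cfg$mn$edge_rule, sigma_mode = cfg$mn$sigma_mode
  )
  mn <- add_centrality(mn, weight_mode = cfg$mn$weight_mode)
  write_mn(mn, artifact(out_dir, "mn_edges.csv"), artifact(out_dir, "mn_nodes.csv"))
  write_manifest(out_dir, "build-mn", cfg, seed,
    list(nodes = nrow(mn$nodes), edges = nrow(mn$edges),
      patients = mn$n_patients), inputs = "filtered.csv")
}

# Shared by the featurize/psn/reduce stages: modeling-era rows, the default
# split (stage-seeded), and the featurized object.
featurize_for_pipeline <- function(cfg, out_dir, seed) {
  rec_path <- require_artifact(out_dir, "filtered.csv", "filter")
  require_artifact(out_dir, "mn_nodes.csv", "build-mn")
  records <- read_admissions(rec_path)
  catalog <- load_catalog(cfg, out_dir)
  nodes <- readr::read_csv(artifact(out_dir, "mn_nodes.csv"),
    col_types = readr::cols(), progress = FALSE)
  if (!"evc" %in% names(nodes)) {
    abort("mn_nodes.csv lacks centrality scores: rerun build-mn",
      class = "losnet_stage_error")
  }
  evc <- setNames(nodes$evc, nodes$code)
  era <- as.Date(cfg$modeling_era)
  modeling <- records[records$admission_date >= era[1] &
    records$admission_date <= era[2], , drop = FALSE]
  split <- split_rows(modeling$record_id, seed = seed)
  fz <- featurize(modeling, records, catalog, evc, split,
    eci_map = load_eci_map(cfg, catalog),
    k_neighbors = cfg$psn$k,
    window_years = cfg$features$window_years,
    exclude_same_patient = cfg$psn$exclude_same_patient,
    lda = cfg$features$lda,
    lda_candidates = cfg$features$lda_candidates,
    lda_components = cfg$features$lda_components
  )
  list(fz = fz, modeling = modeling, records = records, catalog = catalog, evc = evc)
}

stage_featurize <- function(cfg, out_dir, seed) {
  env <- featurize_for_pipeline(cfg, out_dir, stage_seed(cfg$seed, "featurize"))
  fz <- env$fz
  readr::write_csv(fz$table, artifact(out_dir, "features.csv"), progress = FALSE)
  jsonlite::write_json(as.list(feature_groups(fz$table)),
    artifact(out_dir, "feature_schema.json"), auto_unbox = TRUE, pretty = TRUE)
  readr::write_csv(fz$neighbors, artifact(out_dir, "neighbors.csv"), progress = FALSE)
  if (!is.null(fz$projection)) {
    readr::write_csv(as_tibble(fz$projection$rotation, rownames = "feature"),
      artifact(out_dir, "lda_projection.csv"), progress = FALSE)
    jsonlite::write_json(
      list(n_components = fz$projection$n_components,
        n_classes = length(fz$projection$classes),
        n_train = fz$projection$n_train),
      artifact(out_dir, "lda_meta.json"), auto_unbox = TRUE, pretty = TRUE
    )
  }
  jsonlite::write_json(fz$split, artifact(out_dir, "split.json"), pretty = TRUE)
  write_manifest(out_dir, "featurize", cfg, stage_seed(cfg$seed, "featurize"),
    list(rows = nrow(fz$table), features = length(feature_groups(fz$table)),
      vocab = length(fz$vocab)),
    inputs = c("filtered.csv", "mn_nodes.csv"))
}

stage_psn_export <- function(cfg, out_dir, seed) {
  require_artifact(out_dir, "neighbors.csv", "featurize")
  n <- nrow(readr::read_csv(artifact(out_dir, "neighbors.csv"),
    col_types = readr::cols(), progress = FALSE))
  write_manifest(out_dir, "build-psn", cfg, seed,
    list(neighbor_pairs = n), inputs = "neighbors.csv")
}

stage_reduce_export <- function(cfg, out_dir, seed) {
  require_artifact(out_dir, "lda_projection.csv", "featurize")
  p <- readr::read_csv(artifact(out_dir, "lda_projection.csv"),
    col_types = readr::cols(), progress = FALSE)
  write_manifest(out_dir, "reduce", cfg, seed,
    list(features = nrow(p), components = ncol(p) - 1L),
    inputs = "lda_projection.csv")
}

stage_train <- function(cfg, out_dir, seed) {
  env <- featurize_for_pipeline(cfg, out_dir, stage_seed(cfg$seed, "featurize"))
  models <- setNames(
    lapply(cfg$plan$models, model_spec),
    cfg$plan$models
  )
  plan <- experiment_plan(
    models = models, repeats = cfg$plan$repeats, base_seed = seed,
    tune = cfg$plan$tune,
    feature_opts = list(
      k_neighbors = cfg$psn$k, window_years = cfg$features$window_years,
      exclude_same_patient = cfg$psn$exclude_same_patient,
      lda = cfg$features$lda, lda_candidates = cfg$features$lda_candidates,
      lda_components = cfg$features$lda_components
    )
  )
  report <- run_ablation(env$modeling, env$records, env$catalog, env$evc, plan,
    eci_map = load_eci_map(cfg, env$catalog))
  readr::write_csv(
    report$results |> mutate(params = purrr::map_chr(.data$params,
      ~ as.character(jsonlite::toJSON(.x, auto_unbox = TRUE)))),
    artifact(out_dir, "ablation_results.csv"), progress = FALSE
  )
  if (!is.null(report$predictions)) {
    readr::write_csv(report$predictions, artifact(out_dir, "test_predictions.csv"),
      progress = FALSE)
  }
  for (mname in names(report$importance)) {
    readr::write_csv(report$importance[[mname]]$group_importance,
      artifact(out_dir, paste0("importance_groups_", mname, ".csv")), progress = FALSE)
    readr::write_csv(report$importance[[mname]]$top_features,
      artifact(out_dir, paste0("importance_top_", mname, ".csv")), progress = FALSE)
  }
  write_manifest(out_dir, "train", cfg, seed,
    list(cells = nrow(report$results)), inputs = c("filtered.csv", "mn_nodes.csv"))
}

stage_evaluate <- function(cfg, out_dir, seed) {
  res_path <- require_artifact(out_dir, "ablation_results.csv", "train")
  results <- readr::read_csv(res_path, col_types = readr::cols(), progress = FALSE)
  summary <- results |>
    group_by(.data$model, .data$subset) |>
    summarise(
      mae_mean = mean(.data$mae), mae_sd = stats::sd(.data$mae),
      rmse_mean = mean(.data$rmse), rmse_sd = stats::sd(.data$rmse),
      r2_mean = mean(.data$r2), r2_sd = stats::sd(.data$r2),
      .groups = "drop"
    )
  readr::write_csv(summary, artifact(out_dir, "evaluation_summary.csv"), progress = FALSE)
  pred_path <- artifact(out_dir, "test_predictions.csv")
  if (file.exists(pred_path)) {
    preds <- readr::read_csv(pred_path, col_types = readr::cols(), progress = FALSE)
    profile <- per_los_mae(preds, by = c("sex", "age_band"))
    readr::write_csv(profile, artifact(out_dir, "per_los_mae.csv"), progress = FALSE)
  }
  write_manifest(out_dir, "evaluate", cfg, seed,
    list(cells = nrow(summary)), inputs = "ablation_results.csv")
}

stage_report <- function(cfg, out_dir, seed) {
  sum_path <- require_artifact(out_dir, "evaluation_summary.csv", "evaluate")
  summary <- readr::read_csv(sum_path, col_types = readr::cols(), progress = FALSE)
  lines <- c(
    "# Pipeline report",
    "",
    paste0("Config hash: ", config_hash(cfg), "; global seed: ", cfg$seed),
    "",
    "model | subset | MAE (mean+/-sd) | RMSE | R2",
    "----- | ------ | --------------- | ---- | --"
  )
  for (i in seq_len(nrow(summary))) {
    s <- summary[i, ]
    lines <- c(lines, sprintf(
      "%s | %s | %.3f+/-%.3f | %.3f+/-%.3f | %.3f+/-%.3f",
      s$model, s$subset, s$mae_mean, s$mae_sd, s$rmse_mean, s$rmse_sd,
      s$r2_mean, s$r2_sd
    ))
  }
  writeLines(lines, artifact(out_dir, "report.md"))
  write_manifest(out_dir, "report", cfg, seed,
    list(rows = nrow(summary)), inputs = "evaluation_summary.csv")
}
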