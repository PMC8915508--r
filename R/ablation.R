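#' Split-aware feature computation for one train/val/test partition
#'
#' Computes the full group-tagged feature table for the modeling admissions
#' under a given partition, using training rows only for every statistic a
#' row's features could leak through: the centrality-feature vocabulary
#' (multimorbidity-network nodes seen at PoA among training rows), the
#' per-disease mean LOS and disease-risk table, the patient-similarity
#' index, and the discriminant projection of the centrality block.
#' Baseline and historical blocks are row-local and may be passed in via
#' `cache` to avoid recomputation across repeats.
#'
#' @param records Modeling admission tibble (post-inclusion, modeling era).
#' @param history Admission tibble to draw patients' past stays from.
#' @param catalog [chronic_catalog()].
#' @param evc Named centrality vector from [eigenvector_centrality()] on the
#'   construction-era network.
#' @param split A list with `train`, `val`, `test` record-id vectors from
#'   [split_rows()].
#' @param eci_map Code-to-Elixhauser map (see [baseline_features()]).
#' @param k_neighbors Similarity neighbours per admission (default 100).
#' @param window_years Historical lookback (default 3).
#' @param exclude_same_patient Same-patient exclusion in the similarity
#'   queries (default `TRUE`).
#' @param lda Apply discriminant compression to the centrality block
#'   (default `TRUE`).
#' @param lda_candidates Candidate output dimensions for validation-driven
#'   selection (default `c(8, 16, 32, 64)`).
#' @param lda_components Fixed output dimension, skipping selection
#'   (`NULL`, the default, selects on the validation split).
#' @param cache Optional list with precomputed `baseline` and `history`
#'   blocks.
#' @return A list of class `featurized`: `table` (the `feature_table`),
#'   `split`, `projection`, `vocab`, `risk_table`, `neighbors`, `cache`.
#' @export
featurize <- function(records, history, catalog, evc, split,
                      eci_map = NULL,
                      k_neighbors = 100L,
                      window_years = 3,
                      exclude_same_patient = TRUE,
                      lda = TRUE,
                      lda_candidates = c(8L, 16L, 32L, 64L),
                      lda_components = NULL,
                      cache = NULL) {
  ids <- records$record_id
  stopifnot(setequal(c(split$train, split$val, split$test), ids))
  in_train <- ids %in% split$train
  train_records <- records[in_train, , drop = FALSE]

  base_blk <- cache$baseline %||% baseline_features(records, eci_map)
  hist_blk <- cache$history %||% historical_features(records, history, window_years)

  # Vocabulary and risk statistics from training rows only (leakage guard).
  train_poa <- unique(unlist(diagnosis_sets(train_records, poa_only = TRUE, catalog = catalog)))
  vocab <- sort(intersect(names(evc), train_poa))
  if (length(vocab) == 0) abort("empty centrality vocabulary: no network disease seen at PoA in training")
  risk_tab <- disease_risk_table(evc, los_mean_per_disease(train_records, catalog))
  risk_blk <- disease_risk_features(records, risk_tab, catalog)
  evc_blk <- evc_features(records, evc, vocab, catalog)

  projection <- NULL
  if (lda) {
    evc_mat <- as.matrix(evc_blk[, -1, drop = FALSE])
    tr <- which(in_train)
    va <- which(ids %in% split$val)
    if (is.null(lda_components)) {
      lda_components <- select_components(
        lda_candidates, evc_mat[tr, , drop = FALSE], records$los[tr],
        evc_mat[va, , drop = FALSE], records$los[va]
      )
    }
    projection <- fit_lda(evc_mat[tr, , drop = FALSE], records$los[tr],
      as.integer(lda_components))
    mn_main <- bind_cols(
      tibble(record_id = ids),
      as_tibble(lda_transform(projection, evc_mat))
    )
  } else {
    mn_main <- evc_blk
  }

  index <- build_similarity_index(train_records, catalog)
  neighbors <- query_neighbors(index, records, catalog,
    k = k_neighbors, exclude_same_patient = exclude_same_patient)
  psn_blk <- psn_features(records, neighbors)

  table <- assemble_features(records, list(
    baseline = list(base_blk),
    history = list(hist_blk),
    mn = list(mn_main, risk_blk),
    psn = list(psn_blk)
  ))
  structure(
    list(
      table = table, split = split, projection = projection,
      vocab = vocab, risk_table = risk_tab, neighbors = neighbors,
      cache = list(baseline = base_blk, history = hist_blk)
    ),
    class = "featurized"
  )
}

#' Define an ablation experiment plan
#'
#' The default plan mirrors the standard design: five feature-subset
#' combinations (baseline alone, baseline plus each other group, and all
#' four), each model tuned by grid search on a validation split, the whole
#' experiment repeated over reseeded splits and summarized as mean and
#' standard deviation per cell.
#'
#' @param models Named list of [model_spec()]s (default: boosted trees).
#' @param subsets Named list of group-tag vectors.
#' @param repeats Number of reseeded repeats (default 10).
#' @param base_seed Base seed; repeat `r` uses `base_seed + r`.
#' @param tune Run grid search per cell (default `TRUE`; `FALSE` uses each
#'   spec's fixed parameters, which is faster).
#' @param feature_opts Named list forwarded to [featurize()].
#' @return A list of class `experiment_plan`.
#' @export
experiment_plan <- function(models = list(xgboost = model_spec("xgboost")),
                            subsets = default_subsets(),
                            repeats = 10L,
                            base_seed = 42L,
                            tune = TRUE,
                            feature_opts = list()) {
  stopifnot(repeats >= 1, length(models) >= 1, length(subsets) >= 1)
  structure(
    list(
      models = models, subsets = subsets, repeats = as.integer(repeats),
      base_seed = as.integer(base_seed), tune = tune,
      feature_opts = feature_opts
    ),
    class = "experiment_plan"
  )
}

#' @rdname experiment_plan
#' @export
default_subsets <- function() {
  list(
    baseline = "baseline",
    baseline_history = c("baseline", "history"),
    baseline_mn = c("baseline", "mn"),
    baseline_psn = c("baseline", "psn"),
    full = c("baseline", "history", "mn", "psn")
  )
}

#' Run the feature-subset ablation experiment
#'
#' For each repeat `r`: reseed the train/val/test split with
#' `base_seed + r`, recompute all split-dependent features on the training
#' rows ([featurize()]), then for every feature subset and model run grid
#' search on train/validation, refit the winner on the training rows and
#' score the test rows with MAE, RMSE and R-squared.
#'
#' @param records Modeling admission tibble.
#' @param history Admission tibble for historical lookups.
#' @param catalog [chronic_catalog()].
#' @param evc Named centrality vector of the construction-era network.
#' @param plan An [experiment_plan()].
#' @param eci_map Optional code-to-Elixhauser map.
#' @return An object of class `ablation_report`: `results` (one row per
#'   model x subset x repeat with metrics and tuned parameters),
#'   `importance` (per model: [grouped_importance()] of the full subset,
#'   last repeat), `predictions` (test-row predictions of the full subset,
#'   last repeat, for error profiling), and `plan`.
#' @export
run_ablation <- function(records, history, catalog, evc, plan = experiment_plan(),
                         eci_map = NULL) {
  unknown <- setdiff(unique(unlist(plan$subsets)), c("baseline", "history", "mn", "psn"))
  if (length(unknown) > 0) {
    abort(paste0("unknown feature group(s) in subsets: ", paste(unknown, collapse = ", ")))
  }
  results <- list()
  importance <- list()
  predictions <- NULL
  cache <- NULL
  for (r in seq_len(plan$repeats)) {
    seed_r <- plan$base_seed + r
    split <- split_rows(records$record_id, seed = seed_r)
    fz <- rlang::exec(featurize,
      records = records, history = history, catalog = catalog,
      evc = evc, split = split, eci_map = eci_map, cache = cache,
      !!!plan$feature_opts
    )
    cache <- fz$cache
    ft <- fz$table
    groups <- feature_groups(ft)
    idx_of <- function(ids) match(ids, ft$record_id)
    tr <- idx_of(split$train)
    va <- idx_of(split$val)
    te <- idx_of(split$test)
    y <- ft$los
    for (sname in names(plan$subsets)) {
      cols <- names(groups)[groups %in% plan$subsets[[sname]]]
      x <- as.matrix(ft[, cols, drop = FALSE])
      for (mname in names(plan$models)) {
        spec <- plan$models[[mname]]
        params <- if (plan$tune) {
          grid_search(spec, x[tr, , drop = FALSE], y[tr],
            x[va, , drop = FALSE], y[va], seed = seed_r)
        } else {
          spec$params
        }
        fit <- spec$fit(x[tr, , drop = FALSE], y[tr], params, seed_r)
        pred <- spec$predict(fit, x[te, , drop = FALSE])
        results[[length(results) + 1]] <- tibble(
          model = mname, subset = sname, repeat_ = r, seed = seed_r,
          mae = mae(y[te], pred), rmse = rmse(y[te], pred), r2 = r2(y[te], pred),
          params = list(params[setdiff(names(params), "")])
        )
        if (sname == "full" && r == plan$repeats) {
          if (!is.null(spec$importance)) {
            imp <- tryCatch(spec$importance(fit), error = function(e) NULL)
            if (!is.null(imp)) importance[[mname]] <- grouped_importance(imp, groups)
          }
          if (is.null(predictions) || mname == names(plan$models)[1]) {
            predictions <- records[te, c("record_id", "sex", "age", "los")] |>
              mutate(age_band = age_group(.data$age), pred = pred, model = mname)
          }
        }
      }
    }
  }
  structure(
    list(
      results = bind_rows(results), importance = importance,
      predictions = predictions, plan = plan
    ),
    class = "ablation_report"
  )
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("<ablation_report>", length(unique(x$results$model)), "model(s) x",
    length(unique(x$results$subset)), "subset(s) x",
    max(x$results$repeat_), "repeat(s)\n")
  print(tidy(x), n = 30)
  invisible(x)
}
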