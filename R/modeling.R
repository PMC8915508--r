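#' Train/validation/test split of row ids
#'
#' Draws the test set first (`test_frac` of all rows), then the validation
#' set (`val_frac` of the remaining training rows); deterministic given the
#' seed.
#'
#' @param ids Vector of row ids (>= 10).
#' @param seed Integer seed.
#' @param test_frac Test fraction of all rows (default 0.2).
#' @param val_frac Validation fraction of the non-test rows (default 0.2).
#' @return A list with `train`, `val`, `test` id vectors (disjoint, covering
#'   `ids`).
#' @export
#' @examples
#' s <- split_rows(1:100, seed = 1)
#' lengths(s) # 64, 16, 20
split_rows <- function(ids, seed, test_frac = 0.2, val_frac = 0.2) {
  if (length(ids) < 10) abort("need at least 10 rows to split")
  withr::with_seed(as.integer(seed), {
    test <- sample(ids, size = round(test_frac * length(ids)))
    rest <- setdiff(ids, test)
    val <- sample(rest, size = round(val_frac * length(rest)))
    list(train = setdiff(rest, val), val = val, test = test)
  })
}

#' Regression evaluation metrics
#'
#' Mean absolute error, root mean squared error and the coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot`, with `SS_tot` taken around the
#' mean of the observed values, so a mean-forecast model scores exactly 0.
#'
#' @param y Observed values.
#' @param y_hat Predicted values (same length).
#' @return A single numeric value.
#' @export
#' @examples
#' mae(c(1, 3), c(2, 2)) # 1
#' rmse(c(1, 3), c(2, 2)) # 1
#' r2(c(1, 3), c(2, 2)) # 0
mae <- function(y, y_hat) {
  check_lengths(y, y_hat)
  mean(abs(y - y_hat))
}

#' @rdname mae
#' @export
rmse <- function(y, y_hat) {
  check_lengths(y, y_hat)
  sqrt(mean((y - y_hat)^2))
}

#' @rdname mae
#' @export
r2 <- function(y, y_hat) {
  check_lengths(y, y_hat)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) abort("R^2 undefined for constant observed values")
  1 - sum((y - y_hat)^2) / ss_tot
}

check_lengths <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) == 0) {
    abort("y and y_hat must have equal, non-zero length")
  }
}

#' Pluggable regressor specifications
#'
#' A uniform fit/predict/importance surface over established
#' implementations: `"xgboost"` (gradient-boosted trees, the default
#' model), `"random_forest"` (ranger) and `"linear_svm"` (e1071, inputs
#' standardized to training mean/sd before fitting). Each spec carries a
#' small default hyper-parameter grid for [grid_search()].
#'
#' @param name Model name.
#' @param params Fixed parameters merged over the defaults.
#' @param grid Named list of vectors to tune over (overrides the default
#'   grid).
#' @return An object of class `model_spec` with elements `name`, `params`,
#'   `grid`, and functions `fit(x, y, params, seed)`, `predict(fit, x)`,
#'   `importance(fit)` (`NULL` if the model has none).
#' @export
model_spec <- function(name = c("xgboost", "random_forest", "linear_svm"),
                       params = list(), grid = NULL) {
  name <- match.arg(name)
  spec <- switch(name,
    xgboost = list(
      params = list(nrounds = 100, max_depth = 6, learning_rate = 0.1,
        subsample = 0.9, colsample_bytree = 0.9),
      grid = list(max_depth = c(3, 6)),
      fit = function(x, y, params, seed) {
        xgboost::xgboost(
          x, y,
          nrounds = params$nrounds, max_depth = params$max_depth,
          learning_rate = params$learning_rate, subsample = params$subsample,
          colsample_bytree = params$colsample_bytree,
          nthreads = 1, verbosity = 0, seed = seed %% 2147483647
        )
      },
      predict = function(fit, x) predict(fit, x),
      importance = function(fit) {
        imp <- xgboost::xgb.importance(model = fit)
        setNames(imp$Gain, imp$Feature)
      }
    ),
    random_forest = list(
      params = list(num.trees = 300, min.node.size = 5),
      grid = list(min.node.size = c(5, 20)),
      fit = function(x, y, params, seed) {
        if (!requireNamespace("ranger", quietly = TRUE)) {
          abort("the random_forest spec requires the ranger package")
        }
        ranger::ranger(
          x = as.data.frame(x), y = y,
          num.trees = params$num.trees, min.node.size = params$min.node.size,
          importance = "impurity", seed = seed, num.threads = 1
        )
      },
      predict = function(fit, x) predict(fit, data = as.data.frame(x))$predictions,
      importance = function(fit) fit$variable.importance
    ),
    linear_svm = list(
      params = list(cost = 1),
      grid = list(cost = c(0.1, 1)),
      fit = function(x, y, params, seed) {
        if (!requireNamespace("e1071", quietly = TRUE)) {
          abort("the linear_svm spec requires the e1071 package")
        }
        ctr <- colMeans(x)
        scl <- apply(x, 2, stats::sd)
        scl[scl == 0] <- 1
        xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
        fit <- e1071::svm(x = xs, y = y, kernel = "linear",
          cost = params$cost, scale = FALSE)
        list(fit = fit, center = ctr, scale = scl)
      },
      predict = function(fit, x) {
        xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
        as.numeric(predict(fit$fit, xs))
      },
      importance = function(fit) NULL
    )
  )
  structure(
    list(
      name = name,
      params = modifyList(spec$params, params),
      grid = grid %||% spec$grid,
      fit = spec$fit, predict = spec$predict, importance = spec$importance
    ),
    class = "model_spec"
  )
}

#' Exhaustive grid search on a validation split
#'
#' Evaluates every combination of the grid (in declared order), scoring
#' validation MAE; returns the first-best parameter set merged over the
#' spec's fixed parameters.
#'
#' @param spec A [model_spec()].
#' @param x_train,y_train Training matrix and labels.
#' @param x_val,y_val Validation matrix and labels.
#' @param grid Named list of vectors (default: the spec's grid).
#' @param seed Seed forwarded to the model fits.
#' @return The best parameter list, with the per-combination results tibble
#'   as attribute `results`.
#' @export
grid_search <- function(spec, x_train, y_train, x_val, y_val,
                        grid = NULL, seed = 1L) {
  grid <- grid %||% spec$grid
  if (length(grid) == 0) abort("empty tuning grid")
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  scores <- numeric(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    params <- modifyList(spec$params, as.list(combos[ci, , drop = FALSE]))
    fit <- tryCatch(
      spec$fit(x_train, y_train, params, seed),
      error = function(e) {
        abort(paste0(
          "model fit failed for params {",
          paste(names(combos), combos[ci, ], sep = "=", collapse = ", "),
          "}: ", conditionMessage(e)
        ))
      }
    )
    scores[ci] <- mae(y_val, spec$predict(fit, x_val))
  }
  best <- which.min(scores) # first minimum wins ties (declared grid order)
  structure(
    modifyList(spec$params, as.list(combos[best, , drop = FALSE])),
    results = bind_cols(as_tibble(combos), tibble(val_mae = scores))
  )
}

#' Per-LOS mean absolute error profile
#'
#' For each observed integer LOS value, the number of test rows and their
#' MAE; optionally repeated within subgroups (e.g. sex, age band). Empty
#' cells are omitted.
#'
#' @param predictions Tibble with columns `los` and `pred`, plus any
#'   subgroup columns.
#' @param by Character vector of subgroup column names (default none).
#' @return Tibble `group`, `level`, `los`, `n`, `mae`; the overall profile
#'   uses `group = "overall"`.
#' @export
per_los_mae <- function(predictions, by = character(0)) {
  profile_one <- function(df, group, level) {
    df |>
      group_by(los = .data$los) |>
      summarise(n = n(), mae = mean(abs(.data$los - .data$pred)), .groups = "drop") |>
      mutate(group = group, level = level, .before = 1)
  }
  out <- list(profile_one(predictions, "overall", "all"))
  for (g in by) {
    for (lv in sort(unique(as.character(predictions[[g]])))) {
      out <- c(out, list(profile_one(
        predictions[as.character(predictions[[g]]) == lv, , drop = FALSE], g, lv
      )))
    }
  }
  bind_rows(out)
}

#' Group-aggregated and top-k feature importances
#'
#' Sums per-feature importances within each feature group, and lists the
#' `top_k` features by raw importance with min-max relative importance
#' (RI = 1 for the top feature, 0 for the k-th) over the top-k set.
#'
#' @param importance Named numeric vector of per-feature importances (e.g.
#'   from a fitted spec's `importance()`), or `NULL`.
#' @param groups Named character vector: feature column -> group tag (see
#'   [feature_groups()]).
#' @param top_k Number of top features to list (default 10).
#' @return A list with `group_importance` (tibble `group`, `importance`)
#'   and `top_features` (tibble `feature`, `group`, `importance`, `ri`).
#' @export
grouped_importance <- function(importance, groups, top_k = 10L) {
  if (is.null(importance)) {
    abort("this model does not expose per-feature importances")
  }
  imp <- setNames(rep(0, length(groups)), names(groups))
  known <- intersect(names(importance), names(imp))
  imp[known] <- importance[known]
  group_imp <- tibble(feature = names(imp), importance = unname(imp)) |>
    mutate(group = unname(groups[.data$feature])) |>
    group_by(.data$group) |>
    summarise(importance = sum(.data$importance), .groups = "drop")
  top <- tibble(
    feature = names(imp), importance = unname(imp),
    group = unname(groups[names(imp)])
  ) |>
    arrange(dplyr::desc(.data$importance), .data$feature) |>
    head(top_k)
  rng <- range(top$importance)
  top$ri <- if (diff(rng) == 0) rep(1, nrow(top)) else (top$importance - rng[1]) / diff(rng)
  list(group_importance = group_imp, top_features = top)
}
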