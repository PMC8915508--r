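#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   facet_wrap labs position_dodge theme_minimal
#' @export
ggplot2::autoplot

#' Tidy the multimorbidity network into its edge list
#'
#' @param x A `multimorbidity_network`.
#' @param ... Unused.
#' @return The edge tibble (`code_i`, `code_j`, `c_ij`, `rr`, `ci_low`,
#'   `ci_high`).
#' @export
tidy.multimorbidity_network <- function(x, ...) x$edges

#' One-row summary of a multimorbidity network
#'
#' @param x A `multimorbidity_network`.
#' @param ... Unused.
#' @return Tibble: node, edge and candidate counts, patient count, edge
#'   density among candidate pairs.
#' @export
glance.multimorbidity_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_candidates = x$n_candidates,
    n_patients = x$n_patients,
    retained_frac = if (x$n_candidates > 0) nrow(x$edges) / x$n_candidates else NA_real_
  )
}

#' Tidy an inclusion result into its exclusion tally
#'
#' @param x An `inclusion_result`.
#' @param ... Unused.
#' @return The tally tibble (`criterion`, `removed`).
#' @export
tidy.inclusion_result <- function(x, ...) x$tally

#' @export
glance.inclusion_result <- function(x, ...) {
  tibble(n_kept = nrow(x$records), n_removed = sum(x$tally$removed), los_cutoff = x$cutoff)
}

#' Tidy a discriminant projection into its loadings
#'
#' @param x An `lda_projection`.
#' @param ... Unused.
#' @return Long tibble `feature`, `component`, `loading`.
#' @export
tidy.lda_projection <- function(x, ...) {
  as_tibble(x$rotation, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "component", values_to = "loading")
}

#' @export
glance.lda_projection <- function(x, ...) {
  tibble(
    n_features = nrow(x$rotation), n_components = x$n_components,
    n_classes = length(x$classes), n_train = x$n_train
  )
}

#' Summarize ablation results as mean and spread per cell
#'
#' @param x An `ablation_report`.
#' @param ... Unused.
#' @return Tibble: one row per model x subset with `mae_mean`, `mae_sd`,
#'   `rmse_mean`, `rmse_sd`, `r2_mean`, `r2_sd` over the repeats.
#' @export
tidy.ablation_report <- function(x, ...) {
  x$results |>
    group_by(.data$model, .data$subset) |>
    summarise(
      n_repeats = n(),
      mae_mean = mean(.data$mae), mae_sd = stats::sd(.data$mae),
      rmse_mean = mean(.data$rmse), rmse_sd = stats::sd(.data$rmse),
      r2_mean = mean(.data$r2), r2_sd = stats::sd(.data$r2),
      .groups = "drop"
    )
}

#' @export
glance.ablation_report <- function(x, ...) {
  s <- tidy(x)
  best <- s[which.max(s$r2_mean), ]
  tibble(
    n_models = length(unique(s$model)), n_subsets = length(unique(s$subset)),
    n_repeats = max(x$results$repeat_),
    best_model = best$model, best_subset = best$subset,
    best_r2 = best$r2_mean, best_mae = best$mae_mean
  )
}

#' Plot ablation performance by feature subset
#'
#' Bar chart of mean test R-squared per feature subset, one facet per
#' model, in the subset order of the plan.
#'
#' @param object An `ablation_report`.
#' @param metric `"r2"` (default), `"mae"` or `"rmse"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ablation_report <- function(object, metric = c("r2", "mae", "rmse"), ...) {
  metric <- match.arg(metric)
  s <- tidy(object)
  s$subset <- factor(s$subset, levels = names(object$plan$subsets))
  ggplot(s, aes(x = .data$subset, y = .data[[paste0(metric, "_mean")]])) +
    geom_col(fill = "steelblue") +
    facet_wrap(~model) +
    labs(
      x = "feature subset", y = paste("mean test", toupper(metric)),
      title = "Predictive performance by feature subset"
    ) +
    theme_minimal()
}

#' Plot the relative-risk distribution of network edges
#'
#' @param object A `multimorbidity_network`.
#' @param ... Unused.
#' @return A ggplot object (log10 RR histogram of retained edges).
#' @export
autoplot.multimorbidity_network <- function(object, ...) {
  ggplot(object$edges, aes(x = .data$rr)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue") +
    ggplot2::scale_x_log10() +
    labs(
      x = "edge relative risk (log scale)", y = "edges",
      title = "Multimorbidity-network edge weights"
    ) +
    theme_minimal()
}

#' Plot a per-LOS error profile
#'
#' @param profile Output of [per_los_mae()].
#' @return A ggplot object: MAE against observed LOS, one line per subgroup
#'   level.
#' @export
plot_los_profile <- function(profile) {
  ggplot(profile, aes(x = .data$los, y = .data$mae,
    colour = paste(.data$group, .data$level, sep = ": "))) +
    geom_line() +
    geom_point(aes(size = .data$n), alpha = 0.5) +
    labs(x = "observed LOS (days)", y = "MAE (days)", colour = "subgroup",
      size = "n", title = "Prediction error by length of stay") +
    theme_minimal()
}
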