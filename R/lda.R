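#' Fit a regularized linear discriminant projection
#'
#' Fisher's linear discriminant: directions maximizing between-class scatter
#' relative to within-class scatter, computed by symmetric whitening of the
#' ridge-regularized within-class scatter followed by an eigendecomposition.
#' Classes are the distinct integer LOS values of the training rows, so at
#' most `K - 1` components exist for `K` distinct values. The ridge term
#' keeps the fit defined on rank-deficient blocks (sparse multi-hot inputs
#' routinely have constant or collinear columns).
#'
#' @param x Numeric matrix (training rows x input features).
#' @param labels Integer class labels (one per row), e.g. LOS day values.
#' @param n_components Output dimension; must be at most `K - 1`.
#' @param ridge Relative ridge added to the within-class scatter diagonal
#'   (default 1e-6 of its mean diagonal).
#' @return An object of class `lda_projection`: `rotation` (features x
#'   components), `center`, `classes`, `n_components`, `n_train`.
#' @export
fit_lda <- function(x, labels, n_components, ridge = 1e-6) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels))
  classes <- sort(unique(labels))
  k <- length(classes)
  if (k < 2) abort("LDA needs at least two classes")
  if (n_components > k - 1) {
    abort(sprintf(
      "n_components = %d exceeds the K - 1 = %d bound (K = %d distinct labels)",
      n_components, k - 1, k
    ))
  }
  p <- ncol(x)
  mu <- colMeans(x)
  sw <- matrix(0, p, p)
  sb <- matrix(0, p, p)
  for (cl in classes) {
    rows <- which(labels == cl)
    xc <- x[rows, , drop = FALSE]
    mc <- colMeans(xc)
    dc <- sweep(xc, 2, mc)
    sw <- sw + crossprod(dc)
    db <- mc - mu
    sb <- sb + length(rows) * tcrossprod(db)
  }
  scale_ <- mean(diag(sw))
  if (scale_ <= 0) scale_ <- 1
  sw_reg <- sw + diag(ridge * scale_, p)

  es <- eigen(sw_reg, symmetric = TRUE)
  vals <- pmax(es$values, ridge * scale_)
  w <- es$vectors %*% (t(es$vectors) / sqrt(vals))
  m <- w %*% sb %*% w
  m <- (m + t(m)) / 2
  em <- eigen(m, symmetric = TRUE)
  rot <- w %*% em$vectors[, seq_len(n_components), drop = FALSE]
  # unit-norm columns with a deterministic sign (largest component positive)
  for (cix in seq_len(ncol(rot))) {
    v <- rot[, cix]
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v
    rot[, cix] <- v
  }
  colnames(rot) <- paste0("lda_", seq_len(n_components))
  rownames(rot) <- colnames(x)
  structure(
    list(
      rotation = rot, center = mu, classes = classes,
      n_components = as.integer(n_components), n_train = nrow(x)
    ),
    class = "lda_projection"
  )
}

#' Apply a fitted discriminant projection
#'
#' Rows are mapped independently: centred then multiplied by the rotation.
#'
#' @param projection An `lda_projection` from [fit_lda()].
#' @param x Numeric matrix with the fit's input width.
#' @return Matrix with `n_components` columns (`lda_1`, `lda_2`, ...).
#' @export
lda_transform <- function(projection, x) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(projection$rotation)) {
    abort(sprintf(
      "input width %d does not match the fitted width %d",
      ncol(x), nrow(projection$rotation)
    ))
  }
  sweep(x, 2, projection$center) %*% projection$rotation
}

#' @export
print.lda_projection <- function(x, ...) {
  cat("<lda_projection>", nrow(x$rotation), "->", x$n_components,
    "components;", length(x$classes), "classes;", x$n_train, "training rows\n")
  invisible(x)
}

# Fixed fast probe regressor used for validation-driven selection.
probe_fit_predict <- function(x_train, y_train, x_val, seed = 7L) {
  fit <- xgboost::xgboost(
    x_train, y_train,
    nrounds = 30, max_depth = 3, learning_rate = 0.3,
    nthreads = 1, verbosity = 0, seed = seed
  )
  predict(fit, x_val)
}

#' Select the discriminant output dimension on a validation split
#'
#' Fits one projection per candidate dimension on the training block,
#' scores a fixed small boosted-tree probe on the transformed validation
#' block, and returns the candidate with the lowest validation MAE
#' (smallest dimension on ties). Candidates above the `K - 1` bound are
#' dropped with a warning.
#'
#' @param candidates Integer vector of candidate dimensions.
#' @param x_train,labels_train Training block and integer labels.
#' @param x_val,labels_val Validation block and labels.
#' @param ridge Passed to [fit_lda()].
#' @return The selected dimension (integer), with the per-candidate scores
#'   as attribute `scores`.
#' @export
select_components <- function(candidates, x_train, labels_train,
                              x_val, labels_val, ridge = 1e-6) {
  k <- length(unique(labels_train))
  feasible <- sort(unique(as.integer(candidates[candidates <= k - 1])))
  dropped <- setdiff(candidates, feasible)
  if (length(dropped) > 0) {
    warn(paste0(
      "dropped infeasible candidate dimension(s) above K - 1 = ", k - 1, ": ",
      paste(dropped, collapse = ", ")
    ))
  }
  feasible <- feasible[feasible <= ncol(as.matrix(x_train))]
  if (length(feasible) == 0) abort("no feasible candidate dimensions")
  scores <- purrr::map_dbl(feasible, function(d) {
    proj <- fit_lda(x_train, labels_train, d, ridge)
    pred <- probe_fit_predict(
      lda_transform(proj, x_train), labels_train,
      lda_transform(proj, x_val)
    )
    mae(labels_val, pred)
  })
  best <- feasible[which.min(scores)] # which.min takes the first: smallest dim on ties
  structure(best, scores = tibble(n_components = feasible, val_mae = scores))
}
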