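test_that("splits honour the ratios, determinism and coverage", {
  s <- split_rows(1:100, seed = 1)
  expect_identical(lengths(s), c(train = 64L, val = 16L, test = 20L))
  expect_identical(sort(unlist(s, use.names = FALSE)), 1:100)
  expect_identical(split_rows(1:100, seed = 1), s)
  expect_false(identical(split_rows(1:100, seed = 2), s))
  expect_error(split_rows(1:5, seed = 1), "at least 10")
})

test_that("metrics match their closed forms and identities", {
  y <- c(1, 3)
  expect_equal(mae(y, c(2, 2)), 1)
  expect_equal(rmse(y, c(2, 2)), 1)
  expect_equal(r2(y, c(2, 2)), 0)
  # perfect predictor
  expect_equal(mae(y, y), 0)
  expect_equal(rmse(y, y), 0)
  expect_equal(r2(y, y), 1)
  # mean predictor scores exactly zero
  yy <- c(4, 8, 15, 16, 23, 42)
  expect_equal(r2(yy, rep(mean(yy), 6)), 0)
  expect_error(r2(c(2, 2), c(1, 2)), "constant")
  expect_error(mae(1:3, 1:2), "equal")
})

test_that("RMSE dominates MAE on random vectors", {
  withr::local_seed(3)
  for (i in 1:200) {
    y <- rnorm(50)
    yh <- rnorm(50)
    expect_gte(rmse(y, yh) + 1e-12, mae(y, yh))
  }
})

test_that("grid search is exhaustive, seeded and tie-stable", {
  withr::local_seed(5)
  n <- 400
  x <- matrix(runif(n * 3), n, 3)
  # stepwise target: a stump cannot represent the two-way interaction, a
  # depth-2 tree can
  y <- 2 * (x[, 1] > 0.5 & x[, 2] > 0.5) + 0.05 * rnorm(n)
  idx <- split_rows(seq_len(n), seed = 2)
  spec <- model_spec("xgboost", params = list(nrounds = 30, learning_rate = 0.3))
  best <- grid_search(spec,
    x[idx$train, ], y[idx$train], x[idx$val, ], y[idx$val],
    grid = list(max_depth = c(1, 2)), seed = 9
  )
  expect_identical(best$max_depth, 2)
  res <- attr(best, "results")
  expect_identical(nrow(res), 2L)

  # singleton grid returns trivially
  one <- grid_search(spec, x[idx$train, ], y[idx$train],
    x[idx$val, ], y[idx$val], grid = list(max_depth = 4), seed = 9)
  expect_identical(one$max_depth, 4)

  # exact ties resolve to the first declared combination
  spec2 <- model_spec("xgboost", params = list(nrounds = 5))
  tied <- grid_search(spec2, x[idx$train, ], y[idx$train],
    x[idx$val, ], y[idx$val],
    grid = list(subsample = c(1, 1)), seed = 9)
  res2 <- attr(tied, "results")
  expect_identical(which.min(res2$val_mae), 1L)
  expect_error(grid_search(spec, x, y, x, y, grid = list()), "empty")
})

test_that("all three model backends fit, predict and report importance", {
  withr::local_seed(6)
  n <- 200
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- 3 * x[, 1] + rnorm(n, 0, 0.2)
  for (nm in c("xgboost", "random_forest", "linear_svm")) {
    spec <- model_spec(nm)
    fit <- spec$fit(x, y, spec$params, seed = 1)
    pred <- spec$predict(fit, x)
    expect_identical(length(pred), as.integer(n))
    expect_gt(r2(y, pred), 0.5)
    imp <- spec$importance(fit)
    if (!is.null(imp)) expect_identical(names(which.max(imp)), "f1")
  }
})

test_that("the per-LOS error profile aggregates and conserves counts", {
  preds <- tibble::tibble(
    los = c(5, 5, 7, 7, 7),
    pred = c(4, 8, 7, 7, 7),
    sex = c("male", "female", "male", "male", "female")
  )
  prof <- per_los_mae(preds, by = "sex")
  overall5 <- prof[prof$group == "overall" & prof$los == 5, ]
  expect_identical(overall5$n, 2L)
  expect_equal(overall5$mae, 2) # |5-4| and |5-8| -> mean 2
  # perfect rows yield zero cells
  expect_equal(prof$mae[prof$group == "overall" & prof$los == 7], 0)
  # subgroup counts sum to the overall count per LOS
  bysex <- prof[prof$group == "sex", ]
  sums <- tapply(bysex$n, bysex$los, sum)
  overall <- prof[prof$group == "overall", ]
  expect_identical(as.integer(sums[as.character(overall$los)]), overall$n)
})

test_that("importances aggregate by group and min-max normalize the top set", {
  groups <- c(a1 = "baseline", a2 = "baseline", b1 = "psn", c1 = "mn")
  imp <- c(a1 = 4, a2 = 1, b1 = 2)
  out <- grouped_importance(imp, groups, top_k = 3)
  gi <- setNames(out$group_importance$importance, out$group_importance$group)
  expect_equal(gi[["baseline"]], 5)
  expect_equal(gi[["psn"]], 2)
  expect_equal(gi[["mn"]], 0)
  # conservation: group sums equal the total mass
  expect_equal(sum(gi), sum(imp))
  # toy (4, 2, 1) -> RI (1, 1/3, 0)
  expect_equal(out$top_features$ri, c(1, 1 / 3, 0))
  expect_identical(out$top_features$feature, c("a1", "b1", "a2"))
  # concentration: everything on one psn column
  out2 <- grouped_importance(c(b1 = 7), groups, top_k = 1)
  gi2 <- setNames(out2$group_importance$importance, out2$group_importance$group)
  expect_equal(gi2[["psn"]], 7)
  expect_equal(sum(gi2), 7)
  expect_equal(out2$top_features$ri, 1)
  expect_error(grouped_importance(NULL, groups), "importances")
})
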