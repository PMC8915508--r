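test_that("patient-disease matrix ORs all records and restricts to the catalog", {
  cat3 <- chronic_catalog(c("A01", "B02", "C03"))
  recs <- tibble::tibble(
    record_id = c("R1", "R2", "R3", "R4"),
    patient_id = c("P1", "P1", "P2", "P3"),
    sex = "male", age = 70L, ethnic_group = "han",
    admission_date = as.Date("2016-01-01") + c(0, 10, 0, 0),
    discharge_date = as.Date("2016-01-05") + c(0, 10, 0, 0),
    los = 4L, hospital_id = "H1", hospital_level = 3L,
    hospital_affiliation = 1L, hospital_address_code = 1L,
    patient_address_code = 1L, admission_status = 3L,
    admission_source = 1L, job = 1L, marital_status = 2L
  ) |>
    add_diagnoses(list(
      list(c("A01", "B02"), c(1L, 0L)), # P1, first stay
      list(c("B02", "C03"), c(0L, 1L)), # P1, second stay: OR-aggregated
      list(c("A01"), c(1L)),
      list(c("X99"), c(1L)) # not in catalog: contributes no column
    ))
  M <- build_disease_matrix(recs, cat3)
  expect_identical(sort(colnames(M)), c("A01", "B02", "C03"))
  expect_identical(rownames(M), c("P1", "P2"))
  expect_equal(as.numeric(M["P1", c("A01", "B02", "C03")]), c(1, 1, 1))
  expect_equal(as.numeric(M["P2", c("A01", "B02", "C03")]), c(1, 0, 0))

  # two patients with disjoint single diseases: identity pattern
  M2 <- build_disease_matrix(recs[3:4, ], chronic_catalog(c("A01", "X99")))
  expect_equal(unname(as.matrix(M2)), diag(2))

  expect_error(build_disease_matrix(recs[4, ], cat3), "empty")
})

test_that("cross-product co-occurrence equals brute-force pair counting", {
  co <- tiny_cohort()
  M <- build_disease_matrix(co$records, co$catalog)
  counts <- cooccurrence_counts(M)
  expect_equal(unname(as.matrix(counts)), unname(brute_cooccurrence(M)))

  # single patient with two diseases: all counts 1
  M1 <- Matrix::sparseMatrix(i = c(1, 1), j = c(1, 2), x = 1, dims = c(1, 2),
    dimnames = list("P1", c("A01", "B02")))
  expect_equal(as.numeric(as.matrix(cooccurrence_counts(M1))), rep(1, 4))

  # empty matrix: all-zero table
  M0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
    dims = c(3, 2))
  expect_true(all(as.matrix(cooccurrence_counts(M0)) == 0))
})

test_that("relative risk follows its closed form and symmetry", {
  expect_equal(relative_risk(10, 20, 50, 1000), 10)
  expect_equal(relative_risk(10, 50, 20, 1000), 10) # symmetric in (i, j)
  expect_equal(relative_risk(1, 20, 50, 1000), 1) # independence point: C_ij = C_i C_j / N
  expect_equal(relative_risk(0, 20, 50, 1000), 0)
  expect_error(relative_risk(1, 0, 50, 1000), ">= 1")
  expect_error(relative_risk(30, 20, 50, 1000), "exceed")
})

test_that("the Katz-style interval matches hand arithmetic in both modes", {
  s <- 1 / 10 + 1 / (20 * 50) - 1 / 1000 - 1 / 1000^2
  expect_equal(s, 0.099999, tolerance = 1e-12)
  ci <- katz_ci(10, 10, 20, 50, 1000) # as-printed dispersion
  expect_equal(ci$ci_low, 10 * exp(-2.58 * s), tolerance = 1e-12)
  expect_equal(ci$ci_high, 10 * exp(2.58 * s), tolerance = 1e-12)
  expect_equal(ci$ci_low, 7.725, tolerance = 1e-3)
  expect_equal(ci$ci_high, 12.944, tolerance = 1e-3)

  ci2 <- katz_ci(10, 10, 20, 50, 1000, sigma_mode = "sqrt")
  expect_equal(ci2$ci_low, 10 * exp(-2.58 * sqrt(s)), tolerance = 1e-12)

  ci0 <- katz_ci(10, 10, 20, 50, 1000, z = 0)
  expect_equal(c(ci0$ci_low, ci0$ci_high), c(10, 10))
  expect_error(katz_ci(10, 0, 20, 50, 1000), "C_ij")
})

test_that("interval width shrinks as counts grow with ratios fixed", {
  widths <- purrr::map_dbl(c(1, 2, 5, 10), function(m) {
    ci <- katz_ci(
      relative_risk(10 * m, 20 * m, 50 * m, 1000 * m),
      10 * m, 20 * m, 50 * m, 1000 * m
    )
    ci$ci_high - ci$ci_low
  })
  expect_true(all(diff(widths) < 0))
})

test_that("edge retention rules behave on the tiny fixture", {
  co <- tiny_cohort()
  M <- build_disease_matrix(co$records, co$catalog)
  mn_all <- build_mn(M, edge_rule = "all")
  bf <- brute_cooccurrence(M)
  expect_identical(nrow(mn_all$edges), sum(bf[upper.tri(bf)] >= 1))
  expect_identical(mn_all$n_candidates, nrow(mn_all$edges))

  mn_sig <- build_mn(M, edge_rule = "ci_low_gt_1")
  expect_true(all(mn_sig$edges$ci_low > 1))
  expect_lte(nrow(mn_sig$edges), nrow(mn_all$edges))
  mn_rr <- build_mn(M, edge_rule = "rr_gt_1")
  expect_true(all(mn_rr$edges$rr > 1))
  # structural invariants
  expect_true(all(mn_all$edges$ci_low <= mn_all$edges$rr + 1e-12))
  expect_true(all(mn_all$edges$rr <= mn_all$edges$ci_high + 1e-12))
  expect_true(all(c(mn_all$edges$code_i, mn_all$edges$code_j) %in% mn_all$nodes$code))
})

test_that("power-iteration centrality matches the dense eigenvector oracle", {
  withr::local_seed(42)
  for (trial in 1:20) {
    n <- sample(5:50, 1)
    A <- matrix(0, n, n)
    pairs <- which(upper.tri(A), arr.ind = TRUE)
    on <- pairs[runif(nrow(pairs)) < 0.2, , drop = FALSE]
    if (nrow(on) == 0) next
    w <- runif(nrow(on), 0.5, 10)
    A[on] <- w
    A <- A + t(A)
    codes <- synthetic_disease_codes(n)
    mn <- structure(
      list(
        nodes = tibble::tibble(code = codes, count = 1L),
        edges = tibble::tibble(
          code_i = codes[on[, 1]], code_j = codes[on[, 2]],
          c_ij = 1L, rr = w, ci_low = w, ci_high = w
        ),
        n_patients = n, n_candidates = nrow(on),
        options = list()
      ),
      class = "multimorbidity_network"
    )
    evc <- eigenvector_centrality(mn)
    # oracle: dense principal eigenvector, per connected component
    eig <- eigen(A, symmetric = TRUE)
    # compare on the dominant component only: find it via the oracle vector
    v <- abs(eig$vectors[, which.max(eig$values)])
    comp <- v > 1e-8
    expect_lt(max(abs(evc[comp] - v[comp] / sqrt(sum(v[comp]^2)))), 1e-6)
  }
})

test_that("centrality has the known symmetric-graph solutions", {
  complete_mn <- function(n, w = 1) {
    codes <- synthetic_disease_codes(n)
    pairs <- utils::combn(n, 2)
    structure(
      list(
        nodes = tibble::tibble(code = codes, count = 1L),
        edges = tibble::tibble(
          code_i = codes[pairs[1, ]], code_j = codes[pairs[2, ]],
          c_ij = 1L, rr = w, ci_low = w, ci_high = w
        ),
        n_patients = n, n_candidates = ncol(pairs), options = list()
      ),
      class = "multimorbidity_network"
    )
  }
  evc <- eigenvector_centrality(complete_mn(6))
  expect_equal(unname(evc), rep(1 / sqrt(6), 6), tolerance = 1e-9)

  # star graph: the hub dominates every leaf
  codes <- synthetic_disease_codes(5)
  star <- structure(
    list(
      nodes = tibble::tibble(code = codes, count = 1L),
      edges = tibble::tibble(
        code_i = codes[1], code_j = codes[2:5],
        c_ij = 1L, rr = 1, ci_low = 1, ci_high = 1
      ),
      n_patients = 5, n_candidates = 4, options = list()
    ),
    class = "multimorbidity_network"
  )
  evc_star <- eigenvector_centrality(star)
  expect_true(all(evc_star[1] > evc_star[2:5]))

  # scaling invariance: multiplying all weights leaves scores unchanged
  evc_w <- eigenvector_centrality(complete_mn(6, w = 7.3))
  expect_equal(evc_w, evc, tolerance = 1e-9)
})

test_that("centrality agrees with igraph on a weighted graph", {
  skip_if_not_installed("igraph")
  co <- small_cohort()
  M <- build_disease_matrix(co$records, co$catalog)
  mn <- build_mn(M, edge_rule = "all")
  evc <- eigenvector_centrality(mn)
  g <- igraph::graph_from_data_frame(
    mn$edges[, c("code_i", "code_j", "rr")],
    directed = FALSE,
    vertices = mn$nodes$code
  )
  ig <- igraph::eigen_centrality(g, weights = igraph::E(g)$rr)$vector
  # same dominant component, igraph normalizes by the max entry
  dom <- names(evc)[evc > 1e-8]
  expect_equal(
    unname(evc[dom] / max(evc[dom])),
    unname(ig[dom]),
    tolerance = 1e-6
  )
})

test_that("network exports are plain tables", {
  co <- tiny_cohort()
  M <- build_disease_matrix(co$records, co$catalog)
  mn <- add_centrality(build_mn(M, edge_rule = "all"))
  e_path <- withr::local_tempfile(fileext = ".csv")
  n_path <- withr::local_tempfile(fileext = ".csv")
  write_mn(mn, e_path, n_path)
  expect_identical(nrow(readr::read_csv(e_path, show_col_types = FALSE)), nrow(mn$edges))
  nodes <- readr::read_csv(n_path, show_col_types = FALSE)
  expect_true(all(c("code", "count", "evc") %in% names(nodes)))
  expect_identical(glance(mn)$n_edges, nrow(mn$edges))
  expect_identical(tidy(mn), mn$edges)
})
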