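test_that("the baseline block has the 69-column admission-time schema", {
  recs <- hand_records()
  eci <- tibble::tibble(code = c("I10", "E11"), category = c(
    "hypertension_uncomplicated", "diabetes_uncomplicated"
  ))
  bl <- baseline_features(recs, eci)
  expect_identical(ncol(bl) - 1L, 69L) # record_id + 69 features
  expect_false(anyNA(bl))

  # address flag: equal codes on rows 1-2, unequal on row 3
  expect_equal(bl$address_match, c(1, 1, 0))
  # PoA disease count ignores non-PoA diagnoses
  expect_equal(bl$n_poa_diseases, c(1, 1, 2))
  # one-hot blocks each sum to at most 1 per row
  for (pre in c("sex_", "source_", "ethnic_", "job_", "marital_")) {
    block <- bl[, startsWith(names(bl), pre), drop = FALSE]
    expect_true(all(rowSums(block) <= 1))
  }
  # Elixhauser: row 1's PoA set {I10} maps to one category; row 3 has no
  # mapped PoA code beyond I10
  expect_equal(bl$eci_hypertension_uncomplicated, c(1, 1, 1))
  expect_equal(bl$eci_diabetes_uncomplicated, c(0, 0, 0)) # E11 not at PoA
  # no mapping at all: all 31 flags and the score are zero
  bl0 <- baseline_features(recs, eci_map = NULL)
  expect_true(all(bl0[, startsWith(names(bl0), "eci_")] == 0))
  # unknown categorical level: all-zero one-hot with a warning
  odd <- recs
  odd$sex[1] <- "unknown"
  expect_warning(blw <- baseline_features(odd, eci), "unknown level")
  expect_equal(blw$sex_male[1] + blw$sex_female[1], 0)
})

test_that("the weighted comorbidity score sums the set flags", {
  f <- setNames(rep(0, 31), eci_categories())
  expect_identical(eci_score(f), 0L)
  f["metastatic_cancer"] <- 1
  expect_identical(eci_score(f), 12L)
  f["drug_abuse"] <- 1
  expect_identical(eci_score(f), 5L) # 12 - 7
  w <- setNames(c(5L, -2L, rep(0L, 29)), eci_categories())
  f2 <- setNames(c(1, 1, rep(0, 29)), eci_categories())
  expect_identical(eci_score(f2, w), 3L)
})

test_that("historical features summarize the three-year lookback", {
  base <- hand_records()
  # R2 is one year after R1 (same patient): R1 is in R2's window
  hf <- historical_features(base, base)
  r2 <- hf[hf$record_id == "R2", ]
  expect_equal(
    unname(unlist(r2[, -1])),
    c(1, 10, 0, 10, 10, 10, as.numeric(as.Date("2019-03-01") - as.Date("2018-03-11")), 10)
  )
  # R1 and R3 have no history: all zeros
  expect_true(all(hf[hf$record_id %in% c("R1", "R3"), -1] == 0))

  # window boundary: a stay exactly 3 years back is included, one day
  # earlier is not
  old <- base[1, ]
  old$record_id <- "R0"
  old$admission_date <- as.Date("2016-03-01")
  old$discharge_date <- old$admission_date + 10
  cur <- base[2, ] # admitted 2019-03-01
  hf2 <- historical_features(cur, dplyr::bind_rows(old, cur))
  expect_equal(hf2$hist_n, 1)
  old$admission_date <- as.Date("2016-02-28")
  old$discharge_date <- old$admission_date + 10
  hf3 <- historical_features(cur, dplyr::bind_rows(old, cur))
  expect_equal(hf3$hist_n, 0)

  # two priors: population sd and the most recent stay's fields
  p1 <- base[1, ]
  p2 <- base[1, ]
  p2$record_id <- "R1b"
  p2$admission_date <- as.Date("2018-09-01")
  p2$discharge_date <- p2$admission_date + 4
  p2$los <- 4L
  hf4 <- historical_features(base[2, ], dplyr::bind_rows(p1, p2, base[2, ]))
  expect_equal(hf4$hist_n, 2)
  expect_equal(hf4$hist_mean, 7)
  expect_equal(hf4$hist_sd, 3) # population convention: sqrt(((10-7)^2+(4-7)^2)/2)
  expect_equal(hf4$last_los, 4)
})

test_that("per-disease mean LOS and risk features follow their formulas", {
  cat2 <- chronic_catalog(c("A01", "B02", "C03"))
  base <- hand_records()[1, ]
  mk <- function(id, codes, flags, los) {
    r <- base
    r$record_id <- id
    r$los <- los
    r$discharge_date <- r$admission_date + los
    r |>
      dplyr::select(-dplyr::starts_with("diag_"), -dplyr::starts_with("poa_")) |>
      add_diagnoses(list(list(codes, flags)))
  }
  train <- dplyr::bind_rows(
    mk("T1", c("A01"), c(1L), 4L),
    mk("T2", c("A01", "B02"), c(1L, 1L), 6L),
    mk("T3", c("C03"), c(0L), 9L) # C03 never at PoA
  )
  lm_tab <- los_mean_per_disease(train, cat2)
  expect_equal(lm_tab$los_mean[lm_tab$code == "A01"], 5) # (4+6)/2
  expect_equal(lm_tab$los_mean[lm_tab$code == "B02"], 6)
  expect_false("C03" %in% lm_tab$code)

  evc <- c(A01 = 0.5, B02 = 0.25, C03 = 0.8)
  risk <- disease_risk_table(evc, lm_tab)
  expect_equal(risk$risk[risk$code == "A01"], 2.5) # 0.5 * 5
  expect_false("C03" %in% risk$code) # unseen at PoA: contributes nothing

  q <- mk("Q1", c("A01", "B02"), c(1L, 1L), 3L)
  rf <- disease_risk_features(q, risk, cat2)
  expect_equal(unname(unlist(rf[, -1])), c(2, 2.5, 2, 4)) # n, max, mean, sum
  q0 <- mk("Q2", c("C03"), c(1L), 3L)
  expect_true(all(disease_risk_features(q0, risk, cat2)[, -1] == 0))

  # single covered disease: score 5 -> (1, 5, 5, 5)
  risk1 <- disease_risk_table(c(A01 = 0.5), tibble::tibble(code = "A01", los_mean = 10))
  rf1 <- disease_risk_features(mk("Q3", "A01", 1L, 2L), risk1, cat2)
  expect_equal(unname(unlist(rf1[, -1])), c(1, 5, 5, 5))
})

test_that("centrality multi-hot features respect the vocabulary", {
  cat2 <- chronic_catalog(c("A01", "B02", "C03"))
  base <- hand_records()[1, ]
  q <- base |>
    dplyr::select(-dplyr::starts_with("diag_"), -dplyr::starts_with("poa_")) |>
    add_diagnoses(list(list(c("A01", "C03"), c(1L, 1L))))
  evc <- c(A01 = 0.7, B02 = 0.2)
  ef <- evc_features(q, evc, vocab = c("A01", "B02"), catalog = cat2)
  expect_equal(unname(unlist(ef[, -1])), c(0.7, 0)) # C03 outside vocab: no effect
  # empty PoA chronic set: zero vector
  q0 <- base |>
    dplyr::select(-dplyr::starts_with("diag_"), -dplyr::starts_with("poa_")) |>
    add_diagnoses(list(list(c("X99"), c(1L))))
  expect_true(all(evc_features(q0, evc, c("A01", "B02"), cat2)[, -1] == 0))
})

test_that("neighbour-LOS features aggregate with the population convention", {
  recs <- hand_records()
  nb <- tibble::tibble(
    query_id = c("R1", "R1", "R1"),
    rank = 1:3, neighbor_id = c("a", "b", "c"),
    similarity = c(0.9, 0.5, 0.2), neighbor_los = c(2, 4, 9)
  )
  pf <- psn_features(recs, nb)
  r1 <- pf[pf$record_id == "R1", ]
  expect_equal(r1$psn_mean, 5)
  expect_equal(r1$psn_sd, sqrt(((2 - 5)^2 + (4 - 5)^2 + (9 - 5)^2) / 3))
  expect_equal(r1$psn_median, 4)
  expect_equal(r1$psn_min, 2)
  expect_equal(r1$psn_max, 9)
  # rows without neighbours: all zero
  expect_true(all(pf[pf$record_id != "R1", -1] == 0))
  # constant neighbours: sd 0
  nbc <- tibble::tibble(query_id = "R2", rank = 1:4, neighbor_id = letters[1:4],
    similarity = 0.5, neighbor_los = 9)
  expect_equal(unname(unlist(psn_features(recs, nbc)[2, -1])), c(9, 0, 9, 9, 9))
})

test_that("assembly tags groups, forbids missingness and supports ablation", {
  recs <- hand_records()
  bl <- baseline_features(recs)
  hf <- historical_features(recs, recs)
  nb <- tibble::tibble(query_id = "R1", rank = 1L, neighbor_id = "x",
    similarity = 1, neighbor_los = 5)
  pf <- psn_features(recs, nb)
  ft <- assemble_features(recs, list(
    baseline = list(bl), history = list(hf), psn = list(pf)
  ))
  g <- feature_groups(ft)
  expect_identical(as.integer(table(g)[c("baseline", "history", "psn")]),
    c(69L, 8L, 5L))
  expect_identical(ncol(ft), 2L + 69L + 8L + 5L)
  expect_false(anyNA(ft))

  # dropping a group shrinks by exactly its width
  sub <- select_groups(ft, c("baseline", "history"))
  expect_identical(ncol(ft) - ncol(sub), 5L)
  expect_error(select_groups(ft, "mystery"), "unknown feature group")

  # misaligned ids are refused
  bad <- bl
  bad$record_id <- rev(bad$record_id)
  expect_error(assemble_features(recs, list(baseline = list(bad))), "misaligned")

  # full-scale vocabulary: a 653-wide centrality block gives mn width 657
  vocab <- sprintf("%s%02d", rep(LETTERS, each = 26), 1:26)[1:653]
  evc <- setNames(runif(653), vocab)
  fake <- recs[1, ] |>
    dplyr::select(-dplyr::starts_with("diag_"), -dplyr::starts_with("poa_")) |>
    add_diagnoses(list(list(vocab[1], 1L)))
  ef <- evc_features(fake, evc, vocab, chronic_catalog(vocab))
  rf <- disease_risk_features(fake,
    disease_risk_table(evc, tibble::tibble(code = vocab, los_mean = 10)),
    chronic_catalog(vocab))
  ft2 <- assemble_features(fake, list(mn = list(ef, rf)))
  expect_identical(sum(feature_groups(ft2) == "mn"), 657L)
})

test_that("feature rows do not depend on input record order", {
  co <- small_cohort()
  recs <- small_filtered()[1:120, ]
  perm <- withr::with_seed(1, sample(nrow(recs)))
  eci <- synthetic_eci_map(as.character(co$catalog))
  a <- baseline_features(recs, eci)
  b <- baseline_features(recs[perm, ], eci)
  expect_equal(
    as.data.frame(dplyr::arrange(a, record_id)),
    as.data.frame(dplyr::arrange(b, record_id))
  )
  ha <- historical_features(recs, recs)
  hb <- historical_features(recs[perm, ], recs[perm, ])
  expect_equal(
    as.data.frame(dplyr::arrange(ha, record_id)),
    as.data.frame(dplyr::arrange(hb, record_id))
  )
})

test_that("the synthetic comorbidity map is deterministic and valid", {
  m <- synthetic_eci_map(synthetic_disease_codes(20))
  expect_identical(m, synthetic_eci_map(synthetic_disease_codes(20)))
  expect_true(all(m$category %in% eci_categories()))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(m, path)
  expect_identical(read_eci_map(path), m)
  bad <- m
  bad$category[1] <- "gout"
  readr::write_csv(bad, path)
  expect_error(read_eci_map(path), "unknown Elixhauser")
})
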