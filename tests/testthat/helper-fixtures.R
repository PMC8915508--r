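# Shared fixtures, computed lazily once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

tiny_cohort <- function() memo("tiny", make_fixture("tiny"))
small_cohort <- function() memo("small", make_fixture("small"))

small_filtered <- function() {
  memo("small_filtered", {
    co <- small_cohort()
    apply_inclusion_criteria(co$records, co$catalog,
      date_range = c("2015-01-01", "2019-12-31"))$records
  })
}

# A hand-written three-record table exercising every mandatory column.
hand_records <- function() {
  tibble::tibble(
    record_id = c("R1", "R2", "R3"),
    patient_id = c("P1", "P1", "P2"),
    sex = c("male", "male", "female"),
    age = c(70L, 71L, 80L),
    ethnic_group = c("han", "han", "minority"),
    admission_date = as.Date(c("2018-03-01", "2019-03-01", "2018-06-15")),
    discharge_date = as.Date(c("2018-03-11", "2019-03-06", "2018-06-22")),
    los = c(10L, 5L, 7L),
    hospital_id = c("H1", "H1", "H2"),
    hospital_level = c(3L, 3L, 2L),
    hospital_affiliation = c(1L, 1L, 2L),
    hospital_address_code = c(5L, 5L, 9L),
    patient_address_code = c(5L, 5L, 2L),
    admission_status = c(3L, 2L, 3L),
    admission_source = c(1L, 2L, 2L),
    job = c(4L, 4L, 11L),
    marital_status = c(2L, 2L, 2L)
  ) |>
    add_diagnoses(list(
      list(c("I10", "E11"), c(1L, 0L)),
      list(c("I10"), c(1L)),
      list(c("N18", "I10", "J44"), c(1L, 1L, 0L))
    ))
}

# Attach wide diagnosis columns from a list of (codes, poa_flags) pairs.
add_diagnoses <- function(records, diag_list) {
  n <- nrow(records)
  dmat <- matrix(NA_character_, n, 16)
  pmat <- matrix(NA_integer_, n, 16)
  for (i in seq_len(n)) {
    codes <- diag_list[[i]][[1]]
    flags <- diag_list[[i]][[2]]
    dmat[i, seq_along(codes)] <- codes
    pmat[i, seq_along(codes)] <- flags
  }
  colnames(dmat) <- sprintf("diag_%02d", 1:16)
  colnames(pmat) <- sprintf("poa_%02d", 1:16)
  dplyr::bind_cols(records, tibble::as_tibble(dmat), tibble::as_tibble(pmat))
}

# Brute-force pairwise co-occurrence counting (the oracle for the sparse
# cross-product path): loops over patients and their disease pairs.
brute_cooccurrence <- function(M) {
  M <- as.matrix(M)
  d <- ncol(M)
  out <- matrix(0, d, d, dimnames = list(colnames(M), colnames(M)))
  for (p in seq_len(nrow(M))) {
    ds <- which(M[p, ] != 0)
    for (i in ds) {
      for (j in ds) {
        out[i, j] <- out[i, j] + 1
      }
    }
  }
  out
}

# Brute-force exact top-k Jaccard neighbours for one query against a record
# table (the oracle for the blocked sparse path).
brute_neighbors <- function(records, catalog, query_row, k = 100,
                            exclude_same_patient = TRUE) {
  sets <- diagnosis_sets(records, poa_only = TRUE, catalog = catalog)
  q <- query_row
  qset <- diagnosis_sets(q, poa_only = TRUE, catalog = catalog)[[1]]
  qblock <- paste(q$sex, as.character(age_group(q$age)))
  sims <- purrr::map_dbl(seq_len(nrow(records)), function(i) {
    if (records$record_id[i] == q$record_id) return(0)
    if (exclude_same_patient && records$patient_id[i] == q$patient_id) return(0)
    if (paste(records$sex[i], as.character(age_group(records$age[i]))) != qblock) return(0)
    if (length(sets[[i]]) == 0 && length(qset) == 0) return(0)
    jaccard_similarity(qset, sets[[i]])
  })
  keep <- which(sims > 0)
  ord <- keep[order(-sims[keep], records$record_id[keep])]
  ord <- head(ord, k)
  tibble::tibble(
    neighbor_id = records$record_id[ord],
    similarity = sims[ord]
  )
}

# Shared split-aware featurization on the small fixture.
small_featurized <- function() {
  memo("small_fz", {
    co <- small_cohort()
    recs <- small_filtered()
    M <- build_disease_matrix(recs, co$catalog, era = c("2015-01-01", "2017-12-31"))
    mn <- add_centrality(build_mn(M))
    evc <- setNames(mn$nodes$evc, mn$nodes$code)
    era <- as.Date(c("2018-01-01", "2019-12-31"))
    modeling <- recs[recs$admission_date >= era[1] & recs$admission_date <= era[2], ]
    split <- split_rows(modeling$record_id, seed = 1)
    fz <- suppressWarnings(featurize(
      modeling, recs, co$catalog, evc, split,
      eci_map = synthetic_eci_map(as.character(co$catalog))
    ))
    list(co = co, recs = recs, evc = evc, modeling = modeling, split = split, fz = fz)
  })
}

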