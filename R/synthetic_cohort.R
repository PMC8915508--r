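#' Parameters for the synthetic discharge-record generator
#'
#' The generator emulates the structure of an elderly multi-year hospital
#' discharge cohort: each patient carries a persistent set of chronic
#' diseases (Bernoulli marginals, optionally with planted pairwise
#' co-occurrence at a target relative risk), is admitted one or more times
#' over the date span, and accrues an integer LOS driven by disease effects,
#' an age slope, a patient-level frailty and noise.
#'
#' For a planted pair (i, j, RR) the two indicators are drawn jointly from
#' the 2x2 table with `P(both) = RR * p_i * p_j` and the stated margins,
#' which makes the population relative risk of the pair exactly `RR`.
#' Feasibility requires `RR * p_i * p_j <= min(p_i, p_j)` and a non-negative
#' probability for the neither-disease cell.
#'
#' @param n_patients Number of patients.
#' @param n_diseases Number of chronic diseases in the synthetic catalog.
#' @param prevalence Per-disease carriage probability (scalar or vector).
#' @param planted_pairs Tibble with columns `i`, `j` (disease indices,
#'   disjoint across pairs) and `rr` (target relative risk, >= 1), or `NULL`.
#' @param admissions_mean,admissions_dispersion Mean and negative-binomial
#'   dispersion of admissions per patient (at least one admission each).
#' @param date_span Length-2 character/Date vector of the cohort period.
#' @param base_days Baseline LOS in days.
#' @param disease_effects Per-disease additive LOS effect in days (length
#'   `n_diseases`); default cycles 0..4.
#' @param age_slope LOS days per year of age above 65.
#' @param frailty_sd Patient-level random-effect SD in days.
#' @param noise_sd Per-admission noise SD in days.
#' @param poa_rate Probability a carried disease is flagged at admission.
#' @param new_disease_rate Per-admission probability of acquiring one new
#'   catalog disease (default 0: strictly persistent sets).
#' @param prop_male,prop_han Demographic proportions.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 2000L,
                          n_diseases = 20L,
                          prevalence = 0.1,
                          planted_pairs = NULL,
                          admissions_mean = 1.8,
                          admissions_dispersion = 1.5,
                          date_span = c("2015-01-01", "2019-12-31"),
                          base_days = 7,
                          disease_effects = NULL,
                          age_slope = 0.05,
                          frailty_sd = 2,
                          noise_sd = 2,
                          poa_rate = 0.9,
                          new_disease_rate = 0,
                          prop_male = 0.487,
                          prop_han = 0.996,
                          seed = 1L) {
  prevalence <- rep_len(prevalence, n_diseases)
  stopifnot(all(prevalence >= 0 & prevalence <= 1), poa_rate >= 0, poa_rate <= 1)
  if (is.null(disease_effects)) {
    disease_effects <- rep_len(c(0, 1, 2, 3, 4), n_diseases)
  }
  stopifnot(length(disease_effects) == n_diseases)
  if (!is.null(planted_pairs)) {
    planted_pairs <- as_tibble(planted_pairs)
    stopifnot(all(c("i", "j", "rr") %in% names(planted_pairs)))
    idx <- c(planted_pairs$i, planted_pairs$j)
    if (anyDuplicated(idx) || any(idx < 1 | idx > n_diseases)) {
      abort("planted pairs must use disjoint, in-range disease indices")
    }
    if (any(planted_pairs$rr < 1)) abort("target RR must be >= 1")
    p11 <- planted_pairs$rr * prevalence[planted_pairs$i] * prevalence[planted_pairs$j]
    pmin_ <- pmin(prevalence[planted_pairs$i], prevalence[planted_pairs$j])
    p00 <- 1 - prevalence[planted_pairs$i] - prevalence[planted_pairs$j] + p11
    if (any(p11 > pmin_) || any(p00 < 0)) {
      abort("infeasible planted RR: requires P(both) <= min(p_i, p_j) and P(neither) >= 0")
    }
  }
  structure(
    list(
      n_patients = as.integer(n_patients), n_diseases = as.integer(n_diseases),
      prevalence = prevalence, planted_pairs = planted_pairs,
      admissions_mean = admissions_mean, admissions_dispersion = admissions_dispersion,
      date_span = as.Date(date_span), base_days = base_days,
      disease_effects = disease_effects, age_slope = age_slope,
      frailty_sd = frailty_sd, noise_sd = noise_sd, poa_rate = poa_rate,
      new_disease_rate = new_disease_rate,
      prop_male = prop_male, prop_han = prop_han, seed = as.integer(seed)
    ),
    class = "cohort_params"
  )
}

#' Synthetic catalog codes
#'
#' Deterministic well-formed three-character codes (`A01`, `B02`, ...) for
#' the synthetic chronic-disease catalog.
#'
#' @param n Number of codes (max 99).
#' @return Character vector of codes.
#' @export
synthetic_disease_codes <- function(n) {
  stopifnot(n >= 1, n <= 99)
  sprintf("%s%02d", LETTERS[(seq_len(n) - 1L) %% 26L + 1L], seq_len(n))
}

# Age distribution shaped like an elderly inpatient cohort: five-year bands
# from 65 with decreasing mass, uniform within band (90+ spread to 99).
sample_base_ages <- function(n) {
  band_p <- c(0.2335, 0.2537, 0.2264, 0.1639, 0.0899, 0.0326)
  lo <- c(65, 70, 75, 80, 85, 90)
  hi <- c(69, 74, 79, 84, 89, 99)
  band <- sample.int(6, n, replace = TRUE, prob = band_p)
  lo[band] + floor(runif(n) * (hi[band] - lo[band] + 1))
}

#' Generate a synthetic discharge-record cohort with known structure
#'
#' @param params A [cohort_params()] object.
#' @return A list with `records` (admission tibble in the [admission-records]
#'   schema), `catalog` (the synthetic [chronic_catalog()]), and `truth`
#'   (planted pairs, per-disease effects, per-patient frailties and carried
#'   disease sets, and the generating params).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(n_patients = 100, seed = 7))
#' nrow(cohort$records)
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  withr::with_seed(params$seed, generate_cohort_impl(params))
}

generate_cohort_impl <- function(p) {
  n <- p$n_patients
  d <- p$n_diseases
  codes <- synthetic_disease_codes(d)

  # Persistent disease indicator matrix, planted pairs sampled jointly.
  carry <- matrix(0L, n, d)
  planted_idx <- integer(0)
  if (!is.null(p$planted_pairs)) {
    for (r in seq_len(nrow(p$planted_pairs))) {
      i <- p$planted_pairs$i[r]
      j <- p$planted_pairs$j[r]
      p11 <- p$planted_pairs$rr[r] * p$prevalence[i] * p$prevalence[j]
      p10 <- p$prevalence[i] - p11
      p01 <- p$prevalence[j] - p11
      cell <- sample.int(4, n, replace = TRUE, prob = c(p11, p10, p01, 1 - p11 - p10 - p01))
      carry[, i] <- as.integer(cell %in% c(1L, 2L))
      carry[, j] <- as.integer(cell %in% c(1L, 3L))
      planted_idx <- c(planted_idx, i, j)
    }
  }
  for (k in setdiff(seq_len(d), planted_idx)) {
    carry[, k] <- rbinom(n, 1, p$prevalence[k])
  }

  patient_id <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(runif(n) < p$prop_male, "male", "female")
  ethnic <- ifelse(runif(n) < p$prop_han, "han", "minority")
  base_age <- sample_base_ages(n)
  frailty <- rnorm(n, 0, p$frailty_sd)
  job <- sample.int(13, n, replace = TRUE)
  marital <- sample.int(4, n, replace = TRUE, prob = c(0.05, 0.8, 0.05, 0.1))
  addr <- sample.int(20, n, replace = TRUE)

  n_adm <- 1L + rnbinom(n, size = p$admissions_dispersion, mu = p$admissions_mean - 1)
  total <- sum(n_adm)
  pid_row <- rep(seq_len(n), n_adm)

  span_days <- as.integer(p$date_span[2] - p$date_span[1])
  adm_offset <- floor(runif(total) * (span_days + 1))
  ord <- order(pid_row, adm_offset)
  pid_row <- pid_row[ord]
  adm_date <- p$date_span[1] + adm_offset[ord]

  start_year <- as.integer(format(p$date_span[1], "%Y"))
  age_at_adm <- base_age[pid_row] + (as.integer(format(adm_date, "%Y")) - start_year)

  # Optional disease accrual: one new catalog disease per admission at a
  # configurable rate (chronic semantics: once acquired, carried for good;
  # with the default rate 0 the sets are strictly persistent).
  if (p$new_disease_rate > 0) {
    acquire <- which(runif(total) < p$new_disease_rate)
    for (a in acquire) {
      pt <- pid_row[a]
      open <- which(carry[pt, ] == 0L)
      if (length(open) > 0) carry[pt, open[sample.int(length(open), 1)]] <- 1L
    }
  }

  effect_sum <- as.numeric(carry %*% p$disease_effects)
  los <- round(p$base_days + effect_sum[pid_row] +
    p$age_slope * (age_at_adm - 65) + frailty[pid_row] + rnorm(total, 0, p$noise_sd))
  los <- pmax(1L, as.integer(los))

  # Diagnosis lists: carried chronic diseases ordered by effect size
  # (descending), each flagged PoA at poa_rate; a principal must exist, so
  # the first listed diagnosis is the highest-effect PoA disease when any is
  # flagged. Disease-free patients get an acute filler code outside the
  # catalog (they are removed by the chronic-at-PoA inclusion criterion).
  dmat <- matrix(NA_character_, total, N_DIAG)
  pmat <- matrix(NA_integer_, total, N_DIAG)
  eff_order <- order(-p$disease_effects)
  for (row in seq_len(total)) {
    ds <- which(carry[pid_row[row], ] == 1L)
    if (length(ds) == 0) {
      dmat[row, 1] <- "Z00"
      pmat[row, 1] <- 1L
      next
    }
    ds <- ds[order(match(ds, eff_order))]
    if (length(ds) > N_DIAG) ds <- ds[seq_len(N_DIAG)]
    poa <- rbinom(length(ds), 1, p$poa_rate)
    first <- c(which(poa == 1L), seq_along(ds))[1]
    ordx <- c(first, setdiff(seq_along(ds), first))
    dmat[row, seq_along(ds)] <- codes[ds[ordx]]
    pmat[row, seq_along(ds)] <- poa[ordx]
  }
  colnames(dmat) <- diag_cols()
  colnames(pmat) <- poa_cols()

  records <- bind_cols(
    tibble(
      record_id = sprintf("R%07d", seq_len(total)),
      patient_id = patient_id[pid_row],
      sex = sex[pid_row],
      age = as.integer(age_at_adm),
      ethnic_group = ethnic[pid_row],
      admission_date = adm_date,
      discharge_date = adm_date + los,
      los = los,
      hospital_id = sprintf("H%02d", sample.int(10, total, replace = TRUE)),
      hospital_level = sample.int(3, total, replace = TRUE, prob = c(0.2, 0.3, 0.5)),
      hospital_affiliation = sample.int(3, total, replace = TRUE),
      hospital_address_code = sample.int(20, total, replace = TRUE),
      patient_address_code = addr[pid_row],
      admission_status = sample.int(3, total, replace = TRUE, prob = c(0.05, 0.15, 0.8)),
      admission_source = sample.int(4, total, replace = TRUE, prob = c(0.3, 0.5, 0.15, 0.05)),
      job = job[pid_row],
      marital_status = marital[pid_row]
    ),
    as_tibble(dmat), as_tibble(pmat)
  )

  list(
    records = records,
    catalog = chronic_catalog(codes, "synthetic generator"),
    truth = list(
      planted_pairs = p$planted_pairs,
      disease_effects = setNames(p$disease_effects, codes),
      frailty = tibble(patient_id = patient_id, frailty = frailty),
      carriage = carry,
      params = p
    )
  )
}

#' Named reproducible cohort presets
#'
#' Presets used across the test suite and examples, each with a fixed seed
#' and two planted co-occurrence pairs (target RR 5 and 3) so downstream
#' stages have recoverable signal: `tiny` (50 patients), `small` (2000),
#' `medium` (20000).
#'
#' @param name One of `"tiny"`, `"small"`, `"medium"`.
#' @return As [generate_cohort()].
#' @export
make_fixture <- function(name) {
  presets <- list(
    tiny = list(n = 50L, seed = 101L),
    small = list(n = 2000L, seed = 202L),
    medium = list(n = 20000L, seed = 303L)
  )
  if (!name %in% names(presets)) {
    abort(paste0("unknown preset '", name, "' (use tiny, small or medium)"))
  }
  pr <- presets[[name]]
  generate_cohort(cohort_params(
    n_patients = pr$n,
    planted_pairs = tibble(i = c(1L, 3L), j = c(2L, 4L), rr = c(5, 3)),
    seed = pr$seed
  ))
}
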