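#' The 31 Elixhauser comorbidity categories
#'
#' Standard category names, in fixed order, used for the 31 baseline
#' comorbidity flags and the weighted comorbidity score.
#'
#' @return Character vector of 31 category names.
#' @export
eci_categories <- function() {
  c(
    "congestive_heart_failure", "cardiac_arrhythmias", "valvular_disease",
    "pulmonary_circulation", "peripheral_vascular",
    "hypertension_uncomplicated", "hypertension_complicated", "paralysis",
    "other_neurological", "chronic_pulmonary", "diabetes_uncomplicated",
    "diabetes_complicated", "hypothyroidism", "renal_failure",
    "liver_disease", "peptic_ulcer", "aids_hiv", "lymphoma",
    "metastatic_cancer", "solid_tumor", "rheumatoid_arthritis",
    "coagulopathy", "obesity", "weight_loss", "fluid_electrolyte",
    "blood_loss_anemia", "deficiency_anemia", "alcohol_abuse",
    "drug_abuse", "psychoses", "depression"
  )
}

#' van Walraven weights for the Elixhauser score
#'
#' Integer weight per category; the comorbidity score of an admission is the
#' sum of weights over its flagged categories.
#'
#' @return Named integer vector over [eci_categories()].
#' @export
eci_weights <- function() {
  setNames(
    c(
      7L, 5L, -1L, 4L, 2L, 0L, 0L, 7L, 6L, 3L, 0L, 0L, 0L, 5L, 11L, 0L,
      0L, 9L, 12L, 4L, 0L, 3L, -4L, 6L, 5L, -2L, -2L, 0L, -7L, 0L, -3L
    ),
    eci_categories()
  )
}

#' A synthetic code-to-Elixhauser mapping
#'
#' Deterministically assigns each code to one of the first ten categories by
#' cycling, emulating the many-codes-to-few-categories coarseness of the
#' real mapping. Intended for synthetic cohorts and tests; real analyses
#' supply the published ICD-10 mapping via [read_eci_map()].
#'
#' @param codes Character vector of diagnosis codes.
#' @return Tibble `code`, `category`.
#' @export
synthetic_eci_map <- function(codes) {
  codes <- unique(codes)
  tibble(
    code = codes,
    category = eci_categories()[(seq_along(codes) - 1L) %% 10L + 1L]
  )
}

#' Read a code-to-Elixhauser mapping from CSV
#'
#' @param path CSV with columns `code` and `category` (category names must
#'   be among [eci_categories()]).
#' @return Tibble `code`, `category`.
#' @export
read_eci_map <- function(path) {
  m <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  if (!all(c("code", "category") %in% names(m))) {
    abort("an Elixhauser map needs columns 'code' and 'category'")
  }
  bad <- setdiff(unique(m$category), eci_categories())
  if (length(bad) > 0) {
    abort(paste0("unknown Elixhauser categories: ", paste(bad, collapse = ", ")))
  }
  as_tibble(m)
}

#' Weighted Elixhauser comorbidity score
#'
#' @param flags Numeric/logical vector (or matrix, categories in columns)
#'   of the 31 category indicators, named/ordered as [eci_categories()].
#' @param weights Named weights, default [eci_weights()].
#' @return Integer score(s): sum of weights over set flags.
#' @export
#' @examples
#' f <- setNames(rep(0, 31), eci_categories())
#' f["liver_disease"] <- 1
#' eci_score(f) # 11
eci_score <- function(flags, weights = eci_weights()) {
  if (is.matrix(flags)) {
    as.integer(as.numeric(flags %*% weights[colnames(flags)]))
  } else {
    as.integer(sum(weights[names(flags)][flags != 0]))
  }
}

one_hot_block <- function(values, levels, prefix) {
  m <- matrix(0, length(values), length(levels),
    dimnames = list(NULL, paste0(prefix, "_", levels))
  )
  hit <- match(as.character(values), as.character(levels))
  unknown <- which(!is.na(values) & is.na(hit))
  if (length(unknown) > 0) {
    warn(paste0(
      "unknown level(s) in '", prefix, "' left as all-zero one-hot: ",
      paste(unique(values[unknown]), collapse = ", ")
    ))
  }
  ok <- which(!is.na(hit))
  m[cbind(ok, hit[ok])] <- 1
  m
}

#' Baseline features available at the point of admission
#'
#' The reference 69-column baseline block: admission date parts, age,
#' hospital attributes, address codes and their equality flag, the count of
#' PoA diagnoses (numeric features); one-hot sex, admission source, ethnic
#' group, job and marital status; and the 31 Elixhauser flags plus the
#' weighted score computed from the PoA diagnosis codes. Hospital level is
#' emitted as two numeric columns (ordinal grade and a top-grade indicator).
#' Unknown categorical levels yield an all-zero one-hot block with a
#' warning.
#'
#' @param records Admission-record tibble (post-inclusion).
#' @param eci_map Code-to-category tibble (`code`, `category`), e.g. from
#'   [synthetic_eci_map()] or [read_eci_map()]; `NULL` leaves all flags 0.
#' @return Tibble: `record_id` plus 69 numeric feature columns.
#' @export
baseline_features <- function(records, eci_map = NULL) {
  poa_sets <- diagnosis_sets(records, poa_only = TRUE)
  num <- tibble(
    adm_year = as.numeric(lubridate::year(records$admission_date)),
    adm_month = as.numeric(lubridate::month(records$admission_date)),
    adm_dow = as.numeric(lubridate::wday(records$admission_date, week_start = 1)),
    age = as.numeric(records$age),
    hospital_affiliation = as.numeric(records$hospital_affiliation),
    admission_status = as.numeric(records$admission_status),
    patient_address_code = as.numeric(records$patient_address_code),
    hospital_address_code = as.numeric(records$hospital_address_code),
    address_match = as.numeric(records$patient_address_code == records$hospital_address_code),
    hospital_level = as.numeric(records$hospital_level),
    hospital_level_top = as.numeric(records$hospital_level >= 3),
    n_poa_diseases = as.numeric(lengths(poa_sets))
  )
  oh <- cbind(
    one_hot_block(records$sex, c("male", "female"), "sex"),
    one_hot_block(records$admission_source, 1:4, "source"),
    one_hot_block(records$ethnic_group, c("han", "minority"), "ethnic"),
    one_hot_block(records$job, 1:13, "job"),
    one_hot_block(records$marital_status, 1:4, "marital")
  )
  flags <- matrix(0, nrow(records), 31, dimnames = list(NULL, eci_categories()))
  if (!is.null(eci_map)) {
    for (i in seq_len(nrow(records))) {
      cats <- unique(eci_map$category[eci_map$code %in% poa_sets[[i]]])
      flags[i, cats] <- 1
    }
  }
  score <- eci_score(flags)
  colnames(flags) <- paste0("eci_", colnames(flags))
  bind_cols(
    tibble(record_id = records$record_id),
    num, as_tibble(oh), as_tibble(flags), tibble(eci_score = as.numeric(score))
  )
}

#' Historical-LOS features over a lookback window
#'
#' For each admission, the same patient's prior admissions with admission
#' date in `[current - window_years years, current)` contribute eight
#' features: count, mean, standard deviation (population convention, 0 for
#' a single stay), median, min and max of their LOS; the days between the
#' most recent prior discharge and the current admission; and the most
#' recent prior LOS. Patients with no history in the window get all zeros.
#'
#' @param records Admissions to featurize.
#' @param history Admission tibble to look up history in (typically the full
#'   filtered dataset, so earlier-era stays count).
#' @param window_years Lookback horizon in years (default 3).
#' @return Tibble: `record_id` plus `hist_n`, `hist_mean`, `hist_sd`,
#'   `hist_median`, `hist_min`, `hist_max`, `last_interval`, `last_los`.
#' @export
historical_features <- function(records, history, window_years = 3) {
  hist_by_patient <- split(
    history[, c("record_id", "admission_date", "discharge_date", "los")],
    history$patient_id
  )
  feats <- matrix(0, nrow(records), 8)
  colnames(feats) <- c(
    "hist_n", "hist_mean", "hist_sd", "hist_median",
    "hist_min", "hist_max", "last_interval", "last_los"
  )
  for (i in seq_len(nrow(records))) {
    h <- hist_by_patient[[records$patient_id[i]]]
    if (is.null(h)) next
    cur <- records$admission_date[i]
    lo <- cur - lubridate::years(window_years)
    h <- h[h$admission_date >= lo & h$admission_date < cur &
      h$record_id != records$record_id[i], , drop = FALSE]
    if (nrow(h) == 0) next
    last <- which.max(h$admission_date)
    feats[i, ] <- c(
      nrow(h), mean(h$los), pop_sd(h$los), median(h$los),
      min(h$los), max(h$los),
      as.numeric(cur - h$discharge_date[last]), h$los[last]
    )
  }
  bind_cols(tibble(record_id = records$record_id), as_tibble(feats))
}

#' Mean LOS per disease over training admissions
#'
#' For each chronic disease, the mean LOS of the training admissions whose
#' PoA diagnosis set contains it. Computed on training rows only so that
#' held-out rows never contribute to any row's features.
#'
#' @param train_records Training admission tibble.
#' @param catalog [chronic_catalog()].
#' @return Tibble `code`, `los_mean`, `n_admissions`.
#' @export
los_mean_per_disease <- function(train_records, catalog) {
  sets <- diagnosis_sets(train_records, poa_only = TRUE, catalog = catalog)
  tibble(
    code = unlist(sets),
    los = rep(train_records$los, lengths(sets))
  ) |>
    group_by(.data$code) |>
    summarise(los_mean = mean(.data$los), n_admissions = n(), .groups = "drop")
}

#' Disease-risk table: centrality times mean LOS
#'
#' `risk(v) = EVC(v) * los_mean(v)` blends how central a disease is in the
#' multimorbidity network with how long its carriers stay.
#'
#' @param evc Named eigenvector-centrality vector from
#'   [eigenvector_centrality()].
#' @param los_means Tibble from [los_mean_per_disease()].
#' @return Tibble `code`, `evc`, `los_mean`, `risk` over the intersection of
#'   the two inputs.
#' @export
disease_risk_table <- function(evc, los_means) {
  tibble(code = names(evc), evc = unname(evc)) |>
    inner_join(los_means[, c("code", "los_mean")], by = "code") |>
    mutate(risk = .data$evc * .data$los_mean)
}

#' Disease-risk aggregate features
#'
#' Count, max, mean and sum of the disease-risk scores of the admission's
#' chronic PoA diseases covered by the risk table; all zero when none are
#' covered.
#'
#' @param records Admissions to featurize.
#' @param risk_table Tibble from [disease_risk_table()].
#' @param catalog [chronic_catalog()].
#' @return Tibble: `record_id`, `risk_n`, `risk_max`, `risk_mean`,
#'   `risk_sum`.
#' @export
disease_risk_features <- function(records, risk_table, catalog) {
  sets <- diagnosis_sets(records, poa_only = TRUE, catalog = catalog)
  risk <- setNames(risk_table$risk, risk_table$code)
  feats <- t(vapply(sets, function(s) {
    r <- risk[s[s %in% names(risk)]]
    if (length(r) == 0) return(c(0, 0, 0, 0))
    c(length(r), max(r), mean(r), sum(r))
  }, numeric(4)))
  colnames(feats) <- c("risk_n", "risk_max", "risk_mean", "risk_sum")
  bind_cols(tibble(record_id = records$record_id), as_tibble(feats))
}

#' Centrality-weighted multi-hot disease features
#'
#' A multi-hot encoding of the admission's chronic PoA diseases over a fixed
#' vocabulary, with each one replaced by the disease's eigenvector
#' centrality; diseases outside the vocabulary contribute nothing.
#'
#' @param records Admissions to featurize.
#' @param evc Named centrality vector.
#' @param vocab Ordered character vector of vocabulary codes.
#' @param catalog [chronic_catalog()].
#' @return Tibble: `record_id` plus one `evc_<code>` column per vocabulary
#'   entry.
#' @export
evc_features <- function(records, evc, vocab, catalog) {
  sets <- diagnosis_sets(records, poa_only = TRUE, catalog = catalog)
  m <- matrix(0, nrow(records), length(vocab),
    dimnames = list(NULL, paste0("evc_", vocab))
  )
  for (i in seq_len(nrow(records))) {
    hit <- match(intersect(sets[[i]], vocab), vocab)
    m[i, hit] <- evc[vocab[hit]]
  }
  bind_cols(tibble(record_id = records$record_id), as_tibble(m))
}

#' Neighbour-LOS features from the patient-similarity network
#'
#' Mean, standard deviation (population convention), median, min and max of
#' the LOS of an admission's similarity neighbours; all zero for admissions
#' without neighbours.
#'
#' @param records Admissions to featurize.
#' @param neighbors Neighbour tibble from [query_neighbors()] (carries
#'   `neighbor_los`).
#' @return Tibble: `record_id`, `psn_mean`, `psn_sd`, `psn_median`,
#'   `psn_min`, `psn_max`.
#' @export
psn_features <- function(records, neighbors) {
  agg <- neighbors |>
    group_by(.data$query_id) |>
    summarise(
      psn_mean = mean(.data$neighbor_los),
      psn_sd = pop_sd(.data$neighbor_los),
      psn_median = median(.data$neighbor_los),
      psn_min = min(.data$neighbor_los),
      psn_max = max(.data$neighbor_los),
      .groups = "drop"
    )
  out <- tibble(record_id = records$record_id) |>
    left_join(agg, by = c(record_id = "query_id"))
  out[is.na(out)] <- 0
  out
}

#' Assemble group-tagged feature blocks into one feature table
#'
#' Column-binds the blocks (each a tibble keyed by `record_id`), checks the
#' row ids align and no cell is missing, and tags every feature column with
#' its group.
#'
#' @param records Admission tibble supplying `record_id` and the `los`
#'   label.
#' @param blocks Named list of lists: `group tag -> list of block tibbles`.
#' @return A tibble of class `feature_table` with `record_id`, `los` and all
#'   feature columns; attribute `groups` maps each feature column to its
#'   group tag.
#' @export
assemble_features <- function(records, blocks) {
  out <- tibble(record_id = records$record_id, los = records$los)
  groups <- character(0)
  for (g in names(blocks)) {
    for (blk in blocks[[g]]) {
      if (!identical(blk$record_id, out$record_id)) {
        abort(paste0("misaligned record ids in a '", g, "' feature block"))
      }
      cols <- setdiff(names(blk), "record_id")
      dup <- intersect(cols, names(out))
      if (length(dup) > 0) {
        abort(paste0("duplicate feature column(s): ", paste(dup, collapse = ", ")))
      }
      out <- bind_cols(out, blk[cols])
      groups[cols] <- g
    }
  }
  if (anyNA(out)) abort("assembled feature table contains missing values")
  structure(out, groups = groups, class = c("feature_table", class(out)))
}

#' Group tags of a feature table
#'
#' @param ft A `feature_table`.
#' @return Named character vector: feature column -> group tag.
#' @export
feature_groups <- function(ft) attr(ft, "groups")

#' Restrict a feature table to selected feature groups
#'
#' @param ft A `feature_table`.
#' @param groups Character vector of group tags to keep.
#' @return A `feature_table` with only those groups' columns.
#' @export
select_groups <- function(ft, groups) {
  g <- feature_groups(ft)
  unknown <- setdiff(groups, unique(g))
  if (length(unknown) > 0) {
    abort(paste0("unknown feature group(s): ", paste(unknown, collapse = ", ")))
  }
  keep <- names(g)[g %in% groups]
  out <- ft[, c("record_id", "los", keep)]
  structure(out, groups = g[keep], class = c("feature_table", class(tibble())))
}

# Numeric model matrix of a feature table (drops id and label).
feature_matrix <- function(ft) {
  as.matrix(ft[, names(feature_groups(ft)), drop = FALSE])
}
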