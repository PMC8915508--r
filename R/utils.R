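#' @importFrom rlang .data .env abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows bind_cols n across rename pull
#'   distinct slice row_number if_else
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median quantile rnorm rbinom rnbinom runif sd setNames
#'   predict
#' @importFrom utils head modifyList
NULL

# Age-group blocking used throughout: sex x five-year band from 65, open at 90.
AGE_BREAKS <- c(65, 70, 75, 80, 85, 90, Inf)
AGE_LABELS <- c("65-69", "70-74", "75-79", "80-84", "85-89", "90+")

#' Assign the five-year age band used for patient-similarity blocking
#'
#' Bands are `65-69`, `70-74`, `75-79`, `80-84`, `85-89` and `90+`. Ages below
#' 65 (which the inclusion criteria remove) map to `NA`.
#'
#' @param age Integer vector of ages in years.
#' @return A factor with the six band labels.
#' @export
#' @examples
#' age_group(c(65, 69, 70, 92))
age_group <- function(age) {
  cut(age, breaks = AGE_BREAKS, labels = AGE_LABELS, right = FALSE)
}

# Stable 32-bit FNV-1a hash of a string; used to fan a global seed out into
# independent per-stage seeds without any order dependence.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30) + 2^30, b) # keep in int range
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% 2^31)
}

#' Derive a deterministic per-stage seed from a global seed
#'
#' @param seed Global integer seed.
#' @param stage Character stage name.
#' @return An integer seed below 2^31, stable in `seed` and `stage`.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + fnv1a32(stage)) %% 2147483647L)
}

# Population standard deviation with the single-observation convention sd = 0.
pop_sd <- function(x) {
  n <- length(x)
  if (n <= 1) return(0)
  sqrt(sum((x - mean(x))^2) / n)
}

# Nearest-rank quantile: the ceil(q*n)-th order statistic.
nearest_rank_quantile <- function(x, q) {
  stopifnot(length(x) > 0, q > 0, q < 1)
  sort(x)[ceiling(q * length(x))]
}

is_icd3 <- function(code) {
  grepl("^[A-Z][0-9]{2}$", code)
}
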