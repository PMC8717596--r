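#' @keywords internal
"_PACKAGE"

# Canonical category sets used across the generator, cohort builder and models.
REGION_LEVELS <- c("major_city", "inner_regional", "outer_regional",
                   "remote", "very_remote")
AGE_BANDS <- c("<45", "45-54", "55-64", "65-74", "75-84", "85-94", "95+")
MARITAL_LEVELS <- c("divorced_separated", "married", "never_married", "widowed")
BIRTH_LEVELS <- c("America", "Asia", "Europe", "Oceania", "Africa")
COMORB_LEVELS <- c("0", "1", "2+")

#' Normalise an ICD-10 code for prefix matching
#'
#' Strips dots and whitespace and upper-cases, so that `"t81.4"` and
#' `"T814"` compare equal. Prefix matching throughout the package operates
#' on normalised codes.
#'
#' @param code character vector of ICD-10(-AM) codes.
#' @return character vector of normalised codes.
#' @export
normalise_icd10 <- function(code) {
  toupper(gsub("[.[:space:]]", "", as.character(code)))
}

# Longest-prefix match of normalised codes against a table of normalised
# prefixes. Returns the row index of the matching entry (NA if none).
# Duplicate prefixes are rejected at map-load time, so the longest match
# is unique.
match_longest_prefix <- function(codes, prefixes) {
  best <- rep(NA_integer_, length(codes))
  best_len <- rep(0L, length(codes))
  ord <- order(nchar(prefixes))  # longer prefixes processed later win
  for (k in ord) {
    p <- prefixes[k]
    hit <- startsWith(codes, p) & nchar(p) > best_len
    best[hit] <- k
    best_len[hit] <- nchar(p)
  }
  best
}

#' Complement of a HAC rate on the percent scale
#'
#' The patient-safety output used in the benchmarking analysis:
#' `100 * (1 - hac_rate)`.
#'
#' @param hac_rate fraction of episodes with at least one hospital-acquired
#'   complication, in `[0, 1]`.
#' @return safety rate in percent, in `[0, 100]`.
#' @export
safety_rate <- function(hac_rate) {
  stopifnot(is.numeric(hac_rate), all(hac_rate >= 0 & hac_rate <= 1))
  100 * (1 - hac_rate)
}

#' HAC prevalence from episode counts
#'
#' @param n_hac number of episodes with at least one complication.
#' @param n_total total number of episodes.
#' @return prevalence in percent.
#' @export
hac_prevalence_pct <- function(n_hac, n_total) {
  stopifnot(n_total > 0, n_hac >= 0, n_hac <= n_total)
  100 * n_hac / n_total
}

#' Reducible complication episodes implied by a mean technical efficiency
#'
#' If the cohort-average technical efficiency is `te` (fraction), the share
#' `1 - te` of observed HAC episodes could be avoided by matching
#' best-practice hospitals: `round(n_hac * (1 - te))`.
#'
#' @param n_hac observed number of HAC episodes.
#' @param mean_te mean technical efficiency as a fraction in `(0, 1]`.
#' @return rounded count of reducible episodes.
#' @export
reducible_hac_episodes <- function(n_hac, mean_te) {
  stopifnot(n_hac >= 0, mean_te > 0, mean_te <= 1)
  round(n_hac * (1 - mean_te))
}

#' Projected cost saving from avoided complication episodes
#'
#' @param n_reducible number of avoidable HAC episodes.
#' @param excess_cost mean excess hospital cost of a HAC episode (currency
#'   units per episode).
#' @return projected saving in millions of the same currency unit.
#' @export
projected_saving_millions <- function(n_reducible, excess_cost) {
  stopifnot(n_reducible >= 0, excess_cost >= 0)
  n_reducible * excess_cost / 1e6
}

# Stable salted pseudonym for a unit identifier (privacy-preserving export).
pseudonymise_ids <- function(ids, salt) {
  vapply(as.character(ids), function(id) {
    paste0("DMU-", substr(digest::digest(paste0(salt, "::", id),
                                         algo = "sha1"), 1L, 8L))
  }, character(1), USE.NAMES = FALSE)
}

# Odds-ratio vector -> named log-odds vector (generator defaults are
# specified on the odds/multiplier scale, models work on the log scale).
log_or <- function(x) log(x)
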