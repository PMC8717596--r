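# Charlson comorbidity index (Quan ICD-10 algorithm, updated 12-condition
# weights) and hospital-level complexity aggregation.

#' Load a Charlson condition map
#'
#' CSV columns: `code_prefix`, `condition`, `weight`. The shipped map uses
#' the Quan ICD-10 coding prefixes for the 12 conditions with non-zero
#' weight in the updated (mortality-calibrated) index. A hierarchy table
#' (`mild`, `severe`) lists condition pairs where only the severe member
#' scores when both are present (mild vs moderate/severe liver disease;
#' any malignancy vs metastatic solid tumour).
#'
#' @param path map CSV path.
#' @param hierarchy_path hierarchy CSV path.
#' @return object of class `charlson_map`: list with `entries`,
#'   `weights` (named per condition), `hierarchy`.
#' @export
load_charlson_map <- function(
    path = hacbench_extdata("charlson_map.csv"),
    hierarchy_path = hacbench_extdata("charlson_hierarchy.csv")) {
  if (!file.exists(path)) stop("Charlson map file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "integer"))
  if (nrow(raw) == 0) stop("Charlson map file is empty: ", path)
  raw$code_prefix <- normalise_icd10(raw$code_prefix)
  if (anyDuplicated(raw$code_prefix))
    stop("Charlson map: duplicate code prefixes")
  conds <- unique(raw$condition)
  if (length(conds) != 12)
    stop("Charlson map must define exactly 12 conditions, found ",
         length(conds))
  w <- tapply(raw$weight, raw$condition, unique)
  if (any(vapply(w, length, integer(1)) != 1))
    stop("Charlson map: a condition has inconsistent weights")
  weights <- vapply(w, identity, numeric(1))
  if (any(weights <= 0 | weights != round(weights)))
    stop("Charlson map: weights must be positive integers")
  hierarchy <- utils::read.csv(hierarchy_path, stringsAsFactors = FALSE)
  if (!all(c(hierarchy$mild, hierarchy$severe) %in% conds))
    stop("Charlson hierarchy references unknown conditions")
  structure(list(entries = raw, weights = weights, hierarchy = hierarchy),
            class = "charlson_map")
}

# Distinct Charlson conditions matched by a set of codes (no hierarchy).
matched_conditions <- function(codes, map) {
  hit <- match_longest_prefix(normalise_icd10(codes),
                              map$entries$code_prefix)
  unique(map$entries$condition[hit[!is.na(hit)]])
}

#' Charlson comorbidity index for one diagnosis list
#'
#' Sum of condition weights over distinct matched conditions, each counted
#' once, with hierarchy rules applied (the severe member of a pair
#' supersedes the mild one). Unmapped codes are ignored.
#'
#' @param codes character vector of ICD-10 codes.
#' @param map a `charlson_map`.
#' @return integer score.
#' @export
compute_cci <- function(codes, map) {
  conds <- matched_conditions(codes, map)
  if (length(conds) == 0) return(0L)
  if (nrow(map$hierarchy) > 0) {
    drop <- map$hierarchy$mild[map$hierarchy$severe %in% conds]
    conds <- setdiff(conds, drop)
  }
  as.integer(sum(map$weights[conds]))
}

#' Per-episode Charlson scores and comorbidity counts for a cohort
#'
#' @param episodes episode table.
#' @param diagnoses long diagnosis table.
#' @param map a `charlson_map`.
#' @return `episodes` with `cci` (hierarchy-adjusted score) and
#'   `n_comorbidities` (distinct matched conditions, pre-hierarchy) and a
#'   factor `comorb_cat` (`0`, `1`, `2+`).
#' @export
score_comorbidities <- function(episodes, diagnoses, map) {
  hit <- match_longest_prefix(normalise_icd10(diagnoses$icd10),
                              map$entries$code_prefix)
  matched <- !is.na(hit)
  md <- data.frame(episode_id = diagnoses$episode_id[matched],
                   condition = map$entries$condition[hit[matched]],
                   stringsAsFactors = FALSE)
  md <- unique(md)
  sev <- map$hierarchy$severe
  mild <- map$hierarchy$mild
  by_ep <- split(md$condition, md$episode_id)
  cci <- vapply(by_ep, function(conds) {
    drop <- mild[sev %in% conds]
    sum(map$weights[setdiff(conds, drop)])
  }, numeric(1))
  ncond <- vapply(by_ep, length, integer(1))
  i <- match(episodes$episode_id, names(by_ep))
  episodes$cci <- as.integer(ifelse(is.na(i), 0L, cci[i]))
  episodes$n_comorbidities <- as.integer(ifelse(is.na(i), 0L, ncond[i]))
  episodes$comorb_cat <- factor(
    ifelse(episodes$n_comorbidities >= 2, "2+",
           as.character(episodes$n_comorbidities)),
    levels = COMORB_LEVELS)
  episodes
}

#' Aggregate episodes to hospital-level benchmarking inputs and outputs
#'
#' Per hospital: HAC rate, safety rate `100 * (1 - hac_rate)` (the DEA
#' output), mean Charlson score, ICU admission rate, and the complexity /
#' simplicity indices (DEA input). The complexity index is a documented
#' stand-in (the construction behind the original analysis is not public):
#' an equal-weight average of the capped, normalised mean Charlson score
#' and the ICU rate, `w_cci * min(mean_cci / cci_cap, 1) + w_icu *
#' icu_rate`, which respects the unit range and both stated ingredients. `cci_cap` defaults to the cohort's 97.5th percentile of
#' episode-level Charlson scores.
#'
#' @param episodes flagged, scored episode table (needs `hospital_id`,
#'   `hac`, `cci`, `icu`).
#' @param hospitals hospital table (needs `hospital_id`, `region`, `beds`).
#' @param cci_cap normalising constant for the mean Charlson score;
#'   `NULL` = cohort 97.5th percentile.
#' @param weights length-2 non-negative weights (Charlson, ICU) summing
#'   to 1.
#' @return data.frame of class `hospital_aggregates`.
#' @export
build_hospital_aggregates <- function(episodes, hospitals, cci_cap = NULL,
                                      weights = c(0.5, 0.5)) {
  stopifnot(length(weights) == 2, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-9)
  for (col in c("hac", "cci", "icu"))
    if (!col %in% names(episodes))
      stop("episodes table lacks required column '", col,
           "' (pipeline-order error)")
  if (is.null(cci_cap)) {
    cci_cap <- as.numeric(stats::quantile(episodes$cci, 0.975, type = 7))
    if (cci_cap <= 0) cci_cap <- 1
  }
  empty <- setdiff(hospitals$hospital_id, unique(episodes$hospital_id))
  if (length(empty) > 0)
    warning("dropping hospital(s) with no retained episodes: ",
            paste(empty, collapse = ", "))
  agg <- do.call(rbind, lapply(split(episodes, episodes$hospital_id),
                               function(d) {
    data.frame(hospital_id = d$hospital_id[1],
               n_episodes = nrow(d),
               hac_rate = mean(d$hac),
               mean_cci = mean(d$cci),
               icu_rate = mean(d$icu),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  hi <- match(agg$hospital_id, hospitals$hospital_id)
  if (anyNA(hi))
    stop("episodes reference unknown hospital(s): ",
         paste(agg$hospital_id[is.na(hi)], collapse = ", "))
  agg$region <- hospitals$region[hi]
  agg$beds <- hospitals$beds[hi]
  agg$safety_rate <- safety_rate(agg$hac_rate)
  agg$complexity <- weights[1] * pmin(agg$mean_cci / cci_cap, 1) +
    weights[2] * agg$icu_rate
  agg$simplicity <- 1 - agg$complexity
  attr(agg, "cci_cap") <- cci_cap
  attr(agg, "complexity_weights") <- weights
  class(agg) <- c("hospital_aggregates", "data.frame")
  agg
}
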