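# Hospital-acquired complication (HAC) classification.
#
# An episode's diagnosis contributes a HAC group iff it is a subsequent
# (non-principal) diagnosis, its condition-onset flag (COF) equals 1
# ("condition with onset during the episode of admitted patient care"),
# its ICD-10 code longest-prefix-matches the HAC mapping, and the matched
# group is not excluded. Groups 5 (unplanned ICU admission) and 15/16
# (maternity/neonatal) are excluded by default.

#' Path to a shipped reference data file
#'
#' @param file file name under `extdata`.
#' @return absolute path.
#' @export
hacbench_extdata <- function(file) {
  path <- system.file("extdata", file, package = "hacbench")
  if (path == "") {
    # during development (package sources not installed)
    path <- file.path("inst", "extdata", file)
  }
  path
}

#' Load a HAC mapping table
#'
#' The mapping is a CSV with columns `code_prefix`, `hac_group_id`
#' (1..16) and `group_name`. The shipped default is a reduced,
#' clearly-versioned reference mapping with representative ICD-10 code
#' prefixes for each included group; a user-supplied full ICD-10-AM
#' mapping with the same columns can be substituted.
#'
#' @param path CSV path; default is the shipped reference mapping.
#' @param excluded_groups group ids never reported as HACs; default
#'   `c(5, 15, 16)`.
#' @return object of class `hac_mapping`: list with `entries` (normalised
#'   prefixes), `excluded_groups`, `version`.
#' @export
load_hac_mapping <- function(path = hacbench_extdata("hac_mapping.csv"),
                             excluded_groups = c(5L, 15L, 16L)) {
  if (!file.exists(path)) stop("HAC mapping file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "integer", "character"))
  if (nrow(raw) == 0) stop("HAC mapping file is empty: ", path)
  needed <- c("code_prefix", "hac_group_id", "group_name")
  if (!all(needed %in% names(raw)))
    stop("HAC mapping must have columns: ", paste(needed, collapse = ", "))
  bad <- which(is.na(raw$hac_group_id) | raw$hac_group_id < 1 |
                 raw$hac_group_id > 16)
  if (length(bad) > 0)
    stop("HAC mapping: group id outside 1..16 at row(s) ",
         paste(bad, collapse = ", "))
  bad <- which(is.na(raw$code_prefix) | raw$code_prefix == "")
  if (length(bad) > 0)
    stop("HAC mapping: malformed code at row(s) ", paste(bad, collapse = ", "))
  raw$code_prefix <- normalise_icd10(raw$code_prefix)
  dup <- duplicated(raw$code_prefix)
  if (any(dup))
    stop("HAC mapping: duplicate code prefix(es): ",
         paste(unique(raw$code_prefix[dup]), collapse = ", "))
  structure(list(entries = raw,
                 excluded_groups = as.integer(excluded_groups),
                 version = "hacbench-reference-0.1"),
            class = "hac_mapping")
}

#' Classify one episode's diagnoses into HAC groups
#'
#' @param diagnoses data.frame for a single episode with columns `seq`
#'   (1 = principal diagnosis), `icd10`, `cof`.
#' @param mapping a `hac_mapping`.
#' @return list with `hac_groups` (sorted integer vector of included
#'   group ids) and `hac` (logical).
#' @export
classify_episode <- function(diagnoses, mapping) {
  if (nrow(diagnoses) == 0)
    return(list(hac_groups = integer(0), hac = FALSE))
  eligible <- diagnoses$seq > 1 & diagnoses$cof == 1
  codes <- normalise_icd10(diagnoses$icd10[eligible])
  hit <- match_longest_prefix(codes, mapping$entries$code_prefix)
  groups <- mapping$entries$hac_group_id[hit[!is.na(hit)]]
  groups <- sort(unique(groups[!(groups %in% mapping$excluded_groups)]))
  list(hac_groups = groups, hac = length(groups) > 0)
}

#' Flag a cohort for hospital-acquired complications
#'
#' Vectorised classification of every episode. An episode is a HAC episode
#' iff at least one subsequent diagnosis with condition-onset flag 1 maps
#' to a non-excluded HAC group.
#'
#' @param episodes episode table (must have `episode_id`).
#' @param diagnoses long diagnosis table (`episode_id`, `seq`, `icd10`,
#'   `cof`).
#' @param mapping a `hac_mapping`.
#' @return list with `episodes` (input plus `hac` logical and `hac_groups`
#'   comma-separated string columns), `group_freq` (episode counts per
#'   included group; an episode with two groups counts once per group) and
#'   `unmapped` diagnostics (count and rate of eligible codes with no
#'   mapping entry).
#' @export
flag_cohort <- function(episodes, diagnoses, mapping) {
  eligible <- diagnoses[diagnoses$seq > 1 & diagnoses$cof == 1, ,
                        drop = FALSE]
  codes <- normalise_icd10(eligible$icd10)
  hit <- match_longest_prefix(codes, mapping$entries$code_prefix)
  n_unmapped <- sum(is.na(hit))
  grp <- mapping$entries$hac_group_id[hit]
  ok <- !is.na(grp) & !(grp %in% mapping$excluded_groups)
  calls <- data.frame(episode_id = eligible$episode_id[ok],
                      group = grp[ok], stringsAsFactors = FALSE)
  calls <- unique(calls)
  calls <- calls[order(calls$episode_id, calls$group), , drop = FALSE]

  by_ep <- split(calls$group, calls$episode_id)
  hac_groups <- vapply(by_ep, function(g) paste(sort(g), collapse = ","),
                       character(1))
  episodes$hac <- episodes$episode_id %in% names(by_ep)
  episodes$hac_groups <- unname(
    hac_groups[match(episodes$episode_id, names(by_ep))])
  episodes$hac_groups[is.na(episodes$hac_groups)] <- ""

  included <- sort(setdiff(unique(mapping$entries$hac_group_id),
                           mapping$excluded_groups))
  group_freq <- data.frame(
    hac_group_id = included,
    group_name = mapping$entries$group_name[
      match(included, mapping$entries$hac_group_id)],
    n_episodes = as.integer(table(factor(calls$group, levels = included))),
    stringsAsFactors = FALSE)

  list(episodes = episodes, group_freq = group_freq,
       unmapped = list(n = n_unmapped,
                       rate = if (nrow(eligible) > 0)
                         n_unmapped / nrow(eligible) else 0))
}
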