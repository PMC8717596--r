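# Cohort construction: inclusion/exclusion rules and derived outcomes.
#
# Exclusions follow the study design for overnight public-hospital
# admissions: same-day episodes are removed first (they rarely carry
# hospital-acquired complications), then episodes at private-sector
# hospitals (whose characteristics and costs are not observed).
# The 30-day readmission flag is re-derived from dates: an episode is a
# readmission source if the same patient has a later retained admission
# starting within 0..30 days (inclusive) of its separation date.

#' Apply cohort exclusion rules
#'
#' @param episodes episode table (`hospital_id`, `same_day` required).
#' @param hospitals hospital table (`hospital_id`, `sector`).
#' @return list with `episodes` (retained rows) and `summary`, a
#'   `cohort_summary` list of exclusion accounting counts. Same-day
#'   exclusion is applied before the private-sector exclusion, and the
#'   counts are attributed in that order.
#' @export
apply_exclusions <- function(episodes, hospitals) {
  unknown <- setdiff(unique(episodes$hospital_id), hospitals$hospital_id)
  if (length(unknown) > 0)
    stop("episodes reference unknown hospital id(s): ",
         paste(unknown, collapse = ", "))
  n_raw <- nrow(episodes)
  same_day <- episodes$same_day
  n_same_day <- sum(same_day)
  kept <- episodes[!same_day, , drop = FALSE]
  sector <- hospitals$sector[match(kept$hospital_id, hospitals$hospital_id)]
  private <- sector == "private"
  n_private <- sum(private)
  kept <- kept[!private, , drop = FALSE]
  rownames(kept) <- NULL
  summary <- structure(list(
    n_episodes_raw = n_raw,
    n_excluded_same_day = n_same_day,
    n_excluded_private = n_private,
    n_episodes_final = nrow(kept),
    n_patients_final = length(unique(kept$patient_id)),
    n_hospitals_final = length(unique(kept$hospital_id))),
    class = "cohort_summary")
  stopifnot(summary$n_episodes_final ==
              n_raw - n_same_day - n_private)
  list(episodes = kept, summary = summary)
}

#' Derive the 30-day readmission flag from admission dates
#'
#' `readmit30` is TRUE iff the same patient has a later retained episode
#' whose admission date falls within 0..30 days (inclusive) after this
#' episode's separation date. A readmission beginning on the discharge
#' day itself (gap 0) counts. Episodes ending in in-hospital death are
#' checked to have no later admissions. Overlapping episodes for one
#' patient trigger a warning and are used as recorded.
#'
#' @param episodes retained episode table (`patient_id`, `admit_date`,
#'   `separation_date`; `died_in_hospital` optional).
#' @return `episodes` with a logical `readmit30` column, original row
#'   order preserved.
#' @export
derive_readmission <- function(episodes) {
  if (nrow(episodes) == 0) {
    episodes$readmit30 <- logical(0)
    return(episodes)
  }
  ord <- order(episodes$patient_id, episodes$admit_date,
               episodes$separation_date)
  ep <- episodes[ord, , drop = FALSE]
  readmit <- logical(nrow(ep))
  overlap <- FALSE
  dead_with_successor <- FALSE
  start <- 1L
  pid <- ep$patient_id
  n <- nrow(ep)
  for (i in seq_len(n)) {
    if (i == n || pid[i + 1] != pid[i]) {
      rows <- start:i
      if (length(rows) > 1) {
        adm <- as.numeric(ep$admit_date[rows])
        sep <- as.numeric(ep$separation_date[rows])
        for (k in seq_along(rows)[-length(rows)]) {
          later <- (k + 1):length(rows)
          gaps <- adm[later] - sep[k]
          if (any(gaps < 0)) overlap <- TRUE
          readmit[rows[k]] <- any(gaps >= 0 & gaps <= 30)
        }
        if (!is.null(ep$died_in_hospital) &&
            any(ep$died_in_hospital[rows[-length(rows)]]))
          dead_with_successor <- TRUE
      }
      start <- i + 1L
    }
  }
  if (overlap)
    warning("overlapping episodes detected for at least one patient; ",
            "dates used as recorded")
  if (dead_with_successor)
    warning("episode(s) ending in in-hospital death have later ",
            "admissions for the same patient")
  episodes$readmit30 <- readmit[order(ord)]
  episodes
}

#' Summarise a flagged cohort
#'
#' @param episodes retained episodes with the `hac` flag filled.
#' @param summary optional `cohort_summary` from [apply_exclusions()],
#'   carried through.
#' @return list: exclusion counts (if given), episode / patient /
#'   hospital counts, `n_hac_episodes`, `hac_prevalence` (fraction) and
#'   `hac_prevalence_pct_display` (percent, 1 decimal).
#' @export
summarize_cohort <- function(episodes, summary = NULL) {
  if (!"hac" %in% names(episodes))
    stop("'hac' column missing: run flag_cohort() first (pipeline-order ",
         "error)")
  n <- nrow(episodes)
  n_hac <- sum(episodes$hac)
  prev <- if (n > 0) n_hac / n else 0
  out <- list(
    n_episodes = n,
    n_patients = length(unique(episodes$patient_id)),
    n_hospitals = length(unique(episodes$hospital_id)),
    n_hac_episodes = n_hac,
    hac_prevalence = prev,
    hac_prevalence_pct_display = round(100 * prev, 1))
  if (!is.null(summary)) out <- c(unclass(summary), out)
  out
}
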