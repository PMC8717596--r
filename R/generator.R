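# Synthetic admissions-cohort generator.
#
# Emulates a linked administrative cohort of cardiovascular-disease
# patients: multi-episode patients, a five-level hospital remoteness mix,
# HAC incidence driven by age / ICU / comorbidity burden plus a latent
# hospital-level safety inefficiency, and outcome models (in-hospital
# death, next-admission gap, cost, length of stay) with known effect
# sizes so the analysis pipeline can be validated by parameter recovery.

# Design terms shared by the generator's linear predictors. Coefficient
# vectors are named with these terms (plus "intercept" and, for outcome
# models, "hac").
DESIGN_TERMS <- c(
  "sex_male", "indigenous",
  "age_45_54", "age_55_64", "age_65_74", "age_75_84", "age_85_94", "age_95p",
  "seifa_q2", "seifa_q3", "seifa_q4", "seifa_q5",
  "marital_married", "marital_never_married", "marital_widowed",
  "birth_asia", "birth_europe", "birth_oceania", "birth_africa",
  "insurance", "acute", "icu", "comorb_1", "comorb_2p",
  "region_inner_regional", "region_outer_regional", "region_remote",
  "region_very_remote")

named_log <- function(values, terms) {
  stats::setNames(log(values), terms)
}

default_model_coeffs <- function(model = c("hac", "death", "readmit",
                                           "cost", "los")) {
  model <- match.arg(model)
  age <- paste0("age_", c("45_54", "55_64", "65_74", "75_84", "85_94", "95p"))
  seifa <- paste0("seifa_q", 2:5)
  marital <- paste0("marital_", c("married", "never_married", "widowed"))
  birth <- paste0("birth_", c("asia", "europe", "oceania", "africa"))
  region <- paste0("region_", c("inner_regional", "outer_regional",
                                "remote", "very_remote"))
  switch(model,
    hac = c(
      named_log(0.04, "intercept"),
      named_log(c(0.96, 1.01), c("sex_male", "indigenous")),
      named_log(c(1.09, 1.35, 1.70, 2.15, 2.40, 2.65), age),
      named_log(c(1.08, 1.21, 1.03, 0.94), seifa),
      named_log(c(1.01, 1.05, 1.08), marital),
      named_log(c(0.91, 0.98, 1.02, 0.76), birth),
      named_log(0.95, "insurance"),
      named_log(c(0.57, 10.07), c("acute", "icu")),
      named_log(c(1.17, 1.41), c("comorb_1", "comorb_2p")),
      named_log(c(0.85, 1.09, 0.34, 0.47), region)),
    death = c(
      named_log(0.04, "intercept"), named_log(2.54, "hac"),
      named_log(c(1.20, 1.00), c("sex_male", "indigenous")),
      named_log(c(1.54, 2.02, 2.84, 3.57, 5.33, 8.46), age),
      named_log(c(1.13, 1.06, 1.03, 1.06), seifa),
      named_log(c(1.21, 1.10, 1.10), marital),
      named_log(c(0.63, 0.62, 0.67, 0.60), birth),
      named_log(0.98, "insurance"),
      named_log(c(0.16, 4.48), c("acute", "icu")),
      named_log(c(1.21, 1.40), c("comorb_1", "comorb_2p")),
      named_log(c(0.91, 1.39, 1.06, 1.05), region)),
    readmit = c(
      named_log(0.02, "intercept"), named_log(0.53, "hac"),
      named_log(c(1.06, 1.50), c("sex_male", "indigenous")),
      named_log(c(0.89, 0.82, 0.77, 0.73, 0.71, 0.60), age),
      named_log(c(1.00, 0.96, 1.06, 1.13), seifa),
      named_log(c(0.92, 0.98, 0.94), marital),
      named_log(c(0.96, 1.13, 1.15, 1.31), birth),
      named_log(1.08, "insurance"),
      named_log(c(7.63, 0.61), c("acute", "icu")),
      named_log(c(1.37, 2.02), c("comorb_1", "comorb_2p")),
      named_log(c(1.14, 1.20, 1.43, 0.95), region)),
    cost = c(
      named_log(3669, "intercept"), named_log(3.10, "hac"),
      named_log(c(0.98, 0.96), c("sex_male", "indigenous")),
      named_log(c(0.98, 1.03, 1.08, 1.08, 1.05, 1.02), age),
      named_log(c(1.01, 1.02, 0.98, 0.89), seifa),
      named_log(c(1.02, 1.04, 1.03), marital),
      named_log(c(1.01, 1.01, 1.01, 0.95), birth),
      named_log(0.88, "insurance"),
      named_log(c(0.67, 3.78), c("acute", "icu")),
      named_log(c(1.08, 1.23), c("comorb_1", "comorb_2p")),
      named_log(c(0.95, 1.01, 1.22, 2.19), region)),
    los = c(
      named_log(4.48, "intercept"), named_log(2.93, "hac"),
      named_log(c(0.97, 0.91), c("sex_male", "indigenous")),
      named_log(c(0.99, 1.03, 1.10, 1.17, 1.22, 1.18), age),
      named_log(c(1.03, 1.00, 0.99, 0.99), seifa),
      named_log(c(0.96, 1.07, 1.01), marital),
      named_log(c(0.98, 0.98, 1.00, 0.89), birth),
      named_log(0.95, "insurance"),
      named_log(c(0.44, 1.88), c("acute", "icu")),
      named_log(c(1.15, 1.30), c("comorb_1", "comorb_2p")),
      named_log(c(1.00, 1.12, 0.99, 1.07), region)))
}

#' Configuration for the synthetic admissions-cohort generator
#'
#' Returns a validated configuration object. Defaults emulate the structure
#' of a state-wide cardiovascular admissions cohort at desk scale: 30
#' hospitals over five remoteness regions, 5,000 patients with a mean of
#' ~4 admission episodes each, 65% same-day episodes, and outcome models
#' whose coefficients (on the odds-ratio / multiplier scale) encode the
#' study-size effect estimates the pipeline is expected to recover, e.g. a
#' HAC-to-death odds ratio of 2.54, a hospital-cost multiplier of 3.10 and
#' a length-of-stay multiplier of 2.93.
#'
#' @param seed integer seed; all generation is deterministic given it.
#' @param n_hospitals,n_patients positive integers.
#' @param mean_episodes_per_patient positive real; episodes per patient are
#'   `1 + Poisson(mean - 1)` before truncation at in-hospital death.
#' @param region_probs named length-5 probability vector over the
#'   remoteness levels (must sum to 1).
#' @param private_fraction probability a hospital is in the private sector.
#' @param bed_range integer vector `c(min, max)` of hospital bed counts.
#' @param same_day_fraction probability an episode is a same-day admission.
#' @param inefficiency_sigma scale of the latent hospital inefficiency
#'   `u_h = |Normal(0, sigma)|` added to the HAC log-odds.
#' @param hac_model_coeffs,death_model_coeffs,readmit_model_coeffs named
#'   log-odds vectors (see `hacbench:::DESIGN_TERMS`); `intercept = -Inf`
#'   is accepted as a "never" sentinel for the HAC model.
#' @param cost_model,los_model lists with `coeffs` (log-scale linear
#'   coefficients) and a positive dispersion parameter `shape` (Gamma
#'   shape for cost; negative-binomial size for the whole-day length of
#'   stay).
#' @param patient_mix,episode_mix lists of categorical mix probabilities
#'   (see defaults in the function body).
#' @param gap_model list: `p_long` geometric rate for gaps beyond the
#'   30-day readmission window.
#' @return object of class `hacbench_config`.
#' @export
generator_config <- function(
    seed = 42L,
    n_hospitals = 30L,
    n_patients = 5000L,
    mean_episodes_per_patient = 4,
    region_probs = c(major_city = 0.25, inner_regional = 0.25,
                     outer_regional = 0.25, remote = 0.15,
                     very_remote = 0.10),
    private_fraction = 0.2,
    bed_range = c(20L, 800L),
    same_day_fraction = 0.65,
    inefficiency_sigma = 0.5,
    hac_model_coeffs = default_model_coeffs("hac"),
    death_model_coeffs = default_model_coeffs("death"),
    readmit_model_coeffs = default_model_coeffs("readmit"),
    cost_model = list(coeffs = default_model_coeffs("cost"), shape = 2),
    los_model = list(coeffs = default_model_coeffs("los"), shape = 1.5),
    patient_mix = list(
      age_probs = c(0.08, 0.10, 0.17, 0.24, 0.26, 0.13, 0.02),
      sex_male_prob = 0.55,
      indigenous_prob = 0.05,
      seifa_probs = rep(0.2, 5),
      marital_probs = c(divorced_separated = 0.15, married = 0.55,
                        never_married = 0.10, widowed = 0.20),
      birth_probs = c(America = 0.02, Asia = 0.07, Europe = 0.15,
                      Oceania = 0.75, Africa = 0.01),
      insurance_prob = 0.30),
    episode_mix = list(
      icu_prob = 0.056,
      acute_prob = 0.868,
      comorbidity_probs = c("0" = 0.50, "1" = 0.25, "2+" = 0.25)),
    gap_model = list(p_long = 0.03)) {
  config <- structure(
    list(seed = as.integer(seed), n_hospitals = as.integer(n_hospitals),
         n_patients = as.integer(n_patients),
         mean_episodes_per_patient = mean_episodes_per_patient,
         region_probs = region_probs, private_fraction = private_fraction,
         bed_range = as.integer(bed_range),
         same_day_fraction = same_day_fraction,
         inefficiency_sigma = inefficiency_sigma,
         hac_model_coeffs = hac_model_coeffs,
         death_model_coeffs = death_model_coeffs,
         readmit_model_coeffs = readmit_model_coeffs,
         cost_model = cost_model, los_model = los_model,
         patient_mix = patient_mix, episode_mix = episode_mix,
         gap_model = gap_model),
    class = "hacbench_config")
  validate_generator_config(config)
  config
}

config_error <- function(field, why) {
  stop(structure(class = c("hacbench_config_error", "error", "condition"),
                 list(message = sprintf("invalid generator config: %s %s",
                                        field, why),
                      call = NULL)))
}

#' Validate a generator configuration
#'
#' @param config a `hacbench_config` object.
#' @return the config, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_generator_config <- function(config) {
  with(config, {
    if (length(seed) != 1 || is.na(seed))
      config_error("seed", "must be a single integer")
    if (n_hospitals < 1) config_error("n_hospitals", "must be >= 1")
    if (n_patients < 1) config_error("n_patients", "must be >= 1")
    if (mean_episodes_per_patient <= 0)
      config_error("mean_episodes_per_patient", "must be positive")
    if (length(region_probs) != 5 || any(region_probs < 0) ||
        any(region_probs > 1))
      config_error("region_probs", "must be 5 probabilities in [0,1]")
    if (abs(sum(region_probs) - 1) > 1e-9)
      config_error("region_probs", "must sum to 1")
    if (private_fraction < 0 || private_fraction > 1)
      config_error("private_fraction", "must be in [0,1]")
    if (length(bed_range) != 2 || bed_range[1] < 1 ||
        bed_range[2] < bed_range[1])
      config_error("bed_range", "must be (min >= 1, max >= min)")
    if (same_day_fraction < 0 || same_day_fraction > 1)
      config_error("same_day_fraction", "must be in [0,1]")
    if (inefficiency_sigma < 0)
      config_error("inefficiency_sigma", "must be >= 0")
    for (nm in c("hac_model_coeffs", "death_model_coeffs",
                 "readmit_model_coeffs")) {
      cf <- config[[nm]]
      if (!("intercept" %in% names(cf)))
        config_error(nm, "must contain an 'intercept' term")
      if (any(!is.finite(cf[names(cf) != "intercept"])))
        config_error(nm, "non-intercept terms must be finite")
    }
    for (nm in c("cost_model", "los_model")) {
      md <- config[[nm]]
      if (!is.list(md) || is.null(md$coeffs) || is.null(md$shape) ||
          md$shape <= 0)
        config_error(nm, "must be list(coeffs, shape > 0)")
    }
    if (gap_model$p_long <= 0 || gap_model$p_long > 1)
      config_error("gap_model$p_long", "must be in (0,1]")
  })
  invisible(config)
}

#' Replace all HAC covariate effects with a flat rate
#'
#' Utility for frontier rank-recovery experiments: keeps only the latent
#' hospital inefficiency as a source of between-hospital HAC variation by
#' zeroing every covariate effect and setting the intercept to
#' `qlogis(p)`.
#'
#' @param config a `hacbench_config`.
#' @param p marginal HAC probability at `u_h = 0`.
#' @return modified config.
#' @export
homogeneous_hac_config <- function(config, p = 0.093) {
  cf <- config$hac_model_coeffs
  cf[] <- 0
  cf["intercept"] <- stats::qlogis(p)
  config$hac_model_coeffs <- cf
  validate_generator_config(config)
  config
}

#' Evaluation-scale generator configuration
#'
#' The desk-scale default (5,000 patients) retains only a few thousand
#' overnight public-hospital episodes once the 65% same-day and the
#' private-sector exclusions are applied. For effect-recovery analyses the
#' package uses this larger configuration, sized so that roughly 20,000
#' episodes survive the exclusions.
#'
#' @param seed integer seed.
#' @param ... further overrides passed to [generator_config()].
#' @return a `hacbench_config`.
#' @export
study_scale_config <- function(seed = 42L, ...) {
  generator_config(seed = seed, n_patients = 22000L, ...)
}

#' Generate the hospital table
#'
#' @param config a validated `hacbench_config`.
#' @return data.frame with columns `hospital_id`, `sector`, `region`,
#'   `beds` and the hidden `latent_inefficiency` (exported separately by
#'   [export_truth()]; the analysis pipeline never reads it).
#' @export
generate_hospitals <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed + 1L)
  n <- config$n_hospitals
  data.frame(
    hospital_id = sprintf("H%02d", seq_len(n)),
    sector = ifelse(stats::runif(n) < config$private_fraction,
                    "private", "public"),
    region = factor(sample(REGION_LEVELS, n, replace = TRUE,
                           prob = config$region_probs),
                    levels = REGION_LEVELS),
    beds = sample(seq(config$bed_range[1], config$bed_range[2]), n,
                  replace = TRUE),
    latent_inefficiency = abs(stats::rnorm(n, 0, config$inefficiency_sigma)),
    stringsAsFactors = FALSE)
}

#' Generate the patient table
#'
#' @param config a validated `hacbench_config`.
#' @return data.frame of patient demographics (sex, indigenous status,
#'   7-level age band, SEIFA quintile, marital status, region of birth,
#'   private insurance flag).
#' @export
generate_patients <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed + 2L)
  n <- config$n_patients
  pm <- config$patient_mix
  data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    sex = ifelse(stats::runif(n) < pm$sex_male_prob, "male", "female"),
    indigenous = stats::runif(n) < pm$indigenous_prob,
    age_band = factor(sample(AGE_BANDS, n, replace = TRUE,
                             prob = pm$age_probs), levels = AGE_BANDS),
    seifa_quintile = sample(1:5, n, replace = TRUE, prob = pm$seifa_probs),
    marital_status = factor(sample(MARITAL_LEVELS, n, replace = TRUE,
                                   prob = pm$marital_probs),
                            levels = MARITAL_LEVELS),
    region_of_birth = factor(sample(BIRTH_LEVELS, n, replace = TRUE,
                                    prob = pm$birth_probs),
                             levels = BIRTH_LEVELS),
    insurance = stats::runif(n) < pm$insurance_prob,
    stringsAsFactors = FALSE)
}

# Model matrix over the shared design terms. `ep` must carry the episode
# covariates; returns matrix with an intercept column first.
episode_design <- function(ep, include_hac = FALSE) {
  X <- cbind(
    intercept = rep(1, nrow(ep)),
    sex_male = as.numeric(ep$sex == "male"),
    indigenous = as.numeric(ep$indigenous),
    age_45_54 = as.numeric(ep$age_band == "45-54"),
    age_55_64 = as.numeric(ep$age_band == "55-64"),
    age_65_74 = as.numeric(ep$age_band == "65-74"),
    age_75_84 = as.numeric(ep$age_band == "75-84"),
    age_85_94 = as.numeric(ep$age_band == "85-94"),
    age_95p = as.numeric(ep$age_band == "95+"),
    seifa_q2 = as.numeric(ep$seifa_quintile == 2),
    seifa_q3 = as.numeric(ep$seifa_quintile == 3),
    seifa_q4 = as.numeric(ep$seifa_quintile == 4),
    seifa_q5 = as.numeric(ep$seifa_quintile == 5),
    marital_married = as.numeric(ep$marital_status == "married"),
    marital_never_married = as.numeric(ep$marital_status == "never_married"),
    marital_widowed = as.numeric(ep$marital_status == "widowed"),
    birth_asia = as.numeric(ep$region_of_birth == "Asia"),
    birth_europe = as.numeric(ep$region_of_birth == "Europe"),
    birth_oceania = as.numeric(ep$region_of_birth == "Oceania"),
    birth_africa = as.numeric(ep$region_of_birth == "Africa"),
    insurance = as.numeric(ep$insurance),
    acute = as.numeric(ep$acute),
    icu = as.numeric(ep$icu),
    comorb_1 = as.numeric(ep$n_comorb_cat == "1"),
    comorb_2p = as.numeric(ep$n_comorb_cat == "2+"),
    region_inner_regional = as.numeric(ep$region == "inner_regional"),
    region_outer_regional = as.numeric(ep$region == "outer_regional"),
    region_remote = as.numeric(ep$region == "remote"),
    region_very_remote = as.numeric(ep$region == "very_remote"))
  if (include_hac) X <- cbind(X, hac = as.numeric(ep$hac))
  X
}

# Linear predictor for a named coefficient vector; terms absent from the
# coefficient vector contribute zero (so reduced models are allowed).
linear_predictor <- function(X, coeffs) {
  use <- intersect(colnames(X), names(coeffs))
  if (!("intercept" %in% use))
    stop("coefficient vector lacks an intercept term")
  drop(X[, use, drop = FALSE] %*% coeffs[use])
}

#' Generate admission episodes and their diagnosis lists
#'
#' Per patient, a planned number of episodes is generated sequentially in
#' time; an in-hospital death truncates the sequence. Each episode gets
#' admission/separation dates, same-day, acute and ICU flags, a diagnosis
#' list (principal cardiovascular diagnosis first, comorbidity codes drawn
#' from the Charlson reference map with onset flag 2, unmapped filler
#' codes, and — when the episode's HAC Bernoulli draw fires — one or two
#' HAC-group codes with condition-onset flag 1), and cost / length-of-stay
#' / death outcomes drawn conditional on the realised HAC indicator. The
#' next-admission gap is drawn from the 30-day readmission model so the
#' cohort builder can re-derive the readmission flag from dates.
#'
#' @param config a validated `hacbench_config`.
#' @param hospitals,patients tables from [generate_hospitals()] /
#'   [generate_patients()] under the same config.
#' @param hac_map,charlson_map code maps used as diagnosis-code pools;
#'   defaults are the shipped reference maps.
#' @return list with `episodes` (one row per episode) and `diagnoses`
#'   (long table: `episode_id`, `seq`, `icd10`, `cof`).
#' @export
generate_episodes <- function(config, hospitals, patients,
                              hac_map = load_hac_mapping(),
                              charlson_map = load_charlson_map()) {
  validate_generator_config(config)
  if (missing(hospitals) || is.null(hospitals) || nrow(hospitals) == 0)
    stop("hospitals table is missing or empty")
  if (missing(patients) || is.null(patients) || nrow(patients) == 0)
    stop("patients table is missing or empty")
  set.seed(config$seed + 3L)

  em <- config$episode_mix
  n_pat <- nrow(patients)
  n_ep_pat <- 1L + stats::rpois(n_pat,
                                max(config$mean_episodes_per_patient - 1, 0))
  idx_pat <- rep(seq_len(n_pat), n_ep_pat)
  n <- length(idx_pat)

  ep <- patients[idx_pat, , drop = FALSE]
  rownames(ep) <- NULL
  ep$ep_seq <- sequence(n_ep_pat)

  # Hospital assignment proportional to bed capacity.
  h_idx <- sample(nrow(hospitals), n, replace = TRUE, prob = hospitals$beds)
  ep$hospital_id <- hospitals$hospital_id[h_idx]
  ep$region <- hospitals$region[h_idx]
  u_h <- hospitals$latent_inefficiency[h_idx]

  ep$same_day <- stats::runif(n) < config$same_day_fraction
  ep$icu <- stats::runif(n) < em$icu_prob
  ep$acute <- stats::runif(n) < em$acute_prob
  ep$n_comorb_cat <- factor(sample(COMORB_LEVELS, n, replace = TRUE,
                                   prob = em$comorbidity_probs),
                            levels = COMORB_LEVELS)

  X <- episode_design(ep)
  p_hac <- stats::plogis(linear_predictor(X, config$hac_model_coeffs) + u_h)
  ep$hac_true <- stats::runif(n) < p_hac

  Xh <- cbind(X, hac = as.numeric(ep$hac_true))
  ep$died_in_hospital <-
    stats::runif(n) < stats::plogis(linear_predictor(Xh,
                                                     config$death_model_coeffs))

  mu_cost <- exp(linear_predictor(Xh, config$cost_model$coeffs))
  sh_c <- config$cost_model$shape
  ep$cost <- stats::rgamma(n, shape = sh_c, rate = sh_c / mu_cost)
  mu_los <- exp(linear_predictor(Xh, config$los_model$coeffs))
  sh_l <- config$los_model$shape
  # Overnight stays are whole days >= 1: 1 + NegBin with mean exp(lp) - 1,
  # so the conditional mean equals exp(lp) exactly and the log-link
  # multiplier stays recoverable. Same-day episodes have LOS 0.
  los_int <- 1L + stats::rnbinom(n, size = sh_l,
                                 mu = pmax(mu_los - 1, 1e-6))
  ep$los <- ifelse(ep$same_day, 0L, los_int)

  # Truncate each patient's sequence at the first in-hospital death.
  deaths_before <- stats::ave(as.numeric(ep$died_in_hospital), idx_pat,
                              FUN = function(v) cumsum(c(0, v[-length(v)])))
  keep <- deaths_before == 0
  ep <- ep[keep, , drop = FALSE]
  idx_pat <- idx_pat[keep]
  n <- nrow(ep)

  # Next-admission gap from the 30-day readmission model: with probability
  # plogis(lp) the next admission starts within the 30-day window.
  Xk <- episode_design(ep)
  Xk <- cbind(Xk, hac = as.numeric(ep$hac_true))
  p_re <- stats::plogis(linear_predictor(Xk, config$readmit_model_coeffs))
  readmit_planned <- stats::runif(n) < p_re
  gap <- ifelse(readmit_planned,
                sample(0:30, n, replace = TRUE),
                31L + stats::rgeom(n, config$gap_model$p_long))

  # Admission date = patient entry (in 2010) + cumulated (los + gap) of
  # prior episodes.
  entry_offset <- sample(0:364, n_pat, replace = TRUE)
  dur <- ep$los + gap
  offset <- stats::ave(dur, idx_pat,
                       FUN = function(v) cumsum(c(0, v[-length(v)])))
  ep$admit_date <- as.Date("2010-01-01") + entry_offset[idx_pat] + offset
  ep$separation_date <- ep$admit_date + ep$los

  ep$episode_id <- sprintf("E%07d", seq_len(n))

  diagnoses <- generate_diagnoses(config, ep, hac_map, charlson_map)

  episodes <- data.frame(
    episode_id = ep$episode_id,
    patient_id = ep$patient_id,
    hospital_id = ep$hospital_id,
    admit_date = ep$admit_date,
    separation_date = ep$separation_date,
    same_day = ep$same_day,
    acute = ep$acute,
    icu = ep$icu,
    died_in_hospital = ep$died_in_hospital,
    cost = ep$cost,
    los = ep$los,
    sex = ep$sex,
    indigenous = ep$indigenous,
    age_band = ep$age_band,
    seifa_quintile = ep$seifa_quintile,
    marital_status = ep$marital_status,
    region_of_birth = ep$region_of_birth,
    insurance = ep$insurance,
    region = ep$region,
    stringsAsFactors = FALSE)
  list(episodes = episodes, diagnoses = diagnoses)
}

# Principal cardiovascular diagnoses and filler codes that map to neither
# the HAC groups nor the Charlson conditions.
PRINCIPAL_POOL <- c("I10", "I200", "I214", "I251", "I350", "I480", "I639",
                    "I700")
FILLER_POOL <- c("R05", "R509", "M545", "Z501", "K219", "J069", "E119",
                 "R42")

generate_diagnoses <- function(config, ep, hac_map, charlson_map) {
  n <- nrow(ep)
  # principal diagnosis, present on admission
  principal <- data.frame(
    episode_id = ep$episode_id,
    icd10 = sample(PRINCIPAL_POOL, n, replace = TRUE),
    cof = 2L, block = 1L, stringsAsFactors = FALSE)

  # comorbidity codes matching the generated burden category
  conds <- charlson_map$entries
  cond_names <- unique(conds$condition)
  partner <- stats::setNames(rep(NA_character_, length(cond_names)),
                             cond_names)
  if (nrow(charlson_map$hierarchy) > 0) {
    partner[charlson_map$hierarchy$mild] <- charlson_map$hierarchy$severe
    partner[charlson_map$hierarchy$severe] <- charlson_map$hierarchy$mild
  }
  n_com <- c("0" = 0L, "1" = 1L, "2+" = 2L)[as.character(ep$n_comorb_cat)]
  com_rows <- NULL
  any_com <- which(n_com >= 1L)
  if (length(any_com) > 0) {
    c1 <- sample(cond_names, length(any_com), replace = TRUE)
    com_rows <- data.frame(
      episode_id = ep$episode_id[any_com],
      icd10 = cond_code(c1, conds), cof = 2L, block = 2L,
      stringsAsFactors = FALSE)
    two <- which(n_com == 2L)
    if (length(two) > 0) {
      first <- c1[match(two, any_com)]
      c2 <- sample(cond_names, length(two), replace = TRUE)
      is_bad <- function(c2) c2 == first |
        (!is.na(partner[first]) & c2 == partner[first])
      bad <- is_bad(c2)
      while (any(bad)) {  # avoid duplicates and hierarchy pairs
        c2[bad] <- sample(cond_names, sum(bad), replace = TRUE)
        bad <- is_bad(c2)
      }
      com_rows <- rbind(com_rows, data.frame(
        episode_id = ep$episode_id[two],
        icd10 = cond_code(c2, conds), cof = 2L, block = 2L,
        stringsAsFactors = FALSE))
    }
  }

  # unmapped filler codes
  n_fill <- pmin(stats::rpois(n, 0.7), 2L)
  fill_idx <- rep(seq_len(n), n_fill)
  fill_rows <- if (length(fill_idx) > 0) data.frame(
    episode_id = ep$episode_id[fill_idx],
    icd10 = sample(FILLER_POOL, length(fill_idx), replace = TRUE),
    cof = sample(c(2L, 9L), length(fill_idx), replace = TRUE,
                 prob = c(0.7, 0.3)),
    block = 3L, stringsAsFactors = FALSE) else NULL

  # HAC codes, onset during the episode (COF = 1)
  inc <- hac_map$entries[!(hac_map$entries$hac_group_id %in%
                             hac_map$excluded_groups), , drop = FALSE]
  hac_idx <- which(ep$hac_true)
  hac_rows <- NULL
  if (length(hac_idx) > 0) {
    n_groups <- 1L + (stats::runif(length(hac_idx)) < 0.2)
    gi <- rep(hac_idx, n_groups)
    rows <- sample(nrow(inc), length(gi), replace = TRUE)
    hac_rows <- data.frame(
      episode_id = ep$episode_id[gi],
      icd10 = inc$code_prefix[rows],
      cof = 1L, block = 4L, stringsAsFactors = FALSE)
  }

  out <- rbind(principal, com_rows, fill_rows, hac_rows)
  out <- out[order(out$episode_id, out$block), , drop = FALSE]
  out$seq <- stats::ave(rep(1L, nrow(out)), out$episode_id, FUN = cumsum)
  rownames(out) <- NULL
  out[, c("episode_id", "seq", "icd10", "cof")]
}

# Representative full code for a Charlson condition: its first prefix,
# padded to look like a complete code.
cond_code <- function(condition, entries) {
  first <- entries[!duplicated(entries$condition), , drop = FALSE]
  pref <- first$code_prefix[match(condition, first$condition)]
  ifelse(nchar(pref) >= 4, pref, paste0(pref, "9"))
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper chaining [generate_hospitals()],
#' [generate_patients()] and [generate_episodes()].
#'
#' @inheritParams generate_episodes
#' @return list with `hospitals`, `patients`, `episodes`, `diagnoses` and
#'   the `config` used.
#' @export
generate_cohort <- function(config = generator_config(),
                            hac_map = load_hac_mapping(),
                            charlson_map = load_charlson_map()) {
  hospitals <- generate_hospitals(config)
  patients <- generate_patients(config)
  eps <- generate_episodes(config, hospitals, patients, hac_map, charlson_map)
  list(hospitals = hospitals, patients = patients,
       episodes = eps$episodes, diagnoses = eps$diagnoses, config = config)
}

#' Export the generator's hidden truth
#'
#' Writes the generating coefficients and the latent hospital inefficiency
#' ranking to JSON for recovery tests. The analysis pipeline itself never
#' reads this file.
#'
#' @param config the generating `hacbench_config`.
#' @param hospitals the generated hospital table.
#' @param path output path (JSON).
#' @return the truth list, invisibly.
#' @export
export_truth <- function(config, hospitals, path) {
  truth <- list(
    seed = config$seed,
    inefficiency_sigma = config$inefficiency_sigma,
    hac_model_coeffs = as.list(config$hac_model_coeffs),
    death_model_coeffs = as.list(config$death_model_coeffs),
    readmit_model_coeffs = as.list(config$readmit_model_coeffs),
    cost_model = list(coeffs = as.list(config$cost_model$coeffs),
                      shape = config$cost_model$shape),
    los_model = list(coeffs = as.list(config$los_model$coeffs),
                     shape = config$los_model$shape),
    hospital_inefficiency = data.frame(
      hospital_id = hospitals$hospital_id,
      latent_inefficiency = hospitals$latent_inefficiency,
      rank = rank(-hospitals$latent_inefficiency, ties.method = "min")))
  if (!missing(path)) {
    jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(truth)
}
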