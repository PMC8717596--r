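# Shared fixtures: tiny hand-built tables plus the shipped reference maps.

ref_hac_map <- load_hac_mapping()
ref_charlson <- load_charlson_map()

tiny_hospitals <- function(n = 3, sector = rep("public", n),
                           region = rep("major_city", n),
                           beds = rep(100L, n)) {
  data.frame(hospital_id = sprintf("H%02d", seq_len(n)), sector = sector,
             region = factor(region, levels = hacbench:::REGION_LEVELS),
             beds = beds, latent_inefficiency = 0,
             stringsAsFactors = FALSE)
}

tiny_episodes <- function(patient_id, hospital_id = "H01",
                          admit, sep = admit,
                          same_day = admit == sep,
                          died = FALSE) {
  n <- length(patient_id)
  data.frame(
    episode_id = sprintf("E%03d", seq_len(n)),
    patient_id = patient_id,
    hospital_id = rep_len(hospital_id, n),
    admit_date = as.Date(admit),
    separation_date = as.Date(sep),
    same_day = rep_len(same_day, n),
    died_in_hospital = rep_len(died, n),
    stringsAsFactors = FALSE)
}

# single-episode diagnosis table
diag_rows <- function(codes, cof, seq = seq_along(codes),
                      episode_id = "E001") {
  data.frame(episode_id = episode_id, seq = seq, icd10 = codes, cof = cof,
             stringsAsFactors = FALSE)
}

# hospital aggregates frame straight from numbers (for DEA tests)
make_dea_frame <- function(ids, beds, simplicity, safety, group = "all") {
  data.frame(dmu_id = ids, group = rep_len(group, length(ids)),
             beds = beds, simplicity = simplicity, safety_rate = safety,
             stringsAsFactors = FALSE)
}

# small generated cohort shared by several test files (desk scale)
small_cohort <- local({
  cfg <- generator_config(seed = 11L, n_patients = 800L)
  co <- generate_cohort(cfg, ref_hac_map, ref_charlson)
  ex <- apply_exclusions(co$episodes, co$hospitals)
  eps <- derive_readmission(ex$episodes)
  fl <- flag_cohort(eps, co$diagnoses, ref_hac_map)
  eps <- score_comorbidities(fl$episodes, co$diagnoses, ref_charlson)
  list(config = cfg, hospitals = co$hospitals, patients = co$patients,
       raw_episodes = co$episodes, diagnoses = co$diagnoses,
       episodes = eps, summary = ex$summary, group_freq = fl$group_freq)
})
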