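test_that("generation is bit-identical under a fixed seed", {
  cfg <- generator_config(seed = 1L, n_hospitals = 30L, n_patients = 300L)
  a <- generate_cohort(cfg, ref_hac_map, ref_charlson)
  b <- generate_cohort(cfg, ref_hac_map, ref_charlson)
  expect_identical(a$hospitals, b$hospitals)
  expect_identical(a$patients, b$patients)
  expect_identical(a$episodes, b$episodes)
  expect_identical(a$diagnoses, b$diagnoses)
})

test_that("degenerate configurations behave as specified", {
  cfg0 <- generator_config(seed = 2L, inefficiency_sigma = 0)
  expect_true(all(generate_hospitals(cfg0)$latent_inefficiency == 0))

  cfg1 <- generator_config(seed = 3L,
                           region_probs = c(major_city = 1, inner_regional = 0,
                                            outer_regional = 0, remote = 0,
                                            very_remote = 0))
  expect_true(all(generate_hospitals(cfg1)$region == "major_city"))

  # "never" sentinel: no HAC codes anywhere
  cfg <- generator_config(seed = 4L, n_patients = 300L)
  cfg$hac_model_coeffs["intercept"] <- -Inf
  co <- generate_cohort(cfg, ref_hac_map, ref_charlson)
  fl <- flag_cohort(co$episodes, co$diagnoses, ref_hac_map)
  expect_false(any(fl$episodes$hac))
  expect_false(any(co$diagnoses$cof == 1))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(generator_config(n_hospitals = 0), "n_hospitals")
  expect_error(generator_config(inefficiency_sigma = -1),
               "inefficiency_sigma")
  expect_error(generator_config(region_probs = c(0.5, 0.5, 0.2, 0, 0)),
               "region_probs")
  expect_error(generator_config(bed_range = c(0L, 10L)), "bed_range")
  expect_error(generator_config(same_day_fraction = 1.2),
               "same_day_fraction")
})

test_that("episode structure matches the admission rules", {
  co <- small_cohort
  eps <- co$raw_episodes
  expect_true(all(eps$separation_date >= eps$admit_date))
  expect_identical(eps$same_day, eps$separation_date == eps$admit_date)
  expect_true(all(eps$los[!eps$same_day] >= 1))
  expect_true(all(eps$los[eps$same_day] == 0))
  expect_true(all(eps$cost > 0))
  # death truncates the patient's sequence: a death episode is always the
  # patient's last by admission date
  last_by_pat <- tapply(seq_len(nrow(eps)), eps$patient_id, function(i)
    i[which.max(as.numeric(eps$admit_date[i]))])
  died_rows <- which(eps$died_in_hospital)
  expect_true(all(died_rows %in% unlist(last_by_pat)))
})

test_that("designed marginal HAC rate is recovered with flat covariates", {
  p <- 0.12
  cfg <- homogeneous_hac_config(
    generator_config(seed = 5L, n_patients = 3000L,
                     inefficiency_sigma = 0), p = p)
  co <- generate_cohort(cfg, ref_hac_map, ref_charlson)
  fl <- flag_cohort(co$episodes, co$diagnoses, ref_hac_map)
  n <- nrow(fl$episodes)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(fl$episodes$hac) - p), 3 * se)
})

test_that("larger inefficiency scale increases between-hospital HAC variance", {
  rate_var <- function(sigma, seed) {
    cfg <- homogeneous_hac_config(
      generator_config(seed = seed, n_patients = 4000L,
                       inefficiency_sigma = sigma, private_fraction = 0))
    co <- generate_cohort(cfg, ref_hac_map, ref_charlson)
    fl <- flag_cohort(co$episodes, co$diagnoses, ref_hac_map)
    rates <- tapply(fl$episodes$hac, fl$episodes$hospital_id, mean)
    stats::var(rates)
  }
  expect_gt(rate_var(1.0, 6L), rate_var(0.05, 6L))
})

test_that("exported truth round-trips the generating parameters", {
  cfg <- generator_config(seed = 7L, n_patients = 50L)
  h <- generate_hospitals(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  truth <- export_truth(cfg, h, path)
  on_disk <- jsonlite::read_json(path)
  expect_setequal(names(on_disk$hac_model_coeffs),
                  names(cfg$hac_model_coeffs))
  expect_equal(unlist(on_disk$hac_model_coeffs),
               unlist(as.list(cfg$hac_model_coeffs)), tolerance = 1e-12)
  ranking <- do.call(rbind, lapply(on_disk$hospital_inefficiency,
                                   as.data.frame))
  expect_identical(ranking$hospital_id, h$hospital_id)
  expect_equal(ranking$latent_inefficiency, h$latent_inefficiency,
               tolerance = 1e-12)
  # hidden truth never flows into the pipeline inputs
  expect_false("latent_inefficiency" %in%
                 names(small_cohort$episodes))
})
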