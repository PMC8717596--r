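test_that("exclusions count and filter in the documented order", {
  h <- tiny_hospitals(2, sector = c("public", "private"))
  ep <- tiny_episodes(patient_id = sprintf("P%d", 1:10),
                      hospital_id = "H01",
                      admit = as.Date("2010-01-01") + 0:9,
                      sep = as.Date("2010-01-01") + 0:9 + rep(c(0, 1), 5))
  # 5 same-day (even offsets), none private
  res <- apply_exclusions(ep, h)
  s <- res$summary
  expect_equal(s$n_episodes_raw, 10)
  expect_equal(s$n_excluded_same_day, 5)
  expect_equal(s$n_excluded_private, 0)
  expect_equal(s$n_episodes_final, 5)
  expect_false(any(res$episodes$same_day))

  # all private -> empty cohort allowed
  ep2 <- ep
  ep2$hospital_id <- "H02"
  ep2$same_day <- FALSE
  ep2$separation_date <- ep2$admit_date + 1
  res2 <- apply_exclusions(ep2, h)
  expect_equal(res2$summary$n_episodes_final, 0)
  expect_equal(nrow(res2$episodes), 0)

  # referential integrity
  ep3 <- ep
  ep3$hospital_id[1] <- "H99"
  expect_error(apply_exclusions(ep3, h), "H99")
})

test_that("exclusion is idempotent and conserves counts", {
  co <- small_cohort
  once <- apply_exclusions(co$raw_episodes, co$hospitals)
  twice <- apply_exclusions(once$episodes, co$hospitals)
  expect_identical(once$episodes, twice$episodes)
  expect_equal(twice$summary$n_excluded_same_day, 0)
  expect_equal(twice$summary$n_excluded_private, 0)
  s <- once$summary
  expect_equal(s$n_episodes_raw,
               s$n_episodes_final + s$n_excluded_same_day +
                 s$n_excluded_private)
})

test_that("same-day exclusion fraction matches the design rate", {
  co <- small_cohort
  s <- apply_exclusions(co$raw_episodes, co$hospitals)$summary
  p <- co$config$same_day_fraction
  frac <- s$n_excluded_same_day / s$n_episodes_raw
  se <- sqrt(p * (1 - p) / s$n_episodes_raw)
  expect_lt(abs(frac - p), 3 * se)
})

test_that("30-day readmission window is inclusive and from discharge", {
  ep <- tiny_episodes(patient_id = c("P1", "P1", "P2", "P2", "P3"),
                      admit = c("2010-01-01", "2010-01-31",
                                "2010-01-01", "2010-02-01",
                                "2010-01-01"),
                      sep = c("2010-01-01", "2010-02-05",
                              "2010-01-01", "2010-02-02",
                              "2010-01-02"),
                      same_day = FALSE)
  out <- derive_readmission(ep)
  # P1: gap separation Jan 1 -> admit Jan 31 = 30 days, inclusive
  expect_true(out$readmit30[1])
  # P2: gap Jan 1 -> Feb 1 = 31 days
  expect_false(out$readmit30[3])
  # single-episode patient
  expect_false(out$readmit30[5])
  # last episodes have no successor
  expect_false(out$readmit30[2])
  expect_false(out$readmit30[4])

  # same-day gap counts (admission on the discharge day itself)
  ep0 <- tiny_episodes(patient_id = c("P1", "P1"),
                       admit = c("2010-01-01", "2010-01-05"),
                       sep = c("2010-01-05", "2010-01-07"),
                       same_day = FALSE)
  expect_true(derive_readmission(ep0)$readmit30[1])
})

test_that("readmission derivation is invariant to row order", {
  co <- small_cohort
  ex <- apply_exclusions(co$raw_episodes, co$hospitals)$episodes
  a <- derive_readmission(ex)
  set.seed(1)
  perm <- sample(nrow(ex))
  b <- derive_readmission(ex[perm, , drop = FALSE])
  expect_equal(a$readmit30[perm], b$readmit30)
})

test_that("overlapping episodes trigger a warning but still compute", {
  ep <- tiny_episodes(patient_id = c("P1", "P1"),
                      admit = c("2010-01-01", "2010-01-03"),
                      sep = c("2010-01-10", "2010-01-05"),
                      same_day = FALSE)
  expect_warning(out <- derive_readmission(ep), "overlap")
  expect_type(out$readmit30, "logical")
})

test_that("cohort summary reports prevalence and guards pipeline order", {
  ep <- tiny_episodes(patient_id = sprintf("P%d", 1:8),
                      admit = "2010-01-01", sep = "2010-01-02",
                      same_day = FALSE)
  expect_error(summarize_cohort(ep), "hac")
  ep$hac <- c(TRUE, rep(FALSE, 7))
  s <- summarize_cohort(ep)
  expect_equal(s$hac_prevalence, 1 / 8)
  expect_equal(s$hac_prevalence_pct_display, 12.5)
  ep$hac <- FALSE
  expect_equal(summarize_cohort(ep)$hac_prevalence_pct_display, 0)
})
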