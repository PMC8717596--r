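test_that("shipped reference mapping loads with 13 included groups", {
  m <- ref_hac_map
  included <- setdiff(unique(m$entries$hac_group_id), m$excluded_groups)
  expect_length(included, 13)
  expect_setequal(included, setdiff(1:16, c(5, 15, 16)))
  # every included group carries at least 3 representative codes
  tab <- table(m$entries$hac_group_id[!(m$entries$hac_group_id %in%
                                          m$excluded_groups)])
  expect_true(all(tab >= 3))
})

test_that("malformed mappings are rejected at load", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("code_prefix,hac_group_id,group_name", "X10,17,Bogus"), f)
  expect_error(load_hac_mapping(f), "1..16")

  writeLines("code_prefix,hac_group_id,group_name", f)
  expect_error(load_hac_mapping(f), "empty")

  writeLines(c("code_prefix,hac_group_id,group_name",
               "T814,3,Healthcare-associated infection",
               "T814,4,Surgical complications"), f)
  expect_error(load_hac_mapping(f), "duplicate")
})

test_that("classification applies the COF, position and exclusion gates", {
  m <- ref_hac_map
  # subsequent diagnosis, COF 1, maps to an included group
  r <- classify_episode(diag_rows(c("I214", "T814"), cof = c(2, 1)), m)
  expect_true(r$hac)
  expect_equal(r$hac_groups, 3L)
  # same code with COF 2: not hospital-acquired
  r2 <- classify_episode(diag_rows(c("I214", "T814"), cof = c(2, 2)), m)
  expect_false(r2$hac)
  # excluded maternity group never fires
  r3 <- classify_episode(diag_rows(c("I214", "O702"), cof = c(2, 1)), m)
  expect_false(r3$hac)
  expect_length(r3$hac_groups, 0)
  # principal diagnosis never triggers, even with COF 1
  r4 <- classify_episode(diag_rows(c("T814", "I214"), cof = c(1, 2)), m)
  expect_false(r4$hac)
  # unmapped code is silently non-contributing
  r5 <- classify_episode(diag_rows(c("I214", "Z999"), cof = c(2, 1)), m)
  expect_false(r5$hac)
})

test_that("codes are matched case-insensitively with dots stripped", {
  m <- ref_hac_map
  r <- classify_episode(diag_rows(c("I21.4", "t81.4"), cof = c(2, 1)), m)
  expect_equal(r$hac_groups, 3L)
})

test_that("longest prefix wins when entries nest", {
  m <- ref_hac_map
  # T81 -> group 4 umbrella, T814 -> group 3; code T814 takes the longer
  r <- classify_episode(diag_rows(c("I10", "T814"), cof = c(2, 1)), m)
  expect_equal(r$hac_groups, 3L)
  # T813 only matches the T81 umbrella
  r2 <- classify_episode(diag_rows(c("I10", "T813"), cof = c(2, 1)), m)
  expect_equal(r2$hac_groups, 4L)
})

test_that("flag_cohort separates episode and group-count semantics", {
  d <- rbind(diag_rows(c("I10", "N170", "K920"), cof = c(2, 1, 1),
                       episode_id = "E001"),
             diag_rows(c("I10"), cof = 2, episode_id = "E002"))
  eps <- data.frame(episode_id = c("E001", "E002"),
                    stringsAsFactors = FALSE)
  out <- flag_cohort(eps, d, ref_hac_map)
  expect_equal(out$episodes$hac, c(TRUE, FALSE))
  expect_equal(out$episodes$hac_groups, c("8,9", ""))
  gf <- out$group_freq
  # one episode, two groups: counted once per group, once in prevalence
  expect_equal(gf$n_episodes[gf$hac_group_id == 8], 1L)
  expect_equal(gf$n_episodes[gf$hac_group_id == 9], 1L)
  expect_equal(sum(out$episodes$hac), 1)
})

test_that("classification is invariant to diagnosis row order within seq", {
  co <- small_cohort
  d <- co$diagnoses
  set.seed(2)
  perm <- sample(nrow(d))
  a <- flag_cohort(co$episodes[, c("episode_id", "patient_id")], d,
                   ref_hac_map)
  b <- flag_cohort(co$episodes[, c("episode_id", "patient_id")],
                   d[perm, , drop = FALSE], ref_hac_map)
  expect_equal(a$episodes$hac, b$episodes$hac)
  expect_equal(a$episodes$hac_groups, b$episodes$hac_groups)
  expect_equal(a$group_freq, b$group_freq)
})

test_that("adding a mapping entry never removes a call (monotonicity)", {
  m <- ref_hac_map
  d <- rbind(diag_rows(c("I10", "N170", "Q999"), cof = c(2, 1, 1),
                       episode_id = "E001"))
  base <- classify_episode(d, m)
  m2 <- m
  m2$entries <- rbind(m2$entries,
                      data.frame(code_prefix = "Q999", hac_group_id = 6L,
                                 group_name = "Respiratory complications",
                                 stringsAsFactors = FALSE))
  more <- classify_episode(d, m2)
  expect_true(all(base$hac_groups %in% more$hac_groups))
  expect_setequal(more$hac_groups, c(6L, 8L))
})

test_that("excluded groups never surface regardless of mapping content", {
  m <- ref_hac_map
  m$excluded_groups <- c(5L, 15L, 16L, 8L)  # exclude renal failure too
  r <- classify_episode(diag_rows(c("I10", "N170"), cof = c(2, 1)), m)
  expect_false(r$hac)
})
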