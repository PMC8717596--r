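test_that("a unit alone on its frontier is self-efficient", {
  for (rts in c("crs", "vrs")) {
    r <- solve_output_oriented(c(3, 0.5), 90, matrix(c(3, 0.5)),
                               matrix(90), rts = rts,
                               frontier_ids = "A")
    expect_equal(r$phi, 1, tolerance = 1e-9)
    expect_equal(r$te, 1, tolerance = 1e-9)
    expect_equal(unname(r$lambda), 1, tolerance = 1e-9)
    expect_true(r$is_efficient)
  }
})

test_that("CRS single-ratio analytic oracle holds", {
  # A(x=2,y=4), B(x=4,y=4): te(B) = (y_B/x_B)/max_j(y_j/x_j) = 0.5
  X <- matrix(c(2, 4), 1)
  Y <- matrix(c(4, 4), 1)
  r <- solve_output_oriented(4, 4, X, Y, rts = "crs",
                             frontier_ids = c("A", "B"))
  expect_equal(r$te, 0.5, tolerance = 1e-9)
  expect_equal(r$peers, "A")
  # and in general for random 1-in/1-out CRS instances
  set.seed(10)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    x <- runif(n, 1, 10); y <- runif(n, 1, 10)
    j <- sample(n, 1)
    te_an <- (y[j] / x[j]) / max(y / x)
    r <- solve_output_oriented(x[j], y[j], matrix(x, 1), matrix(y, 1),
                               rts = "crs")
    expect_equal(r$te, te_an, tolerance = 1e-9)
  }
})

test_that("dominated units are inefficient; domination is detected", {
  d <- make_dea_frame(c("A", "B"), beds = c(100, 120),
                      simplicity = c(0.5, 0.5), safety = c(95, 90))
  xy <- list(X = rbind(d$beds, d$simplicity), Y = rbind(d$safety_rate))
  for (rts in c("crs", "vrs")) {
    r <- solve_output_oriented(c(120, 0.5), 90, xy$X, xy$Y, rts = rts,
                               frontier_ids = d$dmu_id)
    expect_lt(r$te, 1)
    expect_equal(r$peers, "A")
  }
})

test_that("envelopment and multiplier forms agree (duality)", {
  set.seed(20)
  worst <- 0
  for (i in 1:40) {
    n <- sample(2:10, 1); m <- sample(1:3, 1)
    X <- matrix(runif(m * n, 1, 10), m, n)
    Y <- matrix(runif(n, 1, 10), 1, n)
    j <- sample(n, 1)
    rts <- sample(c("crs", "vrs"), 1)
    env <- solve_output_oriented(X[, j], Y[, j], X, Y, rts = rts)
    dua <- solve_output_oriented_dual(X[, j], Y[, j], X, Y, rts = rts)
    worst <- max(worst, abs(env$te - dua$te))
  }
  expect_lt(worst, 1e-7)
})

test_that("projections dominate the observed bundle and peers are efficient", {
  set.seed(21)
  n <- 12
  d <- make_dea_frame(sprintf("D%02d", 1:n), beds = runif(n, 50, 500),
                      simplicity = runif(n, 0.3, 0.9),
                      safety = runif(n, 80, 99))
  res <- score_frontiers(d, rts = "vrs")
  sc <- res$scores[res$scores$frontier == "meta", ]
  expect_true(all(sc$te > 0 & sc$te <= 1 + 1e-9))
  expect_true(any(sc$is_efficient))  # at least one unit spans the frontier
  expect_true(all(sc$target_safety >= d$safety_rate[
    match(sc$dmu_id, d$dmu_id)] - 1e-7))
  expect_true(all(sc$target_beds <= d$beds[match(sc$dmu_id, d$dmu_id)] +
                    1e-7))
  expect_true(all(sc$target_simplicity <=
                    d$simplicity[match(sc$dmu_id, d$dmu_id)] + 1e-7))
  # peers of any unit are themselves efficient units
  pe <- res$peers[res$peers$frontier == "meta", ]
  eff <- sc$dmu_id[sc$is_efficient]
  expect_true(all(pe$peer_id %in% eff))
  # VRS: intensity weights sum to one
  sums <- tapply(pe$lambda, pe$dmu_id, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("group scores never beat the pooled meta frontier", {
  set.seed(22)
  n <- 15
  d <- make_dea_frame(sprintf("D%02d", 1:n), beds = runif(n, 50, 500),
                      simplicity = runif(n, 0.3, 0.9),
                      safety = runif(n, 80, 99),
                      group = sample(c("g1", "g2", "g3"), n,
                                     replace = TRUE))
  for (rts in c("crs", "vrs")) {
    res <- score_frontiers(d, rts = rts)
    expect_true(all(res$comparison$te_meta <=
                      res$comparison$te_group + 1e-7))
    expect_true(all(res$comparison$metatechnology_ratio <= 1 + 1e-7))
  }
  # single region: the two frontiers coincide
  d1 <- d; d1$group <- "all"
  res1 <- score_frontiers(d1, rts = "vrs")
  expect_equal(res1$comparison$te_group, res1$comparison$te_meta,
               tolerance = 1e-9)
})

test_that("CRS efficiency is invariant to rescaling an input column", {
  set.seed(23)
  n <- 8
  d <- make_dea_frame(sprintf("D%02d", 1:n), beds = runif(n, 50, 500),
                      simplicity = runif(n, 0.3, 0.9),
                      safety = runif(n, 80, 99))
  r1 <- score_frontiers(d, rts = "crs")
  d2 <- d; d2$beds <- d2$beds * 1000
  r2 <- score_frontiers(d2, rts = "crs")
  expect_equal(r1$scores$te, r2$scores$te, tolerance = 1e-9)
})

test_that("adding a dominated unit leaves the others' scores unchanged", {
  set.seed(24)
  n <- 7
  d <- make_dea_frame(sprintf("D%02d", 1:n), beds = runif(n, 50, 500),
                      simplicity = runif(n, 0.3, 0.9),
                      safety = runif(n, 80, 99))
  r1 <- score_frontiers(d, rts = "vrs")
  dom <- data.frame(dmu_id = "DOM", group = "all",
                    beds = max(d$beds) + 10,
                    simplicity = max(d$simplicity),
                    safety_rate = min(d$safety_rate) - 1,
                    stringsAsFactors = FALSE)
  r2 <- score_frontiers(rbind(d, dom), rts = "vrs")
  old <- r2$scores[r2$scores$dmu_id != "DOM", ]
  old <- old[order(old$dmu_id, old$frontier), ]
  new <- r1$scores[order(r1$scores$dmu_id, r1$scores$frontier), ]
  expect_equal(old$te, new$te, tolerance = 1e-9)
})

test_that("bootstrap interval behaves at the edges and validates inputs", {
  expect_error(bootstrap_ci(c(0.5, 1), B = 1), "B >= 2")
  expect_error(bootstrap_ci(c(0.5, 1), alpha = 1), "alpha")
  ci <- bootstrap_ci(rep(0.8, 6), B = 200, seed = 1)
  expect_equal(ci, c(0.8, 0.8))
  ci2 <- bootstrap_ci(c(0.5, 1.0), B = 500, seed = 2)
  expect_true(ci2[1] >= 0.5 && ci2[2] <= 1.0)
  expect_warning(ci3 <- bootstrap_ci(0.7, B = 10, seed = 3), "single")
  expect_equal(ci3, c(0.7, 0.7))
  # reproducible under a fixed seed
  scores <- seq(0.5, 0.95, length.out = 10)
  expect_identical(bootstrap_ci(scores, B = 300, seed = 7),
                   bootstrap_ci(scores, B = 300, seed = 7))
})

test_that("group means reduce correctly in degenerate cases", {
  sc <- data.frame(dmu_id = c("A", "B", "C"), region = c("r1", "r1", "r2"),
                   frontier = "group", te = c(1, 1, 1),
                   stringsAsFactors = FALSE)
  gm <- suppressWarnings(group_mean_scores(sc, B = 50, seed = 1))
  expect_true(all(gm$mean_te_pct == 100))
  expect_true(all(gm$ci_low_pct == 100 & gm$ci_high_pct == 100))
  # uniform weights equal to episode counts reduce to the unweighted mean
  sc$te <- c(0.5, 0.7, 0.9)
  w_uni <- stats::setNames(c(3, 3, 3), sc$dmu_id)
  gm2 <- suppressWarnings(group_mean_scores(sc, w_uni, B = 50, seed = 1))
  expect_equal(gm2$mean_te_pct[gm2$region == "average"],
               100 * mean(sc$te))
})
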