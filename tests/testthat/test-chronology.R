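test_that("calibration transports measurement densities onto the cal axis", {
  grid <- seq(0, 4000, by = 1)
  # identity curve, negligible curve error: posterior ~ Normal(measured, err)
  ident <- calibration_curve(grid, grid, 1e-3)
  post <- calibrate(2000, 50, "radiocarbon", ident)
  expect_equal(sum(post$density), 1, tolerance = 1e-9)
  m <- sum(post$cal_age * post$density)
  s <- pollendiv:::posterior_sd(post)
  expect_equal(m, 2000, tolerance = 0.5)
  expect_equal(s, 50, tolerance = 0.5)

  # calendar-kind control is untouched by the curve
  post2 <- calibrate(1500, 20, "calendar", ident)
  expect_equal(sum(post2$cal_age * post2$density), 1500, tolerance = 0.1)
  expect_equal(pollendiv:::posterior_sd(post2), 20, tolerance = 0.1)

  # slope-2 curve compresses the lab error by the delta method: sd ~ 20
  steep <- calibration_curve(grid, 2 * grid, 1e-3)
  post3 <- calibrate(4000, 40, "radiocarbon", steep)
  expect_equal(pollendiv:::posterior_sd(post3), 20, tolerance = 0.5)

  expect_error(calibrate(99000, 40, "radiocarbon", ident), "outside")
})

test_that("degenerate controls give exact piecewise-linear age models", {
  counts <- matrix(300L, 3, 2, dimnames = list(NULL, c("A", "B")))
  rec <- pollen_record("t", 45, 5, depths = c(10, 55, 100), counts,
                       controls = data.frame(depth = c(10, 100),
                                             age = c(1000, 9000),
                                             error = c(0.01, 0.01),
                                             kind = "calendar"))
  curve <- pollendiv:::synthetic_curves()$northern
  draws <- sample_age_models(rec, curve, n_draws = 25, seed = 5)
  expect_true(all(draws[, 2] == 5000))
  expect_true(all(draws[, 1] == 1000 & draws[, 3] == 9000))
})

test_that("age draws respect superposition and the extrapolation limit", {
  w <- small_world()
  for (rec in small_filtered()$kept[1:3]) {
    curve <- curve_for_latitude(rec$lat, w$curves)
    draws <- sample_age_models(rec, curve, n_draws = 30, seed = 3)
    mono <- apply(draws, 1, function(a) !is.unsorted(a[!is.na(a)]))
    expect_true(all(mono))
  }
  # sample extrapolated 4,000 yr beyond the oldest control is age-undefined
  counts <- matrix(300L, 3, 2, dimnames = list(NULL, c("A", "B")))
  rec <- pollen_record("t", 45, 5, depths = c(10, 20, 60), counts,
                       controls = data.frame(depth = c(10, 20),
                                             age = c(1000, 2000),
                                             error = c(0.01, 0.01),
                                             kind = "calendar"))
  curve <- pollendiv:::synthetic_curves()$northern
  draws <- sample_age_models(rec, curve, n_draws = 5, seed = 1)
  # slope 100 yr/cm -> depth 60 would be 6,000: 4,000 beyond the 2,000 control
  expect_true(all(is.na(draws[, 3])))
  expect_true(all(!is.na(draws[, 1:2])))
})

test_that("monotone-conditioned draw dispersion matches a rejection oracle", {
  grid <- seq(0, 12000, by = 5)
  curve <- calibration_curve(grid, grid, 1e-3)
  counts <- matrix(300L, 3, 2, dimnames = list(NULL, c("A", "B")))
  rec <- pollen_record("t", 45, 5, depths = c(10, 50, 90), counts,
                       controls = data.frame(depth = c(10, 50, 90),
                                             age = c(3000, 3500, 4000),
                                             error = c(300, 300, 300),
                                             kind = "radiocarbon"))
  n <- 4000
  draws <- sample_age_models(rec, curve, n_draws = n, seed = 9)

  # oracle: joint independent Gaussians accepted iff monotone
  set.seed(99)
  keep <- matrix(NA_real_, 0, 3)
  while (nrow(keep) < n) {
    cand <- cbind(rnorm(n, 3000, 300), rnorm(n, 3500, 300),
                  rnorm(n, 4000, 300))
    ok <- cand[, 1] <= cand[, 2] & cand[, 2] <= cand[, 3]
    keep <- rbind(keep, cand[ok, , drop = FALSE])
  }
  keep <- keep[seq_len(n), ]
  for (j in 1:3) {
    expect_equal(sd(draws[, j]), sd(keep[, j]), tolerance = 0.07)
    expect_equal(mean(draws[, j]), mean(keep[, j]), tolerance = 0.03)
  }
})

test_that("the inclusion filter applies the three criteria with reasons", {
  w <- small_world()
  curve_grid <- seq(0, 14000, by = 5)
  mk <- function(ctl_ages, n_samples = 8, grains = 2000L) {
    depths <- seq(5, 100, length.out = n_samples)
    counts <- matrix(as.integer(grains), n_samples, 2,
                     dimnames = list(NULL, c("A", "B")))
    ages <- seq(min(ctl_ages), max(ctl_ages), length.out = n_samples)
    d_of_a <- approxfun(ages, depths, rule = 2)
    pollen_record("m", 45, 5, depths, counts,
                  controls = data.frame(depth = d_of_a(ctl_ages),
                                        age = ctl_ages, error = 30,
                                        kind = "calendar"))
  }
  # two Holocene controls -> too-few-controls
  f <- filter_records(list(mk(c(2000, 6000))), w$curves)
  expect_false(f$report$kept)
  expect_equal(f$report$reason, "too-few-controls")
  # controls at 9,000/5,500/1,000: 3,500-yr gap -> control-gap
  f <- filter_records(list(mk(c(1000, 5500, 9000))), w$curves)
  expect_equal(f$report$reason, "control-gap")
  # 6 samples >= 300 grains, controls at 8,000/6,000/4,000 -> kept
  f <- filter_records(list(mk(c(4000, 6000, 8000), n_samples = 6)),
                      w$curves)
  expect_true(f$report$kept)
  # enough samples but low counts -> low-count-samples
  f <- filter_records(list(mk(c(4000, 6000, 8000), n_samples = 6,
                              grains = 100L)), w$curves)
  expect_equal(f$report$reason, "low-count-samples")
  # every input record appears exactly once in the report
  recs <- list(mk(c(2000, 6000)), mk(c(4000, 6000, 8000), 6))
  recs[[1]]$record_id <- "a"
  recs[[2]]$record_id <- "b"
  f <- filter_records(recs, w$curves)
  expect_equal(sort(f$report$record_id), c("a", "b"))
})

test_that("filter_records is idempotent on its own output", {
  w <- small_world()
  f1 <- small_filtered()
  f2 <- filter_records(f1$kept, w$curves)
  expect_true(all(f2$report$kept))
  expect_equal(vapply(f2$kept, function(r) length(r$depths), 0L),
               vapply(f1$kept, function(r) length(r$depths), 0L))
})
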