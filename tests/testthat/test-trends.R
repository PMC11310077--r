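test_that("standardization is an exact, invertible z-score within region", {
  df <- data.frame(continent = "A", record_id = "r", age = 1:2,
                   value = c(1, 3))
  st <- standardize(df)
  expect_equal(st$value_st, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  sc <- attr(st, "scale")
  expect_equal(unstandardize(st$value_st, st$continent, sc), df$value,
               tolerance = 1e-10)
  # standardizing an already standardized series is (near) identity
  st2 <- standardize(data.frame(continent = "A", record_id = "r",
                                age = 1:2, value = st$value_st))
  expect_equal(st2$value_st, st$value_st, tolerance = 1e-12)
  expect_error(standardize(data.frame(continent = "A", record_id = "r",
                                      age = 1:3, value = rep(2, 3))),
               "zero variance")
})

test_that("flat-truth data yields a flat low-edf smooth", {
  set.seed(21)
  n_rec <- 8
  df <- do.call(rbind, lapply(seq_len(n_rec), function(i) {
    ages <- sort(runif(40, 100, 11700))
    data.frame(continent = "A", record_id = paste0("r", i), age = ages,
               value = 5 + rnorm(1, 0, 0.5) + rnorm(40, 0, 0.3))
  }))
  st <- standardize(df)
  fit <- fit_region_trends(st, k = 10)
  pr <- predict_trends(fit, seq(300, 11500, length.out = 40))
  # the constant truth lies inside the 2 SE band everywhere
  m0 <- mean(df$value)
  expect_true(all(pr$lower <= m0 & pr$upper >= m0))
  expect_lt(diff(range(pr$fit)), 0.6)
  s <- smooth_pvalues(fit)
  expect_lt(s$edf[grepl("age", s$term)][1], 2.5) # ~1 for a flat truth
})

test_that("a noiseless cubic is reproduced exactly with the right penalty order", {
  ages <- seq(100, 11700, length.out = 80)
  x <- (ages - 5000) / 3000
  y <- 0.3 * x^3 - 0.5 * x^2 + x + 2
  df <- standardize(data.frame(continent = "A", record_id = "r1",
                               age = ages, value = y))
  fit <- suppressWarnings(fit_region_trends(df, k = 10, spline_m = 4))
  pr <- predict_trends(fit, ages)
  expect_lt(max(abs(pr$fit - y)), 1e-6)
})

test_that("opposite true trends fit with opposite mean slopes", {
  set.seed(33)
  mk <- function(region, sign) {
    do.call(rbind, lapply(1:6, function(i) {
      ages <- sort(runif(40, 100, 11700))
      data.frame(continent = region, record_id = paste0(region, i),
                 age = ages,
                 value = sign * (ages / 11700) + rnorm(1, 0, 0.2) +
                   rnorm(40, 0, 0.2))
    }))
  }
  st <- standardize(rbind(mk("up", 1), mk("down", -1)))
  fit <- fit_region_trends(st, k = 10)
  pr <- predict_trends(fit, seq(500, 11000, length.out = 30))
  slope_of <- function(rg) {
    d <- pr[pr$region == rg, ]
    coef(lm(fit ~ age, d))[2]
  }
  expect_gt(slope_of("up"), 0)
  expect_lt(slope_of("down"), 0)
})

test_that("AIC comparison uses 2*edf - 2*loglik and guards its inputs", {
  set.seed(4)
  df <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(continent = c("A", "B")[1 + i %% 2],
               record_id = paste0("r", i),
               age = seq(100, 11000, length.out = 30),
               value = rnorm(30))
  }))
  st <- standardize(df)
  f1 <- fit_region_trends(st, k = 8)
  d <- fit_diagnostics(f1)
  expect_equal(d$aic, 2 * d$edf - 2 * d$loglik)
  # comparing a model with itself: delta 0, no improvement
  cmp <- compare_aic(f1, f1)
  expect_equal(cmp$delta_aic, 0)
  expect_equal(cmp$verdict, "no-improvement")
  # mismatched data refuses
  st2 <- st[-1, ]
  attr(st2, "scale") <- attr(st, "scale")
  f2 <- fit_pooled_trend(st2, k = 8)
  expect_error(compare_aic(f1, f2), "not on identical data")
})

test_that("resample summaries follow the percentile conventions", {
  curves <- data.frame(region = "A", age = rep(1000, 3),
                       fit = c(0, 1, 2), resample = 1:3)
  s <- summarize_resamples(curves)
  expect_equal(s$median, 1)
  expect_equal(s$q25, 0.5)
  expect_equal(s$q75, 1.5)
  one <- summarize_resamples(data.frame(region = "A", age = c(1, 2),
                                        fit = c(3, 4), resample = 1))
  expect_equal(one$median, one$q25)
  expect_equal(one$median, one$q75)
})

test_that("k exceeding the unique-age support is refused with advice", {
  df <- standardize(data.frame(continent = "A", record_id = "r",
                               age = rep(1:6, 4), value = rnorm(24)))
  expect_error(fit_region_trends(df, k = 50), "smaller k")
  expect_error(fit_region_trends(df[df$age < 5, ], k = 3), "too few")
})
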