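test_that("pairwise dissimilarities match their formulas and properties", {
  expect_equal(bray_curtis(c(10, 0, 5), c(4, 6, 5)), 12 / 30)
  expect_equal(bray_curtis(c(3, 1), c(3, 1)), 0)
  expect_equal(bray_curtis(c(5, 0), c(0, 7)), 1)
  expect_equal(jaccard(c(1, 2, 3, 0), c(0, 5, 1, 9)), 1 - 2 / 4)
  expect_equal(jaccard(c(1, 2, 0), c(9, 1, 0)), 0) # abundance-only change
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "empty")
  expect_error(jaccard(c(0, 0), c(0, 0)), "undefined")

  set.seed(11)
  for (i in 1:25) {
    x <- rpois(12, 3)
    y <- rpois(12, 3)
    x[1] <- x[1] + 1 # nonzero totals
    y[2] <- y[2] + 1
    expect_equal(bray_curtis(x, y), bray_curtis(y, x))
    expect_gte(bray_curtis(x, y), 0)
    expect_lte(bray_curtis(x, y), 1)
    # equal-total counts: invariant to conversion to proportions
    xs <- x / sum(x)
    ys <- y / sum(y)
    if (sum(x) == sum(y)) {
      expect_equal(bray_curtis(x, y), bray_curtis(xs, ys))
    }
    expect_equal(jaccard(x, y), jaccard(y, x))
  }
})

test_that("richness and evenness follow Shannon/Pielou arithmetic", {
  expect_equal(richness(c(300, 0, 0)), 1)
  expect_true(is.na(evenness(c(300, 0, 0))))
  expect_equal(richness(c(100, 100, 100)), 3)
  expect_equal(evenness(c(100, 100, 100)), 1)
  expect_equal(evenness(c(50, 50, 100, 100)),
               ((1 / 3) * log(6) + (2 / 3) * log(3)) / log(4),
               tolerance = 1e-12)
  expect_error(richness(c(10, 10)), "summing to 300")
  expect_error(evenness(rep(100, 4)), "summing to 300")
})

test_that("interval adjustment equals pooled OLS residuals on log interval", {
  # single shared interval: flat expectation = global mean
  p <- data.frame(interval = rep(100, 4), raw = c(0.1, 0.2, 0.3, 0.4))
  a <- adjust_turnover(p)
  expect_equal(a$adjusted, p$raw - mean(p$raw))

  # closed-form simple-regression residuals on three points
  iv <- c(10, 100, 1000)
  raw <- c(0.2, 0.4, 0.6)
  x <- log(iv + 1)
  beta <- sum((x - mean(x)) * (raw - mean(raw))) / sum((x - mean(x))^2)
  alpha <- mean(raw) - beta * mean(x)
  a <- adjust_turnover(data.frame(interval = iv, raw = raw))
  expect_equal(a$adjusted, raw - (alpha + beta * x), tolerance = 1e-12)
  expect_equal(mean(a$adjusted), 0, tolerance = 1e-12)

  # a pair exactly on the fitted line adjusts to zero; residual slope ~ 0
  set.seed(2)
  iv <- exp(runif(40, 2, 8))
  raw <- 0.05 + 0.03 * log(iv + 1) + rnorm(40, 0, 0.01)
  a <- adjust_turnover(data.frame(interval = iv, raw = raw))
  refit <- lm(a$adjusted ~ log(iv + 1))
  expect_equal(unname(coef(refit)[2]), 0, tolerance = 1e-10)
  expect_equal(nrow(adjust_turnover(data.frame(interval = numeric(0),
                                               raw = numeric(0)))), 0)
})

test_that("multiple-site dissimilarities reduce, bound and match the oracle", {
  # hand-frozen 3-site example (worked through the formulas by hand)
  m <- rbind(A = c(a = 2, b = 1, c = 0),
             B = c(a = 0, b = 3, c = 1),
             C = c(a = 1, b = 0, c = 2))
  expect_equal(multi_site_jaccard(m), 2 / 3, tolerance = 1e-12)
  expect_equal(multi_site_bray(m), 0.7, tolerance = 1e-12)

  # two sites reduce exactly to the pairwise index
  x <- c(10, 0, 5)
  y <- c(4, 6, 5)
  expect_equal(multi_site_bray(rbind(x, y)), bray_curtis(x, y))
  expect_equal(multi_site_jaccard(rbind(x, y)), jaccard(x, y))

  # identical sites -> 0; pairwise-disjoint sites -> 1
  id <- rbind(c(3, 1, 0), c(3, 1, 0), c(3, 1, 0))
  expect_equal(multi_site_bray(id), 0)
  expect_equal(multi_site_jaccard(id), 0)
  dj <- diag(c(5, 7, 9))
  expect_equal(multi_site_bray(dj), 1)
  expect_equal(multi_site_jaccard(dj), 1)

  set.seed(5)
  for (i in 1:20) {
    m <- random_count_table(sample(3:6, 1), 8)
    expect_equal(multi_site_jaccard(m), oracle_multi_jaccard(m),
                 tolerance = 1e-12)
    expect_equal(multi_site_bray(m), oracle_multi_bray(m),
                 tolerance = 1e-12)
    # order invariance
    perm <- sample(nrow(m))
    expect_equal(multi_site_bray(m[perm, ]), multi_site_bray(m))
    expect_equal(multi_site_jaccard(m[perm, ]), multi_site_jaccard(m))
    # (note: replacing a site by a duplicate of another is NOT monotone
    # for these indices - removing a generalist can raise them - so no
    # such assertion is made)
  }
})

test_that("heterogeneity hits its boundary cases and skips small regions", {
  # build a fake resample: one region, records identical in one bin
  mk_rec <- function(id, region, ages, counts) {
    list(record_id = id, continent = region, biome = region,
         dep_env = "env_1", ages = ages, counts = counts, included = TRUE)
  }
  base <- matrix(c(100L, 200L), 1, 2, dimnames = list(NULL, c("A", "B")))
  recs <- lapply(1:6, function(i) mk_rec(paste0("r", i), "X", 350, base))
  rs <- structure(list(resample_index = 1L, records = recs),
                  class = "resampled_dataset")
  h <- heterogeneity(rs, B = 5L, min_records = 5L, seed = 1)
  expect_true(all(h$value == 0))
  expect_true(all(h$bin_start == 100 & h$bin_end == 600))

  # pairwise-disjoint records -> 1
  recs <- lapply(1:6, function(i) {
    m <- matrix(0L, 1, 6, dimnames = list(NULL, paste0("t", 1:6)))
    m[1, i] <- 300L
    mk_rec(paste0("r", i), "X", 350, m)
  })
  rs <- structure(list(resample_index = 1L, records = recs),
                  class = "resampled_dataset")
  h <- heterogeneity(rs, B = 5L, min_records = 5L, seed = 1)
  expect_true(all(h$value == 1))

  # region below the record rule is skipped and reported
  h2 <- heterogeneity(rs, B = 5L, min_records = 20L, seed = 1)
  expect_equal(nrow(h2), 0)
  expect_equal(attr(h2, "skipped"), "X")
})

test_that("diversity_series computes all metrics on a resample", {
  d <- diversity_series(small_resamples()[[1]])
  expect_setequal(unique(d$metric),
                  c("richness", "evenness", "turnover_bc", "turnover_jac",
                    "turnover_bc_raw", "turnover_jac_raw"))
  rich <- d$value[d$metric == "richness"]
  expect_true(all(rich == floor(rich) & rich >= 1 & rich <= 300))
  ev <- d$value[d$metric == "evenness"]
  expect_true(all(is.na(ev) | (ev >= 0 & ev <= 1)))
  raw <- d$value[d$metric %in% c("turnover_bc_raw", "turnover_jac_raw")]
  expect_true(all(raw >= 0 & raw <= 1))
  # adjusted turnover averages ~0 per dataset per metric
  for (met in c("turnover_bc", "turnover_jac")) {
    expect_equal(mean(d$value[d$metric == met]), 0, tolerance = 1e-8)
  }
})
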