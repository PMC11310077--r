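test_that("logistic ALCC series behaves like its formula", {
  expect_equal(generate_alcc_series(4000, 0, 0)$fraction,
               rep(0, length(8000:100)))
  s <- generate_alcc_series(4000, Inf, 0.6)
  expect_equal(s$fraction[s$years > 4000], rep(0, sum(s$years > 4000)))
  expect_equal(s$fraction[s$years < 4000], rep(0.6, sum(s$years < 4000)))
  # midpoint of the logistic is half the plateau
  s <- generate_alcc_series(4000, 0.002, 0.5)
  expect_equal(s$fraction[s$years == 4000], 0.25, tolerance = 1e-12)
  # monotone non-decreasing toward the present when rate > 0
  expect_true(all(diff(s$fraction) >= 0)) # years stored old -> young
  expect_true(all(s$fraction >= 0 & s$fraction <= 1))
  expect_error(generate_alcc_series(4000, 0.002, 1.2), "plateau")
})

test_that("world_config validates and reports offending fields", {
  expect_error(world_config(time_span = c(100, 11700)), "time_span")
  expect_error(world_config(noise_sd = -1), "noise_sd")
  err <- tryCatch(world_config(noise_sd = -1, records_per_region = -2),
                  error = conditionMessage)
  expect_match(err, "records_per_region")
  expect_match(err, "noise_sd")
})

test_that("worlds and records are deterministic in (config, seed)", {
  cfg <- world_config(n_regions = 2, records_per_region = 2, seed = 123)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(records_to_long(w1$records), records_to_long(w2$records))
  expect_identical(w1$map, w2$map)
  expect_identical(w1$grid$fractions, w2$grid$fractions)
  expect_identical(
    lapply(w1$records, `[[`, "controls"),
    lapply(w2$records, `[[`, "controls"))

  g1 <- generate_record(1, w1$truth, seed = 7)
  g2 <- generate_record(1, w1$truth, seed = 7)
  expect_identical(g1$record$counts, g2$record$counts)
  expect_identical(g1$record$controls, g2$record$controls)
})

test_that("world outputs are mutually consistent", {
  w <- small_world()
  cfg <- w$truth$config
  expect_equal(nrow(w$map), cfg$n_regions)
  validate <- pollendiv:::validate_region_map(w$map) # disjoint rectangles
  expect_equal(nrow(validate), cfg$n_regions)
  # every record's region is in the map
  regions <- vapply(assign_regions(w$records, w$map), `[[`, "", "continent")
  expect_true(all(regions %in% w$map$region))
  # regional mean of the grid equals the region's series at every year
  means <- regional_alcc_mean(w$grid, w$map)
  for (rg in names(means)) {
    expect_equal(means[[rg]]$fraction, w$alcc[[rg]]$fraction,
                 tolerance = 1e-12)
  }
  # zero records still yields a non-empty map and grid
  w0 <- generate_world(world_config(records_per_region = 0))
  expect_equal(length(w0$records), 0)
  expect_gt(nrow(w0$map), 0)
  expect_gt(nrow(w0$grid$cells), 0)
})

test_that("a constant generative world produces exchangeable samples", {
  cfg <- world_config(records_per_region = 1, trend_amplitude = 0,
                      noise_sd = 0, intercept_sd = 0,
                      diversity_effects = data.frame(richness = 0,
                                                     evenness = 0,
                                                     turnover = 0),
                      seed = 5)
  w <- generate_world(cfg)
  tr <- w$truth
  # composition is the same at any age and any record offset
  p1 <- tr$composition(1, 10000)
  p2 <- tr$composition(1, 500)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("generated mean richness matches the stored truth function", {
  # Monte-Carlo check of the closed-form expected rarefied richness
  cfg <- world_config(records_per_region = 0, trend_amplitude = 0,
                      noise_sd = 0, intercept_sd = 0, seed = 8)
  w <- generate_world(cfg)
  age <- 3000
  p <- w$truth$composition(2, age)
  set.seed(31)
  draws <- stats::rmultinom(3000, 300, p)
  mc <- mean(colSums(draws > 0))
  se <- sd(colSums(draws > 0)) / sqrt(3000)
  expect_lt(abs(mc - w$truth$richness_fn(2, age)), 4 * se)
})

test_that("compliant records pass the filter; grain totals respect the floor", {
  f <- small_filtered()
  expect_true(all(f$report$kept))
  for (r in f$kept) expect_true(all(sample_totals(r) >= 300))
})

test_that("defective records violate exactly the named criterion", {
  w <- small_world()
  for (d in c("too-few-controls", "control-gap", "too-few-samples",
              "low-count-samples")) {
    g <- generate_record(2, w$truth, seed = 17, defect = d)
    recs <- assign_regions(
      apply_harmonization(list(g$record), w$harmonization), w$map)
    f <- filter_records(recs, w$curves)
    expect_equal(f$report$reason, d)
  }
  expect_error(generate_record(9, small_world()$truth, seed = 1),
               "does not exist")
})
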