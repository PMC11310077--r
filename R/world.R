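#' Configuration of a synthetic pollen world
#'
#' A "world" emulates the statistical structure of the inputs the analysis
#' assumes: multi-record pollen count matrices with heterogeneous grain
#' totals and sample spacing, radiocarbon-style chronological controls,
#' depositional-environment labels, region rectangles, invertible
#' calibration curves, and regional land-use (ALCC) curves that causally
#' drive taxon turnover, richness and evenness with configurable sign and
#' magnitude per region.
#'
#' @param n_regions number of regions (disjoint lat/lon rectangles; <= 8).
#' @param records_per_region records generated per region.
#' @param taxon_pool_size global taxon pool (core + disturbance taxa).
#' @param time_span `c(old, young)` cal yr BP; old > young (BP convention).
#' @param alcc_params data.frame with one row per region: `onset` (cal yr
#'   BP), `rate` (per yr), `plateau` (fraction in `[0, 1]`); recycled.
#' @param diversity_effects data.frame with one row per region: signed
#'   effect sizes in `[-1, 1]` of ALCC on `richness`, `evenness`,
#'   `turnover`; recycled.
#' @param trend_amplitude amplitude of the smooth background (climate)
#'   compositional drift; 0 freezes composition in time.
#' @param intercept_sd sd of per-record random intercepts on the (log)
#'   dominance scale.
#' @param noise_sd count-level overdispersion: sample compositions are
#'   Dirichlet-perturbed with concentration `1 / noise_sd^2` (0 = pure
#'   multinomial).
#' @param dominance baseline dominance (log-abundance range over the core
#'   taxon pool); larger = steeper rank-abundance curve, fewer types seen
#'   in 300 grains.
#' @param n_dep_envs number of depositional-environment labels.
#' @param samples_range,grain_range,controls_range,lab_error_range ranges
#'   for per-record sample counts, per-sample terrestrial grain totals,
#'   control counts and radiocarbon lab errors.
#' @param seed integer master seed; identical config + seed gives a
#'   byte-identical world.
#' @return a validated `world_config` list.
#' @export
world_config <- function(n_regions = 3L,
                         records_per_region = 20L,
                         taxon_pool_size = 80L,
                         time_span = c(11700, 100),
                         alcc_params = NULL,
                         diversity_effects = NULL,
                         trend_amplitude = 1,
                         intercept_sd = 0.15,
                         noise_sd = 0.05,
                         dominance = 8,
                         n_dep_envs = 6L,
                         samples_range = c(20L, 50L),
                         grain_range = c(300L, 5000L),
                         controls_range = c(4L, 8L),
                         lab_error_range = c(30, 90),
                         seed = 1L) {
  if (is.null(alcc_params)) {
    alcc_params <- data.frame(onset = c(6000, 4000, 2500),
                              rate = c(0.0015, 0.002, 0.003),
                              plateau = c(0.5, 0.4, 0.3))
  }
  if (is.null(diversity_effects)) {
    diversity_effects <- data.frame(richness = c(1, -1, 0.5),
                                    evenness = c(1, -1, -0.5),
                                    turnover = c(1, 0.5, -0.5))
  }
  recycle <- function(df, n) df[rep_len(seq_len(nrow(df)), n), , drop = FALSE]
  alcc_params <- recycle(alcc_params, n_regions)
  diversity_effects <- recycle(diversity_effects, n_regions)
  rownames(alcc_params) <- rownames(diversity_effects) <- NULL

  cfg <- list(n_regions = as.integer(n_regions),
              records_per_region = as.integer(records_per_region),
              taxon_pool_size = as.integer(taxon_pool_size),
              time_span = as.numeric(time_span),
              alcc_params = alcc_params,
              diversity_effects = diversity_effects,
              trend_amplitude = trend_amplitude,
              intercept_sd = intercept_sd, noise_sd = noise_sd,
              dominance = dominance, n_dep_envs = as.integer(n_dep_envs),
              samples_range = as.integer(samples_range),
              grain_range = as.integer(grain_range),
              controls_range = as.integer(controls_range),
              lab_error_range = as.numeric(lab_error_range),
              seed = as.integer(seed))
  bad <- character(0)
  if (cfg$n_regions < 1L || cfg$n_regions > 8L) bad <- c(bad, "n_regions")
  if (cfg$records_per_region < 0L) bad <- c(bad, "records_per_region")
  if (cfg$taxon_pool_size < 10L) bad <- c(bad, "taxon_pool_size")
  if (length(cfg$time_span) != 2L || cfg$time_span[1L] <= cfg$time_span[2L]) {
    bad <- c(bad, "time_span")
  }
  if (any(cfg$alcc_params$plateau < 0 | cfg$alcc_params$plateau > 1)) {
    bad <- c(bad, "alcc_params$plateau")
  }
  if (any(abs(as.matrix(cfg$diversity_effects)) > 1)) {
    bad <- c(bad, "diversity_effects")
  }
  if (cfg$noise_sd < 0) bad <- c(bad, "noise_sd")
  if (cfg$intercept_sd < 0) bad <- c(bad, "intercept_sd")
  if (length(bad)) {
    stop("invalid world_config field(s): ", paste(bad, collapse = ", "))
  }
  structure(cfg, class = "world_config")
}

#' Logistic regional ALCC series
#'
#' Fraction of land under any human use per year: a logistic ramp
#' `plateau / (1 + exp(-rate * (onset - year)))`, equal to half the plateau
#' at the onset year and rising toward the present (non-decreasing toward
#' younger ages whenever `rate > 0`).  An infinite rate gives a step from 0
#' to `plateau` at the onset.
#'
#' @param onset midpoint of the ramp (cal yr BP).
#' @param rate steepness (per yr, >= 0; may be `Inf`).
#' @param plateau asymptotic land-use fraction in `[0, 1]`.
#' @param region region label attached to the series.
#' @param years annual grid (default `8000:100` cal yr BP).
#' @return an `alcc_series`.
#' @export
generate_alcc_series <- function(onset, rate, plateau, region = "region",
                                 years = 8000:100) {
  if (plateau < 0 || plateau > 1) {
    stop("invalid ALCC config: plateau must lie in [0, 1]")
  }
  if (!is.finite(rate)) {
    frac <- ifelse(years < onset, plateau,
                   ifelse(years > onset, 0, plateau / 2))
  } else {
    frac <- plateau / (1 + exp(-rate * (onset - years)))
  }
  alcc_series(region, years, frac)
}

# --------------------------------------------------------------------------
# Generative composition model.
#
# Region r at age t has a deterministic taxon composition p_r(t):
#   * core taxa follow a geometric rank-abundance profile whose steepness
#     ("dominance") is modulated by the region's signed evenness effect of
#     ALCC, and by smooth background drift along fixed random loadings
#     (the climate trend);
#   * disturbance taxa (absent without land use) are mixed in at a rate
#     proportional to the positive part of the richness effect x ALCC, while
#     a negative richness effect steepens the core tail (fewer types seen in
#     300 grains);
#   * the turnover effect adds extra compositional drift along a second
#     loading vector at a velocity proportional to ALCC (cumulative ALCC
#     enters the log-abundances), so dissimilarity between successive
#     samples rises where land use is high.
# Effect scale constants below set how strongly a unit effect moves each
# metric; they are part of the stated world, chosen once so that default
# worlds have realistic magnitudes (rarefied richness in the 15-30 range,
# evenness 0.6-0.9, land-use-driven changes comparable to the background
# trend).

EFFECT_SCALE <- list(evenness = 0.5, richness_mix = 0.25,
                     richness_tail = 0.6, turnover = 0.35,
                     drift = 0.35)

region_params <- function(cfg) {
  P <- cfg$taxon_pool_size
  n_core <- max(8L, round(0.7 * P))
  lapply(seq_len(cfg$n_regions), function(r) {
    with_seed(derive_seed(cfg$seed, "region-params", r), {
      list(
        region = paste0("region_", r),
        n_core = n_core,
        core_idx = seq_len(n_core),
        dist_idx = if (n_core < P) seq(n_core + 1L, P) else integer(0),
        g = stats::rnorm(n_core),          # climate-drift loadings
        h = stats::rnorm(n_core),          # land-use-drift loadings
        period = stats::runif(1, 9000, 14000),
        phase = stats::runif(1, 0, 14000),
        perm = sample.int(n_core)          # region-specific rank order
      )
    })
  })
}

make_truth <- function(cfg) {
  pars <- region_params(cfg)
  alcc <- lapply(seq_len(cfg$n_regions), function(r) {
    generate_alcc_series(cfg$alcc_params$onset[r], cfg$alcc_params$rate[r],
                         cfg$alcc_params$plateau[r],
                         region = paste0("region_", r))
  })
  names(alcc) <- vapply(pars, `[[`, "", "region")
  # cumulative ALCC toward the present, in plateau-years/1000 units
  alcc_cum <- lapply(alcc, function(s) cumsum(s$fraction) / 1000)

  alcc_at_age <- function(r, age) {
    s <- alcc[[r]]
    ifelse(age > max(s$years), 0,
           ifelse(age < min(s$years), s$fraction[length(s$fraction)],
                  s$fraction[pmax(1L, match(round(pmin(pmax(age,
                    min(s$years)), max(s$years))), s$years))]))
  }
  alcc_cum_at_age <- function(r, age) {
    s <- alcc[[r]]
    cum <- alcc_cum[[r]]
    ifelse(age > max(s$years), 0,
           ifelse(age < min(s$years), cum[length(cum)],
                  cum[pmax(1L, match(round(pmin(pmax(age, min(s$years)),
                    max(s$years))), s$years))]))
  }

  P <- cfg$taxon_pool_size
  taxa <- sprintf("Taxon_%03d", seq_len(P))
  es <- EFFECT_SCALE

  composition <- function(region_index, age, delta = 0) {
    r <- region_index
    pr <- pars[[r]]
    eff <- cfg$diversity_effects[r, ]
    a <- alcc_at_age(r, age)
    acum <- alcc_cum_at_age(r, age)
    # dominance modulated by evenness effect, record intercept, and a
    # negative richness effect steepening the tail
    theta <- cfg$dominance * exp(-es$evenness * eff$evenness * a + delta) *
      (1 + es$richness_tail * pmax(-eff$richness * a, 0))
    rank <- (pr$perm - 1) / (pr$n_core - 1)
    clim <- cfg$trend_amplitude *
      sin(2 * pi * (age - pr$phase) / pr$period)
    drift <- es$drift * clim * pr$g +
      es$turnover * eff$turnover * acum * pr$h
    logw <- -theta * rank + drift
    w <- exp(logw - max(logw))
    p_core <- w / sum(w)
    p <- numeric(P)
    p[pr$core_idx] <- p_core
    if (length(pr$dist_idx)) {
      m <- es$richness_mix * max(eff$richness * a, 0)
      if (m > 0) {
        v <- exp(-3 * (seq_along(pr$dist_idx) - 1) / length(pr$dist_idx))
        p[pr$dist_idx] <- m * v / sum(v)
        p[pr$core_idx] <- (1 - m) * p_core
      }
    }
    stats::setNames(p, taxa)
  }

  # truth functions target the quantity the pipeline estimates: the
  # expected value of each metric for a 300-grain rarefied sample at the
  # zero-intercept composition.  Richness has the closed form
  # E[S] = sum_i (1 - (1 - p_i)^300); evenness and turnover use a seeded
  # Monte-Carlo expectation over multinomial 300-grain draws (the
  # population plug-in values sit on a different scale and can even
  # decorrelate from the sampled metric's trend).
  richness_fn <- function(region_index, age, n = 300L) {
    vapply(age, function(t) {
      p <- composition(region_index, t)
      sum(1 - (1 - p)^n)
    }, 0)
  }
  n_truth_mc <- 400L
  evenness_fn <- function(region_index, age) {
    vapply(age, function(t) {
      p <- composition(region_index, t)
      with_seed(derive_seed(cfg$seed, "truth-ev", region_index,
                            round(t * 100)), {
        draws <- stats::rmultinom(n_truth_mc, 300L, p)
        mean(apply(draws, 2L, function(cc) {
          s <- sum(cc > 0L)
          if (s < 2L) return(NA_real_)
          pp <- cc[cc > 0L] / 300
          -sum(pp * log(pp)) / log(s)
        }), na.rm = TRUE)
      })
    }, 0)
  }
  turnover_fn <- function(region_index, age, dt = 200) {
    vapply(age, function(t) {
      x <- composition(region_index, t + dt / 2)
      y <- composition(region_index, t - dt / 2)
      with_seed(derive_seed(cfg$seed, "truth-to", region_index,
                            round(t * 100)), {
        dx <- stats::rmultinom(n_truth_mc, 300L, x)
        dy <- stats::rmultinom(n_truth_mc, 300L, y)
        mean(colSums(abs(dx - dy))) / 600
      })
    }, 0)
  }

  env_labels <- paste0("env_", seq_len(cfg$n_dep_envs))
  env_offsets <- with_seed(derive_seed(cfg$seed, "env-offsets"), {
    stats::setNames(stats::rnorm(cfg$n_dep_envs, 0, 0.10), env_labels)
  })

  structure(list(
    config = cfg, taxa = taxa, params = pars, alcc = alcc,
    composition = composition, richness_fn = richness_fn,
    evenness_fn = evenness_fn, turnover_fn = turnover_fn,
    effects = cfg$diversity_effects,
    env_labels = env_labels, env_offsets = env_offsets,
    record_intercepts = list()
  ), class = "generative_truth")
}

# --------------------------------------------------------------------------

default_region_map <- function(cfg) {
  lat0 <- seq(-35, 55, length.out = max(cfg$n_regions, 2L))[seq_len(cfg$n_regions)]
  data.frame(region = paste0("region_", seq_len(cfg$n_regions)),
             continent = paste0("region_", seq_len(cfg$n_regions)),
             biome = paste0("region_", seq_len(cfg$n_regions)),
             lat_min = lat0, lat_max = lat0 + 8,
             lon_min = 0, lon_max = 20)
}

synthetic_curves <- function() {
  grid <- seq(0, 14000, by = 5)
  # identity-with-wiggles: invertible (|d c14/d cal| > 0) but nontrivial
  north <- calibration_curve(grid, grid + 35 * sin(2 * pi * grid / 1100),
                             15 + 5 * abs(sin(grid / 700)))
  south <- calibration_curve(grid,
                             grid + 35 * sin(2 * pi * grid / 1100 + 1) + 30,
                             15 + 5 * abs(sin(grid / 700 + 1)))
  list(northern = north, southern = south)
}

default_harmonization <- function(taxa, split_taxa) {
  tab <- data.frame(raw = taxa, harmonized = taxa,
                    group = "terrestrial-pollen")
  if (length(split_taxa)) {
    tab <- rbind(tab, data.frame(raw = paste0(split_taxa, "-type"),
                                 harmonized = split_taxa,
                                 group = "terrestrial-pollen"))
  }
  rbind(tab,
        data.frame(raw = c("Spore_1", "Spore_2"),
                   harmonized = c("Spore_1", "Spore_2"), group = "spore"),
        data.frame(raw = "Aquatic_1", harmonized = "Aquatic_1",
                   group = "aquatic"))
}

#' Generate one synthetic pollen record
#'
#' Samples a record's true ages and depths, draws counts multinomially
#' (optionally Dirichlet-overdispersed) around the region's true composition
#' at each sample's age plus the record's random intercept, and builds
#' radiocarbon-style chronological controls by pushing true calendar ages
#' through the synthetic calibration curve and adding Gaussian lab error.
#' A small number of taxa are emitted under two raw names (`X` and
#' `X-type`) and spore/aquatic counts are added, so harmonization is
#' exercised on every world.
#'
#' `defect` generates records violating exactly one inclusion criterion:
#' `"too-few-controls"` (2 controls), `"control-gap"` (a 3,500-yr gap),
#' `"too-few-samples"` (4 samples), `"low-count-samples"` (5 samples, one
#' with 250 grains).
#'
#' @param region_index region number in the truth object.
#' @param truth a `generative_truth` from [make_truth()]/[generate_world()].
#' @param seed integer seed; identical seed gives an identical record.
#' @param record_id identifier (default derived from region and seed).
#' @param map region map (for site coordinates); default world layout.
#' @param curves calibration curves; default synthetic pair.
#' @param defect `"none"` or one named criterion to violate.
#' @return list with the [pollen_record] (`record`) and its true generative
#'   state (`delta`, `true_ages`, `dep_env`).
#' @export
generate_record <- function(region_index, truth, seed,
                            record_id = NULL, map = NULL, curves = NULL,
                            defect = c("none", "too-few-controls",
                                       "control-gap", "too-few-samples",
                                       "low-count-samples")) {
  defect <- match.arg(defect)
  cfg <- truth$config
  if (region_index < 1L || region_index > cfg$n_regions) {
    stop("region ", region_index, " does not exist in truth")
  }
  if (is.null(map)) map <- default_region_map(cfg)
  if (is.null(curves)) curves <- synthetic_curves()
  if (is.null(record_id)) {
    record_id <- sprintf("r%d_s%d", region_index, seed)
  }
  with_seed(seed, {
    n <- sample(seq(cfg$samples_range[1L], cfg$samples_range[2L]), 1L)
    if (defect == "too-few-samples") n <- 4L
    if (defect == "low-count-samples") n <- 5L
    old <- stats::runif(1, 8500, min(11500, cfg$time_span[1L] - 200))
    young <- stats::runif(1, max(150, cfg$time_span[2L] + 50), 1200)
    # a fixed 8,000-yr span keeps the engineered 3,500-yr gap the *only*
    # violated criterion (both control runs stay below three controls)
    if (defect == "control-gap") old <- young + 8000
    if (defect %in% c("too-few-samples", "low-count-samples")) {
      # keep the few samples well inside the analysis window so the named
      # criterion is the only one violated
      old <- min(old, 10500)
      young <- max(young, 400)
    }
    true_ages <- sort(seq(young, old, length.out = n) +
                        stats::runif(n, -0.3, 0.3) * (old - young) / n)
    # rescale so the outermost samples sit exactly at [young, old]; the
    # outermost controls then anchor the age-depth model without
    # extrapolation
    true_ages <- young + (true_ages - min(true_ages)) /
      (max(true_ages) - min(true_ages)) * (old - young)
    depths <- cumsum(stats::runif(n, 0.5, 4))
    # depth increases with age: youngest sample at the top
    age_of_depth <- stats::approxfun(depths, true_ages, rule = 2)

    grains <- sample(seq(cfg$grain_range[1L], cfg$grain_range[2L]), n,
                     replace = TRUE)
    if (defect == "low-count-samples") grains[3L] <- 250L

    delta <- stats::rnorm(1, 0, cfg$intercept_sd)
    dep_env <- sample(truth$env_labels, 1L)
    delta_total <- delta + truth$env_offsets[[dep_env]]

    P <- length(truth$taxa)
    counts <- matrix(0L, n, P, dimnames = list(NULL, truth$taxa))
    for (s in seq_len(n)) {
      p <- truth$composition(region_index, true_ages[s], delta_total)
      if (cfg$noise_sd > 0) {
        nu <- 1 / cfg$noise_sd^2
        w <- stats::rgamma(P, shape = nu * p)
        if (sum(w) > 0) p <- w / sum(w)
      }
      counts[s, ] <- stats::rmultinom(1L, grains[s], p)[, 1L]
    }
    # split taxa: first three pool taxa are reported under two raw names
    split_taxa <- truth$taxa[1:3]
    for (tx in split_taxa) {
      half <- stats::rbinom(n, counts[, tx], 0.5)
      counts <- cbind(counts, half)
      colnames(counts)[ncol(counts)] <- paste0(tx, "-type")
      counts[, tx] <- counts[, tx] - half
    }
    # spores / aquatics: excluded from terrestrial totals by harmonization
    extra <- cbind(Spore_1 = stats::rpois(n, 8), Spore_2 = stats::rpois(n, 3),
                   Aquatic_1 = stats::rpois(n, 5))
    counts <- cbind(counts, extra)
    storage.mode(counts) <- "integer"

    # chronological controls
    span <- old - young
    k <- sample(seq(cfg$controls_range[1L], cfg$controls_range[2L]), 1L)
    k <- min(15L, max(k, ceiling(span / 2500) + 1L))
    ctl_ages <- seq(min(true_ages), max(true_ages), length.out = k)
    if (k > 2L) {
      jit <- stats::runif(k - 2L, -0.15, 0.15) * span / (k - 1L)
      ctl_ages[2:(k - 1L)] <- ctl_ages[2:(k - 1L)] + jit
    }
    if (defect == "too-few-controls") ctl_ages <- ctl_ages[1:2]
    if (defect == "control-gap") {
      mid <- young + span / 2
      ctl_ages <- c(young, mid - 1750, mid + 1750, old)
    }
    kk <- length(ctl_ages)
    lat0 <- map[map$region == paste0("region_", region_index), ]
    lat <- stats::runif(1, lat0$lat_min, lat0$lat_max)
    lon <- stats::runif(1, lat0$lon_min, lat0$lon_max)
    curve <- if (lat >= 0) curves$northern else curves$southern
    kind <- ifelse(stats::runif(kk) < 0.2, "calendar", "radiocarbon")
    err <- stats::runif(kk, cfg$lab_error_range[1L], cfg$lab_error_range[2L])
    meas <- numeric(kk)
    for (i in seq_len(kk)) {
      if (kind[i] == "calendar") {
        meas[i] <- ctl_ages[i] + stats::rnorm(1, 0, err[i])
      } else {
        c14_true <- stats::approx(curve$cal_age, curve$c14_age,
                                  xout = ctl_ages[i], rule = 2)$y
        meas[i] <- c14_true + stats::rnorm(1, 0, err[i])
      }
    }
    # invert the age-depth relation to place controls at depths
    depth_of_age <- stats::approxfun(true_ages, depths, rule = 2)
    controls <- data.frame(depth = depth_of_age(ctl_ages), age = meas,
                           error = err, kind = kind)

    rec <- pollen_record(record_id, lat, lon, depths, counts, controls,
                         dep_env = dep_env)
    list(record = rec, delta = delta, true_ages = true_ages,
         dep_env = dep_env)
  })
}

#' Generate a complete synthetic world
#'
#' Produces mutually consistent records, calibration curves, harmonization
#' table, region map, ALCC grid (the regional series broadcast uniformly
#' over each region's cells) and the retained generative truth.
#'
#' @param config a [world_config()].
#' @param defects optional named character vector `record_id -> defect`
#'   passed to [generate_record()]; by default all records are compliant.
#' @return list with elements `records`, `curves`, `harmonization`, `map`,
#'   `grid`, `alcc`, `truth`.
#' @export
generate_world <- function(config = world_config(), defects = NULL) {
  cfg <- if (inherits(config, "world_config")) config else
    do.call(world_config, config)
  truth <- make_truth(cfg)
  map <- default_region_map(cfg)
  curves <- synthetic_curves()
  harm <- default_harmonization(truth$taxa, truth$taxa[1:3])

  records <- list()
  for (r in seq_len(cfg$n_regions)) {
    for (j in seq_len(cfg$records_per_region)) {
      rid <- sprintf("region_%d_rec_%02d", r, j)
      defect <- "none"
      if (!is.null(defects) && rid %in% names(defects)) {
        defect <- defects[[rid]]
      }
      g <- generate_record(r, truth, derive_seed(cfg$seed, "record", r, j),
                           record_id = rid, map = map, curves = curves,
                           defect = defect)
      records[[rid]] <- g$record
      truth$record_intercepts[[rid]] <- g$delta
    }
  }
  records <- assign_regions(records, map)

  # ALCC grid: 4 cells per region, the regional series broadcast uniformly,
  # so the regional mean recovers the series exactly
  cells <- do.call(rbind, lapply(seq_len(nrow(map)), function(i) {
    data.frame(lat = map$lat_min[i] + c(2, 2, 6, 6),
               lon = map$lon_min[i] + c(5, 15, 5, 15), region_i = i)
  }))
  years <- truth$alcc[[1L]]$years
  fracs <- do.call(rbind, lapply(seq_len(nrow(cells)), function(ci) {
    truth$alcc[[cells$region_i[ci]]]$fraction
  }))
  grid <- alcc_grid(cells[, c("lat", "lon")], years, fracs)

  list(records = records, curves = curves, harmonization = harm, map = map,
       grid = grid, alcc = truth$alcc, truth = truth)
}

#' Write a world to disk in the pipeline's file formats
#'
#' Records as counts/controls CSV + metadata JSON, curves and harmonization
#' table and region map as CSV, ALCC grid as dense CSV, and the generative
#' truth (trend functions evaluated on an age grid, true effects, record
#' intercepts) as JSON.
#' @param world result of [generate_world()].
#' @param dir output directory.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_records(world$records, file.path(dir, "records"))
  write_calibration_curve(world$curves$northern,
                          file.path(dir, "curve_northern.csv"))
  write_calibration_curve(world$curves$southern,
                          file.path(dir, "curve_southern.csv"))
  write_harmonization(world$harmonization, file.path(dir, "harmonization.csv"))
  write_region_map(world$map, file.path(dir, "region_map.csv"))
  write_alcc_grid(world$grid, file.path(dir, "alcc_grid.csv"))

  ages <- seq(world$truth$config$time_span[1L],
              world$truth$config$time_span[2L], by = -50)
  truth_json <- list(
    config = unclass(world$truth$config)[c("n_regions", "records_per_region",
      "taxon_pool_size", "time_span", "trend_amplitude", "intercept_sd",
      "noise_sd", "dominance", "seed")],
    effects = world$truth$effects,
    env_offsets = as.list(world$truth$env_offsets),
    record_intercepts = world$truth$record_intercepts,
    trend_grid = ages,
    trends = lapply(seq_len(world$truth$config$n_regions), function(r) {
      list(region = paste0("region_", r),
           richness = world$truth$richness_fn(r, ages),
           evenness = world$truth$evenness_fn(r, ages),
           turnover = world$truth$turnover_fn(r, ages))
    })
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
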