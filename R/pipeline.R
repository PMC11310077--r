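#' Pipeline configuration
#'
#' One configuration object drives every stage.  `default_pipeline_config()`
#' carries the study-scale settings (1,000 resamples, k = 50, 500-yr bins,
#' 20-record heterogeneity rule); `test_pipeline_config()` is a scaled-down
#' world for desk-scale runs and the test suite (fewer records and
#' resamples; the heterogeneity record rule relaxed accordingly), with the
#' same structure.  Configurations round-trip through YAML.
#'
#' @param seed master seed.
#' @return a nested list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    world = list(n_regions = 3L, records_per_region = 20L, seed = seed),
    resamples = 1000L,
    n_grains = 300L,
    min_samples = 5L,
    metrics = c("richness", "evenness", "turnover_bc", "turnover_jac"),
    trend = list(k = 50L, family = "gaussian", age_grid_n = 60L,
                 aic_resamples = 3L),
    heterogeneity = list(bin_width = 500, B = 100L, min_records = 20L),
    slopes = list(min_points = 5L)
  )
}

#' @rdname default_pipeline_config
#' @export
test_pipeline_config <- function(seed = 1L) {
  cfg <- default_pipeline_config(seed)
  cfg$world <- list(n_regions = 3L, records_per_region = 8L,
                    samples_range = c(15L, 30L), seed = seed)
  cfg$resamples <- 12L
  cfg$trend$k <- 12L
  cfg$heterogeneity$B <- 25L
  cfg$heterogeneity$min_records <- 5L
  cfg
}

#' @rdname default_pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_pipeline_config(cfg$seed %||% 1L)
  modifyList(base, cfg)
}

#' @rdname default_pipeline_config
#' @param config configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

log_params <- function(dir, stage, params) {
  jsonlite::write_json(c(list(stage = stage), params),
                       file.path(dir, "stage_params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

need_stage <- function(path, stage) {
  if (!file.exists(path)) {
    stop("missing upstream artifact '", path, "': run stage '", stage,
         "' first", call. = FALSE)
  }
}

# ---------------------------------------------------------------------------
# Stages.  Each reads its predecessors' on-disk outputs and writes its own
# under <outdir>/<stage>/, so any stage can be re-run in isolation.

stage_simulate <- function(cfg, outdir) {
  world <- generate_world(do.call(world_config, cfg$world))
  d <- file.path(outdir, "world")
  write_world(world, d)
  log_params(d, "simulate", cfg$world)
  invisible(world)
}

load_world_inputs <- function(outdir) {
  d <- file.path(outdir, "world")
  need_stage(file.path(d, "records", "counts.csv"), "simulate")
  list(records = read_records(file.path(d, "records")),
       curves = list(
         northern = read_calibration_curve(file.path(d, "curve_northern.csv")),
         southern = read_calibration_curve(file.path(d, "curve_southern.csv"))),
       harmonization = read_harmonization(file.path(d, "harmonization.csv")),
       map = read_region_map(file.path(d, "region_map.csv")),
       grid = read_alcc_grid(file.path(d, "alcc_grid.csv")))
}

stage_filter <- function(cfg, outdir) {
  w <- load_world_inputs(outdir)
  recs <- apply_harmonization(w$records, w$harmonization)
  recs <- assign_regions(recs, w$map)
  flt <- filter_records(recs, w$curves,
                        min_grains = cfg$n_grains,
                        min_samples = cfg$min_samples)
  d <- file.path(outdir, "filtered")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  write_records(flt$kept, file.path(d, "records"))
  utils::write.csv(flt$report, file.path(d, "filter_report.csv"),
                   row.names = FALSE)
  log_params(d, "filter", list(n_grains = cfg$n_grains,
                               min_samples = cfg$min_samples,
                               n_in = length(recs),
                               n_kept = length(flt$kept)))
  invisible(flt)
}

stage_resample <- function(cfg, outdir) {
  w <- load_world_inputs(outdir)
  fd <- file.path(outdir, "filtered", "records")
  need_stage(file.path(fd, "counts.csv"), "filter")
  recs <- read_records(fd)
  rs <- run_resamples(recs, w$curves, R = cfg$resamples,
                      master_seed = cfg$seed, n_grains = cfg$n_grains,
                      min_samples = cfg$min_samples)
  d <- file.path(outdir, "resamples")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (r in rs) write_resample(r, file.path(d, sprintf("resample_%04d",
                                                       r$resample_index)))
  utils::write.csv(attr(rs, "summary"), file.path(d, "summary.csv"),
                   row.names = FALSE)
  log_params(d, "resample", list(resamples = cfg$resamples,
                                 seed = cfg$seed))
  invisible(rs)
}

#' Read / write one resampled dataset as plain CSV
#'
#' The on-disk cache lets downstream stages re-run without re-sampling:
#' `ages.csv` (record_id, point, age, included) and `counts.csv`
#' (record_id, point, taxon, count; zero counts omitted).
#' @param resample a `resampled_dataset`.
#' @param dir directory for this resample.
#' @export
write_resample <- function(resample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ages <- do.call(rbind, lapply(resample$records, function(rr) {
    data.frame(record_id = rr$record_id, continent = rr$continent,
               biome = rr$biome, dep_env = rr$dep_env,
               point = seq_along(rr$ages), age = rr$ages,
               included = rr$included)
  }))
  cnt <- do.call(rbind, lapply(resample$records, function(rr) {
    idx <- which(rr$counts > 0L, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(record_id = rr$record_id, point = idx[, 1L],
               taxon = colnames(rr$counts)[idx[, 2L]],
               count = rr$counts[idx])
  }))
  utils::write.csv(ages, file.path(dir, "ages.csv"), row.names = FALSE)
  utils::write.csv(cnt, file.path(dir, "counts.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_resample
#' @param index resample index to assign on read.
#' @export
read_resample <- function(dir, index) {
  ages <- utils::read.csv(file.path(dir, "ages.csv"))
  cnt <- utils::read.csv(file.path(dir, "counts.csv"))
  taxa <- sort(unique(cnt$taxon))
  recs <- lapply(split(ages, ages$record_id), function(a) {
    a <- a[order(a$point), ]
    m <- matrix(0L, nrow(a), length(taxa), dimnames = list(NULL, taxa))
    cc <- cnt[cnt$record_id == a$record_id[1L], ]
    if (nrow(cc)) {
      m[cbind(match(cc$point, a$point), match(cc$taxon, taxa))] <-
        as.integer(cc$count)
    }
    list(record_id = a$record_id[1L], continent = a$continent[1L],
         biome = a$biome[1L], dep_env = a$dep_env[1L],
         ages = a$age, counts = m, included = a$included[1L])
  })
  structure(list(resample_index = index, records = recs),
            class = "resampled_dataset")
}

stage_diversity <- function(cfg, outdir) {
  rd <- file.path(outdir, "resamples")
  need_stage(file.path(rd, "summary.csv"), "resample")
  dirs <- sort(list.dirs(rd, recursive = FALSE))
  div <- list()
  het <- list()
  for (i in seq_along(dirs)) {
    rs <- read_resample(dirs[i], i)
    div[[i]] <- diversity_series(rs)
    het[[i]] <- heterogeneity(rs, bin_width = cfg$heterogeneity$bin_width,
                              B = cfg$heterogeneity$B,
                              min_records = cfg$heterogeneity$min_records,
                              seed = derive_seed(cfg$seed, "het", i))
  }
  d <- file.path(outdir, "diversity")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(do.call(rbind, div), file.path(d, "diversity.csv"),
                   row.names = FALSE)
  hall <- do.call(rbind, het)
  utils::write.csv(hall, file.path(d, "heterogeneity.csv"),
                   row.names = FALSE)
  log_params(d, "diversity",
             list(heterogeneity = cfg$heterogeneity,
                  skipped_regions = unique(unlist(lapply(het,
                    function(h) attr(h, "skipped"))))))
  invisible(list(diversity = do.call(rbind, div), heterogeneity = hall))
}

trend_age_grid <- function(cfg) {
  seq(HOLOCENE_OLD, HOLOCENE_YOUNG, length.out = cfg$trend$age_grid_n)
}

stage_trends <- function(cfg, outdir) {
  dd <- file.path(outdir, "diversity", "diversity.csv")
  need_stage(dd, "diversity")
  div <- utils::read.csv(dd)
  grid <- trend_age_grid(cfg)
  d <- file.path(outdir, "trends")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  diagnostics <- list()
  for (met in cfg$metrics) {
    sub <- div[div$metric == met & !is.na(div$value), ]
    curves <- list()
    aic <- list()
    for (r in sort(unique(sub$resample))) {
      dat <- standardize(sub[sub$resample == r, ])
      k_use <- min(cfg$trend$k,
                   min(tapply(dat$age, dat$continent,
                              function(a) length(unique(a)))) - 1L)
      fit <- fit_region_trends(dat, k = k_use, family = cfg$trend$family)
      pr <- predict_trends(fit, grid)
      pr$resample <- r
      curves[[length(curves) + 1L]] <- pr
      if (r <= cfg$trend$aic_resamples) {
        pooled <- fit_pooled_trend(dat, k = k_use,
                                   family = cfg$trend$family)
        cmp <- compare_aic(fit, pooled)
        aic[[length(aic) + 1L]] <-
          data.frame(metric = met, resample = r,
                     delta_aic = cmp$delta_aic, verdict = cmp$verdict)
      }
    }
    allc <- do.call(rbind, curves)
    utils::write.csv(allc, file.path(d, paste0("curves_", met, ".csv")),
                     row.names = FALSE)
    utils::write.csv(summarize_resamples(allc),
                     file.path(d, paste0("summary_", met, ".csv")),
                     row.names = FALSE)
    diagnostics[[met]] <- do.call(rbind, aic)
  }
  diag <- do.call(rbind, diagnostics)
  utils::write.csv(diag, file.path(d, "aic.csv"), row.names = FALSE)
  log_params(d, "trends", cfg$trend)
  invisible(diag)
}

regional_series_from_world <- function(outdir) {
  w <- load_world_inputs(outdir)
  regional_alcc_mean(w$grid, w$map)
}

#' Land-use regressions for every region x metric x resample
#' @keywords internal
landuse_tables <- function(div, het, alcc, metrics) {
  jobs <- list()
  for (met in metrics) {
    sub <- div[div$metric == met & !is.na(div$value), ]
    for (rg in sort(unique(sub$continent))) {
      for (r in sort(unique(sub$resample))) {
        jobs[[length(jobs) + 1L]] <-
          list(kind = "records", metric = met, region = rg, resample = r,
               data = sub[sub$continent == rg & sub$resample == r, ])
      }
    }
  }
  if (!is.null(het) && nrow(het)) {
    for (met in unique(het$metric)) {
      sub <- het[het$metric == met, ]
      for (rg in sort(unique(sub$region))) {
        for (r in sort(unique(sub$resample))) {
          dd <- sub[sub$region == rg & sub$resample == r, ]
          dd <- data.frame(record_id = "bins", age = dd$bin_mid,
                           value = dd$value)
          jobs[[length(jobs) + 1L]] <-
            list(kind = "bins", metric = met, region = rg, resample = r,
                 data = dd)
        }
      }
    }
  }
  jobs
}

# metrics modelled on the standardized scale (richness is left natural)
STANDARDIZED_METRICS <- c("evenness", "turnover_bc", "turnover_jac",
                          "multi_bc", "multi_jac")

run_landuse_job <- function(job, alcc) {
  series <- alcc[[job$region]]
  if (is.null(series)) {
    stop("region '", job$region, "' missing from the ALCC series")
  }
  tab <- join_alcc(job$data, series)
  if (nrow(tab) < 3L || length(unique(tab$sqrt_alcc)) < 2L) return(NULL)
  scale <- NULL
  if (job$metric %in% STANDARDIZED_METRICS) {
    mu <- mean(tab$value)
    sd <- stats::sd(tab$value)
    if (sd == 0) return(NULL)
    scale <- data.frame(mean = mu, sd = sd)
    tab$value <- (tab$value - mu) / sd
  }
  fit <- if (job$kind == "bins") {
    fit_alcc_model_bins(tab, region = job$region, metric = job$metric,
                        scale = scale)
  } else {
    fit_alcc_model(tab, region = job$region, metric = job$metric,
                   scale = scale)
  }
  fit
}

stage_landuse <- function(cfg, outdir) {
  dd <- file.path(outdir, "diversity", "diversity.csv")
  need_stage(dd, "diversity")
  div <- utils::read.csv(dd)
  hpath <- file.path(outdir, "diversity", "heterogeneity.csv")
  het <- if (file.exists(hpath)) utils::read.csv(hpath) else NULL
  alcc <- regional_series_from_world(outdir)
  jobs <- landuse_tables(div, het, alcc, cfg$metrics)
  rows <- list()
  preds <- list()
  for (job in jobs) {
    fit <- tryCatch(run_landuse_job(job, alcc), error = function(e) NULL)
    if (is.null(fit)) next
    rows[[length(rows) + 1L]] <-
      data.frame(region = fit$region, metric = fit$metric,
                 resample = job$resample, slope = fit$slope, se = fit$se,
                 rho = fit$rho, n = fit$n)
    p <- predict_alcc(fit)
    p$resample <- job$resample
    preds[[length(preds) + 1L]] <- p
  }
  d <- file.path(outdir, "landuse")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(do.call(rbind, rows), file.path(d, "fits.csv"),
                   row.names = FALSE)
  bands <- summarize_alcc_fits(do.call(rbind, preds))
  utils::write.csv(bands, file.path(d, "bands.csv"), row.names = FALSE)
  log_params(d, "landuse", list(metrics = cfg$metrics,
                                standardized = STANDARDIZED_METRICS))
  invisible(do.call(rbind, rows))
}

stage_slopes <- function(cfg, outdir) {
  dd <- file.path(outdir, "diversity", "diversity.csv")
  need_stage(dd, "diversity")
  div <- utils::read.csv(dd)
  med <- median_diversity(split(div, div$resample))
  slope_metrics <- c("richness", "evenness", "turnover_bc_raw",
                     "turnover_jac_raw")
  res <- list()
  for (p in holocene_periods()$label) {
    for (met in intersect(slope_metrics, unique(med$metric))) {
      res[[length(res) + 1L]] <-
        period_slopes(med, p, met, min_points = cfg$slopes$min_points)
    }
  }
  slopes <- do.call(rbind, res)
  d <- file.path(outdir, "slopes")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(slopes, file.path(d, "slopes.csv"), row.names = FALSE)
  utils::write.csv(summarize_slopes(slopes),
                   file.path(d, "slope_summary.csv"), row.names = FALSE)
  log_params(d, "slopes", cfg$slopes)
  invisible(slopes)
}

#' Leave-one-depositional-environment-out sensitivity analysis
#'
#' Reruns the trend and land-use analyses on the median-over-resamples
#' diversity values with all records from one depositional environment
#' excluded, iterating over environments.  Regions dropping below the
#' heterogeneity record rule after exclusion are skipped and reported.
#'
#' @param med median diversity table ([median_diversity()]).
#' @param alcc named list of regional `alcc_series`.
#' @param metrics metrics to refit.
#' @param k,family trend model settings.
#' @param age_grid prediction grid.
#' @param min_region_records minimum records per region for a trend refit.
#' @param envs environments to exclude in turn (default: those present in
#'   the data; an environment with zero records reproduces the full
#'   analysis exactly).
#' @return list with `full` and one entry per excluded environment, each
#'   holding `trends` (data.frame region, age, fit, metric) and `landuse`
#'   (data.frame region, metric, slope, se, rho); skipped region x metric
#'   combinations are recorded in `skipped`.
#' @export
sensitivity_loo <- function(med, alcc, metrics = c("richness", "evenness"),
                            k = 12L, family = "gaussian",
                            age_grid = seq(11700, 100, length.out = 60L),
                            min_region_records = 2L, envs = NULL) {
  if (is.null(envs)) envs <- sort(unique(med$dep_env))
  run_subset <- function(dat) {
    trends <- list()
    lu <- list()
    skipped <- character(0)
    for (met in metrics) {
      sub <- dat[dat$metric == met & !is.na(dat$value), ]
      per_reg <- tapply(sub$record_id, sub$continent,
                        function(x) length(unique(x)))
      bad <- names(per_reg)[per_reg < min_region_records]
      if (length(bad)) {
        skipped <- c(skipped, paste0(met, ":", bad))
        sub <- sub[!sub$continent %in% bad, ]
      }
      if (!nrow(sub)) next
      dat_st <- standardize(sub)
      k_use <- min(k, min(tapply(dat_st$age, dat_st$continent,
                                 function(a) length(unique(a)))) - 1L)
      fit <- fit_region_trends(dat_st, k = k_use, family = family)
      pr <- predict_trends(fit, age_grid)
      pr$metric <- met
      trends[[met]] <- pr
      for (rg in sort(unique(sub$continent))) {
        series <- alcc[[rg]]
        if (is.null(series)) next
        tab <- join_alcc(sub[sub$continent == rg, ], series)
        if (nrow(tab) < 3L || length(unique(tab$sqrt_alcc)) < 2L) next
        scale <- NULL
        if (met %in% STANDARDIZED_METRICS) {
          mu <- mean(tab$value); sdv <- stats::sd(tab$value)
          if (sdv == 0) next
          scale <- data.frame(mean = mu, sd = sdv)
          tab$value <- (tab$value - mu) / sdv
        }
        f <- tryCatch(fit_alcc_model(tab, region = rg, metric = met,
                                     scale = scale),
                      error = function(e) NULL)
        if (!is.null(f)) {
          lu[[length(lu) + 1L]] <- data.frame(region = rg, metric = met,
                                              slope = f$slope, se = f$se,
                                              rho = f$rho)
        }
      }
    }
    list(trends = do.call(rbind, trends), landuse = do.call(rbind, lu),
         skipped = skipped)
  }
  out <- list(full = run_subset(med))
  for (ev in envs) {
    out[[ev]] <- run_subset(med[med$dep_env != ev, ])
  }
  out
}

stage_sensitivity <- function(cfg, outdir) {
  dd <- file.path(outdir, "diversity", "diversity.csv")
  need_stage(dd, "diversity")
  div <- utils::read.csv(dd)
  med <- median_diversity(split(div, div$resample))
  alcc <- regional_series_from_world(outdir)
  k <- min(cfg$trend$k, 20L)
  res <- sensitivity_loo(med, alcc, metrics = cfg$metrics, k = k,
                         family = cfg$trend$family,
                         age_grid = trend_age_grid(cfg))
  d <- file.path(outdir, "sensitivity")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  tr <- do.call(rbind, lapply(names(res), function(nm) {
    if (is.null(res[[nm]]$trends)) return(NULL)
    cbind(excluded = nm, res[[nm]]$trends)
  }))
  lu <- do.call(rbind, lapply(names(res), function(nm) {
    if (is.null(res[[nm]]$landuse)) return(NULL)
    cbind(excluded = nm, res[[nm]]$landuse)
  }))
  utils::write.csv(tr, file.path(d, "trend_curves.csv"), row.names = FALSE)
  utils::write.csv(lu, file.path(d, "landuse_fits.csv"), row.names = FALSE)
  log_params(d, "sensitivity",
             list(k = k, skipped = unique(unlist(lapply(res, `[[`,
                                                        "skipped")))))
  invisible(res)
}

# ---------------------------------------------------------------------------

PIPELINE_STAGES <- c("simulate", "filter", "resample", "diversity",
                     "trends", "landuse", "slopes", "sensitivity")

#' Run pipeline stages
#'
#' Orchestrates the full chain `simulate | filter | resample | diversity |
#' trends | landuse | slopes | sensitivity`; `"all"` runs every stage in
#' order.  Each stage reads its predecessors' outputs from `outdir` and
#' writes its own artifacts plus a `stage_params.json` log; the whole tree
#' is a pure function of (config, seed).
#'
#' @param subcommand one of the stage names or `"all"`.
#' @param config configuration list ([default_pipeline_config()]) or path
#'   to a YAML file.
#' @param outdir output directory.
#' @param seed optional master-seed override.
#' @param resamples optional override of the resample count.
#' @export
run_pipeline <- function(subcommand, config = test_pipeline_config(),
                         outdir = "pollendiv_out", seed = NULL,
                         resamples = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    config$world$seed <- as.integer(seed)
  }
  if (!is.null(resamples)) config$resamples <- as.integer(resamples)
  stages <- if (identical(subcommand, "all")) PIPELINE_STAGES
            else match.arg(subcommand, PIPELINE_STAGES)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (st in stages) {
    fn <- switch(st,
                 simulate = stage_simulate, filter = stage_filter,
                 resample = stage_resample, diversity = stage_diversity,
                 trends = stage_trends, landuse = stage_landuse,
                 slopes = stage_slopes, sensitivity = stage_sensitivity)
    fn(config, outdir)
  }
  invisible(outdir)
}

#' Command-line entry point
#'
#' `Rscript -e 'pollendiv::cli_main()' <subcommand> --config cfg.yml
#' --outdir out --seed 1 --resamples 25`; see [run_pipeline()] for the
#' subcommands.
#' @param args character vector of CLI arguments.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1L] %in% c("-h", "--help")) {
    cat("usage: pollendiv <", paste(c(PIPELINE_STAGES, "all"),
                                    collapse = " | "),
        "> [--config FILE] [--outdir DIR] [--seed N] [--resamples N]\n")
    return(invisible(0L))
  }
  sub <- args[1L]
  opt <- list(config = NULL, outdir = "pollendiv_out", seed = NULL,
              resamples = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) && key != "log-level") {
      stop("unknown option: ", args[i])
    }
    if (key != "log-level") opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  config <- if (is.null(opt$config)) test_pipeline_config()
            else read_pipeline_config(opt$config)
  run_pipeline(sub, config = config, outdir = opt$outdir,
               seed = if (!is.null(opt$seed)) as.integer(opt$seed),
               resamples = if (!is.null(opt$resamples))
                 as.integer(opt$resamples))
  invisible(0L)
}
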