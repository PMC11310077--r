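#' Pairwise dissimilarity between two count vectors
#'
#' `bray_curtis()` is the abundance-based Bray-Curtis index,
#' `sum(|x - y|) / sum(x + y)`; `jaccard()` is the incidence-based Jaccard
#' index, `1 - |shared types| / |union of types|`.  Both are symmetric,
#' bounded in `[0, 1]` and zero on identical input.
#'
#' @param x,y non-negative count vectors on the same taxon axis.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  tot <- sum(x) + sum(y)
  if (sum(x) == 0 || sum(y) == 0) {
    stop("Bray-Curtis undefined for an empty sample")
  }
  sum(abs(x - y)) / tot
}

#' @rdname bray_curtis
#' @export
jaccard <- function(x, y) {
  stopifnot(length(x) == length(y))
  px <- x > 0
  py <- y > 0
  u <- sum(px | py)
  if (u == 0L) stop("Jaccard undefined for two empty samples")
  1 - sum(px & py) / u
}

#' Rarefied richness and Pielou evenness
#'
#' Computed on samples rarefied to exactly 300 grains so values are
#' comparable across records.  Richness is the number of pollen types with a
#' nonzero count; evenness is Shannon entropy over relative abundances
#' divided by its maximum `log(S)`.  For monotypic samples (`S = 1`) evenness
#' is undefined and returned as `NA` (excluded from downstream models).
#'
#' @param counts integer count vector summing to `n`.
#' @param n the rarefaction total (default 300).
#' @export
richness <- function(counts, n = 300L) {
  if (sum(counts) != n) {
    stop("richness is defined on rarefied counts summing to ", n,
         " (got ", sum(counts), ")")
  }
  sum(counts > 0L)
}

#' @rdname richness
#' @export
evenness <- function(counts, n = 300L) {
  if (sum(counts) != n) {
    stop("evenness is defined on rarefied counts summing to ", n,
         " (got ", sum(counts), ")")
  }
  p <- counts[counts > 0L] / n
  s <- length(p)
  if (s < 2L) return(NA_real_)
  -sum(p * log(p)) / log(s)
}

#' Interval-adjust sequential turnover values
#'
#' Samples separated by a longer time interval are expected to be more
#' dissimilar.  The expected turnover given elapsed time is estimated by an
#' ordinary least-squares fit of raw dissimilarity on `log(interval + 1)`,
#' pooled over all sequential pairs in the dataset (one fit per metric per
#' resample), and subtracted: `adjusted = raw - expected`.  Adjusted values
#' therefore average zero over the dataset and may be negative.  When all
#' intervals coincide (or fewer than two distinct intervals exist) the
#' expectation degenerates to the global mean.
#'
#' @param pairs data.frame with columns `interval` (yr, >= 0) and `raw`.
#' @param model `"log-linear"` (default) or `"spline"` (natural spline of
#'   the same predictor, for sensitivity checks).
#' @return `pairs` with columns `expected` and `adjusted` added.
#' @export
adjust_turnover <- function(pairs, model = c("log-linear", "spline")) {
  model <- match.arg(model)
  if (!nrow(pairs)) {
    pairs$expected <- numeric(0)
    pairs$adjusted <- numeric(0)
    return(pairs)
  }
  stopifnot(all(pairs$interval >= 0))
  x <- log(pairs$interval + 1)
  if (length(unique(x)) < 2L) {
    pairs$expected <- mean(pairs$raw)
  } else if (model == "log-linear") {
    fit <- stats::lm.fit(cbind(1, x), pairs$raw)
    pairs$expected <- fit$fitted.values
  } else {
    k <- min(4L, length(unique(x)) - 1L)
    fit <- stats::smooth.spline(x, pairs$raw, df = max(2L, k))
    pairs$expected <- stats::predict(fit, x)$y
  }
  pairs$adjusted <- pairs$raw - pairs$expected
  pairs
}

#' Diversity series for one resampled dataset
#'
#' Computes the four within-record metrics on one joint resample: richness
#' and Pielou evenness per sample, and raw plus interval-adjusted turnover
#' (Bray-Curtis and Jaccard) between depth-consecutive samples.  Turnover
#' adjustment is pooled across all records in the dataset, per metric.
#' Turnover points are dated at the midpoint of the two samples' ages.
#'
#' @param resample a resampled dataset from [build_resample()].
#' @param turnover_model passed to [adjust_turnover()].
#' @return long data.frame: record_id, continent, biome, dep_env, age,
#'   metric (`richness`, `evenness`, `turnover_bc`, `turnover_jac`,
#'   `turnover_bc_raw`, `turnover_jac_raw`), value, resample.
#' @export
diversity_series <- function(resample, turnover_model = "log-linear") {
  recs <- Filter(function(x) x$included, resample$records)
  if (!length(recs)) return(empty_diversity())

  sample_rows <- do.call(rbind, lapply(recs, function(rr) {
    ok <- which(!is.na(rr$ages))
    m <- rr$counts[ok, , drop = FALSE]
    data.frame(
      record_id = rr$record_id, continent = rr$continent, biome = rr$biome,
      dep_env = rr$dep_env,
      point = rep(ok, 2L), # depth-order sample index: stable across resamples
      age = rep(rr$ages[ok], 2L),
      metric = rep(c("richness", "evenness"), each = length(ok)),
      value = c(apply(m, 1L, richness), apply(m, 1L, evenness))
    )
  }))

  pair_rows <- do.call(rbind, lapply(recs, function(rr) {
    ok <- which(!is.na(rr$ages))
    if (length(ok) < 2L) return(NULL)
    i <- ok[-length(ok)]
    j <- ok[-1L]
    m <- rr$counts
    data.frame(
      record_id = rr$record_id, continent = rr$continent, biome = rr$biome,
      dep_env = rr$dep_env,
      point = i, # keyed by the older sample of the pair
      age = (rr$ages[i] + rr$ages[j]) / 2,
      interval = abs(rr$ages[j] - rr$ages[i]),
      bc = vapply(seq_along(i),
                  function(k) bray_curtis(m[i[k], ], m[j[k], ]), 0),
      jac = vapply(seq_along(i),
                   function(k) jaccard(m[i[k], ], m[j[k], ]), 0)
    )
  }))

  out <- sample_rows
  if (!is.null(pair_rows) && nrow(pair_rows)) {
    for (met in c("bc", "jac")) {
      adj <- adjust_turnover(
        data.frame(interval = pair_rows$interval, raw = pair_rows[[met]]),
        model = turnover_model
      )
      out <- rbind(
        out,
        data.frame(record_id = pair_rows$record_id,
                   continent = pair_rows$continent, biome = pair_rows$biome,
                   dep_env = pair_rows$dep_env, point = pair_rows$point,
                   age = pair_rows$age,
                   metric = paste0("turnover_", met), value = adj$adjusted),
        data.frame(record_id = pair_rows$record_id,
                   continent = pair_rows$continent, biome = pair_rows$biome,
                   dep_env = pair_rows$dep_env, point = pair_rows$point,
                   age = pair_rows$age,
                   metric = paste0("turnover_", met, "_raw"),
                   value = adj$raw)
      )
    }
  }
  out$resample <- resample$resample_index
  rownames(out) <- NULL
  out
}

empty_diversity <- function() {
  data.frame(record_id = character(0), continent = character(0),
             biome = character(0), dep_env = character(0),
             point = integer(0), age = numeric(0), metric = character(0),
             value = numeric(0), resample = integer(0))
}

#' Median diversity values across resamples
#'
#' Collapses a list of per-resample diversity tables to one table with the
#' median value (and median age) per record x metric x sample point - the
#' reduced dataset the sensitivity analysis operates on.
#' @param div_list list of [diversity_series()] outputs.
#' @return one long data.frame without a `resample` column.
#' @export
median_diversity <- function(div_list) {
  all <- do.call(rbind, div_list)
  all <- all[!is.na(all$value), , drop = FALSE]
  sp <- split(all, list(all$record_id, all$metric, all$point), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(record_id = d$record_id[1L], continent = d$continent[1L],
               biome = d$biome[1L], dep_env = d$dep_env[1L],
               point = d$point[1L], age = stats::median(d$age),
               metric = d$metric[1L], value = stats::median(d$value))
  }))
  rownames(out) <- NULL
  out[order(out$record_id, out$metric, out$point), ]
}
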