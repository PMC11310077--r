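#' Join diversity points to regional land-use values
#'
#' Restricts to the land-use analysis window (8,000-100 cal yr BP), matches
#' each point's age to the regional ALCC series at the rounded year, and
#' attaches `sqrt_alcc = sqrt(fraction)` (the regression predictor).
#'
#' @param points data.frame with at least `age`; region implicit (one
#'   series per call).
#' @param series an `alcc_series` for the points' region.
#' @return `points` with `alcc` and `sqrt_alcc` columns, out-of-window rows
#'   dropped.
#' @export
join_alcc <- function(points, series) {
  if (!inherits(series, "alcc_series")) stop("series must be an alcc_series")
  lo <- min(series$years)
  hi <- max(series$years)
  keep <- !is.na(points$age) & points$age >= lo & points$age <= hi
  out <- points[keep, , drop = FALSE]
  out$alcc <- alcc_at(series, out$age)
  out$sqrt_alcc <- sqrt(out$alcc)
  rownames(out) <- NULL
  out
}

# pooled lag-1 autocorrelation of residuals within blocks (records), each
# block ordered chronologically; white-noise band is 1.96 / sqrt(N)
pooled_acf1 <- function(res, block) {
  num <- 0
  den <- sum(res^2)
  for (b in split(seq_along(res), block)) {
    if (length(b) < 2L) next
    r <- res[b]
    num <- num + sum(r[-length(r)] * r[-1L])
  }
  if (den == 0) return(0)
  num / den
}

#' Mixed regression of diversity on square-root land use
#'
#' Stage 1 fits `value ~ sqrt_alcc + s(record, bs = "re")` by fast REML.
#' Stage 2 computes the lag-1 autocorrelation of the residuals within
#' records (each record's samples in chronological order); when it exceeds
#' the white-noise 95% band `1.96 / sqrt(N)` the model is refit with AR(1)
#' working residuals at `rho = acf1`.  With a single record the random
#' intercept is dropped.
#'
#' Standardization (turnover, evenness, heterogeneity are standardized
#' before modelling) is the caller's concern; pass `scale` so predictions
#' can be back-transformed.
#'
#' @param table output of [join_alcc()] with columns `record_id`, `age`,
#'   `value`, `sqrt_alcc`.
#' @param region,metric labels stored on the fit.
#' @param scale optional one-row standardization scale (mean, sd) used by
#'   [predict_alcc()] to return natural-scale predictions.
#' @return an `alcc_fit`: list(region, metric, slope, se, intercept, rho,
#'   acf1, n, alcc_range, model, scale).
#' @export
fit_alcc_model <- function(table, region = "region", metric = "metric",
                           scale = NULL) {
  tab <- table[!is.na(table$value), , drop = FALSE]
  if (nrow(tab) < 3L) stop("too few points for the land-use model")
  # chronological order within record (old -> young)
  tab <- tab[order(tab$record_id, -tab$age), , drop = FALSE]
  tab$record <- factor(tab$record_id)
  multi_record <- nlevels(tab$record) > 1L
  form <- if (multi_record) {
    value ~ sqrt_alcc + s(record, bs = "re")
  } else {
    value ~ sqrt_alcc
  }
  m1 <- mgcv::bam(form, data = tab, method = "fREML")
  res <- stats::residuals(m1)
  acf1 <- pooled_acf1(res, tab$record)
  band <- 1.96 / sqrt(length(res))
  rho <- 0
  m <- m1
  if (abs(acf1) > band) {
    rho <- acf1
    ar_start <- !duplicated(tab$record)
    m <- mgcv::bam(form, data = tab, method = "fREML", rho = rho,
                   AR.start = ar_start)
  }
  pt <- summary(m)$p.table
  structure(list(region = region, metric = metric,
                 slope = pt["sqrt_alcc", 1L], se = pt["sqrt_alcc", 2L],
                 intercept = pt["(Intercept)", 1L],
                 rho = rho, acf1 = acf1, acf_band = band,
                 n = nrow(tab), n_records = nlevels(tab$record),
                 alcc_range = range(tab$alcc), model = m,
                 record_levels = levels(tab$record), scale = scale),
            class = "alcc_fit")
}

#' Ordinary land-use regression for binned heterogeneity
#'
#' Heterogeneity has one value per region x bin (no record structure), so
#' the model is an ordinary regression of bin values on the bin-mean
#' sqrt-ALCC, with the same lag-1 rule applied to the bin-ordered residual
#' sequence; an AR(1) refit uses the Prais-Winsten transform.
#'
#' @param table data.frame with `age` (bin midpoint), `value`, `alcc`,
#'   `sqrt_alcc`, chronologically orderable.
#' @inheritParams fit_alcc_model
#' @export
fit_alcc_model_bins <- function(table, region = "region", metric = "metric",
                                scale = NULL) {
  tab <- table[!is.na(table$value), , drop = FALSE]
  if (nrow(tab) < 3L) stop("too few bins for the land-use model")
  tab <- tab[order(-tab$age), , drop = FALSE]
  m1 <- stats::lm(value ~ sqrt_alcc, data = tab)
  res <- stats::residuals(m1)
  acf1 <- pooled_acf1(res, rep(1L, length(res)))
  band <- 1.96 / sqrt(length(res))
  rho <- 0
  m <- m1
  if (abs(acf1) > band) {
    rho <- acf1
    y <- tab$value
    x <- tab$sqrt_alcc
    n <- length(y)
    ys <- c(sqrt(1 - rho^2) * y[1L], y[-1L] - rho * y[-n])
    x0s <- c(sqrt(1 - rho^2), rep(1 - rho, n - 1L))
    xs <- c(sqrt(1 - rho^2) * x[1L], x[-1L] - rho * x[-n])
    m <- stats::lm(ys ~ 0 + x0s + xs)
  }
  co <- summary(m)$coefficients
  slope_row <- grep("^xs$|^sqrt_alcc$", rownames(co))
  int_row <- grep("^x0s$|Intercept", rownames(co))
  structure(list(region = region, metric = metric,
                 slope = co[slope_row, 1L], se = co[slope_row, 2L],
                 intercept = co[int_row, 1L],
                 rho = rho, acf1 = acf1, acf_band = band,
                 n = nrow(tab), n_records = NA_integer_,
                 alcc_range = range(tab$alcc), model = m,
                 record_levels = NULL, scale = scale),
            class = "alcc_fit")
}

#' Predict a land-use fit over its observed ALCC range
#'
#' Fixed-effect prediction `intercept + slope * sqrt(alcc)` (random record
#' intercepts excluded), back-transformed through the stored
#' standardization when present; the x-axis is the ALCC fraction.
#' @param fit an `alcc_fit`.
#' @param alcc fraction grid; default 50 points over the observed range.
#' @return data.frame(region, metric, alcc, fit).
#' @export
predict_alcc <- function(fit, alcc = NULL) {
  if (is.null(alcc)) {
    alcc <- seq(fit$alcc_range[1L], fit$alcc_range[2L], length.out = 50L)
  }
  y <- fit$intercept + fit$slope * sqrt(alcc)
  if (!is.null(fit$scale)) y <- y * fit$scale$sd + fit$scale$mean
  data.frame(region = fit$region, metric = fit$metric, alcc = alcc, fit = y)
}

#' Median / interquartile prediction bands across resamples
#' @param preds data.frame stacking [predict_alcc()] outputs with a
#'   `resample` column.
#' @return data.frame(region, metric, alcc, median, q25, q75).
#' @export
summarize_alcc_fits <- function(preds) {
  agg <- stats::aggregate(
    preds["fit"], by = preds[c("region", "metric", "alcc")],
    FUN = function(v) c(stats::median(v),
                        unname(stats::quantile(v, c(0.25, 0.75), type = 7)))
  )
  out <- data.frame(region = agg$region, metric = agg$metric,
                    alcc = agg$alcc, median = agg$fit[, 1L],
                    q25 = agg$fit[, 2L], q75 = agg$fit[, 3L])
  out[order(out$region, out$metric, out$alcc), ]
}
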