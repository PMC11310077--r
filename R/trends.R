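#' Standardize diversity values within regions
#'
#' Subtracts the region mean and divides by the region standard deviation
#' (denominator `n - 1`), the transformation applied before model fitting;
#' the stored scale makes the inverse exact.
#'
#' @param df data.frame with at least the region and value columns.
#' @param region_col,value_col column names.
#' @return `df` with a `value_st` column and attribute `scale` (data.frame
#'   region, mean, sd).
#' @export
standardize <- function(df, region_col = "continent", value_col = "value") {
  regions <- unique(df[[region_col]])
  sc <- do.call(rbind, lapply(regions, function(rg) {
    v <- df[[value_col]][df[[region_col]] == rg]
    v <- v[!is.na(v)]
    if (length(unique(v)) < 2L) {
      stop("region '", rg, "' has zero variance; cannot standardize")
    }
    data.frame(region = rg, mean = mean(v), sd = stats::sd(v))
  }))
  i <- match(df[[region_col]], sc$region)
  df$value_st <- (df[[value_col]] - sc$mean[i]) / sc$sd[i]
  attr(df, "scale") <- sc
  df
}

#' @rdname standardize
#' @param values standardized values.
#' @param region region label(s) to look up in the scale.
#' @param scale the `scale` attribute produced by [standardize()].
#' @export
unstandardize <- function(values, region, scale) {
  i <- match(region, scale$region)
  values * scale$sd[i] + scale$mean[i]
}

#' Fit region-wise smooth diversity trends
#'
#' The trend model: standardized diversity against age with one penalized
#' spline per region (basis dimension `k`, smoothing parameters by REML or
#' its fast variant) plus a region intercept and a random intercept per
#' record, `value_st ~ region + s(age, by = region, k = k) + s(record, bs =
#' "re")`.  With a single region the region terms collapse to one smooth;
#' with a single record the random intercept is dropped.  The `scat` family
#' (scaled t) covers heavy-tailed conditional distributions; `"auto"` picks
#' it when the Gaussian fit's residual excess kurtosis exceeds 1.
#'
#' @param df data.frame with columns `age`, `value_st`, `record_id`, and the
#'   region column; typically the output of [standardize()].
#' @param k basis dimension per region smooth (study default 50; capped
#'   errors rather than silently shrinking).
#' @param family `"gaussian"`, `"scat"` or `"auto"`.
#' @param region_col region column name.
#' @param engine `"auto"` (bam with discretization for large data, gam
#'   otherwise), `"gam"` or `"bam"`.
#' @param spline_m penalty order of the thin-plate smooth (`NULL` = mgcv
#'   default, which penalizes curvature); order `p` leaves polynomials of
#'   degree `< p` unpenalized, so e.g. `spline_m = 4` reproduces a cubic
#'   trend exactly from noiseless data.
#' @return a `region_trend_fit`: list(model, scale, regions, k, family,
#'   engine).
#' @export
fit_region_trends <- function(df, k = 50L, family = "gaussian",
                              region_col = "continent", engine = "auto",
                              spline_m = NULL) {
  df <- df[!is.na(df$value_st), , drop = FALSE]
  df$region <- factor(df[[region_col]])
  df$record <- factor(df$record_id)
  n_unique <- min(tapply(df$age, df$region, function(a) length(unique(a))))
  if (n_unique < 5L) {
    stop("a region has only ", n_unique, " unique ages; too few for a ",
         "penalized spline - supply more data or a smaller k")
  }
  if (k > n_unique) {
    stop("k = ", k, " exceeds the smallest region's unique ages (",
         n_unique, "); use a smaller k")
  }
  multi_region <- nlevels(df$region) > 1L
  multi_record <- nlevels(df$record) > 1L
  marg <- if (is.null(spline_m)) "" else sprintf(", m = %d", spline_m)
  rhs <- c(
    if (multi_region) "region",
    if (multi_region)
      sprintf("s(age, by = region, bs = 'tp', k = %d%s)", k, marg)
    else sprintf("s(age, bs = 'tp', k = %d%s)", k, marg),
    if (multi_record) "s(record, bs = 're')"
  )
  form <- stats::as.formula(paste("value_st ~", paste(rhs, collapse = " + ")))
  fit1 <- fit_gam(form, df, family = if (family == "auto") "gaussian"
                  else family, engine = engine)
  chosen <- family
  if (family == "auto") {
    r <- stats::residuals(fit1)
    exk <- mean((r - mean(r))^4) / stats::var(r)^2 - 3
    chosen <- if (is.finite(exk) && exk > 1) "scat" else "gaussian"
    if (chosen == "scat") {
      fit1 <- fit_gam(form, df, family = "scat", engine = engine)
    }
  }
  structure(list(model = fit1, scale = attr(df, "scale"),
                 regions = levels(df$region), k = k, family = chosen,
                 engine = engine, n = nrow(df),
                 response_checksum = sum(df$value_st^2)),
            class = "region_trend_fit")
}

#' @rdname fit_region_trends
#' @description `fit_pooled_trend()` is the reduced comparison model: one
#'   global smooth, no region terms (random record intercepts retained).
#' @export
fit_pooled_trend <- function(df, k = 50L, family = "gaussian",
                             region_col = "continent", engine = "auto") {
  df <- df[!is.na(df$value_st), , drop = FALSE]
  df$region <- factor(df[[region_col]])
  df$record <- factor(df$record_id)
  multi_record <- nlevels(df$record) > 1L
  n_unique <- length(unique(df$age))
  if (k > n_unique) k <- max(5L, n_unique - 1L)
  rhs <- c(sprintf("s(age, bs = 'tp', k = %d)", k),
           if (multi_record) "s(record, bs = 're')")
  form <- stats::as.formula(paste("value_st ~", paste(rhs, collapse = " + ")))
  fit1 <- fit_gam(form, df, family = if (family == "auto") "gaussian"
                  else family, engine = engine)
  structure(list(model = fit1, scale = attr(df, "scale"),
                 regions = levels(df$region), k = k, family = family,
                 engine = engine, n = nrow(df),
                 response_checksum = sum(df$value_st^2)),
            class = "region_trend_fit")
}

fit_gam <- function(form, df, family = "gaussian", engine = "auto") {
  fam <- switch(family,
                gaussian = stats::gaussian(),
                scat = mgcv::scat(),
                stop("unknown family: ", family))
  use_bam <- engine == "bam" || (engine == "auto" && nrow(df) >= 4000L)
  if (use_bam) {
    mgcv::bam(form, data = df, family = fam, method = "fREML",
              discrete = TRUE)
  } else {
    mgcv::gam(form, data = df, family = fam, method = "REML")
  }
}

#' Model degrees of freedom, likelihood and AIC
#'
#' AIC is defined as `2 * edf - 2 * loglik` with `edf` the total effective
#' degrees of freedom of the fit (penalized terms counted at their
#' effective, not raw, dimension).
#' @param fit a `region_trend_fit`.
#' @return data.frame(edf, loglik, aic).
#' @export
fit_diagnostics <- function(fit) {
  m <- fit$model
  edf <- sum(m$edf) + if (!is.null(m$family$n.theta)) m$family$n.theta else 0
  ll <- as.numeric(stats::logLik(m))
  data.frame(edf = edf, loglik = ll, aic = 2 * edf - 2 * ll)
}

#' Compare region-structured vs pooled trend models by AIC
#'
#' A drop of two or more AIC units when region smooths are included is read
#' as a significant improvement (verdict `"region-structured"`).
#' @param full fit with per-region smooths.
#' @param pooled fit with a single global smooth on the same data.
#' @return list(delta_aic, verdict, aic_full, aic_pooled).
#' @export
compare_aic <- function(full, pooled) {
  if (full$n != pooled$n ||
      abs(full$response_checksum - pooled$response_checksum) > 1e-6) {
    stop("compare_aic: the two fits are not on identical data")
  }
  a_full <- fit_diagnostics(full)$aic
  a_pooled <- fit_diagnostics(pooled)$aic
  delta <- a_pooled - a_full
  list(delta_aic = delta,
       verdict = if (delta >= 2) "region-structured" else "no-improvement",
       aic_full = a_full, aic_pooled = a_pooled)
}

#' Predict regional trend curves on the natural scale
#'
#' Evaluates each region's smooth (plus region intercept, excluding the
#' record random effect) on an age grid and back-transforms through the
#' stored standardization.
#' @param fit a `region_trend_fit`.
#' @param ages age grid (cal yr BP).
#' @param se_mult half-width of the reported interval in standard errors.
#' @return data.frame(region, age, fit, lower, upper) on the natural scale
#'   (standardized scale if the fit carries no scale).
#' @export
predict_trends <- function(fit, ages, se_mult = 2) {
  m <- fit$model
  rec0 <- m$model$record[1L] %||% NULL
  out <- do.call(rbind, lapply(fit$regions, function(rg) {
    nd <- data.frame(age = ages, region = factor(rg, levels = fit$regions))
    if (!is.null(rec0)) nd$record <- rec0
    pr <- mgcv::predict.gam(m, nd, se.fit = TRUE,
                            exclude = "s(record)",
                            newdata.guaranteed = TRUE)
    data.frame(region = rg, age = ages, fit = as.numeric(pr$fit),
               lower = as.numeric(pr$fit - se_mult * pr$se.fit),
               upper = as.numeric(pr$fit + se_mult * pr$se.fit))
  }))
  if (!is.null(fit$scale)) {
    out$fit <- unstandardize(out$fit, out$region, fit$scale)
    out$lower <- unstandardize(out$lower, out$region, fit$scale)
    out$upper <- unstandardize(out$upper, out$region, fit$scale)
  }
  rownames(out) <- NULL
  out
}

#' Smooth-term significance
#' @param fit a `region_trend_fit`.
#' @return data.frame(term, edf, p_value) for the smooth terms.
#' @export
smooth_pvalues <- function(fit) {
  s <- summary(fit$model)$s.table
  data.frame(term = rownames(s), edf = s[, "edf"],
             p_value = s[, ncol(s)], row.names = NULL)
}

#' Summarize per-resample curves as median and interquartile bands
#'
#' @param curves data.frame(region, age, fit, resample) stacking
#'   [predict_trends()] output over resamples.
#' @return data.frame(region, age, median, q25, q75) using the linear
#'   interpolation percentile convention.
#' @export
summarize_resamples <- function(curves) {
  agg <- stats::aggregate(
    curves["fit"], by = curves[c("region", "age")],
    FUN = function(v) c(stats::median(v),
                        unname(stats::quantile(v, c(0.25, 0.75), type = 7)))
  )
  out <- data.frame(region = agg$region, age = agg$age,
                    median = agg$fit[, 1L], q25 = agg$fit[, 2L],
                    q75 = agg$fit[, 3L])
  out <- out[order(out$region, -out$age), ]
  rownames(out) <- NULL
  out
}
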