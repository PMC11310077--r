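#' Calibration curves
#'
#' A calibration curve maps calendar age (cal yr BP) to the mean and 1-sigma
#' of the radiocarbon age measured for material of that calendar age.  Files
#' use the published curves' column order (cal_age, c14_age, sigma), so real
#' Northern/Southern-Hemisphere curves can be dropped in as 3-column CSVs.
#'
#' @param cal_age strictly increasing grid of calendar ages (cal yr BP).
#' @param c14_age curve mean 14C age at each grid point.
#' @param sigma curve 1-sigma (> 0).
#' @export
calibration_curve <- function(cal_age, c14_age, sigma) {
  stopifnot(length(cal_age) == length(c14_age),
            length(sigma) %in% c(1L, length(cal_age)))
  if (any(diff(cal_age) <= 0)) stop("cal_age must be strictly increasing")
  if (any(sigma <= 0)) stop("curve sigma must be > 0")
  structure(list(cal_age = as.numeric(cal_age),
                 c14_age = as.numeric(c14_age),
                 sigma = rep_len(as.numeric(sigma), length(cal_age))),
            class = "calibration_curve")
}

#' @rdname calibration_curve
#' @param path CSV path with columns cal_age, c14_age, sigma.
#' @export
read_calibration_curve <- function(path) {
  df <- utils::read.csv(path)
  calibration_curve(df[[1L]], df[[2L]], df[[3L]])
}

#' @rdname calibration_curve
#' @param curve a `calibration_curve`.
#' @export
write_calibration_curve <- function(curve, path) {
  utils::write.csv(data.frame(cal_age = curve$cal_age,
                              c14_age = curve$c14_age,
                              sigma = curve$sigma),
                   path, row.names = FALSE)
  invisible(path)
}

#' Pick the hemisphere-appropriate curve
#'
#' Sites at latitude >= 0 use the northern curve, others the southern curve;
#' no mixed curve is used for the tropics.
#' @param lat site latitude, decimal degrees.
#' @param curves named list with elements `northern` and `southern`.
#' @export
curve_for_latitude <- function(lat, curves) {
  if (is.na(lat)) stop("latitude required to select a calibration curve")
  if (lat >= 0) curves$northern else curves$southern
}

#' Calibrate one chronological control
#'
#' For a radiocarbon control the posterior over calendar age on the curve's
#' grid is proportional to
#' `Normal(measured; curve_mean(cal), sqrt(error^2 + curve_sigma(cal)^2))`,
#' normalized to sum to 1.  Calendar-kind controls return a discretized
#' Gaussian directly (the curve only supplies the grid).
#'
#' @param age measured age (14C yr BP for radiocarbon, cal yr BP for
#'   calendar controls).
#' @param error 1-sigma measurement error (yr).
#' @param kind `"radiocarbon"` or `"calendar"`.
#' @param curve a [calibration_curve].
#' @return data.frame with `cal_age` and `density` (probability mass summing
#'   to 1 on the grid).
#' @export
calibrate <- function(age, error, kind, curve) {
  stopifnot(error > 0)
  if (kind == "calendar") {
    d <- stats::dnorm(curve$cal_age, age, error)
  } else if (kind == "radiocarbon") {
    rng <- range(curve$c14_age)
    if (age < rng[1L] - 3 * error || age > rng[2L] + 3 * error) {
      stop("radiocarbon age ", age, " outside calibration curve support [",
           rng[1L], ", ", rng[2L], "]")
    }
    d <- stats::dnorm(age, curve$c14_age,
                      sqrt(error^2 + curve$sigma^2))
  } else {
    stop("unknown control kind: ", kind)
  }
  s <- sum(d)
  if (s <= 0) stop("calibration produced an all-zero posterior")
  data.frame(cal_age = curve$cal_age, density = d / s)
}

posterior_median <- function(post) {
  cum <- cumsum(post$density)
  post$cal_age[which(cum >= 0.5)[1L]]
}

posterior_sd <- function(post) {
  m <- sum(post$cal_age * post$density)
  sqrt(max(sum((post$cal_age - m)^2 * post$density), 0))
}

calibrate_controls <- function(record, curve) {
  lapply(seq_len(nrow(record$controls)), function(i) {
    ct <- record$controls[i, ]
    calibrate(ct$age, ct$error, ct$kind, curve)
  })
}

sample_posterior <- function(post, n) {
  sample(post$cal_age, n, replace = TRUE, prob = post$density)
}

# Age extrapolation limit: no sample is dated beyond this many years from
# the outermost chronological control.
EXTRAPOLATION_LIMIT <- 3000

# Analysis window (cal yr BP): Holocene onset down to 100 BP, the younger
# cut avoiding surface samples.
HOLOCENE_OLD <- 11700
HOLOCENE_YOUNG <- 100

#' Monte-Carlo age models for one record
#'
#' Replaces a full Bayesian accumulation model by a sampler honoring the
#' same contract the pipeline consumes: each draw samples one calendar age
#' per control from its calibrated posterior, conditioned on monotonicity in
#' depth (superposition), then interpolates piecewise-linearly to the sample
#' depths.  Conditioning is by joint rejection sampling with a retry cap,
#' falling back to sorting the drawn ages (always terminating, unbiased when
#' rejection succeeds).  Samples whose (linearly extrapolated) age lies more
#' than 3,000 yr beyond the outermost control's age are marked
#' age-undefined (`NA`).
#'
#' @param record a [pollen_record] with at least one control.
#' @param curve the record's [calibration_curve].
#' @param n_draws number of independent draws.
#' @param seed integer seed for this record's draw stream.
#' @param max_retries rejection-sampling cap before falling back to sorting.
#' @return numeric matrix `n_draws` x `n_samples` of cal yr BP ages (`NA`
#'   where age-undefined); draw independence across rows.
#' @export
sample_age_models <- function(record, curve, n_draws, seed,
                              max_retries = 1e5) {
  nctl <- nrow(record$controls)
  if (nctl < 1L) stop("record '", record$record_id, "' has no controls")
  posts <- calibrate_controls(record, curve)
  depths_c <- record$controls$depth
  with_seed(seed, {
    ages <- matrix(NA_real_, n_draws, length(record$depths))
    for (d in seq_len(n_draws)) {
      ctl_ages <- draw_monotone(posts, max_retries)
      ages[d, ] <- interpolate_ages(record$depths, depths_c, ctl_ages)
    }
    ages
  })
}

# one monotone joint draw of control ages (ordered by increasing depth)
draw_monotone <- function(posts, max_retries) {
  k <- length(posts)
  draw1 <- function() vapply(posts, function(p) sample_posterior(p, 1L), 0)
  if (k == 1L) return(draw1())
  # batched rejection: draw in blocks, accept the first monotone one
  block <- 64L
  tried <- 0L
  while (tried < max_retries) {
    n <- min(block, max_retries - tried)
    cand <- vapply(posts, function(p) sample_posterior(p, n), numeric(n))
    if (n == 1L) cand <- matrix(cand, nrow = 1L)
    ok <- which(apply(cand, 1L, function(a) all(diff(a) >= 0)))
    if (length(ok)) return(cand[ok[1L], ])
    tried <- tried + n
  }
  sort(draw1()) # pathological control set: fall back, preserving marginals' support
}

interpolate_ages <- function(depths, ctl_depths, ctl_ages) {
  k <- length(ctl_depths)
  if (k == 1L) {
    age <- rep(ctl_ages, length(depths))
    age[abs(age - ctl_ages) > EXTRAPOLATION_LIMIT] <- NA_real_
    return(age)
  }
  # piecewise linear inside; linear extrapolation with the end segments'
  # slopes outside, truncated at the 3,000-yr age limit
  out <- numeric(length(depths))
  for (i in seq_along(depths)) {
    d <- depths[i]
    if (d <= ctl_depths[1L]) {
      sl <- slope_of(ctl_depths[1:2], ctl_ages[1:2])
      out[i] <- ctl_ages[1L] + sl * (d - ctl_depths[1L])
      if (ctl_ages[1L] - out[i] > EXTRAPOLATION_LIMIT) out[i] <- NA_real_
    } else if (d >= ctl_depths[k]) {
      sl <- slope_of(ctl_depths[(k - 1L):k], ctl_ages[(k - 1L):k])
      out[i] <- ctl_ages[k] + sl * (d - ctl_depths[k])
      if (out[i] - ctl_ages[k] > EXTRAPOLATION_LIMIT) out[i] <- NA_real_
    } else {
      out[i] <- stats::approx(ctl_depths, ctl_ages, xout = d,
                              ties = "ordered")$y
    }
  }
  # enforce superposition exactly (ties from flat segments are fine)
  defined <- !is.na(out)
  if (any(defined) && is.unsorted(out[defined])) out[defined] <- sort(out[defined])
  out
}

slope_of <- function(d, a) {
  if (diff(d) == 0) 0 else diff(a) / diff(d)
}

#' Deterministic (point-estimate) age model
#'
#' Piecewise-linear interpolation through the calibrated posterior medians;
#' used by the inclusion filter, where a single representative chronology is
#' needed before any Monte-Carlo machinery runs.
#' @inheritParams sample_age_models
#' @return numeric vector of ages (NA where undefined), one per sample.
#' @export
point_age_model <- function(record, curve) {
  posts <- calibrate_controls(record, curve)
  med <- vapply(posts, posterior_median, 0)
  ord <- order(record$controls$depth)
  interpolate_ages(record$depths, record$controls$depth[ord], sort(med[ord]))
}

# ---------------------------------------------------------------------------
# Inclusion filter

#' Record inclusion filter
#'
#' Keeps records (or maximal contiguous sections of records) that satisfy,
#' within the Holocene analysis window (11,700-100 cal yr BP):
#' (1) three or more Holocene chronological controls;
#' (2) no gap larger than 3,000 yr between consecutive controls;
#' (3) at least five Holocene pollen samples of >= 300 terrestrial grains.
#' A control is "Holocene" when its calibrated posterior median lies in the
#' window.  When several sections of one record qualify, the one with the
#' most controls is kept (ties: longer time span, then older section).
#'
#' @param records harmonized [pollen_record]s.
#' @param curves named list of calibration curves (`northern`, `southern`).
#' @param min_grains minimum terrestrial grains per sample (300).
#' @param min_samples minimum qualifying samples (5).
#' @param min_controls minimum Holocene controls (3).
#' @param max_gap maximum age gap between consecutive controls (3,000 yr).
#' @return list with `kept` (list of trimmed records) and `report`
#'   (data.frame: record_id, kept, reason, n_controls, n_samples,
#'   depth_min, depth_max) in which every input record appears exactly once.
#' @export
filter_records <- function(records, curves,
                           min_grains = 300L, min_samples = 5L,
                           min_controls = 3L, max_gap = 3000) {
  kept <- list()
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    res <- filter_one(r, curves, min_grains, min_samples, min_controls,
                      max_gap)
    rows[[i]] <- data.frame(
      record_id = r$record_id, kept = !is.null(res$record),
      reason = res$reason,
      n_controls = res$n_controls, n_samples = res$n_samples,
      depth_min = res$depth_range[1L], depth_max = res$depth_range[2L]
    )
    if (!is.null(res$record)) kept[[length(kept) + 1L]] <- res$record
  }
  names(kept) <- vapply(kept, `[[`, "", "record_id")
  list(kept = kept, report = do.call(rbind, rows))
}

filter_one <- function(r, curves, min_grains, min_samples, min_controls,
                       max_gap) {
  fail <- function(reason) {
    list(record = NULL, reason = reason, n_controls = 0L, n_samples = 0L,
         depth_range = c(NA_real_, NA_real_))
  }
  curve <- curve_for_latitude(r$lat, curves)
  if (nrow(r$controls) == 0L) return(fail("too-few-controls"))
  posts <- calibrate_controls(r, curve)
  med <- vapply(posts, posterior_median, 0)
  holo <- med <= HOLOCENE_OLD & med >= HOLOCENE_YOUNG
  if (sum(holo) < min_controls) return(fail("too-few-controls"))

  # split Holocene controls (in depth order) into runs with age gaps <= max_gap
  hidx <- which(holo)
  ord <- order(r$controls$depth[hidx])
  hdep <- r$controls$depth[hidx][ord]
  hmed <- sort(med[hidx][ord]) # superposition at the point-estimate level
  brk <- c(0L, which(diff(hmed) > max_gap), length(hmed))
  runs <- mapply(function(a, b) seq(a + 1L, b), brk[-length(brk)], brk[-1L],
                 SIMPLIFY = FALSE)
  runs <- Filter(function(ix) length(ix) >= min_controls, runs)
  if (!length(runs)) {
    # at least min_controls Holocene controls exist but every run is broken
    return(fail("control-gap"))
  }

  ages <- point_age_model(r, curve)
  totals <- sample_totals(r)
  best <- NULL
  any_samples_fail <- FALSE
  for (ix in runs) {
    dlo <- hdep[ix[1L]]
    dhi <- hdep[ix[length(ix)]]
    # samples within the section's control depth span (no extrapolated
    # samples are carried into a trimmed section)
    in_sec <- r$depths >= dlo & r$depths <= dhi
    ok <- in_sec & !is.na(ages) & ages <= HOLOCENE_OLD &
      ages >= HOLOCENE_YOUNG & totals >= min_grains
    low_count <- in_sec & !is.na(ages) & ages <= HOLOCENE_OLD &
      ages >= HOLOCENE_YOUNG & totals < min_grains
    if (sum(ok) < min_samples) {
      any_samples_fail <- TRUE
      reason_here <- if (sum(ok) + sum(low_count) >= min_samples)
        "low-count-samples" else "too-few-samples"
      attr(any_samples_fail, "reason") <- reason_here
      next
    }
    cand <- list(idx = which(ok), n_controls = length(ix),
                 span = abs(diff(range(ages[ok]))),
                 old = max(ages[ok]), depth_range = c(dlo, dhi))
    if (is.null(best) ||
        cand$n_controls > best$n_controls ||
        (cand$n_controls == best$n_controls && cand$span > best$span) ||
        (cand$n_controls == best$n_controls && cand$span == best$span &&
         cand$old > best$old)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    reason <- attr(any_samples_fail, "reason") %||% "too-few-samples"
    return(fail(reason))
  }
  out <- r
  keep_sample <- seq_along(r$depths) %in% best$idx
  out$depths <- r$depths[keep_sample]
  out$counts <- r$counts[keep_sample, , drop = FALSE]
  keep_ctl <- r$controls$depth >= best$depth_range[1L] &
    r$controls$depth <= best$depth_range[2L]
  out$controls <- r$controls[keep_ctl, , drop = FALSE]
  list(record = out, reason = "kept", n_controls = best$n_controls,
       n_samples = length(best$idx), depth_range = best$depth_range)
}
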