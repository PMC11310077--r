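#' Holocene analysis periods
#'
#' Three fixed 1,849-1,850-yr periods: Early Holocene (11,700-9,851 cal yr
#' BP), Mid Holocene (6,725-4,876 cal yr BP) and the Common Era (1-1850 CE,
#' i.e. 1,949-100 cal yr BP via `BP = 1950 - CE`).
#' @return data.frame(label, old, young) in cal yr BP.
#' @export
holocene_periods <- function() {
  data.frame(label = c("early_holocene", "mid_holocene", "common_era"),
             old = c(11700, 6725, 1949),
             young = c(9851, 4876, 100))
}

LOGIT_CLAMP <- 1e-6

transform_metric <- function(value, metric) {
  if (startsWith(metric, "richness")) {
    if (any(value < 1, na.rm = TRUE)) stop("richness must be >= 1")
    log(value)
  } else {
    # evenness and (raw) turnover are [0,1]-bounded: logit with clamping
    v <- pmin(pmax(value, LOGIT_CLAMP), 1 - LOGIT_CLAMP)
    log(v / (1 - v))
  }
}

#' Per-record linear slopes within a period
#'
#' For each record with at least `min_points` in-period values, fits an
#' ordinary least-squares line of the transformed metric on age (log for
#' richness; logit for the `[0, 1]`-bounded evenness and raw turnover) and
#' reports the slope multiplied by 1,000 - the millennial linear change on
#' the transformed scale.  Note that turnover slopes use *raw*
#' dissimilarities (`turnover_bc_raw` / `turnover_jac_raw`), since
#' interval-adjusted turnover is not bounded in `[0, 1]`.
#'
#' @param points long data.frame (record_id, continent, age, metric, value).
#' @param period one row label of [holocene_periods()] or a `c(old, young)`
#'   interval in cal yr BP.
#' @param metric which metric to analyse.
#' @param min_points minimum in-period points per record (5).
#' @return data.frame(record_id, continent, period, metric, slope_per_kyr,
#'   n).
#' @export
period_slopes <- function(points, period, metric, min_points = 5L) {
  if (is.character(period)) {
    p <- holocene_periods()
    row <- p[p$label == period, ]
    if (!nrow(row)) stop("unknown period: ", period)
    interval <- c(row$old, row$young)
    label <- period
  } else {
    interval <- period
    label <- paste0(period[1L], "-", period[2L])
  }
  sub <- points[points$metric == metric & !is.na(points$value) &
                  !is.na(points$age) & points$age <= interval[1L] &
                  points$age >= interval[2L], , drop = FALSE]
  out <- lapply(split(sub, sub$record_id), function(d) {
    if (nrow(d) < min_points) return(NULL)
    if (length(unique(d$age)) < 2L) {
      stop("record '", d$record_id[1L], "': all in-period ages identical")
    }
    y <- transform_metric(d$value, metric)
    fit <- stats::lm.fit(cbind(1, d$age), y)
    data.frame(record_id = d$record_id[1L], continent = d$continent[1L],
               period = label, metric = metric,
               slope_per_kyr = fit$coefficients[2L] * 1000,
               n = nrow(d))
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out)) {
    out <- data.frame(record_id = character(0), continent = character(0),
                      period = character(0), metric = character(0),
                      slope_per_kyr = numeric(0), n = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Boxplot-style summaries of site slopes by region
#'
#' Median, quartiles, whiskers at `1.5 * IQR` beyond the hinges, and the
#' fraction of positive slopes, per region x metric x period.
#' @param slopes output of [period_slopes()] (possibly several rbind-ed).
#' @return data.frame(continent, metric, period, n, median, q25, q75,
#'   whisker_lo, whisker_hi, frac_positive).
#' @export
summarize_slopes <- function(slopes) {
  sp <- split(slopes,
              list(slopes$continent, slopes$metric, slopes$period),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    q <- stats::quantile(d$slope_per_kyr, c(0.25, 0.5, 0.75), type = 7)
    iqr <- q[3L] - q[1L]
    data.frame(continent = d$continent[1L], metric = d$metric[1L],
               period = d$period[1L], n = nrow(d),
               median = unname(q[2L]), q25 = unname(q[1L]),
               q75 = unname(q[3L]),
               whisker_lo = unname(q[1L] - 1.5 * iqr),
               whisker_hi = unname(q[3L] + 1.5 * iqr),
               frac_positive = mean(d$slope_per_kyr > 0))
  }))
  rownames(out) <- NULL
  out[order(out$continent, out$metric, out$period), ]
}
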