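#' Multiple-site dissimilarity
#'
#' Multiple-site generalizations of the pairwise indices, following the
#' Baselga family: with `b_ij` the number of types exclusive to site i
#' relative to site j, and `a_M = sum_i(S_i) - S_T` the pooled shared-type
#' surplus, the multiple-site Jaccard dissimilarity is
#' `sum_{i<j}(b_ij + b_ji) / (a_M + sum_{i<j}(b_ij + b_ji))`.
#' The abundance-based Bray-Curtis analogue replaces exclusive type counts
#' by exclusive abundance sums and the shared surplus by
#' `A_M = sum_i(T_i) - sum_k max_i(x_ik)` (with `T_i` the site totals), with
#' the Sorensen-type `2 A_M` denominator term.  Both reduce exactly to the
#' pairwise index for two sites and equal 0 for identical sites and 1 for
#' pairwise-disjoint sites.
#'
#' @param mat sites x taxa count matrix (>= 2 rows with positive totals).
#' @return dissimilarity in `[0, 1]`.
#' @export
multi_site_jaccard <- function(mat) {
  mat <- as.matrix(mat)
  inc <- mat > 0
  stopifnot(nrow(inc) >= 2L)
  if (any(rowSums(inc) == 0L)) stop("empty site in multi-site computation")
  n <- nrow(inc)
  excl <- 0
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    excl <- excl + sum(inc[i, ] & !inc[j, ]) + sum(inc[j, ] & !inc[i, ])
  }
  a_m <- sum(inc) - sum(colSums(inc) > 0L)
  if (a_m + excl == 0) return(0)
  excl / (a_m + excl)
}

#' @rdname multi_site_jaccard
#' @export
multi_site_bray <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) >= 2L)
  if (any(rowSums(mat) == 0)) stop("empty site in multi-site computation")
  n <- nrow(mat)
  excl <- 0
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    shared <- sum(pmin(mat[i, ], mat[j, ]))
    excl <- excl + (sum(mat[i, ]) - shared) + (sum(mat[j, ]) - shared)
  }
  a_m <- sum(mat) - sum(apply(mat, 2L, max))
  if (2 * a_m + excl == 0) return(0)
  excl / (2 * a_m + excl)
}

#' Binned spatial heterogeneity (beta diversity) per region
#'
#' Partitions one resampled dataset's samples into 500-yr bins anchored at
#' 100 cal yr BP, takes one sample per record per bin (the sample nearest
#' the bin center, so densely-sampled records do not dominate), and controls
#' for uneven record counts by repeatedly subsampling each bin, without
#' replacement, down to `n_min` = the minimum record count over all bins and
#' regions considered, averaging the multiple-site dissimilarity over `B`
#' subsamples.  Regions with fewer than `min_records` records overall are
#' skipped (and reported in the `skipped` attribute).
#'
#' @param resample a resampled dataset from [build_resample()].
#' @param regions optional character vector restricting the regions
#'   (continent labels) analysed.
#' @param bin_width bin width in years (500).
#' @param B number of bootstrap subsamples per bin (default 100).
#' @param min_records minimum records per region (20).
#' @param seed integer seed.
#' @return long data.frame: region, bin_start, bin_end, bin_mid, metric
#'   (`multi_bc` / `multi_jac`), value, n_records, resample; attribute
#'   `skipped` lists regions below `min_records`.
#' @export
heterogeneity <- function(resample, regions = NULL, bin_width = 500,
                          B = 100L, min_records = 20L, seed = 1L) {
  recs <- Filter(function(x) x$included, resample$records)
  regs <- vapply(recs, `[[`, "", "continent")
  if (is.null(regions)) regions <- sort(unique(regs))
  counts_by_region <- table(factor(regs, levels = regions))
  skipped <- names(counts_by_region)[counts_by_region < min_records]
  regions <- setdiff(regions, skipped)
  edges <- bin_edges(bin_width)
  if (!length(regions)) {
    out <- empty_heterogeneity()
    attr(out, "skipped") <- skipped
    return(out)
  }

  # one sample per record per bin: nearest the bin center
  picks <- list() # [[region]][[bin]] -> matrix of records x taxa
  for (rg in regions) {
    rg_recs <- recs[regs == rg]
    picks[[rg]] <- lapply(seq_len(nrow(edges)), function(b) {
      mid <- (edges$start[b] + edges$end[b]) / 2
      rows <- lapply(rg_recs, function(rr) {
        ok <- which(!is.na(rr$ages) & rr$ages >= edges$start[b] &
                      rr$ages < edges$end[b])
        if (!length(ok)) return(NULL)
        pick <- ok[which.min(abs(rr$ages[ok] - mid))]
        rr$counts[pick, , drop = FALSE]
      })
      rows <- Filter(Negate(is.null), rows)
      if (!length(rows)) return(NULL)
      do.call(rbind, rows)
    })
  }
  bin_n <- unlist(lapply(picks, function(p) {
    vapply(p, function(m) if (is.null(m)) 0L else nrow(m), 0L)
  }))
  n_min <- min(bin_n[bin_n > 0L])
  if (n_min < 2L) n_min <- 2L

  out <- list()
  with_seed(seed, {
    for (rg in regions) {
      for (b in seq_len(nrow(edges))) {
        m <- picks[[rg]][[b]]
        if (is.null(m) || nrow(m) < max(2L, n_min)) next # bin skipped
        vals_bc <- vals_jac <- numeric(B)
        for (k in seq_len(B)) {
          sub <- m[sample.int(nrow(m), n_min), , drop = FALSE]
          vals_bc[k] <- multi_site_bray(sub)
          vals_jac[k] <- multi_site_jaccard(sub)
        }
        out[[length(out) + 1L]] <- data.frame(
          region = rg, bin_start = edges$start[b], bin_end = edges$end[b],
          bin_mid = (edges$start[b] + edges$end[b]) / 2,
          metric = c("multi_bc", "multi_jac"),
          value = c(mean(vals_bc), mean(vals_jac)),
          n_records = nrow(m)
        )
      }
    }
  })
  res <- if (length(out)) do.call(rbind, out) else empty_heterogeneity()
  if (nrow(res)) res$resample <- resample$resample_index
  attr(res, "skipped") <- skipped
  res
}

# bins anchored at the young end of the window: [100, 600), ...,
# [11100, 11600), plus the terminal [11600, 11700]
bin_edges <- function(bin_width = 500) {
  starts <- seq(HOLOCENE_YOUNG, HOLOCENE_OLD - bin_width, by = bin_width)
  edges <- data.frame(start = starts, end = starts + bin_width)
  if (max(edges$end) < HOLOCENE_OLD) {
    edges <- rbind(edges,
                   data.frame(start = max(edges$end), end = HOLOCENE_OLD))
  }
  edges
}

empty_heterogeneity <- function() {
  data.frame(region = character(0), bin_start = numeric(0),
             bin_end = numeric(0), bin_mid = numeric(0),
             metric = character(0), value = numeric(0),
             n_records = integer(0), resample = integer(0))
}
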