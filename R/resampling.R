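#' Rarefy one pollen sample to a fixed grain total
#'
#' Draws exactly `n` grains without replacement from the sample's counts
#' (a multivariate hypergeometric draw), so per-taxon marginals have mean
#' `n * count / total`.  A sample with exactly `n` grains is returned
#' unchanged; fewer than `n` grains is an error (the inclusion filter should
#' have excluded it).
#'
#' @param counts named integer vector of grain counts.
#' @param n rarefaction total (default 300).
#' @param seed optional integer seed (drawn from the current RNG stream when
#'   `NULL`).
#' @return integer vector on the same taxon axis, summing to `n`.
#' @export
rarefy_sample <- function(counts, n = 300L, seed = NULL) {
  total <- sum(counts)
  if (total < n) {
    stop("cannot rarefy ", total, " grains to ", n,
         " (sample should have been filtered out)")
  }
  if (total == n) {
    return(stats::setNames(as.integer(counts), names(counts)))
  }
  draw <- function() {
    grains <- sample.int(total, n) # grain indices without replacement
    breaks <- c(0L, cumsum(as.integer(counts)))
    tab <- tabulate(findInterval(grains, breaks, left.open = TRUE),
                    nbins = length(counts))
    stats::setNames(as.integer(tab), names(counts))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Assemble one joint resample
#'
#' One of the `R` joint realizations of the dataset: every sample rarefied
#' to 300 grains under this resample's seed, dated by this resample's age
#' draw, windowed to the Holocene (11,700-100 cal yr BP).  Samples that are
#' age-undefined or fall outside the window are dropped (ages set `NA`),
#' and records left with fewer than `min_samples` in-window samples are
#' flagged excluded *for this resample only* — the mechanism by which
#' realized record counts vary slightly across resamples.
#'
#' @param records list of filtered, harmonized [pollen_record]s.
#' @param age_draws named list (by record_id) of age vectors, one age per
#'   sample, from [sample_age_models()].
#' @param resample_index index of this resample (1..R).
#' @param seed integer seed for this resample's rarefaction stream.
#' @param n_grains rarefaction total (300).
#' @param min_samples minimum in-window samples for record inclusion (5).
#' @return a `resampled_dataset`: list(resample_index, records = list of
#'   list(record_id, continent, biome, dep_env, ages, counts, included)).
#' @export
build_resample <- function(records, age_draws, resample_index, seed,
                           n_grains = 300L, min_samples = 5L) {
  out <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    ages <- age_draws[[r$record_id]]
    if (is.null(ages)) {
      stop("no age draw supplied for record '", r$record_id, "'")
    }
    ages[!is.na(ages) &
           (ages > HOLOCENE_OLD | ages < HOLOCENE_YOUNG)] <- NA_real_
    counts <- r$counts
    rare <- matrix(0L, nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
    for (s in seq_len(nrow(counts))) {
      if (is.na(ages[s])) next
      rare[s, ] <- rarefy_sample(counts[s, ], n = n_grains,
                                 seed = derive_seed(seed, i, s))
    }
    list(record_id = r$record_id, continent = r$continent, biome = r$biome,
         dep_env = r$dep_env, ages = ages, counts = rare,
         included = sum(!is.na(ages)) >= min_samples)
  })
  names(out) <- vapply(records, `[[`, "", "record_id")
  structure(list(resample_index = resample_index, records = out),
            class = "resampled_dataset")
}

#' Run the full joint resampling procedure
#'
#' Draws `R` Monte-Carlo age models per record and builds `R` joint
#' resamples; resample `r` uses draw `r` of every record.  All seeds derive
#' from `master_seed` by a counter-based splitting rule, so results are
#' independent of iteration order.
#'
#' @param records filtered, harmonized records.
#' @param curves named list of calibration curves (`northern`/`southern`).
#' @param R number of resamples (the study default is 1,000; tests use
#'   25-50).
#' @param master_seed integer master seed.
#' @param n_grains,min_samples passed to [build_resample()].
#' @return list of `resampled_dataset`s, plus a `summary` attribute
#'   (data.frame resample, n_records_included).
#' @export
run_resamples <- function(records, curves, R, master_seed,
                          n_grains = 300L, min_samples = 5L) {
  if (R < 1L) stop("R must be >= 1")
  draws <- lapply(records, function(r) {
    sample_age_models(r, curve_for_latitude(r$lat, curves), n_draws = R,
                      seed = derive_seed(master_seed, "ages", r$record_id))
  })
  names(draws) <- vapply(records, `[[`, "", "record_id")
  resamples <- lapply(seq_len(R), function(rix) {
    age_draws <- lapply(draws, function(m) m[rix, ])
    build_resample(records, age_draws, rix,
                   seed = derive_seed(master_seed, "rarefy", rix),
                   n_grains = n_grains, min_samples = min_samples)
  })
  summary <- data.frame(
    resample = seq_len(R),
    n_records_included = vapply(resamples, function(rs) {
      sum(vapply(rs$records, `[[`, TRUE, "included"))
    }, 0L)
  )
  attr(resamples, "summary") <- summary
  resamples
}
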