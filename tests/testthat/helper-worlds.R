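# Shared fixtures, built in code and memoized per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# small default-world fixture: 3 regions x 5 records
small_world <- function() {
  memo("small_world", generate_world(
    world_config(n_regions = 3L, records_per_region = 5L, seed = 42L)))
}

# filtered + harmonized records of the small world
small_filtered <- function() {
  memo("small_filtered", {
    w <- small_world()
    recs <- assign_regions(apply_harmonization(w$records, w$harmonization),
                           w$map)
    filter_records(recs, w$curves)
  })
}

# a couple of joint resamples of the small world
small_resamples <- function() {
  memo("small_resamples", {
    w <- small_world()
    run_resamples(small_filtered()$kept, w$curves, R = 3L, master_seed = 7L)
  })
}

# independent oracle: multiple-site dissimilarities computed from taxon-name
# sets / per-pair tables, structured differently from the package code
oracle_multi_jaccard <- function(mat) {
  sets <- apply(mat > 0, 1L, function(r) colnames(mat)[r],
                simplify = FALSE)
  n <- length(sets)
  excl <- 0
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    excl <- excl + length(setdiff(sets[[i]], sets[[j]])) +
      length(setdiff(sets[[j]], sets[[i]]))
  }
  a_m <- sum(lengths(sets)) - length(unique(unlist(sets)))
  if (a_m + excl == 0) return(0)
  excl / (a_m + excl)
}

oracle_multi_bray <- function(mat) {
  n <- nrow(mat)
  num <- 0
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    # exclusive abundance of each member of the pair: sum |x - y| split
    num <- num + sum(mat[i, ] - pmin(mat[i, ], mat[j, ])) +
      sum(mat[j, ] - pmin(mat[i, ], mat[j, ]))
  }
  a_m <- sum(mat) - sum(apply(mat, 2L, max))
  if (2 * a_m + num == 0) return(0)
  num / (2 * a_m + num)
}

random_count_table <- function(n_sites, n_taxa, lambda = 4) {
  m <- matrix(stats::rpois(n_sites * n_taxa, lambda), n_sites, n_taxa,
              dimnames = list(NULL, paste0("t", seq_len(n_taxa))))
  # guarantee positive row totals
  empty <- rowSums(m) == 0
  m[empty, 1L] <- 1L
  m
}
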