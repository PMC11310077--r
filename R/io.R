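#' Read and write pollen datasets
#'
#' On-disk layout mirrors the content of a Neotoma-style extract without a
#' database client: one long-form counts CSV (record_id, depth, taxon,
#' count), one controls CSV (record_id, depth, age, error, kind) and one
#' JSON file of site metadata.  All CSVs are UTF-8 with a header row and "."
#' decimal separator.
#'
#' @param records list of [pollen_record] objects.
#' @param dir directory to write into (created if missing).
#' @return `write_records()` returns the directory, invisibly;
#'   `read_records()` returns a named list of [pollen_record]s.
#' @export
write_records <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- records_to_long(records)
  ctrl <- do.call(rbind, lapply(records, function(r) {
    if (!nrow(r$controls)) return(NULL)
    cbind(record_id = r$record_id, r$controls)
  }))
  meta <- lapply(records, function(r) {
    list(record_id = r$record_id, lat = r$lat, lon = r$lon,
         continent = r$continent, biome = r$biome, dep_env = r$dep_env)
  })
  utils::write.csv(counts, file.path(dir, "counts.csv"), row.names = FALSE)
  utils::write.csv(ctrl, file.path(dir, "controls.csv"), row.names = FALSE)
  jsonlite::write_json(meta, file.path(dir, "records.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(dir)
}

#' @rdname write_records
#' @export
read_records <- function(dir) {
  counts <- utils::read.csv(file.path(dir, "counts.csv"))
  ctrl <- utils::read.csv(file.path(dir, "controls.csv"))
  meta <- jsonlite::read_json(file.path(dir, "records.json"))
  recs <- lapply(meta, function(m) {
    cc <- counts[counts$record_id == m$record_id, , drop = FALSE]
    depths <- sort(unique(cc$depth))
    taxa <- sort(unique(cc$taxon))
    mat <- matrix(0L, length(depths), length(taxa),
                  dimnames = list(NULL, taxa))
    mat[cbind(match(cc$depth, depths), match(cc$taxon, taxa))] <-
      as.integer(cc$count)
    ctl <- ctrl[ctrl$record_id == m$record_id,
                c("depth", "age", "error", "kind"), drop = FALSE]
    pollen_record(m$record_id, m$lat %||% NA_real_, m$lon %||% NA_real_,
                  depths, mat, ctl,
                  continent = m$continent %||% NA_character_,
                  biome = m$biome %||% NA_character_,
                  dep_env = m$dep_env %||% NA_character_)
  })
  names(recs) <- vapply(recs, `[[`, "", "record_id")
  recs
}

# ---------------------------------------------------------------------------
# Harmonization

#' Read / write a taxonomic harmonization table
#'
#' CSV columns: `raw` (name as found in the data), `harmonized` (name to
#' merge into), `group` (one of `terrestrial-pollen`, `spore`, `aquatic`,
#' `other`).  Only `terrestrial-pollen` taxa survive harmonization.
#' @param path CSV path.
#' @export
read_harmonization <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character")
  validate_harmonization(tab)
}

#' @rdname read_harmonization
#' @param table the harmonization data.frame.
#' @export
write_harmonization <- function(table, path) {
  utils::write.csv(validate_harmonization(table), path, row.names = FALSE)
  invisible(path)
}

validate_harmonization <- function(tab) {
  need <- c("raw", "harmonized", "group")
  if (!all(need %in% names(tab))) {
    stop("harmonization table needs columns: ", paste(need, collapse = ", "))
  }
  ok <- c("terrestrial-pollen", "spore", "aquatic", "other")
  if (!all(tab$group %in% ok)) {
    stop("unknown harmonization group(s): ",
         paste(setdiff(unique(tab$group), ok), collapse = ", "))
  }
  if (anyDuplicated(tab$raw)) {
    stop("duplicated raw names in harmonization table: ",
         paste(unique(tab$raw[duplicated(tab$raw)]), collapse = ", "))
  }
  tab[, need]
}

#' Harmonize the taxonomy of pollen records
#'
#' Maps every raw taxon name through the table: synonymous taxa are merged
#' by summing their counts, and taxa whose group is not `terrestrial-pollen`
#' (spores, aquatics, ...) are dropped.  Totals are thereby recomputed: after
#' harmonization `sample_totals()` is the terrestrial grain total.
#' Idempotent when harmonized names map to themselves.
#'
#' @param records list of [pollen_record]s.
#' @param table harmonization data.frame (raw, harmonized, group).
#' @return the harmonized record list.
#' @export
apply_harmonization <- function(records, table) {
  table <- validate_harmonization(table)
  lapply(records, function(r) {
    raw <- colnames(r$counts)
    hit <- match(raw, table$raw)
    if (anyNA(hit)) {
      stop("record '", r$record_id, "': raw taxa not in harmonization table: ",
           paste(raw[is.na(hit)], collapse = ", "))
    }
    keep <- table$group[hit] == "terrestrial-pollen"
    target <- table$harmonized[hit]
    out <- matrix(0L, nrow(r$counts), 0L)
    if (any(keep)) {
      sub <- r$counts[, keep, drop = FALSE]
      grp <- factor(target[keep])
      out <- t(rowsum(t(sub), grp))
      storage.mode(out) <- "integer"
      colnames(out) <- levels(grp)
    }
    r$counts <- out
    r
  })
}

# ---------------------------------------------------------------------------
# Region maps

#' Read / write a rectangular region map
#'
#' Regions are axis-aligned lat/lon rectangles (CSV columns: region,
#' continent, biome, lat_min, lat_max, lon_min, lon_max).  Rectangles must be
#' pairwise disjoint; membership is decided by point containment with the
#' lower/left edge closed and the upper/right edge open, so tiled maps have
#' no ambiguous boundaries.
#' @param path CSV path.
#' @export
read_region_map <- function(path) {
  validate_region_map(utils::read.csv(path))
}

#' @rdname read_region_map
#' @param map region map data.frame.
#' @export
write_region_map <- function(map, path) {
  utils::write.csv(validate_region_map(map), path, row.names = FALSE)
  invisible(path)
}

validate_region_map <- function(map) {
  need <- c("region", "continent", "biome",
            "lat_min", "lat_max", "lon_min", "lon_max")
  if (!all(need %in% names(map))) {
    stop("region map needs columns: ", paste(need, collapse = ", "))
  }
  if (any(map$lat_min >= map$lat_max) || any(map$lon_min >= map$lon_max)) {
    stop("region map: degenerate rectangle(s)")
  }
  n <- nrow(map)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (map$lat_min[i] < map$lat_max[j] && map$lat_min[j] < map$lat_max[i] &&
          map$lon_min[i] < map$lon_max[j] && map$lon_min[j] < map$lon_max[i]) {
        stop("region map: rectangles '", map$region[i], "' and '",
             map$region[j], "' overlap")
      }
    }
  }
  map[, need]
}

region_of_point <- function(lat, lon, map) {
  hit <- which(lat >= map$lat_min & lat < map$lat_max &
               lon >= map$lon_min & lon < map$lon_max)
  if (length(hit) == 0L) return(NA_integer_)
  hit[1L] # disjointness validated upstream
}

#' Assign a record to its region
#'
#' Labels the record with the continent/biome of the unique map rectangle
#' containing its site coordinates.
#' @param record a [pollen_record].
#' @param map validated region map (see [read_region_map()]).
#' @return the record with `continent` and `biome` set.
#' @export
assign_region <- function(record, map) {
  map <- validate_region_map(map)
  i <- region_of_point(record$lat, record$lon, map)
  if (is.na(i)) {
    stop("record '", record$record_id, "' at (", record$lat, ", ",
         record$lon, ") falls in no region rectangle")
  }
  record$continent <- map$continent[i]
  record$biome <- map$biome[i]
  record
}

#' @rdname assign_region
#' @param records a list of records.
#' @export
assign_regions <- function(records, map) {
  lapply(records, assign_region, map = map)
}

# ---------------------------------------------------------------------------
# ALCC grids and regional series

#' Construct an anthropogenic land-cover change (ALCC) grid
#'
#' Dense annual grid of the fraction of each cell under any human land use,
#' on the analysis window 8,000-100 cal yr BP.  Stored as a cell table plus
#' a cells x years fraction matrix.
#' @param cells data.frame with `lat`, `lon` (cell centers).
#' @param years integer vector, typically `8000:100`.
#' @param fractions matrix `nrow(cells)` x `length(years)` in `[0, 1]`.
#' @export
alcc_grid <- function(cells, years, fractions) {
  fractions <- as.matrix(fractions)
  stopifnot(nrow(fractions) == nrow(cells),
            ncol(fractions) == length(years))
  if (any(fractions < 0 | fractions > 1)) {
    stop("ALCC fractions must lie in [0, 1]")
  }
  structure(list(cells = as.data.frame(cells)[, c("lat", "lon")],
                 years = as.integer(years), fractions = fractions),
            class = "alcc_grid")
}

#' @rdname alcc_grid
#' @param path CSV path; layout is one row per cell: lat, lon, then one
#'   column per year (`y<year>`).
#' @param grid an `alcc_grid`.
#' @export
write_alcc_grid <- function(grid, path) {
  df <- cbind(grid$cells,
              as.data.frame(grid$fractions,
                            col.names = paste0("y", grid$years)))
  names(df) <- c("lat", "lon", paste0("y", grid$years))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname alcc_grid
#' @export
read_alcc_grid <- function(path) {
  df <- utils::read.csv(path)
  yc <- grep("^y[0-9]+$", names(df), value = TRUE)
  alcc_grid(df[, c("lat", "lon")], as.integer(sub("^y", "", yc)),
            as.matrix(df[, yc, drop = FALSE]))
}

#' Regional mean ALCC series
#'
#' Unweighted mean over all grid-cell centers falling in each region's
#' rectangle, per year; the reduction the analysis uses in place of
#' site-specific land-use reconstructions.
#' @param grid an [alcc_grid].
#' @param map region map.
#' @return named list of `alcc_series` objects (region, years, fraction).
#' @export
regional_alcc_mean <- function(grid, map) {
  map <- validate_region_map(map)
  out <- lapply(seq_len(nrow(map)), function(i) {
    inside <- grid$cells$lat >= map$lat_min[i] &
      grid$cells$lat < map$lat_max[i] &
      grid$cells$lon >= map$lon_min[i] &
      grid$cells$lon < map$lon_max[i]
    if (!any(inside)) {
      stop("region '", map$region[i], "' contains no ALCC grid cells")
    }
    alcc_series(map$region[i], grid$years,
                colMeans(grid$fractions[inside, , drop = FALSE]))
  })
  names(out) <- map$region
  out
}

#' ALCC series for one region
#' @param region region label.
#' @param years annual grid (cal yr BP).
#' @param fraction values in `[0, 1]`, one per year.
#' @export
alcc_series <- function(region, years, fraction) {
  stopifnot(length(years) == length(fraction))
  if (any(fraction < -1e-12 | fraction > 1 + 1e-12)) {
    stop("ALCC fractions must lie in [0, 1]")
  }
  structure(list(region = region, years = as.integer(years),
                 fraction = pmin(pmax(as.numeric(fraction), 0), 1)),
            class = "alcc_series")
}

#' Look up an ALCC series at given ages
#'
#' Ages are matched to the annual grid by rounding; ages outside the series
#' window return `NA`.
#' @param series an `alcc_series`.
#' @param ages cal yr BP.
#' @export
alcc_at <- function(series, ages) {
  series$fraction[match(round(ages), series$years)]
}
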