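#' Pollen record objects
#'
#' A `pollen_record` holds one site's depth-ordered pollen count samples and
#' its chronological controls, plus site metadata.  Counts are stored as an
#' integer matrix (samples x taxa); depths are cm, strictly increasing
#' downcore; ages are cal yr BP (1950 CE = 0 BP, larger = older).
#'
#' @param record_id unique identifier (character).
#' @param lat,lon site coordinates, decimal degrees.
#' @param depths numeric vector of sample depths (cm), strictly increasing.
#' @param counts integer matrix, `length(depths)` rows, named taxon columns.
#' @param controls data.frame with columns `depth`, `age`, `error`, `kind`
#'   (`kind` in `"radiocarbon"`/`"calendar"`; radiocarbon `age` is 14C yr BP).
#' @param continent,biome,dep_env optional labels (`NA` until assigned).
#' @return an object of class `pollen_record`.
#' @export
pollen_record <- function(record_id, lat, lon, depths, counts, controls,
                          continent = NA_character_, biome = NA_character_,
                          dep_env = NA_character_) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  stopifnot(
    is.character(record_id), length(record_id) == 1L,
    length(depths) >= 1L, nrow(counts) == length(depths),
    !is.null(colnames(counts)), all(counts >= 0L)
  )
  if (any(diff(depths) <= 0)) {
    stop("record '", record_id, "': sample depths must be strictly increasing")
  }
  controls <- as.data.frame(controls)
  need <- c("depth", "age", "error", "kind")
  if (!all(need %in% names(controls))) {
    stop("controls must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(controls) && any(controls$error <= 0)) {
    stop("record '", record_id, "': control errors must be > 0")
  }
  if (nrow(controls) && !all(controls$kind %in% c("radiocarbon", "calendar"))) {
    stop("record '", record_id, "': unknown control kind")
  }
  controls <- controls[order(controls$depth), need, drop = FALSE]
  rownames(controls) <- NULL
  structure(
    list(record_id = record_id, lat = lat, lon = lon,
         continent = continent, biome = biome, dep_env = dep_env,
         depths = as.numeric(depths), counts = counts, controls = controls),
    class = "pollen_record"
  )
}

#' @export
print.pollen_record <- function(x, ...) {
  cat("<pollen_record> ", x$record_id, "\n",
      "  site: ", format(x$lat, digits = 5), ", ", format(x$lon, digits = 5),
      "  region: ", x$continent %||% NA, "  dep. env.: ", x$dep_env, "\n",
      "  samples: ", nrow(x$counts), " (depths ",
      min(x$depths), "-", max(x$depths), " cm), taxa: ", ncol(x$counts), "\n",
      "  chronological controls: ", nrow(x$controls), "\n", sep = "")
  invisible(x)
}

#' Terrestrial grain totals per sample
#'
#' Sum of counts over taxa; after harmonization only terrestrial-pollen taxa
#' remain, so this is the terrestrial total the 300-grain filter refers to.
#' @param record a [pollen_record].
#' @return integer vector, one total per sample.
#' @export
sample_totals <- function(record) {
  as.integer(rowSums(record$counts))
}

#' Bind a record list into a long count table
#' @param records list of [pollen_record] objects.
#' @return data.frame (record_id, depth, taxon, count), zero counts omitted.
#' @export
records_to_long <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    idx <- which(r$counts > 0L, arr.ind = TRUE)
    if (!nrow(idx)) {
      # keep at least one row per sample so depths round-trip
      idx <- cbind(row = seq_along(r$depths), col = 1L)
      cnt <- rep(0L, length(r$depths))
    } else {
      cnt <- r$counts[idx]
    }
    data.frame(record_id = r$record_id,
               depth = r$depths[idx[, 1L]],
               taxon = colnames(r$counts)[idx[, 2L]],
               count = as.integer(cnt))
  }))
}
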