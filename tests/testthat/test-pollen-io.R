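test_that("records round-trip through the CSV/JSON layout exactly", {
  w <- small_world()
  dir <- withr::local_tempdir()
  write_records(w$records, dir)
  back <- read_records(dir)
  expect_setequal(names(back), names(w$records))
  for (id in names(w$records)) {
    a <- w$records[[id]]
    b <- back[[id]]
    expect_equal(b$depths, a$depths)
    expect_equal(b$controls, a$controls)
    expect_equal(b$lat, a$lat)
    expect_equal(b$dep_env, a$dep_env)
    # taxon order may differ; compare as aligned matrices over nonzero taxa
    taxa <- sort(colnames(a$counts)[colSums(a$counts) > 0])
    expect_true(all(taxa %in% colnames(b$counts)))
    expect_equal(unname(b$counts[, taxa]), unname(a$counts[, taxa]))
  }
})

test_that("harmonization merges synonyms, drops non-terrestrial, errors on gaps", {
  tab <- data.frame(
    raw = c("Quercus", "Quercus-type", "Pinus", "SporeX", "Lemna"),
    harmonized = c("Quercus", "Quercus", "Pinus", "SporeX", "Lemna"),
    group = c("terrestrial-pollen", "terrestrial-pollen",
              "terrestrial-pollen", "spore", "aquatic"))
  counts <- matrix(c(5L, 7L, 3L, 10L, 2L), 1, 5,
                   dimnames = list(NULL, tab$raw))
  rec <- pollen_record("x", 50, 5, 1, counts,
                       data.frame(depth = 1, age = 500, error = 30,
                                  kind = "calendar"))
  h <- apply_harmonization(list(rec), tab)[[1]]
  expect_equal(sort(colnames(h$counts)), c("Pinus", "Quercus"))
  expect_equal(h$counts[1, "Quercus"], c(Quercus = 12L))
  expect_equal(sample_totals(h), 15L)

  # sample of only spores -> empty sample, total 0
  rec2 <- pollen_record("y", 50, 5, 1,
                        matrix(4L, 1, 1, dimnames = list(NULL, "SporeX")),
                        rec$controls)
  h2 <- apply_harmonization(list(rec2), tab)[[1]]
  expect_equal(sample_totals(h2), 0L)

  # unmapped taxon errors, naming taxon and record
  rec3 <- pollen_record("z", 50, 5, 1,
                        matrix(4L, 1, 1, dimnames = list(NULL, "Mystery")),
                        rec$controls)
  expect_error(apply_harmonization(list(rec3), tab), "Mystery")
  expect_error(apply_harmonization(list(rec3), tab), "z")

  # idempotence on already-harmonized records
  h3 <- apply_harmonization(list(h), tab)[[1]]
  expect_equal(h3$counts, h$counts)
})

test_that("region assignment is point-in-rectangle with strict disjointness", {
  map <- data.frame(region = c("A", "B"), continent = c("A", "B"),
                    biome = c("A", "B"),
                    lat_min = c(0, 20), lat_max = c(10, 30),
                    lon_min = c(0, 0), lon_max = c(10, 10))
  rec <- pollen_record("p", 5, 5, 1,
                       matrix(1L, 1, 1, dimnames = list(NULL, "T")),
                       data.frame(depth = 1, age = 1, error = 1,
                                  kind = "calendar"))
  expect_equal(assign_region(rec, map)$continent, "A")
  rec$lat <- -5
  expect_error(assign_region(rec, map), "no region")
  bad <- map
  bad$lat_min <- c(0, 5) # overlap
  expect_error(assign_region(rec, bad), "overlap")
})

test_that("regional ALCC means average cell centers and round-trip", {
  map <- data.frame(region = "R", continent = "R", biome = "R",
                    lat_min = 0, lat_max = 10, lon_min = 0, lon_max = 10)
  years <- 8000:7996
  g <- alcc_grid(data.frame(lat = c(1, 2, 3, 4), lon = rep(5, 4)), years,
                 matrix(c(0, 0.1, 0.2, 0.5), 4, 5))
  s <- regional_alcc_mean(g, map)$R
  expect_equal(s$fraction, rep(0.2, 5))

  g2 <- alcc_grid(data.frame(lat = c(1, 2), lon = c(5, 5)), years,
                  rbind(rep(0.2, 5), rep(0.4, 5)))
  expect_equal(regional_alcc_mean(g2, map)$R$fraction, rep(0.3, 5))

  # invariant to cell order
  perm <- c(3, 1, 4, 2)
  g3 <- alcc_grid(g$cells[perm, ], years, g$fractions[perm, ])
  expect_equal(regional_alcc_mean(g3, map)$R$fraction, s$fraction)

  # empty region errors
  map2 <- rbind(map, data.frame(region = "S", continent = "S", biome = "S",
                                lat_min = 50, lat_max = 60, lon_min = 0,
                                lon_max = 10))
  expect_error(regional_alcc_mean(g, map2), "no ALCC grid cells")

  # grid CSV round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_alcc_grid(g, path)
  g4 <- read_alcc_grid(path)
  expect_equal(g4$years, g$years)
  expect_equal(g4$fractions, g$fractions, ignore_attr = TRUE)
})

test_that("alcc series lookup rounds ages to the annual grid", {
  s <- alcc_series("R", 8000:100, seq(0, 1, length.out = 7901))
  expect_equal(alcc_at(s, 4500.4), s$fraction[match(4500, s$years)])
  expect_true(is.na(alcc_at(s, 9000)))
})
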