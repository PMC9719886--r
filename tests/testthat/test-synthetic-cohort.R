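# One large cohort shared by the calibration checks below.
big_cohort <- generate_cohort(cohort_config(n_patients = 10000L, seed = 2024L))

test_that("generation is deterministic in the seed and seeds differ", {
  cfg <- cohort_config(n_patients = 60L, seed = 5L)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  other <- generate_cohort(cohort_config(n_patients = 60L, seed = 6L))
  expect_false(identical(generate_cohort(cfg), other))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_patients = 0L), "positive integer")
  expect_error(cohort_config(metastasis_fraction = 1.2), "\\(0, 1\\)")
  expect_error(cohort_config(
    lesion_node_rank_correlation = c(metastasis = 1.0, non_metastasis = 0.14)
  ), "rank_correlation|\\(-1, 1\\)")
  bad <- default_morphology_params()
  bad$metastasis$short <- c(7.6, 0)
  expect_error(cohort_config(morphology_params = bad), "strictly positive")
  badp <- default_pathology_params()
  badp$metastasis$nuclear_grade <- c(0.5, 0.4, 0.4, 0)
  expect_error(cohort_config(pathology_params = badp), "summing to 1")
})

test_that("large-cohort marginals converge to the configured moments", {
  co <- big_cohort
  expect_equal(mean(co$group), 39 / 137, tolerance = 0.02 / (39 / 137))

  cfg <- cohort_config()
  for (g in c(1L, 0L)) {
    gname <- if (g == 1L) "metastasis" else "non_metastasis"
    sub <- co[co$group == g, ]
    m <- nrow(sub)
    for (site in c("node", "lesion")) {
      for (p in c("att40", "att70", "ic", "effz")) {
        ls <- cfg$group_marginals[[gname]][[site]][[p]]
        col <- paste0(site, "_", p,
                      switch(p, att40 = "_hu", att70 = "_hu", "effz" = "",
                             ic = "_mgcm3"))
        se <- ls[2L] / sqrt(m)
        expect_lt(abs(mean(sub[[col]]) - ls[1L]), 3 * se)
      }
    }
  }
  # all physically constrained quantities strictly positive
  expect_true(all(co$node_short_mm > 0))
  expect_true(all(co$node_long_mm > co$node_short_mm))
  expect_true(all(co$lesion_ic_mgcm3 > 0 & co$node_ic_mgcm3 > 0))
  expect_true(all(co$lesion_att40_hu > co$lesion_att70_hu))
  expect_true(all(co$node_att40_hu > co$node_att70_hu))
  expect_true(all(co$ki67_pct > 0 & co$ki67_pct < 100))
})

test_that("lesion-node rank correlation shows the configured group contrast", {
  co <- big_cohort
  met <- co[co$group == 1L, ]
  non <- co[co$group == 0L, ]
  rho_met <- spearman_cor(met$lesion_att40_hu, met$node_att40_hu)$rho
  rho_non <- spearman_cor(non$lesion_att40_hu, non$node_att40_hu)$rho
  expect_gt(rho_met, 0.55)
  expect_lt(rho_met, 0.75)
  expect_gte(rho_non, 0.0)
  expect_lte(rho_non, 0.25)
})

test_that("cohort CSV round-trips exactly, including missing values", {
  co <- tiny_cohort(20L, seed = 9L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back, co)

  # empty cohort: header-only file
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co[0, ], path2)
  expect_identical(length(readLines(path2)), 1L)
  expect_equal(nrow(read_cohort(path2)), 0L)
})

test_that("a missing Ki67 field is flagged missing, not dropped", {
  co <- tiny_cohort(6L, seed = 10L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  lines <- readLines(path)
  header <- strsplit(lines[1L], ",")[[1L]]
  k <- which(header == "ki67_pct")
  row3 <- strsplit(lines[4L], ",")[[1L]]
  row3[k] <- ""
  lines[4L] <- paste(row3, collapse = ",")
  writeLines(lines, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), 6L)
  expect_true(is.na(back$ki67_pct[3L]))
  expect_false(any(is.na(back$ki67_pct[-3L])))
})

test_that("a non-numeric cell raises a parse error naming row and column", {
  co <- tiny_cohort(4L, seed = 11L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  lines <- readLines(path)
  header <- strsplit(lines[1L], ",")[[1L]]
  k <- which(header == "node_ic_mgcm3")
  row2 <- strsplit(lines[3L], ",")[[1L]]
  row2[k] <- "oops"
  lines[3L] <- paste(row2, collapse = ",")
  writeLines(lines, path)
  expect_error(read_cohort(path), "row 2.*node_ic_mgcm3")
})

test_that("configuration JSON round-trips", {
  cfg <- cohort_config(n_patients = 55L, seed = 77L)
  path <- withr::local_tempfile(fileext = ".json")
  write_cohort_config(cfg, path)
  back <- read_cohort_config(path)
  expect_identical(generate_cohort(back), generate_cohort(cfg))
})

test_that("phantom generation honours its specification", {
  # noiseless disk carries exactly the lesion value
  sp <- phantom_spec(grid_shape = c(40L, 40L), background_value = 10,
                     lesion_center = c(20, 20), lesion_radius = 8,
                     lesion_value = 99, noise_sd = 0, seed = 3L)
  ph <- generate_phantom(sp)
  inside <- (row(ph$maps[[1L]]) - 1 - 20)^2 + (col(ph$maps[[1L]]) - 1 - 20)^2 <= 64
  expect_true(all(ph$maps[[1L]][inside] == 99))
  expect_true(all(ph$maps[[1L]][!inside] == 10))
  expect_false(any(ph$mask))

  # deterministic in the seed
  expect_identical(generate_phantom(sp), generate_phantom(sp))

  # noisy disk mean within 3 standard errors of the lesion value
  spn <- phantom_spec(grid_shape = c(64L, 64L), background_value = 50,
                      lesion_center = c(31, 31), lesion_radius = 20,
                      lesion_value = 240, noise_sd = 5, seed = 4L)
  phn <- generate_phantom(spn)
  disk <- (row(phn$maps[[1L]]) - 1 - 31)^2 + (col(phn$maps[[1L]]) - 1 - 31)^2 <= 400
  expect_lt(abs(mean(phn$maps[[1L]][disk]) - 240), 3 * 5 / sqrt(pi * 20^2))

  # disk must fit inside the grid
  expect_error(phantom_spec(grid_shape = c(32L, 32L), lesion_center = c(30, 16),
                            lesion_radius = 5), "inside the grid")
  expect_error(phantom_spec(lesion_radius = 5, excluded_core_radius = 6),
               "core")
})

test_that("phantom CSV round-trip preserves maps and mask", {
  sp <- phantom_spec(grid_shape = c(16L, 16L),
                     background_value = c(att40 = 60, ic = 2),
                     lesion_center = c(7, 7), lesion_radius = 4,
                     lesion_value = c(att40 = 250, ic = 25),
                     excluded_core_radius = 2, noise_sd = 1, seed = 5L)
  ph <- generate_phantom(sp)
  prefix <- file.path(withr::local_tempdir(), "ph")
  write_phantom(ph, prefix)
  back <- read_phantom(prefix, names(ph$maps))
  expect_equal(back$maps, ph$maps, tolerance = 1e-12)
  expect_identical(back$mask, ph$mask)
  expect_true(any(back$mask))
})
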