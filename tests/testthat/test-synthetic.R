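test_that("degenerate mixture weights put every interneuron dorsal-ipsilateral", {
  w <- c(ipsi_dorsal = 1, ipsi_ventral = 0, contra_ventral = 0, contra_dorsal = 0)
  spec <- cohort_spec(weights = w, jitter_sd_um = 0, seed = 3,
                      cells_per_animal_mean = 200,
                      cluster_sds = list(ipsi_dorsal = c(40, 40),
                                         ipsi_ventral = c(40, 40),
                                         contra_ventral = c(40, 40),
                                         contra_dorsal = c(40, 40)))
  exp <- normalize_experiment(generate_experiment(spec, 1))
  ins <- exp$cells[exp$cells$cell_class == "interneuron", ]
  q <- quadrant_of(ins$x_norm_um, ins$y_norm_um)
  expect_gt(mean(q == "ipsi_dorsal"), 0.99) # Gaussian tails may graze a boundary
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(weights = c(ipsi_dorsal = 2, ipsi_ventral = 0,
                                       contra_ventral = 0, contra_dorsal = 0.5)),
               class = "premotormap_spec_error")
  expect_error(cohort_spec(sampling_fraction = 0), class = "premotormap_spec_error")
})

test_that("generation is deterministic under (seed, animal index)", {
  spec <- cohort_spec(seed = 17, n_animals = 2, cells_per_animal_mean = 150)
  e1 <- generate_experiment(spec, 2, "TA")
  e2 <- generate_experiment(spec, 2, "TA")
  expect_identical(e1$cells, e2$cells)
  expect_identical(e1$sections, e2$sections)
  e3 <- generate_experiment(spec, 1, "TA")
  expect_false(identical(e1$cells, e3$cells))
})

test_that("generated experiments satisfy the io and normalization invariants", {
  spec <- cohort_spec(seed = 23, cells_per_animal_mean = 300)
  exp <- generate_experiment(spec, 1)
  # constructor re-validates: vocabularies, finite coordinates, section signs
  expect_s3_class(experiment(exp$cells, exp$sections,
                             experiment_id = exp$experiment_id), "pm_experiment")
  norm <- normalize_experiment(exp)
  expect_true(all(abs(norm$cells$x_norm_um) <= 850 + 1e-9))
  expect_true(all(norm$cells$y_norm_um <= 450 + 1e-9 &
                    norm$cells$y_norm_um >= -450 - 1e-9))
  expect_equal(sign(norm$cells$x_norm_um), sign(norm$cells$x_um))
  # every cell's section resolves to a geometry row
  expect_true(all(norm$cells$section_id %in% norm$sections$section_id))
  # motor neurons sit in the ventral ipsilateral horn
  mn <- norm$cells[norm$cells$cell_class == "motor_neuron", ]
  expect_gt(mean(quadrant_of(mn$x_norm_um, mn$y_norm_um) == "ipsi_ventral"), 0.9)
})

test_that("section thinning tracks the sampling fraction", {
  full <- generate_experiment(cohort_spec(seed = 4, sampling_fraction = 1,
                                          cells_per_animal_mean = 400), 1)
  half <- generate_experiment(cohort_spec(seed = 4, sampling_fraction = 0.5,
                                          cells_per_animal_mean = 400), 1)
  expect_equal(nrow(half$sections) / nrow(full$sections), 0.5, tolerance = 0.02)
  expect_equal(nrow(half$cells) / nrow(full$cells), 0.5, tolerance = 0.15)
})

test_that("a written cohort round-trips and is reproducible file by file", {
  spec <- cohort_spec(n_animals = 1, seed = 31, cells_per_animal_mean = 120)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(spec, d1)
  generate_cohort(spec, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_true(file.exists(file.path(d1, "manifest.json")))
  cohort <- read_cohort(d1)
  expect_length(cohort$experiments, 2L)
  expect_equal(cohort$experiments[["LG_a01"]]$muscle, "LG")

  # empty cohort still produces a manifest
  d3 <- withr::local_tempdir()
  empty <- generate_cohort(cohort_spec(n_animals = 0, seed = 1), d3)
  expect_length(empty, 0L)
  expect_true(file.exists(file.path(d3, "manifest.json")))
})

test_that("per-experiment totals fall in the empirically observed range", {
  spec <- cohort_spec(seed = 41)
  totals <- vapply(1:4, function(i) nrow(generate_experiment(spec, i)$cells),
                   numeric(1))
  expect_true(all(totals > 50 & totals < 5000))
})

test_that("a medio-lateral offset between muscles is recovered in the medians", {
  spec <- cohort_spec(delta_um = 100, seed = 13, n_animals = 4,
                      cells_per_animal_mean = 600)
  med <- function(m, i) {
    median_position(normalize_experiment(generate_experiment(spec, i, m)))$median_um
  }
  d <- mean(vapply(1:4, function(i) med("TA", i), 1)) -
    mean(vapply(1:4, function(i) med("LG", i), 1))
  expect_equal(d, 100, tolerance = 0.35)
})

test_that("synthetic count tables behave under their noise parameter", {
  clean <- generate_count_table(a = 3, b = 0.8, noise_sd = 0, n_experiments = 30,
                                seed = 5)
  fit <- fit_power_law(clean)
  # rounding to integer counts leaves only a sub-percent bias
  expect_equal(fit$b, 0.8, tolerance = 0.02)
  expect_gt(fit$r_squared, 0.99)
  expect_identical(generate_count_table(seed = 8), generate_count_table(seed = 8))
  expect_error(fit_power_law(generate_count_table(n_experiments = 2, seed = 1)),
               class = "premotormap_insufficient_data_error")
})
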