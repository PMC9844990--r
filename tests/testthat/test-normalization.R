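test_that("quadrant-wise scaling maps landmarks to the frame and fixes the origin", {
  frame <- idealized_frame()
  geom <- toy_geometry()
  cells <- toy_cells(x = c(0, 250, 500, -640, 0),
                     y = c(0, 0, 400, -360, 200))
  out <- normalize_section(cells, geom, frame)
  expect_equal(out$x_norm_um[1], 0)
  expect_equal(out$y_norm_um[1], 0)
  expect_equal(out$x_norm_um[2], 250 / 500 * 850) # = 425
  expect_equal(out$x_norm_um[3], 850)             # ipsi edge -> +halfwidth
  expect_equal(out$y_norm_um[3], 450)             # dorsal-ipsi landmark -> dv_dorsal
  expect_equal(out$x_norm_um[4], -850)            # contra edge -> -halfwidth
  expect_equal(out$y_norm_um[4], -450)            # ventral-contra landmark -> dv_ventral
  expect_equal(out$y_norm_um[5], 200 / 400 * 450) # = 225
})

test_that("a dorsal landmark of 400 maps an ipsilateral cell at 200 to 225", {
  geom <- toy_geometry() # y_dorsal_ipsi = 400
  out <- normalize_section(toy_cells(x = 10, y = 200), geom,
                           idealized_frame(dv_dorsal_um = 450))
  expect_equal(out$y_norm_um, 225)
})

test_that("normalization preserves quadrants and is monotone within each", {
  frame <- idealized_frame()
  geom <- toy_geometry()
  set.seed(42)
  for (rep in 1:5) {
    cells <- toy_cells(x = runif(200, -640, 500), y = runif(200, -360, 320))
    out <- normalize_section(cells, geom, frame)
    expect_equal(sign(out$x_norm_um), sign(cells$x_um))
    expect_equal(sign(out$y_norm_um), sign(cells$y_um))
    expect_equal(quadrant_of(out$x_norm_um, out$y_norm_um),
                 quadrant_of(cells$x_um, cells$y_um))
    for (q in unique(quadrant_of(cells$x_um, cells$y_um))) {
      sel <- quadrant_of(cells$x_um, cells$y_um) == q
      ord <- order(cells$x_um[sel])
      expect_false(is.unsorted(out$x_norm_um[sel][ord]))
    }
  }
})

test_that("normalizing an already-idealized section is the identity", {
  exp <- toy_experiment(x = c(-500, 0, 123.4, 849), y = c(-449, 0, 200.5, 449))
  expect_equal(exp$cells$x_norm_um, exp$cells$x_um)
  expect_equal(exp$cells$y_norm_um, exp$cells$y_um)
})

test_that("degenerate landmarks raise a geometry error naming the section", {
  geom <- toy_geometry(section_id = "sX")
  geom$y_dorsal_ipsi <- 0
  expect_error(validate_sections <- normalize_section(toy_cells(1, 1), geom),
               "sX", class = "premotormap_geometry_error")
})

test_that("missing per-section geometry falls back to the experiment mean", {
  cells <- dplyr::bind_rows(toy_cells(100, 100, section_id = "s1"),
                            toy_cells(100, 100, section_id = "s99"))
  exp <- experiment(cells, sections = toy_geometry("s1"), experiment_id = "fb")
  expect_warning(out <- normalize_experiment(exp), "s99")
  # with a single section the fallback equals that section's geometry
  expect_equal(out$cells$x_norm_um[1], out$cells$x_norm_um[2])
})

test_that("quadrant labels follow signs with zeros going ipsi/dorsal", {
  expect_equal(quadrant_of(100, 200), "ipsi_dorsal")
  expect_equal(quadrant_of(-1, -1), "contra_ventral")
  expect_equal(quadrant_of(0, 0), "ipsi_dorsal")
  expect_equal(quadrant_of(0, -5), "ipsi_ventral")
  expect_equal(quadrant_of(-5, 0), "contra_dorsal")
})

test_that("alignment shifts the widest section to the common reference", {
  mk <- function(id, z_peak) {
    z <- seq(0, 4000, by = 200)
    secs <- toy_geometry(section_id = sprintf("%s_s%02d", id, seq_along(z)), z_um = z)
    width <- 1200 + 300 * exp(-((z - z_peak)^2) / (2 * 400^2))
    secs$x_edge_ipsi <- width / 2
    secs$x_edge_contra <- -width / 2
    experiment(toy_cells(1, 1, section_id = secs$section_id[1]),
               sections = secs, experiment_id = id)
  }
  exps <- list(mk("e1", 3000), mk("e2", 3400))
  off <- align_rostrocaudal(exps)
  expect_equal(off$z_widest, c(3000, 3400))
  expect_equal(off$offset[1] - off$offset[2], 400)

  # already centred at the reference -> offset 0
  off0 <- align_rostrocaudal(list(mk("e3", 0)))
  expect_equal(off0$offset, 0)

  # tie in maximal width -> most rostral maximal section wins
  tied <- mk("e4", 2000)
  width <- tied$sections$x_edge_ipsi - tied$sections$x_edge_contra
  tied$sections$x_edge_ipsi[c(5, 9)] <- max(width)
  tied$sections$x_edge_contra[c(5, 9)] <- -max(width)
  off_tie <- align_rostrocaudal(list(tied))
  expect_equal(off_tie$z_widest, tied$sections$z_um[5])

  # single-section experiment skipped with warning, offset 0
  single <- mk("e5", 100)
  single$sections <- single$sections[1, ]
  expect_warning(off1 <- align_rostrocaudal(list(single)), "skipped")
  expect_equal(off1$offset, 0)
})

test_that("rostro-caudal binning is a half-open partition", {
  cells <- toy_cells(x = c(1, 1, 1), y = c(1, 1, 1), z = c(0, 799, 800))
  bins <- bin_rostrocaudal(cells, 800)
  expect_equal(sort(names(bins)), c("0", "1"))
  expect_equal(nrow(bins[["0"]]), 2L)
  expect_equal(nrow(bins[["1"]]), 1L)

  expect_equal(bin_rostrocaudal(toy_cells(numeric(0), numeric(0)), 800), list())
  expect_error(bin_rostrocaudal(cells, -10), class = "premotormap_parameter_error")

  set.seed(3)
  big <- toy_cells(x = rep(1, 6000), y = rep(1, 6000), z = runif(6000, 0, 4800))
  bins <- bin_rostrocaudal(big, 800)
  expect_equal(length(bins), 6L)
  expect_equal(sum(vapply(bins, nrow, 1L)), 6000L)
  expect_true(all(abs(vapply(bins, nrow, 1L) - 1000) < 120))
})
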