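test_that("bandwidth follows the SD * n^(-1/5) rule and its equivariances", {
  set.seed(1)
  x <- rnorm(100)
  x <- (x - mean(x)) / sd(x) * 100 # exact SD 100
  expect_equal(bandwidth_from_sd(x), 100 * 100^(-0.2), tolerance = 1e-12)
  expect_equal(bandwidth_from_sd(2 * x), 2 * bandwidth_from_sd(x))
  expect_warning(b1 <- bandwidth_from_sd(5), "minimum")
  expect_equal(b1, 25)
  expect_warning(b0 <- bandwidth_from_sd(rep(3, 10)), "minimum")
  expect_gt(b0, 0)
})

test_that("a single cell yields a unimodal unit-mass map peaked at the cell", {
  exp <- toy_experiment(x = 120, y = -80)
  d <- density_matrix(exp, bandwidth = c(50, 50))
  expect_equal(sum(d$values), 1, tolerance = 1e-12)
  peak <- which(d$values == max(d$values), arr.ind = TRUE)
  expect_equal(d$grid_x[peak[1]], 112.5) # grid cell containing x = 120
  expect_equal(d$grid_y[peak[2]], -87.5)
  expect_true(all(d$values >= 0))
})

test_that("x-symmetric cells give an x-symmetric map and marginal", {
  exp <- toy_experiment(x = c(-300, 300), y = c(100, 100))
  d <- density_matrix(exp, bandwidth = c(60, 60))
  flipped <- d$values[rev(seq_along(d$grid_x)), ]
  expect_equal(d$values, flipped, tolerance = 1e-12)
  mx <- marginal(d, "x")
  expect_equal(mx$weights, rev(mx$weights), tolerance = 1e-12)
})

test_that("density mass matches the generating Gaussian within Monte-Carlo error", {
  set.seed(8)
  n <- 1000
  exp <- toy_experiment(x = rnorm(n, 200, 80), y = rnorm(n, -100, 60))
  d <- density_matrix(exp, bandwidth = c(20, 20))
  inside <- abs(d$grid_x - 200) <= 160 # +/- 2 sigma in x
  mass <- sum(d$values[inside, ])
  expect_equal(mass, 0.954, tolerance = 0.05)
  expect_equal(sum(d$values), 1, tolerance = 1e-9)
})

test_that("marginals of densities and cells all sum to 1", {
  set.seed(5)
  for (rep in 1:3) {
    exp <- random_experiment(n = sample(3:400, 1))
    d <- density_matrix(exp)
    expect_equal(sum(d$values), 1, tolerance = 1e-9)
    expect_equal(sum(marginal(d, "x")$weights), 1, tolerance = 1e-9)
    expect_equal(sum(marginal(d, "y")$weights), 1, tolerance = 1e-9)
    expect_equal(sum(marginal(exp$cells, "z")$weights), 1, tolerance = 1e-9)
    expect_equal(marginal(d, "x")$weights, rowSums(d$values))
  }
  expect_error(density_matrix(toy_experiment(numeric(0), numeric(0))),
               class = "premotormap_empty_error")
  expect_error(marginal(toy_cells(numeric(0), numeric(0)), "x"),
               class = "premotormap_empty_error")
})

test_that("the median-centred correlation matches brute force on random matrices", {
  set.seed(99)
  for (rep in 1:100) {
    nr <- sample(2:5, 1)
    nc <- sample(2:5, 1)
    an <- matrix(runif(nr * nc), nr, nc)
    am <- matrix(runif(nr * nc), nr, nc)
    r <- density_correlation(an, am)
    expect_equal(r, brute_force_r(an, am), tolerance = 1e-12)
    expect_equal(r, density_correlation(am, an), tolerance = 1e-12)
    expect_true(r >= -1 - 1e-12 && r <= 1 + 1e-12)
  }
})

test_that("self-comparison and positive affine transforms give exactly 1", {
  set.seed(12)
  a <- matrix(runif(25), 5, 5)
  expect_equal(density_correlation(a, a), 1, tolerance = 1e-12)
  expect_equal(density_correlation(a, 3.7 * a + 0.2), 1, tolerance = 1e-12)
})

test_that("the orthogonal 2x2 example gives exactly 0", {
  expect_equal(density_correlation(matrix(c(1, 0, 0, 0), 2, 2),
                                   matrix(c(0, 0, 0, 1), 2, 2)), 0)
})

test_that("degenerate matrices raise an undefined-correlation error", {
  flat <- matrix(1, 3, 3)
  expect_error(density_correlation(flat, matrix(runif(9), 3, 3)),
               class = "premotormap_degenerate_error")
  expect_error(density_correlation(matrix(1, 2, 2), matrix(1, 3, 3)),
               class = "premotormap_parameter_error")
})

test_that("cell order does not change the density", {
  exp <- random_experiment(n = 120, seed = 4)
  shuffled <- exp
  shuffled$cells <- shuffled$cells[sample(nrow(shuffled$cells)), ]
  d1 <- density_matrix(exp, bandwidth = c(40, 40))
  d2 <- density_matrix(shuffled, bandwidth = c(40, 40))
  expect_equal(d1$values, d2$values, tolerance = 1e-12)
})

test_that("correlations are stable under grid refinement on smooth inputs", {
  set.seed(21)
  e1 <- toy_experiment(x = rnorm(400, 300, 120), y = rnorm(400, 200, 100), id = "a")
  e2 <- toy_experiment(x = rnorm(400, 280, 120), y = rnorm(400, 220, 100), id = "b")
  r25 <- density_correlation(density_matrix(e1, grid_um = 25, bandwidth = c(80, 80)),
                             density_matrix(e2, grid_um = 25, bandwidth = c(80, 80)))
  r12 <- density_correlation(density_matrix(e1, grid_um = 12.5, bandwidth = c(80, 80)),
                             density_matrix(e2, grid_um = 12.5, bandwidth = c(80, 80)))
  expect_lt(abs(r25 - r12), 0.02)
})

test_that("correlation matrices are symmetric with unit diagonal", {
  e <- random_experiment(n = 200, seed = 31)
  dup <- list(a = e, b = e, c = e)
  m <- correlation_matrix(dup, bandwidth = c(60, 60))
  expect_true(all(abs(m - 1) < 1e-12))

  # disjoint clouds in opposite quadrants with narrow kernels: r near 0
  c1 <- toy_experiment(x = rnorm(300, 500, 40), y = rnorm(300, 300, 40), id = "dq")
  c2 <- toy_experiment(x = rnorm(300, -500, 40), y = rnorm(300, -300, 40), id = "vq")
  r <- density_correlation(density_matrix(c1, bandwidth = c(30, 30)),
                           density_matrix(c2, bandwidth = c(30, 30)))
  expect_lt(abs(r), 0.1)

  # two large same-distribution cohorts correlate strongly
  set.seed(77)
  s1 <- toy_experiment(x = c(rnorm(700, 320, 90), rnorm(300, -300, 120)),
                       y = c(rnorm(700, 250, 90), rnorm(300, -200, 100)), id = "s1")
  s2 <- toy_experiment(x = c(rnorm(700, 320, 90), rnorm(300, -300, 120)),
                       y = c(rnorm(700, 250, 90), rnorm(300, -200, 100)), id = "s2")
  m2 <- correlation_matrix(list(s1 = s1, s2 = s2))
  expect_gt(m2["s1", "s2"], 0.9)
  expect_equal(m2["s1", "s2"], m2["s2", "s1"])
})
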