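#' Data-driven Gaussian kernel bandwidth
#'
#' Kernel size for the Gaussian convolution of cell positions, evaluated
#' from the standard deviation of the data with Scott's n^(−1/5) factor:
#' `sigma = sd(coords) * n^(-1/5)`. Degenerate samples (n < 2 or zero SD)
#' fall back to a configured minimum bandwidth with a warning.
#'
#' @param coords Numeric sample of coordinates along one axis (μm).
#' @param min_bandwidth_um Fallback bandwidth for degenerate samples.
#' @return Strictly positive bandwidth in μm.
#' @export
bandwidth_from_sd <- function(coords, min_bandwidth_um = 25) {
  coords <- coords[is.finite(coords)]
  n <- length(coords)
  if (n < 2L || sd(coords) == 0) {
    warn("Degenerate coordinate sample; using the minimum bandwidth.")
    return(min_bandwidth_um)
  }
  max(sd(coords) * n^(-1 / 5), min_bandwidth_um * .Machine$double.eps)
}

# Regular grid of bin centres with spacing `by` covering [lo, hi].
grid_centres <- function(lo, hi, by) {
  seq(lo + by / 2, hi - by / 2 + 1e-9, by = by)
}

# One-dimensional truncated-Gaussian weight matrix: rows = points, columns =
# grid centres; each row sums to 1 (kernel mass renormalized after
# truncation at `trunc` standard deviations).
kernel_weights <- function(points, centres, sigma, trunc = 4) {
  w <- outer(points, centres, function(p, g) dnorm(g, mean = p, sd = sigma))
  w[abs(outer(points, centres, "-")) > trunc * sigma] <- 0
  rs <- rowSums(w)
  zero <- rs == 0
  if (any(zero)) {
    # Point falls farther than `trunc` sigma outside the grid: assign its
    # mass to the nearest grid cell so total mass is conserved.
    nearest <- vapply(points[zero], function(p) which.min(abs(centres - p)), 1L)
    w[cbind(which(zero), nearest)] <- 1
    rs[zero] <- 1
  }
  w / rs
}

#' Gaussian-convolved density matrix of cell positions
#'
#' Projects normalized cell positions along the rostro-caudal axis onto the
#' transverse plane and convolves them with a separable truncated Gaussian
#' kernel evaluated on a regular grid. Each cell contributes total mass
#' `1/n`, so the matrix sums to exactly 1.
#'
#' @param cells Tibble with `x_norm_um` / `y_norm_um` columns (or a
#'   `pm_experiment`; motor neurons are excluded when classified unless
#'   `include_motor_neurons = TRUE`).
#' @param frame An [idealized_frame()] delimiting the grid.
#' @param grid_um Grid spacing in μm (default 25).
#' @param bandwidth Length-2 numeric `(sigma_x, sigma_y)` in μm, or `NULL`
#'   to use [bandwidth_from_sd()] per axis.
#' @param truncation_sigmas Kernel truncation radius in standard deviations.
#' @param include_motor_neurons Keep classified motor neurons in the map.
#' @return An object of class `pm_density` with fields `values` (matrix,
#'   x by y), `grid_x`, `grid_y`, `bandwidth`, `n_cells`.
#' @export
density_matrix <- function(cells,
                           frame = idealized_frame(),
                           grid_um = 25,
                           bandwidth = NULL,
                           truncation_sigmas = 4,
                           include_motor_neurons = FALSE) {
  if (inherits(cells, "pm_experiment")) cells <- premotor_cells(cells, include_motor_neurons)
  if (!all(c("x_norm_um", "y_norm_um") %in% names(cells))) {
    abort("Cells carry no normalized coordinates; run normalize_experiment() first.",
          class = "premotormap_state_error")
  }
  if (nrow(cells) == 0L) {
    abort("Cannot compute a density matrix from an empty cell set.",
          class = "premotormap_empty_error")
  }
  x <- cells$x_norm_um
  y <- cells$y_norm_um
  if (is.null(bandwidth)) {
    bandwidth <- c(bandwidth_from_sd(x), bandwidth_from_sd(y))
  }
  if (length(bandwidth) == 1L) bandwidth <- rep(bandwidth, 2L)
  gx <- grid_centres(-frame$ml_halfwidth_um, frame$ml_halfwidth_um, grid_um)
  gy <- grid_centres(frame$dv_ventral_um, frame$dv_dorsal_um, grid_um)
  wx <- kernel_weights(x, gx, bandwidth[1L], truncation_sigmas)
  wy <- kernel_weights(y, gy, bandwidth[2L], truncation_sigmas)
  values <- crossprod(wx, wy) / length(x) # [n_gx x n_gy]
  structure(list(values = values, grid_x = gx, grid_y = gy,
                 bandwidth = bandwidth, n_cells = length(x)),
            class = "pm_density")
}

# Interneuron coordinates of an experiment: classified motor neurons are
# excluded from premotor distributions; unclassified cells are kept.
premotor_cells <- function(exp, include_motor_neurons = FALSE) {
  cells <- exp$cells
  if (!include_motor_neurons) {
    cells <- cells[cells$cell_class != "motor_neuron", , drop = FALSE]
  }
  cells
}

#' @export
print.pm_density <- function(x, ...) {
  cat(sprintf("<pm_density> %d x %d grid, %d cells, bandwidth (%.1f, %.1f) um, sum %.6f\n",
              length(x$grid_x), length(x$grid_y), x$n_cells,
              x$bandwidth[1L], x$bandwidth[2L], sum(x$values)))
  invisible(x)
}

#' Marginal distribution along one axis
#'
#' For a density matrix, the marginal is the row (x) or column (y) sum, so
#' it inherits the matrix's unit mass. For a cell table, a one-dimensional
#' Gaussian convolution is computed directly along `x`, `y` or `z`. All
#' marginals sum to 1.
#'
#' @param input A `pm_density` or a tibble of normalized cells.
#' @param axis `"x"`, `"y"` or `"z"` (`"z"` for cell input only).
#' @param grid_um Grid spacing for cell input.
#' @param bandwidth Kernel SD in μm, or `NULL` for [bandwidth_from_sd()].
#' @param range Grid range for cell input; defaults to the idealized frame
#'   extent for x/y and the data range for z.
#' @return An object of class `pm_marginal` with `axis`, `centres`, `weights`.
#' @export
marginal <- function(input, axis = c("x", "y", "z"),
                     grid_um = 25, bandwidth = NULL, range = NULL) {
  axis <- match.arg(axis)
  if (inherits(input, "pm_density")) {
    if (axis == "z") {
      abort("A transverse density matrix has no z marginal.",
            class = "premotormap_parameter_error")
    }
    w <- if (axis == "x") rowSums(input$values) else colSums(input$values)
    centres <- if (axis == "x") input$grid_x else input$grid_y
    return(structure(list(axis = axis, centres = centres, weights = w),
                     class = "pm_marginal"))
  }
  cells <- input
  if (nrow(cells) == 0L) {
    abort("Cannot compute a marginal from an empty cell set.",
          class = "premotormap_empty_error")
  }
  coords <- switch(axis,
                   x = cells$x_norm_um,
                   y = cells$y_norm_um,
                   z = if ("z_aligned_um" %in% names(cells)) cells$z_aligned_um else cells$z_um)
  if (is.null(coords)) {
    abort("Requested coordinates are not present on the cells.",
          class = "premotormap_state_error")
  }
  if (is.null(range)) {
    frame <- idealized_frame()
    range <- switch(axis,
                    x = c(-frame$ml_halfwidth_um, frame$ml_halfwidth_um),
                    y = c(frame$dv_ventral_um, frame$dv_dorsal_um),
                    z = base::range(coords) + c(-2, 2) * grid_um)
  }
  if (is.null(bandwidth)) bandwidth <- bandwidth_from_sd(coords)
  centres <- grid_centres(range[1L], range[2L], grid_um)
  w <- colSums(kernel_weights(coords, centres, bandwidth)) / length(coords)
  structure(list(axis = axis, centres = centres, weights = w),
            class = "pm_marginal")
}

#' Median-centred correlation between two density matrices
#'
#' The correlation coefficient between experiments n and m is the
#' cross-product of their median-centred density matrices over all grid
#' entries, normalized by the median-centred sums of squares:
#' \deqn{r_{nm} = \frac{\sum_i \sum_j (\rho_n(x_i, y_j) - \mathrm{med}\,\rho_n)
#'   (\rho_m(x_i, y_j) - \mathrm{med}\,\rho_m)}
#'   {\sqrt{\sum_i \sum_j (\rho_n - \mathrm{med}\,\rho_n)^2
#'          \sum_i \sum_j (\rho_m - \mathrm{med}\,\rho_m)^2}}}
#' Centring on the median (not the mean) makes the coefficient robust to the
#' large empty background of anatomical maps.
#'
#' @param dn,dm `pm_density` objects on the same grid (or bare matrices of
#'   identical dimension).
#' @return Correlation in \[−1, 1\]; symmetric in its arguments.
#' @export
density_correlation <- function(dn, dm) {
  an <- if (inherits(dn, "pm_density")) dn$values else as.matrix(dn)
  am <- if (inherits(dm, "pm_density")) dm$values else as.matrix(dm)
  if (!all(dim(an) == dim(am))) {
    abort("Density matrices must share the same grid.",
          class = "premotormap_parameter_error")
  }
  if (inherits(dn, "pm_density") && inherits(dm, "pm_density") &&
      (!isTRUE(all.equal(dn$grid_x, dm$grid_x)) ||
       !isTRUE(all.equal(dn$grid_y, dm$grid_y)))) {
    abort("Density matrices must share the same grid.",
          class = "premotormap_parameter_error")
  }
  cn <- an - median(an)
  cm <- am - median(am)
  den <- sqrt(sum(cn^2) * sum(cm^2))
  if (den == 0) {
    abort("Undefined correlation: a matrix has zero median-centred variance.",
          class = "premotormap_degenerate_error")
  }
  sum(cn * cm) / den
}

#' Pairwise density-correlation matrix
#'
#' Computes the median-centred density correlation for every pair of
#' experiments (or pre-computed densities) on a shared grid. In group mode
#' (a named list of experiment lists) cells are pooled by concatenation
#' before the density computation, mirroring pooled-panel comparisons.
#'
#' @param objects List of `pm_experiment` or `pm_density` objects (≥ 2),
#'   named; names become dimnames.
#' @param ... Passed to [density_matrix()] when densities must be computed.
#' @return Symmetric numeric matrix with unit diagonal; undefined pairs are
#'   recorded as `NA` with a warning.
#' @export
correlation_matrix <- function(objects, ...) {
  if (length(objects) < 2L) {
    abort("Need at least two experiments for a correlation matrix.",
          class = "premotormap_parameter_error")
  }
  densities <- lapply(objects, function(obj) {
    if (inherits(obj, "pm_density")) obj else density_matrix(obj, ...)
  })
  ids <- names(objects)
  if (is.null(ids)) {
    ids <- vapply(seq_along(objects), function(i) {
      obj <- objects[[i]]
      if (inherits(obj, "pm_experiment")) obj$experiment_id else paste0("d", i)
    }, character(1))
  }
  k <- length(densities)
  m <- diag(1, k)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      r <- tryCatch(density_correlation(densities[[i]], densities[[j]]),
                    premotormap_degenerate_error = function(e) {
                      warn(sprintf("Correlation undefined for pair (%s, %s); recorded as NA.",
                                   ids[i], ids[j]))
                      NA_real_
                    })
      m[i, j] <- r
      m[j, i] <- r
    }
  }
  m
}

#' Pool experiments by concatenating their normalized cells
#'
#' @param experiments List of `pm_experiment` objects.
#' @param id Identifier for the pooled pseudo-experiment.
#' @return A `pm_experiment` whose cells are the concatenation of the
#'   inputs' cells (sections dropped; coordinates are already normalized).
#' @export
pool_experiments <- function(experiments, id = "pooled") {
  cells <- dplyr::bind_rows(lapply(experiments, function(e) e$cells))
  exp <- experiments[[1L]]
  exp$experiment_id <- id
  exp$cells <- cells
  exp$sections <- NULL
  exp
}
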