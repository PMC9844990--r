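# Small in-code fixtures shared across the test files.

# A single-section geometry with distinct landmark magnitudes per quadrant,
# so sign and scaling errors cannot cancel.
toy_geometry <- function(section_id = "s1", z_um = 0) {
  tibble::tibble(
    section_id = section_id,
    z_um = z_um,
    x_edge_ipsi = 500,
    x_edge_contra = -640,
    y_dorsal_ipsi = 400,
    y_dorsal_contra = 320,
    y_ventral_ipsi = -480,
    y_ventral_contra = -360
  )
}

# Geometry whose landmarks coincide with the idealized frame extents, so
# normalization must be the identity.
ideal_geometry <- function(section_id = "s1", z_um = 0,
                           frame = idealized_frame()) {
  tibble::tibble(
    section_id = section_id,
    z_um = z_um,
    x_edge_ipsi = frame$ml_halfwidth_um,
    x_edge_contra = -frame$ml_halfwidth_um,
    y_dorsal_ipsi = frame$dv_dorsal_um,
    y_dorsal_contra = frame$dv_dorsal_um,
    y_ventral_ipsi = frame$dv_ventral_um,
    y_ventral_contra = frame$dv_ventral_um
  )
}

toy_cells <- function(x, y, z = 0, section_id = "s1",
                      channel = "eGFP", cell_class = "interneuron",
                      glyt2 = "unknown") {
  tibble::tibble(section_id = section_id, x_um = x, y_um = y, z_um = z,
                 channel = channel, cell_class = cell_class, glyt2 = glyt2)
}

# A tiny normalized experiment built directly in idealized coordinates.
toy_experiment <- function(x, y, z = 0, id = "toy", muscle = "LG", ...) {
  cells <- toy_cells(x, y, z, ...)
  exp <- experiment(cells, sections = ideal_geometry(), experiment_id = id,
                    muscle = muscle)
  normalize_experiment(exp)
}

# Random valid experiment for property-style tests (already normalized).
random_experiment <- function(n = 50, id = "rand", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  toy_experiment(
    x = runif(n, -840, 840),
    y = runif(n, -440, 440),
    z = runif(n, 0, 4000),
    id = id
  )
}

# Brute-force (scalar-loop) evaluation of the median-centred density
# correlation, independent of the package's vectorised implementation.
brute_force_r <- function(an, am) {
  med_n <- median(as.vector(an))
  med_m <- median(as.vector(am))
  num <- 0
  ssn <- 0
  ssm <- 0
  for (i in seq_len(nrow(an))) {
    for (j in seq_len(ncol(an))) {
      dn <- an[i, j] - med_n
      dm <- am[i, j] - med_m
      num <- num + dn * dm
      ssn <- ssn + dn^2
      ssm <- ssm + dm^2
    }
  }
  num / sqrt(ssn * ssm)
}

# Textbook Hedges' g oracle written from the definition, kept independent of
# the implementation under test.
oracle_hedges_g <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  d <- (mean(a) - mean(b)) / sp
  d * (1 - 3 / (4 * (na + nb) - 9))
}
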