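#' Specification of a synthetic tracing cohort
#'
#' Describes virtual muscle-injection experiments with the statistical
#' structure the analysis assumes: per-quadrant Gaussian mixtures of
#' premotor interneurons (main clusters dorsal-ipsilateral and ventral,
#' with a minority contralateral component), ventral-horn starter motor
#' neurons, per-animal positional jitter, raw-frame section geometry with a
#' width profile peaking at the L4/L5 border, section subsampling, and
#' quadrant-dependent GlyT2 composition. Defaults place the
#' dorsal-ipsilateral cluster at a medio-lateral centre of 320 μm and give
#' per-experiment totals in the range observed across real experiments
#' (hundreds to a few thousand cells).
#'
#' @param muscles Muscles simulated (default an antagonist pair LG, TA).
#' @param n_animals Animals per muscle.
#' @param cells_per_animal_mean,cells_per_animal_sdlog Log-normal cell-count
#'   distribution per animal.
#' @param weights Mixture weights per quadrant (non-negative, sum to 1).
#' @param cluster_means,cluster_sds Named lists of length-2 numeric vectors
#'   (x, y in idealized μm) per quadrant.
#' @param delta_um Medio-lateral offset applied to the second muscle's
#'   cluster centres, laterally (away from the midline); 0 reproduces the
#'   intermingled (null) configuration.
#' @param jitter_sd_um SD of the per-animal positional offset (applied to
#'   both in-plane axes).
#' @param starter_mn_mean Poisson mean of the starter motor-neuron count.
#' @param mn_centre,mn_sd Motor-neuron cluster centre and SD (ventral horn).
#' @param glyt2_p Probability of GlyT2-on per quadrant (glycinergic cells
#'   enriched ventral-ipsilaterally by default).
#' @param sampling_fraction Fraction of sections kept after thinning.
#' @param z_range_um Rostro-caudal extent of the simulated lumbar cord.
#' @param section_spacing_um Distance between consecutive sections.
#' @param titre_IU_per_ml Nominal titre recorded in metadata.
#' @param seed Root seed of the cohort.
#' @return A list of class `pm_cohort_spec`.
#' @export
cohort_spec <- function(muscles = c("LG", "TA"),
                        n_animals = 6,
                        cells_per_animal_mean = 800,
                        cells_per_animal_sdlog = 0.5,
                        weights = c(ipsi_dorsal = 0.55, ipsi_ventral = 0.30,
                                    contra_ventral = 0.10, contra_dorsal = 0.05),
                        cluster_means = list(ipsi_dorsal = c(320, 250),
                                             ipsi_ventral = c(300, -200),
                                             contra_ventral = c(-300, -200),
                                             contra_dorsal = c(-320, 250)),
                        cluster_sds = list(ipsi_dorsal = c(90, 90),
                                           ipsi_ventral = c(120, 100),
                                           contra_ventral = c(120, 100),
                                           contra_dorsal = c(90, 90)),
                        delta_um = 0,
                        jitter_sd_um = 15,
                        starter_mn_mean = 35,
                        mn_centre = c(400, -150),
                        mn_sd = c(60, 50),
                        glyt2_p = c(ipsi_dorsal = 0.3, ipsi_ventral = 0.7,
                                    contra_ventral = 0.25, contra_dorsal = 0.3),
                        sampling_fraction = 0.5,
                        z_range_um = c(0, 4800),
                        section_spacing_um = 40,
                        titre_IU_per_ml = 1e10,
                        seed = 1) {
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    abort("Mixture weights must be non-negative and sum to 1.",
          class = "premotormap_spec_error")
  }
  if (!setequal(names(weights), .quadrants) ||
      !setequal(names(cluster_means), .quadrants) ||
      !setequal(names(cluster_sds), .quadrants)) {
    abort("Weights, cluster means and SDs must be named by the four quadrants.",
          class = "premotormap_spec_error")
  }
  if (any(unlist(cluster_sds) <= 0) || jitter_sd_um < 0) {
    abort("Cluster SDs must be positive and jitter SD non-negative.",
          class = "premotormap_spec_error")
  }
  if (sampling_fraction <= 0 || sampling_fraction > 1) {
    abort("`sampling_fraction` must lie in (0, 1].",
          class = "premotormap_spec_error")
  }
  spec <- as.list(environment())
  structure(spec, class = "pm_cohort_spec")
}

# Raw-frame landmark geometry for a ladder of sections: the medio-lateral
# half-width peaks at the (per-animal) L4/L5 border so the widest-section
# alignment is exercised end to end; small per-section noise mimics
# section-to-section deformation.
synth_sections <- function(spec, z_peak) {
  z <- seq(spec$z_range_um[1L], spec$z_range_um[2L] - spec$section_spacing_um,
           by = spec$section_spacing_um)
  halfwidth <- 700 + 150 * exp(-((z - z_peak)^2) / (2 * 600^2))
  n <- length(z)
  noise <- function() 1 + rnorm(n, 0, 0.03)
  tibble::tibble(
    section_id = sprintf("s%03d", seq_len(n)),
    z_um = z,
    x_edge_ipsi = halfwidth * noise(),
    x_edge_contra = -halfwidth * noise(),
    y_dorsal_ipsi = 400 * noise(),
    y_dorsal_contra = 400 * noise(),
    y_ventral_ipsi = -500 * noise(),
    y_ventral_contra = -500 * noise()
  )
}

# Map idealized coordinates back into a section's raw frame by inverting the
# quadrant-wise normalization, so the pipeline's normalization step is
# tested end to end rather than bypassed.
denormalize <- function(x_ideal, y_ideal, geom, frame) {
  ipsi <- x_ideal >= 0
  dorsal <- y_ideal >= 0
  x_scale <- ifelse(ipsi, abs(geom$x_edge_ipsi), abs(geom$x_edge_contra))
  y_land <- ifelse(dorsal,
                   ifelse(ipsi, geom$y_dorsal_ipsi, geom$y_dorsal_contra),
                   ifelse(ipsi, geom$y_ventral_ipsi, geom$y_ventral_contra))
  y_target <- ifelse(dorsal, frame$dv_dorsal_um, frame$dv_ventral_um)
  list(x = x_ideal / frame$ml_halfwidth_um * x_scale,
       y = y_ideal / y_target * y_land)
}

#' Generate one synthetic tracing experiment
#'
#' Draws one animal's labelled cells from the cohort's quadrant mixture
#' (after adding the animal's positional jitter), places starter motor
#' neurons in the ventral ipsilateral horn, spreads cells over the lumbar
#' rostro-caudal extent, maps them into each section's raw landmark frame,
#' and thins sections at the spec's sampling fraction. Deterministic given
#' `(spec$seed, muscle, animal_index)`.
#'
#' @param spec A [cohort_spec()].
#' @param animal_index Animal number within the muscle group (1-based).
#' @param muscle One of `spec$muscles`; the second muscle receives the
#'   `delta_um` lateral offset.
#' @return A `pm_experiment` in raw coordinates.
#' @export
generate_experiment <- function(spec, animal_index, muscle = spec$muscles[[1L]]) {
  stopifnot(inherits(spec, "pm_cohort_spec"))
  m_idx <- match(muscle, spec$muscles)
  if (is.na(m_idx)) {
    abort(sprintf("Muscle '%s' is not part of the cohort spec.", muscle),
          class = "premotormap_spec_error")
  }
  frame <- idealized_frame()
  seed <- child_seed(spec$seed, m_idx, animal_index)
  with_seed(seed, {
    jitter <- rnorm(2L, 0, spec$jitter_sd_um)
    z_peak <- mean(spec$z_range_um) + runif(1L, -200, 200)
    sections <- synth_sections(spec, z_peak)

    n_cells <- max(20L, round(rlnorm(1L, log(spec$cells_per_animal_mean),
                                     spec$cells_per_animal_sdlog)))
    quad <- sample(names(spec$weights), n_cells, replace = TRUE,
                   prob = spec$weights)
    mu <- do.call(rbind, spec$cluster_means[quad])
    sdv <- do.call(rbind, spec$cluster_sds[quad])
    delta <- if (m_idx == 2L) spec$delta_um else 0
    x_ideal <- rnorm(n_cells, mu[, 1L] + sign(mu[, 1L]) * delta + jitter[1L], sdv[, 1L])
    y_ideal <- rnorm(n_cells, mu[, 2L] + jitter[2L], sdv[, 2L])
    glyt2 <- ifelse(rbinom(n_cells, 1L, spec$glyt2_p[quad]) == 1L, "on", "off")

    n_mn <- rpois(1L, spec$starter_mn_mean)
    if (n_mn > 0L) {
      x_ideal <- c(x_ideal, rnorm(n_mn, spec$mn_centre[1L] + jitter[1L], spec$mn_sd[1L]))
      y_ideal <- c(y_ideal, rnorm(n_mn, spec$mn_centre[2L] + jitter[2L], spec$mn_sd[2L]))
      glyt2 <- c(glyt2, rep("unknown", n_mn))
    }
    cls <- c(rep("interneuron", n_cells), rep("motor_neuron", n_mn))
    n_tot <- n_cells + n_mn
    # Clip the rare mixture tail that would escape the idealized frame.
    x_ideal <- pmin(pmax(x_ideal, -frame$ml_halfwidth_um + 1), frame$ml_halfwidth_um - 1)
    y_ideal <- pmin(pmax(y_ideal, frame$dv_ventral_um + 1), frame$dv_dorsal_um - 1)

    z <- runif(n_tot, spec$z_range_um[1L], spec$z_range_um[2L])
    sec_idx <- pmin(findInterval(z, sections$z_um), nrow(sections))
    geom <- sections[sec_idx, , drop = FALSE]
    raw <- denormalize(x_ideal, y_ideal, geom, frame)

    channel <- if (m_idx == 1L) "eGFP" else "mCherry"
    cells <- tibble::tibble(
      section_id = sections$section_id[sec_idx],
      x_um = raw$x,
      y_um = raw$y,
      z_um = z,
      channel = channel,
      cell_class = cls,
      glyt2 = glyt2
    )

    # Section thinning: analyse p out of every q consecutive sections.
    f <- spec$sampling_fraction
    pq <- fraction_parts(f)
    keep_idx <- (seq_len(nrow(sections)) - 1L) %% pq[2L] < pq[1L]
    kept_ids <- sections$section_id[keep_idx]
    cells <- cells[cells$section_id %in% kept_ids, , drop = FALSE]
    sections <- sections[keep_idx, , drop = FALSE]

    experiment(
      cells = cells,
      sections = sections,
      experiment_id = sprintf("%s_a%02d", muscle, animal_index),
      muscle = muscle,
      lab = "synthetic",
      mouse_line = "simulated",
      titre_IU_per_ml = spec$titre_IU_per_ml,
      sampling_fraction = f,
      injection_age = 2,
      perfusion_age = 10
    )
  })
}

# Small-denominator rational approximation of a sampling fraction.
fraction_parts <- function(f, max_q = 64L) {
  for (q in seq_len(max_q)) {
    p <- round(f * q)
    if (p >= 1L && abs(p / q - f) < 1e-9) return(c(p, q))
  }
  c(round(f * max_q), max_q)
}

sampling_string <- function(f, thickness_um) {
  if (abs(f - 1) < 1e-12) return(sprintf("All (%g um)", thickness_um))
  pq <- fraction_parts(f)
  sprintf("%d/%d (%g um)", pq[1L], pq[2L], thickness_um)
}

#' Generate a full synthetic cohort
#'
#' Generates `n_animals` experiments per muscle from a [cohort_spec()]. When
#' `dir` is given, each experiment's cells and sections tables are written in
#' the package's CSV schema together with a cohort-level metadata table and
#' a `manifest.json` recording the spec and seed.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory.
#' @return Named list of `pm_experiment` objects (invisibly when writing).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "pm_cohort_spec"))
  exps <- list()
  for (m in spec$muscles) {
    for (i in seq_len(spec$n_animals)) {
      e <- generate_experiment(spec, i, m)
      exps[[e$experiment_id]] <- e
    }
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    meta <- lapply(exps, function(e) {
      readr::write_csv(dplyr::mutate(e$cells, experiment_id = e$experiment_id,
                                     .before = 1L),
                       file.path(dir, paste0(e$experiment_id, "_cells.csv")),
                       progress = FALSE)
      readr::write_csv(e$sections,
                       file.path(dir, paste0(e$experiment_id, "_sections.csv")),
                       progress = FALSE)
      tibble::tibble(
        experiment_id = e$experiment_id,
        lab = e$lab,
        muscle = e$muscle,
        titre_IU_per_ml = e$titre_IU_per_ml,
        n_starter_mn = sum(e$cells$cell_class == "motor_neuron"),
        n_double_mn = NA_real_,
        n_premotor = sum(e$cells$cell_class == "interneuron"),
        sampling = sampling_string(e$sampling_fraction, spec$section_spacing_um)
      )
    })
    readr::write_csv(dplyr::bind_rows(meta), file.path(dir, "metadata.csv"),
                     progress = FALSE)
    manifest <- spec
    class(manifest) <- NULL
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(exps))
  }
  exps
}

#' Generate a synthetic count table following a power law
#'
#' Starter motor-neuron counts are drawn log-uniformly over `mn_range` and
#' premotor counts follow `round(a * mn^b * exp(eps))` with log-normal noise
#' `eps ~ Normal(0, noise_sd)`, emulating the empirical relation between
#' secondary and primary infected cell numbers.
#'
#' @param a,b Power-law amplitude (> 0) and exponent.
#' @param noise_sd SD of the multiplicative log-noise (0 = noiseless).
#' @param n_experiments Number of records.
#' @param seed Integer seed.
#' @param mn_range Range of motor-neuron counts.
#' @return A tibble of count records compatible with [fit_power_law()].
#' @export
generate_count_table <- function(a = 100, b = 0.5, noise_sd = 0.5,
                                 n_experiments = 50, seed = 1,
                                 mn_range = c(1, 120)) {
  if (a <= 0) {
    abort("`a` must be positive.", class = "premotormap_parameter_error")
  }
  with_seed(seed, {
    mn <- pmax(1, round(exp(runif(n_experiments, log(mn_range[1L]),
                                  log(mn_range[2L])))))
    ins <- pmax(1, round(a * mn^b * exp(rnorm(n_experiments, 0, noise_sd))))
    tibble::tibble(
      experiment_id = sprintf("sim%03d", seq_len(n_experiments)),
      muscle = NA_character_,
      titre_IU_per_ml = NA_real_,
      n_starter_mn = mn,
      n_premotor = ins,
      sampling_fraction = 1
    )
  })
}
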