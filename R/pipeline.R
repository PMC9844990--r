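#' Pipeline run configuration
#'
#' Collects every knob of the analysis in one validated object: the input
#' source (a directory of CSV tables or a synthetic [cohort_spec()]), the
#' idealized frame, density and bootstrap settings, count-analysis options
#' and the output directory. The configuration is persisted verbatim into
#' the output directory so a run is reproducible from its artefacts.
#'
#' @param input_dir Directory holding `*_cells.csv` / `*_sections.csv` and
#'   `metadata.csv` (as written by [generate_cohort()]), or `NULL`.
#' @param synthetic A [cohort_spec()] used when `input_dir` is `NULL`.
#' @param output_dir Where reports, figures and tables are written.
#' @param frame An [idealized_frame()].
#' @param grid_um,bandwidth,truncation_sigmas Density settings (see
#'   [density_matrix()]).
#' @param bin_width_um Rostro-caudal bin width (default 800).
#' @param alignment `"widest_section"` or `"none"`.
#' @param n_replicas,seed Bootstrap settings; `seed` is the root seed for
#'   every random stage.
#' @param effect_thresholds Band edges passed to [effect_band()].
#' @param figures Emit PDF figures (default `TRUE`).
#' @return A list of class `pm_config`.
#' @export
run_config <- function(input_dir = NULL,
                       synthetic = NULL,
                       output_dir = tempfile("premotormap_run_"),
                       frame = idealized_frame(),
                       grid_um = 25,
                       bandwidth = NULL,
                       truncation_sigmas = 4,
                       bin_width_um = 800,
                       alignment = c("widest_section", "none"),
                       n_replicas = 5000,
                       seed = 1,
                       effect_thresholds = c(small = 0.2, medium = 0.5, large = 0.8),
                       figures = TRUE) {
  alignment <- match.arg(alignment)
  if (is.null(input_dir) && is.null(synthetic)) {
    abort("Provide either `input_dir` or a synthetic cohort spec.",
          class = "premotormap_config_error")
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "pm_cohort_spec"))
  if (bin_width_um <= 0 || grid_um <= 0 || n_replicas < 1) {
    abort("Grid spacing, bin width and replica count must be positive.",
          class = "premotormap_config_error")
  }
  structure(as.list(environment()), class = "pm_config")
}

# Read every experiment of a cohort directory written in the package schema.
read_cohort <- function(dir) {
  cell_files <- sort(list.files(dir, pattern = "_cells\\.csv$", full.names = TRUE))
  if (length(cell_files) == 0L) {
    abort(sprintf("No *_cells.csv files found in %s.", dir),
          class = "premotormap_io_error")
  }
  meta_path <- file.path(dir, "metadata.csv")
  meta <- if (file.exists(meta_path)) read_metadata(meta_path) else NULL
  exps <- lapply(cell_files, function(cf) {
    id <- sub("_cells\\.csv$", "", basename(cf))
    sf <- file.path(dir, paste0(id, "_sections.csv"))
    extra <- list()
    if (!is.null(meta)) {
      row <- meta[meta$experiment_id == id, , drop = FALSE]
      if (nrow(row) >= 1L) {
        extra <- list(muscle = row$muscle[[1L]],
                      lab = if ("lab" %in% names(row)) row$lab[[1L]] else NA,
                      titre_IU_per_ml = if ("titre_IU_per_ml" %in% names(row)) row$titre_IU_per_ml[[1L]] else NA,
                      sampling_fraction = row$sampling_fraction[[1L]])
      }
    }
    do.call(read_cells, c(list(path = cf,
                               sections = if (file.exists(sf)) sf else NULL,
                               experiment_id = id),
                          extra))
  })
  names(exps) <- vapply(exps, function(e) e$experiment_id, character(1))
  list(experiments = exps, metadata = meta)
}

log_stage <- function(lines, stage, msg) {
  c(lines, sprintf("[%s] %s", stage, msg))
}

#' Run the full analysis pipeline
#'
#' Reads (or simulates) a cohort, normalizes every section into the
#' idealized frame, aligns experiments rostro-caudally, computes per-
#' experiment and per-muscle pooled density maps, pairwise density
#' correlations and pairwise Hedges' g, per-experiment dorsal-ipsilateral
#' medio-lateral medians, rostro-caudal bin occupancies, the muscle-group
#' hierarchical-bootstrap contrast, GlyT2-split summaries when labels are
#' present, and the count analyses when metadata is available. All numeric
#' outputs are written as machine-readable JSON/CSV next to the figures;
#' the run is deterministic given the config's root seed.
#'
#' @param config A [run_config()].
#' @return A list of class `pm_report` (also serialised to
#'   `summary.json` in the output directory).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pm_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)

  # --- load -----------------------------------------------------------
  metadata <- NULL
  if (!is.null(config$input_dir)) {
    cohort <- read_cohort(config$input_dir)
    experiments <- cohort$experiments
    metadata <- cohort$metadata
    log_lines <- log_stage(log_lines, "load",
                           sprintf("read %d experiments from %s",
                                   length(experiments), config$input_dir))
  } else {
    experiments <- generate_cohort(config$synthetic)
    log_lines <- log_stage(log_lines, "load",
                           sprintf("generated %d synthetic experiments (seed %d)",
                                   length(experiments), config$synthetic$seed))
  }
  n_cells_in <- vapply(experiments, function(e) nrow(e$cells), 1L)

  # --- normalize and align -------------------------------------------
  experiments <- lapply(experiments, normalize_experiment, frame = config$frame)
  offsets <- if (config$alignment == "widest_section") {
    align_rostrocaudal(experiments)
  } else {
    tibble::tibble(experiment_id = names(experiments),
                   z_widest = NA_real_, offset = 0)
  }
  experiments <- apply_alignment(experiments, offsets)
  for (e in experiments) {
    write_normalized(e, file.path(out, paste0(e$experiment_id, "_normalized.csv")))
  }
  n_mn <- vapply(experiments, function(e) sum(e$cells$cell_class == "motor_neuron"), 1L)
  log_lines <- log_stage(log_lines, "normalize",
                         sprintf("cells in: %d; motor neurons excluded from distributions: %d",
                                 sum(n_cells_in), sum(n_mn)))

  # --- densities and correlations ------------------------------------
  densities <- lapply(experiments, density_matrix, frame = config$frame,
                      grid_um = config$grid_um, bandwidth = config$bandwidth,
                      truncation_sigmas = config$truncation_sigmas)
  muscles <- vapply(experiments, function(e) e$muscle, character(1))
  pooled <- lapply(split(experiments, muscles), pool_experiments)
  pooled_dens <- lapply(pooled, density_matrix, frame = config$frame,
                        grid_um = config$grid_um, bandwidth = config$bandwidth,
                        truncation_sigmas = config$truncation_sigmas)
  for (id in names(densities)) {
    readr::write_csv(tibble::as_tibble(as.data.frame(densities[[id]]$values)),
                     file.path(out, paste0(id, "_density.csv")), progress = FALSE)
  }
  corr <- if (length(experiments) >= 2L) correlation_matrix(densities) else NULL
  log_lines <- log_stage(log_lines, "density",
                         sprintf("%d per-experiment maps, %d pooled maps",
                                 length(densities), length(pooled_dens)))

  # --- positional summaries ------------------------------------------
  medians <- dplyr::bind_rows(lapply(experiments, median_position))
  pairwise <- if (length(experiments) >= 2L) {
    pairwise_effect_matrix(experiments)
  }
  bins <- lapply(experiments, function(e) {
    b <- bin_rostrocaudal(premotor_cells(e), config$bin_width_um)
    tibble::tibble(experiment_id = e$experiment_id,
                   bin = as.integer(names(b)),
                   n_cells = vapply(b, nrow, 1L))
  })
  bins <- dplyr::bind_rows(bins)
  readr::write_csv(medians, file.path(out, "medians.csv"), progress = FALSE)
  readr::write_csv(bins, file.path(out, "rostrocaudal_bins.csv"), progress = FALSE)

  # --- muscle contrast -------------------------------------------------
  comparison <- NULL
  if (length(unique(muscles)) >= 2L) {
    pair <- sort(unique(muscles))[1:2]
    comparison <- compare_groups(experiments,
                                 group_a = pair[1L], group_b = pair[2L],
                                 config = config)
    log_lines <- log_stage(log_lines, "compare",
                           sprintf("%s vs %s: r = %.3f, g_median = %.3f (band %s)",
                                   pair[1L], pair[2L], comparison$correlation,
                                   comparison$effect$g_median,
                                   comparison$band))
  } else {
    log_lines <- log_stage(log_lines, "compare",
                           "single group: comparison stages skipped")
  }

  # --- GlyT2 split -----------------------------------------------------
  glyt2_summary <- NULL
  all_cells <- dplyr::bind_rows(lapply(experiments, function(e) {
    dplyr::mutate(premotor_cells(e), experiment_id = e$experiment_id)
  }))
  if (any(all_cells$glyt2 %in% c("on", "off"))) {
    lab <- all_cells[all_cells$glyt2 %in% c("on", "off"), , drop = FALSE]
    glyt2_summary <- lab |>
      dplyr::mutate(quadrant = quadrant_of(.data$x_norm_um, .data$y_norm_um)) |>
      dplyr::count(.data$quadrant, .data$glyt2) |>
      tidyr::pivot_wider(names_from = "glyt2", values_from = "n",
                         values_fill = 0L)
  }

  # --- counts ----------------------------------------------------------
  counts_report <- NULL
  if (!is.null(metadata)) {
    counts_report <- tryCatch({
      fit <- fit_power_law(metadata)
      ratios <- ratio_summary(metadata)
      list(power_law = list(a = fit$a, b = fit$b, r_squared = fit$r_squared,
                            n_points = fit$n_points),
           ratio_summary = ratios)
    }, error = function(e) {
      log_lines <<- log_stage(log_lines, "counts",
                              paste("count analysis skipped:", conditionMessage(e)))
      NULL
    })
  }

  # --- figures ---------------------------------------------------------
  if (isTRUE(config$figures)) {
    for (m in names(pooled)) {
      ggplot2::ggsave(file.path(out, paste0("map_", m, ".pdf")),
                      plot_transverse_map(pooled[[m]], pooled_dens[[m]]),
                      width = 7, height = 6)
    }
    if (!is.null(corr)) {
      ggplot2::ggsave(file.path(out, "correlation_matrix.pdf"),
                      plot_correlation_matrix(corr), width = 6, height = 5)
    }
  }

  report <- list(
    n_experiments = length(experiments),
    muscles = unname(sort(unique(muscles))),
    cells_in = unname(sum(n_cells_in)),
    motor_neurons_excluded = unname(sum(n_mn)),
    offsets = offsets,
    medians = medians,
    correlation = corr,
    pairwise = if (!is.null(pairwise)) pairwise$summary,
    comparison = if (!is.null(comparison)) {
      list(groups = comparison$groups,
           correlation = comparison$correlation,
           g_median = comparison$effect$g_median,
           g_iqr = comparison$effect$g_iqr,
           band = comparison$band,
           medians = comparison$medians)
    },
    glyt2 = glyt2_summary,
    counts = counts_report,
    seed = config$seed
  )
  json <- report
  json$correlation <- if (!is.null(corr)) as.data.frame(corr)
  jsonlite::write_json(json, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "columns", force = TRUE)
  writeLines(log_lines, file.path(out, "run.log"))
  cfg <- config
  cfg$frame <- unclass(cfg$frame)
  cfg$synthetic <- if (!is.null(cfg$synthetic)) unclass(cfg$synthetic)
  jsonlite::write_json(lapply(cfg, function(v) if (is.function(v)) NULL else v),
                       file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  structure(report, class = "pm_report")
}

#' Compare two groups of experiments
#'
#' Pools each group's normalized cells, computes the pooled-density
#' median-centred correlation, the hierarchical-bootstrap Hedges' g of the
#' dorsal-ipsilateral medio-lateral coordinates (animals as first level),
#' and the per-group pooled medians.
#'
#' @param experiments Named list of normalized `pm_experiment` objects.
#' @param group_a,group_b Either a muscle label, or a predicate function
#'   taking a `pm_experiment` and returning `TRUE`/`FALSE`.
#' @param config A [run_config()] (for bootstrap and density settings);
#'   `NULL` uses defaults.
#' @param quadrant,axis Coordinate selection for the effect size.
#' @return List with `groups`, `correlation`, `effect` (a `pm_effect`),
#'   `band` and `medians`.
#' @export
compare_groups <- function(experiments, group_a, group_b, config = NULL,
                           quadrant = "ipsi_dorsal", axis = "x") {
  if (is.null(config)) config <- run_config(synthetic = cohort_spec())
  select <- function(sel) {
    if (is.function(sel)) {
      Filter(sel, experiments)
    } else {
      Filter(function(e) identical(e$muscle, sel), experiments)
    }
  }
  ga <- select(group_a)
  gb <- select(group_b)
  label <- function(sel) if (is.function(sel)) "<predicate>" else sel
  if (length(ga) == 0L || length(gb) == 0L) {
    abort(sprintf("Empty selector (%s / %s). Available muscles: %s.",
                  label(group_a), label(group_b),
                  paste(unique(vapply(experiments, function(e) e$muscle,
                                      character(1))), collapse = ", ")),
          class = "premotormap_selector_error")
  }
  dens_a <- density_matrix(pool_experiments(ga, "A"), frame = config$frame,
                           grid_um = config$grid_um, bandwidth = config$bandwidth)
  dens_b <- density_matrix(pool_experiments(gb, "B"), frame = config$frame,
                           grid_um = config$grid_um, bandwidth = config$bandwidth)
  r <- density_correlation(dens_a, dens_b)
  coords_a <- lapply(ga, quadrant_coords, quadrant = quadrant, axis = axis)
  coords_b <- lapply(gb, quadrant_coords, quadrant = quadrant, axis = axis)
  eff <- hierarchical_bootstrap(coords_a, coords_b,
                                n_replicas = config$n_replicas,
                                seed = child_seed(config$seed, 101))
  med <- function(coords) median(unlist(coords))
  list(
    groups = c(a = label(group_a), b = label(group_b)),
    n_animals = c(a = length(ga), b = length(gb)),
    correlation = r,
    effect = eff,
    band = effect_band(eff$g_median, config$effect_thresholds),
    medians = c(a = med(coords_a), b = med(coords_b))
  )
}
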