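#' Construct a tracing experiment
#'
#' Bundles the per-cell coordinate table of one injected animal/channel with
#' its per-section landmark geometry and injection metadata. Coordinates are
#' in raw micrometres with the central canal as the in-plane origin: `x_um`
#' medio-lateral (positive toward the injected side), `y_um` dorso-ventral
#' (positive dorsal), `z_um` rostro-caudal (increasing caudally).
#'
#' @param cells Tibble of cell records with columns `section_id`, `x_um`,
#'   `y_um`, `z_um`, `channel`, `cell_class`, `glyt2`.
#' @param sections Tibble of per-section landmark geometry (see
#'   [read_sections()]), or `NULL` if only an experiment-level fallback
#'   geometry is available.
#' @param experiment_id Identifier for the animal/channel.
#' @param muscle Injected muscle, one of `"LG"`, `"MG"`, `"GS"`, `"TA"`,
#'   `"PL"` (or `NA`).
#' @param lab,mouse_line Free-text provenance annotations.
#' @param titre_IU_per_ml Viral titre in infectious units per millilitre.
#' @param injection_age,perfusion_age Postnatal days.
#' @param sampling_fraction Fraction of serial sections analysed, in (0, 1].
#' @param fallback_geometry Optional single-row geometry used for cells whose
#'   `section_id` has no entry in `sections`.
#'
#' @return An object of class `pm_experiment`.
#' @export
experiment <- function(cells,
                       sections = NULL,
                       experiment_id,
                       muscle = NA_character_,
                       lab = NA_character_,
                       mouse_line = NA_character_,
                       titre_IU_per_ml = NA_real_,
                       injection_age = NA_real_,
                       perfusion_age = NA_real_,
                       sampling_fraction = 1,
                       fallback_geometry = NULL) {
  cells <- validate_cells(tibble::as_tibble(cells))
  if (!is.null(sections)) {
    sections <- validate_sections(tibble::as_tibble(sections))
  }
  if (!is.numeric(sampling_fraction) || length(sampling_fraction) != 1L ||
      is.na(sampling_fraction) || sampling_fraction <= 0 || sampling_fraction > 1) {
    abort("`sampling_fraction` must be a single number in (0, 1].",
          class = "premotormap_parameter_error")
  }
  if (!is.na(muscle) && !muscle %in% .muscles) {
    abort(sprintf("Unknown muscle '%s'; expected one of %s.",
                  muscle, paste(.muscles, collapse = ", ")),
          class = "premotormap_vocab_error")
  }
  structure(
    list(
      experiment_id = as.character(experiment_id),
      muscle = muscle,
      lab = lab,
      mouse_line = mouse_line,
      titre_IU_per_ml = titre_IU_per_ml,
      injection_age = injection_age,
      perfusion_age = perfusion_age,
      sampling_fraction = sampling_fraction,
      cells = cells,
      sections = sections,
      fallback_geometry = fallback_geometry
    ),
    class = "pm_experiment"
  )
}

#' @export
print.pm_experiment <- function(x, ...) {
  cat(sprintf("<pm_experiment> %s  muscle: %s  cells: %d  sections: %s\n",
              x$experiment_id, x$muscle %||% NA, nrow(x$cells),
              if (is.null(x$sections)) "fallback" else nrow(x$sections)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

required_cell_cols <- c("section_id", "x_um", "y_um", "z_um",
                        "channel", "cell_class")

validate_cells <- function(cells) {
  missing <- setdiff(required_cell_cols, names(cells))
  if (length(missing) > 0L) {
    abort(sprintf("Cells table is missing required column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "premotormap_schema_error")
  }
  if (!"glyt2" %in% names(cells)) cells$glyt2 <- "unknown"
  for (col in c("x_um", "y_um", "z_um")) {
    bad <- which(!is.finite(cells[[col]]))
    if (length(bad) > 0L) {
      abort(sprintf("Non-finite %s at row(s) %s.", col,
                    paste(head(bad, 5L), collapse = ", ")),
            class = "premotormap_row_error")
    }
  }
  check_vocab(cells$channel, .channels, "channel")
  check_vocab(cells$cell_class, .cell_classes, "cell_class")
  check_vocab(cells$glyt2, .glyt2_levels, "glyt2")
  cells$section_id <- as.character(cells$section_id)
  cells
}

check_vocab <- function(values, vocab, what) {
  bad <- setdiff(unique(values), vocab)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown %s token(s): %s. Allowed: %s.",
                  what, paste(bad, collapse = ", "),
                  paste(vocab, collapse = ", ")),
          class = "premotormap_vocab_error")
  }
  invisible(values)
}

required_section_cols <- c("section_id", "z_um", "x_edge_ipsi", "x_edge_contra",
                           "y_dorsal_ipsi", "y_dorsal_contra",
                           "y_ventral_ipsi", "y_ventral_contra")

validate_sections <- function(sections) {
  missing <- setdiff(required_section_cols, names(sections))
  if (length(missing) > 0L) {
    abort(sprintf("Sections table is missing required column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "premotormap_schema_error")
  }
  signs <- list(x_edge_ipsi = 1, x_edge_contra = -1,
                y_dorsal_ipsi = 1, y_dorsal_contra = 1,
                y_ventral_ipsi = -1, y_ventral_contra = -1)
  for (col in names(signs)) {
    v <- sections[[col]] * signs[[col]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      abort(sprintf("Landmark %s violates its sign constraint (%s).",
                    col, if (signs[[col]] > 0) "must be > 0" else "must be < 0"),
            class = "premotormap_geometry_error")
    }
  }
  sections$section_id <- as.character(sections$section_id)
  sections
}

#' Read a per-cell coordinate table
#'
#' Reads a delimited cells file (one record per labelled cell) into a
#' [experiment()]. Unknown columns are preserved as opaque annotations and
#' row order is kept. Channel tokens may be normalized through an alias map,
#' and the medio-lateral axis is reflected when the injected side is recorded
#' as anatomical left, so that positive `x_um` is always ipsilateral.
#'
#' @param path Path to a CSV file with a header naming at least
#'   `section_id`, `x_um`, `y_um`, `z_um`, `channel`, `cell_class`.
#' @param sections Optional path to the matching sections CSV (see
#'   [read_sections()]), or an already-read sections tibble.
#' @param channel_aliases Named character vector mapping file tokens to the
#'   canonical channels, e.g. `c(GFP = "eGFP", RFP = "mCherry")`.
#' @param injected_side `"right"` (default) if positive raw x already points
#'   to the injected side, `"left"` to reflect the x axis.
#' @param experiment_id Identifier; defaults to the file's `experiment_id`
#'   column (first value) or the file stem.
#' @inheritParams experiment
#' @param ... Further metadata passed to [experiment()].
#'
#' @return A `pm_experiment`.
#' @export
read_cells <- function(path,
                       sections = NULL,
                       channel_aliases = NULL,
                       injected_side = c("right", "left"),
                       experiment_id = NULL,
                       ...) {
  injected_side <- match.arg(injected_side)
  if (!file.exists(path)) {
    abort(sprintf("Cells file not found: %s", path),
          class = "premotormap_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(required_cell_cols, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("File %s is missing required column(s): %s.",
                  basename(path), paste(missing, collapse = ", ")),
          class = "premotormap_schema_error")
  }
  num_cols <- intersect(c("x_um", "y_um", "z_um",
                          "x_norm_um", "y_norm_um", "z_aligned_um"), names(raw))
  for (col in num_cols) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (col %in% c("x_um", "y_um", "z_um") && length(bad) > 0L) {
      # +1 for the header line, so the number matches the file line.
      abort(sprintf("Unparsable %s in %s at line(s) %s.", col, basename(path),
                    paste(head(bad + 1L, 5L), collapse = ", ")),
            class = "premotormap_row_error")
    }
    raw[[col]] <- parsed
  }
  if (!is.null(channel_aliases)) {
    hit <- raw$channel %in% names(channel_aliases)
    raw$channel[hit] <- unname(channel_aliases[raw$channel[hit]])
  }
  if (injected_side == "left") {
    raw$x_um <- -raw$x_um
    if ("x_norm_um" %in% names(raw)) raw$x_norm_um <- -raw$x_norm_um
  }
  if (is.null(experiment_id)) {
    experiment_id <- if ("experiment_id" %in% names(raw) && nrow(raw) > 0L) {
      raw$experiment_id[[1L]]
    } else {
      sub("\\.[^.]*$", "", basename(path))
    }
  }
  if (is.character(sections) && length(sections) == 1L) {
    sections <- read_sections(sections)
  }
  experiment(cells = raw[, setdiff(names(raw), "experiment_id")],
             sections = sections, experiment_id = experiment_id, ...)
}

#' Read per-section landmark geometry
#'
#' Each section carries the white-matter landmarks used for quadrant-wise
#' normalization: the lateral white-matter edge at central-canal level on each
#' side (`x_edge_ipsi` > 0, `x_edge_contra` < 0) and the outermost dorsal and
#' ventral white-matter points per side (`y_dorsal_*` > 0, `y_ventral_*` < 0).
#'
#' @param path Path to a CSV file with header columns `section_id`, `z_um`,
#'   `x_edge_ipsi`, `x_edge_contra`, `y_dorsal_ipsi`, `y_dorsal_contra`,
#'   `y_ventral_ipsi`, `y_ventral_contra`.
#' @return A validated tibble.
#' @export
read_sections <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Sections file not found: %s", path),
          class = "premotormap_io_error")
  }
  validate_sections(readr::read_csv(path, col_types = readr::cols(), progress = FALSE))
}

#' Parse a section-sampling annotation
#'
#' Experiment tables record the fraction of serial sections analysed as
#' strings such as `"1/2 (30 μm)"`, `"1/8 (60 μm)"` or
#' `"All (40 μm)"`; the parenthesised value is the section thickness.
#' The parser is total over the grammar `<All | p/q> [(<n> μm)]` and
#' errors on anything else, quoting the offending token.
#'
#' @param x Character vector of sampling annotations.
#' @return Numeric vector of fractions in (0, 1].
#' @export
parse_sampling <- function(x) {
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  pat <- "^\\s*(All|[0-9]+\\s*/\\s*[0-9]+)\\s*(\\(\\s*[0-9.]+\\s*(μm|um)\\s*\\))?\\s*$"
  for (i in seq_along(x)) {
    if (is.na(x[i])) next
    m <- regmatches(x[i], regexec(pat, x[i]))[[1L]]
    if (length(m) == 0L) {
      abort(sprintf("Unparsable section-sampling token: '%s'.", x[i]),
            class = "premotormap_parse_error")
    }
    frac <- m[2L]
    if (frac == "All") {
      out[i] <- 1
    } else {
      pq <- as.numeric(strsplit(gsub("\\s", "", frac), "/")[[1L]])
      if (pq[2L] == 0 || pq[1L] == 0 || pq[1L] > pq[2L]) {
        abort(sprintf("Sampling fraction '%s' is outside (0, 1].", x[i]),
              class = "premotormap_parse_error")
      }
      out[i] <- pq[1L] / pq[2L]
    }
  }
  out
}

#' Read an experiment-summary metadata table
#'
#' Reads a metadata CSV shaped like the study-wide experiment table: one row
#' per injected muscle/channel with lab, ages, titre, labelled motor-neuron
#' count, premotor-interneuron counts and the section-sampling annotation.
#' Blank, `"-"` or `"N/A"` count entries become `NA` (unknown), never zero.
#'
#' @param path Path to a CSV file with at least `experiment_id`, `muscle`,
#'   `n_starter_mn`, `n_premotor`, `sampling` columns; `lab`,
#'   `titre_IU_per_ml` and `n_double_mn` are used when present.
#' @return A tibble of count records with a parsed `sampling_fraction` column.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Metadata file not found: %s", path),
          class = "premotormap_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = c("", "-", "N/A", "NA"))
  needed <- c("experiment_id", "muscle", "n_starter_mn", "n_premotor", "sampling")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("Metadata file is missing required column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "premotormap_schema_error")
  }
  for (col in intersect(c("n_starter_mn", "n_double_mn", "n_premotor",
                          "n_premotor_ipsi", "n_premotor_contra",
                          "titre_IU_per_ml", "ipsi_dorsal_median_um"),
                        names(raw))) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  raw$sampling_fraction <- parse_sampling(raw$sampling)
  raw
}

#' The study-wide experiment table shipped with the package
#'
#' Per-experiment metadata (lab, muscle, titre, labelled motor-neuron and
#' premotor-interneuron counts, section sampling) for the full set of tracing
#' experiments, as transcribed into `inst/extdata/table1_metadata.csv`.
#' Double injections appear as two rows sharing one `experiment_id`; the
#' double-labelled motor-neuron count is recorded once per experiment on its
#' first row.
#'
#' @return A tibble of count records (see [read_metadata()]).
#' @export
table1_counts <- function() {
  read_metadata(system.file("extdata", "table1_metadata.csv",
                            package = "premotormap", mustWork = TRUE))
}

#' Write normalized cells to disk
#'
#' Writes the experiment's cell table, including normalized coordinate
#' columns, as CSV with a fixed column order so output is byte-stable. The
#' file round-trips through [read_cells()].
#'
#' @param exp A `pm_experiment` whose cells carry `x_norm_um` / `y_norm_um`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_normalized <- function(exp, path) {
  stopifnot(inherits(exp, "pm_experiment"))
  cells <- exp$cells
  if (nrow(cells) > 0L && !all(c("x_norm_um", "y_norm_um") %in% names(cells))) {
    abort("Experiment has no normalized coordinates; run normalize_experiment() first.",
          class = "premotormap_state_error")
  }
  lead <- c("section_id", "x_um", "y_um", "z_um",
            intersect(c("x_norm_um", "y_norm_um", "z_aligned_um"), names(cells)),
            "channel", "cell_class", "glyt2")
  cols <- c("experiment_id", lead, setdiff(names(cells), lead))
  cells$experiment_id <- exp$experiment_id
  readr::write_csv(cells[, cols], path, progress = FALSE)
  invisible(path)
}
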