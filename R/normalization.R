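#' The idealized transverse spinal-cord frame
#'
#' All sections are scaled into a common transverse coordinate space of
#' 1700 μm medio-laterally and 900 μm dorso-ventrally, centred on the
#' central canal. The dorso-ventral split of the 900 μm is symmetric by
#' default (+450/−450) and configurable.
#'
#' @param ml_halfwidth_um Medio-lateral half-extent (default 850).
#' @param dv_dorsal_um Dorsal extent, > 0 (default +450).
#' @param dv_ventral_um Ventral extent, < 0 (default −450).
#' @return An object of class `pm_frame`.
#' @export
idealized_frame <- function(ml_halfwidth_um = 850,
                            dv_dorsal_um = 450,
                            dv_ventral_um = -450) {
  if (ml_halfwidth_um <= 0 || dv_dorsal_um <= 0 || dv_ventral_um >= 0) {
    abort("Frame extents must satisfy ml_halfwidth > 0, dv_dorsal > 0, dv_ventral < 0.",
          class = "premotormap_parameter_error")
  }
  structure(list(ml_halfwidth_um = ml_halfwidth_um,
                 dv_dorsal_um = dv_dorsal_um,
                 dv_ventral_um = dv_ventral_um),
            class = "pm_frame")
}

#' Quadrant of a normalized position
#'
#' Side is the sign of the medio-lateral coordinate, half the sign of the
#' dorso-ventral coordinate; exact zeros are assigned to the ipsilateral /
#' dorsal side so the partition is deterministic.
#'
#' @param x,y Numeric vectors of (normalized) medio-lateral and
#'   dorso-ventral coordinates.
#' @return Character vector with values `"ipsi_dorsal"`, `"ipsi_ventral"`,
#'   `"contra_dorsal"`, `"contra_ventral"`.
#' @export
quadrant_of <- function(x, y) {
  side <- ifelse(x >= 0, "ipsi", "contra")
  half <- ifelse(y >= 0, "dorsal", "ventral")
  paste(side, half, sep = "_")
}

#' Normalize one section's cells into the idealized frame
#'
#' Applies the quadrant-wise piecewise-linear map: the medio-lateral
#' coordinate is scaled so the same-side white-matter edge at central-canal
#' level lands on ±`ml_halfwidth_um`; the dorso-ventral coordinate is scaled
#' per quadrant so the same-side outermost dorsal white-matter point lands on
#' `dv_dorsal_um` and the outermost ventral point on `dv_ventral_um`. The
#' central canal (origin) is a fixed point and quadrant membership is
#' preserved.
#'
#' @param cells Tibble of cell records belonging to the section.
#' @param geom Single-row section geometry (see [read_sections()]).
#' @param frame An [idealized_frame()].
#' @return `cells` with `x_norm_um` and `y_norm_um` columns added.
#' @export
normalize_section <- function(cells, geom, frame = idealized_frame()) {
  geom <- as.list(geom)
  lm_cols <- c("x_edge_ipsi", "x_edge_contra", "y_dorsal_ipsi",
               "y_dorsal_contra", "y_ventral_ipsi", "y_ventral_contra")
  mags <- abs(unlist(geom[lm_cols]))
  if (any(!is.finite(mags)) || any(mags == 0)) {
    abort(sprintf("Degenerate geometry for section '%s': zero-magnitude landmark.",
                  geom$section_id %||% "?"),
          class = "premotormap_geometry_error")
  }
  x <- cells$x_um
  y <- cells$y_um
  ipsi <- x >= 0
  dorsal <- y >= 0
  x_scale <- ifelse(ipsi, abs(geom$x_edge_ipsi), abs(geom$x_edge_contra))
  y_land <- ifelse(dorsal,
                   ifelse(ipsi, geom$y_dorsal_ipsi, geom$y_dorsal_contra),
                   ifelse(ipsi, geom$y_ventral_ipsi, geom$y_ventral_contra))
  y_target <- ifelse(dorsal, frame$dv_dorsal_um, frame$dv_ventral_um)
  cells$x_norm_um <- x / x_scale * frame$ml_halfwidth_um
  cells$y_norm_um <- y / y_land * y_target
  cells
}

#' Normalize a whole experiment
#'
#' Normalizes each section independently against its own landmarks. Cells
#' whose `section_id` has no geometry are normalized against the experiment's
#' fallback geometry when one exists (explicit, or the column-wise mean of
#' the available sections), with a warning; otherwise an error is raised.
#'
#' @param exp A `pm_experiment`.
#' @param frame An [idealized_frame()].
#' @return The experiment with normalized coordinates attached to its cells.
#' @export
normalize_experiment <- function(exp, frame = idealized_frame()) {
  stopifnot(inherits(exp, "pm_experiment"))
  cells <- exp$cells
  if (nrow(cells) == 0L) {
    cells$x_norm_um <- numeric(0)
    cells$y_norm_um <- numeric(0)
    exp$cells <- cells
    return(exp)
  }
  sections <- exp$sections
  fallback <- exp$fallback_geometry
  if (is.null(fallback) && !is.null(sections) && nrow(sections) > 0L) {
    fallback <- as.list(colMeans(sections[, setdiff(names(sections), "section_id")]))
    fallback$section_id <- "<experiment mean>"
  }
  known <- if (is.null(sections)) character(0) else sections$section_id
  orphan <- setdiff(unique(cells$section_id), known)
  if (length(orphan) > 0L) {
    if (is.null(fallback)) {
      abort(sprintf("No geometry for section(s) %s and no fallback available.",
                    paste(orphan, collapse = ", ")),
            class = "premotormap_geometry_error")
    }
    warn(sprintf("Experiment %s: no landmarks for section(s) %s; using experiment-level fallback geometry.",
                 exp$experiment_id, paste(orphan, collapse = ", ")))
  }
  out <- vector("list", length(unique(cells$section_id)))
  cells$.row <- seq_len(nrow(cells))
  pieces <- split(cells, cells$section_id)
  pieces <- lapply(pieces, function(piece) {
    sid <- piece$section_id[[1L]]
    geom <- if (sid %in% known) {
      sections[sections$section_id == sid, , drop = FALSE][1L, ]
    } else {
      fallback
    }
    normalize_section(piece, geom, frame)
  })
  merged <- dplyr::bind_rows(pieces)
  merged <- merged[order(merged$.row), , drop = FALSE]
  merged$.row <- NULL
  exp$cells <- merged
  exp
}

#' Align experiments rostro-caudally at the widest section
#'
#' The border between the L4 and L5 segments is identified as the section
#' with the largest medio-lateral width (`x_edge_ipsi − x_edge_contra`);
#' each experiment's z axis is shifted so that section sits at a common
#' reference (default z = 0). Ties are broken toward the most rostral
#' (smallest z) maximal section. Relative z spacings within an experiment
#' are unchanged.
#'
#' @param experiments List of `pm_experiment` objects.
#' @param reference_z Target z for the widest section (default 0).
#' @return A tibble with `experiment_id`, `z_widest`, `offset`; experiments
#'   with fewer than 2 sections are skipped with a warning and offset 0.
#' @export
align_rostrocaudal <- function(experiments, reference_z = 0) {
  rows <- lapply(experiments, function(exp) {
    secs <- exp$sections
    if (is.null(secs) || nrow(secs) < 2L) {
      warn(sprintf("Experiment %s has < 2 sections; rostro-caudal alignment skipped.",
                   exp$experiment_id))
      return(tibble::tibble(experiment_id = exp$experiment_id,
                            z_widest = NA_real_, offset = 0))
    }
    width <- secs$x_edge_ipsi - secs$x_edge_contra
    widest <- secs$z_um[width == max(width)]
    z_widest <- min(widest) # tie-break: most rostral maximal section
    tibble::tibble(experiment_id = exp$experiment_id,
                   z_widest = z_widest,
                   offset = reference_z - z_widest)
  })
  dplyr::bind_rows(rows)
}

#' Apply rostro-caudal offsets to experiments
#'
#' @param experiments List of `pm_experiment` objects.
#' @param offsets Tibble from [align_rostrocaudal()].
#' @return The experiments with a `z_aligned_um` column added to their cells.
#' @export
apply_alignment <- function(experiments, offsets) {
  lapply(experiments, function(exp) {
    off <- offsets$offset[match(exp$experiment_id, offsets$experiment_id)]
    if (is.na(off)) off <- 0
    exp$cells$z_aligned_um <- exp$cells$z_um + off
    if (!is.null(exp$sections)) {
      exp$sections$z_aligned_um <- exp$sections$z_um + off
    }
    exp
  })
}

#' Bin cells along the rostro-caudal axis
#'
#' Half-open bins `[k·w, (k+1)·w)` indexed by integer `k`; every cell falls
#' in exactly one bin, so the bins partition the input.
#'
#' @param cells Tibble of cell records with aligned z (column
#'   `z_aligned_um`, falling back to `z_um`).
#' @param bin_width_um Bin width in μm (default 800).
#' @param origin Z value at the lower edge of bin 0.
#' @return Named list mapping bin index to the cells in that bin.
#' @export
bin_rostrocaudal <- function(cells, bin_width_um = 800, origin = 0) {
  if (!is.numeric(bin_width_um) || length(bin_width_um) != 1L || bin_width_um <= 0) {
    abort("`bin_width_um` must be a single positive number.",
          class = "premotormap_parameter_error")
  }
  if (nrow(cells) == 0L) return(list())
  z <- if ("z_aligned_um" %in% names(cells)) cells$z_aligned_um else cells$z_um
  idx <- floor((z - origin) / bin_width_um)
  split(cells, idx)
}
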