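#' Hedges' g standardized mean difference
#'
#' Bias-corrected standardized difference of means:
#' `g = J * (mean(a) - mean(b)) / s_pooled` with
#' `s_pooled = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))` and
#' small-sample correction `J = 1 - 3 / (4 (n_a + n_b) - 9)`. Antisymmetric
#' under swapping the samples. Absolute values are conventionally banded as
#' no effect (< 0.2), small (0.2–0.49), medium (0.5–0.79), large (≥ 0.8).
#'
#' @param a,b Numeric samples, each of length ≥ 2.
#' @return Signed effect size.
#' @export
hedges_g <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  if (na < 2L || nb < 2L) {
    abort("Each sample needs at least 2 observations.",
          class = "premotormap_insufficient_data_error")
  }
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (sp == 0) {
    abort("Undefined effect size: pooled standard deviation is zero.",
          class = "premotormap_degenerate_error")
  }
  j <- 1 - 3 / (4 * (na + nb) - 9)
  j * (mean(a) - mean(b)) / sp
}

#' Effect-size band of an absolute Hedges' g
#'
#' @param g Numeric vector of (signed) effect sizes.
#' @param thresholds Lower edges of the small/medium/large bands.
#' @return Character vector: `"none"`, `"small"`, `"medium"` or `"large"`.
#' @export
effect_band <- function(g, thresholds = c(small = 0.2, medium = 0.5, large = 0.8)) {
  cut(abs(g), breaks = c(0, thresholds, Inf), right = FALSE,
      labels = c("none", names(thresholds))) |> as.character()
}

# Fast mean/var summaries of one two-level bootstrap replica of a group:
# animals resampled with replacement, then coordinates within each drawn
# animal resampled with replacement keeping the animal's own sample size.
replica_stats <- function(group, sizes, n_replicas) {
  k <- length(group)
  means <- numeric(n_replicas)
  vars <- numeric(n_replicas)
  ns <- integer(n_replicas)
  for (r in seq_len(n_replicas)) {
    idx <- sample.int(k, k, replace = TRUE)
    draw <- unlist(lapply(idx, function(i) {
      v <- group[[i]]
      v[sample.int(sizes[i], sizes[i], replace = TRUE)]
    }), use.names = FALSE)
    means[r] <- mean(draw)
    vars[r] <- stats::var(draw)
    ns[r] <- length(draw)
  }
  list(mean = means, var = vars, n = ns)
}

#' Two-level hierarchical bootstrap of Hedges' g
#'
#' Respects the nested animal/cell structure of tracing data: for each
#' replica, animals are resampled with replacement (first level) and the
#' coordinate sample within each drawn animal is resampled with replacement
#' at its own size (second level). Replicas of group A are paired with
#' independently drawn replicas of group B and Hedges' g is computed per
#' pair; the median and (25th, 75th) percentile interval of the resulting g
#' distribution summarise the contrast. With a single animal per group the
#' procedure degrades gracefully to a flat bootstrap of that animal's cells.
#'
#' @param group_a,group_b Lists of per-animal numeric coordinate vectors.
#' @param n_replicas Number of bootstrap replicas (default 5000).
#' @param seed Integer seed; the result is fully reproducible given the seed.
#' @return An object of class `pm_effect` with `g_median`, `g_iqr`,
#'   `g_values`, `n_replicas`, `seed` and group sizes.
#' @export
hierarchical_bootstrap <- function(group_a, group_b, n_replicas = 5000, seed = 1) {
  for (g in list(group_a, group_b)) {
    if (length(g) == 0L || any(vapply(g, length, 1L) == 0L)) {
      abort("Each group needs at least one animal with at least one coordinate.",
            class = "premotormap_insufficient_data_error")
    }
  }
  group_a <- lapply(group_a, as.numeric)
  group_b <- lapply(group_b, as.numeric)
  sizes_a <- vapply(group_a, length, 1L)
  sizes_b <- vapply(group_b, length, 1L)
  res <- with_seed(seed, {
    sa <- replica_stats(group_a, sizes_a, n_replicas)
    sb <- replica_stats(group_b, sizes_b, n_replicas)
    pair <- sample.int(n_replicas, n_replicas, replace = TRUE)
    list(sa = sa, sb = sb, pair = pair)
  })
  sa <- res$sa
  sb <- lapply(res$sb, function(v) v[res$pair])
  sp <- sqrt(((sa$n - 1) * sa$var + (sb$n - 1) * sb$var) / (sa$n + sb$n - 2))
  j <- 1 - 3 / (4 * (sa$n + sb$n) - 9)
  g <- j * (sa$mean - sb$mean) / sp
  q <- unname(quantile(g, c(0.25, 0.5, 0.75), names = FALSE))
  structure(list(g_median = q[2L],
                 g_iqr = c(q[1L], q[3L]),
                 g_values = g,
                 n_replicas = n_replicas,
                 seed = seed,
                 n_animals = c(a = length(group_a), b = length(group_b)),
                 n_cells = c(a = sum(sizes_a), b = sum(sizes_b))),
            class = "pm_effect")
}

#' @export
print.pm_effect <- function(x, ...) {
  cat(sprintf("<pm_effect> hierarchical bootstrap Hedges' g = %.3f (IQR %.3f, %.3f), %d replicas, band: %s\n",
              x$g_median, x$g_iqr[1L], x$g_iqr[2L], x$n_replicas,
              effect_band(x$g_median)))
  invisible(x)
}

#' Median position of premotor interneurons in a quadrant
#'
#' The headline positional summary: the median normalized coordinate (by
#' default medio-lateral, in the dorsal ipsilateral quadrant) over the
#' experiment's interneurons. Classified motor neurons are excluded.
#'
#' @param exp A normalized `pm_experiment`.
#' @param quadrant One of `"ipsi_dorsal"`, `"ipsi_ventral"`,
#'   `"contra_dorsal"`, `"contra_ventral"`.
#' @param axis `"x"` (medio-lateral) or `"y"` (dorso-ventral).
#' @return One-row tibble with `experiment_id`, `quadrant`, `axis`,
#'   `median_um`, `n_cells` and an `empty` flag (when the quadrant holds no
#'   cells, `median_um` is `NA`).
#' @export
median_position <- function(exp, quadrant = "ipsi_dorsal", axis = c("x", "y")) {
  axis <- match.arg(axis)
  quadrant <- match.arg(quadrant, .quadrants)
  coords <- quadrant_coords(exp, quadrant, axis)
  tibble::tibble(
    experiment_id = exp$experiment_id,
    quadrant = quadrant,
    axis = axis,
    median_um = if (length(coords) == 0L) NA_real_ else median(coords),
    n_cells = length(coords),
    empty = length(coords) == 0L
  )
}

# Normalized coordinates of the experiment's interneurons in one quadrant.
quadrant_coords <- function(exp, quadrant, axis = "x") {
  cells <- premotor_cells(exp)
  if (nrow(cells) == 0L) return(numeric(0))
  if (!all(c("x_norm_um", "y_norm_um") %in% names(cells))) {
    abort("Cells carry no normalized coordinates; run normalize_experiment() first.",
          class = "premotormap_state_error")
  }
  q <- quadrant_of(cells$x_norm_um, cells$y_norm_um)
  coords <- if (axis == "x") cells$x_norm_um else cells$y_norm_um
  coords[q == quadrant]
}

#' Pairwise Hedges' g matrix across experiments
#'
#' Plain (non-bootstrap) Hedges' g on the chosen quadrant coordinate for
#' every pair of experiments, stored lower-triangular in input order, with a
#' median/IQR summary of the signed pairwise values.
#'
#' @param experiments List of ≥ 2 normalized `pm_experiment` objects.
#' @param quadrant,axis Passed to the per-experiment coordinate extraction.
#' @return List of class `pm_pairwise` with `g` (lower-triangular matrix),
#'   `summary` (tibble with median and IQR of the signed pairwise values)
#'   and `n_pairs`. Undefined pairs are `NA`.
#' @export
pairwise_effect_matrix <- function(experiments, quadrant = "ipsi_dorsal",
                                   axis = "x") {
  if (length(experiments) < 2L) {
    abort("Need at least two experiments.",
          class = "premotormap_parameter_error")
  }
  ids <- vapply(experiments, function(e) e$experiment_id, character(1))
  coords <- lapply(experiments, quadrant_coords, quadrant = quadrant, axis = axis)
  k <- length(coords)
  m <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  vals <- c()
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      gij <- tryCatch(hedges_g(coords[[i]], coords[[j]]),
                      error = function(e) NA_real_)
      m[j, i] <- gij # lower triangle, row j > column i
      vals <- c(vals, gij)
    }
  }
  vals_ok <- vals[!is.na(vals)]
  q <- if (length(vals_ok) > 0L) {
    quantile(vals_ok, c(0.25, 0.5, 0.75), names = FALSE)
  } else {
    rep(NA_real_, 3L)
  }
  structure(list(
    g = m,
    summary = tibble::tibble(quadrant = quadrant, axis = axis,
                             g_median = q[2L], g_q25 = q[1L], g_q75 = q[3L],
                             n_pairs = length(vals_ok)),
    n_pairs = length(vals_ok)
  ), class = "pm_pairwise")
}
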