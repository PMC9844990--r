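#' Scale a cell count by the section-sampling fraction
#'
#' Experiments that analysed only every k-th section undercount cells by the
#' sampling fraction; dividing by the fraction estimates the whole-cord
#' total.
#'
#' @param count Non-negative cell count(s).
#' @param sampling_fraction Fraction(s) of sections analysed, in (0, 1].
#' @return `count / sampling_fraction`.
#' @export
scale_count <- function(count, sampling_fraction) {
  if (any(!is.finite(sampling_fraction)) || any(sampling_fraction <= 0) ||
      any(sampling_fraction > 1)) {
    abort("`sampling_fraction` must lie in (0, 1].",
          class = "premotormap_parameter_error")
  }
  if (any(count[is.finite(count)] < 0)) {
    abort("`count` must be non-negative.",
          class = "premotormap_parameter_error")
  }
  count / sampling_fraction
}

#' Power-law fit of premotor-interneuron vs starter motor-neuron counts
#'
#' Fits `y = a * x^b` by ordinary least squares on (log x, log y) — the
#' conventional reading of a power-law fit with an R² on log axes. By
#' default both counts are first scaled by the section-sampling fraction,
#' since both are per-animal totals undercounted by the same sampling.
#' Records with unknown or non-positive motor-neuron counts are excluded and
#' reported.
#'
#' @param records Count records (see [read_metadata()]) with columns
#'   `n_starter_mn`, `n_premotor`, `sampling_fraction`.
#' @param scale_by_sampling Scale both counts by the sampling fraction
#'   before fitting (default `TRUE`).
#' @return Object of class `pm_powerlaw` with `a`, `b`, `r_squared`,
#'   `n_points`, `excluded` (experiment/muscle labels of dropped rows) and
#'   the fitted data.
#' @export
fit_power_law <- function(records, scale_by_sampling = TRUE) {
  usable <- is.finite(records$n_starter_mn) & records$n_starter_mn > 0 &
    is.finite(records$n_premotor) & records$n_premotor > 0
  excluded <- records[!usable, , drop = FALSE]
  rec <- records[usable, , drop = FALSE]
  if (nrow(rec) < 3L) {
    abort("Need at least 3 records with known positive counts.",
          class = "premotormap_insufficient_data_error")
  }
  x <- rec$n_starter_mn
  y <- rec$n_premotor
  if (scale_by_sampling) {
    x <- scale_count(x, rec$sampling_fraction)
    y <- scale_count(y, rec$sampling_fraction)
  }
  if (stats::var(log(y)) == 0) {
    abort("Undefined fit: zero variance in log counts.",
          class = "premotormap_degenerate_error")
  }
  fit <- lm(log(y) ~ log(x))
  label <- if (all(c("experiment_id", "muscle") %in% names(excluded))) {
    paste(excluded$experiment_id, excluded$muscle)
  } else {
    rownames(excluded)
  }
  structure(list(
    a = unname(exp(stats::coef(fit)[1L])),
    b = unname(stats::coef(fit)[2L]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n_points = nrow(rec),
    excluded = label,
    data = tibble::tibble(mn = x, premotor = y)
  ), class = "pm_powerlaw")
}

#' @export
print.pm_powerlaw <- function(x, ...) {
  cat(sprintf("<pm_powerlaw> y = %.2f * x^%.3f, R^2 = %.3f (n = %d, %d excluded)\n",
              x$a, x$b, x$r_squared, x$n_points, length(x$excluded)))
  invisible(x)
}

#' Interneuron / motor-neuron count-ratio summary per group
#'
#' Median and interquartile range of the per-experiment premotor-IN to
#' starter-MN ratio within groups defined by an explicit grouping rule on
#' the records (by default a titre classification: high ≥ 5e9 IU/ml, low
#' < 1e9 IU/ml, in-between unclassified).
#'
#' @param records Count records with `n_starter_mn`, `n_premotor` and the
#'   columns the grouping rule uses.
#' @param grouping Function mapping the records tibble to a character vector
#'   of group labels (`NA` = unclassified, dropped).
#' @return Tibble with one row per group: `group`, `median`, `q25`, `q75`,
#'   `n`. Empty groups are flagged with `n = 0` and `NA` statistics.
#' @export
ratio_summary <- function(records, grouping = titre_grouping()) {
  ok <- is.finite(records$n_starter_mn) & records$n_starter_mn > 0 &
    is.finite(records$n_premotor)
  rec <- records[ok, , drop = FALSE]
  labels <- grouping(rec)
  ratio <- rec$n_premotor / rec$n_starter_mn
  keep <- !is.na(labels)
  out <- lapply(unique(labels[keep]), function(gr) {
    r <- ratio[keep & labels == gr]
    q <- quantile(r, c(0.25, 0.5, 0.75), names = FALSE)
    tibble::tibble(group = gr, median = q[2L], q25 = q[1L], q75 = q[3L],
                   n = length(r))
  })
  if (length(out) == 0L) {
    return(tibble::tibble(group = character(0), median = numeric(0),
                          q25 = numeric(0), q75 = numeric(0), n = integer(0)))
  }
  dplyr::bind_rows(out)
}

#' Titre-class grouping rule
#'
#' High-titre injections are defined as ≥ 5e9 IU/ml, low-titre as < 1e9
#' IU/ml; titres in between are unclassified (`NA`).
#'
#' @param high,low Thresholds in IU/ml.
#' @return A function usable as the `grouping` argument of [ratio_summary()].
#' @export
titre_grouping <- function(high = 5e9, low = 1e9) {
  function(records) {
    t <- records$titre_IU_per_ml
    ifelse(!is.finite(t), NA_character_,
           ifelse(t >= high, "high", ifelse(t < low, "low", NA_character_)))
  }
}

#' Starter motor-neuron bookkeeping for double injections
#'
#' Sums labelled motor-neuron counts per muscle, and double-labelled
#' motor-neuron counts, over the experiments selected by an explicit
#' predicate — by default the double injections of the given muscle pair
#' whose double-label count was recorded. Selected experiments missing a
#' required count are excluded with a warning.
#'
#' @param metadata Metadata tibble (see [read_metadata()]); double
#'   injections appear as two rows sharing one `experiment_id`, with the
#'   double-label count on the first row.
#' @param muscles Muscle pair defining the selection (default LG + TA).
#' @param require_double_count Keep only experiments whose double-label
#'   count is recorded (default `TRUE`).
#' @return List with `per_muscle` (named vector of summed MN counts),
#'   `double` (summed double-labelled count), `n_experiments`,
#'   `experiment_ids` and an `empty` flag.
#' @export
starter_mn_summary <- function(metadata, muscles = c("LG", "TA"),
                               require_double_count = TRUE) {
  groups <- split(metadata, metadata$experiment_id)
  selected <- Filter(function(g) {
    setequal(g$muscle, muscles) && nrow(g) == length(muscles) &&
      (!require_double_count || any(is.finite(g$n_double_mn)))
  }, groups)
  per_muscle <- stats::setNames(numeric(length(muscles)), muscles)
  double <- 0
  kept <- character(0)
  for (g in selected) {
    if (any(!is.finite(g$n_starter_mn))) {
      warn(sprintf("Experiment %s selected but missing a motor-neuron count; excluded.",
                   g$experiment_id[[1L]]))
      next
    }
    for (m in muscles) {
      per_muscle[[m]] <- per_muscle[[m]] + g$n_starter_mn[g$muscle == m]
    }
    double <- double + sum(g$n_double_mn[is.finite(g$n_double_mn)])
    kept <- c(kept, g$experiment_id[[1L]])
  }
  list(per_muscle = per_muscle,
       double = double,
       n_experiments = length(kept),
       experiment_ids = kept,
       empty = length(kept) == 0L)
}
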