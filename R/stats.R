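#' Per-animal means of each metric
#'
#' Collapses an object-level metrics table to one arithmetic mean per
#' (group, animal, metric) — the "black dots" level of a hierarchical
#' two-group design.
#'
#' @param table Metrics tibble with `animal` (and optionally `group`)
#'   columns plus numeric metric columns.
#' @param metrics Character vector of metric column names; default all
#'   numeric columns except bookkeeping ones.
#' @return Long tibble: `group` (if present), `animal`, `metric`, `mean`.
#' @export
animal_means <- function(table, metrics = NULL) {
  if (!"animal" %in% names(table)) {
    abort("metrics table has no `animal` column.", class = "mitomorph_validation_error")
  }
  if (is.null(metrics)) metrics <- default_metric_cols(table)
  keys <- intersect(c("group", "animal"), names(table))
  table |>
    dplyr::select(dplyr::all_of(c(keys, metrics))) |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric", values_to = "value") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "metric")))) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE), .groups = "drop")
}

default_metric_cols <- function(table) {
  drop <- c("object_id", "crista_id", "parent_mito_id", "mito_id", "voxel_count",
            "centroid_z_nm", "centroid_y_nm", "centroid_x_nm", "overlap_fraction",
            "n_cristae", "n_raters")
  num <- names(table)[vapply(table, is.numeric, TRUE)]
  setdiff(num, drop)
}

#' Significance stars for a p-value
#'
#' Strict thresholds: `p < 0.05` one star, `< 0.01` two, `< 0.001` three,
#' `< 0.0001` four, otherwise `ns` (so p = 0.05 exactly is `ns`).
#'
#' @param p Numeric p-value(s).
#' @return Character vector in `{ns, *, **, ***, ****}`.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) NA_character_
    else if (pp < 1e-4) "****"
    else if (pp < 1e-3) "***"
    else if (pp < 1e-2) "**"
    else if (pp < 0.05) "*"
    else "ns"
  }, "")
}

sem <- function(x) sd(x) / sqrt(length(x))

#' Two-group comparison of one metric
#'
#' The workhorse test behind every figure-style comparison: Welch's
#' unequal-variance t-test by default (`pooled = TRUE` gives classical
#' Student's t), with a non-parametric branch. Under `method = "auto"` a
#' normality screen (Shapiro-Wilk at alpha = 0.05 on either sample;
#' Anderson-Darling for n > 5000) switches the primary inference to the
#' Mann-Whitney rank-sum test; both tests' p-values are always recorded.
#'
#' @param values_a,values_b Numeric samples (n >= 2 each).
#' @param method `"auto"`, `"t"` or `"mann_whitney"`.
#' @param labels Length-2 group labels.
#' @param metric Metric name carried into the output.
#' @param level `"object"` or `"animal"`, bookkeeping only.
#' @param pooled Use pooled-variance Student's t instead of Welch.
#' @return A `group_comparison` object; see [tidy.group_comparison()].
#' @export
compare_groups <- function(values_a, values_b, method = c("auto", "t", "mann_whitney"),
                           labels = c("a", "b"), metric = "value",
                           level = "object", pooled = FALSE) {
  method <- match.arg(method)
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs n >= 2 finite values.", class = "mitomorph_validation_error")
  }
  degenerate <- sd(a) == 0 && sd(b) == 0
  if (degenerate && mean(a) == mean(b)) {
    t_stat <- 0; p_t <- 1; p_mw <- 1
  } else if (degenerate) {
    t_stat <- Inf * sign(mean(b) - mean(a)); p_t <- 0; p_mw <- 0
  } else {
    tt <- t.test(a, b, var.equal = pooled)
    t_stat <- unname(tt$statistic); p_t <- tt$p.value
    p_mw <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }
  norm_p <- vapply(list(a, b), function(x) {
    if (sd(x) == 0) return(0)
    if (length(x) < 3) return(1) # too few values to screen; assume normal
    if (length(x) <= 5000) shapiro.test(x)$p.value else nortest::ad.test(x)$p.value
  }, 0.0)
  primary <- switch(method,
    t = "t",
    mann_whitney = "mann_whitney",
    auto = if (any(norm_p < 0.05)) "mann_whitney" else "t")
  p <- if (primary == "t") p_t else p_mw
  diff_means <- mean(b) - mean(a)
  structure(list(
    metric = metric, level = level, groups = labels,
    n = c(length(a), length(b)),
    test = if (primary == "t") (if (pooled) "student_t" else "welch_t") else "mann_whitney",
    statistic = if (degenerate || primary == "t") t_stat else
      unname(suppressWarnings(wilcox.test(a, b, exact = FALSE)$statistic)),
    p_value = p, p_t = p_t, p_mann_whitney = p_mw,
    normality_p = norm_p,
    direction = if (diff_means > 0) "increase" else if (diff_means < 0) "decrease" else "none",
    stars = significance_stars(p),
    means = c(mean(a), mean(b)), sems = c(sem(a), sem(b))
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s level): %s vs %s (n = %d, %d)\n",
              x$metric, x$level, x$groups[1], x$groups[2], x$n[1], x$n[2]))
  cat(sprintf("  %s: p = %.3g %s; means %.4g vs %.4g (%s in %s)\n",
              x$test, x$p_value, x$stars, x$means[1], x$means[2],
              x$direction, x$groups[2]))
  invisible(x)
}

#' Tidy a two-group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return One-row tibble with test, statistic, p-values, stars, per-group
#'   means/SEMs and the direction of change in the second group.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(
    metric = x$metric, level = x$level,
    group_a = x$groups[1], group_b = x$groups[2],
    n_a = x$n[1], n_b = x$n[2],
    test = x$test, statistic = x$statistic,
    p_value = x$p_value, p_t = x$p_t, p_mann_whitney = x$p_mann_whitney,
    mean_a = x$means[1], mean_b = x$means[2],
    sem_a = x$sems[1], sem_b = x$sems[2],
    direction = x$direction, stars = x$stars
  )
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         stars = x$stars, direction = x$direction)
}

#' Compare every metric of a table between two groups
#'
#' Object-level inference is primary (matching per-structure figure
#' panels); `level = "animal"` first collapses via [animal_means()] for the
#' hierarchical per-animal view.
#'
#' @param table Metrics tibble with a `group` column (exactly two groups).
#' @param metrics Metric columns (default: numeric, minus bookkeeping).
#' @param level `"object"` or `"animal"`.
#' @param ... Passed to [compare_groups()].
#' @return Tidy tibble, one row per metric.
#' @export
compare_metrics <- function(table, metrics = NULL, level = c("object", "animal"), ...) {
  level <- match.arg(level)
  if (!"group" %in% names(table)) abort("metrics table needs a `group` column.")
  gs <- sort(unique(as.character(table$group)))
  if (length(gs) != 2) abort("exactly two groups required.")
  if (is.null(metrics)) metrics <- default_metric_cols(table)
  if (level == "animal") {
    am <- animal_means(table, metrics)
    purrr::map_dfr(metrics, function(m) {
      sub <- am[am$metric == m, ]
      tidy(compare_groups(sub$mean[sub$group == gs[1]], sub$mean[sub$group == gs[2]],
                          labels = gs, metric = m, level = "animal", ...))
    })
  } else {
    purrr::map_dfr(metrics, function(m) {
      tidy(compare_groups(table[[m]][table$group == gs[1]],
                          table[[m]][table$group == gs[2]],
                          labels = gs, metric = m, level = "object", ...))
    })
  }
}

#' Within- and between-animal heterogeneity of each metric
#'
#' Within-animal coefficient of variation (sample sd / mean per animal) and
#' the between-animal CV of the animal means, per group and metric. CVs are
#' undefined (NA, flagged) for animals with a single object or mean zero.
#'
#' @param table Metrics tibble with `group`, `animal` and metric columns.
#' @param metrics Metric columns (default auto-detected).
#' @return List with `$within` (group, animal, metric, n, mean, cv,
#'   flagged) and `$between` (group, metric, between_animal_cv).
#' @export
heterogeneity <- function(table, metrics = NULL) {
  if (is.null(metrics)) metrics <- default_metric_cols(table)
  long <- table |>
    dplyr::select(dplyr::all_of(c("group", "animal", metrics))) |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric", values_to = "value")
  within <- long |>
    dplyr::group_by(.data$group, .data$animal, .data$metric) |>
    dplyr::summarise(n = sum(is.finite(.data$value)),
                     mean = mean(.data$value, na.rm = TRUE),
                     cv = if (sum(is.finite(.data$value)) >= 2 &&
                              mean(.data$value, na.rm = TRUE) != 0)
                       sd(.data$value, na.rm = TRUE) / mean(.data$value, na.rm = TRUE)
                     else NA_real_,
                     .groups = "drop") |>
    dplyr::mutate(flagged = !is.finite(.data$cv))
  between <- within |>
    dplyr::group_by(.data$group, .data$metric) |>
    dplyr::summarise(between_animal_cv = if (dplyr::n() >= 2 && mean(.data$mean) != 0)
      sd(.data$mean) / mean(.data$mean) else NA_real_,
      .groups = "drop")
  list(within = within, between = between)
}
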