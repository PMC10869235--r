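#' Measure a whole synthetic (or loaded) cohort
#'
#' Runs mitochondrial morphometry, cristae morphometry, cristae-parent
#' assignment, normalized cristae records and per-mitochondrion summaries
#' for every animal volume pair, and attaches `group`/`animal` labels.
#'
#' @param cohort List as returned by [generate_cohort()] (`$volumes`,
#'   `$groups`), or a compatible structure built from files.
#' @param min_voxels Speck threshold passed to [measure_all()].
#' @param min_overlap Assignment threshold passed to [assign_cristae()].
#' @return List of tibbles: `mito`, `cristae` (CristaeRecord rows),
#'   `summaries` (MitoCristaeSummary rows).
#' @export
measure_cohort <- function(cohort, min_voxels = 10, min_overlap = 0.5) {
  srcs <- names(cohort$volumes)
  res <- purrr::map(srcs, function(src) {
    pair <- cohort$volumes[[src]]
    mito <- dplyr::filter(measure_all(pair$mito, min_voxels = min_voxels), .data$ok)
    cr <- dplyr::filter(measure_all(pair$cristae, min_voxels = min_voxels), .data$ok)
    asg <- assign_cristae(pair$cristae, pair$mito, min_overlap = min_overlap)
    rec <- cristae_records(cr, mito, asg)
    summ <- summarize_cristae_by_mito(mito, rec)
    list(mito = mito, cristae = rec, summaries = summ)
  })
  lab <- function(tbl) {
    tbl <- dplyr::left_join(tbl, cohort$groups, by = "source_id")
    dplyr::mutate(tbl, animal = .data$source_id, .after = "group")
  }
  list(mito = lab(purrr::map_dfr(res, "mito")),
       cristae = lab(purrr::map_dfr(res, "cristae")),
       summaries = lab(purrr::map_dfr(res, "summaries")))
}

mito_metric_cols <- c("volume_um3", "surface_area_um2", "perimeter_um", "sphericity", "mci")
cristae_metric_cols <- c("norm_volume", "norm_area", "norm_perimeter")

#' Full two-group comparison battery for a measured cohort
#'
#' Object-level comparisons of the five mitochondrial metrics, the three
#' volume-normalized cristae metrics, cristae density and the consensus
#' cristae score, plus animal-level comparisons of the mitochondrial
#' metrics as the hierarchical caveat. No multiple-testing correction is
#' applied by default (`p_adjust = "none"`), mirroring per-figure testing;
#' any [stats::p.adjust()] method can be requested.
#'
#' @param measured Output of [measure_cohort()].
#' @param scores Rater-level score table (e.g. `cohort$scores`).
#' @param groups Source-to-group map.
#' @param p_adjust Multiple-testing correction method (default `"none"`).
#' @param ... Passed to [compare_groups()] (e.g. `method`, `pooled`).
#' @return Tidy tibble, one row per (metric, level) comparison.
#' @export
compare_cohort <- function(measured, scores = NULL, groups = NULL,
                           p_adjust = "none", ...) {
  n_animals <- measured$mito |>
    dplyr::distinct(.data$group, .data$animal) |>
    dplyr::count(.data$group)
  out <- list(
    compare_metrics(measured$mito, mito_metric_cols, level = "object", ...),
    # the hierarchical per-animal view needs >= 2 animals per group
    if (all(n_animals$n >= 2))
      compare_metrics(measured$mito, mito_metric_cols, level = "animal", ...),
    compare_metrics(dplyr::filter(measured$cristae, .data$parent_mito_id > 0),
                    cristae_metric_cols, level = "object", ...),
    compare_metrics(measured$summaries, "cristae_density", level = "object", ...)
  )
  if (!is.null(scores)) {
    cons <- consensus_scores(scores)
    cons <- dplyr::left_join(cons, groups, by = "source_id")
    out <- c(out, list(compare_metrics(cons, "score", level = "object", ...)))
  }
  res <- dplyr::bind_rows(out)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = p_adjust)
  res
}

#' Assemble a pipeline run configuration
#'
#' @param spec A [cohort_spec()] (simulation input), or `NULL` when
#'   `inputs` point at existing volume files.
#' @param inputs Optional tibble/list with `source_id`, `group`,
#'   `mito_path`, `cristae_path`, `scores_path` for measured data.
#' @param stages Stages to run, in order, from `simulate`, `measure`,
#'   `cristae`, `score`, `compare`, `otype`, `report`.
#' @param n_bins,representatives Otyping layout.
#' @param min_voxels,min_overlap,perimeter_reducer,stats_method Module options.
#' @param write_volumes Write the simulated label volumes as NRRD pairs
#'   (off by default; the metric tables are the primary artifacts).
#' @param seed Run seed (defaults to the spec's).
#' @return A `run_config` list.
#' @export
pipeline_config <- function(spec = cohort_spec(), inputs = NULL,
                            stages = c("simulate", "measure", "cristae", "score",
                                       "compare", "otype", "report"),
                            n_bins = 7, representatives = 1,
                            min_voxels = 10, min_overlap = 0.5,
                            perimeter_reducer = "mean", stats_method = "auto",
                            write_volumes = FALSE, seed = NULL) {
  structure(list(spec = spec, inputs = inputs, stages = stages, n_bins = n_bins,
                 representatives = representatives, min_voxels = min_voxels,
                 min_overlap = min_overlap, perimeter_reducer = perimeter_reducer,
                 stats_method = stats_method, write_volumes = write_volumes,
                 seed = seed %||% (spec$seed %||% 1L)),
            class = "run_config")
}

#' Run the full morphometry pipeline
#'
#' Orchestrates simulate -> measure -> cristae -> score -> compare -> otype
#' -> report with file-based stage contracts: every stage writes its CSV /
#' PNG / JSON artifacts into `out_dir`, the configuration is serialized
#' verbatim to `config.json`, and re-running from the same config and seed
#' reproduces all deterministic outputs byte-for-byte. A stage failure is
#' logged to `pipeline.log` and downstream stages are skipped.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `$tables`, `$status` (stage, ok, note)
#'   and `$paths`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- file.path(out_dir, "config.json")
  ser <- config
  ser$spec <- unclass(ser$spec)
  jsonlite::write_json(unclass(ser), cfg_json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  logf <- file.path(out_dir, "pipeline.log")
  status <- list()
  note <- function(stage, ok, msg = "") {
    status[[stage]] <<- tibble(stage = stage, ok = ok, note = msg)
    cat(sprintf("[%s] %s %s\n", stage, if (ok) "ok" else "FAILED", msg),
        file = logf, append = TRUE)
  }
  state <- new.env(parent = emptyenv())
  failed <- FALSE
  run_stage <- function(stage, fun) {
    if (failed || !stage %in% config$stages) return(invisible())
    tryCatch({ fun(); note(stage, TRUE) },
             error = function(e) { failed <<- TRUE; note(stage, FALSE, conditionMessage(e)) })
  }

  run_stage("simulate", function() {
    spec <- config$spec
    spec$seed <- config$seed
    state$cohort <- generate_cohort(spec)
    readr::write_csv(dplyr::select(state$cohort$truth, -"shape_params"),
                     file.path(out_dir, "ground_truth.csv"), progress = FALSE)
    readr::write_csv(state$cohort$scores, file.path(out_dir, "scores.csv"),
                     progress = FALSE)
    if (isTRUE(config$write_volumes)) write_cohort(state$cohort, file.path(out_dir, "volumes"))
  })
  if (!"simulate" %in% config$stages && !is.null(config$inputs)) {
    state$cohort <- load_cohort_inputs(config$inputs)
  }

  run_stage("measure", function() {
    state$measured <- measure_cohort(state$cohort, min_voxels = config$min_voxels,
                                     min_overlap = config$min_overlap)
    write_metrics_table(state$measured$mito, file.path(out_dir, "mito_metrics.csv"))
  })
  run_stage("cristae", function() {
    write_metrics_table(dplyr::rename(state$measured$cristae, object_id = "crista_id"),
                        file.path(out_dir, "cristae_metrics.csv"))
    readr::write_csv(state$measured$summaries,
                     file.path(out_dir, "mito_cristae_summary.csv"), progress = FALSE)
  })
  run_stage("score", function() {
    tbl <- ingest_scores(state$cohort$scores)
    cons <- consensus_scores(tbl)
    state$score_summary <- summarize_scores(cons, state$cohort$groups)
    readr::write_csv(dplyr::left_join(state$score_summary$by_level,
                                      state$score_summary$overall, by = "group"),
                     file.path(out_dir, "score_summary.csv"), progress = FALSE)
    ggplot2::ggsave(file.path(out_dir, "score_histogram.png"),
                    autoplot(state$score_summary), width = 5, height = 3.2, dpi = 150,
                    bg = "white")
  })
  run_stage("compare", function() {
    state$comparisons <- compare_cohort(state$measured, state$cohort$scores,
                                        state$cohort$groups,
                                        method = config$stats_method)
    readr::write_csv(state$comparisons, file.path(out_dir, "comparisons.csv"),
                     progress = FALSE)
  })
  run_stage("otype", function() {
    mito_vols <- purrr::map(state$cohort$volumes, "mito")
    state$mito_panel <- make_otype_panel(state$measured$mito, mito_vols,
                                         n_bins = config$n_bins, k = config$representatives)
    render_gallery(state$mito_panel, file.path(out_dir, "mito_otyping.png"))
    cr_vols <- purrr::map(state$cohort$volumes, "cristae")
    cr_tbl <- state$measured$cristae |>
      dplyr::filter(.data$parent_mito_id > 0) |>
      dplyr::rename(object_id = "crista_id")
    state$cristae_panel <- make_otype_panel(cr_tbl, cr_vols,
                                            n_bins = config$n_bins, k = config$representatives)
    render_gallery(state$cristae_panel, file.path(out_dir, "cristae_otyping.png"))
  })
  run_stage("report", function() {
    write_report(state, config, out_dir)
  })

  invisible(list(
    tables = list(mito = state$measured$mito, cristae = state$measured$cristae,
                  summaries = state$measured$summaries,
                  comparisons = state$comparisons),
    status = dplyr::bind_rows(status),
    paths = list(out_dir = out_dir, config = cfg_json, log = logf)
  ))
}

load_cohort_inputs <- function(inputs) {
  inputs <- as_tibble(inputs)
  volumes <- purrr::map(seq_len(nrow(inputs)), function(i) {
    list(mito = read_label_volume(inputs$mito_path[i]),
         cristae = read_label_volume(inputs$cristae_path[i]))
  })
  names(volumes) <- inputs$source_id
  scores <- if ("scores_path" %in% names(inputs) && !is.na(inputs$scores_path[1]))
    readr::read_csv(inputs$scores_path[1], show_col_types = FALSE, progress = FALSE)
  else NULL
  list(volumes = volumes, scores = scores,
       groups = dplyr::distinct(inputs[, c("source_id", "group")]))
}

write_report <- function(state, config, out_dir) {
  lines <- c("# Mitochondrial and cristae 3D morphometry report", "",
             sprintf("Seed: %d. Groups: %s.", config$seed,
                     paste(unique(state$cohort$groups$group), collapse = " vs ")), "")
  if (!is.null(state$measured)) {
    lines <- c(lines, sprintf("Objects measured: %d mitochondria, %d cristae.",
                              nrow(state$measured$mito), nrow(state$measured$cristae)), "")
  }
  if (!is.null(state$comparisons)) {
    cmp <- state$comparisons
    lines <- c(lines, "## Two-group comparisons", "",
               "| metric | level | test | p | stars | direction |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %.3g | %s | %s |",
                       cmp$metric, cmp$level, cmp$test, cmp$p_value, cmp$stars,
                       cmp$direction), "")
  }
  if (!is.null(state$score_summary)) {
    ov <- state$score_summary$overall
    lines <- c(lines, "## Cristae scores", "",
               sprintf("- %s: mean %.3f (SEM %.3f, n = %d)",
                       ov$group, ov$mean_score, ov$sem, ov$n), "")
  }
  lines <- c(lines, "Artifacts: mito_metrics.csv, cristae_metrics.csv,",
             "mito_cristae_summary.csv, score_summary.csv, comparisons.csv,",
             "mito_otyping.png, cristae_otyping.png (with JSON manifests).")
  writeLines(lines, file.path(out_dir, "report.md"))
}

#' Mean +- SEM comparison plot for one metric
#'
#' Bar chart of group means with SEM error bars and jittered per-object
#' points — the standard presentation for two-group morphometry panels.
#'
#' @param table Metrics tibble with `group` and the metric column.
#' @param metric Metric column name.
#' @param jitter_seed Seed for the deterministic point jitter.
#' @return A ggplot object.
#' @export
plot_comparison <- function(table, metric, jitter_seed = 1) {
  summ <- table |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean = mean(.data[[metric]], na.rm = TRUE),
                     sem = sd(.data[[metric]], na.rm = TRUE) /
                       sqrt(sum(is.finite(.data[[metric]]))), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey75", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem), width = 0.15) +
    ggplot2::geom_point(data = table,
                        ggplot2::aes(x = .data$group, y = .data[[metric]]),
                        alpha = 0.3, size = 0.6,
                        position = ggplot2::position_jitter(width = 0.15, seed = jitter_seed)) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_classic()
}
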