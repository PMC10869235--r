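#' Ingest a cristae-score annotation table
#'
#' Cristae scores are blinded human ratings of cristae normality on an
#' ordinal 1-4 scale (1 = minimal normal cristae, 2 = <50% normal, 3 =
#' 50-75% normal, 4 = normal cristae). They are ingested annotations, never
#' computed from geometry.
#'
#' @param path CSV with columns `source_id`, `object_id`, `rater_id`,
#'   `score` (or a data frame with those columns).
#' @return Validated `ScoreTable` tibble.
#' @export
ingest_scores <- function(path) {
  tbl <- if (is.data.frame(path)) as_tibble(path) else
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("source_id", "object_id", "rater_id", "score")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("score table lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "mitomorph_validation_error")
  }
  bad <- which(!(tbl$score %in% 1:4))
  if (length(bad) > 0) {
    abort(sprintf("score out of 1-4 range in row(s): %s",
                  paste(head(bad, 10), collapse = ", ")),
          class = "mitomorph_validation_error")
  }
  if (anyDuplicated(tbl[, c("source_id", "object_id", "rater_id")])) {
    abort("duplicate (source_id, object_id, rater_id) rows in score table.",
          class = "mitomorph_validation_error")
  }
  tbl$score <- as.integer(tbl$score)
  tbl
}

round_half_down <- function(x) ceiling(x - 0.5)

#' Per-object consensus score across blinded raters
#'
#' Default rule is the median across raters with half-valued ties rounded
#' down — toward the worse cristae call, a conservative, ordinal-safe
#' choice. `mean_rounded` averages then rounds (ties also half-down).
#'
#' @param table `ScoreTable` from [ingest_scores()].
#' @param rule `"median"` or `"mean_rounded"`.
#' @return Tibble `source_id`, `object_id`, `n_raters`, `score` with the
#'   rule recorded in the `consensus_rule` attribute.
#' @export
consensus_scores <- function(table, rule = c("median", "mean_rounded")) {
  rule <- match.arg(rule)
  out <- table |>
    dplyr::group_by(.data$source_id, .data$object_id) |>
    dplyr::summarise(
      n_raters = dplyr::n(),
      score = as.integer(round_half_down(
        if (rule == "median") median(.data$score) else mean(.data$score))),
      .groups = "drop")
  attr(out, "consensus_rule") <- rule
  out
}

#' Group-level cristae score aggregation
#'
#' Reproduces the score histogram layer: per group, the count and
#' percentage of objects at each score level plus mean score, SEM and n.
#'
#' @param scores Per-object scores: tibble with `source_id`, `object_id`,
#'   `score` (e.g. from [consensus_scores()]).
#' @param groups Either `NULL` (a `group` column is already present) or a
#'   two-column data frame `source_id`, `group` mapping every source to its
#'   group.
#' @return `ScoreSummary` list with `$by_level` (group, score, count,
#'   percentage) and `$overall` (group, n, mean_score, sem).
#' @export
summarize_scores <- function(scores, groups = NULL) {
  if (!is.null(groups)) {
    unmapped <- setdiff(unique(scores$source_id), groups$source_id)
    if (length(unmapped) > 0) {
      abort(paste0("source(s) not mapped to a group: ", paste(unmapped, collapse = ", ")),
            class = "mitomorph_validation_error")
    }
    scores <- dplyr::left_join(scores, groups, by = "source_id")
  }
  if (!"group" %in% names(scores)) {
    abort("no `group` column and no `groups` mapping supplied.",
          class = "mitomorph_validation_error")
  }
  by_level <- scores |>
    dplyr::count(.data$group, score = factor(.data$score, levels = 1:4), .drop = FALSE,
                 name = "count") |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(percentage = 100 * .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(score = as.integer(as.character(.data$score)))
  overall <- scores |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_score = mean(.data$score),
                     sem = sd(.data$score) / sqrt(dplyr::n()),
                     .groups = "drop")
  structure(list(by_level = by_level, overall = overall), class = "score_summary")
}

#' @export
print.score_summary <- function(x, ...) {
  cat("<score_summary>\n")
  print(x$overall)
  print(x$by_level)
  invisible(x)
}

#' @rdname summarize_scores
#' @param object A `score_summary`.
#' @param ... Unused.
#' @export
autoplot.score_summary <- function(object, ...) {
  ggplot2::ggplot(object$by_level,
                  ggplot2::aes(x = factor(.data$score), y = .data$percentage,
                               fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = "cristae score", y = "% of objects", fill = NULL) +
    ggplot2::theme_minimal()
}
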