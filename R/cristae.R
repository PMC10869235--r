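#' Assign cristae to parent mitochondria
#'
#' Mitochondria and cristae come from independent co-registered
#' segmentations, so cristae voxels need not be strict subsets of a
#' mitochondrion mask. Each crista is assigned to the mitochondrion label
#' containing the plurality of its voxels, provided that overlap fraction
#' reaches `min_overlap`; otherwise it is left unassigned (`parent_mito_id
#' = 0`). Ties break deterministically toward the lower mitochondrion id.
#'
#' @param cristae_vol,mito_vol Co-registered [label_volume()]s of identical
#'   shape and spacing.
#' @param min_overlap Minimum fraction of crista voxels inside the parent
#'   (default 0.5).
#' @return Tibble: `crista_id`, `parent_mito_id`, `overlap_fraction`,
#'   `crista_voxels`.
#' @export
assign_cristae <- function(cristae_vol, mito_vol, min_overlap = 0.5) {
  stopifnot(inherits(cristae_vol, "label_volume"), inherits(mito_vol, "label_volume"))
  if (!identical(dim(cristae_vol$grid), dim(mito_vol$grid)) ||
      !isTRUE(all.equal(unname(cristae_vol$spacing), unname(mito_vol$spacing)))) {
    abort("cristae and mitochondria volumes are not co-registered (shape/spacing mismatch).",
          class = "mitomorph_registration_error")
  }
  fg <- cristae_vol$grid > 0L
  if (!any(fg)) {
    return(tibble(crista_id = integer(), parent_mito_id = integer(),
                  overlap_fraction = double(), crista_voxels = integer()))
  }
  df <- tibble(crista_id = cristae_vol$grid[fg], mito = mito_vol$grid[fg])
  df |>
    dplyr::count(.data$crista_id, .data$mito, name = "n") |>
    dplyr::group_by(.data$crista_id) |>
    dplyr::mutate(total = sum(.data$n)) |>
    dplyr::filter(.data$mito > 0L) |>
    # plurality winner; ties toward lower mito id
    dplyr::arrange(dplyr::desc(.data$n), .data$mito, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::right_join(
      df |> dplyr::count(.data$crista_id, name = "total2"),
      by = "crista_id") |>
    dplyr::transmute(
      crista_id = .data$crista_id,
      overlap_fraction = ifelse(is.na(.data$n), 0, .data$n / .data$total2),
      parent_mito_id = ifelse(!is.na(.data$mito) & .data$overlap_fraction >= min_overlap,
                              .data$mito, 0L),
      crista_voxels = .data$total2
    ) |>
    dplyr::arrange(.data$crista_id)
}

#' Normalize one crista's metrics by its parent mitochondrion volume
#'
#' Each raw metric (volume, surface area, perimeter) is divided by the
#' parent mitochondrion's volume, per-crista, giving `norm_volume`
#' (dimensionless), `norm_area` (\eqn{\mu m^{-1}}) and `norm_perimeter`
#' (\eqn{\mu m^{-2}}). Raw values are retained.
#'
#' @param crista One-row metrics tibble (or list) for the crista with
#'   `volume_um3`, `surface_area_um2`, `perimeter_um`.
#' @param parent Same for the parent mitochondrion; `volume_um3` must be > 0.
#' @return One-row `CristaeRecord` tibble.
#' @export
normalized_metrics <- function(crista, parent) {
  if (is.null(parent) || !is.finite(parent$volume_um3) || parent$volume_um3 <= 0) {
    abort(paste0("crista has no valid parent mitochondrion; exclude unassigned ",
                 "cristae or opt into cohort-mean normalization explicitly."),
          class = "mitomorph_unassigned_error")
  }
  pv <- parent$volume_um3
  tibble(
    crista_id = crista$object_id %||% crista$crista_id,
    parent_mito_id = parent$object_id %||% parent$mito_id,
    volume_um3 = crista$volume_um3,
    surface_area_um2 = crista$surface_area_um2,
    perimeter_um = crista$perimeter_um,
    norm_volume = crista$volume_um3 / pv,
    norm_area = crista$surface_area_um2 / pv,
    norm_perimeter = crista$perimeter_um / pv
  )
}

#' Build the full cristae record table for a cohort volume pair
#'
#' Joins measured cristae metrics with their assignment and parent
#' mitochondrion metrics; unassigned cristae are retained with
#' `parent_mito_id = 0` and `NA` normalized values (and are excluded from
#' group statistics downstream).
#'
#' @param cristae_metrics Metrics tibble from [measure_all()] on the cristae
#'   volume.
#' @param mito_metrics Metrics tibble from [measure_all()] on the
#'   mitochondria volume.
#' @param assignment Output of [assign_cristae()].
#' @return `CristaeRecord` tibble, one row per measured crista.
#' @export
cristae_records <- function(cristae_metrics, mito_metrics, assignment) {
  parents <- mito_metrics |>
    dplyr::select(parent_mito_id = "object_id", parent_volume_um3 = "volume_um3")
  cristae_metrics |>
    dplyr::rename(crista_id = "object_id") |>
    dplyr::left_join(assignment, by = "crista_id") |>
    dplyr::mutate(parent_mito_id = dplyr::coalesce(.data$parent_mito_id, 0L),
                  overlap_fraction = dplyr::coalesce(.data$overlap_fraction, 0)) |>
    dplyr::left_join(parents, by = "parent_mito_id") |>
    dplyr::mutate(
      norm_volume = .data$volume_um3 / .data$parent_volume_um3,
      norm_area = .data$surface_area_um2 / .data$parent_volume_um3,
      norm_perimeter = .data$perimeter_um / .data$parent_volume_um3
    ) |>
    dplyr::select("source_id", "crista_id", "parent_mito_id", "overlap_fraction",
                  "voxel_count", "volume_um3", "surface_area_um2", "perimeter_um",
                  "sphericity", "mci", "parent_volume_um3",
                  "norm_volume", "norm_area", "norm_perimeter")
}

#' Summarize cristae content of one mitochondrion
#'
#' Computes cristae count, total cristae volume, cristae density
#' (\eqn{\sum} cristae volume / mitochondrion volume) and matrix volume
#' (mitochondrion volume \eqn{-} \eqn{\sum} cristae volume). The
#' conservation identity `matrix_volume + total_cristae_volume ==
#' mito_volume` holds exactly by construction (set difference by volume, so
#' 1-voxel registration slack does not break it).
#'
#' @param mito One-row mitochondrion metrics (needs `object_id`, `volume_um3`).
#' @param cristae `CristaeRecord` rows assigned to this mitochondrion.
#' @return One-row `MitoCristaeSummary` tibble.
#' @export
summarize_mito <- function(mito, cristae) {
  total <- if (is.null(cristae) || nrow(cristae) == 0) 0 else
    sum(cristae$volume_um3, na.rm = TRUE)
  if (total >= mito$volume_um3 && total > 0) {
    abort("total cristae volume >= mitochondrial volume: inconsistent segmentation (cristae must be subsets).",
          class = "mitomorph_inconsistency_error")
  }
  tibble(
    mito_id = mito$object_id %||% mito$mito_id,
    n_cristae = if (is.null(cristae)) 0L else nrow(cristae),
    mito_volume_um3 = mito$volume_um3,
    total_cristae_volume_um3 = total,
    cristae_density = total / mito$volume_um3,
    matrix_volume_um3 = mito$volume_um3 - total
  )
}

#' Per-mitochondrion cristae summaries for a whole table
#'
#' @param mito_metrics Metrics tibble for mitochondria.
#' @param records `CristaeRecord` tibble ([cristae_records()]); unassigned
#'   rows (`parent_mito_id == 0`) are ignored.
#' @return `MitoCristaeSummary` tibble, one row per mitochondrion.
#' @export
summarize_cristae_by_mito <- function(mito_metrics, records) {
  assigned <- records[records$parent_mito_id > 0, , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(mito_metrics)), function(i) {
    row <- mito_metrics[i, ]
    kids <- assigned[assigned$parent_mito_id == row$object_id, , drop = FALSE]
    out <- summarize_mito(row, kids)
    out$source_id <- row$source_id
    out
  }) |>
    dplyr::relocate("source_id")
}
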