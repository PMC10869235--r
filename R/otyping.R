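#' Bin objects by volume
#'
#' Mito-otyping and cristae-otyping arrange representative objects by
#' volume; this assigns each object to one of `n_bins` contiguous,
#' ascending volume bins. The `quantile` scheme (default) gives near-equal
#' counts; `log_width` uses equal-width bins in log10 volume.
#'
#' @param table Metrics tibble with `volume_um3`.
#' @param n_bins Number of bins (>= 2).
#' @param scheme `"quantile"` or `"log_width"`.
#' @return Input tibble plus `volume_bin` (integer 1..n_bins); bin edges in
#'   \eqn{\mu m^3} as attribute `bin_edges`.
#' @export
bin_by_volume <- function(table, n_bins = 7, scheme = c("quantile", "log_width")) {
  scheme <- match.arg(scheme)
  if (n_bins < 2) abort("`n_bins` must be >= 2.", class = "mitomorph_parameter_error")
  v <- table$volume_um3
  if (length(v) < n_bins) abort("fewer objects than bins.", class = "mitomorph_parameter_error")
  edges <- if (scheme == "quantile") {
    unname(quantile(v, probs = seq(0, 1, length.out = n_bins + 1), type = 7))
  } else {
    10^seq(log10(min(v)), log10(max(v)), length.out = n_bins + 1)
  }
  if (anyDuplicated(edges)) {
    abort("degenerate volume distribution collapses bins; use fewer bins.",
          class = "mitomorph_parameter_error")
  }
  bin <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  out <- dplyr::mutate(table, volume_bin = as.integer(bin))
  attr(out, "bin_edges") <- edges
  out
}

#' Select representative objects from one volume bin
#'
#' Picks the `k` objects whose volume is closest to the bin median,
#' deterministic ties toward the lower object id.
#'
#' @param bin Tibble of one bin's rows (`object_id`, `volume_um3`).
#' @param k Number of representatives.
#' @return Integer object ids, ordered by closeness then id.
#' @export
select_representatives <- function(bin, k = 1) {
  if (nrow(bin) == 0) abort("empty bin.", class = "mitomorph_parameter_error")
  if (k > nrow(bin)) {
    warn(sprintf("k = %d exceeds bin size %d; returning all members.", k, nrow(bin)))
    k <- nrow(bin)
  }
  med <- median(bin$volume_um3)
  ord <- order(abs(bin$volume_um3 - med), bin$object_id)
  bin$object_id[ord][seq_len(k)]
}

#' Build an otyping panel (volume-binned representative gallery)
#'
#' For each group, objects are binned by volume (bins computed on the
#' pooled table so columns align across groups) and the representative
#' closest to each bin median is rendered as a deterministic 2D silhouette:
#' the max-intensity projection of the object mask along z, with its
#' mid-slice cross-section contour marked.
#'
#' @param table Metrics tibble with `group`, `source_id`, `object_id`,
#'   `volume_um3`.
#' @param volumes Named list of [label_volume()]s, one per `source_id`.
#' @param n_bins Number of volume bins.
#' @param k Representatives per bin.
#' @param scheme Binning scheme, see [bin_by_volume()].
#' @return An `otype_panel` object with `$cells` (silhouette pixel tibble),
#'   `$manifest` (group, bin, edges, chosen ids) and layout metadata.
#' @export
make_otype_panel <- function(table, volumes, n_bins = 7, k = 1,
                             scheme = "quantile") {
  binned <- bin_by_volume(table, n_bins, scheme)
  edges <- attr(binned, "bin_edges")
  manifest <- binned |>
    dplyr::group_by(.data$group, .data$volume_bin) |>
    dplyr::group_modify(function(df, key) {
      ids <- select_representatives(df, min(k, nrow(df)))
      df[match(ids, df$object_id), c("source_id", "object_id", "volume_um3")]
    }) |>
    dplyr::ungroup()
  cells <- purrr::pmap_dfr(manifest, function(group, volume_bin, source_id, object_id, volume_um3) {
    vol <- volumes[[source_id]]
    if (is.null(vol)) {
      return(tibble(group = group, volume_bin = volume_bin, object_id = object_id,
                    missing = TRUE, y = NA_real_, x = NA_real_, mid = NA))
    }
    sil <- object_silhouette(vol, object_id)
    if (nrow(sil) == 0) {
      return(tibble(group = group, volume_bin = volume_bin, object_id = object_id,
                    missing = TRUE, y = NA_real_, x = NA_real_, mid = NA))
    }
    dplyr::mutate(sil, group = group, volume_bin = volume_bin,
                  object_id = object_id, missing = FALSE)
  })
  structure(list(cells = cells, manifest = manifest, bin_edges = edges,
                 n_bins = n_bins, groups = sort(unique(as.character(table$group))),
                 spacing = volumes[[1]]$spacing),
            class = "otype_panel")
}

object_silhouette <- function(vol, object_id) {
  hit <- vol$grid == object_id
  if (!any(hit)) return(tibble(y = double(), x = double(), mid = logical()))
  idx <- which(hit, arr.ind = TRUE)
  z0 <- min(idx[, 1]); z1 <- max(idx[, 1])
  sub <- hit[z0:z1, min(idx[, 2]):max(idx[, 2]), min(idx[, 3]):max(idx[, 3]), drop = FALSE]
  proj <- apply(sub, c(2, 3), any)
  midz <- sub[ceiling(dim(sub)[1] / 2), , ]
  px <- which(proj, arr.ind = TRUE)
  tibble(y = (px[, 1] - 1) * vol$spacing["y"] / NM_PER_UM,
         x = (px[, 2] - 1) * vol$spacing["x"] / NM_PER_UM,
         mid = midz[proj])
}

#' @export
print.otype_panel <- function(x, ...) {
  cat(sprintf("<otype_panel> %d group(s) x %d volume bins, %d cell(s)\n",
              length(x$groups), x$n_bins, nrow(x$manifest)))
  invisible(x)
}

#' @rdname make_otype_panel
#' @param object An `otype_panel`.
#' @param ... Unused.
#' @export
autoplot.otype_panel <- function(object, ...) {
  cells <- object$cells[!object$cells$missing, , drop = FALSE]
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$mid)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "grey20"),
                               guide = "none") +
    ggplot2::facet_grid(group ~ volume_bin) +
    ggplot2::labs(x = expression(x ~ (mu * m)), y = expression(y ~ (mu * m)),
                  title = "volume-binned representative objects (z projection)") +
    ggplot2::theme_minimal()
}

#' Render an otyping gallery to an image file
#'
#' Deterministic settings (fixed device size and resolution) so identical
#' panels reproduce identical files; the bin manifest is written alongside
#' as JSON for reproducibility.
#'
#' @param panel An `otype_panel` from [make_otype_panel()].
#' @param path Output image path (`.png` or `.svg`).
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
render_gallery <- function(panel, path, width = 2 * panel$n_bins, height = 2.4 * length(panel$groups)) {
  p <- autoplot(panel)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150, bg = "white")
  jsonlite::write_json(
    list(bin_edges_um3 = panel$bin_edges,
         representatives = panel$manifest),
    paste0(tools::file_path_sans_ext(path), "_manifest.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
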