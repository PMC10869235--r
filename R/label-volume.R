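#' Construct a 3D instance label volume
#'
#' A `label_volume` holds a 3D grid of non-negative integer instance labels
#' (0 = background) together with its physical voxel spacing in nanometres.
#' The axis convention is fixed: the array is indexed `grid[z, y, x]` with z
#' the serial-sectioning axis, so `dim(grid) = c(nz, ny, nx)`. Voxel indices
#' are 0-based in physical terms: the centre of voxel `(i, j, k)` (1-based R
#' index) sits at `((i-1)*sz, (j-1)*sy, (k-1)*sx)` nm.
#'
#' Anisotropic spacing is the norm for serial block face-SEM data; the
#' default `c(10, 10, 50)` nm reflects typical x/y pixel size and section
#' thickness.
#'
#' @param grid 3D array of non-negative integers; dimensions `(nz, ny, nx)`.
#' @param spacing Numeric length-3 voxel spacing `(sx, sy, sz)` in nm; all
#'   components must be positive.
#' @param source_id Free-text provenance (animal, group, block).
#' @param spacing_source Either `"metadata"` or `"override"`; recorded by the
#'   readers so downstream tables can state where geometry came from.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, spacing = c(10, 10, 50), source_id = "",
                         spacing_source = "override") {
  if (!is.array(grid) || length(dim(grid)) != 3L) {
    abort("`grid` must be a 3D array (dims z, y, x).", class = "mitomorph_shape_error")
  }
  if (any(dim(grid) < 1L)) {
    abort("every grid dimension must be >= 1.", class = "mitomorph_shape_error")
  }
  if (is.double(grid)) {
    if (any(grid != round(grid), na.rm = TRUE)) {
      abort("labels must be integers (0 = background).", class = "mitomorph_format_error")
    }
    storage.mode(grid) <- "integer"
  }
  if (!is.integer(grid)) {
    abort("labels must be of integer type.", class = "mitomorph_format_error")
  }
  if (anyNA(grid) || any(grid < 0L)) {
    abort("labels must be non-negative and non-missing.", class = "mitomorph_validation_error")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive numbers (sx, sy, sz) in nm.",
          class = "mitomorph_metadata_error")
  }
  structure(
    list(grid = grid, spacing = setNames(spacing, c("x", "y", "z")),
         axis_order = "zyx", source_id = as.character(source_id)[1],
         spacing_source = match.arg(spacing_source, c("metadata", "override"))),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$grid)
  labs <- unique(as.vector(x$grid))
  cat(sprintf("<label_volume> %d x %d x %d (z, y, x), spacing %g x %g x %g nm (x, y, z)\n",
              d[1], d[2], d[3], x$spacing["x"], x$spacing["y"], x$spacing["z"]))
  cat(sprintf("  %d foreground label(s); source '%s' (spacing from %s)\n",
              sum(labs > 0), x$source_id, x$spacing_source))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$grid)

voxel_volume_nm3 <- function(vol) prod(vol$spacing)

spacing_zyx <- function(vol) unname(vol$spacing[c("z", "y", "x")])

sidecar_path <- function(path) paste0(path, ".json")

#' Read an instance label volume from disk
#'
#' Supports multi-page TIFF stacks (uint8/16) and NRRD (raw encoding, integer
#' types). TIFF carries no standard 3D spacing tag, so spacing is taken from
#' a JSON sidecar (`<path>.json`, written by [write_label_volume()]) or from
#' `spacing_override`. NRRD spacing comes from the `spacings` header field.
#'
#' TIFF pages are stacked along z in page order; each page is a `(ny, nx)`
#' matrix, giving the package's fixed `(z, y, x)` axis order.
#'
#' @param path File path ending in `.tif`/`.tiff` or `.nrrd`.
#' @param spacing_override Optional `(sx, sy, sz)` nm triple taking precedence
#'   over file metadata.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, spacing_override = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "mitomorph_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    read_label_tiff(path, spacing_override)
  } else if (ext == "nrrd") {
    read_label_nrrd(path, spacing_override)
  } else {
    abort(sprintf("unsupported volume format '.%s' (use TIFF or NRRD).", ext),
          class = "mitomorph_format_error")
  }
}

read_label_tiff <- function(path, spacing_override = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 1L) abort("TIFF has no pages.", class = "mitomorph_shape_error")
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, TRUE))) {
    abort("TIFF pages must be single-channel 2D label images.",
          class = "mitomorph_format_error")
  }
  if (any(vapply(pages, function(p) is.double(p) && any(p != round(p)), TRUE))) {
    abort("TIFF pixel type is not integer-valued.", class = "mitomorph_format_error")
  }
  d2 <- dim(pages[[1]])
  grid <- array(0L, c(length(pages), d2[1], d2[2]))
  for (i in seq_along(pages)) grid[i, , ] <- as.integer(round(pages[[i]]))
  meta <- if (file.exists(sidecar_path(path))) jsonlite::read_json(sidecar_path(path)) else NULL
  source_id <- if (!is.null(meta$source_id)) meta$source_id else ""
  if (!is.null(spacing_override)) {
    label_volume(grid, spacing_override, source_id, spacing_source = "override")
  } else if (!is.null(meta$spacing_nm)) {
    sp <- unlist(meta$spacing_nm)[c("x", "y", "z")]
    label_volume(grid, sp, source_id, spacing_source = "metadata")
  } else {
    abort("no spacing metadata (sidecar JSON) and no `spacing_override` given.",
          class = "mitomorph_metadata_error")
  }
}

#' Write an instance label volume to disk
#'
#' The extension picks the format. TIFF output is a multi-page stack (8- or
#' 16-bit depending on the label range) plus a JSON sidecar holding spacing
#' and provenance; NRRD output is a self-describing raw-encoded file (32-bit
#' labels). Both round-trip exactly through [read_label_volume()].
#'
#' @param vol A [label_volume()].
#' @param path Output path (`.tif`/`.tiff` or `.nrrd`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_label_tiff(vol, path)
  } else if (ext == "nrrd") {
    write_label_nrrd(vol, path)
  } else {
    abort(sprintf("unsupported volume format '.%s' (use TIFF or NRRD).", ext),
          class = "mitomorph_format_error")
  }
  invisible(path)
}

write_label_tiff <- function(vol, path) {
  mx <- max(vol$grid)
  bits <- if (mx <= 255L) 8L else if (mx <= 65535L) 16L else
    abort("labels exceed 16-bit range; write NRRD instead.", class = "mitomorph_format_error")
  denom <- 2^bits - 1
  d <- dim(vol$grid)
  pages <- lapply(seq_len(d[1]), function(i) {
    m <- matrix(as.numeric(vol$grid[i, , ]), d[2], d[3])
    m / denom
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(spacing_nm = as.list(vol$spacing), source_id = vol$source_id,
         axis_order = "zyx", writer = "mitomorph"),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- minimal NRRD (raw encoding) --------------------------------------------
# Header stores sizes/spacings in file order = (z, y, x) fastest-first to
# match the package's column-major array layout; the axis-label field records
# this so the files are self-describing.

nrrd_types <- list(
  "int8" = list(what = "integer", size = 1, signed = TRUE),
  "uint8" = list(what = "integer", size = 1, signed = FALSE),
  "int16" = list(what = "integer", size = 2, signed = TRUE),
  "uint16" = list(what = "integer", size = 2, signed = FALSE),
  "int32" = list(what = "integer", size = 4, signed = TRUE)
)

write_label_nrrd <- function(vol, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  d <- dim(vol$grid)
  sp <- spacing_zyx(vol)
  hdr <- c(
    "NRRD0004",
    "# mitomorph label volume",
    "type: int32",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("spacings: %.10g %.10g %.10g", sp[1], sp[2], sp[3]),
    'labels: "z" "y" "x"',
    "encoding: raw",
    "endian: little",
    paste0("source_id:=", vol$source_id),
    ""
  )
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(vol$grid), con, size = 4, endian = "little")
  invisible(path)
}

read_label_nrrd <- function(path, spacing_override = NULL) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) abort("not an NRRD file.", class = "mitomorph_format_error")
  fields <- list(); kv <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    if (grepl("^#", line)) next
    if (grepl(":=", line, fixed = TRUE)) {
      p <- strsplit(line, ":=", fixed = TRUE)[[1]]
      kv[[trimws(p[1])]] <- trimws(paste(p[-1], collapse = ":="))
    } else if (grepl(": ", line, fixed = TRUE)) {
      p <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
      fields[[tolower(trimws(p[1]))]] <- trimws(p[2])
    }
  }
  type <- fields[["type"]]
  if (is.null(type) || !type %in% names(nrrd_types)) {
    abort(sprintf("NRRD type '%s' is not an integer label type.", type %||% "?"),
          class = "mitomorph_format_error")
  }
  ndim <- as.integer(fields[["dimension"]] %||% "0")
  if (ndim != 3L) {
    abort(sprintf("NRRD dimension %d; label volumes must be 3D.", ndim),
          class = "mitomorph_shape_error")
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L || any(sizes < 1L)) {
    abort("invalid NRRD sizes.", class = "mitomorph_shape_error")
  }
  if (!identical(fields[["encoding"]], "raw")) {
    abort("only raw-encoded NRRD is supported.", class = "mitomorph_format_error")
  }
  endian <- fields[["endian"]] %||% "little"
  tp <- nrrd_types[[type]]
  n <- prod(sizes)
  vals <- readBin(con, what = tp$what, n = n, size = tp$size,
                  signed = if (tp$size < 4) tp$signed else TRUE, endian = endian)
  if (length(vals) != n) abort("NRRD data truncated.", class = "mitomorph_io_error")
  grid <- array(as.integer(vals), sizes)
  if (!is.null(spacing_override)) {
    label_volume(grid, spacing_override, kv[["source_id"]] %||% "", "override")
  } else if (!is.null(fields[["spacings"]])) {
    sp_zyx <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
    label_volume(grid, sp_zyx[c(3, 2, 1)], kv[["source_id"]] %||% "", "metadata")
  } else {
    abort("NRRD lacks a spacings field and no `spacing_override` was given.",
          class = "mitomorph_metadata_error")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
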