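#' Two-channel tile scan container
#'
#' Pairs the co-registered narrow (second-harmonic, 405/10 nm role) and broad
#' (autofluorescence, 550/200 nm role) detection channels with the geometry
#' metadata that volumetric quantification depends on. Pixel coordinates are
#' (row, col) with origin at the top-left; all geometry is carried in
#' micrometres and reported downstream in mm^2 / mm^3.
#'
#' @param narrow,broad Numeric intensity matrices of identical shape.
#' @param pixel_size_um Pixel size in micrometres (> 0); required because
#'   loads are volumetric.
#' @param section_thickness_um Physical section thickness in micrometres.
#' @param sample_id,region_id Identifiers.
#' @return A `tile_scan` object.
#' @export
tile_scan <- function(narrow, broad, pixel_size_um,
                      section_thickness_um = 7,
                      sample_id = NA_character_, region_id = NA_integer_) {
  narrow <- as.matrix(narrow); broad <- as.matrix(broad)
  if (!all(dim(narrow) == dim(broad))) {
    stop("narrow and broad channels must have identical shape", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || is.na(pixel_size_um) ||
      pixel_size_um <= 0) {
    stop("pixel_size_um must be a positive number (loads are volumetric)",
         call. = FALSE)
  }
  if (min(narrow) < 0 || min(broad) < 0) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  structure(
    list(narrow = narrow, broad = broad,
         pixel_size_um = pixel_size_um,
         section_thickness_um = section_thickness_um,
         sample_id = sample_id, region_id = region_id),
    class = "tile_scan"
  )
}

#' @export
print.tile_scan <- function(x, ...) {
  cat(sprintf("<tile_scan> %d x %d px, %.3g um/px, %g um section\n",
              nrow(x$narrow), ncol(x$narrow), x$pixel_size_um,
              x$section_thickness_um))
  invisible(x)
}

tiff_scale <- 65535

#' Write / read a tile scan as multi-page TIFF plus JSON sidecar
#'
#' The two channels are stored as a two-page 16-bit TIFF (page order given by
#' the sidecar's `channels` field, by convention `SHG405` then `TPAF550`).
#' Geometry and identifiers live in a sidecar JSON next to the TIFF; channel
#' roles are always resolved from that metadata, never guessed from page
#' order alone. Intensities are integer counts and round-trip exactly up to
#' the 16-bit range.
#'
#' @param tile A [tile_scan()].
#' @param path TIFF path; the sidecar is written at `<path>.json`.
#' @return `write_tile()` returns `path` invisibly; `read_tile()` a
#'   [tile_scan()].
#' @export
write_tile <- function(tile, path) {
  stopifnot(inherits(tile, "tile_scan"))
  pages <- list(tile$narrow / tiff_scale, tile$broad / tiff_scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(
    channels = c("SHG405", "TPAF550"),
    pixel_size_um = tile$pixel_size_um,
    section_thickness_um = tile$section_thickness_um,
    sample_id = tile$sample_id,
    region_id = tile$region_id
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tile
#' @param metadata Optional metadata list overriding the sidecar (must
#'   contain `pixel_size_um` and `channels`).
#' @export
read_tile <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(metadata)) {
    side <- paste0(path, ".json")
    if (!file.exists(side)) {
      stop("missing sidecar metadata: ", side,
           " (pixel size is required, loads are volumetric)", call. = FALSE)
    }
    metadata <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  if (is.null(metadata$pixel_size_um)) {
    stop("metadata lacks pixel_size_um (hard error, loads are volumetric)",
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2) {
    stop("missing channel: expected two channels, found ", length(pages),
         call. = FALSE)
  }
  chans <- metadata$channels
  if (is.null(chans) || length(chans) != length(pages)) {
    stop("metadata must name the role of every channel", call. = FALSE)
  }
  i_narrow <- grep("SHG|405", chans)[1]
  i_broad <- grep("TPAF|550", chans)[1]
  if (is.na(i_narrow) || is.na(i_broad)) {
    stop("cannot resolve narrow/broad roles from channel names: ",
         paste(chans, collapse = ", "), call. = FALSE)
  }
  tile_scan(
    narrow = round(pages[[i_narrow]] * tiff_scale),
    broad = round(pages[[i_broad]] * tiff_scale),
    pixel_size_um = metadata$pixel_size_um,
    section_thickness_um = metadata$section_thickness_um %||% 7,
    sample_id = metadata$sample_id %||% NA_character_,
    region_id = metadata$region_id %||% NA_integer_
  )
}

#' Write / read a tissue mask as single-channel 8-bit TIFF
#'
#' @param mask Logical matrix (a `tissue_mask` or plain logical matrix).
#' @param path TIFF path.
#' @return `read_mask()` returns a logical matrix.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path,
                  bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) > 2) m <- m[, , 1]
  m > 0.5
}

#' Tissue area of a mask in mm^2
#'
#' `area = (number of TRUE pixels) * pixel_size_um^2 * 1e-6`.
#'
#' @param mask Logical matrix.
#' @param pixel_size_um Pixel size in micrometres; taken from the mask's
#'   attribute when present.
#' @return Area in mm^2.
#' @export
mask_area <- function(mask, pixel_size_um = attr(mask, "pixel_size_um")) {
  if (is.null(pixel_size_um)) {
    stop("pixel_size_um required to compute a physical area", call. = FALSE)
  }
  sum(mask) * (pixel_size_um * 1e-3)^2
}

#' Orthogonal maximum-intensity projections of a z-stack
#'
#' Projects a stack (rows x cols x slices) along the column axis (xz view)
#' and the row axis (yz view). The axis scaling of the projections differs
#' between the lateral (pixel size) and axial (slice spacing) directions and
#' is recorded in the result attributes.
#'
#' @param z A `z_stack` (3-D array with `pixel_size_um` and
#'   `slice_spacing_um` attributes) or plain 3-D array.
#' @return List with matrices `xz` (slices x cols) and `yz` (slices x rows),
#'   each carrying `lateral_um` and `axial_um` attributes.
#' @export
orthogonal_projections <- function(z) {
  d <- dim(z)
  if (is.null(d) || length(d) != 3 || d[3] < 2) {
    stop("orthogonal projections need a stack of at least 2 slices",
         call. = FALSE)
  }
  xz <- t(apply(z, c(2, 3), max))   # slices x cols
  yz <- t(apply(z, c(1, 3), max))   # slices x rows
  lat <- attr(z, "pixel_size_um"); ax <- attr(z, "slice_spacing_um")
  attr(xz, "lateral_um") <- lat; attr(xz, "axial_um") <- ax
  attr(yz, "lateral_um") <- lat; attr(yz, "axial_um") <- ax
  list(xz = xz, yz = yz)
}
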