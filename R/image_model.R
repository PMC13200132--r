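#' Construct a grayscale image object
#'
#' `gray_image` is the universal container of the package: a 2D matrix of
#' finite intensities, row-major with pixel centers at integer coordinates
#' (row 1 = top). All metric and edge operations require a normalized image
#' (intensities in \[0, 1\]) of at least 8 x 8 pixels.
#'
#' @param pixels numeric matrix (H x W) of finite intensities.
#' @param source_id opaque label carried through results.
#' @param normalized logical; set by [normalize_intensity()].
#' @return An object of class `gray_image` with fields `pixels`, `height`,
#'   `width`, `source_id`, `normalized` and a `warning_flags` character
#'   vector.
#' @export
gray_image <- function(pixels, source_id = "", normalized = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("image intensities must all be finite", call. = FALSE)
  if (isTRUE(normalized) && (min(pixels) < 0 || max(pixels) > 1))
    stop("normalized image must have intensities in [0, 1]", call. = FALSE)
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         source_id = as.character(source_id), normalized = isTRUE(normalized),
         warning_flags = character(0)),
    class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d  [%s]  range [%.4g, %.4g]%s\n",
              x$height, x$width,
              if (x$normalized) "normalized" else "raw",
              min(x$pixels), max(x$pixels),
              if (nzchar(x$source_id)) paste0("  id=", x$source_id) else ""))
  if (length(x$warning_flags))
    cat("  flags:", paste(x$warning_flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.gray_image <- function(x) c(x$height, x$width)

stopifnot_gray <- function(img, normalized = FALSE, min_side = 1L) {
  if (!inherits(img, "gray_image")) stop("expected a `gray_image`", call. = FALSE)
  if (normalized && !img$normalized)
    stop("image must be normalized first (see normalize_intensity())", call. = FALSE)
  if (img$height < min_side || img$width < min_side)
    stop(sprintf("image must be at least %d x %d", min_side, min_side), call. = FALSE)
  invisible(img)
}

png_bit_depth <- function(path) {
  # IHDR layout: 8-byte signature, 4-byte length, "IHDR", width, height, depth
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) stop("not a PNG file: ", path, call. = FALSE)
  as.integer(hdr[25L])
}

#' Load a 2D grayscale image from disk
#'
#' Reads PNG, TIFF (8/16-bit), single-frame DICOM or one slice of a NIfTI
#' volume into an un-normalized [gray_image]. Stored integer values are
#' preserved (PNG/TIFF readers' unit-scale output is multiplied back by the
#' container's maximum); DICOM rescale slope/intercept is applied. RGB or
#' multi-channel rasters are rejected.
#'
#' @param path file path; format chosen by extension
#'   (`.png`, `.tif`/`.tiff`, `.dcm`, `.nii`/`.nii.gz`).
#' @param slice 1-based slice index, required for 3D NIfTI volumes.
#' @param source_id label for the result; defaults to the file name.
#' @return An un-normalized [gray_image].
#' @seealso [save_image()], [normalize_intensity()]
#' @export
load_image <- function(path, slice = NULL, source_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  px <- switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) {
        if (dim(a)[3] == 2L) a <- a[, , 1L]  # gray + alpha: drop alpha
        else stop("RGB input not supported; supply a grayscale raster", call. = FALSE)
      }
      a * (2^png_bit_depth(path) - 1)
    },
    tif = ,
    tiff = {
      a <- tiff::readTIFF(path, as.is = TRUE)
      if (length(dim(a)) == 3L) {
        if (dim(a)[3] == 2L) a <- a[, , 1L]
        else stop("RGB input not supported; supply a grayscale raster", call. = FALSE)
      }
      a
    },
    dcm = read_dicom_gray(path),
    nii = {
      v <- RNifti::readNifti(path)
      d <- dim(v)
      if (length(d) == 2L) as.matrix(v)
      else if (length(d) == 3L) {
        if (is.null(slice))
          stop("3D NIfTI volume: a `slice` index is required", call. = FALSE)
        if (slice < 1L || slice > d[3])
          stop("slice index out of range 1..", d[3], call. = FALSE)
        as.matrix(v[, , slice])
      } else stop("volumes with >3 dimensions are not supported", call. = FALSE)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  storage.mode(px) <- "double"
  gray_image(px, source_id = source_id)
}

#' Save a grayscale image to disk
#'
#' Writes 16-bit TIFF (default) or 8-bit PNG; intensities are linearly
#' mapped from `range` onto the container's integer scale. Intended for
#' generating fixtures and exporting phantoms, not for archival fidelity.
#'
#' @param img a [gray_image].
#' @param path output path; `.tif`/`.tiff` or `.png`.
#' @param range intensity range mapped to \[0, max\]; defaults to \[0, 1\]
#'   for normalized images and the data range otherwise.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path, range = NULL) {
  stopifnot_gray(img)
  if (is.null(range))
    range <- if (img$normalized) c(0, 1) else range(img$pixels)
  span <- diff(range)
  unit <- if (span > 0) pmin(pmax((img$pixels - range[1]) / span, 0), 1)
          else matrix(0, img$height, img$width)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(unit, path, bits.per.sample = 16L)
  else if (ext == "png")
    png::writePNG(unit, path)
  else stop("unsupported output format: .", ext, call. = FALSE)
  invisible(path)
}

#' Normalize image intensities to \[0, 1\]
#'
#' Linear min-max rescale, optionally after clipping to a pair of
#' percentiles (useful for noisy inputs with hot pixels). A constant image
#' maps to all zeros and carries the `"constant_input"` warning flag rather
#' than erroring, so batch pipelines do not abort. The operation is
#' idempotent.
#'
#' @param img a [gray_image].
#' @param clip_percentiles optional numeric pair `(p_low, p_high)` in
#'   \[0, 100\]; intensities are clipped to these percentiles before
#'   rescaling.
#' @return A normalized [gray_image].
#' @export
normalize_intensity <- function(img, clip_percentiles = NULL) {
  stopifnot_gray(img)
  px <- img$pixels
  if (!is.null(clip_percentiles)) {
    stopifnot(length(clip_percentiles) == 2L, clip_percentiles[1] < clip_percentiles[2])
    q <- stats::quantile(px, clip_percentiles / 100, names = FALSE)
    px <- pmin(pmax(px, q[1]), q[2])
  }
  lo <- min(px); hi <- max(px)
  out <- img
  if (hi > lo) {
    out$pixels <- (px - lo) / (hi - lo)
  } else {
    out$pixels <- matrix(0, img$height, img$width)
    out$warning_flags <- union(out$warning_flags, "constant_input")
  }
  out$normalized <- TRUE
  out
}

#' Central-difference image gradient
#'
#' Computes per-pixel horizontal (`gx`) and vertical (`gy`) derivatives with
#' interior central differences `(I[i+1] - I[i-1]) / 2` and one-sided first
#' differences at the borders — the convention of MATLAB's `gradient()` —
#' plus the Euclidean gradient magnitude `sqrt(gx^2 + gy^2)`, which is
#' rotationally invariant at the 90-degree grid level.
#'
#' @param img a normalized [gray_image] (at least 2 x 2).
#' @return A list of class `gradient_field` with matrices `gx`, `gy`,
#'   `magnitude` (all H x W, units intensity/pixel).
#' @export
compute_gradient <- function(img) {
  stopifnot_gray(img, normalized = TRUE, min_side = 2L)
  m <- img$pixels
  gx <- axis_gradient(m, along = "col")
  gy <- axis_gradient(m, along = "row")
  structure(list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2)),
            class = "gradient_field")
}

# MATLAB gradient() convention along one axis of a matrix.
axis_gradient <- function(m, along = c("col", "row")) {
  along <- match.arg(along)
  if (along == "row") return(t(axis_gradient(t(m), "col")))
  n <- ncol(m)
  g <- matrix(0, nrow(m), n)
  if (n == 1L) return(g)
  g[, 1L] <- m[, 2L] - m[, 1L]
  g[, n]  <- m[, n] - m[, n - 1L]
  if (n > 2L) g[, 2:(n - 1L)] <- (m[, 3:n] - m[, 1:(n - 2L)]) / 2
  g
}
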