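#' Calibrated grayscale image
#'
#' A raster of pixel intensities together with the physical pixel pitch
#' (nm per pixel side) and a provenance trail of the operations applied so
#' far.  All processing functions in the package take and return this
#' container; none mutates it in place, each appends to `provenance`.
#'
#' @param pixels numeric matrix of intensities (any finite scale; 8-bit
#'   micrographs are read as 0--255).
#' @param pixel_pitch_nm physical length of one pixel side, in nm.
#'   The default of 2.34 nm/px corresponds to TEM micrographs acquired at
#'   20000x magnification.
#' @param provenance list of previously applied operations (internal).
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_pitch_nm = 2.34, provenance = list()) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!is.numeric(pixel_pitch_nm) || length(pixel_pitch_nm) != 1L ||
      !is.finite(pixel_pitch_nm) || pixel_pitch_nm <= 0)
    stop("pixel_pitch_nm must be a single positive number")
  if (!all(is.finite(pixels)))
    stop("pixels must be finite")
  structure(
    list(pixels = pixels, pixel_pitch_nm = pixel_pitch_nm,
         provenance = provenance),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("calibrated_image: %d x %d px, pitch %.4g nm/px, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch_nm,
              min(x$pixels), max(x$pixels)))
  if (length(x$provenance)) {
    cat("provenance:\n")
    for (p in x$provenance)
      cat("  -", p$op, ":",
          paste(names(p$params), unlist(p$params), sep = "=", collapse = ", "),
          "\n")
  }
  invisible(x)
}

# append an operation record; returns a new calibrated_image
with_step <- function(img, pixels, op, params) {
  calibrated_image(pixels, img$pixel_pitch_nm,
                   c(img$provenance, list(list(op = op, params = params))))
}

#' Read a grayscale micrograph from TIFF or PNG
#'
#' 8- and 16-bit grayscale rasters are supported; intensities are rescaled
#' to their native integer range (0--255 or 0--65535).  Multichannel images
#' are rejected.
#'
#' @param path file path (.tif/.tiff/.png).
#' @param pixel_pitch_nm physical pixel pitch in nm/px.
#' @return A [calibrated_image()].
#' @export
read_micrograph <- function(path, pixel_pitch_nm = 2.34) {
  if (!file.exists(path)) stop("file not found: ", path)
  im <- EBImage::readImage(path)
  d <- dim(im)
  if (length(d) > 2 && d[3] > 1) {
    dat <- EBImage::imageData(im)
    if (max(abs(dat[, , 1] - dat[, , min(2, d[3])])) > 1e-8)
      stop("multichannel image not supported: ", path)
    im <- im[, , 1]
  }
  m <- as.matrix(EBImage::imageData(im))
  # EBImage normalizes to [0,1]; restore an 8-bit-like scale
  calibrated_image(m * 255, pixel_pitch_nm,
                   provenance = list(list(op = "read",
                                          params = list(path = path))))
}

#' Write a raster as an 8-bit grayscale image
#'
#' Intensities are clipped to `[0, 255]` and scaled; binary masks
#' (0/1 matrices) are written as 0/255.
#'
#' @param x matrix, [calibrated_image()], or binary mask.
#' @param path output path (.tif or .png).
#' @export
write_raster <- function(x, path) {
  m <- if (inherits(x, "calibrated_image")) x$pixels else as.matrix(x)
  if (all(m %in% c(0, 1))) m <- m * 255
  m <- pmin(pmax(m, 0), 255) / 255
  EBImage::writeImage(EBImage::Image(m), path)
  invisible(path)
}

# Gaussian smoothing with reflective (mirror) padding, so that no
# artificial gradients are introduced at the frame edge.  For images
# smaller than the requested footprint, sigma and the kernel radius are
# capped to what the frame can support.
gauss_smooth <- function(m, sigma) {
  stopifnot(sigma > 0)
  sigma <- min(sigma, (min(dim(m)) - 1) / 2)
  pad <- min(ceiling(3 * sigma) + 1, min(dim(m)) - 1L)
  mp <- pad_reflect(m, pad)
  radius <- min(2 * ceiling(3 * sigma) + 1, floor((min(dim(mp)) - 1) / 2))
  if (radius %% 2 == 0) radius <- radius - 1
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(mp), sigma = sigma,
                                          radius = radius))
  sm[(pad + 1):(pad + nrow(m)), (pad + 1):(pad + ncol(m))]
}

pad_reflect <- function(m, pad) {
  nr <- nrow(m); nc <- ncol(m)
  if (pad >= nr || pad >= nc)
    pad <- min(nr, nc) - 1L
  ri <- c(rev(seq_len(pad) + 1L), seq_len(nr), nr - seq_len(pad))
  ci <- c(rev(seq_len(pad) + 1L), seq_len(nc), nc - seq_len(pad))
  m[ri, ci]
}

# shift a matrix by (dr, dc) with edge replication (Neumann boundary)
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci]
}
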