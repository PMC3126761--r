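#' Two-phase mask with labelled cavities
#'
#' Binary partition of a micrograph into the alginate (solid, value 1) and
#' cavity (value 0) phases, with cavity connected components labelled.
#' Cavities are labelled with 4-connectivity and the solid phase treated as
#' 8-connected -- the standard complementary pairing that avoids topological
#' paradoxes.
#'
#' @param mask integer matrix, alginate = 1, cavity = 0.
#' @param pixel_pitch_nm physical pixel pitch, nm/px.
#' @param min_lumen_area_nm2 lumen-area cutoff already applied (NA if none).
#' @param meta list of segmentation metadata (threshold, polarity, ...).
#' @return An object of class `phase_mask`.
#' @export
phase_mask <- function(mask, pixel_pitch_nm, min_lumen_area_nm2 = NA_real_,
                       meta = list()) {
  storage.mode(mask) <- "integer"
  if (!all(mask %in% c(0L, 1L))) stop("mask must be binary (0/1)")
  labels <- cc_label(mask == 0L, 4L)
  structure(
    list(mask = mask, labels = labels, pixel_pitch_nm = pixel_pitch_nm,
         min_lumen_area_nm2 = min_lumen_area_nm2, meta = meta),
    class = "phase_mask")
}

#' @export
print.phase_mask <- function(x, ...) {
  cat(sprintf("phase_mask: %d x %d px, %d cavity components, cavity fraction %.3f\n",
              nrow(x$mask), ncol(x$mask), max(x$labels),
              mean(x$mask == 0L)))
  if (!is.na(x$min_lumen_area_nm2))
    cat(sprintf("  min lumen area: %.1f nm^2\n", x$min_lumen_area_nm2))
  invisible(x)
}

#' Binarize a preprocessed micrograph into alginate and cavity phases
#'
#' Thresholds the image (Otsu by default, or a fixed threshold) and assigns
#' phase identity.  Which side of the threshold is the alginate phase is
#' decided automatically from morphology: the matrix is a network of thin
#' fibrils while the cavities are comparatively wide lumina, so of the two
#' candidate phases the one with the smaller median distance-transform
#' value (the thinner phase) is taken to be alginate; on a tie the darker
#' phase wins, since the osmium-stained matrix renders electron-dense.
#' The detected polarity is recorded in the result's `meta`, and a
#' `polarity` override is available for unusual stains.
#'
#' @param img a [calibrated_image()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold numeric threshold, required for `method = "fixed"`.
#' @param polarity `"auto"` (default), `"dark"` (alginate below threshold)
#'   or `"bright"`.
#' @return A [phase_mask()].
#' @export
binarize <- function(img, method = c("otsu", "fixed"), threshold = NULL,
                     polarity = c("auto", "dark", "bright")) {
  stopifnot(inherits(img, "calibrated_image"))
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  px <- img$pixels
  rng <- range(px)
  if (diff(rng) == 0)
    stop("degenerate image: single intensity value, no threshold exists")
  if (method == "otsu") {
    threshold <- EBImage::otsu(EBImage::Image(px), range = rng, levels = 256L)
  } else {
    if (is.null(threshold)) stop("method = 'fixed' requires a threshold")
    if (threshold <= rng[1] || threshold >= rng[2])
      stop("fixed threshold outside the image's value range")
  }
  dark <- px <= threshold
  if (polarity == "auto") {
    polarity <- if (phase_half_width(dark) <= phase_half_width(!dark))
      "dark" else "bright"
  }
  alg <- if (polarity == "dark") dark else !dark
  phase_mask((alg * 1L), img$pixel_pitch_nm,
             meta = list(method = method, threshold = as.numeric(threshold),
                         polarity = polarity))
}

# median distance-transform value of a phase: its characteristic half-width
phase_half_width <- function(bin) {
  if (!any(bin)) return(Inf)
  if (all(bin)) return(Inf)
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(bin * 1)))
  stats::median(d[bin])
}

#' Remove sub-threshold lumina
#'
#' Cavity components with physical area below `min_area_nm2` (strictly
#' less, area = pixel count times pitch squared) are reassigned to the
#' alginate phase; remaining cavity labels are re-indexed contiguously.
#' At the default pitch of 2.34 nm/px one pixel covers 5.4756 nm^2, so the
#' default 275 nm^2 cutoff corresponds to 50.2 px: a 50-pixel lumen is
#' removed, a 51-pixel lumen kept.  The operation is idempotent.
#'
#' @param pm a [phase_mask()].
#' @param min_area_nm2 lumen-area cutoff in nm^2.
#' @return A filtered [phase_mask()].
#' @export
filter_small_lumina <- function(pm, min_area_nm2 = 275) {
  stopifnot(inherits(pm, "phase_mask"))
  px_area <- pm$pixel_pitch_nm^2
  sizes <- tabulate(pm$labels, nbins = max(pm$labels))
  drop <- which(sizes * px_area < min_area_nm2)
  mask <- pm$mask
  if (length(drop))
    mask[pm$labels %in% drop] <- 1L
  if (length(sizes) && length(drop) == length(sizes))
    warning("filter_small_lumina: all cavities below cutoff; mask is all alginate")
  phase_mask(mask, pm$pixel_pitch_nm, min_lumen_area_nm2 = min_area_nm2,
             meta = c(pm$meta, list(lumina_removed = length(drop))))
}

#' Write a phase mask and its metadata sidecar
#'
#' The mask is written as an 8-bit TIFF (alginate = 255) and the
#' segmentation metadata (cutoff, polarity, threshold, connectivity
#' convention) as a JSON sidecar.
#'
#' @param pm a [phase_mask()].
#' @param path output TIFF path; the sidecar replaces the extension by
#'   `.json`.
#' @return Invisibly, the two paths.
#' @export
write_phase_mask <- function(pm, path) {
  write_raster(pm$mask, path)
  side <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(
    list(min_lumen_area_nm2 = pm$min_lumen_area_nm2,
         pixel_pitch_nm = pm$pixel_pitch_nm,
         n_cavities = max(pm$labels),
         connectivity = list(cavity = 4, alginate = 8),
         meta = pm$meta),
    side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(path, side))
}
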