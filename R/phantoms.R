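#' Synthetic phantom container
#'
#' A phantom is a synthetic two-phase scene with known ground truth used to
#' validate the measurement chain end to end: a binary `truth_mask`
#' (alginate = 1, cavity = 0), optionally a corrupted grayscale rendering
#' (`rendered`, see [render_tem()]), the physical pixel pitch, the true
#' wall-to-wall gap widths (`truth_gaps`, nm, with multiplicity) and fibril
#' widths (`truth_fibril_widths`, nm), and optionally a binary cell mask.
#'
#' @name phantom
#' @keywords internal
NULL

new_phantom <- function(truth_mask, pixel_pitch_nm, truth_gaps = numeric(),
                        truth_fibril_widths = numeric(), rendered = NULL,
                        cell_mask = NULL, seed = NA_integer_, params = list(),
                        truth_gap_weights = NULL) {
  storage.mode(truth_mask) <- "integer"
  stopifnot(all(truth_mask %in% c(0L, 1L)))
  if (!is.null(cell_mask)) {
    storage.mode(cell_mask) <- "integer"
    stopifnot(identical(dim(cell_mask), dim(truth_mask)))
  }
  if (!is.null(rendered))
    stopifnot(identical(dim(rendered), dim(truth_mask)))
  if (length(truth_gaps) && any(truth_gaps <= 0))
    stop("truth_gaps must be strictly positive")
  if (length(truth_fibril_widths) && any(truth_fibril_widths <= 0))
    stop("truth_fibril_widths must be strictly positive")
  if (is.null(truth_gap_weights)) truth_gap_weights <- rep(1, length(truth_gaps))
  stopifnot(length(truth_gap_weights) == length(truth_gaps))
  structure(
    list(truth_mask = truth_mask, rendered = rendered,
         pixel_pitch_nm = pixel_pitch_nm, truth_gaps = truth_gaps,
         truth_gap_weights = truth_gap_weights,
         truth_fibril_widths = truth_fibril_widths, cell_mask = cell_mask,
         seed = seed, params = params),
    class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %d x %d px, pitch %.4g nm/px, cavity fraction %.3f%s%s\n",
              nrow(x$truth_mask), ncol(x$truth_mask), x$pixel_pitch_nm,
              mean(x$truth_mask == 0L),
              if (is.null(x$rendered)) "" else ", rendered",
              if (is.null(x$cell_mask)) "" else ", cell mask"))
  invisible(x)
}

#' Straight-slit phantom
#'
#' One straight rectangular cavity of exactly `width_px` pixels between two
#' solid alginate walls: the canonical test case for slit-shaped pores.
#' The true wall-to-wall gap is `width_px * pixel_pitch_nm`.
#'
#' @param width_px slit width in pixels (>= 1).
#' @param length_px slit length in pixels.
#' @param wall_px thickness of each wall in pixels.
#' @param pixel_pitch_nm physical pixel pitch, nm/px.
#' @return A `phantom`.
#' @export
generate_slit_phantom <- function(width_px, length_px = 64L, wall_px = 8L,
                                  pixel_pitch_nm = 2.34) {
  if (width_px < 1 || length_px < 1 || wall_px < 1)
    stop("slit phantom dimensions must be positive")
  nr <- 2L * wall_px + width_px
  m <- matrix(1L, nr, length_px)
  m[(wall_px + 1L):(wall_px + width_px), ] <- 0L
  new_phantom(m, pixel_pitch_nm,
              truth_gaps = width_px * pixel_pitch_nm,
              params = list(width_px = width_px, length_px = length_px,
                            wall_px = wall_px))
}

#' Disc-cavity phantom
#'
#' A single circular cavity (pixels whose centre lies within `radius_px` of
#' the disc centre) in a solid alginate field.
#'
#' @param radius_px disc radius in pixels (>= 2).
#' @param pixel_pitch_nm physical pixel pitch, nm/px.
#' @param size_px image side length; default leaves a generous wall.
#' @return A `phantom`.
#' @export
generate_disc_phantom <- function(radius_px, pixel_pitch_nm = 2.34,
                                  size_px = NULL) {
  if (radius_px < 2) stop("radius_px must be >= 2")
  if (is.null(size_px)) size_px <- 2L * radius_px + 2L * max(8L, radius_px) + 1L
  if (2 * radius_px + 2 >= size_px)
    stop("disc does not fit in the image")
  ctr <- (size_px + 1) / 2
  rr <- matrix(seq_len(size_px), size_px, size_px)
  cc <- t(rr)
  m <- matrix(1L, size_px, size_px)
  m[(rr - ctr)^2 + (cc - ctr)^2 <= radius_px^2] <- 0L
  new_phantom(m, pixel_pitch_nm,
              truth_gaps = 2 * radius_px * pixel_pitch_nm,
              params = list(radius_px = radius_px, size_px = size_px))
}

# Rasterize a thick straight segment into mask (set to 1).  Endpoints are
# (row, col) in continuous pixel coordinates; width is in pixels.  A pixel
# belongs to the fibril if its centre lies within width/2 of the segment
# axis; with continuous (non-lattice) axis positions this covers exactly
# `width_px` pixel rows across the fibril almost surely.
draw_fibril <- function(mask, p1, p2, width_px) {
  nr <- nrow(mask); nc <- ncol(mask)
  v <- p2 - p1
  len <- sqrt(sum(v^2))
  if (len < 1e-9) return(mask)
  u <- v / len
  half <- width_px / 2
  r0 <- max(1L, floor(min(p1[1], p2[1]) - half - 1))
  r1 <- min(nr, ceiling(max(p1[1], p2[1]) + half + 1))
  c0 <- max(1L, floor(min(p1[2], p2[2]) - half - 1))
  c1 <- min(nc, ceiling(max(p1[2], p2[2]) + half + 1))
  if (r0 > r1 || c0 > c1) return(mask)
  rr <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
  cc <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
  # distance from pixel centres to the segment
  wx <- rr - p1[1]; wy <- cc - p1[2]
  t <- pmin(pmax((wx * (p2[1] - p1[1]) + wy * (p2[2] - p1[2])) / len^2, 0), 1)
  dx <- wx - t * (p2[1] - p1[1]); dy <- wy - t * (p2[2] - p1[2])
  hit <- sqrt(dx^2 + dy^2) <= half
  sub <- mask[r0:r1, c0:c1]
  sub[hit] <- 1L
  mask[r0:r1, c0:c1] <- sub
  mask
}

sample_fibril_widths <- function(n, width_px, width_prob) {
  if (is.null(width_prob)) width_prob <- rep(1 / length(width_px), length(width_px))
  stopifnot(length(width_prob) == length(width_px), all(width_px >= 1))
  width_px[sample.int(length(width_px), n, replace = TRUE, prob = width_prob)]
}

#' Random fibril-network phantom
#'
#' The solid phase is a union of straight thick segments ("fibrils") with
#' random position and orientation, emulating the fibril-like network of an
#' alginate hydrogel as seen in TEM sections; the cavity phase is its
#' complement.  Ground-truth gap widths are measured on the clean mask with
#' [scan_gap_widths()] -- a directional run-scan that shares no code with
#' the distance-transform/skeleton chain under test, so closed-loop
#' comparisons pit two independent measurement routes against each other.
#'
#' @param image_px image side length in pixels (scalar, square image).
#' @param fibril_count number of fibrils (>= 2).
#' @param width_px candidate fibril widths in pixels.
#' @param width_prob sampling probabilities for `width_px` (default uniform).
#' @param length_px fibril length in pixels; the default spans the frame so
#'   the solid phase forms one connected network.
#' @param pixel_pitch_nm physical pixel pitch, nm/px.
#' @param seed integer seed; generation is bit-reproducible.
#' @return A `phantom` with `truth_gaps` and `truth_fibril_widths` filled in.
#' @export
generate_fibril_network <- function(image_px = 512L, fibril_count = 50L,
                                    width_px = c(1L, 2L, 3L),
                                    width_prob = c(0.5, 0.35, 0.15),
                                    length_px = NULL,
                                    pixel_pitch_nm = 2.34, seed = 1L) {
  if (fibril_count < 2) stop("fibril_count must be >= 2")
  if (missing(width_prob) && length(width_px) != length(width_prob))
    width_prob <- NULL                     # custom widths, uniform sampling
  if (is.null(length_px)) length_px <- ceiling(sqrt(2) * image_px) + 2L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  m <- matrix(0L, image_px, image_px)
  widths <- sample_fibril_widths(fibril_count, width_px, width_prob)
  frame_ctr <- (image_px + 1) / 2
  half_diag <- sqrt(2) * image_px / 2
  for (i in seq_len(fibril_count)) {
    # homogeneous line process: uniform orientation and uniform signed
    # offset from the frame centre, so line density is spatially uniform
    # (uniform chord centres would concentrate coverage centrally)
    th <- runif(1, 0, pi)
    rho <- runif(1, -half_diag, half_diag)
    foot <- frame_ctr + rho * c(cos(th), sin(th))
    u <- c(-sin(th), cos(th))
    m <- draw_fibril(m, foot - u * length_px / 2, foot + u * length_px / 2,
                     widths[i])
  }
  if (!any(m == 0L))
    stop("degenerate phantom: fibril density leaves no cavity pixels")
  gaps <- scan_gap_widths(m, pixel_pitch_nm)
  new_phantom(m, pixel_pitch_nm,
              truth_gaps = gaps$gap_nm,
              truth_gap_weights = gaps$weight,
              truth_fibril_widths = widths * pixel_pitch_nm,
              seed = seed,
              params = list(image_px = image_px, fibril_count = fibril_count,
                            width_px = width_px, width_prob = width_prob,
                            length_px = length_px))
}

#' Ground-truth gap widths by directional run scanning
#'
#' Independent reference measurement of wall-to-wall gaps on a clean binary
#' mask, free of any distance-transform or skeleton code: for every cavity
#' pixel the runs of contiguous cavity pixels through it are measured along
#' the two axes and the two diagonals (diagonal counts scaled by sqrt(2) to
#' geometric length), and the gap at that pixel is the shortest of the
#' four.  Each pixel carries weight `1 / gap_px`, so a channel contributes
#' in proportion to its length, not its area -- the same weighting a
#' one-pixel-wide centre-line sample gives.
#'
#' @param mask binary matrix, solid phase = 1, cavity = 0.
#' @param pixel_pitch_nm physical pixel pitch, nm/px.
#' @return A data frame with `gap_nm` and `weight`, one row per cavity
#'   pixel.
#' @export
scan_gap_widths <- function(mask, pixel_pitch_nm = 2.34) {
  cav <- mask == 0L
  if (!any(cav) || all(cav)) stop("mask must contain both phases")
  nr <- nrow(cav); nc <- ncol(cav)
  runlen <- function(groups) {
    # per-pixel TRUE-run length along index groups (each group a vector of
    # matrix indices in path order)
    out <- numeric(nr * nc)
    for (g in groups) {
      r <- rle(cav[g])
      out[g] <- rep(ifelse(r$values, r$lengths, NA_real_), r$lengths)
    }
    out
  }
  idx <- matrix(seq_len(nr * nc), nr, nc)
  rows <- lapply(seq_len(nr), function(i) idx[i, ])
  cols <- lapply(seq_len(nc), function(j) idx[, j])
  d1 <- split(seq_len(nr * nc), row(idx) - col(idx))
  d2 <- split(seq_len(nr * nc), row(idx) + col(idx))
  g <- pmin(runlen(rows), runlen(cols),
            sqrt(2) * runlen(d1), sqrt(2) * runlen(d2))
  keep <- which(cav)
  data.frame(gap_nm = g[keep] * pixel_pitch_nm, weight = 1 / g[keep])
}

#' Gap widths at cavity medial points
#'
#' Independent reference measurement of wall-to-wall gaps on a clean binary
#' mask: the exact Euclidean distance transform of the cavity phase is
#' evaluated at its medial points (pixels whose distance value is >= that of
#' all 8 neighbours), and the gap is twice that nearest-wall distance.  This
#' routine is deliberately kept free of the skeleton-thinning code used by
#' the measurement chain, so the two can serve as mutual cross-checks.
#'
#' @param mask binary matrix, solid phase = 1, cavity = 0.
#' @param pixel_pitch_nm physical pixel pitch, nm/px.
#' @return Numeric vector of gap widths (nm), one per medial point.
#' @export
medial_gap_widths <- function(mask, pixel_pitch_nm = 2.34) {
  cav <- mask == 0L
  if (!any(cav) || all(cav)) stop("mask must contain both phases")
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(cav * 1)))
  is_max <- cav
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (d >= shift_mat(d, dr, dc))
  }
  2 * d[is_max & cav] * pixel_pitch_nm
}

# save/restore .Random.seed so seeded generators do not disturb the
# caller's RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Render a phantom as a corrupted TEM-like micrograph
#'
#' Maps the binary truth mask to a two-level image (alginate is
#' electron-dense and renders dark), adds a smooth low-frequency
#' illumination bias field (heavily smoothed seeded noise, zero mean, unit
#' variance, scaled by `inhomogeneity_amplitude`) and white Gaussian noise,
#' then clips to the 8-bit range.  With zero amplitude and zero noise the
#' rendering is exactly the two-level image.
#'
#' @param phantom a `phantom`.
#' @param noise_sd additive Gaussian noise standard deviation (intensity units).
#' @param inhomogeneity_amplitude bias-field standard deviation (intensity units).
#' @param inhomogeneity_scale_px correlation scale of the bias field, px.
#' @param contrast two intensities `c(fg_level, bg_level)` for the alginate
#'   (foreground) and cavity phases; must differ.
#' @param seed integer seed.
#' @return The phantom with its `rendered` field filled in.
#' @export
render_tem <- function(phantom, noise_sd = 15, inhomogeneity_amplitude = 20,
                       inhomogeneity_scale_px = 100, contrast = c(60, 180),
                       seed = 1L) {
  stopifnot(inherits(phantom, "phantom"))
  if (contrast[1] == contrast[2]) stop("fg and bg levels must differ")
  if (noise_sd < 0 || inhomogeneity_amplitude < 0)
    stop("noise_sd and inhomogeneity_amplitude must be non-negative")
  m <- phantom$truth_mask
  img <- ifelse(m == 1L, contrast[1], contrast[2])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (inhomogeneity_amplitude > 0) {
    z <- matrix(rnorm(length(m)), nrow(m), ncol(m))
    b <- gauss_smooth(z, inhomogeneity_scale_px)
    b <- (b - mean(b)) / sd(b) * inhomogeneity_amplitude
    img <- img + b
  }
  if (noise_sd > 0)
    img <- img + matrix(rnorm(length(m), sd = noise_sd), nrow(m), ncol(m))
  img <- pmin(pmax(img, 0), 255)
  phantom$rendered <- img
  phantom$params$render <- list(noise_sd = noise_sd,
                                inhomogeneity_amplitude = inhomogeneity_amplitude,
                                inhomogeneity_scale_px = inhomogeneity_scale_px,
                                contrast = contrast, seed = seed)
  phantom
}

#' Cell-in-matrix phantom with a densified interface halo
#'
#' A fibril network with a disc-shaped cell in the centre and, within
#' `halo_depth_nm` of the cell boundary, extra thin fibrils added until the
#' small-gap fraction of the near field exceeds that of the far field by
#' approximately `halo_small_pore_boost`.  This emulates matrix compaction
#' around a growing entrapped cell.  Ground truth records near-field and
#' far-field gap distributions separately (`truth_gaps_near`,
#' `truth_gaps_far`), measured on the clean mask with
#' [medial_gap_widths()]-style medial sampling restricted by zone.
#'
#' @param cell_radius_px cell disc radius, px.
#' @param halo_depth_nm halo depth from the cell boundary, nm (<= 400).
#' @param halo_small_pore_boost target elevation of the near-field small-gap
#'   (gap/2 <= 10 nm) fraction over the far field, in `[0, 1]`.
#' @param image_px image side, px.
#' @param fibril_count fibrils in the base network.
#' @param width_px,width_prob base fibril width distribution.
#' @param small_gap_nm radius threshold defining "small" gaps (nm).
#' @param pixel_pitch_nm physical pixel pitch, nm/px.
#' @param seed integer seed.
#' @param cell_body `"solid"` renders the cell as a solid body (the
#'   realistic scene; measurements near it are boundary-censored),
#'   `"virtual"` keeps the matrix running under the contour, giving an
#'   undisturbed null control for the depth-profiling machinery.  The
#'   default is `"solid"` when a halo is requested and `"virtual"` for
#'   `halo_small_pore_boost = 0`, so the no-effect case is free of
#'   boundary censoring.
#' @return A `phantom` with `cell_mask`, `truth_gaps_near`, `truth_gaps_far`.
#' @export
generate_cell_phantom <- function(cell_radius_px = 60L, halo_depth_nm = 40,
                                  halo_small_pore_boost = 0.3,
                                  image_px = 384L, fibril_count = 38L,
                                  width_px = c(1L, 2L, 3L),
                                  width_prob = c(0.5, 0.35, 0.15),
                                  small_gap_nm = 10, pixel_pitch_nm = 2.34,
                                  seed = 1L, cell_body = NULL) {
  if (halo_depth_nm > 400) stop("halo_depth_nm must be <= 400")
  if (halo_small_pore_boost < 0 || halo_small_pore_boost > 1)
    stop("halo_small_pore_boost must be in [0, 1]")
  if (2 * cell_radius_px >= image_px)
    stop("cell larger than image")
  if (is.null(cell_body))
    cell_body <- if (halo_small_pore_boost > 0) "solid" else "virtual"
  cell_body <- match.arg(cell_body, c("solid", "virtual"))
  if (missing(width_prob) && length(width_px) != length(width_prob))
    width_prob <- NULL
  base <- generate_fibril_network(image_px = image_px,
                                  fibril_count = fibril_count,
                                  width_px = width_px, width_prob = width_prob,
                                  pixel_pitch_nm = pixel_pitch_nm, seed = seed)
  m <- base$truth_mask
  ctr <- (image_px + 1) / 2
  rr <- matrix(seq_len(image_px), image_px, image_px)
  cc <- t(rr)
  rad <- sqrt((rr - ctr)^2 + (cc - ctr)^2)
  cell <- (rad <= cell_radius_px) * 1L
  halo_px <- halo_depth_nm / pixel_pitch_nm
  in_halo <- rad > cell_radius_px & rad <= cell_radius_px + halo_px

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + 1L)
  if (halo_small_pore_boost > 0) {
    seg_len <- 3 * halo_px
    for (batch in seq_len(60L)) {
      zf <- zone_small_fractions(m, cell, rad, cell_radius_px, halo_px,
                                 small_gap_nm, pixel_pitch_nm)
      if (!is.na(zf$near) && !is.na(zf$far) &&
          zf$near - zf$far >= halo_small_pore_boost) break
      for (k in seq_len(4L)) {
        th0 <- runif(1, 0, 2 * pi)
        r0 <- cell_radius_px + runif(1, 0, halo_px)
        p0 <- c(ctr + r0 * cos(th0), ctr + r0 * sin(th0))
        th <- runif(1, 0, pi)
        u <- c(cos(th), sin(th))
        m <- draw_fibril(m, p0 - u * seg_len / 2, p0 + u * seg_len / 2, 1L)
      }
    }
  }
  if (cell_body == "solid")
    m[cell == 1L] <- 1L   # cell body is solid; it is excluded downstream

  zone <- zone_gap_widths(m, cell, rad, cell_radius_px, halo_px,
                          pixel_pitch_nm, cell_body)
  ph <- new_phantom(m, pixel_pitch_nm,
                    truth_gaps = c(zone$near$gap_nm, zone$far$gap_nm),
                    truth_gap_weights = c(zone$near$weight, zone$far$weight),
                    truth_fibril_widths = base$truth_fibril_widths,
                    cell_mask = cell, seed = seed,
                    params = c(base$params,
                               list(cell_radius_px = cell_radius_px,
                                    halo_depth_nm = halo_depth_nm,
                                    halo_small_pore_boost = halo_small_pore_boost)))
  ph$truth_gaps_near <- zone$near
  ph$truth_gaps_far <- zone$far
  ph
}

# scan-based gap widths split into near (within halo of the cell rim) and
# far (beyond 2x halo) zones.  A solid cell body is excluded from the wall
# set (treated as open space) so that gaps reflect matrix structure only,
# not proximity to the cell itself -- the same convention run_interface()
# uses; cell-interior pixels carry no samples either way.
zone_gap_widths <- function(m, cell, rad, cell_radius_px, halo_px, pitch,
                            cell_body = "solid") {
  mm <- m
  if (cell_body == "solid") mm[cell == 1L] <- 0L
  if (!any(mm == 0L) || !any(mm == 1L))
    return(list(near = data.frame(gap_nm = numeric(), weight = numeric()),
                far = data.frame(gap_nm = numeric(), weight = numeric())))
  g <- scan_gap_widths(mm, pitch)
  depth <- (rad - cell_radius_px)[mm == 0L]
  list(near = g[depth > 0 & depth <= halo_px, ],
       far = g[depth > 2 * halo_px, ])
}

zone_small_fractions <- function(m, cell, rad, cell_radius_px, halo_px,
                                 small_gap_nm, pitch) {
  z <- zone_gap_widths(m, cell, rad, cell_radius_px, halo_px, pitch, "solid")
  frac <- function(df) if (nrow(df))
    sum(df$weight[df$gap_nm / 2 <= small_gap_nm]) / sum(df$weight)
    else NA_real_
  list(near = frac(z$near), far = frac(z$far))
}

#' Write phantom rasters and ground truth to disk
#'
#' Writes `truth_mask`, `rendered` and `cell_mask` (when present) as TIFF
#' images plus a JSON sidecar with the ground-truth gap and fibril-width
#' statistics and generator parameters.
#'
#' @param phantom a `phantom`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir, stem = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(dir, paste0(stem, "_truth.tif"))
  write_raster(phantom$truth_mask, p); paths <- c(paths, p)
  if (!is.null(phantom$rendered)) {
    p <- file.path(dir, paste0(stem, "_rendered.tif"))
    write_raster(phantom$rendered, p); paths <- c(paths, p)
  }
  if (!is.null(phantom$cell_mask)) {
    p <- file.path(dir, paste0(stem, "_cell.tif"))
    write_raster(phantom$cell_mask, p); paths <- c(paths, p)
  }
  truth <- list(pixel_pitch_nm = phantom$pixel_pitch_nm,
                truth_gaps_nm = phantom$truth_gaps,
                truth_fibril_widths_nm = phantom$truth_fibril_widths,
                seed = phantom$seed, params = phantom$params)
  p <- file.path(dir, paste0(stem, "_truth.json"))
  jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
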