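#' Exact Euclidean distance transform of one phase
#'
#' For every pixel of the target phase, the shortest Euclidean distance (in
#' pixels, between pixel centres) to the nearest pixel of the complementary
#' phase; zero on the complementary phase itself.  `"pore"` measures the
#' cavity phase against the alginate walls; `"fibril"` inverts the mask and
#' measures the solid phase against the cavities.  Distances are exact, not
#' chamfer approximations.  Pixels outside the frame belong to no phase, so
#' the image border never acts as an artificial wall.
#'
#' @param pm a [phase_mask()].
#' @param target_phase `"pore"` or `"fibril"`.
#' @return An object of class `distance_map`: list with `values` (px),
#'   `pixel_pitch_nm`, `phase`.
#' @export
distance_transform <- function(pm, target_phase = c("pore", "fibril")) {
  stopifnot(inherits(pm, "phase_mask"))
  target_phase <- match.arg(target_phase)
  tgt <- if (target_phase == "pore") pm$mask == 0L else pm$mask == 1L
  if (!any(tgt) || all(tgt))
    stop("degenerate mask: both phases must be present")
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(tgt * 1)))
  d <- as.matrix(d)
  structure(list(values = d, pixel_pitch_nm = pm$pixel_pitch_nm,
                 phase = target_phase),
            class = "distance_map")
}

#' Medial-axis skeleton of a phase
#'
#' One-pixel-wide, connectivity-preserving centre axis of the target phase,
#' passing through the local maxima of the distance transform.  Implemented
#' as anchored sequential thinning: phase pixels are peeled in order of
#' increasing distance value, a pixel being removable only if its deletion
#' preserves local topology and it is neither a curve endpoint nor a strict
#' local maximum of the distance map.  The peeling order and its
#' column-major tie-break are fixed, so the result is deterministic; for an
#' even-width slit, where the two centre rows tie, the convention keeps
#' exactly one of them.  Every cavity component retains at least one
#' skeleton pixel.
#'
#' @param dmap a [distance_transform()] result.
#' @param pm the [phase_mask()] the map was computed on.
#' @return Logical matrix: `TRUE` on skeleton pixels.
#' @export
extract_skeleton <- function(dmap, pm) {
  stopifnot(inherits(dmap, "distance_map"), inherits(pm, "phase_mask"))
  if (!identical(dim(dmap$values), dim(pm$mask)))
    stop("distance map and mask dimensions differ")
  tgt <- if (dmap$phase == "pore") pm$mask == 0L else pm$mask == 1L
  thin_skeleton(tgt, dmap$values)
}

#' Sample radii along a skeleton
#'
#' One measurement per skeleton pixel: the distance-transform value there is
#' the distance to the nearest wall, i.e. half the wall-to-wall gap, and is
#' reported in nm via the pixel pitch.  For the pore phase this is the
#' relative pore radius (rpr); for the fibril phase, the fibril-like radius
#' (flr).  The frequency table counts how many skeleton pixels share each
#' quantized radius value (pixel distances rounded to 2 decimals before
#' scaling, matching the discrete granularity of exact pixel distances).
#'
#' @param dmap a [distance_transform()] result.
#' @param skeleton logical matrix from [extract_skeleton()].
#' @param pitch_nm pixel pitch override; defaults to the map's.
#' @return An object of class `radius_samples`: `samples` data frame
#'   (`row`, `col`, `radius_px`, `radius_nm`), `frequency` table, `phase`,
#'   `pixel_pitch_nm`.  An empty skeleton yields an empty set with a
#'   warning.
#' @export
measure_radii <- function(dmap, skeleton, pitch_nm = NULL) {
  stopifnot(inherits(dmap, "distance_map"))
  if (is.null(pitch_nm)) pitch_nm <- dmap$pixel_pitch_nm
  idx <- which(skeleton, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warning("measure_radii: empty skeleton, returning empty sample set")
    samples <- data.frame(row = integer(), col = integer(),
                          radius_px = numeric(), radius_nm = numeric())
  } else {
    d <- dmap$values[idx]
    keep <- d > 0
    idx <- idx[keep, , drop = FALSE]
    d <- d[keep]
    samples <- data.frame(row = idx[, 1], col = idx[, 2],
                          radius_px = d, radius_nm = d * pitch_nm)
  }
  q <- round(samples$radius_px, 2) * pitch_nm
  structure(list(samples = samples,
                 frequency = table(q),
                 phase = dmap$phase,
                 pixel_pitch_nm = pitch_nm),
            class = "radius_samples")
}

#' @export
print.radius_samples <- function(x, ...) {
  cat(sprintf("radius_samples (%s): %d samples", x$phase, nrow(x$samples)))
  if (nrow(x$samples))
    cat(sprintf(", median %.2f nm, max %.2f nm",
                stats::median(x$samples$radius_nm), max(x$samples$radius_nm)))
  cat("\n")
  invisible(x)
}

#' Bin-edge schemes for radius distributions
#'
#' `"rpr_table1"` is the standard relative-pore-radius scheme
#' (<= 10, 10--20, 20--25, 25--40, 40--70, > 70 nm); `"flr_table2"` is the
#' fibril-radius scheme with class width equal to the 2.34 nm pixel pitch
#' (<= 2.34, 2.34--4.68, 4.68--7.02, 7.02--9.36, > 9.36 nm).
#'
#' @param scheme scheme name or a numeric vector of custom edges
#'   (finite interior edges; 0 and Inf are added if absent).
#' @return Numeric vector of bin edges including 0 and Inf.
#' @export
bin_scheme <- function(scheme = "rpr_table1") {
  if (is.numeric(scheme)) {
    e <- sort(unique(scheme))
    if (e[1] > 0) e <- c(0, e)
    if (is.finite(e[length(e)])) e <- c(e, Inf)
    if (length(e) < 3) stop("custom scheme needs at least one interior edge")
    return(e)
  }
  switch(match.arg(scheme, c("rpr_table1", "flr_table2")),
         rpr_table1 = c(0, 10, 20, 25, 40, 70, Inf),
         flr_table2 = c(0, 2.34, 4.68, 7.02, 9.36, Inf))
}

#' Binned percent-frequency distribution
#'
#' Percentages of radius samples per class.  Classes are right-closed,
#' `(lo, hi]`, so the first class is "radius <= first edge" as convention-
#' ally printed and no sample falls between classes.
#'
#' @param samples a [measure_radii()] result, or a numeric vector of radii
#'   in nm.
#' @param scheme passed to [bin_scheme()].
#' @param weights optional non-negative per-sample weights (e.g. the
#'   length-weighting of [scan_gap_widths()]); default unweighted.
#' @return An object of class `binned_distribution`: `bin_edges_nm`,
#'   `percent`, `n_samples`, `bin_labels`.
#' @export
bin_distribution <- function(samples, scheme = "rpr_table1", weights = NULL) {
  x <- if (inherits(samples, "radius_samples")) samples$samples$radius_nm
       else as.numeric(samples)
  if (length(x) == 0L) stop("cannot bin an empty sample set")
  if (is.null(weights)) weights <- rep(1, length(x))
  stopifnot(length(weights) == length(x), all(weights >= 0))
  edges <- bin_scheme(scheme)
  bin <- findInterval(x, edges, left.open = TRUE)
  wsum <- vapply(seq_len(length(edges) - 1L),
                 function(k) sum(weights[bin == k]), numeric(1))
  new_binned_distribution(edges, 100 * wsum / sum(weights), length(x))
}

#' Ground-truth radius distribution of a phantom
#'
#' Bins the phantom's recorded gap widths (as radii, gap/2) with their
#' multiplicity weights.
#'
#' @param phantom a `phantom` with recorded `truth_gaps`.
#' @param scheme passed to [bin_scheme()].
#' @return A `binned_distribution`.
#' @export
truth_distribution <- function(phantom, scheme = "rpr_table1") {
  stopifnot(inherits(phantom, "phantom"))
  if (!length(phantom$truth_gaps)) stop("phantom records no truth gaps")
  bin_distribution(phantom$truth_gaps / 2, scheme,
                   weights = phantom$truth_gap_weights)
}

new_binned_distribution <- function(edges, percent, n, tol = 0.5) {
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  if (any(percent < 0)) stop("percentages must be non-negative")
  if (abs(sum(percent) - 100) > tol)
    stop(sprintf("percentages sum to %.2f, outside 100 +/- %g",
                 sum(percent), tol))
  ne <- length(edges)
  labs <- c(sprintf("<=%g", edges[2]),
            if (ne > 3) sprintf("%g-%g", edges[2:(ne - 2)], edges[3:(ne - 1)]),
            sprintf(">%g", edges[ne - 1]))
  structure(list(bin_edges_nm = edges, percent = as.numeric(percent),
                 n_samples = as.integer(n), bin_labels = labs),
            class = "binned_distribution")
}

#' Construct a binned distribution from published percentages
#'
#' Wraps externally reported class percentages (e.g. from a physisorption
#' analyzer report) in the same container the image pipeline produces, so
#' the two can be compared with [compare_distributions()].  Printed tables
#' carry per-class rounding, so their sum is accepted within 100 +/- 1
#' (computed distributions are held to +/- 0.5).
#'
#' @param percent numeric vector of class percentages.
#' @param scheme passed to [bin_scheme()].
#' @param n_samples sample count if known.
#' @return A `binned_distribution`.
#' @export
as_binned_distribution <- function(percent, scheme = "rpr_table1",
                                   n_samples = NA_integer_) {
  edges <- bin_scheme(scheme)
  if (length(percent) != length(edges) - 1L)
    stop("percent length does not match the scheme's class count")
  new_binned_distribution(edges, percent, n_samples, tol = 1)
}

#' @export
print.binned_distribution <- function(x, ...) {
  cat(sprintf("binned_distribution (n = %s):\n",
              ifelse(is.na(x$n_samples), "?", x$n_samples)))
  for (i in seq_along(x$percent))
    cat(sprintf("  %-12s %6.1f %%\n", x$bin_labels[i], x$percent[i]))
  invisible(x)
}

#' Compare two binned distributions
#'
#' Per-class absolute difference in percentage points, the maximum
#' difference, and the total-variation distance (half the L1 difference on
#' the probability scale).  Used to quantify cross-method agreement, e.g.
#' image-derived versus physisorption-derived pore-size distributions.
#'
#' @param a,b `binned_distribution`s over identical edges.
#' @return List with `per_bin` (named numeric), `max_diff` (percentage
#'   points) and `tv_distance` (in `[0, 1]`).
#' @export
compare_distributions <- function(a, b) {
  stopifnot(inherits(a, "binned_distribution"),
            inherits(b, "binned_distribution"))
  if (!isTRUE(all.equal(a$bin_edges_nm, b$bin_edges_nm)))
    stop("distributions have different bin edges")
  d <- abs(a$percent - b$percent)
  names(d) <- a$bin_labels
  list(per_bin = d, max_diff = max(d), tv_distance = sum(d) / 200)
}

#' Write a radius sample set or distribution to CSV/JSON
#'
#' @param x a `radius_samples` or `binned_distribution`.
#' @param path output path; `.csv` writes tabular form, `.json` structured.
#' @return Invisibly, the path.
#' @export
write_porometry <- function(x, path) {
  if (grepl("\\.json$", path)) {
    obj <- if (inherits(x, "binned_distribution"))
      list(bin_edges_nm = x$bin_edges_nm[is.finite(x$bin_edges_nm)],
           bin_labels = x$bin_labels, percent = x$percent,
           n_samples = x$n_samples)
    else list(phase = x$phase, pixel_pitch_nm = x$pixel_pitch_nm,
              samples = x$samples)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else if (inherits(x, "binned_distribution")) {
    write.csv(data.frame(bin = x$bin_labels, percent = x$percent),
              path, row.names = FALSE)
  } else {
    write.csv(x$samples, path, row.names = FALSE)
  }
  invisible(path)
}

#' Bar chart of a binned distribution
#'
#' @param x a `binned_distribution`.
#' @param path PNG output path.
#' @param main plot title.
#' @return Invisibly, the path.
#' @export
plot_distribution <- function(x, path, main = "Pore-size distribution") {
  grDevices::png(path, width = 640, height = 480)
  graphics::barplot(x$percent, names.arg = x$bin_labels,
                    ylab = "frequency (%)", xlab = "radius class (nm)",
                    main = main)
  grDevices::dev.off()
  invisible(path)
}
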