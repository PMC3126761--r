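#' Pipeline configuration
#'
#' One serializable object holding every tunable of the measurement chain.
#' Defaults reproduce the standard analysis settings: 2.34 nm/px pitch,
#' Otsu thresholding, 275 nm^2 minimum lumen area, the standard rpr bin
#' scheme, and 0--400 nm depth bins in 20 nm steps.
#'
#' @param pixel_pitch_nm physical pixel pitch, nm/px.
#' @param preprocess list of per-stage parameter lists (see [preprocess()]).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold value (if used).
#' @param polarity `"auto"`, `"dark"` or `"bright"`.
#' @param min_lumen_area_nm2 lumen-area cutoff, nm^2.
#' @param scheme radius bin scheme.
#' @param depth_edges_nm depth-bin edges for interface profiling.
#' @param seed integer seed echoed into outputs.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_pitch_nm = 2.34,
                            preprocess = list(),
                            threshold_method = "otsu",
                            threshold = NULL,
                            polarity = "auto",
                            min_lumen_area_nm2 = 275,
                            scheme = "rpr_table1",
                            depth_edges_nm = seq(0, 400, 20),
                            seed = 1L) {
  cfg <- list(pixel_pitch_nm = pixel_pitch_nm, preprocess = preprocess,
              threshold_method = threshold_method, threshold = threshold,
              polarity = polarity, min_lumen_area_nm2 = min_lumen_area_nm2,
              scheme = scheme, depth_edges_nm = depth_edges_nm, seed = seed)
  stopifnot(pixel_pitch_nm > 0, min_lumen_area_nm2 >= 0)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  cat(sprintf("  pitch %.4g nm/px | threshold %s | min lumen %.0f nm^2 | scheme %s\n",
              x$pixel_pitch_nm, x$threshold_method, x$min_lumen_area_nm2,
              if (is.character(x$scheme)) x$scheme else "custom"))
  cat(sprintf("  hash %s\n", config_hash(x)))
  invisible(x)
}

#' Stable hash of a configuration
#'
#' MD5 of the JSON serialization, embedded in every output file so results
#' can be traced to the exact settings that produced them.
#'
#' @param cfg a [pipeline_config()].
#' @return Character MD5 digest.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tf))
}

# run the single-image measurement chain; input is a path, a
# calibrated_image, or a rendered phantom.  exclude_mask (e.g. a cell body)
# is removed from the wall set after segmentation so that radii measure
# matrix structure only; samples inside it are dropped downstream.
measure_one <- function(input, cfg, exclude_mask = NULL) {
  img <- if (inherits(input, "calibrated_image")) {
    input
  } else if (inherits(input, "phantom")) {
    if (is.null(input$rendered))
      stop("phantom has no rendering; call render_tem() first")
    calibrated_image(input$rendered, input$pixel_pitch_nm)
  } else {
    read_micrograph(input, cfg$pixel_pitch_nm)
  }
  pre <- preprocess(img, cfg$preprocess)
  pmk <- binarize(pre, method = cfg$threshold_method,
                  threshold = cfg$threshold, polarity = cfg$polarity)
  pmk <- filter_small_lumina(pmk, cfg$min_lumen_area_nm2)
  if (!is.null(exclude_mask)) {
    m <- pmk$mask
    if (!identical(dim(exclude_mask), dim(m)))
      stop("image and cell mask dimensions differ")
    m[exclude_mask] <- 0L
    pmk <- phase_mask(m, pmk$pixel_pitch_nm, pmk$min_lumen_area_nm2,
                      c(pmk$meta, list(excluded_px = sum(exclude_mask))))
  }
  dm <- distance_transform(pmk, "pore")
  sk <- extract_skeleton(dm, pmk)
  rs <- measure_radii(dm, sk)
  list(image = img, mask = pmk, dmap = dm, skeleton = sk, samples = rs,
       distribution = bin_distribution(rs, cfg$scheme))
}

#' Batch pore-size analysis
#'
#' Runs the full measurement chain (preprocess, binarize, lumen filter,
#' distance transform, skeleton, radius sampling, binning) on each input
#' and pools radius samples across images by concatenation -- each skeleton
#' pixel is one measurement, so pooling weights images by their sample
#' counts.  Unreadable inputs are skipped with a logged error; if all fail,
#' the run errors.
#'
#' @param images list/vector of image paths, [calibrated_image()]s, or
#'   rendered phantoms.
#' @param cfg a [pipeline_config()].
#' @param out_dir optional output directory; if given, per-image sample
#'   CSVs, pooled distribution JSON/CSV and a bar chart are written, each
#'   stamped with the config hash and package version.
#' @return List: `per_image` (list of `binned_distribution`), `pooled`
#'   (`binned_distribution`), `pooled_radii_nm`, `n_failed`, `log`.
#' @export
run_porometry <- function(images, cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(length(images) >= 1)
  per <- list()
  radii <- numeric()
  log <- character()
  n_failed <- 0L
  for (i in seq_along(images)) {
    nm <- if (is.character(images[[i]])) images[[i]] else sprintf("input %d", i)
    res <- tryCatch(measure_one(images[[i]], cfg), error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      log <- c(log, sprintf("ERROR %s: %s", nm, conditionMessage(res)))
      next
    }
    per[[length(per) + 1L]] <- res$distribution
    radii <- c(radii, res$samples$samples$radius_nm)
    log <- c(log, sprintf("ok %s: %d samples", nm,
                          nrow(res$samples$samples)))
  }
  if (!length(per)) stop("all inputs failed:\n", paste(log, collapse = "\n"))
  pooled <- bin_distribution(radii, cfg$scheme)
  out <- list(per_image = per, pooled = pooled, pooled_radii_nm = radii,
              n_failed = n_failed, log = log,
              config_hash = config_hash(cfg),
              version = as.character(utils::packageVersion("poremetry")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(config_hash = out$config_hash, version = out$version,
           pooled = list(bin_labels = pooled$bin_labels,
                         percent = pooled$percent,
                         n_samples = pooled$n_samples),
           log = log),
      file.path(out_dir, "porometry.json"), auto_unbox = TRUE, digits = NA)
    write_porometry(pooled, file.path(out_dir, "pooled_distribution.csv"))
    plot_distribution(pooled, file.path(out_dir, "pooled_distribution.png"))
  }
  out
}

#' Batch interface profiling
#'
#' Pairs each micrograph with a cell-contour mask of identical dimensions,
#' runs the measurement chain on the matrix, and assigns every radius
#' sample to its depth bin from the interface.  Pooling concatenates
#' samples across images per depth bin.  A dimension mismatch fails that
#' pair only.
#'
#' @param images as in [run_porometry()].
#' @param cell_masks list of binary matrices or mask image paths, same
#'   length as `images`.
#' @param cfg a [pipeline_config()].
#' @param out_dir optional output directory for the pooled profile.
#' @param exclude_cell if `TRUE` (default) the cell body is removed from
#'   the wall set before the distance transform, so radii reflect matrix
#'   structure rather than proximity to the cell; measurements within
#'   about one pore radius of a solid body remain boundary-censored either
#'   way.  Set `FALSE` when the mask is a virtual delineation over
#'   continuous matrix (e.g. a null control).
#' @return List: `per_image` (list of `depth_profile`), `pooled`
#'   (`depth_profile`), `n_failed`, `log`.
#' @export
run_interface <- function(images, cell_masks, cfg = pipeline_config(),
                          out_dir = NULL, exclude_cell = TRUE) {
  if (length(cell_masks) == 0L) stop("empty cell mask list")
  if (length(images) != length(cell_masks))
    stop("images and cell_masks must have equal length")
  per <- list()
  all_r <- numeric(); all_d <- numeric()
  log <- character(); n_failed <- 0L
  for (i in seq_along(images)) {
    res <- tryCatch({
      cm <- cell_masks[[i]]
      if (is.character(cm)) cm <- read_micrograph(cm, cfg$pixel_pitch_nm)$pixels > 0
      cm <- as.matrix(cm) != 0
      one <- measure_one(images[[i]], cfg,
                         exclude_mask = if (exclude_cell) cm)
      idm <- interface_distance_map(cm, cfg$pixel_pitch_nm)
      profile_by_depth(one$samples, idm, cfg$depth_edges_nm, cfg$scheme)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      log <- c(log, sprintf("ERROR pair %d: %s", i, conditionMessage(res)))
      next
    }
    per[[length(per) + 1L]] <- res
    all_r <- c(all_r, res$samples$radius_nm)
    all_d <- c(all_d, res$samples$depth_nm)
    log <- c(log, sprintf("ok pair %d: %d samples within ceiling", i,
                          sum(res$n_per_depth)))
  }
  if (!length(per)) stop("all pairs failed:\n", paste(log, collapse = "\n"))
  pooled <- pool_depth_profile(all_r, all_d, cfg$depth_edges_nm, cfg$scheme)
  out <- list(per_image = per, pooled = pooled, n_failed = n_failed,
              log = log, config_hash = config_hash(cfg),
              version = as.character(utils::packageVersion("poremetry")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_depth_profile(pooled, file.path(out_dir, "depth_profile.csv"))
    write_depth_profile(pooled, file.path(out_dir, "depth_profile.json"))
  }
  out
}

# build a depth_profile from pooled (radius, depth) samples
pool_depth_profile <- function(radius_nm, depth_nm, depth_edges_nm, scheme) {
  bin <- findInterval(depth_nm, depth_edges_nm, left.open = TRUE)
  bin[depth_nm <= depth_edges_nm[1]] <- 1L
  nb <- length(depth_edges_nm) - 1L
  n_per <- tabulate(bin, nb)
  per <- vector("list", nb)
  for (k in seq_len(nb))
    if (n_per[k] > 0L)
      per[[k]] <- bin_distribution(radius_nm[bin == k], scheme)
  structure(list(depth_edges_nm = depth_edges_nm, per_depth = per,
                 n_per_depth = n_per, low_confidence = n_per < 30L,
                 samples = data.frame(radius_nm = radius_nm,
                                      depth_nm = depth_nm),
                 scheme = scheme),
            class = "depth_profile")
}
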