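# Independent oracles used across test files.

# O(n^2) brute-force Euclidean distance transform: for each pixel of the
# target phase, minimum distance to any complementary-phase pixel centre.
brute_force_edt <- function(target) {
  comp <- which(!target, arr.ind = TRUE)
  out <- matrix(0, nrow(target), ncol(target))
  tgt <- which(target, arr.ind = TRUE)
  for (k in seq_len(nrow(tgt))) {
    out[tgt[k, 1], tgt[k, 2]] <-
      sqrt(min((comp[, 1] - tgt[k, 1])^2 + (comp[, 2] - tgt[k, 2])^2))
  }
  out
}

# random binary mask with both phases guaranteed
random_mask <- function(n, p = 0.1, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n * n, 1L, p), n, n)
  if (!any(m == 1L)) m[1, 1] <- 1L
  if (!any(m == 0L)) m[n, n] <- 0L
  m
}

# modal quantized pixel radius of a pooled radius vector
modal_radius_px <- function(radius_nm, pitch = 2.34) {
  tab <- table(round(radius_nm / pitch, 2))
  as.numeric(names(tab)[which.max(tab)])
}

# default rendered network phantom + measured distribution, memoised so
# several tests can share one closed-loop run
measured_network <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    net <- generate_fibril_network(seed = 7)
    net <- render_tem(net, seed = 7)
    img <- calibrated_image(net$rendered, net$pixel_pitch_nm)
    pre <- preprocess(img)
    pm <- filter_small_lumina(binarize(pre))
    dm <- distance_transform(pm, "pore")
    sk <- extract_skeleton(dm, pm)
    rs <- measure_radii(dm, sk)
    cache <<- list(net = net, pre = pre, mask = pm, dmap = dm,
                   skeleton = sk, samples = rs,
                   dist = bin_distribution(rs, "rpr_table1"))
    cache
  }
})
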