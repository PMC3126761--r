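test_that("distance transform matches hand geometry", {
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  dm <- distance_transform(phase_mask(m, 1), "pore")
  expect_equal(dm$values[1, 1], sqrt(8))
  expect_equal(dm$values[3, 3], 0)

  ph <- generate_slit_phantom(3, length_px = 16, wall_px = 4)
  d <- distance_transform(phase_mask(ph$truth_mask, 2.34), "pore")$values
  expect_true(all(d[6, ] == 2))            # centre row of the slit
  expect_true(all(d[5, ] == 1))
  expect_true(all(d[ph$truth_mask == 1L] == 0))
})

test_that("distance transform equals the brute-force oracle on random masks", {
  for (s in 1:20) {
    m <- random_mask(32, p = 0.12, seed = s)
    dm <- distance_transform(phase_mask(m, 1), "pore")
    expect_equal(dm$values, brute_force_edt(m == 0L), tolerance = 1e-12)
  }
})

test_that("fibril mode measures the solid phase against the cavities", {
  ph <- generate_slit_phantom(3, length_px = 16, wall_px = 4)
  dm <- distance_transform(phase_mask(ph$truth_mask, 2.34), "fibril")
  expect_true(all(dm$values[ph$truth_mask == 0L] == 0))
  expect_true(all(dm$values[4, ] == 1))    # wall row adjacent to the slit
  expect_error(distance_transform(phase_mask(matrix(1L, 8, 8), 1), "pore"),
               "degenerate")
})

test_that("distance map is 1-Lipschitz between neighbours", {
  m <- random_mask(48, p = 0.1, seed = 3)
  d <- distance_transform(phase_mask(m, 1), "pore")$values
  expect_lte(max(abs(d[-1, ] - d[-nrow(d), ])), sqrt(2) + 1e-9)
  expect_lte(max(abs(d[, -1] - d[, -ncol(d)])), sqrt(2) + 1e-9)
})

test_that("slit skeletons are the centre row, with a deterministic even-width tie-break", {
  for (w in c(3, 9, 15)) {
    ph <- generate_slit_phantom(w, length_px = 24, wall_px = 8)
    pm <- phase_mask(ph$truth_mask, 2.34)
    sk <- extract_skeleton(distance_transform(pm, "pore"), pm)
    expect_equal(unique(which(sk, arr.ind = TRUE)[, 1]), 8 + (w + 1) %/% 2)
    expect_equal(sum(sk), 24)
  }
  for (w in c(4, 10)) {
    ph <- generate_slit_phantom(w, length_px = 24, wall_px = 8)
    pm <- phase_mask(ph$truth_mask, 2.34)
    sk1 <- extract_skeleton(distance_transform(pm, "pore"), pm)
    sk2 <- extract_skeleton(distance_transform(pm, "pore"), pm)
    rows <- unique(which(sk1, arr.ind = TRUE)[, 1])
    expect_length(rows, 1)                 # one of the two tied centre rows
    expect_equal(rows, 8 + w %/% 2)        # the first (smaller index) row
    expect_identical(sk1, sk2)
  }
})

test_that("a disc skeleton degenerates to a small cluster containing the centre", {
  ph <- generate_disc_phantom(8)
  pm <- phase_mask(ph$truth_mask, 2.34)
  sk <- extract_skeleton(distance_transform(pm, "pore"), pm)
  ctr <- (nrow(ph$truth_mask) + 1) / 2
  expect_true(sk[ctr, ctr])
  expect_lte(sum(sk), 5)
})

test_that("skeletons strictly thin every phase wider than one pixel", {
  m <- measured_network()
  expect_lt(sum(m$skeleton), sum(m$mask$mask == 0L))
  # every retained cavity component keeps at least one skeleton pixel
  labs <- unique(m$mask$labels[m$mask$labels > 0L])
  sk_labs <- unique(m$mask$labels[m$skeleton])
  expect_true(all(labs %in% sk_labs))
})

test_that("radius sampling along the slit skeleton gives the half-gap", {
  ph <- generate_slit_phantom(10, length_px = 64, wall_px = 8)
  pm <- phase_mask(ph$truth_mask, 2.34)
  dm <- distance_transform(pm, "pore")
  sk <- extract_skeleton(dm, pm)
  rs <- measure_radii(dm, sk)
  expect_lte(abs(modal_radius_px(rs$samples$radius_nm) - 5), 0.5)
  expect_equal(sum(rs$frequency), sum(sk))
  expect_equal(nrow(rs$samples), sum(sk))
})

test_that("disc radius sampling reaches the disc radius", {
  ph <- generate_disc_phantom(8)
  pm <- phase_mask(ph$truth_mask, 2.34)
  dm <- distance_transform(pm, "pore")
  rs <- measure_radii(dm, extract_skeleton(dm, pm))
  expect_lte(abs(max(rs$samples$radius_px) - 8), 1)
})

test_that("an empty skeleton yields an empty sample set with a warning", {
  ph <- generate_slit_phantom(3, length_px = 8, wall_px = 3)
  pm <- phase_mask(ph$truth_mask, 2.34)
  dm <- distance_transform(pm, "pore")
  none <- matrix(FALSE, nrow(pm$mask), ncol(pm$mask))
  expect_warning(rs <- measure_radii(dm, none), "empty")
  expect_equal(nrow(rs$samples), 0)
  expect_error(bin_distribution(rs), "empty")
})

test_that("binning honours the standard class edges and boundary convention", {
  d <- bin_distribution(rep(5, 10), "rpr_table1")
  expect_equal(d$percent, c(100, 0, 0, 0, 0, 0))
  # boundary: 10 nm falls in the first class ("rpr <= 10"), 10.01 in the second
  expect_equal(bin_distribution(c(10), "rpr_table1")$percent[1], 100)
  expect_equal(bin_distribution(c(10.01), "rpr_table1")$percent[2], 100)
  expect_equal(bin_scheme("flr_table2"), c(0, 2.34, 4.68, 7.02, 9.36, Inf))
  expect_equal(bin_scheme(c(5, 10)), c(0, 5, 10, Inf))
})

test_that("binning a large uniform sample approaches the analytic bin shares", {
  set.seed(17)
  x <- runif(1e5, 0, 80)
  d <- bin_distribution(x, "rpr_table1")
  want <- c(10, 10, 5, 15, 30, 10) / 80 * 100
  expect_lt(max(abs(d$percent - want)), 1)
})

test_that("printed reference tables are representable within the rounding tolerance", {
  img08 <- as_binned_distribution(c(49.4, 16.7, 11.1, 9.3, 11.0, 3.0))
  expect_equal(sum(img08$percent), 100.5)
  expect_error(as_binned_distribution(c(60, 20, 10, 5, 5, 3)), "outside")
  expect_error(as_binned_distribution(c(50, 50)), "class count")
})

test_that("distribution comparison reports per-bin and maximum discrepancies", {
  a <- as_binned_distribution(c(49.4, 16.7, 11.1, 9.3, 11.0, 3.0))
  expect_equal(compare_distributions(a, a)$max_diff, 0)

  # cross-method comparison, 0.8% w/v alginate: N2 physisorption vs image
  n2_08 <- as_binned_distribution(c(48.9, 15.4, 13.3, 11.3, 9.0, 2.2))
  cmp08 <- compare_distributions(n2_08, a)
  expect_equal(cmp08$max_diff, 2.2, tolerance = 1e-9)
  expect_equal(unname(cmp08$per_bin[4]), 2.0, tolerance = 1e-9)

  # 1.4% w/v alginate columns
  n2_14 <- as_binned_distribution(c(59.8, 16.1, 8.9, 8.8, 5.3, 1.1))
  img14 <- as_binned_distribution(c(62.8, 19.9, 9.4, 4.7, 2.9, 1.0),
                                  n_samples = NA)
  cmp14 <- compare_distributions(n2_14, img14)
  expect_equal(cmp14$max_diff, 4.1, tolerance = 1e-9)
  expect_lt(cmp08$max_diff, 5); expect_lt(cmp14$max_diff, 5)
  b <- as_binned_distribution(c(100, 0, 0, 0), scheme = c(1, 2, 3))
  expect_error(compare_distributions(a, b), "edges")
})

test_that("fibril-phase measurement recovers the generator's width mode", {
  net <- generate_fibril_network(image_px = 256, fibril_count = 20, seed = 6)
  pm <- phase_mask(net$truth_mask, 2.34)
  dm <- distance_transform(pm, "fibril")
  rs <- measure_radii(dm, extract_skeleton(dm, pm))
  modal_px <- modal_radius_px(rs$samples$radius_nm)
  # generator width mode is 1 px (radius ~0.5 px, quantized to 1 px by the
  # pixel-centre convention)
  expect_lte(abs(modal_px - 1), 1)
  flr <- bin_distribution(rs, "flr_table2")
  # thin-fibril classes dominate, as for alginate networks
  expect_gt(sum(flr$percent[1:2]), 80)
})

test_that("truth distributions and measured distributions agree in closed loop", {
  m <- measured_network()
  tru <- truth_distribution(m$net)
  cmp <- compare_distributions(m$dist, tru)
  expect_lte(cmp$tv_distance, 0.15)
})

test_that("porometry serialization round-trips CSV and JSON", {
  m <- measured_network()
  fc <- tempfile(fileext = ".csv")
  write_porometry(m$dist, fc)
  back <- read.csv(fc)
  expect_equal(back$percent, m$dist$percent)
  fj <- tempfile(fileext = ".json")
  write_porometry(m$dist, fj)
  expect_equal(unlist(jsonlite::read_json(fj)$percent), m$dist$percent)
  fp <- tempfile(fileext = ".png")
  plot_distribution(m$dist, fp)
  expect_true(file.exists(fp))
  unlink(c(fc, fj, fp))
})
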