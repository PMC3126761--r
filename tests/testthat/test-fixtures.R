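test_that("slit phantom records exact truth gaps and validates input", {
  expect_equal(generate_slit_phantom(3, pixel_pitch_nm = 2.34)$truth_gaps, 7.02)
  expect_equal(generate_slit_phantom(1, pixel_pitch_nm = 2.34)$truth_gaps, 2.34)
  ph <- generate_slit_phantom(5, length_px = 20, wall_px = 4)
  expect_equal(sum(ph$truth_mask == 0L), 5 * 20)
  expect_error(generate_slit_phantom(0), "positive")
  expect_error(generate_slit_phantom(3, length_px = -1), "positive")
})

test_that("disc phantom has the discrete-disc geometry", {
  ph <- generate_disc_phantom(8)
  area <- sum(ph$truth_mask == 0L)
  expect_lt(abs(area - pi * 64) / (pi * 64), 0.05)
  expect_equal(sum(generate_disc_phantom(2)$truth_mask == 0L), 13L)
  expect_error(generate_disc_phantom(1), ">= 2")
  expect_error(generate_disc_phantom(20, size_px = 30), "fit")
})

test_that("disc phantom maximum cavity distance equals the radius", {
  ph <- generate_disc_phantom(8)
  d <- brute_force_edt(ph$truth_mask == 0L)
  expect_lt(abs(max(d) - 8), 0.5)
})

test_that("fibril network generation is seeded, validated and density-monotone", {
  expect_error(generate_fibril_network(fibril_count = 0), ">= 2")
  a <- generate_fibril_network(image_px = 128, fibril_count = 12, seed = 4)
  b <- generate_fibril_network(image_px = 128, fibril_count = 12, seed = 4)
  expect_identical(a$truth_mask, b$truth_mask)
  expect_identical(a$truth_gaps, b$truth_gaps)
  frac <- sapply(1:5, function(s) {
    lo <- mean(generate_fibril_network(image_px = 128, fibril_count = 10,
                                       seed = s)$truth_mask == 0L)
    hi <- mean(generate_fibril_network(image_px = 128, fibril_count = 20,
                                       seed = s)$truth_mask == 0L)
    c(lo, hi)
  })
  expect_lt(mean(frac[2, ]), mean(frac[1, ]))
})

test_that("degenerate all-solid network is rejected", {
  expect_error(
    generate_fibril_network(image_px = 24, fibril_count = 200,
                            width_px = 9L, seed = 1),
    "degenerate")
})

test_that("rendering with zero corruption is the identity on the two-level image", {
  ph <- generate_slit_phantom(4, length_px = 16, wall_px = 4)
  r <- render_tem(ph, noise_sd = 0, inhomogeneity_amplitude = 0,
                  contrast = c(60, 180), seed = 1)
  expect_identical(r$rendered, ifelse(ph$truth_mask == 1L, 60, 180))
  expect_error(render_tem(ph, contrast = c(100, 100)), "differ")
})

test_that("render noise is unbiased: seeded-render mean approaches the clean image", {
  ph <- generate_slit_phantom(4, length_px = 24, wall_px = 6)
  clean <- ifelse(ph$truth_mask == 1L, 60, 180)
  acc <- 0
  n <- 100
  for (s in 1:n)
    acc <- acc + render_tem(ph, noise_sd = 10, inhomogeneity_amplitude = 0,
                            seed = s)$rendered
  se <- 10 / sqrt(n)
  expect_lt(max(abs(acc / n - clean)), 3 * se + 1e-9)
})

test_that("bias field introduces the low-frequency drift the corrector removes", {
  ph <- generate_fibril_network(image_px = 192, fibril_count = 15, seed = 2)
  r <- render_tem(ph, noise_sd = 0, inhomogeneity_amplitude = 25,
                  inhomogeneity_scale_px = 60, seed = 2)
  clean <- ifelse(ph$truth_mask == 1L, 60, 180)
  corner <- function(m) {
    n <- 48
    abs(mean(m[1:n, 1:n]) - mean(m[(nrow(m) - n + 1):nrow(m),
                                   (ncol(m) - n + 1):ncol(m)]))
  }
  expect_gt(corner(r$rendered), corner(clean))
})

test_that("render is bit-reproducible and leaves the caller's RNG untouched", {
  ph <- generate_slit_phantom(4, length_px = 16, wall_px = 4)
  set.seed(99)
  before <- .Random.seed
  r1 <- render_tem(ph, seed = 3)
  expect_identical(.Random.seed, before)
  r2 <- render_tem(ph, seed = 3)
  expect_identical(r1$rendered, r2$rendered)
})

test_that("cell phantom geometry and halo ground truth behave as designed", {
  cp <- generate_cell_phantom(cell_radius_px = 40, image_px = 192,
                              fibril_count = 8, halo_small_pore_boost = 0,
                              seed = 2)
  area <- sum(cp$cell_mask)
  expect_lt(abs(area - pi * 40^2) / (pi * 40^2), 0.05)
  expect_error(generate_cell_phantom(cell_radius_px = 100, image_px = 150),
               "larger than image")
  expect_error(generate_cell_phantom(halo_depth_nm = 500), "400")
})

test_that("halo boost elevates the near-field small-gap fraction in truth", {
  cp <- generate_cell_phantom(halo_depth_nm = 40, halo_small_pore_boost = 0.3,
                              seed = 5)
  frac <- function(df) sum(df$weight[df$gap_nm / 2 <= 10]) / sum(df$weight)
  expect_gt(frac(cp$truth_gaps_near), frac(cp$truth_gaps_far))
})

test_that("boost-free cell phantoms have statistically matching near/far truth", {
  # the near zone is small, so single-seed fractions are noisy; the signed
  # difference must average out across seeds if there is no halo effect
  diffs <- sapply(c(2, 5, 9, 13, 17), function(s) {
    cp <- generate_cell_phantom(halo_small_pore_boost = 0, seed = s)
    frac <- function(df) sum(df$weight[df$gap_nm / 2 <= 10]) / sum(df$weight)
    frac(cp$truth_gaps_near) - frac(cp$truth_gaps_far)
  })
  expect_lt(abs(mean(diffs)), 0.1)
})

test_that("scan and distance-transform gap measurements agree on simple shapes", {
  for (w in c(3, 6, 9)) {
    ph <- generate_slit_phantom(w, length_px = 32, wall_px = 6)
    scan <- scan_gap_widths(ph$truth_mask, 1)
    expect_equal(max(scan$gap_nm), w)           # slit width exactly
    med <- medial_gap_widths(ph$truth_mask, 1)
    # pixel-centre convention differs by at most one pixel from run width
    expect_lte(abs(stats::median(med) - w), 1 + 1e-9)
  }
})

test_that("phantom writer emits rasters plus a JSON truth sidecar", {
  td <- tempfile()
  ph <- render_tem(generate_slit_phantom(5), seed = 1)
  paths <- write_phantom(ph, td, "s5")
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(file.path(td, "s5_truth.json"))
  expect_equal(truth$pixel_pitch_nm, 2.34)
  expect_equal(truth$truth_gaps_nm, 5 * 2.34)
  unlink(td, recursive = TRUE)
})

test_that("synthetic BET isotherms follow the BET equation", {
  iso <- generate_bet_isotherm(245, C_bet = 80)
  expect_true(all(diff(iso$adsorption$amount_mol_g) > 0))
  expect_error(generate_bet_isotherm(245, p_grid = c(0, 0.1)), "strictly")
  expect_error(generate_bet_isotherm(245, C_bet = 0.5), "exceed 1")
  expect_error(generate_bet_isotherm(-5), "positive")
  n1 <- generate_bet_isotherm(245, noise_rel = 0.02, seed = 3)
  n2 <- generate_bet_isotherm(245, noise_rel = 0.02, seed = 3)
  expect_identical(n1$adsorption, n2$adsorption)
})
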