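# Physical constants for N2 physisorption at 77 K
.N_AVOGADRO <- 6.02214076e23
.N2_CROSS_SECTION_NM2 <- 0.162      # area covered by one adsorbed N2 molecule
.N2_LIQUID_MOLAR_CM3 <- 34.68       # molar volume of liquid N2, cm^3/mol
.GAS_STP_MOLAR_CM3 <- 22414         # molar volume of ideal gas at STP, cm^3/mol
.KELVIN_NM <- 0.9537                # 2 gamma V_L / (R T) for N2 at 77 K, nm

#' Nitrogen physisorption isotherm
#'
#' Adsorption and desorption branches of an N2 isotherm at 77 K: relative
#' pressures strictly inside (0, 1), amounts adsorbed per gram of material.
#' Amounts are stored internally in mol/g; `units` records the input unit
#' (`"cm3stp_g"` for cm^3 STP per gram -- the usual analyzer output -- or
#' `"mmol_g"`).
#'
#' @param adsorption,desorption data frames with columns `p_rel`, `amount`
#'   (either branch may be empty).
#' @param units unit of the `amount` column.
#' @param temperature_K nominal measurement temperature.
#' @param cross_section_nm2 molecular cross-section used for BET areas.
#' @return An object of class `isotherm` with amounts in mol/g.
#' @export
isotherm <- function(adsorption, desorption = NULL, units = "cm3stp_g",
                     temperature_K = 77, cross_section_nm2 = .N2_CROSS_SECTION_NM2) {
  conv <- switch(units,
                 cm3stp_g = 1 / .GAS_STP_MOLAR_CM3,
                 mmol_g = 1e-3,
                 mol_g = 1,
                 stop("unknown units: ", units))
  fix <- function(br, name) {
    if (is.null(br) || nrow(br) == 0L)
      return(data.frame(p_rel = numeric(), amount_mol_g = numeric()))
    stopifnot(all(c("p_rel", "amount") %in% names(br)))
    if (any(br$p_rel <= 0 | br$p_rel >= 1))
      stop(name, " branch: relative pressures must lie strictly in (0, 1)")
    if (any(br$amount < 0)) stop(name, " branch: amounts must be >= 0")
    br <- br[order(br$p_rel), ]
    data.frame(p_rel = br$p_rel, amount_mol_g = br$amount * conv)
  }
  structure(list(adsorption = fix(adsorption, "adsorption"),
                 desorption = fix(desorption, "desorption"),
                 temperature_K = temperature_K,
                 cross_section_nm2 = cross_section_nm2,
                 units_in = units),
            class = "isotherm")
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf("isotherm: %d adsorption / %d desorption points, %g K\n",
              nrow(x$adsorption), nrow(x$desorption), x$temperature_K))
  invisible(x)
}

#' Read/write isotherm CSV
#'
#' Three-column CSV (`branch` in \{ads, des\}, `p_rel`, `amount`) with a
#' `# units: <unit>` header comment line.
#'
#' @param path CSV path.
#' @return For the reader, an [isotherm()].
#' @export
read_isotherm_csv <- function(path) {
  first <- readLines(path, n = 1L)
  units <- if (grepl("^#\\s*units:", first))
    trimws(sub("^#\\s*units:", "", first)) else "cm3stp_g"
  df <- read.csv(path, comment.char = "#")
  stopifnot(all(c("branch", "p_rel", "amount") %in% names(df)))
  isotherm(df[df$branch == "ads", c("p_rel", "amount")],
           df[df$branch == "des", c("p_rel", "amount")],
           units = units)
}

#' @rdname read_isotherm_csv
#' @param iso an [isotherm()].
#' @param units output unit for the `amount` column.
#' @export
write_isotherm_csv <- function(iso, path, units = "cm3stp_g") {
  conv <- switch(units, cm3stp_g = .GAS_STP_MOLAR_CM3, mmol_g = 1e3, mol_g = 1)
  rows <- rbind(
    if (nrow(iso$adsorption))
      data.frame(branch = "ads", p_rel = iso$adsorption$p_rel,
                 amount = iso$adsorption$amount_mol_g * conv),
    if (nrow(iso$desorption))
      data.frame(branch = "des", p_rel = iso$desorption$p_rel,
                 amount = iso$desorption$amount_mol_g * conv))
  con <- file(path, "w")
  writeLines(paste0("# units: ", units), con)
  write.csv(rows, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Synthetic BET isotherm with known surface area
#'
#' Forward-models adsorbed amounts from the two-parameter BET equation,
#' \deqn{n(p) = n_m C p / ((1 - p)(1 + (C - 1) p)),}
#' with the monolayer capacity \eqn{n_m} derived from the target specific
#' surface area via the 0.162 nm^2 molecular cross-section.  Optional
#' multiplicative Gaussian noise emulates measurement scatter.
#'
#' @param S_true_m2_per_g target specific surface area, m^2/g.
#' @param C_bet BET energy constant (> 1).
#' @param p_grid relative pressures strictly inside (0, 1).
#' @param seed integer seed for the noise.
#' @param noise_rel relative noise standard deviation (0 = noiseless).
#' @return An [isotherm()] with an adsorption branch only.
#' @export
generate_bet_isotherm <- function(S_true_m2_per_g, C_bet = 80,
                                  p_grid = seq(0.02, 0.30, by = 0.01),
                                  seed = 1L, noise_rel = 0) {
  if (S_true_m2_per_g <= 0) stop("S_true_m2_per_g must be positive")
  if (C_bet <= 1) stop("C_bet must exceed 1")
  if (any(p_grid <= 0 | p_grid >= 1))
    stop("p_grid must lie strictly in (0, 1)")
  if (noise_rel < 0) stop("noise_rel must be >= 0")
  n_m <- S_true_m2_per_g / (.N_AVOGADRO * .N2_CROSS_SECTION_NM2 * 1e-18)
  n <- n_m * C_bet * p_grid / ((1 - p_grid) * (1 + (C_bet - 1) * p_grid))
  if (noise_rel > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    n <- n * (1 + rnorm(length(n), sd = noise_rel))
    n <- pmax(n, 0)
  }
  isotherm(data.frame(p_rel = p_grid, amount = n), units = "mol_g")
}

#' BET specific surface area
#'
#' Linear fit of the BET transform \eqn{p / (n (1 - p))} against \eqn{p}
#' over the adsorption window `[p_lo, p_hi]` (the classical 0.05--0.2
#' range).  Monolayer capacity \eqn{n_m = 1 / (slope + intercept)}, energy
#' constant \eqn{C = slope/intercept + 1}; the specific surface area is
#' \eqn{n_m N_A \sigma} with \eqn{\sigma} the molecular cross-section.
#'
#' @param iso an [isotherm()] with an adsorption branch.
#' @param p_lo,p_hi relative-pressure fit window.
#' @return List: `S_m2_g`, `C`, `n_monolayer_mol_g`, `r_squared`,
#'   `n_points`.
#' @export
bet_surface_area <- function(iso, p_lo = 0.05, p_hi = 0.2) {
  stopifnot(inherits(iso, "isotherm"))
  a <- iso$adsorption
  a <- a[a$p_rel >= p_lo & a$p_rel <= p_hi & a$amount_mol_g > 0, ]
  if (nrow(a) < 3)
    stop("insufficient data: need >= 3 adsorption points in the BET window")
  y <- a$p_rel / (a$amount_mol_g * (1 - a$p_rel))
  fit <- lm(y ~ a$p_rel)
  ic <- coef(fit)[[1]]; sl <- coef(fit)[[2]]
  C <- sl / ic + 1
  if (!is.finite(C) || C <= 0 || sl + ic <= 0)
    stop(sprintf("invalid BET fit: C = %.3g (slope %.3g, intercept %.3g)",
                 C, sl, ic))
  n_m <- 1 / (sl + ic)
  r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  list(S_m2_g = n_m * .N_AVOGADRO * iso$cross_section_nm2 * 1e-18,
       C = C, n_monolayer_mol_g = n_m,
       r_squared = r2, n_points = nrow(a))
}

# Kelvin core radius (nm) at relative pressure p (desorption meniscus,
# cylindrical geometry)
kelvin_radius_nm <- function(p) .KELVIN_NM / log(1 / p)

# Harkins-Jura statistical film thickness (nm)
thickness_nm <- function(p, model = "harkins_jura") {
  switch(match.arg(model, "harkins_jura"),
         harkins_jura = 0.1 * sqrt(13.99 / (0.034 - log10(p))))
}

#' Forward-model a desorption isotherm from a pore-size distribution
#'
#' Cylindrical-pore forward model consistent with the BJH inversion: at
#' each relative pressure a pore of radius \eqn{r_p} is either full
#' (if \eqn{r_p \le r_K(p) + t(p)}) or emptied down to an adsorbed film of
#' thickness \eqn{t(p)}.  Total adsorbed liquid volume is converted to
#' mol/g.  The adsorption branch is modelled with delayed condensation
#' (condensation core radius twice the desorption one), producing the
#' familiar hysteresis loop of mesoporous slit/plate networks.
#'
#' @param psd data frame with `radius_nm`, `volume_cm3_g` (pore volume per
#'   gram in each radius class).
#' @param p_grid relative pressures.
#' @param thickness_model film thickness model.
#' @return An [isotherm()] with both branches.
#' @export
simulate_physisorption <- function(psd, p_grid = seq(0.30, 0.995, by = 0.005),
                                   thickness_model = "harkins_jura") {
  stopifnot(all(c("radius_nm", "volume_cm3_g") %in% names(psd)),
            all(psd$radius_nm > 0), all(psd$volume_cm3_g >= 0))
  branch_amount <- function(p, scale) {
    t <- thickness_nm(p, thickness_model)
    rc <- scale * kelvin_radius_nm(p) + t
    v <- vapply(seq_along(p), function(i) {
      full <- psd$radius_nm <= rc[i]
      film_frac <- 1 - ((pmax(psd$radius_nm - t[i], 0)) / psd$radius_nm)^2
      sum(psd$volume_cm3_g[full]) +
        sum(psd$volume_cm3_g[!full] * film_frac[!full])
    }, numeric(1))
    v / .N2_LIQUID_MOLAR_CM3
  }
  p <- sort(p_grid)
  isotherm(data.frame(p_rel = p, amount = branch_amount(p, 2)),
           data.frame(p_rel = p, amount = branch_amount(p, 1)),
           units = "mol_g")
}

#' BJH pore-size distribution from the desorption branch
#'
#' Classic Barrett-Joyner-Halenda descending-pressure recursion with
#' cylindrical pore geometry: at each pressure step the desorbed liquid
#' volume is split into the cores of pores emptying in that step (Kelvin
#' radius plus film thickness) and film thinning in pores already emptied;
#' core volumes are scaled to full pore volumes by the area ratio
#' \eqn{(r_p / (r_p - \bar t))^2}.  Cylindrical geometry is the analyzer
#' convention even for materials whose hysteresis indicates slit-like
#' pores, so distributions remain comparable with stock analyzer output.
#'
#' @param iso an [isotherm()] with a desorption branch of >= 5 points
#'   spanning the mesopore pressure range.
#' @param thickness_model film thickness model (`"harkins_jura"`).
#' @param branch only `"desorption"` is supported.
#' @param scheme radius bin scheme for the volume-percent distribution.
#' @return List: `psd` data frame (`radius_nm` step midpoints, `dV_cm3_g`
#'   incremental volumes, `r_hi_nm`/`r_lo_nm` step bounds, `p_hi`/`p_lo`
#'   pressures, `density_cm3_g_nm` = dV/dr), `total_volume_cm3_g`,
#'   `modal_radius_nm` (mode of the volume density), and `binned`
#'   (volume-percent `binned_distribution` over `scheme`).
#' @export
bjh_distribution <- function(iso, thickness_model = "harkins_jura",
                             branch = "desorption", scheme = "rpr_table1") {
  stopifnot(inherits(iso, "isotherm"))
  branch <- match.arg(branch, "desorption")
  des <- iso$desorption
  if (nrow(des) < 5)
    stop("desorption branch needs >= 5 points")
  des <- des[order(des$p_rel, decreasing = TRUE), ]
  if (any(diff(des$amount_mol_g) > 1e-12))
    stop("desorption branch must be non-increasing with decreasing pressure")
  p <- des$p_rel
  v_liq <- des$amount_mol_g * .N2_LIQUID_MOLAR_CM3   # cm^3 liquid / g
  t <- thickness_nm(p, thickness_model)
  rk <- kelvin_radius_nm(p)
  rp <- rk + t
  n <- length(p)
  out_r <- out_v <- out_phi <- out_plo <- out_rhi <- out_rlo <- numeric(0)
  emp_r <- emp_v <- numeric(0)      # already-emptied pores (pore radius, volume)
  for (i in seq_len(n - 1L)) {
    dV <- v_liq[i] - v_liq[i + 1L]
    if (dV <= 0) next
    t_bar <- (t[i] + t[i + 1L]) / 2
    rp_bar <- (rp[i] + rp[i + 1L]) / 2
    # film thinning in previously emptied pores (annulus volume decrease)
    dV_film <- if (length(emp_r))
      sum(emp_v * ((emp_r - t[i + 1L])^2 - (emp_r - t[i])^2) / emp_r^2)
      else 0
    core <- dV - dV_film
    if (core <= 0) next
    Vp <- core * (rp_bar / (rp_bar - t_bar))^2
    out_r <- c(out_r, rp_bar); out_v <- c(out_v, Vp)
    out_phi <- c(out_phi, p[i]); out_plo <- c(out_plo, p[i + 1L])
    out_rhi <- c(out_rhi, rp[i]); out_rlo <- c(out_rlo, rp[i + 1L])
    emp_r <- c(emp_r, rp_bar); emp_v <- c(emp_v, Vp)
  }
  if (!length(out_r)) {
    warning("bjh_distribution: empty mesopore range")
    return(list(psd = data.frame(radius_nm = numeric(), dV_cm3_g = numeric(),
                                 p_hi = numeric(), p_lo = numeric()),
                total_volume_cm3_g = 0, binned = NULL))
  }
  psd <- data.frame(radius_nm = out_r, dV_cm3_g = out_v,
                    r_hi_nm = out_rhi, r_lo_nm = out_rlo,
                    p_hi = out_phi, p_lo = out_plo)
  # volume density dV/dr makes the mode independent of the pressure grid
  psd$density_cm3_g_nm <- psd$dV_cm3_g / (psd$r_hi_nm - psd$r_lo_nm)
  edges <- bin_scheme(scheme)
  cls <- findInterval(psd$radius_nm, edges, left.open = TRUE)
  volcls <- vapply(seq_len(length(edges) - 1L),
                   function(k) sum(psd$dV_cm3_g[cls == k]), numeric(1))
  binned <- new_binned_distribution(edges, 100 * volcls / sum(volcls),
                                    nrow(psd))
  list(psd = psd, total_volume_cm3_g = sum(psd$dV_cm3_g),
       modal_radius_nm = psd$radius_nm[which.max(psd$density_cm3_g_nm)],
       binned = binned)
}

#' Detect adsorption-desorption hysteresis
#'
#' Compares the two branches over the loop window 0.4 < p/p0 < 0.95 (linear
#' interpolation of the desorption branch onto the adsorption pressures).
#' A relative gap beyond `tol` of the maximum uptake labels the isotherm
#' hysteretic, the signature of capillary condensation in mesopores
#' (type IV; slit-shaped pores give the H3 loop shape).
#'
#' @param iso an [isotherm()] with both branches.
#' @param tol relative gap threshold.
#' @return List: `hysteretic` logical, `max_rel_gap`.
#' @export
classify_isotherm <- function(iso, tol = 0.02) {
  stopifnot(inherits(iso, "isotherm"))
  a <- iso$adsorption; d <- iso$desorption
  if (nrow(a) < 2 || nrow(d) < 2) stop("both branches required")
  w <- a$p_rel > 0.4 & a$p_rel < 0.95
  if (!any(w)) stop("no points in the hysteresis window")
  des_i <- stats::approx(d$p_rel, d$amount_mol_g, xout = a$p_rel[w],
                         rule = 2)$y
  gap <- max(abs(des_i - a$amount_mol_g[w]))
  ref <- max(c(a$amount_mol_g, d$amount_mol_g))
  list(hysteretic = gap > tol * ref, max_rel_gap = gap / ref)
}
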