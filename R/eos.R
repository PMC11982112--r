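# Freshwater equation of state and related thermodynamic quantities.
#
# Limnological-range formulation of the Chen-Millero type: a pure-water
# density polynomial in temperature, a linear "volumetric salinity"
# correction (lake waters are far too dilute for the full seawater
# haline terms to matter), and a secant-bulk-modulus pressure correction.
# The polynomial places the density maximum of fresh water at ~3.98 C,
# the anchor for the whole inverse-stratification analysis.

# Pure-water density polynomial coefficients, kg m^-3 per degC^k, k = 0..6.
.rho_w_coef <- c(
  999.8395, 6.7914e-2, -9.0894e-3, 1.0171e-4,
  -1.2846e-6, 1.1592e-8, -5.0125e-11
)

# Haline density slope A(T): rho = rho_w + A(T) * S, S in g L^-1.
.haline_coef <- c(8.221e-1, -3.87e-3, 4.99e-5)

# Secant bulk modulus K(T, S, p) in bar (pressure argument in bar).
.bulk_t_coef <- c(19652.17, 148.113, -2.293, 1.256e-2, -4.18e-5)
.bulk_p_coef <- c(3.2726, -2.147e-4, 1.128e-4)
.bulk_s_coef <- c(53.238, -0.313)

# Pure-water specific heat polynomial, J kg^-1 degC^-1.
.cp_coef <- c(4217.4, -3.720283, 0.1412855, -2.654387e-3, 2.093236e-5)

.polyval <- function(coef, x) {
  out <- 0
  for (k in rev(seq_along(coef))) out <- out * x + coef[[k]]
  out
}

.check_tsp <- function(temp_c, salinity_g_l, pressure_dbar) {
  if (any(!is.finite(temp_c)) || any(temp_c < 0 | temp_c > 30)) {
    abort("`temp_c` must be finite and within [0, 30] degC.")
  }
  if (any(salinity_g_l < 0) || any(salinity_g_l > 5)) {
    abort("`salinity_g_l` must be within [0, 5] g/L (limnological range).")
  }
  if (any(pressure_dbar < 0)) {
    abort("`pressure_dbar` must be non-negative.")
  }
}

#' Freshwater density
#'
#' Density of lake water from temperature, volumetric salinity and
#' pressure, using a limnological-range polynomial equation of state.
#' At zero salinity and surface pressure the curve has its single
#' interior maximum near 4.0 degC, the property that makes cold winter
#' water columns inversely stratified yet stable.
#'
#' @param temp_c Temperature, degC, in `[0, 30]`.
#' @param salinity_g_l Volumetric salinity, g per litre (see
#'   [volumetric_salinity()]); small for fresh waters.
#' @param pressure_dbar Pressure, decibar (approximately depth in metres).
#' @return Density in kg per cubic metre, vectorised over the inputs.
#' @examples
#' water_density(4, 0, 0) > water_density(0, 0, 0)
#' @export
water_density <- function(temp_c, salinity_g_l = 0, pressure_dbar = 0) {
  .check_tsp(temp_c, salinity_g_l, pressure_dbar)
  rho0 <- .polyval(.rho_w_coef, temp_c) +
    .polyval(.haline_coef, temp_c) * salinity_g_l
  p_bar <- pressure_dbar / 10
  k <- .polyval(.bulk_t_coef, temp_c) +
    (.bulk_p_coef[1] + .bulk_p_coef[2] * temp_c +
       .bulk_p_coef[3] * temp_c^2) * p_bar +
    (.bulk_s_coef[1] + .bulk_s_coef[2] * temp_c) * salinity_g_l
  rho0 / (1 - p_bar / k)
}

#' Thermal expansibility
#'
#' alpha = -(1/rho) d(rho)/dT, by central finite difference of
#' [water_density()] with a 0.01 degC step. Negative below the
#' density-maximum temperature (~4 degC), zero at it, positive above;
#' the sign decides whether solar heating lightens or densifies water,
#' i.e. whether it can drive convection under ice.
#'
#' @inheritParams water_density
#' @param step Finite-difference half-step in degC.
#' @return alpha in per degC.
#' @export
thermal_expansibility <- function(temp_c, salinity_g_l = 0,
                                  pressure_dbar = 0, step = 0.01) {
  .check_tsp(temp_c, salinity_g_l, pressure_dbar)
  t_hi <- pmin(temp_c + step, 30)
  t_lo <- pmax(temp_c - step, 0)
  rho <- water_density(temp_c, salinity_g_l, pressure_dbar)
  drho <- (water_density(t_hi, salinity_g_l, pressure_dbar) -
             water_density(t_lo, salinity_g_l, pressure_dbar)) / (t_hi - t_lo)
  -drho / rho
}

#' Specific heat capacity of lake water
#'
#' Pure-water polynomial with a first-order salinity correction; about
#' 4.2e3 J kg^-1 degC^-1 for cold fresh water.
#'
#' @inheritParams water_density
#' @return c_p in J per kg per degC.
#' @export
specific_heat <- function(temp_c, salinity_g_l = 0) {
  .check_tsp(temp_c, salinity_g_l, 0)
  .polyval(.cp_coef, temp_c) +
    (-7.6444 + 0.107276 * temp_c - 1.3839e-3 * temp_c^2) * salinity_g_l
}

#' Temperature of maximum density
#'
#' Scans [water_density()] over a temperature range at fixed salinity and
#' pressure and returns the argmax temperature.
#'
#' @inheritParams water_density
#' @param t_range Temperature scan range, degC.
#' @param t_step Scan step, degC.
#' @return Temperature of maximum density in degC (not rounded).
#' @examples
#' round(density_maximum_temperature(), 1) # ~4.0
#' @export
density_maximum_temperature <- function(salinity_g_l = 0, pressure_dbar = 0,
                                        t_range = c(0, 8), t_step = 0.01) {
  tt <- seq(t_range[1], t_range[2], by = t_step)
  tt[which.max(water_density(tt, salinity_g_l, pressure_dbar))]
}

#' Carbonate system speciation
#'
#' Two-pK equilibrium partition of dissolved inorganic carbon into
#' dissolved CO2, bicarbonate and carbonate as a function of pH
#' (freshwater constants at 25 degC).
#'
#' @param ph pH value(s).
#' @param pk1,pk2 Carbonic acid dissociation constants (as pK).
#' @return Tibble with columns `co2`, `hco3`, `co3`; rows sum to 1.
#' @export
carbonate_fractions <- function(ph, pk1 = 6.35, pk2 = 10.33) {
  h <- 10^(-ph)
  k1 <- 10^(-pk1)
  k2 <- 10^(-pk2)
  denom <- h^2 + k1 * h + k1 * k2
  tibble(co2 = h^2 / denom, hco3 = k1 * h / denom, co3 = k1 * k2 / denom)
}
.carbonate_fractions <- carbonate_fractions

#' Default water chemistry for a soft-water temperate lake
#'
#' Major-ion concentrations (mg/L), pH and a single dissolved inorganic
#' carbon value (mol/L) of the kind measured by low-frequency limnological
#' sampling programs; inputs to [volumetric_salinity()].
#'
#' @return A one-row tibble with columns `ca`, `mg`, `na`, `k`, `cl`,
#'   `so4`, `nh4`, `no3` (mg/L), `ph`, and `dic_mol_l`.
#' @export
default_chemistry <- function() {
  tibble(
    ca = 5.0, mg = 1.5, na = 2.0, k = 0.6,
    cl = 2.0, so4 = 4.0, nh4 = 0.02, no3 = 0.2,
    ph = 7.2, dic_mol_l = 2.5e-4
  )
}

#' Volumetric salinity from lake chemistry
#'
#' Sums the mass concentrations of the eight major ions, the carbonate
#' system species (dissolved CO2, bicarbonate and carbonate, partitioned
#' from total DIC by pH with a two-pK equilibrium) and the H+/OH- ions
#' implied by pH, to give a lake-specific volumetric salinity in g/L for
#' the equation of state.
#'
#' @param chemistry A one-row data frame as returned by
#'   [default_chemistry()]: ion columns in mg/L plus `ph` and `dic_mol_l`.
#' @param ph Optional pH overriding the chemistry table's value.
#' @param dic_mol_l Optional DIC (mol/L) overriding the table's value.
#' @return Salinity in g/L (single number).
#' @examples
#' volumetric_salinity(default_chemistry())
#' @export
volumetric_salinity <- function(chemistry = default_chemistry(),
                                ph = NULL, dic_mol_l = NULL) {
  chemistry <- as_tibble(chemistry)
  ions <- c("ca", "mg", "na", "k", "cl", "so4", "nh4", "no3")
  missing_cols <- setdiff(ions, names(chemistry))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`chemistry` lacks ion column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  conc <- unlist(chemistry[1, ions])
  if (any(conc < 0)) abort("Ion concentrations must be non-negative.")
  ph <- ph %||% chemistry$ph[1]
  dic_mol_l <- dic_mol_l %||% chemistry$dic_mol_l[1]
  if (!is.finite(ph) || ph < 4 || ph > 11) {
    abort("`ph` must be within [4, 11].")
  }
  if (dic_mol_l < 0) abort("`dic_mol_l` must be non-negative.")

  ion_g_l <- sum(conc) / 1000

  fr <- .carbonate_fractions(ph)
  # molar masses: CO2 44.01, HCO3- 61.02, CO3^2- 60.01 g/mol
  carb_g_l <- dic_mol_l *
    (fr$co2 * 44.01 + fr$hco3 * 61.02 + fr$co3 * 60.01)

  h_g_l <- 10^(-ph) * 1.008
  oh_g_l <- 10^(-(14 - ph)) * 17.008

  ion_g_l + carb_g_l + h_g_l + oh_g_l
}
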