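R_GAS <- 8.314       # J mol^-1 K^-1

# moles of trace gas corresponding to `ppmv` in a headspace of `volume_l`
# litres at `pressure_pa` and `temperature_k` (ideal gas; litres -> m^3)
ppmv_to_mol <- function(ppmv, volume_l, temperature_k, pressure_pa) {
  ppmv * 1e-6 * pressure_pa * (volume_l * 1e-3) / (R_GAS * temperature_k)
}

#' Headspace volume of a soil microcosm
#'
#' Nominal bottle volume minus the volume displaced by the soil, computed
#' from a bulk density. Defaults describe a 500 ml bottle holding 20 g of
#' soil at 1.0 g cm^-3.
#'
#' @param bottle_volume_l Nominal bottle volume (litres).
#' @param dry_mass_g Soil dry mass (g).
#' @param bulk_density_g_cm3 Soil bulk density (g cm^-3).
#' @return Headspace volume in litres.
#' @export
headspace_volume <- function(bottle_volume_l = 0.5, dry_mass_g = 20,
                             bulk_density_g_cm3 = 1.0) {
  bottle_volume_l - dry_mass_g / bulk_density_g_cm3 / 1000
}

#' Fit a first-order trace-gas uptake rate from a headspace time series
#'
#' The mixing-ratio decay towards the compensation point `floor` is
#' log-linearized and fitted by ordinary least squares:
#' k = -slope of ln(chi(t) - floor) on t. The soil uptake rate references
#' the initial molar quantity: rate = k * n0 / dry_mass, with
#' n0 = (chi(0) - floor) converted to moles by the ideal-gas law, reported
#' in nmol g_dw^-1 h^-1 as a positive magnitude.
#'
#' @param data Data frame with columns `time_h` (strictly increasing hours)
#'   and `ppmv` (mixing ratio); >= 5 points, all above `floor`.
#' @param dry_mass_g Soil dry mass (g dry weight).
#' @param volume_l Headspace volume (litres); see [headspace_volume()].
#' @param temperature_k Incubation temperature (K); default 25 degrees C.
#' @param pressure_pa Headspace pressure (Pa).
#' @param floor Compensation point (ppmv).
#' @param rate_reference `"initial"` (default): rate = k n0 / m, the
#'   instantaneous rate at t = 0; `"interval_mean"`: net quantity consumed
#'   over the fitted interval divided by its duration, (n0 - n_end) / dt / m.
#'   The assay description does not determine which convention was meant,
#'   so both are exposed.
#' @return One-row tibble: `mode`, `k_or_slope` (h^-1), `rate`
#'   (nmol g^-1 h^-1), `fit_r2`, `n_points`.
#' @export
#' @examples
#' ts <- generate_gas_timeseries(0.5, c0 = 2.5, times = seq(0, 1, 0.25))
#' fit_first_order_uptake(ts)$k_or_slope  # 0.5
fit_first_order_uptake <- function(data, dry_mass_g = 20,
                                   volume_l = headspace_volume(),
                                   temperature_k = 298.15,
                                   pressure_pa = 101325,
                                   floor = 0,
                                   rate_reference = c("initial",
                                                      "interval_mean")) {
  rate_reference <- match.arg(rate_reference)
  check_series(data)
  if (nrow(data) < 5) {
    abort("first-order uptake fits need at least 5 points.",
          class = "mfsoil_gas")
  }
  if (any(data$ppmv <= floor)) {
    abort("all mixing ratios must exceed `floor` (log is undefined).",
          class = "mfsoil_gas")
  }
  y <- log(data$ppmv - floor)
  f <- ols_slope(data$time_h, y)
  k <- -f$slope
  n0 <- ppmv_to_mol(data$ppmv[1] - floor, volume_l, temperature_k, pressure_pa)
  rate <- if (rate_reference == "initial") {
    k * n0 / dry_mass_g
  } else {
    dt <- diff(range(data$time_h))
    n0 * (1 - exp(-k * dt)) / dt / dry_mass_g
  }
  tibble(mode = "uptake",
         k_or_slope = k,
         rate = rate * 1e9,
         fit_r2 = f$r2,
         n_points = nrow(data))
}

#' Fit a linear gas production rate (CO2 mode)
#'
#' Ordinary least squares of mixing ratio on time over the incubation
#' (typically 4 points spanning 72 h); the slope in ppmv h^-1 is converted
#' to umol g_dw^-1 h^-1 by the ideal-gas law.
#'
#' @inheritParams fit_first_order_uptake
#' @return One-row tibble as [fit_first_order_uptake()], `rate` in
#'   umol g^-1 h^-1.
#' @export
fit_linear_production <- function(data, dry_mass_g = 20,
                                  volume_l = headspace_volume(),
                                  temperature_k = 298.15,
                                  pressure_pa = 101325) {
  check_series(data)
  if (nrow(data) < 4) {
    abort("linear production fits need at least 4 points.",
          class = "mfsoil_gas")
  }
  f <- ols_slope(data$time_h, data$ppmv)
  mol_per_h <- ppmv_to_mol(f$slope, volume_l, temperature_k, pressure_pa)
  tibble(mode = "production",
         k_or_slope = f$slope,
         rate = abs(mol_per_h) * 1e6 / dry_mass_g,
         fit_r2 = f$r2,
         n_points = nrow(data))
}

check_series <- function(data) {
  if (!all(c("time_h", "ppmv") %in% names(data))) {
    abort("series needs `time_h` and `ppmv` columns.", class = "mfsoil_gas")
  }
  if (any(diff(data$time_h) <= 0)) {
    abort("`time_h` must be strictly increasing.", class = "mfsoil_gas")
  }
  if (any(data$ppmv < 0)) {
    abort("mixing ratios must be >= 0.", class = "mfsoil_gas")
  }
  invisible(data)
}

ols_slope <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  slope <- sum(xc * yc) / sum(xc^2)
  ss_res <- sum((yc - slope * xc)^2)
  ss_tot <- sum(yc^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = slope, r2 = r2)
}

#' Fit fluxes for a tidy table of gas time series
#'
#' Splits a long table by sample and gas, fitting first-order uptake for H2
#' and CO and linear production for CO2.
#'
#' @param data Long tibble with columns `sample_id`, `gas` (`H2`/`CO`/`CO2`),
#'   `time_h`, `ppmv`.
#' @inheritParams fit_first_order_uptake
#' @return Tibble with one row per (sample, gas): `sample_id`, `gas`, plus
#'   the columns of [fit_first_order_uptake()].
#' @export
fit_gas_fluxes <- function(data, dry_mass_g = 20,
                           volume_l = headspace_volume(),
                           temperature_k = 298.15, pressure_pa = 101325,
                           floor = 0) {
  stopifnot(all(c("sample_id", "gas", "time_h", "ppmv") %in% names(data)))
  data |>
    group_by(.data$sample_id, .data$gas) |>
    dplyr::group_modify(function(d, key) {
      d <- arrange(d, .data$time_h)
      if (key$gas == "CO2") {
        fit_linear_production(d, dry_mass_g, volume_l, temperature_k,
                              pressure_pa)
      } else {
        fit_first_order_uptake(d, dry_mass_g, volume_l, temperature_k,
                               pressure_pa, floor)
      }
    }) |>
    ungroup()
}

#' Coefficient of variation, in percent
#'
#' 100 * sample SD (n - 1 denominator) / mean. Reported as a raw percentage;
#' round only at display time.
#'
#' @param values Numeric vector (>= 2 values, mean != 0).
#' @return CV in percent.
#' @export
#' @examples
#' cv_percent(c(1, 2, 3))  # 50
cv_percent <- function(values) {
  if (length(values) < 2) {
    abort("CV needs at least two values.", class = "mfsoil_cv")
  }
  m <- mean(values)
  if (m == 0) abort("CV undefined: mean is zero.", class = "mfsoil_cv")
  100 * sd(values) / m
}
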