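#' Simulate a headspace gas mole-fraction time series
#'
#' Uptake mode follows first-order decay towards a compensation point:
#' chi(t) = floor + (c0 - floor) exp(-k t) + N(0, noise_sd). Production mode
#' is linear: chi(t) = c0 + slope t + N(0, noise_sd). Typical microcosm
#' assays measure H2/CO uptake with >= 5 points within ~1 h after headspace
#' amendment to 2.5-3 ppmv, and CO2 production with 4 points over 72 h.
#'
#' @param true_k First-order rate constant (per hour, >= 0); uptake mode.
#' @param c0 Initial mixing ratio (ppmv), must exceed `c_floor`.
#' @param c_floor Compensation point (ppmv, >= 0).
#' @param times Strictly increasing sampling times (hours).
#' @param noise_sd Gaussian measurement noise SD (ppmv).
#' @param seed Integer seed.
#' @param mode `"uptake"` (exponential decay) or `"production"` (linear).
#' @param slope Production slope (ppmv per hour); production mode only.
#' @return A tibble with `time_h` and `ppmv`.
#' @export
#' @examples
#' ts <- generate_gas_timeseries(0.5, c0 = 2.5, times = seq(0, 1, 0.25))
#' ts$ppmv[5] / 2.5  # exp(-0.5)
generate_gas_timeseries <- function(true_k = 0.5, c0 = 2.5, c_floor = 0,
                                    times = seq(0, 1, length.out = 5),
                                    noise_sd = 0, seed = 1L,
                                    mode = c("uptake", "production"),
                                    slope = 0) {
  mode <- match.arg(mode)
  if (any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing.", class = "mfsoil_gas")
  }
  if (mode == "uptake") {
    if (true_k < 0) abort("`true_k` must be >= 0.", class = "mfsoil_gas")
    if (!(c0 > c_floor && c_floor >= 0)) {
      abort("need c0 > c_floor >= 0.", class = "mfsoil_gas")
    }
    mu <- c_floor + (c0 - c_floor) * exp(-true_k * times)
  } else {
    mu <- c0 + slope * times
  }
  eps <- if (noise_sd > 0) with_seed(seed, rnorm(length(times), 0, noise_sd))
         else rep(0, length(times))
  tibble(time_h = as.numeric(times), ppmv = mu + eps)
}
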