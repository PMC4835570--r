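#' Soil variable set used for multifunctional classification
#'
#' Ten descriptors: total carbon and nitrogen (%), pH, texture fractions
#' (sand/silt/clay, %), potential H2 and CO uptake (nmol g_dw^-1 h^-1),
#' potential CO2 production (umol g_dw^-1 h^-1) and bacterial 16S rRNA gene
#' abundance (copies g_dw^-1).
#'
#' @return Character vector of variable names.
#' @export
soil_variables <- function() {
  c("C", "N", "pH", "sand", "silt", "clay", "H2", "CO", "CO2", "bacteria")
}

#' Default treatment-level distribution parameters
#'
#' Means and standard deviations of each soil variable under each treatment.
#' These defaults describe a boreal loamy-sand larch-plantation setting and
#' are generator seeds, not fitted parameters: acidic soil (pH 4.3-4.7),
#' C 3-5.4%, N 0.13-0.27%, net H2/CO uptake of a few nmol g^-1 h^-1, CO2
#' production around 1-4 umol g^-1 h^-1, and 1.5-7.9 x 10^9 16S rRNA gene
#' copies g^-1, with the unlogged reference showing the tightest spread.
#'
#' @return A tibble with columns `treatment`, `variable`, `mean`, `sd`.
#' @export
#' @examples
#' default_treatment_params() |> dplyr::filter(variable == "CO2")
default_treatment_params <- function() {
  tr <- c("unlogged", "simple", "double", "inversion", "mound")
  mk <- function(variable, means, sds) {
    tibble(treatment = tr, variable = variable, mean = means, sd = sds)
  }
  bind_rows(
    mk("C",        c(4.9, 5.4, 4.1, 3.0, 4.3),  c(1.1, 1.3, 1.2, 1.4, 0.8)),
    mk("sand",     c(83, 86, 84, 76, 85),       c(3, 3, 2, 2, 8)),
    mk("silt",     c(13, 13, 14, 22, 14),       c(3, 3, 2, 2, 8)),
    mk("clay",     c(4, 1, 2, 2, 1),            c(1, 1, 0, 0, 1)),
    mk("N",        c(0.22, 0.27, 0.21, 0.13, 0.17), c(0.04, 0.06, 0.06, 0.04, 0.03)),
    mk("pH",       c(4.3, 4.6, 4.7, 4.7, 4.6),  c(0.1, 0.2, 0.2, 0.2, 0.2)),
    mk("H2",       c(6.3, 5.8, 5.2, 3.0, 6.6),  c(0.4, 1.6, 1.4, 2.3, 4.1)),
    mk("CO",       c(4.5, 4.5, 3.8, 2.1, 4.8),  c(0.6, 2.0, 1.7, 1.4, 1.8)),
    mk("CO2",      c(4.1, 3.1, 1.5, 1.4, 1.1),  c(1.3, 1.4, 0.5, 0.2, 2.3)),
    mk("bacteria", c(7.9, 4.9, 2.0, 1.5, 1.8) * 1e9,
                   c(1.3, 3.6, 2.6, 1.4, 2.1) * 1e9)
  )
}

#' Uniform (no-treatment-effect) parameters
#'
#' Every treatment shares the reference treatment's mean and SD; useful for
#' null-calibration simulations where the data must be homogeneous.
#'
#' @param params A parameter tibble as from [default_treatment_params()].
#' @param reference_treatment Treatment whose row is propagated to all others.
#' @return A parameter tibble of the same shape.
#' @export
uniform_treatment_params <- function(params = default_treatment_params(),
                                     reference_treatment = "unlogged") {
  ref <- params |>
    filter(.data$treatment == reference_treatment) |>
    select("variable", "mean", "sd")
  params |>
    distinct(.data$treatment) |>
    tidyr::expand_grid(ref) |>
    select("treatment", "variable", "mean", "sd")
}

# physically valid ranges used for truncated sampling
variable_bounds <- function(variable) {
  pct <- c(0, 100)
  switch(variable,
         C = pct, N = pct, sand = pct, silt = pct, clay = pct,
         pH = c(0, 14),
         c(0, Inf))
}

#' Multifunctional class assignment of the default composites
#'
#' A four-class layout over the fifteen default composites: a singleton class
#' (I), a pair (II), the three reference composites (III) and the remaining
#' nine (IV). Used to plant recoverable class structure in synthetic data.
#'
#' @return A tibble with columns `composite_id`, `class`.
#' @export
default_class_assignment <- function() {
  tibble(
    composite_id = c("M-B",
                     "S-A", "S-B",
                     "N-A", "N-B", "N-C",
                     "S-C", "I-A", "I-B", "I-C", "M-A", "M-C",
                     "D-A", "D-B", "D-C"),
    class = rep(c("I", "II", "III", "IV"), times = c(1, 2, 3, 9))
  )
}

#' Default planted class effects
#'
#' Mean offsets, in units of each variable's pooled (across-treatment mean)
#' SD, applied to replicate draws of composites assigned to a class. The
#' reference class III carries no offset. Deviations span most of the
#' multifunctional profile, as a whole-profile disturbance would: class II
#' deviates slightly (+/- 2 SD on six descriptors), class IV strongly
#' (+/- 3 SD on eight), and the singleton class I most intensely (+/- 4 SD,
#' with the highest H2 and CO uptake). Every class pair is separated by
#' well over 3 pooled SDs in Euclidean norm, across several descriptors, so
#' profile-based tests can resolve the planted partition.
#'
#' @return A tibble with columns `class`, `variable`, `shift_sd`.
#' @export
default_class_effects <- function() {
  eff <- function(class, ...) {
    v <- c(...)
    tibble(class = class, variable = names(v), shift_sd = unname(v))
  }
  bind_rows(
    eff("I",  H2 = 4, CO = 4, C = -4, N = -4, CO2 = -4, bacteria = -4,
        pH = 4, sand = -3),
    eff("II", C = 2, N = 2, pH = 2, CO2 = -2, H2 = -2, bacteria = -2),
    eff("IV", C = -3, N = -3, pH = 3, CO2 = -3, H2 = -3, CO = -3,
        bacteria = -3, silt = 2)
  )
}
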