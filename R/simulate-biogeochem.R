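# truncated-normal draws by inverse-CDF inversion: exact for any truncation,
# including means far outside the bounds where rejection would not terminate.
# sd = 0 collapses to the (clamped) mean.
rtruncnorm_icdf <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    return(pmin(pmax(rep(mean, n), lower), upper))
  }
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  x <- stats::qnorm(runif(n, pl, pu), mean, sd)
  # degenerate tails (pl == pu to machine precision) collapse to the nearest bound
  x[!is.finite(x)] <- if (mean < lower) lower else upper
  pmin(pmax(x, lower), upper)
}

#' Simulate a composite-level biogeochemical table
#'
#' Replicate-level values are drawn from treatment-specific normal
#' distributions truncated to physically valid ranges (percentages in
#' \[0, 100\], pH in \[0, 14\], rates and abundances >= 0); each composite is
#' the arithmetic mean of its replicates, the numerical analogue of physical
#' soil pooling. Optional class effects shift the replicate-level mean of
#' selected variables for composites assigned to a class, planting a
#' recoverable multifunctional structure.
#'
#' @param design A [study_design()].
#' @param params Treatment parameter tibble (`treatment`, `variable`, `mean`,
#'   `sd`); see [default_treatment_params()].
#' @param seed Integer seed; fixed seed gives a bit-identical table.
#' @param class_assignment Optional tibble (`composite_id`, `class`).
#' @param class_effects Optional tibble (`class`, `variable`, `shift_sd`)
#'   of mean offsets in pooled-SD units; requires `class_assignment`.
#' @param drop_bacteria_composite Optional composite id whose bacterial
#'   abundance is replaced by `bacteria_floor`, emulating a failed DNA
#'   extraction where only an assay detection limit is available.
#' @param bacteria_floor Value substituted for the dropped composite.
#' @return A tibble with `composite_id`, `treatment`, `block`,
#'   `is_reference`, optional `class`, and one column per variable. The
#'   replicate-level draws are attached as `attr(, "replicates")`.
#' @export
#' @examples
#' bg <- generate_biogeochem(seed = 42)
#' dim(bg)
generate_biogeochem <- function(design = study_design(),
                                params = default_treatment_params(),
                                seed = 1L,
                                class_assignment = NULL,
                                class_effects = NULL,
                                drop_bacteria_composite = NULL,
                                bacteria_floor = 1e6) {
  stopifnot(inherits(design, "study_design"))
  vars <- unique(params$variable)
  missing <- setdiff(
    paste(rep(design$treatments, each = length(vars)), vars, sep = "."),
    paste(params$treatment, params$variable, sep = ".")
  )
  if (length(missing) > 0) {
    abort(paste0("missing (treatment, variable) parameters: ",
                 paste(missing, collapse = ", ")),
          class = "mfsoil_config")
  }
  if (any(params$sd < 0)) abort("sd must be >= 0.", class = "mfsoil_config")

  meta <- generate_design(design, seed)
  composites <- meta |> distinct(.data$composite_id, .data$treatment,
                                 .data$block, .data$is_reference)

  pooled_sd <- params |>
    group_by(.data$variable) |>
    summarise(pooled_sd = mean(.data$sd), .groups = "drop")

  shift_for <- function(comp, variable) {
    if (is.null(class_assignment) || is.null(class_effects)) return(0)
    cls <- class_assignment$class[match(comp, class_assignment$composite_id)]
    if (is.na(cls)) return(0)
    hit <- class_effects$class == cls & class_effects$variable == variable
    if (!any(hit)) return(0)
    sum(class_effects$shift_sd[hit]) *
      pooled_sd$pooled_sd[pooled_sd$variable == variable]
  }

  nrep <- design$n_replicates_per_plot
  reps <- with_seed(seed, {
    purrr::pmap(composites, function(composite_id, treatment, block,
                                     is_reference) {
      vals <- purrr::map(vars, function(v) {
        row <- params[params$treatment == treatment & params$variable == v, ]
        b <- variable_bounds(v)
        mu <- row$mean[1] + shift_for(composite_id, v)
        rtruncnorm_icdf(nrep, mu, row$sd[1], b[1], b[2])
      })
      tibble(composite_id = composite_id, treatment = treatment,
             block = block, is_reference = is_reference,
             replicate = seq_len(nrep),
             !!!setNames(vals, vars))
    }) |> bind_rows()
  })

  out <- reps |>
    group_by(.data$composite_id, .data$treatment, .data$block,
             .data$is_reference) |>
    summarise(across(dplyr::all_of(vars), mean), .groups = "drop") |>
    arrange(match(.data$composite_id, composites$composite_id))

  if (!is.null(class_assignment)) {
    out <- out |> left_join(class_assignment, by = "composite_id") |>
      select("composite_id", "treatment", "block", "is_reference", "class",
             dplyr::all_of(vars))
  }
  if (!is.null(drop_bacteria_composite)) {
    if (!"bacteria" %in% vars) {
      abort("no `bacteria` variable to impute.", class = "mfsoil_config")
    }
    out$bacteria[out$composite_id %in% drop_bacteria_composite] <- bacteria_floor
  }
  attr(out, "replicates") <- reps
  out
}
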