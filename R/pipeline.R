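# invert the flux unit conversions so simulated gas series reproduce a
# target table-level rate when refitted
uptake_rate_to_k <- function(rate_nmol, dry_mass_g = 20,
                             volume_l = headspace_volume(),
                             temperature_k = 298.15, pressure_pa = 101325,
                             c0 = 2.75, floor = 0) {
  n0 <- ppmv_to_mol(c0 - floor, volume_l, temperature_k, pressure_pa)
  rate_nmol * dry_mass_g / (n0 * 1e9)
}

production_rate_to_slope <- function(rate_umol, dry_mass_g = 20,
                                     volume_l = headspace_volume(),
                                     temperature_k = 298.15,
                                     pressure_pa = 101325) {
  rate_umol * dry_mass_g /
    (ppmv_to_mol(1, volume_l, temperature_k, pressure_pa) * 1e6)
}

#' Simulate a complete study: metadata, biogeochemistry, gas series, OTUs
#'
#' One call produces every input of the analysis pipeline with known ground
#' truth: the replicate/composite design, a composite-level biogeochemical
#' table with planted class structure, per-composite H2/CO uptake and CO2
#' production headspace series whose true rates equal the table's values,
#' and an OTU table with planted rare-biosphere indicators. A single seed
#' expands deterministically into per-stage child seeds.
#'
#' @param seed Integer master seed.
#' @param design A [study_design()].
#' @param params Treatment parameters. The default is
#'   [uniform_treatment_params()]: when a class partition is planted it must
#'   be the only multivariate structure, so treatment-level mean differences
#'   (which univariate tests cannot resolve but profile tests can) are
#'   suppressed; pass [default_treatment_params()] for treatment-structured
#'   nulls instead.
#' @param class_assignment,class_effects Planted class structure (set both
#'   `NULL` for a structureless null study).
#' @param community A [planted_community()].
#' @param gas_noise_sd Measurement noise (ppmv) of the uptake series; the
#'   CO2 series gets 10x this (its signal is three orders larger).
#' @return List with `metadata`, `biogeochem`, `gas`, `otu`, `truth`.
#' @export
simulate_study <- function(seed = 1L,
                           design = study_design(),
                           params = uniform_treatment_params(),
                           class_assignment = default_class_assignment(),
                           class_effects = default_class_effects(),
                           community = planted_community(),
                           gas_noise_sd = 0.005) {
  seeds <- child_seeds(seed, 4)
  metadata <- generate_design(design, seeds[1])
  biogeochem <- generate_biogeochem(design, params, seeds[2],
                                    class_assignment = class_assignment,
                                    class_effects = class_effects)
  gas_seeds <- child_seeds(seeds[3], nrow(biogeochem) * 3)
  gas <- purrr::map(seq_len(nrow(biogeochem)), function(i) {
    cid <- biogeochem$composite_id[i]
    bind_rows(
      generate_gas_timeseries(
        uptake_rate_to_k(biogeochem$H2[i]), c0 = 2.75,
        times = seq(0, 1, 0.25), noise_sd = gas_noise_sd,
        seed = gas_seeds[3 * i - 2]) |>
        mutate(sample_id = cid, gas = "H2"),
      generate_gas_timeseries(
        uptake_rate_to_k(biogeochem$CO[i]), c0 = 2.75,
        times = seq(0, 1, 0.25), noise_sd = gas_noise_sd,
        seed = gas_seeds[3 * i - 1]) |>
        mutate(sample_id = cid, gas = "CO"),
      generate_gas_timeseries(
        0, c0 = 400, times = seq(0, 72, 24), noise_sd = 10 * gas_noise_sd,
        seed = gas_seeds[3 * i], mode = "production",
        slope = production_rate_to_slope(biogeochem$CO2[i])) |>
        mutate(sample_id = cid, gas = "CO2")
    )
  }) |> bind_rows() |>
    select("sample_id", "gas", "time_h", "ppmv")
  otu <- if (!is.null(class_assignment)) {
    generate_otu_table(design, community, class_assignment, seeds[4])
  } else NULL
  list(metadata = metadata, biogeochem = biogeochem, gas = gas, otu = otu,
       truth = list(class_assignment = class_assignment,
                    class_effects = class_effects,
                    indicators = if (!is.null(otu)) attr(otu, "truth")))
}

#' Assemble the pipeline configuration
#'
#' Defaults follow the study conventions: SIMPROF and IndVal at 999
#' permutations, RDA at 1000, alpha 0.05, rarefaction to the smallest
#' library, rare-OTU filter at 0.005% of per-library reads,
#' group-equalized IndVal.
#'
#' @param outdir Output directory.
#' @param seed Master seed.
#' @param simprof_n_perm,rda_n_perm,indval_n_perm Permutation counts.
#' @param alpha Significance level shared by all tests.
#' @param rarefaction_depth `"min"` or an integer depth.
#' @param filter_fraction Rare-OTU filter fraction.
#' @param indval_mode `"group_equalized"` or `"classic"`.
#' @param variables Classification variable set.
#' @param inputs Optional named list of input paths (`metadata`,
#'   `biogeochem`, `gas`, `otu`); when absent the pipeline simulates them.
#' @param classify_only Skip the community stages (no OTU input needed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            simprof_n_perm = 999, rda_n_perm = 1000,
                            indval_n_perm = 999, alpha = 0.05,
                            rarefaction_depth = "min",
                            filter_fraction = 5e-5,
                            indval_mode = "group_equalized",
                            variables = soil_variables(),
                            inputs = NULL,
                            classify_only = FALSE) {
  stopifnot(simprof_n_perm >= 1, rda_n_perm >= 1, indval_n_perm >= 1,
            alpha > 0, alpha < 1)
  structure(
    list(outdir = outdir, seed = as.integer(seed),
         simprof_n_perm = simprof_n_perm, rda_n_perm = rda_n_perm,
         indval_n_perm = indval_n_perm, alpha = alpha,
         rarefaction_depth = rarefaction_depth,
         filter_fraction = filter_fraction,
         indval_mode = indval_mode, variables = variables,
         inputs = inputs, classify_only = classify_only),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param config A [pipeline_config()].
#' @param file Path to a YAML file.
#' @return The config (read) or the path (write).
#' @export
write_pipeline_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(file) {
  raw <- yaml::read_yaml(file)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Fluxes from gas series, biogeochemical assembly, multifunctional
#' classification, OTU processing and diversity, constrained ordination,
#' and indicator analysis, writing every result table plus a JSON manifest
#' to `config$outdir`. Without input paths the pipeline simulates a study
#' from the configured seed; the run is a pure function of (inputs, config,
#' seed), so repeated runs are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- child_seeds(config$seed, 6)
  out_path <- function(f) file.path(config$outdir, f)

  if (is.null(config$inputs)) {
    sim <- simulate_study(seed = config$seed)
    metadata <- sim$metadata; biogeochem <- sim$biogeochem
    gas <- sim$gas; otu <- sim$otu
    readr::write_tsv(metadata, out_path("metadata.tsv"))
    write_biogeochem(biogeochem, out_path("biogeochem.tsv"))
    write_gas_series(gas, out_path("gas_timeseries.csv"))
    if (!is.null(otu)) write_otu_table(otu, out_path("otu_table.tsv"))
  } else {
    metadata <- readr::read_tsv(config$inputs$metadata, show_col_types = FALSE)
    biogeochem <- read_biogeochem(config$inputs$biogeochem)
    gas <- read_gas_series(config$inputs$gas)
    otu <- if (!is.null(config$inputs$otu)) read_otu_table(config$inputs$otu)
           else NULL
  }
  if (is.null(otu) && !config$classify_only) {
    abort("no OTU table: supply one or set `classify_only = TRUE`.",
          class = "mfsoil_config")
  }

  # fluxes -> biogeochemical assembly: refit H2/CO/CO2 from the series
  fluxes <- fit_gas_fluxes(gas)
  rates <- fluxes |>
    select("sample_id", "gas", "rate") |>
    tidyr::pivot_wider(names_from = "gas", values_from = "rate")
  for (g in intersect(c("H2", "CO", "CO2"), names(rates))) {
    biogeochem[[g]] <- rates[[g]][match(biogeochem$composite_id,
                                        rates$sample_id)]
  }
  readr::write_tsv(fluxes, out_path("flux_table.tsv"))

  cl <- classify_multifunctional(biogeochem, variables = config$variables,
                                 alpha = config$alpha,
                                 n_perm = config$simprof_n_perm,
                                 seed = seeds[1])
  assignments <- tidy(cl)
  readr::write_tsv(assignments, out_path("class_assignments.tsv"))
  node_p <- rep(NA_real_, length(cl$tree$height))
  node_p[cl$tests$node] <- cl$tests$p
  write_tree_newick(cl$tree, out_path("upgma.nwk"), node_p = node_p)

  pc <- pca_screen(cl$z)
  readr::write_tsv(tidy(pc), out_path("pca_axes.tsv"))
  readr::write_tsv(
    pc$loadings |>
      mutate(loading_length = unname(pc$loading_length[.data$variable]),
             contributing = unname(pc$contributing[.data$variable])),
    out_path("pca_loadings.tsv"))
  readr::write_tsv(pc$scores, out_path("pca_scores.tsv"))

  results <- list(fluxes = fluxes, classification = cl, pca = pc)

  if (!config$classify_only) {
    eq <- equalize_libraries(otu, depth = config$rarefaction_depth,
                             seed = seeds[2])
    filt <- filter_rare_otus(eq, min_fraction = config$filter_fraction)
    div <- alpha_diversity(filt)
    hel <- hellinger_transform(filt)
    bd <- beta_dispersion(dist(z_matrix(hel)),
                          cl$classes$class[match(hel$composite_id,
                                                 cl$classes$composite_id)])
    div <- div |> left_join(bd |> rename(composite_id = "sample_id",
                                         betadisp = "distance"),
                            by = "composite_id")
    readr::write_tsv(div, out_path("diversity.tsv"))

    zt <- cl$z |> filter(.data$composite_id %in% hel$composite_id)
    fs <- forward_select(hel, zt, alpha = config$alpha,
                         n_perm = config$rda_n_perm, seed = seeds[3])
    ord_report <- tibble(
      global_r2 = fs$global$r2, global_adj_r2 = fs$global$adj_r2,
      global_p = fs$global$p,
      selected = paste(fs$selected$variable, collapse = ",")
    )
    readr::write_tsv(ord_report, out_path("ordination_summary.tsv"))
    if (!is.null(fs$model)) {
      readr::write_tsv(
        bind_cols(tibble(otu_id = rownames(fs$model$species_scores)),
                  as_tibble(fs$model$species_scores)),
        out_path("ordination_species_scores.tsv"))
    }

    classes_for_otu <- cl$classes |>
      filter(.data$composite_id %in% filt$composite_id)
    ind <- indval(filt, classes_for_otu, mode = config$indval_mode,
                  n_perm = config$indval_n_perm, alpha = config$alpha,
                  seed = seeds[4]) |>
      select_representatives(filt)
    readr::write_tsv(ind, out_path("indicators.tsv"))
    corr <- correlate_indicators(ind, filt, biogeochem,
                                 alpha = config$alpha)
    readr::write_tsv(corr, out_path("indicator_correlations.tsv"))
    results <- c(results, list(diversity = div, forward_selection = fs,
                               indicators = ind,
                               indicator_correlations = corr))
  }

  manifest <- list(
    package = "mfsoil",
    version = as.character(utils::packageVersion("mfsoil")),
    seed = config$seed,
    parameters = list(
      simprof_n_perm = config$simprof_n_perm,
      rda_n_perm = config$rda_n_perm,
      indval_n_perm = config$indval_n_perm,
      alpha = config$alpha,
      rarefaction_depth = config$rarefaction_depth,
      filter_fraction = config$filter_fraction,
      indval_mode = config$indval_mode,
      variables = config$variables,
      classify_only = config$classify_only
    ),
    n_classes = nrow(cl$ranks),
    schema = "mfsoil-manifest-1"
  )
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
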