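#' Describe a planted bacterial community
#'
#' A shared dominant community with log-normal relative abundances plus
#' class-restricted rare-biosphere indicator OTUs. Indicators must stay
#' below 0.1% relative abundance (the rare-biosphere ceiling) and are
#' entirely absent outside their class.
#'
#' @param n_otus Number of shared (non-indicator) OTUs.
#' @param base_log_abundance_params `(location, scale)` of the log-normal
#'   relative-abundance law of the shared community.
#' @param indicator_spec Tibble with columns `class`, `otu_id`,
#'   `target_rel_abundance` (each < 0.001).
#' @param library_size_range `(min, max)` sequencing depth per sample.
#' @return A list of class `planted_community`.
#' @export
planted_community <- function(n_otus = 1000,
                              base_log_abundance_params = c(0, 1.5),
                              indicator_spec = default_indicator_spec(),
                              library_size_range = c(166040, 166040)) {
  assert_count(n_otus, "n_otus")
  if (any(indicator_spec$target_rel_abundance >= 0.001)) {
    abort("indicator target relative abundance must be < 0.1% (rare biosphere).",
          class = "mfsoil_rare_contract")
  }
  if (anyDuplicated(indicator_spec$otu_id)) {
    abort("indicator otu ids must be unique.", class = "mfsoil_config")
  }
  stopifnot(length(library_size_range) == 2,
            library_size_range[1] <= library_size_range[2],
            library_size_range[1] >= 1)
  structure(
    list(n_otus = as.integer(n_otus),
         base_log_abundance_params = base_log_abundance_params,
         indicator_spec = indicator_spec,
         library_size_range = as.integer(round(library_size_range))),
    class = "planted_community"
  )
}

#' Default planted indicators: two rare OTUs per class
#'
#' The higher-abundance OTU of each pair is the intended representative.
#'
#' @return Tibble with `class`, `otu_id`, `target_rel_abundance`.
#' @export
default_indicator_spec <- function() {
  classes <- c("I", "II", "III", "IV")
  tibble(
    class = rep(classes, each = 2),
    otu_id = paste0("IND_", rep(classes, each = 2), c("_hi", "_lo")),
    target_rel_abundance = rep(c(8e-4, 2e-4), times = 4)
  )
}

# four-rank lineage for simulated OTUs, weighted towards the taxa dominating
# acidic forest soils
simulate_taxonomy <- function(otu_ids) {
  phyla <- c("Proteobacteria", "Acidobacteria", "Actinobacteria",
             "Verrucomicrobia", "Bacteroidetes", "Chloroflexi")
  probs <- c(0.50, 0.19, 0.09, 0.08, 0.08, 0.06)
  ph <- sample(phyla, length(otu_ids), replace = TRUE, prob = probs)
  cl <- ifelse(ph == "Proteobacteria",
               sample(c("Alphaproteobacteria", "Deltaproteobacteria",
                        "Betaproteobacteria"), length(otu_ids),
                      replace = TRUE, prob = c(0.74, 0.11, 0.15)),
               paste0(ph, "_cl"))
  tibble(otu_id = otu_ids,
         taxonomy = paste(ph, cl, paste0(cl, "_or"), paste0(cl, "_fam"),
                          sep = ";"))
}

#' Simulate an OTU count table with planted indicators
#'
#' Counts are multinomial draws per composite sample from a shared
#' log-normal relative-abundance vector; each class's indicator OTUs are
#' added (and the vector renormalized) only for samples of that class, so
#' indicators have count zero everywhere else. Library sizes are uniform in
#' `community$library_size_range`.
#'
#' @param design A [study_design()].
#' @param community A [planted_community()].
#' @param class_assignment Tibble (`composite_id`, `class`) covering every
#'   composite.
#' @param seed Integer seed.
#' @param taxonomy Attach a simulated lineage per OTU?
#' @param drop_composite Optional composite id(s) whose library is omitted,
#'   emulating a failed extraction.
#' @return A wide tibble (`composite_id` + one integer column per OTU) with
#'   attributes `taxonomy` (tibble `otu_id`, `taxonomy`) and `truth` (the
#'   indicator spec, i.e. planted ground truth).
#' @export
#' @examples
#' tab <- generate_otu_table(seed = 1)
#' rowSums(tab[-1])[1:3]
generate_otu_table <- function(design = study_design(),
                               community = planted_community(),
                               class_assignment = default_class_assignment(),
                               seed = 1L,
                               taxonomy = TRUE,
                               drop_composite = NULL) {
  stopifnot(inherits(design, "study_design"),
            inherits(community, "planted_community"))
  composites <- generate_design(design, seed) |>
    distinct(.data$composite_id) |> pull()
  if (!all(composites %in% class_assignment$composite_id)) {
    abort("every composite needs a class assignment.", class = "mfsoil_config")
  }
  cls <- class_assignment$class[match(composites,
                                      class_assignment$composite_id)]
  ind <- community$indicator_spec
  shared_ids <- paste0("OTU_", formatC(seq_len(community$n_otus),
                                       width = 4, flag = "0"))
  otu_ids <- c(shared_ids, ind$otu_id)

  with_seed(seed, {
    p_shared <- stats::rlnorm(community$n_otus,
                              community$base_log_abundance_params[1],
                              community$base_log_abundance_params[2])
    p_shared <- p_shared / sum(p_shared)
    lo <- community$library_size_range[1]
    hi <- community$library_size_range[2]
    depths <- lo + sample.int(hi - lo + 1L, length(composites),
                              replace = TRUE) - 1L
    counts <- matrix(0L, nrow = length(composites), ncol = length(otu_ids),
                     dimnames = list(composites, otu_ids))
    for (i in seq_along(composites)) {
      p_ind <- ifelse(ind$class == cls[i], ind$target_rel_abundance, 0)
      p <- c(p_shared * (1 - sum(p_ind)), p_ind)
      counts[i, ] <- as.integer(rmultinom(1, depths[i], p))
    }
    tax <- if (taxonomy) simulate_taxonomy(otu_ids) else NULL

    keep <- !composites %in% drop_composite
    out <- bind_cols(tibble(composite_id = composites[keep]),
                     as_tibble(counts[keep, , drop = FALSE]))
    attr(out, "taxonomy") <- tax
    attr(out, "truth") <- ind |>
      mutate(representative = .data$target_rel_abundance ==
               stats::ave(.data$target_rel_abundance, .data$class, FUN = max))
    out
  })
}
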