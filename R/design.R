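#' Describe a blocked silvicultural study design
#'
#' The default mirrors the emulated field study: five site-preparation
#' treatments (an unlogged natural-forest reference, simple and double
#' trenching, inversion, and mounding) replicated in three blocks, with ten
#' replicate soil samples per plot that are pooled into one composite sample
#' per plot.
#'
#' @param n_blocks Number of replicated blocks (>= 1).
#' @param treatments Character vector of treatment identifiers.
#' @param n_replicates_per_plot Replicate soil samples collected per plot,
#'   pooled into a single composite (>= 1).
#' @param reference_treatment The treatment used as the undisturbed baseline;
#'   must be one of `treatments`.
#' @return A list of class `study_design`.
#' @export
#' @examples
#' d <- study_design()
#' d$n_blocks * length(d$treatments) # 15 composites
study_design <- function(n_blocks = 3,
                         treatments = c("unlogged", "simple", "double",
                                        "inversion", "mound"),
                         n_replicates_per_plot = 10,
                         reference_treatment = "unlogged") {
  assert_count(n_blocks, "n_blocks")
  assert_count(n_replicates_per_plot, "n_replicates_per_plot")
  treatments <- as.character(treatments)
  if (length(treatments) < 1 || anyDuplicated(treatments)) {
    abort("`treatments` must be a non-empty set of unique identifiers.",
          class = "mfsoil_invalid_design")
  }
  if (!reference_treatment %in% treatments) {
    abort("`reference_treatment` must be one of `treatments`.",
          class = "mfsoil_invalid_design")
  }
  structure(
    list(n_blocks = as.integer(n_blocks),
         treatments = treatments,
         n_replicates_per_plot = as.integer(n_replicates_per_plot),
         reference_treatment = reference_treatment),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", x$n_blocks, "blocks x", length(x$treatments),
      "treatments x", x$n_replicates_per_plot, "replicates/plot\n")
  cat("  treatments:", paste(x$treatments, collapse = ", "), "\n")
  cat("  reference :", x$reference_treatment, "\n")
  invisible(x)
}

# composite label such as "N-A" (treatment code + block letter); the unlogged
# natural reference is coded "N" to match field-style labels
composite_label <- function(treatment, block) {
  known <- c(unlogged = "N", simple = "S", double = "D",
             inversion = "I", mound = "M")
  code_for <- function(tr) {
    ifelse(tr %in% names(known), known[tr], toupper(substr(tr, 1, 1)))
  }
  if (anyDuplicated(code_for(unique(treatment)))) {
    code <- toupper(substr(treatment, 1, 3))
  } else {
    code <- code_for(treatment)
  }
  paste0(code, "-", LETTERS[block])
}

#' Expand a study design into a replicate-sample metadata table
#'
#' @param design A [study_design()].
#' @param seed Integer seed (kept for interface symmetry; the expansion is
#'   deterministic).
#' @return A tibble with one row per replicate sample: `sample_id`, `block`,
#'   `treatment`, `replicate`, `composite_id`, `is_reference`.
#' @export
#' @examples
#' nrow(generate_design(study_design()))        # 150
#' dplyr::n_distinct(generate_design(study_design())$composite_id)  # 15
generate_design <- function(design = study_design(), seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  grid <- tidyr::expand_grid(
    block = seq_len(design$n_blocks),
    treatment = design$treatments,
    replicate = seq_len(design$n_replicates_per_plot)
  )
  grid |>
    mutate(
      composite_id = composite_label(.data$treatment, .data$block),
      sample_id = paste0(.data$composite_id, "-r",
                         formatC(.data$replicate, width = 2, flag = "0")),
      is_reference = .data$treatment == design$reference_treatment
    ) |>
    select("sample_id", "block", "treatment", "replicate", "composite_id",
           "is_reference")
}
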