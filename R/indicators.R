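# IndVal components for every OTU against every class.
# counts: samples x OTUs; cls: factor of class labels per sample.
# A (specificity): class mean abundance / sum of class mean abundances
# (mean-based, i.e. group-equalized in the Dufrene-Legendre sense);
# B (fidelity): fraction of the class's samples where the OTU occurs.
indval_components <- function(counts, cls) {
  sizes <- as.integer(table(cls))
  means <- rowsum(counts, cls) / sizes          # K x J class mean abundance
  denom <- colSums(means)
  A <- sweep(means, 2, ifelse(denom == 0, 1, denom), "/")
  B <- rowsum((counts > 0) + 0, cls) / sizes
  list(A = A, B = B)
}

indval_stat <- function(counts, cls, mode) {
  ab <- indval_components(counts, cls)
  iv <- ab$A * ab$B
  if (mode == "group_equalized") iv <- sqrt(iv)
  best <- max.col(t(iv), ties.method = "first")
  stat <- iv[cbind(best, seq_len(ncol(iv)))]
  list(stat = stat, best = best, A = ab$A, B = ab$B)
}

#' Indicator-value (IndVal) analysis of OTUs across classes
#'
#' For each OTU, the indicator value for a class combines specificity A
#' (concentration of mean abundance in that class) and fidelity B
#' (prevalence within that class); the statistic is the maximum over
#' classes, sqrt(A * B) in the group-equalized default or A * B in the
#' classic form. Significance is assessed by permuting class labels across
#' samples, p = (1 + #\{stat* >= stat\}) / (1 + n_perm).
#'
#' @param data Wide OTU tibble (`composite_id` + count columns), typically
#'   equalized and rare-filtered.
#' @param classes Tibble (`composite_id`, `class`) or a vector of class
#'   labels aligned with the table rows.
#' @param mode `"group_equalized"` (default) or `"classic"`.
#' @param n_perm Number of label permutations.
#' @param alpha Significance level for the `significant` flag.
#' @param seed Integer seed.
#' @return Tibble with one row per OTU: `otu_id`, `class` (best class),
#'   `class_n` (its size), `A`, `B`, `stat`, `p`, `significant`,
#'   `representative` (initialized `FALSE`; see [select_representatives()]).
#'   Classes of size 1 are processed but flagged untestable via `class_n`.
#' @export
indval <- function(data, classes, mode = c("group_equalized", "classic"),
                   n_perm = 999, alpha = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  m <- otu_counts(data)
  if (is.data.frame(classes)) {
    cls <- classes$class[match(rownames(m), classes$composite_id)]
  } else {
    cls <- as.character(classes)
  }
  if (anyNA(cls) || length(cls) != nrow(m)) {
    abort("every sample needs a class label.", class = "mfsoil_schema")
  }
  cls <- factor(cls)
  if (nlevels(cls) < 2) abort("need >= 2 classes.", class = "mfsoil_schema")
  if (any(table(cls) == 0)) abort("empty class.", class = "mfsoil_schema")

  obs <- indval_stat(m, cls, mode)
  n <- nrow(m)
  exceed <- with_seed(seed, {
    acc <- numeric(ncol(m))
    for (b in seq_len(n_perm)) {
      st <- indval_stat(m, cls[sample.int(n)], mode)$stat
      acc <- acc + (st >= obs$stat)
    }
    acc
  })
  p <- (1 + exceed) / (1 + n_perm)
  lev <- levels(cls)
  sizes <- as.integer(table(cls))
  tibble(
    otu_id = colnames(m),
    class = lev[obs$best],
    class_n = sizes[obs$best],
    A = obs$A[cbind(obs$best, seq_len(ncol(m)))],
    B = obs$B[cbind(obs$best, seq_len(ncol(m)))],
    stat = obs$stat,
    p = p,
    significant = p <= alpha,
    representative = FALSE
  )
}

#' Flag the representative indicator of each class
#'
#' Where a class has more than one significant indicator, the OTU with the
#' highest total read count is its representative; ties are broken by
#' identifier order. Classes without a significant indicator get no flag.
#'
#' @param results Tibble from [indval()].
#' @param data The OTU tibble the results were computed on.
#' @return `results` with the `representative` column filled in.
#' @export
select_representatives <- function(results, data) {
  m <- otu_counts(data)
  totals <- colSums(m)
  results |>
    mutate(total_count = totals[.data$otu_id]) |>
    group_by(.data$class) |>
    mutate(representative = .data$significant &
             seq_along(.data$otu_id) == pick_representative(
               .data$significant, .data$total_count, .data$otu_id)) |>
    ungroup() |>
    select(-"total_count")
}

pick_representative <- function(significant, total, otu_id) {
  idx <- which(significant)
  if (length(idx) == 0) return(0L)
  ord <- idx[order(-total[idx], otu_id[idx])]
  ord[1]
}

#' Correlate representative indicators with soil variables
#'
#' Spearman rank correlation (average ranks for ties, two-sided p) between
#' each representative indicator's read counts and each biogeochemical
#' variable across samples.
#'
#' @param results Tibble from [select_representatives()].
#' @param data OTU tibble (abundances).
#' @param env Biogeochemical tibble aligned by `composite_id`.
#' @param variables Environmental variables; defaults to [soil_variables()]
#'   present in `env` plus a derived `C:N` ratio when C and N exist.
#' @param alpha Significance level for the flag.
#' @return Tibble `otu_id`, `class`, `variable`, `rho`, `p`, `significant`;
#'   constant abundance vectors yield `NA` with a warning.
#' @export
correlate_indicators <- function(results, data, env, variables = NULL,
                                 alpha = 0.05) {
  m <- otu_counts(data)
  env <- as_tibble(env)
  if (is.null(variables)) {
    variables <- intersect(soil_variables(), names(env))
    if (all(c("C", "N") %in% names(env)) && !"C:N" %in% names(env)) {
      env[["C:N"]] <- env$C / env$N
      variables <- c(variables, "C:N")
    }
  }
  env <- env[match(rownames(m), env$composite_id), ]
  reps <- results |> filter(.data$representative)
  purrr::map(seq_len(nrow(reps)), function(i) {
    otu <- reps$otu_id[i]
    x <- m[, otu]
    purrr::map(variables, function(v) {
      if (sd(x) == 0 || sd(env[[v]]) == 0) {
        warn(paste0("constant vector for ", otu, " x ", v,
                    "; correlation undefined."))
        return(tibble(otu_id = otu, class = reps$class[i], variable = v,
                      rho = NA_real_, p = NA_real_, significant = NA))
      }
      ct <- suppressWarnings(
        cor.test(x, env[[v]], method = "spearman", exact = FALSE))
      tibble(otu_id = otu, class = reps$class[i], variable = v,
             rho = unname(ct$estimate), p = ct$p.value,
             significant = ct$p.value <= alpha)
    }) |> bind_rows()
  }) |> bind_rows()
}
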