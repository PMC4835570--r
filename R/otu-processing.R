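# wide OTU tibble (sample id column + integer OTU columns) -> counts matrix
otu_counts <- function(data, id_col = "composite_id") {
  m <- df_to_matrix(data, id_col)
  if (any(m < 0)) abort("negative counts.", class = "mfsoil_schema")
  m
}

otu_rebuild <- function(m, data, id_col = "composite_id") {
  out <- bind_cols(tibble(!!id_col := rownames(m)), as_tibble(m))
  attr(out, "taxonomy") <- attr(data, "taxonomy")
  attr(out, "truth") <- attr(data, "truth")
  out
}

#' Equalize sequencing effort by rarefaction
#'
#' Subsamples every library without replacement to a common depth (the
#' smallest library by default), removing the comparative bias introduced by
#' unequal sequencing effort. One deterministic draw per seed.
#'
#' @param data Wide OTU tibble (`composite_id` + integer OTU columns).
#' @param depth Target depth, or `"min"` for the smallest library.
#' @param seed Integer seed.
#' @param drop_shallow Drop samples whose library is smaller than `depth`
#'   instead of erroring.
#' @return Equalized OTU tibble (attributes preserved).
#' @export
equalize_libraries <- function(data, depth = "min", seed = 1L,
                               drop_shallow = FALSE) {
  m <- otu_counts(data)
  sizes <- rowSums(m)
  if (identical(depth, "min")) depth <- min(sizes)
  depth <- as.integer(depth)
  shallow <- rownames(m)[sizes < depth]
  if (length(shallow) > 0) {
    if (!drop_shallow) {
      abort(paste0("depth ", depth, " exceeds the library of: ",
                   paste(shallow, collapse = ", "),
                   ". Lower `depth` or set `drop_shallow = TRUE`."),
            class = "mfsoil_depth")
    }
    m <- m[!rownames(m) %in% shallow, , drop = FALSE]
  }
  # rrarefy heuristically warns when all counts are large ("should be used
  # for observed counts"); integer count tables are exactly its use case here
  r <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  storage.mode(r) <- "integer"
  otu_rebuild(r, data)
}

#' Minimum-count threshold implied by a fractional filter
#'
#' @param depth Uniform library size (reads per library).
#' @param min_fraction Fraction of the per-library reads; default 0.005%.
#' @return `floor(min_fraction * depth)`, the minimum read count.
#' @export
#' @examples
#' rare_count_threshold(166040)  # 8
rare_count_threshold <- function(depth, min_fraction = 5e-5) {
  floor(min_fraction * depth)
}

#' Filter rare OTUs from an equalized table
#'
#' Removes OTUs falling below a fractional read threshold (default 0.005% of
#' the per-library reads). With `rule = "any_sample"` (default) an OTU is
#' kept if it reaches the threshold count in at least one sample; with
#' `rule = "table_total"` the threshold is applied to the OTU's table-wide
#' total. Requires uniform library sizes (equalize first).
#'
#' @inheritParams equalize_libraries
#' @param min_fraction Fraction of per-library reads defining the threshold.
#' @param rule Where the threshold applies.
#' @return Filtered OTU tibble.
#' @export
filter_rare_otus <- function(data, min_fraction = 5e-5,
                             rule = c("any_sample", "table_total")) {
  rule <- match.arg(rule)
  m <- otu_counts(data)
  sizes <- rowSums(m)
  if (length(unique(sizes)) != 1) {
    abort("library sizes are not uniform; run equalize_libraries() first.",
          class = "mfsoil_depth")
  }
  thr <- rare_count_threshold(sizes[1], min_fraction)
  keep <- if (rule == "any_sample") {
    apply(m, 2, max) >= thr
  } else {
    colSums(m) >= thr
  }
  out <- otu_rebuild(m[, keep, drop = FALSE], data)
  tax <- attr(out, "taxonomy")
  if (!is.null(tax)) {
    attr(out, "taxonomy") <- tax[tax$otu_id %in% colnames(m)[keep], ]
  }
  out
}

#' Hellinger transformation
#'
#' Square root of per-sample relative abundances, y'_ij = sqrt(y_ij / y_i+),
#' making Euclidean distances between samples appropriate for species count
#' data (each transformed row has unit sum of squares).
#'
#' @inheritParams equalize_libraries
#' @return Tibble of the same shape with transformed values.
#' @export
hellinger_transform <- function(data) {
  m <- otu_counts(data)
  if (any(rowSums(m) == 0)) {
    abort(paste0("zero-total sample(s): ",
                 paste(rownames(m)[rowSums(m) == 0], collapse = ", ")),
          class = "mfsoil_schema")
  }
  h <- vegan::decostand(m, method = "hellinger")
  otu_rebuild(h, data)
}

#' Shannon diversity (natural log)
#'
#' H = -sum p_i ln p_i over taxa with p_i > 0.
#'
#' @param counts Non-negative abundance vector with positive total.
#' @return Shannon index in nats.
#' @export
#' @examples
#' shannon_index(rep(1, 10))  # log(10)
shannon_index <- function(counts) {
  if (sum(counts) <= 0) abort("empty sample.", class = "mfsoil_diversity")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator:
#' S_ACE = S_abund + S_rare / C_ACE + (F1 / C_ACE) * gamma^2, where rare
#' OTUs have abundance <= `rare_cutoff`, C_ACE = 1 - F1 / N_rare, and
#' gamma^2 = max(S_rare * sum(i (i-1) F_i) / (C_ACE N_rare (N_rare - 1)) - 1, 0).
#' When every rare read is a singleton (C_ACE = 0) the estimate falls back
#' to Chao1 with a warning.
#'
#' @param counts Non-negative abundance vector with positive total.
#' @param rare_cutoff Abundance ceiling for the "rare" group (default 10).
#' @return Estimated richness (>= observed richness).
#' @export
ace_richness <- function(counts, rare_cutoff = 10) {
  if (sum(counts) <= 0) abort("empty sample.", class = "mfsoil_diversity")
  counts <- counts[counts > 0]
  s_obs <- length(counts)
  rare <- counts[counts <= rare_cutoff]
  s_rare <- length(rare)
  s_abund <- s_obs - s_rare
  if (s_rare == 0) return(s_obs)
  n_rare <- sum(rare)
  f <- tabulate(rare, nbins = rare_cutoff)
  f1 <- f[1]
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warn("all rare reads are singletons; falling back to Chao1.")
    f2 <- if (rare_cutoff >= 2) f[2] else 0
    return(s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)))
  }
  i <- seq_len(rare_cutoff)
  gamma2 <- max(s_rare * sum(i * (i - 1) * f) /
                  (c_ace * n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Per-sample alpha diversity summary
#'
#' @inheritParams equalize_libraries
#' @param rare_cutoff Passed to [ace_richness()].
#' @return Tibble with `composite_id`, `observed`, `shannon`, `ace`.
#' @export
alpha_diversity <- function(data, rare_cutoff = 10) {
  m <- otu_counts(data)
  tibble(
    composite_id = rownames(m),
    observed = rowSums(m > 0),
    shannon = apply(m, 1, shannon_index),
    ace = apply(m, 1, ace_richness, rare_cutoff = rare_cutoff)
  )
}

#' Multivariate dispersion (beta diversity)
#'
#' Distance of each sample to its group centroid in the principal-coordinate
#' embedding of a distance matrix, with the standard sign correction for
#' negative eigenvalues; the group mean distance is the beta-diversity
#' measure.
#'
#' @param d A `dist` object (square, symmetric, zero diagonal).
#' @param groups Grouping vector aligned with the distance labels.
#' @return Tibble with `sample_id`, `group`, `distance`; per-group mean
#'   dispersions as `attr(, "group_means")`.
#' @export
beta_dispersion <- function(d, groups) {
  stopifnot(inherits(d, "dist"))
  groups <- as.factor(groups)
  if (any(table(groups) < 1)) abort("empty group.", class = "mfsoil_schema")
  if (any(table(groups) == 1)) {
    warn("group(s) of size 1: dispersion is 0 by construction.")
  }
  bd <- vegan::betadisper(d, groups, type = "centroid")
  samples <- tibble(
    sample_id = labels(d) %||% as.character(seq_along(bd$distances)),
    group = as.character(groups),
    distance = as.numeric(bd$distances)
  )
  attr(samples, "group_means") <- samples |>
    group_by(.data$group) |>
    summarise(dispersion = mean(.data$distance), .groups = "drop")
  samples
}

#' Taxonomic relative-abundance summary
#'
#' @inheritParams equalize_libraries
#' @param level One of `"phylum"`, `"class"`, `"order"`, `"family"`.
#' @param taxonomy Tibble (`otu_id`, `taxonomy`) with `;`-separated
#'   phylum;class;order;family lineages; defaults to the table's attribute.
#' @return Long tibble `composite_id`, `taxon`, `rel_abundance` (percent);
#'   overall (all-sample) percentages attached as `attr(, "overall")`.
#' @export
summarize_taxonomy <- function(data,
                               level = c("phylum", "class", "order", "family"),
                               taxonomy = attr(data, "taxonomy")) {
  level <- match.arg(level)
  if (is.null(taxonomy)) abort("no taxonomy available.", class = "mfsoil_schema")
  m <- otu_counts(data)
  rank_i <- match(level, c("phylum", "class", "order", "family"))
  lineage <- strsplit(taxonomy$taxonomy, ";", fixed = TRUE)
  taxon <- purrr::map_chr(lineage, function(l) {
    if (length(l) >= rank_i && nzchar(trimws(l[rank_i]))) trimws(l[rank_i])
    else "unclassified"
  })
  taxon_of <- setNames(taxon, taxonomy$otu_id)
  grp <- taxon_of[colnames(m)]
  grp[is.na(grp)] <- "unclassified"
  agg <- t(rowsum(t(m), grp))
  rel <- 100 * agg / rowSums(m)
  out <- as_tibble(rel) |>
    mutate(composite_id = rownames(m), .before = 1) |>
    tidyr::pivot_longer(-"composite_id", names_to = "taxon",
                        values_to = "rel_abundance")
  attr(out, "overall") <- tibble(
    taxon = colnames(agg),
    rel_abundance = 100 * colSums(agg) / sum(m)
  ) |> arrange(desc(.data$rel_abundance))
  out
}

#' OTUs detected in every sample
#'
#' @inheritParams equalize_libraries
#' @return Character vector of OTU ids with count > 0 in all samples.
#' @export
ubiquitous_otus <- function(data) {
  m <- otu_counts(data)
  if (nrow(m) == 0) abort("empty table.", class = "mfsoil_schema")
  colnames(m)[colSums(m > 0) == nrow(m)]
}
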