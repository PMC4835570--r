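#' Standardize soil variables to zero mean and unit SD
#'
#' Each variable is centred on its across-sample mean and divided by its
#' sample SD (n - 1 denominator), putting descriptors with different units
#' on a common scale before Euclidean distances are taken.
#'
#' @param data Tibble with an id column and the variables.
#' @param variables Variables to standardize; default [soil_variables()]
#'   intersected with the available columns.
#' @param id_col Sample identifier column.
#' @return Tibble `id_col` + standardized variables.
#' @export
standardize_variables <- function(data, variables = NULL,
                                  id_col = "composite_id") {
  if (is.null(variables)) {
    variables <- intersect(soil_variables(), names(data))
  }
  missing <- setdiff(variables, names(data))
  if (length(missing) > 0) {
    abort(paste0("variables not in data: ", paste(missing, collapse = ", ")),
          class = "mfsoil_schema")
  }
  m <- df_to_matrix(data[c(id_col, variables)], id_col)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant variable(s): ",
                 paste(colnames(m)[sds == 0], collapse = ", ")),
          class = "mfsoil_constant")
  }
  z <- scale(m)
  attr(z, "scaled:center") <- NULL; attr(z, "scaled:scale") <- NULL
  bind_cols(tibble(!!id_col := rownames(m)), as_tibble(z))
}

# standardized tibble -> plain matrix
z_matrix <- function(z, id_col = "composite_id") df_to_matrix(z, id_col)

#' UPGMA (average-linkage) agglomerative clustering
#'
#' Merges the closest pair of clusters at each step, with the new node's
#' height equal to the size-weighted average between-cluster distance
#' (Lance-Williams UPGMA update). Ties are broken towards the pair whose
#' smallest original member indices are lexicographically least, so the
#' topology is reproducible.
#'
#' @param d A `dist` object over >= 2 samples.
#' @return An object of class `hclust` (method `"average"`).
#' @export
upgma_tree <- function(d) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  if (n < 2) abort("need at least 2 samples.", class = "mfsoil_schema")
  lab <- labels(d) %||% as.character(seq_len(n))
  D <- as.matrix(d)
  diag(D) <- Inf

  active <- lapply(seq_len(n), function(i) {
    list(id = -i, members = i, size = 1L)
  })
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    dmin <- min(D[upper.tri(D)])
    cand <- which(D == dmin & upper.tri(D), arr.ind = TRUE)
    if (nrow(cand) > 1) {
      keys <- apply(cand, 1, function(rc) {
        sort(c(min(active[[rc[1]]]$members), min(active[[rc[2]]]$members)))
      })
      ord <- order(keys[1, ], keys[2, ])
      cand <- cand[ord, , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    a <- active[[i]]; b <- active[[j]]
    # list the cluster containing the smallest original index first
    if (min(a$members) <= min(b$members)) {
      merge[step, ] <- c(a$id, b$id)
    } else {
      merge[step, ] <- c(b$id, a$id)
    }
    height[step] <- dmin
    new <- list(id = step, members = c(a$members, b$members),
                size = a$size + b$size)
    # UPGMA update: d(new, C) = (n_a d(a,C) + n_b d(b,C)) / (n_a + n_b)
    drow <- (a$size * D[i, ] + b$size * D[j, ]) / new$size
    D[i, ] <- drow; D[, i] <- drow; D[i, i] <- Inf
    D <- D[-j, -j, drop = FALSE]
    active[[i]] <- new
    active[[j]] <- NULL
  }

  order_leaves <- function(node) {
    if (node < 0) return(-node)
    c(order_leaves(merge[node, 1]), order_leaves(merge[node, 2]))
  }
  structure(
    list(merge = merge, height = height,
         order = order_leaves(n - 1L), labels = lab,
         method = "average", dist.method = attr(d, "method") %||% "euclidean",
         call = match.call()),
    class = "hclust"
  )
}

# members (leaf indices) of each internal node of an hclust tree
node_members <- function(tree) {
  n <- length(tree$height) + 1L
  mem <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    mem[[k]] <- unlist(lapply(tree$merge[k, ], function(ch) {
      if (ch < 0) -ch else mem[[ch]]
    }))
  }
  mem
}

# one null profile: each variable permuted independently across the rows.
# Columns are visited in sorted-name order so the draw does not depend on
# the column order of the input table.
null_profile <- function(z, col_order) {
  zp <- z
  n <- nrow(z)
  for (j in col_order) zp[, j] <- z[sample.int(n), j]
  sort(dist(zp))
}

#' SIMPROF similarity-profile permutation test
#'
#' Tests whether a group of samples has internal multivariate structure.
#' The observed profile is the sorted vector of pairwise Euclidean
#' distances; null profiles are obtained by permuting each variable
#' independently across the samples. The statistic pi is the sum of
#' absolute deviations between the observed profile and the mean of
#' `n_perm_expected` null profiles; its null distribution comes from
#' `n_perm_null` further profiles. Groups of fewer than 3 samples are
#' untestable and return p = 1 by convention.
#'
#' @param z Numeric matrix (samples x standardized variables) or a
#'   standardized tibble from [standardize_variables()].
#' @param n_perm_expected Permutations defining the expected profile.
#' @param n_perm_null Permutations defining the null distribution of pi.
#' @param seed Integer seed.
#' @return List with `pi`, `p`, `n`, `tested`.
#' @export
simprof_test <- function(z, n_perm_expected = 999, n_perm_null = 999,
                         seed = 1L) {
  if (is.data.frame(z)) z <- z_matrix(z)
  n <- nrow(z)
  if (n < 3) {
    return(list(pi = NA_real_, p = 1, n = n, tested = FALSE))
  }
  col_order <- if (!is.null(colnames(z))) order(colnames(z)) else
    seq_len(ncol(z))
  obs <- sort(dist(z))
  with_seed(seed, {
    profiles <- matrix(0, n_perm_expected + n_perm_null, length(obs))
    for (b in seq_len(nrow(profiles))) {
      profiles[b, ] <- null_profile(z, col_order)
    }
    expected <- colMeans(profiles[seq_len(n_perm_expected), , drop = FALSE])
    pi_obs <- sum(abs(obs - expected))
    nulls <- profiles[n_perm_expected + seq_len(n_perm_null), , drop = FALSE]
    pi_null <- rowSums(abs(sweep(nulls, 2, expected)))
    list(pi = pi_obs,
         p = (1 + sum(pi_null >= pi_obs)) / (1 + n_perm_null),
         n = n, tested = TRUE)
  })
}

#' Delineate multifunctional classes on a UPGMA tree
#'
#' Top-down traversal: the root group is SIMPROF-tested; where the test
#' rejects (p <= alpha) the two subtrees are examined in turn, and a
#' subtree whose test fails to reject -- or is too small to test -- becomes
#' one class. The resulting classes partition the samples and are labelled
#' with Roman numerals in dendrogram leaf order.
#'
#' @param tree An `hclust` tree from [upgma_tree()].
#' @param z Standardized tibble or matrix used to build the tree.
#' @param alpha Significance level of the SIMPROF tests.
#' @param n_perm Permutations for both the expected profile and the null.
#' @param seed Integer seed; each node receives a deterministic child seed.
#' @return List with `classes` (tibble `composite_id`, `class`), `tests`
#'   (tibble of per-node SIMPROF results).
#' @export
delineate_classes <- function(tree, z, alpha = 0.05, n_perm = 999,
                              seed = 1L) {
  if (is.data.frame(z)) z <- z_matrix(z)
  n <- nrow(z)
  mem <- node_members(tree)
  seeds <- child_seeds(seed, max(length(mem), 1))
  tests <- list()
  class_groups <- list()

  visit <- function(node) {
    if (node < 0) {
      class_groups[[length(class_groups) + 1]] <<- -node
      return(invisible())
    }
    members <- mem[[node]]
    res <- simprof_test(z[members, , drop = FALSE], n_perm, n_perm,
                        seed = seeds[node])
    tests[[length(tests) + 1]] <<- tibble(
      node = node, n = res$n, pi = res$pi, p = res$p, tested = res$tested,
      height = tree$height[node]
    )
    if (res$tested && res$p <= alpha) {
      visit(tree$merge[node, 1])
      visit(tree$merge[node, 2])
    } else {
      class_groups[[length(class_groups) + 1]] <<- members
    }
  }
  visit(n - 1L)

  # label classes I, II, ... in dendrogram leaf order
  first_pos <- vapply(class_groups, function(g) min(match(g, tree$order)),
                      numeric(1))
  class_groups <- class_groups[order(first_pos)]
  labels <- roman_labels(length(class_groups))
  classes <- purrr::imap(class_groups, function(g, k) {
    tibble(composite_id = tree$labels[g], class = labels[k])
  }) |> bind_rows()
  classes <- classes[match(tree$labels, classes$composite_id), ]

  list(classes = classes, tests = bind_rows(tests))
}

#' Rank classes by deviation from the reference condition
#'
#' The disturbance level of each class is the Euclidean distance between
#' its centroid and the centroid of the reference samples, in standardized
#' variable space; rank 1 is the least disturbed.
#'
#' @param classes Tibble (`composite_id`, `class`).
#' @param z Standardized tibble or matrix.
#' @param reference_ids Sample ids of the reference (e.g. unlogged) plots.
#' @return Tibble `class`, `n`, `distance_to_reference`, `disturbance_rank`.
#' @export
rank_classes <- function(classes, z, reference_ids) {
  if (is.data.frame(z)) z <- z_matrix(z)
  if (length(reference_ids) == 0 || !any(reference_ids %in% rownames(z))) {
    abort("no reference samples found.", class = "mfsoil_schema")
  }
  ref_centroid <- colMeans(z[rownames(z) %in% reference_ids, , drop = FALSE])
  classes |>
    group_by(.data$class) |>
    summarise(
      n = dplyr::n(),
      distance_to_reference = sqrt(sum((colMeans(
        z[.data$composite_id, , drop = FALSE]) - ref_centroid)^2)),
      .groups = "drop"
    ) |>
    mutate(disturbance_rank = rank(.data$distance_to_reference,
                                   ties.method = "min"))
}

#' Multifunctional soil classification
#'
#' The full classification model: standardize the biogeochemical variables,
#' build a Euclidean UPGMA dendrogram, delineate classes with SIMPROF
#' permutation tests, and rank the classes by their distance from the
#' reference centroid.
#'
#' @param data Biogeochemical tibble (one row per composite) with an
#'   `is_reference` logical column or `reference_ids` supplied.
#' @param variables Classification variables (default [soil_variables()]
#'   present in the data).
#' @param id_col Sample id column.
#' @param reference_ids Reference sample ids; defaults to rows flagged
#'   `is_reference`.
#' @param alpha SIMPROF significance level.
#' @param n_perm SIMPROF permutations (expected profile and null each).
#' @param seed Integer seed.
#' @return Object of class `multifunc_classification` with elements
#'   `classes`, `ranks`, `tests`, `tree`, `z`; see [tidy.multifunc_classification()].
#' @export
#' @examples
#' bg <- generate_biogeochem(seed = 7,
#'   class_assignment = default_class_assignment(),
#'   class_effects = default_class_effects())
#' cl <- classify_multifunctional(bg, n_perm = 99, seed = 7)
#' cl$ranks
classify_multifunctional <- function(data, variables = NULL,
                                     id_col = "composite_id",
                                     reference_ids = NULL,
                                     alpha = 0.05, n_perm = 999, seed = 1L) {
  if (is.null(reference_ids)) {
    if (!"is_reference" %in% names(data)) {
      abort("supply `reference_ids` or an `is_reference` column.",
            class = "mfsoil_schema")
    }
    reference_ids <- data[[id_col]][data$is_reference]
  }
  zt <- standardize_variables(data, variables, id_col)
  z <- z_matrix(zt, id_col)
  tree <- upgma_tree(dist(z))
  del <- delineate_classes(tree, z, alpha = alpha, n_perm = n_perm,
                           seed = seed)
  ranks <- rank_classes(del$classes, z, reference_ids)
  structure(
    list(classes = del$classes, ranks = ranks, tests = del$tests,
         tree = tree, z = zt, reference_ids = reference_ids,
         alpha = alpha, n_perm = n_perm, seed = seed),
    class = "multifunc_classification"
  )
}

#' @export
print.multifunc_classification <- function(x, ...) {
  cat("Multifunctional classification:", nrow(x$classes), "samples,",
      nrow(x$ranks), "classes (SIMPROF alpha =", x$alpha, ")\n")
  print(x$ranks)
  invisible(x)
}
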