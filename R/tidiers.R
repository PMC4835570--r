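#' Tidy a multifunctional classification
#'
#' One row per sample: class label (dendrogram order), disturbance rank and
#' distance of the sample's class to the reference centroid.
#'
#' @param x A `multifunc_classification`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy multifunc_classification
#' @export
tidy.multifunc_classification <- function(x, ...) {
  x$classes |>
    left_join(x$ranks, by = "class") |>
    select("composite_id", "class", "disturbance_rank",
           "distance_to_reference")
}

#' @rdname tidy.multifunc_classification
#' @method glance multifunc_classification
#' @export
glance.multifunc_classification <- function(x, ...) {
  tibble(
    n_samples = nrow(x$classes),
    n_classes = nrow(x$ranks),
    n_tested_nodes = sum(x$tests$tested),
    alpha = x$alpha,
    n_perm = x$n_perm,
    min_p = suppressWarnings(min(x$tests$p[x$tests$tested]))
  )
}

#' Tidy an RDA fit
#'
#' One row per canonical (and residual) axis with its eigenvalue and the
#' proportion of total community variance it carries.
#'
#' @param x A `soil_rda` object.
#' @param ... Unused.
#' @return A tibble `axis`, `component`, `eigenvalue`, `prop_variance`.
#' @method tidy soil_rda
#' @export
tidy.soil_rda <- function(x, ...) {
  bind_rows(
    tibble(axis = paste0("RDA", seq_along(x$eigenvalues)),
           component = "canonical", eigenvalue = x$eigenvalues),
    tibble(axis = paste0("PC", seq_along(x$residual_eigenvalues)),
           component = "residual", eigenvalue = x$residual_eigenvalues)
  ) |>
    mutate(prop_variance = .data$eigenvalue / x$total_variance)
}

#' @rdname tidy.soil_rda
#' @method glance soil_rda
#' @export
glance.soil_rda <- function(x, ...) {
  tibble(r2 = x$r2, adj_r2 = x$adj_r2, n = x$n, m = x$m,
         total_variance = x$total_variance,
         max_vif = max(x$vif))
}

#' Tidy a PCA screen
#'
#' @param x A `soil_pca` object.
#' @param ... Unused.
#' @return Tibble `axis`, `eigenvalue`, `prop_variance`, `retained`.
#' @method tidy soil_pca
#' @export
tidy.soil_pca <- function(x, ...) {
  tibble(
    axis = paste0("PC", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    prop_variance = x$prop_variance,
    retained = x$retained
  )
}

#' @rdname tidy.soil_pca
#' @method glance soil_pca
#' @export
glance.soil_pca <- function(x, ...) {
  tibble(
    n_axes = length(x$eigenvalues),
    n_retained = sum(x$retained),
    equilibrium_radius = x$equilibrium_radius,
    n_contributing = sum(x$contributing),
    var_first_two = sum(x$prop_variance[seq_len(min(2,
      length(x$prop_variance)))])
  )
}
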