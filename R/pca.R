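#' Equilibrium-circle radius
#'
#' Radius sqrt(d / p) of the equilibrium contribution circle in a
#' correlation-PCA descriptor plot: descriptors whose loading vectors in
#' the d-dimensional reduced space are longer than this radius contribute
#' more than average to the displayed axes. `sqrt = FALSE` returns the
#' plain ratio d/p instead.
#'
#' @param d Number of displayed axes (default 2).
#' @param p Number of descriptors (default 10).
#' @param sqrt Use the textbook sqrt(d/p) form (default) or the raw ratio.
#' @return The radius.
#' @export
#' @examples
#' equilibrium_radius(2, 10)  # 0.4472
equilibrium_radius <- function(d = 2, p = 10, sqrt = TRUE) {
  if (sqrt) base::sqrt(d / p) else d / p
}

#' Correlation PCA of standardized soil descriptors
#'
#' Eigen-decomposition of the correlation structure (covariance of the
#' standardized matrix). Axes whose eigenvalue exceeds the mean eigenvalue
#' (Kaiser-Guttman) are flagged as meaningful, and descriptors whose
#' loading-vector length in the displayed plane exceeds the equilibrium
#' radius sqrt(d/p) are flagged as contributing.
#'
#' @param z Standardized tibble (from [standardize_variables()]) or matrix.
#' @param d Number of displayed axes for the equilibrium screen.
#' @param id_col Sample id column when `z` is a tibble.
#' @return Object of class `soil_pca`: `eigenvalues`, `scores` (samples x
#'   axes tibble), `loadings` (descriptor coordinates, unit eigenvectors),
#'   `retained` (Kaiser-Guttman flags), `contributing`, `equilibrium_radius`,
#'   `prop_variance`.
#' @export
pca_screen <- function(z, d = 2, id_col = "composite_id") {
  if (is.data.frame(z)) z <- z_matrix(z, id_col)
  if (ncol(z) < 2) abort("need >= 2 variables.", class = "mfsoil_schema")
  if (nrow(z) < 2) abort("need >= 2 samples.", class = "mfsoil_schema")
  pc <- prcomp(z, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  u <- pc$rotation                       # unit eigenvectors (p x k)
  d <- min(d, ncol(u))
  radius <- equilibrium_radius(d, ncol(z))
  load_len <- sqrt(rowSums(u[, seq_len(d), drop = FALSE]^2))
  structure(
    list(
      eigenvalues = ev,
      prop_variance = ev / sum(ev),
      scores = bind_cols(tibble(!!id_col := rownames(z)),
                         as_tibble(pc$x)),
      loadings = bind_cols(tibble(variable = rownames(u)), as_tibble(u)),
      retained = ev > mean(ev),
      contributing = setNames(load_len > radius, rownames(u)),
      loading_length = setNames(load_len, rownames(u)),
      equilibrium_radius = radius,
      d = d
    ),
    class = "soil_pca"
  )
}

#' @export
print.soil_pca <- function(x, ...) {
  cat("Correlation PCA:", length(x$eigenvalues), "descriptors;",
      sum(x$retained), "axes retained (Kaiser-Guttman)\n")
  cat("First", x$d, "axes explain",
      sprintf("%.1f%%", 100 * sum(x$prop_variance[seq_len(x$d)])),
      "of the variance; equilibrium radius",
      sprintf("%.4f", x$equilibrium_radius), "\n")
  cat("Contributing descriptors:",
      paste(names(x$contributing)[x$contributing], collapse = ", "), "\n")
  invisible(x)
}
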