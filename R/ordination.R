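# coerce tibble/matrix pairs to aligned matrices (shared row ids when present)
align_yx <- function(Y, X, id_col = "composite_id") {
  if (is.data.frame(Y)) Y <- df_to_matrix(Y, id_col)
  if (is.data.frame(X)) X <- df_to_matrix(X, id_col)
  if (!is.null(rownames(Y)) && !is.null(rownames(X))) {
    if (!all(rownames(Y) %in% rownames(X))) {
      abort("response and explanatory rows do not match.",
            class = "mfsoil_schema")
    }
    X <- X[rownames(Y), , drop = FALSE]
  }
  if (nrow(Y) != nrow(X)) {
    abort("response and explanatory tables have different sample counts.",
          class = "mfsoil_schema")
  }
  list(Y = Y, X = X)
}

center_cols <- function(m) sweep(m, 2, colMeans(m))

# residuals of M after regressing each column on (intercept + Z)
residualize <- function(M, Z) {
  Zc <- center_cols(Z)
  Mc <- center_cols(M)
  qrz <- qr(Zc)
  Mc - qr.fitted(qrz, Mc)
}

#' Redundancy analysis (RDA)
#'
#' Principal axes of the projection of a (centred) community matrix onto
#' environmental predictors: Y is regressed on X by multivariate least
#' squares, the canonical axes are the principal axes of the fitted values,
#' and the residual axes those of the residual matrix. Eigenvalues are on
#' the variance scale (n - 1 denominator) so canonical + residual
#' eigenvalues sum to the total variance of Y.
#'
#' @param Y Response matrix or tibble (samples x species), typically
#'   Hellinger-transformed counts from [hellinger_transform()].
#' @param X Explanatory matrix or tibble (samples x variables), typically
#'   standardized via [standardize_variables()].
#' @param id_col Sample id column for tibble inputs.
#' @return Object of class `soil_rda`: `eigenvalues` (canonical),
#'   `residual_eigenvalues`, `r2`, `adj_r2`, `site_scores` (fitted, "lc"),
#'   `species_scores` (scaled by sqrt of eigenvalue, a correlation-style
#'   "scaling 2"), `biplot` (predictor arrows), `vif`, `n`, `m`.
#' @export
rda_fit <- function(Y, X, id_col = "composite_id") {
  a <- align_yx(Y, X, id_col)
  Yc <- center_cols(a$Y)
  Xc <- center_cols(a$X)
  n <- nrow(Yc); m <- ncol(Xc)
  if (n <= m) abort("need more samples than explanatory variables.",
                    class = "mfsoil_schema")
  qrx <- qr(Xc)
  if (qrx$rank < m) {
    abort("explanatory variables are collinear to machine precision; screen with vif_scores().",
          class = "mfsoil_collinear")
  }
  Yhat <- qr.fitted(qrx, Yc)
  Yres <- Yc - Yhat
  ss_tot <- sum(Yc^2)
  r2 <- sum(Yhat^2) / ss_tot
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - m - 1)

  sv <- svd(Yhat)
  rank_c <- sum(sv$d > sv$d[1] * 1e-10)
  d <- sv$d[seq_len(rank_c)]
  ev <- d^2 / (n - 1)
  U <- sv$u[, seq_len(rank_c), drop = FALSE]
  V <- sv$v[, seq_len(rank_c), drop = FALSE]
  axis_names <- paste0("RDA", seq_len(rank_c))

  sv_r <- svd(Yres)
  ev_res <- (sv_r$d^2 / (n - 1))
  ev_res <- ev_res[ev_res > max(ev_res[1], .Machine$double.eps) * 1e-10]

  site <- U %*% diag(d, rank_c)                      # fitted ("lc") scores
  species <- V %*% diag(sqrt(ev), rank_c)
  rownames(site) <- rownames(a$Y); colnames(site) <- axis_names
  rownames(species) <- colnames(a$Y); colnames(species) <- axis_names
  biplot <- suppressWarnings(cor(Xc, site))
  biplot[is.na(biplot)] <- 0

  structure(
    list(eigenvalues = ev, residual_eigenvalues = ev_res,
         total_variance = ss_tot / (n - 1),
         r2 = r2, adj_r2 = adj_r2,
         site_scores = site, species_scores = species, biplot = biplot,
         vif = vif_scores(a$X), n = n, m = m,
         variables = colnames(a$X)),
    class = "soil_rda"
  )
}

#' @export
print.soil_rda <- function(x, ...) {
  cat("RDA:", x$n, "samples,", x$m, "explanatory variable(s)\n")
  cat(sprintf("  R2 = %.3f, adjusted R2 = %.3f\n", x$r2, x$adj_r2))
  cat(sprintf("  first two canonical axes explain %.1f%% of total variance\n",
              100 * sum(x$eigenvalues[seq_len(min(2, length(x$eigenvalues)))]) /
                x$total_variance))
  invisible(x)
}

#' Permutation test of RDA significance
#'
#' Pseudo-F = (SS_fit / m) / (SS_resid / (n - m - 1)); rows of Y are freely
#' permuted and p = (1 + #\{F* >= F\}) / (1 + n_perm).
#'
#' @inheritParams rda_fit
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return List with `statistic` (pseudo-F), `p`, `n_perm`.
#' @export
rda_permutation_test <- function(Y, X, n_perm = 1000, seed = 1L,
                                 id_col = "composite_id") {
  if (n_perm < 1) abort("`n_perm` must be >= 1.", class = "mfsoil_config")
  a <- align_yx(Y, X, id_col)
  Yc <- center_cols(a$Y)
  Xc <- center_cols(a$X)
  n <- nrow(Yc); m <- qr(Xc)$rank
  qrx <- qr(Xc)
  pseudo_f <- function(Ym) {
    fit <- qr.fitted(qrx, Ym)
    ssf <- sum(fit^2)
    (ssf / m) / ((sum(Ym^2) - ssf) / (n - m - 1))
  }
  f_obs <- pseudo_f(Yc)
  f_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) pseudo_f(Yc[sample.int(n), ,
                                                    drop = FALSE]),
           numeric(1))
  })
  list(statistic = f_obs,
       p = (1 + sum(f_null >= f_obs)) / (1 + n_perm),
       n_perm = n_perm)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j) from regressing predictor j on the remaining
#' predictors; perfectly collinear predictors are flagged `Inf` rather than
#' raising an error.
#'
#' @param X Matrix or tibble of predictors.
#' @param id_col Sample id column for tibble input.
#' @return Named numeric vector of VIFs (all >= 1, or `Inf`).
#' @export
vif_scores <- function(X, id_col = "composite_id") {
  if (is.data.frame(X)) X <- df_to_matrix(X, id_col)
  m <- ncol(X)
  if (m == 1) return(setNames(1, colnames(X)))
  Xc <- center_cols(X)
  out <- vapply(seq_len(m), function(j) {
    y <- Xc[, j]
    Z <- Xc[, -j, drop = FALSE]
    fit <- qr.fitted(qr(Z), y)
    ss_tot <- sum(y^2)
    if (ss_tot == 0) return(Inf)
    r2 <- sum(fit^2) / ss_tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, colnames(X))
}

# marginal permutation test of one candidate conditioned on selected set:
# Y and x are residualized on Z (partial RDA), then freely permuted
marginal_test <- function(Y, x, Z, n_perm, seed) {
  if (is.null(Z) || ncol(Z) == 0) {
    rda_permutation_test(Y, x, n_perm, seed)
  } else {
    Yr <- residualize(Y, Z)
    xr <- residualize(x, Z)
    rda_permutation_test(Yr, xr, n_perm, seed)
  }
}

#' Forward selection of explanatory variables (double stopping)
#'
#' The parsimonious constrained model: selection runs only if the global
#' model (all candidates) is significant at `alpha`; at each step the
#' candidate adding the most R2 is admitted only if its marginal
#' permutation p-value (conditioned on the already-selected variables via
#' partial RDA) is <= `alpha` and the cumulative adjusted R2 does not
#' exceed the global model's adjusted R2. Selection stops when either rule
#' fails.
#'
#' @inheritParams rda_fit
#' @param alpha Significance level for the global and marginal tests.
#' @param n_perm Permutations per test.
#' @param seed Integer seed.
#' @return List with `selected` (tibble `variable`, `order`, `added_r2`,
#'   `cum_adj_r2`, `p`), `global` (R2, adjusted R2, p), and `model` (the
#'   [rda_fit()] of the selected variables, or `NULL` if none).
#' @export
forward_select <- function(Y, X, alpha = 0.05, n_perm = 1000, seed = 1L,
                           id_col = "composite_id") {
  a <- align_yx(Y, X, id_col)
  if (ncol(a$X) == 0) abort("empty candidate set.", class = "mfsoil_config")
  seeds <- child_seeds(seed, 1 + ncol(a$X))
  glob_fit <- rda_fit(a$Y, a$X)
  glob_p <- rda_permutation_test(a$Y, a$X, n_perm, seeds[1])$p
  global <- list(r2 = glob_fit$r2, adj_r2 = glob_fit$adj_r2, p = glob_p)
  sel <- character(0)
  steps <- list()
  if (glob_p <= alpha) {
    remaining <- colnames(a$X)
    repeat {
      if (length(remaining) == 0) break
      r2_now <- if (length(sel) == 0) 0 else
        rda_fit(a$Y, a$X[, sel, drop = FALSE])$r2
      added <- vapply(remaining, function(v) {
        rda_fit(a$Y, a$X[, c(sel, v), drop = FALSE])$r2 - r2_now
      }, numeric(1))
      best <- remaining[which.max(added)]
      cand <- c(sel, best)
      adj_cand <- rda_fit(a$Y, a$X[, cand, drop = FALSE])$adj_r2
      Z <- if (length(sel)) a$X[, sel, drop = FALSE] else NULL
      p_best <- marginal_test(a$Y, a$X[, best, drop = FALSE], Z, n_perm,
                              seeds[1 + length(sel) + 1])$p
      if (p_best > alpha || adj_cand > global$adj_r2) break
      sel <- cand
      remaining <- setdiff(remaining, best)
      steps[[length(steps) + 1]] <- tibble(
        variable = best, order = length(sel),
        added_r2 = unname(added[best]), cum_adj_r2 = adj_cand, p = p_best
      )
    }
  }
  list(
    selected = if (length(steps)) bind_rows(steps) else
      tibble(variable = character(), order = integer(),
             added_r2 = numeric(), cum_adj_r2 = numeric(), p = numeric()),
    global = global,
    model = if (length(sel)) rda_fit(a$Y, a$X[, sel, drop = FALSE]) else NULL
  )
}

#' OTUs with extreme positions in the canonical plane
#'
#' The k species (OTUs) whose score vectors in the first two canonical axes
#' are longest -- the ones a triplot would display. Ties are broken by
#' identifier order.
#'
#' @param result A `soil_rda` object.
#' @param k Number of OTUs to return (default 14).
#' @return Character vector of OTU ids, by decreasing score length.
#' @export
extreme_otus <- function(result, k = 14) {
  stopifnot(inherits(result, "soil_rda"))
  s <- result$species_scores
  if (k > nrow(s)) abort("k exceeds the number of OTUs.",
                         class = "mfsoil_config")
  plane <- s[, seq_len(min(2, ncol(s))), drop = FALSE]
  len <- sqrt(rowSums(plane^2))
  ord <- order(-len, rownames(s))
  rownames(s)[ord][seq_len(k)]
}
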