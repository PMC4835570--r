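toy_yx <- function(seed = 2, n = 15, q = 20, m = 3) {
  set.seed(seed)
  Y <- vegan::decostand(matrix(abs(rnorm(n * q)), n, q), "hellinger")
  X <- scale(matrix(rnorm(n * m), n, m))
  colnames(X) <- paste0("x", seq_len(m))
  colnames(Y) <- paste0("o", seq_len(q))
  rownames(Y) <- rownames(X) <- paste0("s", seq_len(n))
  list(Y = Y, X = X)
}

test_that("RDA matches the explicit regression-plus-principal-axes oracle", {
  set.seed(6)
  Y <- matrix(rnorm(6 * 4), 6, 4); X <- matrix(rnorm(12), 6, 2)
  rownames(Y) <- rownames(X) <- paste0("s", 1:6)
  colnames(Y) <- paste0("o", 1:4); colnames(X) <- c("a", "b")
  fit <- rda_fit(Y, X)

  # oracle: multivariate OLS then eigen of the fitted cross-product
  Yc <- scale(Y, scale = FALSE); Xc <- scale(X, scale = FALSE)
  B <- solve(crossprod(Xc)) %*% crossprod(Xc, Yc)
  Yhat <- Xc %*% B
  ev_oracle <- eigen(crossprod(Yhat) / (nrow(Y) - 1))$values
  ev_oracle <- ev_oracle[ev_oracle > 1e-10]
  expect_equal(fit$eigenvalues, ev_oracle, tolerance = 1e-9)
  expect_equal(fit$r2, sum(Yhat^2) / sum(Yc^2), tolerance = 1e-12)
})

test_that("RDA agrees with the reference implementation", {
  t <- toy_yx()
  fit <- rda_fit(t$Y, t$X)
  ref <- vegan::rda(t$Y ~ ., data = as.data.frame(t$X))
  expect_equal(fit$eigenvalues, unname(ref$CCA$eig), tolerance = 1e-9)
  expect_equal(fit$r2, vegan::RsquareAdj(ref)$r.squared, tolerance = 1e-9)
  expect_equal(fit$adj_r2, vegan::RsquareAdj(ref)$adj.r.squared,
               tolerance = 1e-9)
  expect_equal(unname(fit$vif), unname(vegan::vif.cca(ref)),
               tolerance = 1e-6)
})

test_that("variance partitions close and perfect fits reach R2 = 1", {
  for (s in 1:5) {
    t <- toy_yx(seed = s)
    fit <- rda_fit(t$Y, t$X)
    expect_equal(sum(fit$eigenvalues) + sum(fit$residual_eigenvalues),
                 fit$total_variance, tolerance = 1e-9)
    expect_true(fit$adj_r2 <= fit$r2)
    expect_true(all(fit$vif >= 1))
  }
  # noise-free construction: Y exactly in the span of X
  set.seed(3)
  X <- scale(matrix(rnorm(30), 15, 2)); colnames(X) <- c("a", "b")
  Y <- X %*% matrix(runif(2 * 6), 2, 6)
  rownames(Y) <- rownames(X) <- paste0("s", 1:15)
  colnames(Y) <- paste0("o", 1:6)
  expect_equal(rda_fit(Y, X)$r2, 1, tolerance = 1e-9)
})

test_that("VIF matches per-variable auxiliary regressions", {
  # Helmert contrasts: zero-sum, mutually orthogonal columns
  X <- stats::contr.helmert(5)
  colnames(X) <- paste0("x", 1:4); rownames(X) <- paste0("s", 1:5)
  expect_equal(unname(vif_scores(X)), rep(1, 4), tolerance = 1e-9)

  set.seed(8)
  Xc <- matrix(rnorm(30), 10, 3)
  Xc[, 3] <- Xc[, 1] * 0.9 + rnorm(10, 0, 0.3)
  colnames(Xc) <- c("a", "b", "c"); rownames(Xc) <- paste0("s", 1:10)
  v <- vif_scores(Xc)
  oracle <- vapply(1:3, function(j) {
    r2 <- summary(lm(Xc[, j] ~ Xc[, -j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(unname(v), oracle, tolerance = 1e-9)

  dup <- cbind(Xc, d = Xc[, 1])
  expect_true(is.infinite(vif_scores(dup)["a"]))
  expect_true(is.infinite(vif_scores(dup)["d"]))
})

test_that("permutation tests honour their conventions", {
  set.seed(3)
  X <- scale(matrix(rnorm(30), 15, 2)); colnames(X) <- c("a", "b")
  rownames(X) <- paste0("s", 1:15)
  Y <- X %*% matrix(runif(12), 2, 6) + matrix(rnorm(90, 0, 1e-3), 15, 6)
  rownames(Y) <- rownames(X); colnames(Y) <- paste0("o", 1:6)
  # planted strong association saturates at the minimum attainable p
  p <- rda_permutation_test(Y, X, n_perm = 199, seed = 4)
  expect_equal(p$p, 1 / 200)

  a <- rda_permutation_test(Y, X, n_perm = 99, seed = 7)
  b <- rda_permutation_test(Y, X, n_perm = 99, seed = 7)
  expect_identical(a, b)
  expect_error(rda_permutation_test(Y, X, n_perm = 0), class = "mfsoil_config")
  Ybad <- Y; rownames(Ybad)[1] <- "not-a-sample"
  expect_error(rda_fit(Ybad, X), class = "mfsoil_schema")
  expect_error(rda_fit(Y, cbind(X, a2 = X[, "a"])),
               class = "mfsoil_collinear")
})

test_that("forward selection recovers the generating variables", {
  set.seed(5)
  X <- scale(matrix(rnorm(15 * 4), 15, 4))
  colnames(X) <- c("pH", "CN", "sand", "noise")
  rownames(X) <- paste0("s", 1:15)
  B <- rbind(runif(20, -1, 1) * 2, runif(20, -1, 1) * 2, 0, 0)
  Y <- X %*% B + matrix(rnorm(300, 0, 0.5), 15, 20)
  rownames(Y) <- rownames(X); colnames(Y) <- paste0("o", 1:20)

  fs <- forward_select(Y, X, n_perm = 199, seed = 3)
  expect_setequal(fs$selected$variable, c("pH", "CN"))
  expect_equal(fs$selected$order, seq_len(nrow(fs$selected)))
  expect_true(all(diff(fs$selected$added_r2) <= 1e-12))
  # double-stopping invariant: cumulative adjusted R2 never beats the global
  expect_true(all(fs$selected$cum_adj_r2 <= fs$global$adj_r2 + 1e-12))

  # pure-noise response: the global gate closes the selection
  set.seed(9)
  Y0 <- matrix(rnorm(300), 15, 20)
  rownames(Y0) <- rownames(X); colnames(Y0) <- paste0("o", 1:20)
  fs0 <- forward_select(Y0, X, n_perm = 199, seed = 3)
  expect_equal(nrow(fs0$selected), 0)
  expect_gt(fs0$global$p, 0.05)

  # both candidates true: selection recovers both, ordered by added R2
  set.seed(21)
  X2 <- scale(matrix(rnorm(30), 15, 2)); colnames(X2) <- c("x1", "x2")
  rownames(X2) <- paste0("s", 1:15)
  Y2 <- X2 %*% rbind(runif(12, -2, 2), runif(12, -1, 1)) +
    matrix(rnorm(15 * 12, 0, 0.4), 15, 12)
  rownames(Y2) <- rownames(X2); colnames(Y2) <- paste0("o", 1:12)
  fs2 <- forward_select(Y2, X2, n_perm = 199, seed = 21)
  expect_setequal(fs2$selected$variable, c("x1", "x2"))
  expect_true(all(diff(fs2$selected$added_r2) <= 1e-12))
})

test_that("forward selection agrees with the reference double-stopping", {
  withr::local_package("vegan")
  # seed-by-seed parity with vegan::ordiR2step on signal-plus-noise designs
  for (s in 1:6) {
    set.seed(s)
    X1 <- scale(matrix(rnorm(30), 15, 2)); colnames(X1) <- c("sig", "noise")
    rownames(X1) <- paste0("s", 1:15)
    Ys <- X1[, 1, drop = FALSE] %*% t(runif(10, -2, 2)) +
      matrix(rnorm(150, 0, 0.4), 15, 10)
    rownames(Ys) <- rownames(X1); colnames(Ys) <- paste0("o", 1:10)
    df <- as.data.frame(X1)
    m0 <- vegan::rda(Ys ~ 1, data = df)
    m1 <- vegan::rda(Ys ~ ., data = df)
    set.seed(s)
    st <- vegan::ordiR2step(m0, scope = stats::formula(m1), trace = FALSE,
                            permutations = 199)
    ref <- attr(stats::terms(st), "term.labels")
    fss <- forward_select(Ys, X1, n_perm = 199, seed = s)
    expect_identical(fss$selected$variable, ref)
  }
})

test_that("extreme OTU ranking is a deterministic top-k by score length", {
  t <- toy_yx(seed = 12, q = 20)
  fit <- rda_fit(t$Y, t$X)
  all_ids <- extreme_otus(fit, k = 20)
  expect_setequal(all_ids, colnames(t$Y))

  s <- fit$species_scores[, 1:2]
  brute <- rownames(s)[order(-sqrt(rowSums(s^2)), rownames(s))]
  expect_identical(extreme_otus(fit, 14), brute[1:14])
  expect_error(extreme_otus(fit, 21), class = "mfsoil_config")

  td <- tidy(fit)
  expect_true(all(c("axis", "component", "eigenvalue") %in% names(td)))
  expect_equal(sum(td$prop_variance), 1, tolerance = 1e-9)
  expect_equal(glance(fit)$r2, fit$r2)
})
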