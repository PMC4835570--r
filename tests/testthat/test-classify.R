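make_z <- function(m, ids = paste0("s", seq_len(nrow(m)))) {
  rownames(m) <- ids
  if (is.null(colnames(m))) colnames(m) <- paste0("v", seq_len(ncol(m)))
  m
}

# four well-separated planted clusters over 10 variables, sizes 1/2/3/9
planted_z <- function(seed) {
  bg <- generate_biogeochem(seed = seed, params = uniform_treatment_params(),
                            class_assignment = default_class_assignment(),
                            class_effects = default_class_effects())
  bg
}

test_that("standardization centres and scales every variable", {
  df <- tibble::tibble(composite_id = c("a", "b", "c"), x = c(1, 2, 3),
                       y = c(10, 30, 20))
  z <- standardize_variables(df, c("x", "y"))
  expect_equal(z$x, c(-1, 0, 1))
  expect_equal(mean(z$y), 0, tolerance = 1e-12)
  expect_equal(sd(z$y), 1, tolerance = 1e-12)
  # idempotence
  z2 <- standardize_variables(z, c("x", "y"))
  expect_equal(z2$x, z$x, tolerance = 1e-12)

  const <- tibble::tibble(composite_id = c("a", "b"), x = c(1, 1))
  expect_error(standardize_variables(const, "x"), "x",
               class = "mfsoil_constant")

  set.seed(1)
  r <- tibble::tibble(composite_id = letters[1:8],
                      u = rnorm(8, 5, 3), w = runif(8))
  zr <- standardize_variables(r, c("u", "w"))
  expect_equal(zr$u, (r$u - mean(r$u)) / sd(r$u), tolerance = 1e-12)
})

test_that("UPGMA agrees with brute-force average linkage and hclust", {
  # two samples merge at their distance
  d2 <- dist(make_z(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)))
  t2 <- upgma_tree(d2)
  expect_equal(t2$height, 5)

  # 4-leaf toy against exhaustive recomputation
  d4 <- dist(make_z(matrix(c(0, 0, 1, 0, 5, 5, 6, 5), 4, byrow = TRUE)))
  t4 <- upgma_tree(d4)
  expect_equal(t4$height, brute_upgma_heights(d4), tolerance = 1e-12)

  # 6-leaf random toys: heights and cophenetic distances match both oracles
  for (s in 1:5) {
    set.seed(s)
    d6 <- dist(make_z(matrix(rnorm(18), 6, 3)))
    mine <- upgma_tree(d6)
    expect_equal(sort(mine$height), sort(brute_upgma_heights(d6)),
                 tolerance = 1e-9)
    ref <- stats::hclust(d6, method = "average")
    expect_equal(stats::cophenetic(mine), stats::cophenetic(ref),
                 tolerance = 1e-9)
  }
})

test_that("UPGMA heights are monotone and ties break deterministically", {
  for (s in 1:10) {
    set.seed(s)
    tr <- upgma_tree(dist(make_z(matrix(rnorm(40), 8, 5))))
    expect_true(all(diff(tr$height) >= -1e-12))
  }
  # equilateral triple: same heights whichever pair merges, smallest indices first
  eq <- matrix(0, 3, 3); eq[lower.tri(eq)] <- 1; eq <- eq + t(eq)
  rownames(eq) <- colnames(eq) <- c("a", "b", "c")
  tr <- upgma_tree(stats::as.dist(eq))
  expect_equal(tr$height, c(1, 1))
  expect_equal(tr$merge[1, ], c(-1L, -2L))
  expect_error(upgma_tree(stats::as.dist(matrix(0, 1, 1))),
               class = "mfsoil_schema")
})

test_that("SIMPROF follows its conventions and is seed-stable", {
  z <- make_z(matrix(rnorm(20), 2, 10))
  r <- simprof_test(z)
  expect_equal(r$p, 1)
  expect_false(r$tested)

  z15 <- make_z(matrix(rnorm(150), 15, 10))
  a <- simprof_test(z15, 99, 99, seed = 5)
  b <- simprof_test(z15, 99, 99, seed = 5)
  expect_identical(a, b)
  expect_gte(a$p, 1 / 100)  # +1 convention: p can never be 0

  # invariant to the order of the variables
  perm <- sample(ncol(z15))
  c <- simprof_test(z15[, perm], 99, 99, seed = 5)
  expect_equal(a$p, c$p)
  expect_equal(a$pi, c$pi)
})

test_that("strong two-cluster structure is detected", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    z <- make_z(rbind(matrix(rnorm(70), 7, 10),
                      matrix(rnorm(80, mean = 10), 8, 10)))
    simprof_test(z, 199, 199, seed = s)$p <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("class delineation recovers planted structure and ranks it", {
  bg <- planted_z(3)
  cl <- classify_multifunctional(bg, n_perm = 999, seed = 3)
  truth <- default_class_assignment()
  ari <- mfsoil:::adjusted_rand_index(
    cl$classes$class,
    truth$class[match(cl$classes$composite_id, truth$composite_id)])
  expect_equal(ari, 1)

  # the reference composites form the zero-distance, rank-1 class
  ref_class <- cl$classes$class[cl$classes$composite_id == "N-A"]
  rk <- cl$ranks[cl$ranks$class == ref_class, ]
  expect_equal(rk$distance_to_reference, 0, tolerance = 1e-12)
  expect_equal(rk$disturbance_rank, 1L)
  expect_true(all(diff(cl$tree$height) >= -1e-12))

  td <- tidy(cl)
  expect_equal(nrow(td), 15)
  expect_true(all(c("class", "disturbance_rank", "distance_to_reference")
                  %in% names(td)))
  g <- glance(cl)
  expect_equal(g$n_classes, 4)
})

test_that("homogeneous profiles collapse to a single class", {
  bg <- generate_biogeochem(seed = 41, params = uniform_treatment_params())
  cl <- classify_multifunctional(bg, n_perm = 999, seed = 41)
  expect_equal(nrow(cl$ranks), 1)
})

test_that("classification is invariant to variable order and rescaling", {
  bg <- planted_z(5)
  base <- classify_multifunctional(bg, n_perm = 199, seed = 5)
  vars <- soil_variables()
  set.seed(99)
  for (i in 1:5) {
    shuffled <- bg[, c("composite_id", "treatment", "block", "is_reference",
                       sample(vars))]
    # affine rescaling of two variables; standardization absorbs it
    shuffled$pH <- shuffled$pH * runif(1, 0.1, 10) + runif(1, -5, 5)
    shuffled$bacteria <- -2 * shuffled$bacteria
    alt <- classify_multifunctional(shuffled, n_perm = 199, seed = 5)
    expect_identical(alt$classes, base$classes)
  }
})

test_that("the internal agreement index matches the reference ARI", {
  set.seed(31)
  for (i in 1:5) {
    a <- sample(letters[1:4], 20, replace = TRUE)
    b <- sample(letters[1:3], 20, replace = TRUE)
    expect_equal(mfsoil:::adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(mfsoil:::adjusted_rand_index(1:5, 1:5), 1)
})

test_that("class ranking measures centroid distance to the reference", {
  z <- tibble::tibble(composite_id = paste0("s", 1:6),
                      x = c(0, 0, 0, 3, 3, 3), y = c(0, 0, 0, 4, 4, 4))
  classes <- tibble::tibble(composite_id = paste0("s", 1:6),
                            class = rep(c("I", "II"), each = 3))
  rk <- rank_classes(classes, z, reference_ids = paste0("s", 1:3))
  expect_equal(rk$distance_to_reference[rk$class == "I"], 0)
  expect_equal(rk$distance_to_reference[rk$class == "II"], 5)
  expect_error(rank_classes(classes, z, reference_ids = "nope"),
               class = "mfsoil_schema")
})

test_that("correlation PCA satisfies its identities", {
  expect_equal(equilibrium_radius(2, 10), sqrt(0.2), tolerance = 1e-12)
  expect_equal(equilibrium_radius(2, 10, sqrt = FALSE), 0.2)

  bg <- planted_z(7)
  z <- standardize_variables(bg)
  pc <- pca_screen(z)
  expect_equal(sum(pc$eigenvalues), 10, tolerance = 1e-9)
  expect_true(all(pc$eigenvalues >= -1e-12))
  expect_equal(pc$retained, pc$eigenvalues > mean(pc$eigenvalues))

  # axes match an independent SVD up to sign
  zm <- mfsoil:::z_matrix(z)
  sv <- svd(scale(zm, scale = FALSE))
  expect_equal(pc$eigenvalues, sv$d^2 / (nrow(zm) - 1), tolerance = 1e-9)
  for (k in 1:2) {
    v_mine <- unlist(pc$loadings[, paste0("PC", k)])
    expect_equal(min(max(abs(v_mine - sv$v[, k])),
                     max(abs(v_mine + sv$v[, k]))), 0, tolerance = 1e-9)
  }
  expect_error(pca_screen(zm[, 1, drop = FALSE]), class = "mfsoil_schema")

  td <- tidy(pc)
  expect_equal(nrow(td), 10)
  expect_equal(glance(pc)$equilibrium_radius, sqrt(0.2))
})

test_that("variable correlations match the textbook formula", {
  df <- tibble::tibble(composite_id = paste0("s", 1:10),
                       x = 1:10, y = 2 * (1:10), z = c(5, -5, rep(0, 8)))
  out <- correlate_variables(df, c("x", "y"), transforms = character(0))
  expect_equal(out$r[1], 1, tolerance = 1e-12)

  set.seed(2)
  df$w <- rnorm(10)
  out2 <- correlate_variables(df, c("x", "w"), transforms = character(0))
  expect_equal(out2$r[1], cor(df$x, df$w), tolerance = 1e-12)
  expect_equal(out2$p[1], cor.test(df$x, df$w)$p.value, tolerance = 1e-12)
  sw <- attr(out2, "shapiro")
  expect_equal(nrow(sw), 2)

  const <- tibble::tibble(composite_id = c("a", "b", "c"),
                          x = c(1, 1, 1), y = c(1, 2, 3))
  expect_error(correlate_variables(const, c("x", "y"),
                                   transforms = character(0)),
               class = "mfsoil_constant")
})

test_that("ANOVA screen reproduces hand-computed F ratios", {
  # equal group means with positive within-group variance: F = 0
  df <- tibble::tibble(composite_id = paste0("s", 1:8),
                       g = rep(c("a", "b"), each = 4),
                       x = c(1, 2, 3, 4, 4, 3, 2, 1))
  out <- anova_screen(df, groups = "g", variables = "x",
                      transforms = character(0))
  expect_equal(out$F, 0, tolerance = 1e-12)
  expect_equal(out$p, 1, tolerance = 1e-12)

  # two-group toy: F = MS_between / MS_within by hand
  y <- c(1, 2, 3, 7, 8, 9)
  g <- rep(c("a", "b"), each = 3)
  df2 <- tibble::tibble(composite_id = paste0("s", 1:6), g = g, x = y)
  out2 <- anova_screen(df2, groups = "g", variables = "x",
                       transforms = character(0))
  ms_b <- sum(3 * (tapply(y, g, mean) - mean(y))^2) / 1
  ms_w <- sum((y - ave(y, g))^2) / 4
  expect_equal(out2$F, ms_b / ms_w, tolerance = 1e-9)
  ph <- attr(out2, "posthoc")$x
  expect_true(is.matrix(ph))

  expect_error(anova_screen(df2[1:3, ], groups = "g", variables = "x"),
               class = "mfsoil_schema")
})

test_that("null treatments yield calibrated per-variable ANOVA rates", {
  ps <- unlist(lapply(1:30, function(s) {
    bg <- generate_biogeochem(seed = 700 + s,
                              params = uniform_treatment_params())
    anova_screen(bg)$p
  }))
  rate <- mean(ps <= 0.05)
  # 300 null p-values; binomial 3 sigma around 0.05 is about +/- 0.04
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.1)
})
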