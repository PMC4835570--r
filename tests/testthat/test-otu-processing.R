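test_that("library equalization conserves totals at the target depth", {
  tab <- toy_otu_table(matrix(c(50, 30, 20, 10, 80, 10, 0, 60, 40), 3,
                             byrow = TRUE))
  eq <- equalize_libraries(tab, depth = 50, seed = 1)
  expect_true(all(rowSums(eq[-1]) == 50))

  # depth equal to a sample's own size leaves its total unchanged
  eq2 <- equalize_libraries(tab, depth = 100, seed = 1)
  expect_true(all(rowSums(eq2[-1]) == 100))

  single <- toy_otu_table(matrix(c(10, 0), 1))
  expect_equal(unname(unlist(equalize_libraries(single, depth = 5,
                                                seed = 2)[-1])), c(5, 0))

  shallow <- toy_otu_table(matrix(c(10, 10, 2, 1), 2, byrow = TRUE))
  expect_error(equalize_libraries(shallow, depth = 10), "s2",
               class = "mfsoil_depth")
  dropped <- equalize_libraries(shallow, depth = 10, drop_shallow = TRUE)
  expect_equal(dropped$composite_id, "s1")
})

test_that("rarefaction is unbiased for OTU proportions", {
  tab <- toy_otu_table(matrix(c(60, 40), 1))
  props <- vapply(seq_len(500), function(s) {
    as.numeric(equalize_libraries(tab, depth = 20, seed = s)[[2]]) / 20
  }, numeric(1))
  # expected proportion 0.6; MC error ~ sqrt(0.6*0.4/20/500) ~ 0.005
  expect_lt(abs(mean(props) - 0.6), 0.02)
})

test_that("the rare-OTU filter applies the fractional count threshold", {
  expect_equal(rare_count_threshold(166040, 5e-5), 8)

  m <- matrix(c(7, 93, 8, 92, 5, 95), 3, byrow = TRUE)
  colnames(m) <- c("rare", "dominant")
  tab <- toy_otu_table(m)
  # threshold floor(0.08 * 100) = 8: kept only if >= 8 in some sample
  kept <- filter_rare_otus(tab, min_fraction = 0.08)
  expect_setequal(setdiff(names(kept), "composite_id"), c("rare", "dominant"))
  kept2 <- filter_rare_otus(tab, min_fraction = 0.09)
  expect_setequal(setdiff(names(kept2), "composite_id"), "dominant")

  # table-total reading: rare totals 20 >= 8
  kept3 <- filter_rare_otus(tab, min_fraction = 0.09, rule = "table_total")
  expect_setequal(setdiff(names(kept3), "composite_id"), c("rare", "dominant"))

  expect_identical(as.data.frame(filter_rare_otus(tab, min_fraction = 0)),
                   as.data.frame(tab))
  uneven <- toy_otu_table(matrix(c(10, 0, 5, 5, 3, 1), 3, byrow = TRUE))
  expect_error(filter_rare_otus(uneven), class = "mfsoil_depth")
})

test_that("Hellinger transform yields unit-norm rows", {
  tab <- toy_otu_table(matrix(c(4, 0, 1, 1), 2, byrow = TRUE))
  h <- hellinger_transform(tab)
  expect_equal(unname(unlist(h[1, -1])), c(1, 0))
  expect_equal(unname(unlist(h[2, -1])), rep(1 / sqrt(2), 2))

  set.seed(7)
  big <- toy_otu_table(matrix(rpois(200, 5), 10))
  hb <- as.matrix(hellinger_transform(big)[-1])
  expect_equal(unname(rowSums(hb^2)), rep(1, 10), tolerance = 1e-12)
  # against the defining formula
  raw <- as.matrix(big[-1])
  expect_equal(unname(hb), unname(sqrt(raw / rowSums(raw))), tolerance = 1e-12)
  # Euclidean distances between unit-norm rows are bounded by sqrt(2)
  expect_lte(max(dist(hb)), sqrt(2) + 1e-12)

  zero <- toy_otu_table(matrix(c(1, 2, 0, 0), 2, byrow = TRUE))
  expect_error(hellinger_transform(zero), class = "mfsoil_schema")
})

test_that("Shannon index matches its formula", {
  expect_equal(shannon_index(rep(3, 17)), log(17), tolerance = 1e-12)
  expect_equal(shannon_index(c(0, 42, 0)), 0)
  p <- c(1, 2, 3) / 6
  expect_equal(shannon_index(c(1, 2, 3)), -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(shannon_index(c(1, 2, 3)), 1.0114, tolerance = 1e-4)
  expect_error(shannon_index(c(0, 0)), class = "mfsoil_diversity")
})

test_that("ACE estimator matches independent formula evaluation", {
  # no OTU at or below the rare cutoff
  expect_equal(ace_richness(c(20, 30, 40)), 3)
  # rare OTUs but no singletons: C_ACE = 1 and the gamma term vanishes
  expect_equal(ace_richness(c(2, 3, 50)), 3)

  set.seed(11)
  for (i in 1:5) {
    x <- c(rpois(40, 2), rpois(10, 60))
    x <- x[x > 0]
    expect_equal(ace_richness(x), brute_ace(x), tolerance = 1e-9)
    expect_gte(ace_richness(x), sum(x > 0))
  }
  # agreement with the reference implementation
  x <- c(rpois(50, 3), rpois(5, 100)); x <- x[x > 0]
  expect_equal(ace_richness(x),
               unname(vegan::estimateR(x)["S.ACE"]), tolerance = 1e-9)

  expect_warning(out <- ace_richness(c(1, 1, 1, 50)), "Chao1")
  expect_equal(out, 4 + 3 * 2 / 2)  # Chao1 with F1 = 3, F2 = 0
})

test_that("multivariate dispersion is a distance to group centroid", {
  m <- matrix(rep(c(1, 2), each = 9), 6, 3)
  rownames(m) <- paste0("s", 1:6)
  expect_warning(regexp = NA, {
    bd <- beta_dispersion(dist(m), rep(c("a", "b"), each = 3))
  })
  expect_equal(bd$distance, rep(0, 6), tolerance = 1e-12)

  set.seed(4)
  m2 <- matrix(rnorm(30), 10, 3)
  rownames(m2) <- paste0("s", 1:10)
  g <- rep(c("a", "b"), each = 5)
  bd2 <- beta_dispersion(dist(m2), g)
  direct <- vapply(seq_len(10), function(i) {
    sqrt(sum((m2[i, ] - colMeans(m2[g == g[i], , drop = FALSE]))^2))
  }, numeric(1))
  expect_equal(bd2$distance, direct, tolerance = 1e-9)

  # doubling one group's spread raises its mean dispersion
  m3 <- rbind(m2[1:5, ], m2[6:10, ] * 3)
  rownames(m3) <- paste0("s", 1:10)
  bd3 <- attr(beta_dispersion(dist(m3), g), "group_means")
  expect_gt(bd3$dispersion[bd3$group == "b"],
            bd3$dispersion[bd3$group == "a"])

  expect_warning(beta_dispersion(dist(m2), c("a", rep("b", 9))), "size 1")
})

test_that("taxonomy summaries are closed relative abundances", {
  m <- matrix(c(3, 1, 6, 2), 2, byrow = TRUE)
  colnames(m) <- c("o1", "o2")
  tab <- toy_otu_table(m)
  attr(tab, "taxonomy") <- tibble::tibble(
    otu_id = c("o1", "o2"),
    taxonomy = c("PhyA;ClA;OrA;FaA", "PhyB;ClB;OrB;FaB"))
  s <- summarize_taxonomy(tab, "phylum")
  expect_equal(sort(s$rel_abundance[s$composite_id == "s1"]), c(25, 75))
  tot <- tapply(s$rel_abundance, s$composite_id, sum)
  expect_equal(as.numeric(tot), rep(100, 2), tolerance = 1e-12)

  one <- tab
  attr(one, "taxonomy") <- tibble::tibble(
    otu_id = c("o1", "o2"), taxonomy = rep("PhyA;ClA;OrA;FaA", 2))
  so <- summarize_taxonomy(one, "phylum")
  expect_true(all(so$rel_abundance == 100))

  expect_error(summarize_taxonomy(toy_otu_table(m)), class = "mfsoil_schema")
})

test_that("ubiquitous OTU selection equals a brute-force scan", {
  set.seed(9)
  m <- matrix(rpois(80, 0.8), 8, 10)
  colnames(m) <- paste0("otu", 1:10)
  tab <- toy_otu_table(m)
  brute <- colnames(m)[apply(m > 0, 2, all)]
  expect_setequal(ubiquitous_otus(tab), brute)

  m2 <- matrix(1, 3, 2); m2[2, 1] <- 0
  colnames(m2) <- c("a", "b")
  expect_setequal(ubiquitous_otus(toy_otu_table(m2)), "b")
})

test_that("alpha diversity table covers every sample", {
  tab <- generate_otu_table(seed = 2,
                            community = planted_community(
                              n_otus = 100,
                              library_size_range = c(5000, 5000)))
  div <- alpha_diversity(tab)
  expect_equal(nrow(div), 15)
  expect_true(all(div$ace >= div$observed))
  expect_true(all(div$shannon > 0))
})
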