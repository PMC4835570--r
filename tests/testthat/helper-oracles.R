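# independent oracles used across tests; deliberately naive implementations

# UPGMA by exhaustive recomputation: cluster-pair heights are the plain mean
# of all cross-pair distances in the ORIGINAL matrix (equivalent to the
# Lance-Williams update, but derived independently of it)
brute_upgma_heights <- function(d) {
  D <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, 1, 2)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(D[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# textbook ACE evaluation, written from the formula, not the package code
brute_ace <- function(x, cutoff = 10) {
  x <- x[x > 0]
  rare <- x[x <= cutoff]
  if (length(rare) == 0) return(length(x))
  f <- sapply(seq_len(cutoff), function(i) sum(rare == i))
  n_rare <- sum(rare)
  c_ace <- 1 - f[1] / n_rare
  g2 <- max(length(rare) * sum(seq_len(cutoff) * (seq_len(cutoff) - 1) * f) /
              (c_ace * n_rare * (n_rare - 1)) - 1, 0)
  (length(x) - length(rare)) + length(rare) / c_ace + f[1] / c_ace * g2
}

# IndVal components by explicit loops
brute_indval <- function(m, cls, mode = "group_equalized") {
  classes <- sort(unique(cls))
  out <- sapply(seq_len(ncol(m)), function(j) {
    a_num <- sapply(classes, function(k) mean(m[cls == k, j]))
    A <- if (sum(a_num) == 0) rep(0, length(classes)) else a_num / sum(a_num)
    B <- sapply(classes, function(k) mean(m[cls == k, j] > 0))
    iv <- A * B
    if (mode == "group_equalized") iv <- sqrt(iv)
    max(iv)
  })
  out
}

toy_otu_table <- function(counts, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("otu", seq_len(ncol(counts)))
  }
  dplyr::bind_cols(tibble::tibble(composite_id = sample_ids),
                   tibble::as_tibble(counts))
}
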