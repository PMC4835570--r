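# internal helpers shared across modules

# one global seed expands to per-stage child seeds: set the parent seed, then
# draw k integers < 2^31 - 1; documented contract, relied on by run_pipeline()
child_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# evaluate expr with a locally-seeded RNG, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x)) {
    abort(sprintf("`%s` must be a positive integer (got %s).", name,
                  paste(format(x), collapse = ", ")),
          class = "mfsoil_invalid_design")
  }
  invisible(as.integer(x))
}

# adjusted Rand index between two labelings (Hubert & Arabie); used to score
# recovery of planted class structure. Cross-checked against mclust in tests.
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# numeric matrix out of a tibble: `id_col` becomes rownames, rest must be numeric
df_to_matrix <- function(data, id_col) {
  data <- as.data.frame(data)
  if (!id_col %in% names(data)) {
    abort(sprintf("column `%s` not found.", id_col), class = "mfsoil_schema")
  }
  ids <- as.character(data[[id_col]])
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicated ids in `%s`: %s", id_col,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "mfsoil_schema")
  }
  m <- as.matrix(data[setdiff(names(data), id_col)])
  if (!is.numeric(m)) abort("non-numeric value columns.", class = "mfsoil_schema")
  rownames(m) <- ids
  m
}

roman_labels <- function(n) as.character(utils::as.roman(seq_len(n)))
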