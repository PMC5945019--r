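# Shared fixtures, built in code and memoised for the session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# k Gaussian blobs with unit SD and given centers (rows)
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  d <- ncol(centers)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * d, sd = sd), ncol = d) +
      matrix(centers[i, ], n_per, d, byrow = TRUE)
  }))
  colnames(X) <- paste0("t", seq_len(d))
  list(m = trait_matrix(X), labels = rep(seq_len(nrow(centers)), each = n_per))
}

# adjusted Rand index between two partitions (closed-form from the
# contingency table; independent of any clustering code)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# small lab training set (full archetype panel, reduced n)
tiny_training <- function() {
  memo("tiny_training", generate_training(n_live = 400, n_other = 1200,
                                          seed = 12))
}

# small field series: 6 samples x 1200 particles
tiny_field <- function() {
  memo("tiny_field", generate_field_series(
    field_scenario(n_samples = 6, particles_per_sample = 1200, seed = 11)))
}

# reduced-size pipeline config for unit tests
tiny_config <- function(...) {
  sfcm_config(trees_importance = 501L, trees_classify = 201L,
              trees_biovolume = 501L, subset_size = 3600L,
              random_seed = 7L, ...)
}

tiny_cleaning <- function() {
  memo("tiny_cleaning",
       run_cleaning(tiny_field()$samples, tiny_training(), tiny_config()))
}

tiny_grouping <- function() {
  memo("tiny_grouping",
       run_grouping(tiny_field()$samples, tiny_cleaning(), tiny_training(),
                    tiny_config()))
}
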