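# Small fixture builders shared across test files. Everything is generated
# in code; no fixture files are stored.

# Linearly separable two-class data: feature 1 carries a wide class gap,
# the rest are low-variance noise.
separable_dataset <- function(n = 40, m = 3, gap = 6, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    x <- matrix(rnorm(n * m, sd = 0.25), n, m)
    x[, 1] <- x[, 1] + ifelse(y == 1L, gap / 2, -gap / 2)
    fs_dataset(x, y, positive = 1L)
  })
}

# Gaussian two-class data with no class signal at all.
null_dataset <- function(n = 100, m = 4, pos_fraction = 0.5, seed = 1) {
  withr::with_seed(seed, {
    n_pos <- round(n * pos_fraction)
    y <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
    fs_dataset(matrix(rnorm(n * m), n, m), y, positive = 1L)
  })
}

# Write a small delimited file and return its path.
write_toy_file <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

toy_schema <- function(...) {
  dataset_schema(label_column = "class", positive_label = "pos", ...)
}

# A normalized synthetic dataset plus its informative truth set.
synth_norm <- function(n = 300, m = 10, r = 3, delta = 2, seed = 1, ...) {
  sim <- generate_synthetic(synthetic_spec(n = n, m = m, r = r, delta = delta,
                                           seed = seed, ...))
  list(ds = normalize_features(sim$dataset)$train,
       informative = sim$informative)
}
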