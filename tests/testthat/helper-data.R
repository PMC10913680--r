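# Small deterministic fixtures built in code.

make_matrix <- function(n, p, seed = 1, prefix = "f") {
  set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(sprintf("S%02d", seq_len(n)),
                         paste0(prefix, seq_len(p))))
}

make_ds <- function(n, p, seed = 1, name = "X", prefix = "f") {
  omics_dataset(name, make_matrix(n, p, seed, prefix))
}

make_count_ds <- function(n, p, seed = 1, name = "asv", lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(n * p, lambda), n, p,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              paste0("asv", seq_len(p))))
  omics_dataset(name, m, is_microbiome = TRUE)
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# Two-class, single shared factor, strong planted effect: the recovery
# setting used throughout the tuning tests.
planted_two_class <- function(seed, p = 50, n_informative = 5,
                              strength = 3, n_per_class = 6) {
  spec <- synthetic_spec(
    classes = 2, n_per_class = n_per_class,
    blocks = list(synthetic_block("blk", p, "continuous",
                                  n_informative, strength)),
    shared_factors = 1, seed = seed
  )
  c(generate_multiomics(spec), list(spec = spec))
}

planted_three_block <- function(seed, p = 30, n_informative = 5,
                                strength = 3, classes = 2, n_per_class = 6) {
  spec <- synthetic_spec(
    classes = classes, n_per_class = n_per_class,
    blocks = list(
      synthetic_block("b1", p, "continuous", n_informative, strength),
      synthetic_block("b2", p, "continuous", n_informative, strength),
      synthetic_block("b3", p, "continuous", n_informative, strength)
    ),
    # equally spaced class means need K-1 simplex dimensions
    shared_factors = classes - 1, seed = seed
  )
  c(generate_multiomics(spec), list(spec = spec))
}

support_of <- function(model, block, ncomp = NULL) {
  L <- model$blocks[[block]]$loadings
  H <- ncomp %||% ncol(L)
  L <- L[, seq_len(H), drop = FALSE]
  rownames(L)[rowSums(abs(L) > 0) > 0]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
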