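# Seeded multi-block, multi-class data generator with planted latent
# structure, so every pipeline stage is testable without external data.

#' Describe one synthetic omics block
#'
#' @param name Block name.
#' @param p Number of features.
#' @param type `"continuous"` or `"counts"` (microbiome-like multinomial).
#' @param n_informative Number of features carrying the planted factors.
#' @param loading_strength Magnitude of the informative loadings; 0 removes
#'   all class signal from the block.
#' @param noise_sd Gaussian noise standard deviation for continuous blocks
#'   (count blocks draw their noise from the multinomial sampling itself).
#' @return A list describing the block.
#' @export
synthetic_block <- function(name, p, type = c("continuous", "counts"),
                            n_informative, loading_strength = 1,
                            noise_sd = 1) {
  type <- match.arg(type)
  stopifnot(n_informative >= 0, n_informative <= p,
            loading_strength >= 0, noise_sd >= 0)
  list(name = name, p = as.integer(p), type = type,
       n_informative = as.integer(n_informative),
       loading_strength = loading_strength, noise_sd = noise_sd)
}

#' Specify a synthetic multi-omics experiment
#'
#' Samples carry latent factors equal to their class mean (classes sit on the
#' vertices of a regular simplex with pairwise distance 2) plus standard
#' normal noise. Each block projects the factors through a sparse loading
#' matrix that is nonzero only on its informative features.
#'
#' @param classes Number of classes K.
#' @param n_per_class Samples per class.
#' @param blocks List of [synthetic_block()] descriptions.
#' @param shared_factors Dimension of the shared latent factors.
#' @param library_size Multinomial total per sample for count blocks.
#' @param seed Integer seed; every draw is derived from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(classes = 4L, n_per_class = 3L, blocks,
                           shared_factors = 1L, library_size = 50000L,
                           seed = 1L) {
  stopifnot(classes >= 2L, n_per_class >= 1L, length(blocks) >= 1L,
            shared_factors >= 1L, library_size >= 1L)
  names(blocks) <- vapply(blocks, `[[`, "", "name")
  structure(list(classes = as.integer(classes),
                 n_per_class = as.integer(n_per_class),
                 blocks = blocks,
                 shared_factors = as.integer(shared_factors),
                 library_size = as.integer(library_size),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Regular simplex vertex coordinates: K points, pairwise distance 2,
# embedded in `dims` dimensions (extra dimensions zero-padded, surplus
# simplex dimensions dropped).
simplex_means <- function(K, dims) {
  C <- diag(K) - 1 / K
  sv <- svd(C)
  coords <- sv$u[, seq_len(K - 1L), drop = FALSE] %*%
    diag(sv$d[seq_len(K - 1L)], K - 1L)
  coords <- coords / (sqrt(2) / 2)  # rescale pairwise distance sqrt(2) -> 2
  out <- matrix(0, K, dims)
  take <- min(dims, K - 1L)
  out[, seq_len(take)] <- coords[, seq_len(take), drop = FALSE]
  out
}

#' Planted informative feature ids per block
#'
#' Deterministic companion of [generate_multiomics()]: recomputes (from the
#' spec seed alone) which feature ids of each block carry the planted
#' factors.
#'
#' @param spec A [synthetic_spec()].
#' @return Named list of character vectors of feature ids.
#' @export
planted_truth <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  out <- lapply(seq_along(spec$blocks), function(k) {
    b <- spec$blocks[[k]]
    feats <- paste0(b$name, "_f", seq_len(b$p))
    if (b$n_informative == 0L) return(character(0))
    idx <- with_seed(spec$seed + 7919L * k,
                     sort(sample.int(b$p, b$n_informative)))
    feats[idx]
  })
  names(out) <- names(spec$blocks)
  out
}

#' Generate a synthetic multi-omics dataset
#'
#' Continuous blocks are `factors %*% t(loadings) + noise`; count blocks are
#' per-sample multinomial draws of `library_size` reads with probabilities
#' `softmax(factors %*% t(loadings))` and are flagged as microbiome blocks.
#' Identical seeds give bit-identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `datasets` (named list of [omics_dataset()]),
#'   `metadata` ([metadata_table()] with a default color scheme), `truth`
#'   (planted feature ids per block, as [planted_truth()]) and `factors`.
#' @export
generate_multiomics <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  K <- spec$classes
  n <- K * spec$n_per_class
  class_names <- paste0("C", seq_len(K))
  labels <- rep(class_names, each = spec$n_per_class)
  samples <- sprintf("S%02d", seq_len(n))
  means <- simplex_means(K, spec$shared_factors)
  truth <- planted_truth(spec)

  datasets <- vector("list", length(spec$blocks))
  names(datasets) <- names(spec$blocks)
  factors <- NULL
  with_seed(spec$seed, {
    class_part <- means[match(labels, class_names), , drop = FALSE]
    noise_part <- matrix(stats::rnorm(n * spec$shared_factors), n)
    factors <- class_part + noise_part
    for (k in seq_along(spec$blocks)) {
      b <- spec$blocks[[k]]
      feats <- paste0(b$name, "_f", seq_len(b$p))
      L <- matrix(0, b$p, spec$shared_factors)
      inf_idx <- match(truth[[b$name]], feats)
      if (length(inf_idx)) {
        L[inf_idx, ] <-
          sample(c(-1, 1), length(inf_idx) * spec$shared_factors,
                 replace = TRUE) *
          stats::runif(length(inf_idx) * spec$shared_factors, 0.75, 1.25)
      }
      # loading_strength scales the class separation seen by this block;
      # the shared factor noise stays at sd 1
      F_k <- b$loading_strength * class_part + noise_part
      eta <- tcrossprod(F_k, L)
      if (b$type == "continuous") {
        vals <- eta + b$noise_sd * matrix(stats::rnorm(n * b$p), n)
      } else {
        # heavy-tailed per-feature baseline abundances: amplicon tables have
        # a few dominant taxa and a long tail of rare ones
        baseline <- stats::rnorm(b$p, mean = 0, sd = 1.5)
        vals <- t(vapply(seq_len(n), function(i) {
          lg <- baseline + eta[i, ]
          pr <- exp(lg - max(lg))
          as.numeric(stats::rmultinom(1L, spec$library_size, pr / sum(pr)))
        }, numeric(b$p)))
      }
      dimnames(vals) <- list(samples, feats)
      datasets[[b$name]] <- omics_dataset(
        b$name, vals, is_microbiome = (b$type == "counts"),
        provenance = list(list(operation = "simulate",
                               parameters = list(seed = spec$seed)))
      )
    }
  })
  metadata <- metadata_table(
    stats::setNames(labels, samples),
    stats::setNames(default_palette(K), class_names)
  )
  list(datasets = datasets, metadata = metadata, truth = truth,
       factors = factors, labels = labels)
}

#' Case-study-shaped synthetic fixture
#'
#' A ready-made spec with 4 classes of 3 samples and four blocks shaped like
#' a typical targeted-metabolomics / 16S / ITS / transcriptomics experiment
#' (23, 779, 290 and 10,000 features). The planted informative feature
#' counts mirror feature-selection sizes typical of such studies.
#'
#' @param seed Integer seed.
#' @param loading_strength Shared effect size for all blocks (default 2).
#' @return A [synthetic_spec()].
#' @export
case_study_spec <- function(seed = 1L, loading_strength = 2) {
  synthetic_spec(
    classes = 4L, n_per_class = 3L,
    blocks = list(
      synthetic_block("metabolome", 23L, "continuous", 12L, loading_strength),
      synthetic_block("bact16S", 779L, "counts", 40L, loading_strength),
      synthetic_block("fungITS", 290L, "counts", 25L, loading_strength),
      synthetic_block("transcriptome", 10000L, "continuous", 16L,
                      loading_strength)
    ),
    shared_factors = 1L, library_size = 50000L, seed = seed
  )
}
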