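# Principal component analysis and its sparse variant.

new_latent_model <- function(algorithm, mode, ncomp, blocks, ...) {
  structure(
    c(list(algorithm = algorithm, mode = mode, ncomp = ncomp, blocks = blocks),
      list(...)),
    class = "latent_model"
  )
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("<latent_model %s> %d component(s), mode '%s'\n",
              x$algorithm, x$ncomp, x$mode))
  for (nm in names(x$blocks)) {
    b <- x$blocks[[nm]]
    cat(sprintf("  block '%s': %d features, keep = %s\n", nm,
                nrow(b$loadings), paste(b$keep, collapse = "/")))
  }
  invisible(x)
}

as_block <- function(x, default_name = "X") {
  if (inherits(x, "omics_dataset")) {
    list(name = x$name, values = x$values)
  } else {
    m <- as.matrix(x)
    if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
    list(name = default_name, values = m)
  }
}

#' Principal component analysis
#'
#' Columns are centered (and unit-variance scaled by default) and decomposed
#' by singular values. The full explained-variance spectrum over all
#' `min(n-1, p)` components is retained so the 80 percent component rule can
#' be applied afterwards.
#'
#' @param ds An [omics_dataset()] or numeric matrix (samples x features).
#' @param ncomp Number of components, at most `min(n-1, p)`.
#' @param center,scale Column standardization flags (both default `TRUE`).
#' @return A `latent_model` with scores, unit-norm loadings,
#'   `explained_variance` (first `ncomp` shares) and
#'   `explained_variance_full`.
#' @export
fit_pca <- function(ds, ncomp, center = TRUE, scale = TRUE) {
  blk <- as_block(ds)
  n <- nrow(blk$values); p <- ncol(blk$values)
  maxcomp <- min(n - 1L, p)
  if (ncomp < 1L || ncomp > maxcomp) {
    stop("ncomp must be in [1, ", maxcomp, "]", call. = FALSE)
  }
  std <- withCallingHandlers(
    standardize(blk$values, center, scale, dataset = blk$name),
    omiclink_tunable_failure = function(e) e  # plain error is fine here
  )
  sv <- svd(std$X)
  ev_full <- (sv$d^2 / sum(sv$d^2))[seq_len(maxcomp)]
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  flips <- apply(loadings, 2L, sign_flip)
  loadings <- sweep(loadings, 2L, flips, "*")
  scores <- std$X %*% loadings
  dimnames(loadings) <- list(colnames(std$X), paste0("comp", seq_len(ncomp)))
  dimnames(scores) <- list(rownames(std$X), colnames(loadings))
  block <- list(name = blk$name, data = std$X, scores = scores,
                loadings = loadings, defl = loadings,
                keep = rep(p, ncomp), center = std$center, scale = std$scale)
  new_latent_model(
    "pca", "unsupervised", ncomp,
    stats::setNames(list(block), blk$name),
    explained_variance = ev_full[seq_len(ncomp)],
    explained_variance_full = ev_full
  )
}

# One sparse rank-one step: regularized power iteration on the residual
# matrix, soft-thresholding the feature weights to exactly `keep` nonzeros.
spca_component <- function(X, keep, tol, max_iter, dataset) {
  v <- svd(X, nu = 0L, nv = 1L)$v[, 1L]
  for (it in seq_len(max_iter)) {
    u <- unit_norm(as.vector(X %*% v), dataset)
    w <- as.vector(crossprod(X, u))
    w <- soft_threshold_keep(w, keep)
    v_new <- unit_norm(w, dataset)
    delta <- max(abs(v_new - v))
    v <- v_new
    if (delta < tol) break
  }
  list(v = v, t = as.vector(X %*% v), iters = it)
}

#' Sparse principal component analysis
#'
#' Iterative soft-thresholded power iteration: each component starts from the
#' leading right singular vector of the current residual, alternates
#' `u <- Xv/||Xv||`, `w <- X'u` soft-thresholded to exactly `keep[h]`
#' nonzeros, `v <- w/||w||` until the maximum absolute loading change falls
#' below `tol`, then deflates `X <- X - t v'` with `t = Xv`. With
#' `keep = p` the thresholding is inactive and the loadings match dense PCA
#' up to column sign.
#'
#' @inheritParams fit_pca
#' @param keep Integer vector (recycled to `ncomp`): number of nonzero
#'   loadings allowed per component.
#' @param tol,max_iter Convergence control.
#' @return A `latent_model` of algorithm `"spca"`.
#' @export
fit_spca <- function(ds, ncomp, keep, center = TRUE, scale = TRUE,
                     tol = 1e-9, max_iter = 500L) {
  blk <- as_block(ds)
  n <- nrow(blk$values); p <- ncol(blk$values)
  if (ncomp < 1L || ncomp > min(n - 1L, p)) {
    stop("ncomp must be in [1, ", min(n - 1L, p), "]", call. = FALSE)
  }
  keep <- rep_len(as.integer(keep), ncomp)
  if (any(keep < 1L | keep > p)) {
    stop("keep values must be in [1, ", p, "]", call. = FALSE)
  }
  std <- standardize(blk$values, center, scale, dataset = blk$name)
  X0 <- std$X
  Xc <- X0
  total_ss <- sum(X0^2)
  loadings <- matrix(0, p, ncomp, dimnames = list(colnames(X0),
                                                  paste0("comp", seq_len(ncomp))))
  scores <- matrix(0, n, ncomp, dimnames = list(rownames(X0),
                                                colnames(loadings)))
  expl <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    cmp <- spca_component(Xc, keep[h], tol, max_iter, blk$name)
    f <- sign_flip(cmp$v)
    v <- f * cmp$v; t <- f * cmp$t
    loadings[, h] <- v
    scores[, h] <- t
    expl[h] <- sum(t^2) / total_ss
    Xc <- Xc - tcrossprod(t, v)
  }
  block <- list(name = blk$name, data = X0, scores = scores,
                loadings = loadings, defl = loadings, keep = keep,
                center = std$center, scale = std$scale)
  new_latent_model(
    "spca", "unsupervised", ncomp,
    stats::setNames(list(block), blk$name),
    explained_variance = expl
  )
}
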