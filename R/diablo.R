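# Supervised multiblock sparse PLS-DA (DIABLO-style integration).

#' Construct a block design matrix
#'
#' Symmetric matrix of weights in `[0, 1]` with zero diagonal specifying how
#' strongly each pair of blocks is forced to covary.
#'
#' @param block_names Ordered character vector of block names.
#' @param values Symmetric numeric matrix (or a single scalar filling every
#'   off-diagonal cell).
#' @return An object of class `design_matrix`.
#' @export
design_matrix <- function(block_names, values) {
  k <- length(block_names)
  if (length(values) == 1L) {
    values <- matrix(values, k, k)
  }
  values <- as.matrix(values)
  diag(values) <- 0
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-12))) {
    stop("design matrix must be symmetric", call. = FALSE)
  }
  if (any(values < 0 | values > 1)) {
    stop("design entries must lie in [0, 1]", call. = FALSE)
  }
  dimnames(values) <- list(block_names, block_names)
  structure(list(block_names = block_names, values = values),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix>\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Multiblock sparse PLS-DA (DIABLO)
#'
#' The dummy-coded class matrix enters as an extra block connected to every
#' data block with weight 1. Per component, block-coordinate ascent maximizes
#' the design-weighted sum of score covariances
#' `sum_{k<j} c_kj cov(X_k a_k, X_j a_j)`, soft-thresholding each data-block
#' loading to `keep[[k]][h]` nonzeros (the class block is never sparsified).
#' Each block is deflated on its own scores.
#'
#' @param blocks Named list of [omics_dataset()] objects (or matrices)
#'   sharing samples in the same order.
#' @param labels Class labels, one per sample.
#' @param ncomp Number of components.
#' @param design A [design_matrix()], or a scalar in `[0, 1]` applied to all
#'   block pairs.
#' @param keep Named list (per block) of integer vectors (per component), or
#'   `NULL` for dense fits.
#' @param center,scale,tol,max_iter As in [fit_spls()].
#' @return A discriminant `latent_model` (algorithm `"diablo"`).
#' @export
fit_diablo <- function(blocks, labels, ncomp, design, keep = NULL,
                       center = TRUE, scale = TRUE,
                       tol = 1e-9, max_iter = 500L) {
  if (length(blocks) < 1L) stop("need at least one block", call. = FALSE)
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    names(blocks) <- vapply(seq_along(blocks), function(i) {
      b <- blocks[[i]]
      if (inherits(b, "omics_dataset")) b$name else paste0("block", i)
    }, "")
  }
  bnames <- names(blocks)
  raw <- lapply(blocks, function(b) as_block(b)$values)
  rn <- rownames(raw[[1L]])
  for (m in raw) {
    if (!identical(rownames(m), rn)) {
      stop("all blocks must share the same samples in the same order",
           call. = FALSE)
    }
  }
  labels <- as.character(labels)
  if (length(labels) != length(rn)) {
    stop("labels length must equal the number of samples", call. = FALSE)
  }
  dummy <- dummy_code(labels)
  rownames(dummy) <- rn
  K <- length(raw)

  if (inherits(design, "design_matrix")) {
    if (!identical(design$block_names, bnames)) {
      dm <- design$values
      if (!all(bnames %in% rownames(dm))) {
        stop("design matrix block names do not match the blocks",
             call. = FALSE)
      }
      design <- design_matrix(bnames, dm[bnames, bnames])
    }
  } else if (is.numeric(design) && length(design) == 1L) {
    design <- design_matrix(bnames, design)
  } else {
    stop("design must be a design_matrix or a scalar in [0, 1]",
         call. = FALSE)
  }
  # full design includes the class block, connected to every data block
  C <- matrix(1, K + 1L, K + 1L)
  C[seq_len(K), seq_len(K)] <- design$values
  diag(C) <- 0

  std <- lapply(bnames, function(nm) standardize(raw[[nm]], center, scale,
                                                 dataset = nm))
  names(std) <- bnames
  sy <- standardize(dummy, center, scale, dataset = ".class")
  X0 <- lapply(std, `[[`, "X")
  Y0 <- sy$X
  Xc <- X0; Yc <- Y0
  n <- length(rn)
  ps <- vapply(X0, ncol, 1L)
  if (is.null(keep)) keep <- lapply(ps, function(p) rep(p, ncomp))
  keep <- lapply(bnames, function(nm) {
    k <- rep_len(as.integer(keep[[nm]] %||% ps[[nm]]), ncomp)
    if (any(k < 1L | k > ps[[nm]])) {
      stop("keep for block '", nm, "' out of [1, p]", call. = FALSE)
    }
    k
  })
  names(keep) <- bnames

  comp_names <- paste0("comp", seq_len(ncomp))
  A <- lapply(bnames, function(nm)
    matrix(0, ps[[nm]], ncomp, dimnames = list(colnames(X0[[nm]]), comp_names)))
  names(A) <- bnames
  P <- A
  Tm <- lapply(bnames, function(nm)
    matrix(0, n, ncomp, dimnames = list(rn, comp_names)))
  names(Tm) <- bnames
  Qk <- lapply(bnames, function(nm)
    matrix(0, ncol(Y0), ncomp, dimnames = list(colnames(Y0), comp_names)))
  names(Qk) <- bnames
  B <- matrix(0, ncol(Y0), ncomp, dimnames = list(colnames(Y0), comp_names))
  U <- matrix(0, n, ncomp, dimnames = list(rn, comp_names))

  for (h in seq_len(ncomp)) {
    # The centered dummy block has rank K-1; once exhausted by deflation its
    # updates collapse to zero and later components are driven purely by the
    # inter-block covariances (the class block drops out instead of failing).
    y_active <- sqrt(sum(Yc^2)) > 1e-9
    if (!y_active && K == 1L) {
      stop("ncomp exceeds the class-block rank (", ncol(Y0) - 1L,
           ") for a single-block model", call. = FALSE)
    }
    a <- lapply(bnames, function(nm) {
      M <- if (y_active) crossprod(Xc[[nm]], Yc) else
        crossprod(Xc[[nm]], Reduce(cbind, Xc[bnames != nm]))
      svd(M, nu = 1L, nv = 0L)$u[, 1L]
    })
    names(a) <- bnames
    t <- lapply(bnames, function(nm) as.vector(Xc[[nm]] %*% a[[nm]]))
    if (y_active) {
      b <- unit_norm(as.vector(crossprod(Yc, Reduce(`+`, t))), ".class")
      u <- as.vector(Yc %*% b)
    } else {
      b <- numeric(ncol(Y0))
      u <- numeric(n)
    }
    for (it in seq_len(max_iter)) {
      delta <- 0
      for (k in seq_len(K)) {
        nm <- bnames[k]
        w <- numeric(ps[[nm]])
        for (j in seq_len(K)) {
          if (j != k && C[k, j] > 0) {
            w <- w + C[k, j] * as.vector(crossprod(Xc[[nm]], t[[j]]))
          }
        }
        if (C[k, K + 1L] > 0) {
          w <- w + C[k, K + 1L] * as.vector(crossprod(Xc[[nm]], u))
        }
        w <- unit_norm(soft_threshold_keep(w, keep[[nm]][h]), nm)
        delta <- max(delta, max(abs(w - a[[nm]])))
        a[[nm]] <- w
        t[[nm]] <- as.vector(Xc[[nm]] %*% w)
      }
      if (y_active) {
        wy <- numeric(ncol(Y0))
        for (k in seq_len(K)) {
          if (C[K + 1L, k] > 0) {
            wy <- wy + C[K + 1L, k] * as.vector(crossprod(Yc, t[[k]]))
          }
        }
        wy <- unit_norm(wy, ".class")
        delta <- max(delta, max(abs(wy - b)))
        b <- wy
        u <- as.vector(Yc %*% b)
      }
      if (delta < tol) break
      # at max_iter the current iterate is kept (see spls_component note)
    }
    for (k in seq_len(K)) {
      nm <- bnames[k]
      f <- sign_flip(a[[nm]])
      a[[nm]] <- f * a[[nm]]; t[[nm]] <- f * t[[nm]]
      A[[nm]][, h] <- a[[nm]]
      Tm[[nm]][, h] <- t[[nm]]
      Qk[[nm]][, h] <- as.vector(crossprod(Yc, t[[nm]])) / sum(t[[nm]]^2)
      cvec <- as.vector(crossprod(Xc[[nm]], t[[nm]])) / sum(t[[nm]]^2)
      P[[nm]][, h] <- cvec
      Xc[[nm]] <- Xc[[nm]] - tcrossprod(t[[nm]], cvec)
    }
    if (y_active) {
      fb <- sign_flip(b)
      b <- fb * b; u <- fb * u
      evec <- as.vector(crossprod(Yc, u)) / sum(u^2)
      Yc <- Yc - tcrossprod(u, evec)
    }
    B[, h] <- b; U[, h] <- u
  }

  model_blocks <- lapply(bnames, function(nm) {
    list(name = nm, data = X0[[nm]], scores = Tm[[nm]], loadings = A[[nm]],
         defl = P[[nm]], q = Qk[[nm]], keep = keep[[nm]],
         center = std[[nm]]$center, scale = std[[nm]]$scale)
  })
  names(model_blocks) <- bnames

  new_latent_model("diablo", "discriminant", ncomp, model_blocks,
                   block_names = bnames,
                   design = design,
                   class_labels = colnames(dummy),
                   labels = labels,
                   dummy_Y = dummy,
                   y_scores = U, y_loadings = B,
                   y_center = sy$center, y_scale = sy$scale)
}
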