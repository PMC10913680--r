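# Sparse partial least squares (regression and canonical mode) and its
# discriminant wrapper.

#' One-hot dummy coding of class labels
#'
#' @param labels Vector or factor with at least two classes.
#' @return An n x K indicator matrix; column order is the sorted class
#'   labels, every row sums to 1.
#' @export
dummy_code <- function(labels) {
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 2L) stop("need at least two classes", call. = FALSE)
  m <- outer(labels, cls, `==`) * 1
  dimnames(m) <- list(names(labels) %||% seq_along(labels), cls)
  m
}

# Sparse NIPALS inner loop for one component of a two-block model. With
# aggressive sparsity on tiny sample sets the alternation can cycle between
# competing supports; after max_iter the current iterate is returned with
# converged = FALSE (any such point is a reasonable stationary solution and
# the choice is deterministic), matching common PLS implementations.
spls_component <- function(X, Y, keepX, keepY, tol, max_iter,
                           xname = "X", yname = "Y") {
  M <- crossprod(X, Y)
  b0 <- svd(M, nu = 0L, nv = 1L)$v[, 1L]
  u <- as.vector(Y %*% b0)
  a <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    a_new <- as.vector(crossprod(X, u))
    a_new <- unit_norm(soft_threshold_keep(a_new, keepX), xname)
    t <- as.vector(X %*% a_new)
    b <- as.vector(crossprod(Y, t))
    b <- unit_norm(soft_threshold_keep(b, keepY), yname)
    u <- as.vector(Y %*% b)
    if (!is.null(a) && max(abs(a_new - a)) < tol) {
      a <- a_new
      converged <- TRUE
      break
    }
    a <- a_new
  }
  list(a = a, b = b, t = as.vector(X %*% a), u = u, iters = it,
       converged = converged)
}

#' Sparse partial least squares for two blocks
#'
#' NIPALS with per-component soft-thresholding of both loading vectors to
#' exactly `keepX[h]` / `keepY[h]` nonzeros. Both blocks are column-centered
#' and unit-variance scaled before fitting. In `regression` mode both blocks
#' are deflated on the X-scores (Y is residualized against X, so swapping the
#' datasets changes the result); in `canonical` mode each block is deflated
#' on its own scores. With full `keepX`/`keepY` and `ncomp = 1` the loading
#' pair equals the leading singular-vector pair of `X'Y` up to sign.
#'
#' @param X,Y [omics_dataset()] objects or numeric matrices sharing the same
#'   samples in the same order.
#' @param ncomp Number of components.
#' @param keepX,keepY Nonzero-loading budgets per component (recycled;
#'   default: all features).
#' @param mode `"regression"` or `"canonical"`.
#' @param center,scale Column standardization flags.
#' @param tol,max_iter Convergence control; if `max_iter` is reached the
#'   current iterate is returned (per-component iteration counts are stored
#'   in `iters`). Zero-variance columns raise a tunable failure consumed by
#'   [nzv_repair()].
#' @return A `latent_model` with one block per dataset, each holding scores,
#'   loadings, deflation loadings and the standardization parameters.
#' @export
fit_spls <- function(X, Y, ncomp, keepX = NULL, keepY = NULL,
                     mode = c("regression", "canonical"),
                     center = TRUE, scale = TRUE,
                     tol = 1e-9, max_iter = 500L) {
  mode <- match.arg(mode)
  bx <- as_block(X, "X")
  by <- as_block(Y, "Y")
  if (!identical(rownames(bx$values), rownames(by$values))) {
    stop("X and Y must share the same samples in the same order ",
         "(see harmonize())", call. = FALSE)
  }
  n <- nrow(bx$values)
  p <- ncol(bx$values); q <- ncol(by$values)
  keepX <- rep_len(as.integer(keepX %||% p), ncomp)
  keepY <- rep_len(as.integer(keepY %||% q), ncomp)
  if (any(keepX < 1L | keepX > p)) stop("keepX out of [1, p]", call. = FALSE)
  if (any(keepY < 1L | keepY > q)) stop("keepY out of [1, q]", call. = FALSE)

  sx <- standardize(bx$values, center, scale, dataset = bx$name)
  sy <- standardize(by$values, center, scale, dataset = by$name)
  X0 <- sx$X; Y0 <- sy$X
  Xc <- X0; Yc <- Y0

  comp_names <- paste0("comp", seq_len(ncomp))
  A <- matrix(0, p, ncomp, dimnames = list(colnames(X0), comp_names))
  B <- matrix(0, q, ncomp, dimnames = list(colnames(Y0), comp_names))
  Tm <- matrix(0, n, ncomp, dimnames = list(rownames(X0), comp_names))
  U <- matrix(0, n, ncomp, dimnames = list(rownames(Y0), comp_names))
  P <- matrix(0, p, ncomp, dimnames = dimnames(A))  # X deflation loadings
  Q <- matrix(0, q, ncomp, dimnames = dimnames(B))  # Y deflation loadings
  iters <- integer(ncomp)

  for (h in seq_len(ncomp)) {
    cmp <- spls_component(Xc, Yc, keepX[h], keepY[h], tol, max_iter,
                          bx$name, by$name)
    fa <- sign_flip(cmp$a); fb <- sign_flip(cmp$b)
    a <- fa * cmp$a; t <- fa * cmp$t
    b <- fb * cmp$b; u <- fb * cmp$u
    A[, h] <- a; B[, h] <- b; Tm[, h] <- t; U[, h] <- u
    iters[h] <- cmp$iters
    cvec <- as.vector(crossprod(Xc, t)) / sum(t^2)
    P[, h] <- cvec
    Xc <- Xc - tcrossprod(t, cvec)
    if (mode == "regression") {
      dvec <- as.vector(crossprod(Yc, t)) / sum(t^2)
      Q[, h] <- dvec
      Yc <- Yc - tcrossprod(t, dvec)
    } else {
      evec <- as.vector(crossprod(Yc, u)) / sum(u^2)
      Q[, h] <- evec
      Yc <- Yc - tcrossprod(u, evec)
    }
  }

  blocks <- stats::setNames(list(
    list(name = bx$name, data = X0, scores = Tm, loadings = A, defl = P,
         keep = keepX, center = sx$center, scale = sx$scale),
    list(name = by$name, data = Y0, scores = U, loadings = B, defl = Q,
         keep = keepY, center = sy$center, scale = sy$scale)
  ), c(bx$name, by$name))

  new_latent_model("spls", mode, ncomp, blocks,
                   x_name = bx$name, y_name = by$name, iters = iters)
}

#' Sparse PLS discriminant analysis
#'
#' Regression-mode [fit_spls()] of the data block against the one-hot dummy
#' coding of the class labels; the dummy side is never sparsified.
#'
#' @inheritParams fit_spls
#' @param ds [omics_dataset()] or matrix of predictors.
#' @param labels Class labels, one per sample (>= 2 classes).
#' @param keep Nonzero-loading budget per component for the data block.
#' @return A discriminant `latent_model` (algorithm `"splsda"`).
#' @export
fit_splsda <- function(ds, labels, ncomp, keep = NULL,
                       center = TRUE, scale = TRUE,
                       tol = 1e-9, max_iter = 500L) {
  blk <- as_block(ds)
  labels <- as.character(labels)
  if (length(labels) != nrow(blk$values)) {
    stop("labels length must equal the number of samples", call. = FALSE)
  }
  dummy <- dummy_code(labels)
  rownames(dummy) <- rownames(blk$values)
  model <- fit_spls(ds, dummy, ncomp = ncomp,
                    keepX = keep %||% ncol(blk$values),
                    keepY = ncol(dummy), mode = "regression",
                    center = center, scale = scale,
                    tol = tol, max_iter = max_iter)
  model$algorithm <- "splsda"
  model$mode <- "discriminant"
  model$class_labels <- colnames(dummy)
  model$labels <- labels
  model$dummy_Y <- dummy
  model
}
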