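# PCA / sPCA -----------------------------------------------------------------

test_that("PCA explained variances equal the eigenvalue shares of the correlation matrix", {
  X <- make_matrix(6, 4, seed = 21)
  m <- fit_pca(X, ncomp = 3)
  ev <- eigen(cov(scale(X)))$values
  expect_equal(m$explained_variance_full, ev / sum(ev), tolerance = 1e-10)
  expect_equal(sum(m$explained_variance_full), 1, tolerance = 1e-10)
  expect_true(all(diff(m$explained_variance_full) <= 1e-12))
})

test_that("PCA degenerate axis and zero-variance errors", {
  m <- cbind(f1 = c(-2, -1, 0, 1, 2), f2 = rep(3, 5))
  rownames(m) <- paste0("s", 1:5)
  fit <- fit_pca(m, ncomp = 1, scale = FALSE)
  expect_equal(fit$explained_variance[1], 1, tolerance = 1e-12)
  expect_error(fit_pca(m, ncomp = 1, scale = TRUE), "f2")
  expect_error(fit_pca(make_matrix(5, 3), ncomp = 4), "ncomp")
})

test_that("sPCA with keep = p reproduces dense PCA up to sign", {
  for (seed in 1:5) {
    X <- make_matrix(8, 6, seed = seed)
    dense <- fit_pca(X, 3)
    sparse <- fit_spca(X, 3, keep = 6)
    expect_equal(abs(sparse$blocks[[1]]$loadings),
                 abs(dense$blocks[[1]]$loadings), tolerance = 1e-6)
  }
})

test_that("sPCA keep = 1 finds the dominant single feature (enumeration oracle)", {
  X <- make_matrix(10, 6, seed = 7)
  X[, 3] <- X[, 3] * 4   # clearly dominant column under center-only scaling
  fit <- fit_spca(X, 1, keep = 1, scale = FALSE)
  sup <- support_of(fit, "X", 1)
  # oracle: the one-sparse rank-1 fit minimizing the residual keeps the
  # column with the largest centered sum of squares
  Xc <- scale(X, scale = FALSE)
  expect_equal(sup, colnames(X)[which.max(colSums(Xc^2))])
  expect_equal(sum(fit$blocks[[1]]$loadings[, 1] != 0), 1L)
})

test_that("sPCA recovers a planted block of informative features", {
  g <- planted_two_class(seed = 5)
  fit <- fit_spca(g$datasets$blk, 1, keep = 5)
  sup <- support_of(fit, "blk", 1)
  expect_gte(length(intersect(sup, g$truth$blk)), 4L)
})

test_that("loading columns are unit norm and nonzero counts respect keep", {
  X <- make_matrix(9, 12, seed = 2)
  fit <- fit_spca(X, 3, keep = c(4, 6, 12))
  L <- fit$blocks[[1]]$loadings
  expect_equal(colSums(L^2), c(comp1 = 1, comp2 = 1, comp3 = 1),
               tolerance = 1e-8)
  expect_equal(colSums(L != 0), c(comp1 = 4, comp2 = 6, comp3 = 12))
})

# sPLS ------------------------------------------------------------------------

test_that("dense sPLS (ncomp = 1) matches the SVD of the scaled cross-covariance", {
  for (seed in 1:10) {
    X <- make_matrix(10, 6, seed = seed, prefix = "x")
    Y <- make_matrix(10, 4, seed = seed + 100, prefix = "y")
    fr <- fit_spls(X, Y, ncomp = 1, mode = "regression")
    fc <- fit_spls(X, Y, ncomp = 1, mode = "canonical")
    sv <- svd(crossprod(scale(X), scale(Y)))
    expect_equal(abs(fr$blocks[["X"]]$loadings[, 1]), abs(sv$u[, 1]),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(abs(fr$blocks[["Y"]]$loadings[, 1]), abs(sv$v[, 1]),
                 tolerance = 1e-6, ignore_attr = TRUE)
    # one component: deflation has not yet happened, modes agree
    expect_equal(fr$blocks[["X"]]$loadings, fc$blocks[["X"]]$loadings)
    expect_equal(fr$blocks[["Y"]]$loadings, fc$blocks[["Y"]]$loadings)
  }
})

test_that("a planted correlated pair is selected at keepX = keepY = 1", {
  set.seed(31)
  n <- 20
  z <- rnorm(n)
  X <- make_matrix(n, 10, seed = 32, prefix = "x")
  Y <- make_matrix(n, 8, seed = 33, prefix = "y")
  X[, 4] <- z + rnorm(n, sd = 0.35)   # cor ~ 0.94 with the shared signal
  Y[, 2] <- z + rnorm(n, sd = 0.35)
  fit <- fit_spls(X, Y, ncomp = 1, keepX = 1, keepY = 1)
  expect_equal(support_of(fit, "X"), "x4")
  expect_equal(support_of(fit, "Y"), "y2")
})

test_that("regression-mode X-scores are orthogonal and the Bessel bound holds", {
  X <- make_matrix(12, 9, seed = 41, prefix = "x")
  Y <- make_matrix(12, 5, seed = 42, prefix = "y")
  fit <- fit_spls(X, Y, ncomp = 4, keepX = 4, keepY = 3, mode = "regression")
  Tm <- fit$blocks[["X"]]$scores
  G <- crossprod(Tm)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  R <- cor(fit$blocks[["X"]]$data, Tm)
  expect_lt(max(rowSums(R^2)), 1 + 1e-6)
})

test_that("solvers are deterministic", {
  X <- make_matrix(10, 7, seed = 51, prefix = "x")
  Y <- make_matrix(10, 4, seed = 52, prefix = "y")
  f1 <- fit_spls(X, Y, ncomp = 2, keepX = 3, keepY = 2, mode = "canonical")
  f2 <- fit_spls(X, Y, ncomp = 2, keepX = 3, keepY = 2, mode = "canonical")
  expect_identical(f1$blocks[["X"]]$loadings, f2$blocks[["X"]]$loadings)
  expect_identical(f1$blocks[["Y"]]$scores, f2$blocks[["Y"]]$scores)
})

# sPLS-DA ---------------------------------------------------------------------

test_that("dummy coding is one-hot in sorted class order", {
  d <- dummy_code(c("A", "B", "A"))
  expect_equal(unname(d), rbind(c(1, 0), c(0, 1), c(1, 0)))
  expect_equal(colnames(d), c("A", "B"))
  expect_true(all(rowSums(d) == 1))
  d4 <- dummy_code(rep(paste0("V", 1:4), each = 3))
  expect_equal(dim(d4), c(12L, 4L))
  expect_equal(unname(colSums(d4)), rep(3, 4))
  expect_error(dummy_code(rep("A", 5)), "two classes")
})

test_that("sPLS-DA separates two well-separated classes on component 1", {
  g <- planted_two_class(seed = 9)
  fit <- fit_splsda(g$datasets$blk, g$labels, ncomp = 1, keep = 5)
  t1 <- fit$blocks[["blk"]]$scores[, 1]
  expect_true(all(sign(t1[g$labels == "C1"]) ==
                    sign(t1[g$labels == "C1"][1])))
  expect_true(all(sign(t1[g$labels == "C2"]) !=
                    sign(t1[g$labels == "C1"][1])))
})

test_that("sPLS-DA with keep = p equals dense PLS-DA", {
  g <- planted_two_class(seed = 10, p = 12)
  dense <- fit_splsda(g$datasets$blk, g$labels, ncomp = 2)
  sparse <- fit_splsda(g$datasets$blk, g$labels, ncomp = 2, keep = c(12, 12))
  expect_equal(dense$blocks[["blk"]]$loadings,
               sparse$blocks[["blk"]]$loadings)
})

# prediction ------------------------------------------------------------------

test_that("all three distances classify a separated training set perfectly", {
  g <- planted_two_class(seed = 12)
  fit <- fit_splsda(g$datasets$blk, g$labels, ncomp = 1, keep = 10)
  for (d in c("centroids", "max", "mahalanobis")) {
    expect_equal(predict_classes(fit, g$datasets$blk, distance = d),
                 g$labels, info = d)
  }
})

test_that("max distance equals the argmax of the replayed dummy prediction", {
  g <- planted_two_class(seed = 13, strength = 1)
  fit <- fit_splsda(g$datasets$blk, g$labels, ncomp = 2, keep = c(5, 5))
  blk <- fit$blocks[["blk"]]
  # independent recomputation of the dummy prediction
  Xs <- scale(g$datasets$blk$values,
              center = blk$center, scale = blk$scale)
  Xc <- Xs
  Tm <- matrix(0, nrow(Xs), 2)
  for (h in 1:2) {
    Tm[, h] <- Xc %*% blk$loadings[, h]
    Xc <- Xc - Tm[, h] %*% t(blk$defl[, h])
  }
  Q <- fit$blocks[["Y"]]$defl
  yhat <- Tm %*% t(Q)
  yhat <- sweep(sweep(yhat, 2, fit$blocks[["Y"]]$scale, "*"),
                2, fit$blocks[["Y"]]$center, "+")
  oracle <- fit$class_labels[max.col(yhat, ties.method = "first")]
  expect_equal(predict_classes(fit, g$datasets$blk, distance = "max"), oracle)
})

test_that("centroids assigns a new score to the nearer centroid", {
  g <- planted_two_class(seed = 14)
  fit <- fit_splsda(g$datasets$blk, g$labels, ncomp = 1, keep = 50)
  cent1 <- mean(fit$blocks$blk$scores[g$labels == "C1", 1])
  # a sample lying slightly to the C1 side of the midpoint
  mid <- (cent1 + mean(fit$blocks$blk$scores[g$labels == "C2", 1])) / 2
  x1 <- g$datasets$blk$values[which(g$labels == "C1")[1], , drop = FALSE]
  x2 <- g$datasets$blk$values[which(g$labels == "C2")[1], , drop = FALSE]
  w <- if (cent1 > mid) 0.55 else 0.45  # mildly C1-weighted mixture
  xm <- w * x1 + (1 - w) * x2
  rownames(xm) <- "new"
  pred <- predict_classes(fit, xm, distance = "centroids")
  # verify against a direct distance computation
  blk <- fit$blocks$blk
  tnew <- (scale(xm, blk$center, blk$scale) %*% blk$loadings[, 1])[1]
  cents <- tapply(blk$scores[, 1], g$labels, mean)
  expect_equal(pred, names(which.min((cents - tnew)^2)))
})

# DIABLO ----------------------------------------------------------------------

test_that("a single-block multiblock model selects the same component-1 features as sPLS-DA", {
  g <- planted_two_class(seed = 15, p = 30)
  d1 <- fit_diablo(g$datasets["blk"], g$labels, ncomp = 1, design = 0.5,
                   keep = list(blk = 5))
  s1 <- fit_splsda(g$datasets$blk, g$labels, ncomp = 1, keep = 5)
  expect_setequal(support_of(d1, "blk"), support_of(s1, "blk"))
})

test_that("two identical blocks with full design get identical loadings", {
  g <- planted_two_class(seed = 16, p = 20)
  twin <- g$datasets$blk
  twin$name <- "twin"
  colnames(twin$values) <- colnames(g$datasets$blk$values)
  fit <- fit_diablo(list(blk = g$datasets$blk, twin = twin), g$labels,
                    ncomp = 1, design = 1,
                    keep = list(blk = 5, twin = 5))
  expect_equal(fit$blocks$blk$loadings, fit$blocks$twin$loadings,
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("a planted shared factor is recovered across three blocks", {
  g <- planted_three_block(seed = 17)
  fit <- fit_diablo(g$datasets, g$labels, ncomp = 1, design = 0.5,
                    keep = list(b1 = 5, b2 = 5, b3 = 5))
  for (nm in names(g$datasets)) {
    expect_gte(length(intersect(support_of(fit, nm), g$truth[[nm]])), 4L,
               label = paste("recovered features in", nm))
  }
  pred <- predict_classes(fit, lapply(g$datasets, `[[`, "values"))
  expect_lte(ber(g$labels, pred), 0.1)
})

test_that("components beyond the class-block rank remain usable", {
  g <- planted_three_block(seed = 18, classes = 2)
  # rank of the centered 2-class dummy is 1; components 2-3 must still fit
  fit <- fit_diablo(g$datasets, g$labels, ncomp = 3, design = 0.7)
  expect_equal(fit$ncomp, 3L)
  expect_true(all(is.finite(fit$blocks$b1$scores)))
})
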