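# Cross-validated tuning of component numbers and per-component feature
# counts, the data-driven design matrix, and dataset reduction.

tune_result <- function(selected_ncomp, selected_keep, criterion_surface,
                        criterion, folds, repeats, seed,
                        repair_log = list(), ...) {
  structure(
    c(list(selected_ncomp = selected_ncomp,
           selected_keep = selected_keep,
           criterion_surface = criterion_surface,
           criterion = criterion,
           folds = folds, repeats = repeats, seed = seed,
           repair_log = repair_log),
      list(...)),
    class = "tune_result"
  )
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("<tune_result %s> ncomp = %d\n", x$criterion, x$selected_ncomp))
  keeps <- x$selected_keep
  if (is.list(keeps)) {
    for (nm in names(keeps)) {
      cat(sprintf("  keep[%s] = %s\n", nm, paste(keeps[[nm]], collapse = ", ")))
    }
  } else {
    cat("  keep =", paste(keeps, collapse = ", "), "\n")
  }
  if (length(x$repair_log)) {
    cat("  repair rounds:", length(x$repair_log), "\n")
  }
  invisible(x)
}

block_values <- function(x) if (inherits(x, "omics_dataset")) x$values else as.matrix(x)

# ---------------------------------------------------------------------------
# Q2 component selection for two-block PLS

#' Cross-validated Q-squared per component
#'
#' For component `h`, `PRESS_h` sums the squared errors of predicting the
#' held-out Y residuals from a single dense PLS component fitted on the
#' training rows of the current residual matrices; `RSS_{h-1}` is the
#' residual sum of squares of Y after `h-1` components on the full data
#' (`RSS_0` = total sum of squares of the standardized Y). The total
#' Q-squared pools PRESS and RSS over all Y columns:
#' `Q2_h = 1 - PRESS_h / RSS_{h-1}`.
#'
#' @inheritParams fit_spls
#' @param folds,repeats,seed Cross-validation layout.
#' @return Numeric vector of per-component total Q-squared values.
#' @export
q2_scores <- function(X, Y, ncomp, folds = 5L, repeats = 10L, seed = 1L,
                      center = TRUE, scale = TRUE) {
  bx <- as_block(X, "X"); by <- as_block(Y, "Y")
  sx <- standardize(bx$values, center, scale, dataset = bx$name)
  sy <- standardize(by$values, center, scale, dataset = by$name)
  Xc <- sx$X; Yc <- sy$X
  n <- nrow(Xc)
  assignments <- plain_folds(n, folds, repeats, seed)
  q2 <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    rss_prev <- sum(Yc^2)
    press_r <- numeric(repeats)
    for (r in seq_len(repeats)) {
      fa <- assignments[[r]]
      press <- 0
      for (f in seq_len(folds)) {
        tr <- fa != f; te <- !tr
        cx <- colMeans(Xc[tr, , drop = FALSE])
        cy <- colMeans(Yc[tr, , drop = FALSE])
        Xtr <- sweep(Xc[tr, , drop = FALSE], 2L, cx)
        Ytr <- sweep(Yc[tr, , drop = FALSE], 2L, cy)
        cmp <- spls_component(Xtr, Ytr, ncol(Xtr), ncol(Ytr),
                              tol = 1e-9, max_iter = 500L,
                              bx$name, by$name)
        d <- as.vector(crossprod(Ytr, cmp$t)) / sum(cmp$t^2)
        t_te <- sweep(Xc[te, , drop = FALSE], 2L, cx) %*% cmp$a
        Yhat <- tcrossprod(t_te, d)
        press <- press + sum((sweep(Yc[te, , drop = FALSE], 2L, cy) - Yhat)^2)
      }
      press_r[r] <- press
    }
    q2[h] <- 1 - mean(press_r) / rss_prev
    # deflate the full data by the dense component for the next h
    cmp <- spls_component(Xc, Yc, ncol(Xc), ncol(Yc),
                          tol = 1e-9, max_iter = 500L, bx$name, by$name)
    cvec <- as.vector(crossprod(Xc, cmp$t)) / sum(cmp$t^2)
    dvec <- as.vector(crossprod(Yc, cmp$t)) / sum(cmp$t^2)
    Xc <- Xc - tcrossprod(cmp$t, cvec)
    Yc <- Yc - tcrossprod(cmp$t, dvec)
  }
  q2
}

# ---------------------------------------------------------------------------
# sPLS-DA tuning by balanced error rate

#' Tune an sPLS-DA model by cross-validated balanced error rate
#'
#' Sequential per-component tuning: with the earlier components' keeps fixed,
#' every grid value is scored by the mean cross-validated BER; the minimizer
#' wins, ties going to the smaller keep. The selected component count is the
#' one whose cumulative model attains the lowest mean BER (ties: fewer
#' components).
#'
#' @inheritParams fit_splsda
#' @param ncomp_max Largest component count examined (the "pre-selected
#'   components").
#' @param grid Candidate keep values (default [default_keep_grid()]).
#' @param folds Cross-validation folds; default `min(5, smallest class)`.
#' @param repeats CV repeats (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param distance Prediction distance used to score folds.
#' @return A `tune_result` with the BER surface.
#' @export
tune_splsda <- function(ds, labels, ncomp_max, grid = NULL,
                        folds = NULL, repeats = 10L, seed = 1L,
                        distance = c("centroids", "max", "mahalanobis")) {
  distance <- match.arg(distance)
  m <- block_values(ds)
  labels <- as.character(labels)
  p <- ncol(m)
  grid <- sort(unique(as.integer(grid %||% default_keep_grid(p))))
  grid <- grid[grid >= 1L & grid <= p]
  folds <- folds %||% min(5L, min(table(labels)))
  assignments <- stratified_folds(labels, folds, repeats, seed)

  sel <- integer(0)
  comp_ber <- numeric(ncomp_max)
  surface <- list()
  for (h in seq_len(ncomp_max)) {
    best_keep <- NA_integer_; best_ber <- Inf
    for (g in grid) {
      bers <- vapply(seq_len(repeats), function(r) {
        fa <- assignments[[r]]
        preds <- character(length(labels))
        for (f in seq_len(folds)) {
          tr <- fa != f
          fit <- fit_splsda(m[tr, , drop = FALSE], labels[tr],
                            ncomp = h, keep = c(sel, g))
          preds[!tr] <- predict_classes(fit, m[!tr, , drop = FALSE],
                                        distance = distance)
        }
        ber(labels, preds)
      }, 1)
      mb <- mean(bers)
      surface[[length(surface) + 1L]] <-
        data.frame(component = h, keep = g, ber = mb)
      if (mb < best_ber - 1e-12) {
        best_ber <- mb; best_keep <- g
      }
    }
    sel <- c(sel, best_keep)
    comp_ber[h] <- best_ber
  }
  selected_ncomp <- which.min(comp_ber)  # ties -> fewer components
  tune_result(
    selected_ncomp = selected_ncomp,
    selected_keep = sel[seq_len(selected_ncomp)],
    criterion_surface = do.call(rbind, surface),
    criterion = "ber",
    folds = folds, repeats = repeats, seed = seed,
    component_ber = comp_ber,
    keep_per_component = sel,
    distance = distance
  )
}

# ---------------------------------------------------------------------------
# sPLS keep tuning by score correlation

project_scores_xy <- function(model, Xnew, Ynew) {
  bx <- model$blocks[[model$x_name]]
  by <- model$blocks[[model$y_name]]
  H <- model$ncomp
  Xc <- Xnew; Yc <- Ynew
  Tm <- matrix(0, nrow(Xnew), H)
  U <- matrix(0, nrow(Ynew), H)
  for (h in seq_len(H)) {
    t <- as.vector(Xc %*% bx$loadings[, h])
    Tm[, h] <- t
    Xc <- Xc - tcrossprod(t, bx$defl[, h])
    u <- as.vector(Yc %*% by$loadings[, h])
    U[, h] <- u
    if (model$mode == "regression") {
      Yc <- Yc - tcrossprod(t, by$defl[, h])
    } else {
      Yc <- Yc - tcrossprod(u, by$defl[, h])
    }
  }
  list(T = Tm, U = U)
}

#' Tune sPLS feature counts by predicted-score correlation
#'
#' Sequentially per component: for every `(keepX, keepY)` grid pair the model
#' is refitted on the training folds and the held-out component scores are
#' predicted; the criterion is the mean (over repeats, and over the X and Y
#' side) absolute correlation between predicted and actual (full-fit) scores.
#' The maximizing pair wins; ties go to the smaller keeps (lexicographic in
#' `(keepX, keepY)`).
#'
#' @inheritParams fit_spls
#' @param ncomp Component count, typically from [select_ncomp_q2()].
#' @param gridX,gridY Candidate keeps per dataset.
#' @param folds,repeats,seed Cross-validation layout.
#' @return A `tune_result` with the correlation surface.
#' @export
tune_spls_keep <- function(X, Y, ncomp, gridX = NULL, gridY = NULL,
                           folds = 5L, repeats = 10L, seed = 1L,
                           mode = c("regression", "canonical")) {
  mode <- match.arg(mode)
  bx <- as_block(X, "X"); by <- as_block(Y, "Y")
  mX <- bx$values; mY <- by$values
  p <- ncol(mX); q <- ncol(mY)
  gridX <- sort(unique(as.integer(gridX %||% default_keep_grid(p))))
  gridY <- sort(unique(as.integer(gridY %||% default_keep_grid(q))))
  gridX <- gridX[gridX >= 1L & gridX <= p]
  gridY <- gridY[gridY >= 1L & gridY <= q]
  n <- nrow(mX)
  assignments <- plain_folds(n, folds, repeats, seed)
  pairs <- expand.grid(keepY = gridY, keepX = gridX)[, c("keepX", "keepY")]
  pairs <- pairs[order(pairs$keepX, pairs$keepY), , drop = FALSE]

  selX <- integer(0); selY <- integer(0)
  surface <- list()
  for (h in seq_len(ncomp)) {
    best <- NULL; best_crit <- -Inf
    for (i in seq_len(nrow(pairs))) {
      kx <- pairs$keepX[i]; ky <- pairs$keepY[i]
      full <- fit_spls(X, Y, ncomp = h, keepX = c(selX, kx),
                       keepY = c(selY, ky), mode = mode)
      t_full <- full$blocks[[full$x_name]]$scores[, h]
      u_full <- full$blocks[[full$y_name]]$scores[, h]
      crits <- vapply(seq_len(repeats), function(r) {
        fa <- assignments[[r]]
        that <- numeric(n); uhat <- numeric(n)
        for (f in seq_len(folds)) {
          tr <- fa != f
          fit <- fit_spls(mX[tr, , drop = FALSE], mY[tr, , drop = FALSE],
                          ncomp = h, keepX = c(selX, kx),
                          keepY = c(selY, ky), mode = mode)
          bxm <- fit$blocks[[fit$x_name]]; bym <- fit$blocks[[fit$y_name]]
          Xte <- apply_standardization(mX[!tr, , drop = FALSE],
                                       bxm$center, bxm$scale)
          Yte <- apply_standardization(mY[!tr, , drop = FALSE],
                                       bym$center, bym$scale)
          proj <- project_scores_xy(fit, Xte, Yte)
          that[!tr] <- proj$T[, h]
          uhat[!tr] <- proj$U[, h]
        }
        (abs(stats::cor(that, t_full)) + abs(stats::cor(uhat, u_full))) / 2
      }, 1)
      crit <- mean(crits)
      surface[[length(surface) + 1L]] <-
        data.frame(component = h, keepX = kx, keepY = ky, cor = crit)
      if (crit > best_crit + 1e-12) {
        best_crit <- crit; best <- c(kx, ky)
      }
    }
    selX <- c(selX, best[1L]); selY <- c(selY, best[2L])
  }
  tune_result(
    selected_ncomp = ncomp,
    selected_keep = list(X = selX, Y = selY),
    criterion_surface = do.call(rbind, surface),
    criterion = "cor",
    folds = folds, repeats = repeats, seed = seed,
    mode = mode, x_name = bx$name, y_name = by$name
  )
}

#' Tune sparse PCA feature counts by predicted-score correlation
#'
#' Companion of [tune_spls_keep()] for the unsupervised single-omics path:
#' per component, each candidate keep is scored by the mean absolute
#' correlation between cross-validation-predicted and full-fit scores.
#'
#' @inheritParams fit_spca
#' @param grid Candidate keep values.
#' @param folds,repeats,seed Cross-validation layout.
#' @return A `tune_result`.
#' @export
tune_spca <- function(ds, ncomp, grid = NULL, folds = 5L, repeats = 10L,
                      seed = 1L) {
  m <- block_values(ds)
  p <- ncol(m); n <- nrow(m)
  grid <- sort(unique(as.integer(grid %||% default_keep_grid(p))))
  grid <- grid[grid >= 1L & grid <= p]
  assignments <- plain_folds(n, folds, repeats, seed)
  sel <- integer(0)
  surface <- list()
  for (h in seq_len(ncomp)) {
    best_keep <- NA_integer_; best_crit <- -Inf
    for (g in grid) {
      full <- fit_spca(ds, ncomp = h, keep = c(sel, g))
      blk_full <- full$blocks[[1L]]
      t_full <- blk_full$scores[, h]
      crits <- vapply(seq_len(repeats), function(r) {
        fa <- assignments[[r]]
        that <- numeric(n)
        for (f in seq_len(folds)) {
          tr <- fa != f
          fit <- fit_spca(m[tr, , drop = FALSE], ncomp = h, keep = c(sel, g))
          blk <- fit$blocks[[1L]]
          Xte <- apply_standardization(m[!tr, , drop = FALSE],
                                       blk$center, blk$scale)
          that[!tr] <- project_scores(blk, Xte)[, h]
        }
        abs(stats::cor(that, t_full))
      }, 1)
      crit <- mean(crits)
      surface[[length(surface) + 1L]] <-
        data.frame(component = h, keep = g, cor = crit)
      if (crit > best_crit + 1e-12) {
        best_crit <- crit; best_keep <- g
      }
    }
    sel <- c(sel, best_keep)
  }
  tune_result(
    selected_ncomp = ncomp, selected_keep = sel,
    criterion_surface = do.call(rbind, surface),
    criterion = "cor", folds = folds, repeats = repeats, seed = seed
  )
}

# ---------------------------------------------------------------------------
# Data-driven design matrix

#' Data-driven design matrix from pairwise PLS correlations
#'
#' For every block pair a dense canonical one-component PLS is fitted (under
#' the repair loop) and the absolute correlation between the two component-1
#' scores recorded. The minimum over pairs fills every off-diagonal cell of
#' the design matrix; by default it is rounded down to the nearest tenth.
#'
#' @param blocks Named list of [omics_dataset()] objects.
#' @param ncomp Components for the pairwise fits (default 1).
#' @param floor_value Round the minimum down with [floor_tenth()] (default
#'   `TRUE`).
#' @param min_features Passed to [nzv_repair()].
#' @return A [design_matrix()] with extra fields `pairwise` (named vector of
#'   pair correlations), `raw_min` and `value`.
#' @export
data_driven_design <- function(blocks, ncomp = 1L, floor_value = TRUE,
                               min_features = 2L) {
  stopifnot(length(blocks) >= 2L, !is.null(names(blocks)))
  bnames <- names(blocks)
  combs <- utils::combn(bnames, 2L)
  pairwise <- numeric(ncol(combs))
  names(pairwise) <- apply(combs, 2L, paste, collapse = "~")
  for (i in seq_len(ncol(combs))) {
    a <- combs[1L, i]; b <- combs[2L, i]
    rep_out <- nzv_repair(function(dss) {
      fit <- fit_spls(dss[[a]], dss[[b]], ncomp = 1L, mode = "canonical")
      abs(stats::cor(fit$blocks[[fit$x_name]]$scores[, 1L],
                     fit$blocks[[fit$y_name]]$scores[, 1L]))
    }, blocks[c(a, b)], min_features = min_features)
    pairwise[i] <- rep_out$result
  }
  raw_min <- min(pairwise)
  value <- if (isTRUE(floor_value)) floor_tenth(raw_min) else raw_min
  dm <- design_matrix(bnames, value)
  dm$pairwise <- pairwise
  dm$raw_min <- raw_min
  dm$value <- value
  dm
}

# ---------------------------------------------------------------------------
# DIABLO tuning

#' Tune a multiblock sPLS-DA model
#'
#' Stage 1 fits dense multiblock models up to `ncomp_max` under
#' cross-validation and selects the component count minimizing the overall
#' BER with the requested distance (default centroids; ties go to fewer
#' components). Stage 2 tunes the per-block keeps sequentially per component
#' over the cartesian product of the per-block grids, again by CV BER.
#' Numerical failures trigger the near-zero-variance repair loop on the
#' failing block(s).
#'
#' @inheritParams fit_diablo
#' @param ncomp_max Largest component count examined.
#' @param grids Named list of candidate keep vectors per block (default
#'   [default_keep_grid()] of each block).
#' @param folds,repeats,seed Cross-validation layout; folds default
#'   `min(5, smallest class)`.
#' @param distance Prediction distance.
#' @param min_features Abort bound for [nzv_repair()].
#' @return A `tune_result` whose `selected_keep` is a named per-block list;
#'   the repair log records any removed columns.
#' @export
tune_diablo <- function(blocks, labels, ncomp_max, grids = NULL,
                        folds = NULL, repeats = 10L, seed = 1L,
                        design = NULL,
                        distance = c("centroids", "max", "mahalanobis"),
                        min_features = 2L) {
  distance <- match.arg(distance)
  stopifnot(length(blocks) >= 1L, !is.null(names(blocks)))
  blocks <- lapply(names(blocks), function(nm) {
    b <- blocks[[nm]]
    if (inherits(b, "omics_dataset")) b else omics_dataset(nm, as.matrix(b))
  })
  names(blocks) <- vapply(blocks, function(b) b$name, "")
  labels <- as.character(labels)
  if (is.null(design)) design <- data_driven_design(blocks,
                                                    min_features = min_features)
  folds <- folds %||% min(5L, min(table(labels)))
  assignments <- stratified_folds(labels, folds, repeats, seed)

  cv_ber <- function(bl, keep, h) {
    bers <- vapply(seq_len(repeats), function(r) {
      fa <- assignments[[r]]
      preds <- character(length(labels))
      for (f in seq_len(folds)) {
        tr <- fa != f
        bl_tr <- lapply(bl, function(d) {
          d$values <- d$values[tr, , drop = FALSE]
          d
        })
        fit <- fit_diablo(bl_tr, labels[tr], ncomp = h, design = design,
                          keep = keep)
        bl_te <- lapply(bl, function(d) d$values[!tr, , drop = FALSE])
        preds[!tr] <- predict_classes(fit, bl_te, distance = distance)
      }
      ber(labels, preds)
    }, 1)
    mean(bers)
  }

  task <- function(bl) {
    ps <- vapply(bl, function(d) ncol(d$values), 1L)
    gr <- lapply(names(bl), function(nm) {
      g <- sort(unique(as.integer(grids[[nm]] %||% default_keep_grid(ps[[nm]]))))
      g[g >= 1L & g <= ps[[nm]]]
    })
    names(gr) <- names(bl)
    # stage 1: component count from dense fits
    ncomp_surface <- data.frame(ncomp = seq_len(ncomp_max),
                                ber = NA_real_)
    for (h in seq_len(ncomp_max)) {
      ncomp_surface$ber[h] <- cv_ber(bl, keep = NULL, h = h)
    }
    selected_ncomp <- which.min(ncomp_surface$ber)
    # stage 2: sequential per-component keep tuning over the grid product
    sel <- lapply(names(bl), function(nm) integer(0))
    names(sel) <- names(bl)
    combos <- expand.grid(rev(gr), KEEP.OUT.ATTRS = FALSE)[, names(bl),
                                                           drop = FALSE]
    keep_surface <- list()
    for (h in seq_len(selected_ncomp)) {
      best_row <- NA_integer_; best_ber <- Inf
      for (i in seq_len(nrow(combos))) {
        keep <- lapply(names(bl), function(nm)
          c(sel[[nm]], combos[i, nm]))
        names(keep) <- names(bl)
        mb <- cv_ber(bl, keep = keep, h = h)
        keep_surface[[length(keep_surface) + 1L]] <-
          cbind(data.frame(component = h), combos[i, , drop = FALSE],
                data.frame(ber = mb))
      if (mb < best_ber - 1e-12) {
          best_ber <- mb; best_row <- i
        }
      }
      for (nm in names(bl)) sel[[nm]] <- c(sel[[nm]], combos[best_row, nm])
    }
    list(selected_ncomp = selected_ncomp,
         selected_keep = sel,
         ncomp_surface = ncomp_surface,
         keep_surface = do.call(rbind, keep_surface))
  }

  out <- nzv_repair(task, blocks, min_features = min_features)
  res <- out$result
  tune_result(
    selected_ncomp = res$selected_ncomp,
    selected_keep = res$selected_keep,
    criterion_surface = list(ncomp = res$ncomp_surface,
                             keep = res$keep_surface),
    criterion = "ber",
    folds = folds, repeats = repeats, seed = seed,
    repair_log = out$repair_log,
    design = design,
    datasets = out$datasets,
    distance = distance
  )
}

# ---------------------------------------------------------------------------

#' Reduce a dataset to the features selected by a sparse model
#'
#' Restricts the dataset to the union of features with nonzero loadings on
#' components `1..selected_ncomp`, preserving the original column order.
#'
#' @param ds The [omics_dataset()] that was fitted.
#' @param model A sparse `latent_model` fitted at the tuned parameters.
#' @param tune Optional `tune_result`; its `selected_ncomp` overrides the
#'   model's component count.
#' @return The reduced [omics_dataset()].
#' @export
reduce_dataset <- function(ds, model, tune = NULL) {
  ncomp <- tune$selected_ncomp %||% model$ncomp
  blk <- model$blocks[[ds$name]] %||% model$blocks[[model$x_name %||%
                                                     names(model$blocks)[1L]]]
  L <- blk$loadings[, seq_len(ncomp), drop = FALSE]
  support <- rownames(L)[rowSums(abs(L) > 0) > 0]
  if (length(support) == 0L) stop("no feature selected; nothing to reduce",
                                  call. = FALSE)
  keep_cols <- colnames(ds$values) %in% support
  ds$values <- ds$values[, keep_cols, drop = FALSE]
  add_provenance(ds, "reduce_dataset",
                 list(ncomp = ncomp, n_selected = sum(keep_cols)))
}
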