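# Class prediction from fitted discriminant models.

# Replay the training deflation on new (already standardized) data to get
# predicted scores; equivalent to T = X W (P'W)^{-1} but numerically direct.
project_scores <- function(block, Xnew_std, ncomp = NULL) {
  H <- ncomp %||% ncol(block$loadings)
  Tm <- matrix(0, nrow(Xnew_std), H,
               dimnames = list(rownames(Xnew_std),
                               colnames(block$loadings)[seq_len(H)]))
  Xc <- Xnew_std
  for (h in seq_len(H)) {
    t <- as.vector(Xc %*% block$loadings[, h])
    Tm[, h] <- t
    Xc <- Xc - tcrossprod(t, block$defl[, h])
  }
  Tm
}

prepare_new_block <- function(block, newdata) {
  m <- if (inherits(newdata, "omics_dataset")) newdata$values else as.matrix(newdata)
  missing <- setdiff(names(block$center), colnames(m))
  if (length(missing)) {
    stop("new data lacks model feature(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ..." else "", call. = FALSE)
  }
  m <- m[, names(block$center), drop = FALSE]
  apply_standardization(m, block$center, block$scale)
}

class_centroids <- function(scores, labels) {
  cls <- sort(unique(labels))
  cent <- do.call(rbind, lapply(cls, function(cl)
    colMeans(scores[labels == cl, , drop = FALSE])))
  rownames(cent) <- cls
  cent
}

pooled_within_cov <- function(scores, labels) {
  cls <- unique(labels)
  n <- nrow(scores); g <- length(cls)
  S <- matrix(0, ncol(scores), ncol(scores))
  for (cl in cls) {
    d <- sweep(scores[labels == cl, , drop = FALSE], 2L,
               colMeans(scores[labels == cl, , drop = FALSE]))
    S <- S + crossprod(d)
  }
  S <- S / max(1L, n - g)
  S + diag(1e-8 * max(diag(S), 1), ncol(S))  # guard against singularity
}

classify_scores <- function(Tnew, block, model, distance) {
  labels <- model$labels
  cls <- model$class_labels
  switch(distance,
    max = {
      Q <- block$q %||% model$blocks[[model$y_name]]$defl
      H <- ncol(Tnew)
      yhat_std <- Tnew %*% t(Q[, seq_len(H), drop = FALSE])
      ysc <- model$y_scale %||% model$blocks[[model$y_name]]$scale
      yct <- model$y_center %||% model$blocks[[model$y_name]]$center
      yhat <- sweep(sweep(yhat_std, 2L, ysc, "*"), 2L, yct, "+")
      cls[max.col(yhat, ties.method = "first")]
    },
    centroids = {
      cent <- class_centroids(block$scores[, seq_len(ncol(Tnew)), drop = FALSE],
                              labels)
      d2 <- outer(rowSums(Tnew^2), rowSums(cent^2), `+`) -
        2 * Tnew %*% t(cent)
      rownames(cent)[max.col(-d2, ties.method = "first")]
    },
    mahalanobis = {
      sc <- block$scores[, seq_len(ncol(Tnew)), drop = FALSE]
      cent <- class_centroids(sc, labels)
      Sinv <- solve(pooled_within_cov(sc, labels))
      d2 <- matrix(0, nrow(Tnew), nrow(cent),
                   dimnames = list(NULL, rownames(cent)))
      for (g in seq_len(nrow(cent))) {
        d <- sweep(Tnew, 2L, cent[g, ])
        d2[, g] <- rowSums((d %*% Sinv) * d)
      }
      rownames(cent)[max.col(-d2, ties.method = "first")]
    },
    stop("distance '", distance, "' not implemented", call. = FALSE)
  )
}

#' Predict class labels from a discriminant model
#'
#' Projects new samples onto the model scores and assigns classes by the
#' requested distance: `"max"` takes the argmax of the predicted dummy
#' response, `"centroids"` the nearest training-class score centroid
#' (Euclidean), `"mahalanobis"` the nearest centroid under the pooled
#' within-class score covariance. For multiblock models the per-block
#' predictions are combined by majority vote; ties go to the block whose
#' component-1 scores correlate most strongly with the class dummy matrix.
#'
#' @param model A discriminant `latent_model` ([fit_splsda()] or
#'   [fit_diablo()]).
#' @param newdata Matrix/[omics_dataset()] (single-block models) or named
#'   list of them (multiblock models) carrying the model's features.
#' @param distance `"max"`, `"centroids"` or `"mahalanobis"`.
#' @param ncomp Number of components to use (default: all fitted).
#' @return Character vector of predicted class labels.
#' @export
predict_classes <- function(model, newdata,
                            distance = c("centroids", "max", "mahalanobis"),
                            ncomp = NULL) {
  distance <- match.arg(distance)
  if (is.null(model$class_labels)) {
    stop("predict_classes() needs a discriminant model", call. = FALSE)
  }
  H <- ncomp %||% model$ncomp
  if (model$algorithm == "diablo") {
    if (!is.list(newdata) || is.null(names(newdata))) {
      stop("multiblock prediction needs a named list of blocks",
           call. = FALSE)
    }
    bnames <- intersect(model$block_names, names(newdata))
    if (length(bnames) == 0L) stop("no block names match the model",
                                   call. = FALSE)
    votes <- vapply(bnames, function(nm) {
      blk <- model$blocks[[nm]]
      Tnew <- project_scores(blk, prepare_new_block(blk, newdata[[nm]]), H)
      classify_scores(Tnew, blk, model, distance)
    }, character(nrow(dummy_if(newdata[[bnames[1L]]]))))
    if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L,
                                             dimnames = list(NULL, bnames))
    # block ranking for tie-breaking: |cor(component-1 scores, dummy)|
    dummy_std <- apply_standardization(model$dummy_Y, model$y_center,
                                       model$y_scale)
    block_cor <- vapply(bnames, function(nm)
      max(abs(stats::cor(model$blocks[[nm]]$scores[, 1L], dummy_std))), 1)
    rank_order <- bnames[order(-block_cor)]
    apply_majority_vote(votes, rank_order)
  } else {
    nm <- model$x_name %||% names(model$blocks)[1L]
    blk <- model$blocks[[nm]]
    Tnew <- project_scores(blk, prepare_new_block(blk, newdata), H)
    # for two-block models the dummy deflation loadings live on the Y block
    if (is.null(blk$q) && !is.null(model$y_name)) {
      blk$q <- model$blocks[[model$y_name]]$defl
      model$y_center <- model$blocks[[model$y_name]]$center
      model$y_scale <- model$blocks[[model$y_name]]$scale
    }
    classify_scores(Tnew, blk, model, distance)
  }
}

dummy_if <- function(x) {
  if (inherits(x, "omics_dataset")) x$values else as.matrix(x)
}

apply_majority_vote <- function(votes, rank_order) {
  apply(votes, 1L, function(v) {
    tab <- table(v)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) return(winners)
    for (nm in rank_order) {
      if (v[[nm]] %in% winners) return(v[[nm]])
    }
    winners[1L]
  })
}
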