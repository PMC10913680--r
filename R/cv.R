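# Cross-validation primitives, selection rules, and the near-zero-variance
# repair loop.

#' Stratified cross-validation fold assignment
#'
#' Each repeat partitions the samples into `folds` groups with balanced class
#' proportions: within every class (sorted order) the samples are shuffled
#' with a seeded RNG and dealt round-robin to the folds. Deterministic given
#' the seed.
#'
#' @param labels Class labels, one per sample.
#' @param folds Number of folds; must be at least 2 and no larger than the
#'   smallest class.
#' @param repeats Number of independent repeats.
#' @param seed Integer seed.
#' @return List of length `repeats`; each element an integer vector of fold
#'   ids (1..folds) per sample.
#' @export
stratified_folds <- function(labels, folds, repeats = 1L, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  cls <- sort(unique(labels))
  min_class <- min(table(labels))
  if (folds < 2L) stop("need at least 2 folds", call. = FALSE)
  if (folds > min_class) {
    stop("folds (", folds, ") exceeds the smallest class size (", min_class,
         ")", call. = FALSE)
  }
  lapply(seq_len(repeats), function(r) {
    with_seed(seed + r - 1L, {
      f <- integer(n)
      for (cl in cls) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        f[idx] <- rep_len(seq_len(folds), length(idx))
      }
      f
    })
  })
}

# Unstratified variant for unsupervised two-block tuning.
plain_folds <- function(n, folds, repeats = 1L, seed = 1L) {
  if (folds < 2L || folds > n) stop("folds must be in [2, n]", call. = FALSE)
  lapply(seq_len(repeats), function(r) {
    with_seed(seed + r - 1L, sample(rep_len(seq_len(folds), n)))
  })
}

#' Balanced error rate
#'
#' Mean over classes of the per-class misclassification rate; insensitive to
#' class imbalance and equal to the plain error rate when classes are
#' balanced.
#'
#' @param true,predicted Equal-length class vectors. Every class level of
#'   `true` must be observed.
#' @return A number in `[0, 1]`.
#' @export
ber <- function(true, predicted) {
  if (length(true) != length(predicted)) {
    stop("true and predicted must have equal length", call. = FALSE)
  }
  tf <- factor(true)
  if (any(table(tf) == 0L)) {
    stop("class level(s) with no observations in `true`", call. = FALSE)
  }
  pred <- as.character(predicted)
  rates <- vapply(levels(tf), function(cl) {
    i <- tf == cl
    mean(pred[i] != cl)
  }, 1)
  mean(rates)
}

#' Number of components reaching a cumulative explained-variance threshold
#'
#' @param model A `latent_model` from [fit_pca()] (carries the full variance
#'   spectrum).
#' @param threshold Cumulative explained-variance target (default 0.80).
#' @return The smallest component count whose cumulative explained variance
#'   reaches the threshold.
#' @export
select_ncomp_variance <- function(model, threshold = 0.80) {
  ev <- model$explained_variance_full
  if (is.null(ev)) stop("model lacks the full variance spectrum", call. = FALSE)
  cum <- cumsum(ev)
  idx <- which(cum >= threshold - 1e-12)
  if (length(idx)) idx[1L] else length(ev)
}

#' Component count from per-component Q-squared values
#'
#' Returns the last component whose total Q-squared exceeds the threshold
#' (default 0.0975, i.e. `1 - 0.95^2`); falls back to 1 when no component
#' passes.
#'
#' @param q2 Numeric vector of per-component total Q-squared values.
#' @param threshold Significance threshold.
#' @return Selected component count (>= 1).
#' @export
select_ncomp_q2 <- function(q2, threshold = 0.0975) {
  if (length(q2) == 0L) stop("need at least one Q2 value", call. = FALSE)
  idx <- which(q2 > threshold)
  if (length(idx)) max(idx) else 1L
}

#' Round down to the nearest tenth
#'
#' @param x Number in `[0, 1]`.
#' @return Largest multiple of 0.1 not exceeding `x` (up to floating point).
#' @export
floor_tenth <- function(x) {
  stopifnot(x >= 0, x <= 1)
  floor(x * 10 + 1e-9) / 10
}

#' Percentage of distinct values in a column
#'
#' @param column Non-empty vector.
#' @return `100 * n_distinct / n`.
#' @export
uniqueness_percent <- function(column) {
  if (length(column) == 0L) stop("empty column", call. = FALSE)
  100 * length(unique(column)) / length(column)
}

#' Default per-component feature-count grid
#'
#' `{1..10, 15, 20, 25, 30, 40, 50}` truncated at the feature count.
#'
#' @param p Number of features.
#' @return Sorted integer vector.
#' @export
default_keep_grid <- function(p) {
  g <- c(1:10, 15L, 20L, 25L, 30L, 40L, 50L)
  sort(unique(g[g <= p]))
}

stop_repair_abort <- function(msg, repair_log) {
  cnd <- structure(
    class = c("omiclink_repair_abort", "error", "condition"),
    list(message = msg, call = sys.call(-1L), repair_log = repair_log)
  )
  stop(cnd)
}

#' Near-zero-variance repair loop
#'
#' Runs a retryable tuning computation; when it fails with a tunable failure
#' (zero-variance column or non-convergence), the percentage of distinct
#' values is computed for every column of the implicated dataset(s), the
#' dataset holding the global minimum is identified, all its columns
#' attaining that minimum are removed, and the task is restarted. The loop
#' ends with success or aborts (classed error `omiclink_repair_abort`
#' carrying the full repair log) once a dataset drops below `min_features`.
#' Non-tunable errors propagate unchanged.
#'
#' @param task Function taking the named list of datasets and returning the
#'   tuning result.
#' @param datasets Named list of [omics_dataset()] objects.
#' @param min_features Abort bound: smallest allowed feature count.
#' @return List with `result`, the possibly reduced `datasets`, and
#'   `repair_log` (one record per removal round).
#' @export
nzv_repair <- function(task, datasets, min_features = 2L) {
  stopifnot(is.function(task), length(datasets) >= 1L,
            !is.null(names(datasets)))
  repair_log <- list()
  iter <- 0L
  repeat {
    res <- tryCatch(task(datasets),
                    omiclink_tunable_failure = function(e) e)
    if (!is_tunable_failure(res)) {
      return(list(result = res, datasets = datasets, repair_log = repair_log))
    }
    iter <- iter + 1L
    implicated <- intersect(res$datasets, names(datasets))
    if (length(implicated) == 0L) implicated <- names(datasets)
    mins <- vapply(implicated, function(nm) {
      min(apply(datasets[[nm]]$values, 2L, uniqueness_percent))
    }, 1)
    target <- implicated[which.min(mins)]
    u <- apply(datasets[[target]]$values, 2L, uniqueness_percent)
    drop_cols <- which(u == min(u))
    removed <- colnames(datasets[[target]]$values)[drop_cols]
    repair_log[[iter]] <- list(iteration = iter, dataset = target,
                               removed_feature_ids = removed,
                               uniqueness_percent = min(u))
    datasets[[target]]$values <-
      datasets[[target]]$values[, -drop_cols, drop = FALSE]
    datasets[[target]] <- add_provenance(datasets[[target]], "nzv_repair",
                                         list(removed = removed))
    if (ncol(datasets[[target]]$values) < min_features) {
      stop_repair_abort(
        sprintf("dataset '%s' dropped below %d features during repair",
                target, min_features),
        repair_log
      )
    }
  }
}
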