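# Upload-time pre-filtering: low-count removal, MAD cap, and the
# compositional (CLR) preprocessing of microbiome count tables.

filter_report <- function(stage, removed_feature_ids, parameters, n_before) {
  structure(
    list(stage = stage,
         removed_feature_ids = as.character(removed_feature_ids),
         parameters = parameters,
         n_before = n_before,
         n_after = n_before - length(removed_feature_ids)),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report %s> %d -> %d features (%d removed)\n",
              x$stage, x$n_before, x$n_after, length(x$removed_feature_ids)))
  invisible(x)
}

#' Median absolute deviation of a column
#'
#' `median(|x - median(x)|)` without the 1.4826 normal-consistency constant:
#' the value is used only to rank features by robust spread, and the constant
#' is ranking-invariant.
#'
#' @param column Non-empty numeric vector.
#' @return A single non-negative number.
#' @export
column_mad <- function(column) {
  if (length(column) == 0L) stop("empty column", call. = FALSE)
  stats::median(abs(column - stats::median(column)))
}

#' Remove features with a low total count
#'
#' Drops every feature column whose column sum is strictly below `min_total`
#' (default 10), preserving the order of survivors.
#'
#' @param ds An [omics_dataset()].
#' @param min_total Minimum column sum to survive.
#' @return A list with `dataset` and a `report` ([filter_report]).
#' @export
low_count_filter <- function(ds, min_total = 10) {
  validate_omics_dataset(ds)
  sums <- colSums(ds$values)
  drop <- sums < min_total
  if (all(drop)) {
    stop("low-count filter would remove every feature of '", ds$name, "'",
         call. = FALSE)
  }
  report <- filter_report("low_count", colnames(ds$values)[drop],
                          list(min_total = min_total), ncol(ds$values))
  ds$values <- ds$values[, !drop, drop = FALSE]
  ds <- add_provenance(ds, "low_count_filter", list(min_total = min_total))
  list(dataset = ds, report = report)
}

#' Cap the feature count by median absolute deviation
#'
#' Datasets with at most `cap` features pass through unchanged. Above the cap,
#' the low-count filter runs first; if more than `cap` features remain, the
#' surplus columns with the smallest [column_mad()] are removed so that
#' exactly `cap` survive. MAD ties at the cutoff are broken by keeping
#' earlier columns.
#'
#' @inheritParams low_count_filter
#' @param cap Maximum number of features to retain (default 10,000).
#' @return A list with `dataset` and `reports` (list of [filter_report]).
#' @export
mad_cap_filter <- function(ds, cap = 10000, min_total = 10) {
  validate_omics_dataset(ds)
  p <- ncol(ds$values)
  if (p <= cap) {
    return(list(dataset = ds,
                reports = list(filter_report("mad_cap", character(),
                                             list(cap = cap), p))))
  }
  lc <- low_count_filter(ds, min_total = min_total)
  ds <- lc$dataset
  reports <- list(lc$report)
  p2 <- ncol(ds$values)
  if (p2 > cap) {
    mads <- apply(ds$values, 2L, column_mad)
    # removal priority: smallest MAD first; ties -> later column removed first
    drop_idx <- order(mads, -seq_along(mads))[seq_len(p2 - cap)]
    removed <- colnames(ds$values)[sort(drop_idx)]
    ds$values <- ds$values[, -drop_idx, drop = FALSE]
    ds <- add_provenance(ds, "mad_cap_filter", list(cap = cap))
    reports <- c(reports, list(filter_report("mad_cap", removed,
                                             list(cap = cap), p2)))
  }
  list(dataset = ds, reports = reports)
}

#' Compositional preprocessing of microbiome count tables
#'
#' Mirrors the standard microbiome recipe for sparse multivariate models:
#' (1) remove features whose total raw count is at or below
#' `rel_threshold` times the grand total (the 0.01 percent rule);
#' (2) add a pseudo-count `offset` to every remaining cell; (3) total-sum
#' scale each sample and apply the centered log-ratio transform
#' `clr(x)_i = ln(x_i) - mean_j ln(x_j)`, after which every row sums to zero.
#' Because CLR is scale-invariant the total-sum scaling does not change the
#' output; it is kept for clarity of provenance.
#'
#' The exact threshold semantics are not pinned down by upstream descriptions,
#' so both knobs are exposed: `strict` switches the comparison between
#' `<=` (default) and `<`, and `offset_before_filter` applies the offset
#' before computing the totals used for filtering.
#'
#' @param ds An [omics_dataset()] flagged `is_microbiome`, holding raw
#'   non-negative integer counts.
#' @param offset Pseudo-count added to every retained cell (default 1).
#' @param rel_threshold Fraction of the grand total below which a feature is
#'   discarded (default `1e-4`).
#' @param strict Use strict `<` instead of `<=` in the low-count rule.
#' @param offset_before_filter Add the offset before computing totals.
#' @return A list with `dataset` (continuous CLR values) and `reports`.
#' @export
mixmc_preprocess <- function(ds, offset = 1, rel_threshold = 1e-4,
                             strict = FALSE, offset_before_filter = FALSE) {
  validate_omics_dataset(ds)
  if (!ds$is_microbiome) {
    stop("dataset '", ds$name, "' is not flagged as microbiome counts",
         call. = FALSE)
  }
  v <- ds$values
  if (any(v < 0)) stop("negative counts in '", ds$name, "'", call. = FALSE)
  if (any(abs(v - round(v)) > 1e-8)) {
    stop("non-integer counts in '", ds$name,
         "'; microbiome blocks must hold raw counts", call. = FALSE)
  }
  if (isTRUE(offset_before_filter)) v <- v + offset
  totals <- colSums(v)
  cutoff <- rel_threshold * sum(v)
  drop <- if (strict) totals < cutoff else totals <= cutoff
  if (all(drop)) {
    stop("low-count rule would remove every feature of '", ds$name, "'",
         call. = FALSE)
  }
  rep_lc <- filter_report("mixmc_low_count", colnames(v)[drop],
                          list(rel_threshold = rel_threshold, strict = strict,
                               offset_before_filter = offset_before_filter),
                          ncol(v))
  v <- v[, !drop, drop = FALSE]
  if (!isTRUE(offset_before_filter)) v <- v + offset
  if (any(rowSums(v) == 0)) {
    bad <- rownames(v)[rowSums(v) == 0]
    stop("all-zero sample row(s) with offset 0: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tss <- v / rowSums(v)
  lg <- log(tss)
  clr <- lg - rowMeans(lg)
  rep_clr <- filter_report("clr", character(),
                           list(offset = offset), ncol(clr))
  out <- ds
  out$values <- clr
  out <- add_provenance(out, "mixmc_preprocess",
                        list(offset = offset, rel_threshold = rel_threshold,
                             strict = strict,
                             offset_before_filter = offset_before_filter))
  list(dataset = out, reports = list(rep_lc, rep_clr))
}

#' Dispatch the upload-time pre-filter
#'
#' Microbiome blocks go through [mixmc_preprocess()]; everything else through
#' [mad_cap_filter()], which is the identity for datasets at or below the cap.
#'
#' @inheritParams mad_cap_filter
#' @param ... Passed on to [mixmc_preprocess()] for microbiome blocks.
#' @return A list with `dataset` and `reports`.
#' @export
prefilter <- function(ds, cap = 10000, min_total = 10, ...) {
  if (ds$is_microbiome) {
    mixmc_preprocess(ds, ...)
  } else {
    mad_cap_filter(ds, cap = cap, min_total = min_total)
  }
}
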