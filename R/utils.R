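# Internal helpers shared by the fitting and tuning code.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so library code never leaks
#' side effects into the user's session.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Tunable failures are the condition class consumed by nzv_repair(): they mark
# numerical failures (zero-variance columns, non-convergence) that can be fixed
# by removing low-uniqueness feature columns and restarting, as opposed to
# genuine user errors which propagate unchanged.
stop_tunable <- function(msg, datasets = character()) {
  cnd <- structure(
    class = c("omiclink_tunable_failure", "error", "condition"),
    list(message = msg, call = sys.call(-1L), datasets = datasets)
  )
  stop(cnd)
}

is_tunable_failure <- function(x) inherits(x, "omiclink_tunable_failure")

#' Column-standardize a matrix
#'
#' Zero-variance columns under `scale = TRUE` raise a tunable failure naming
#' the offending columns and the dataset, so cross-validation loops can hand
#' the problem to the repair machinery.
#' @noRd
standardize <- function(X, center = TRUE, scale = TRUE, dataset = "X") {
  X <- as.matrix(X)
  n <- nrow(X)
  cm <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2L, cm, "-")
  if (scale) {
    csd <- sqrt(colSums(Xc^2) / max(1L, n - 1L))
    bad <- csd < 1e-12
    if (any(bad)) {
      stop_tunable(
        sprintf(
          "zero-variance column(s) in dataset '%s': %s",
          dataset, paste(colnames(X)[bad], collapse = ", ")
        ),
        datasets = dataset
      )
    }
    Xc <- sweep(Xc, 2L, csd, "/")
  } else {
    csd <- rep(1, ncol(X))
  }
  names(cm) <- names(csd) <- colnames(X)
  list(X = Xc, center = cm, scale = csd)
}

apply_standardization <- function(X, center, scale) {
  sweep(sweep(as.matrix(X), 2L, center, "-"), 2L, scale, "/")
}

#' Soft-threshold a weight vector to exactly `keep` nonzero entries
#'
#' The threshold is the (keep+1)-th largest magnitude; entries ranked in the
#' top `keep` (stable order: magnitude descending, then original index) are
#' shrunk towards zero by that amount, the rest are zeroed. Magnitude ties at
#' the boundary are resolved in favour of earlier columns, which then survive
#' with a vanishing but nonzero weight so the nonzero count is exactly `keep`.
#' @noRd
soft_threshold_keep <- function(w, keep) {
  p <- length(w)
  keep <- as.integer(keep)
  if (keep < 1L || keep > p) stop("`keep` must be in [1, p]", call. = FALSE)
  if (keep == p) return(w)
  ord <- order(-abs(w), seq_len(p))
  active <- ord[seq_len(keep)]
  lambda <- abs(w[ord[keep + 1L]])
  mag <- abs(w[active]) - lambda
  mag[mag <= 0] <- .Machine$double.eps
  out <- numeric(p)
  out[active] <- sign(w[active]) * mag
  names(out) <- names(w)
  out
}

unit_norm <- function(v, dataset = "X") {
  nrm <- sqrt(sum(v^2))
  if (!is.finite(nrm) || nrm < 1e-300) {
    stop_tunable("degenerate (all-zero) loading vector", datasets = dataset)
  }
  v / nrm
}

# Deterministic sign convention: flip a loading vector so its largest-magnitude
# entry is positive (first index on ties), making fits comparable across runs.
sign_flip <- function(v) {
  i <- which.max(abs(v))
  if (length(i) && v[i] < 0) -1 else 1
}

is_hex_color <- function(x) grepl("^#?[0-9A-Fa-f]{6}$", x)

normalize_hex <- function(x) {
  ifelse(startsWith(x, "#"), toupper(x), paste0("#", toupper(x)))
}

# Small deterministic palette for classes/blocks lacking user colors.
default_palette <- function(n) {
  base <- c(
    "#1B9E77", "#D95F02", "#7570B3", "#E7298A", "#66A61E",
    "#E6AB02", "#A6761D", "#666666", "#1F78B4", "#B2DF8A"
  )
  rep_len(base, n)
}
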