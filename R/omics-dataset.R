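# Omics data containers and CSV/TSV input-output.

#' Construct an omics dataset
#'
#' An `omics_dataset` is one named samples-by-features numeric block: rows are
#' samples, columns features. The values matrix must carry unique row and
#' column names and contain only finite numbers; missing values are a hard
#' error because imputation belongs upstream of this package.
#'
#' @param name Short identifier for the block (e.g. `"metabolome"`).
#' @param values Numeric matrix, samples in rows, features in columns, with
#'   complete `dimnames`.
#' @param is_microbiome Logical; marks raw amplicon (ASV/OTU) count tables so
#'   that [prefilter()] routes them through the compositional
#'   [mixmc_preprocess()] instead of the MAD cap.
#' @param provenance List of transform records accumulated by filtering and
#'   preprocessing steps.
#' @return An object of class `omics_dataset`.
#' @seealso [read_omics_table()], [prefilter()]
#' @export
omics_dataset <- function(name, values, is_microbiome = FALSE,
                          provenance = list()) {
  ds <- structure(
    list(
      name = as.character(name),
      values = as.matrix(values),
      is_microbiome = isTRUE(is_microbiome),
      provenance = provenance
    ),
    class = "omics_dataset"
  )
  validate_omics_dataset(ds)
  ds
}

validate_omics_dataset <- function(ds) {
  v <- ds$values
  if (is.null(rownames(v)) || is.null(colnames(v))) {
    stop("dataset '", ds$name, "': values must have sample and feature names",
         call. = FALSE)
  }
  dup_s <- unique(rownames(v)[duplicated(rownames(v))])
  if (length(dup_s)) {
    stop("dataset '", ds$name, "': duplicated sample id(s): ",
         paste(dup_s, collapse = ", "), call. = FALSE)
  }
  dup_f <- unique(colnames(v)[duplicated(colnames(v))])
  if (length(dup_f)) {
    stop("dataset '", ds$name, "': duplicated feature id(s): ",
         paste(dup_f, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(v)) {
    stop("dataset '", ds$name, "': values must be numeric", call. = FALSE)
  }
  if (anyNA(v) || any(!is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)[1L, ]
    stop("dataset '", ds$name, "': missing/non-finite value at sample '",
         rownames(v)[bad[1L]], "', feature '", colnames(v)[bad[2L]],
         "'; impute upstream before loading", call. = FALSE)
  }
  invisible(ds)
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf(
    "<omics_dataset '%s'> %d samples x %d features%s\n",
    x$name, nrow(x$values), ncol(x$values),
    if (x$is_microbiome) " (microbiome counts)" else ""
  ))
  if (length(x$provenance)) {
    cat("  transforms:",
        paste(vapply(x$provenance, `[[`, "", "operation"), collapse = " -> "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.omics_dataset <- function(x) dim(x$values)

sample_ids <- function(ds) rownames(ds$values)
feature_ids <- function(ds) colnames(ds$values)

add_provenance <- function(ds, operation, parameters = list()) {
  ds$provenance <- c(ds$provenance,
                     list(list(operation = operation, parameters = parameters)))
  ds
}

sniff_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an omics matrix from CSV/TSV
#'
#' The first column holds the sample ids (or feature ids when
#' `transpose = TRUE`, for tables stored features-by-samples), the header row
#' the other axis. The delimiter is sniffed from the extension (`.csv` comma,
#' anything else tab) unless `sep` is given. Files above 50 Mb trigger a
#' warning only -- the limit is a deployment convention, not an algorithmic
#' one.
#'
#' @inheritParams omics_dataset
#' @param path Path to a delimited text file.
#' @param transpose Flip the matrix before validation (input stored
#'   features-by-samples).
#' @param sep Field delimiter override.
#' @return A validated [omics_dataset()] oriented samples-by-features.
#' @export
read_omics_table <- function(path, name, is_microbiome = FALSE,
                             transpose = FALSE, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (isTRUE(file.size(path) > 50e6)) {
    warning("file '", basename(path), "' exceeds 50 Mb; large uploads are ",
            "discouraged but processed anyway", call. = FALSE)
  }
  sep <- sniff_sep(path, sep)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("table must have an id column plus >=1 data column",
                           call. = FALSE)
  row_ids <- raw[[1L]]
  col_ids <- colnames(raw)[-1L]
  chr <- as.matrix(raw[, -1L, drop = FALSE])
  missing_like <- is.na(chr) | toupper(trimws(chr)) %in% c("", "NA", "NAN", "NULL")
  if (any(missing_like)) {
    bad <- which(missing_like, arr.ind = TRUE)[1L, ]
    stop("missing value at row ", bad[1L], " ('", row_ids[bad[1L]],
         "'), column ", bad[2L], " ('", col_ids[bad[2L]],
         "'); impute upstream before loading", call. = FALSE)
  }
  num <- suppressWarnings(as.numeric(chr))
  if (anyNA(num)) {
    bad <- which(matrix(is.na(num), nrow(chr)), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell '", chr[bad[1L], bad[2L]], "' at row ", bad[1L],
         " ('", row_ids[bad[1L]], "'), column ", bad[2L], " ('",
         col_ids[bad[2L]], "')", call. = FALSE)
  }
  m <- matrix(num, nrow = nrow(chr),
              dimnames = list(row_ids, col_ids))
  if (isTRUE(transpose)) m <- t(m)
  omics_dataset(name, m, is_microbiome = is_microbiome,
                provenance = list(list(operation = "read",
                                       parameters = list(path = path,
                                                         transpose = transpose))))
}

#' Write an omics dataset to CSV
#'
#' Values are printed with 17 significant digits so that
#' `read_omics_table(write_omics_table(ds))` round-trips exactly.
#'
#' @param ds An [omics_dataset()].
#' @param path Output path (`.csv` recommended).
#' @param sep Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_omics_table <- function(ds, path, sep = ",") {
  if (ncol(ds$values) == 0L) {
    stop("dataset '", ds$name, "' has no features; nothing to write",
         call. = FALSE)
  }
  validate_omics_dataset(ds)
  chr <- matrix(sprintf("%.17g", ds$values), nrow = nrow(ds$values))
  out <- cbind(sample = rownames(ds$values), chr)
  colnames(out) <- c("sample", colnames(ds$values))
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct a metadata table
#'
#' Maps every sample to its class label, with an optional hex color per class
#' used by plotting and network export.
#'
#' @param sample_to_class Named character vector: names are sample ids, values
#'   class labels.
#' @param class_to_color Optional named character vector of 6-hex-digit colors
#'   keyed by class label.
#' @return An object of class `metadata_table`.
#' @export
metadata_table <- function(sample_to_class, class_to_color = NULL) {
  if (is.null(names(sample_to_class)) || anyNA(names(sample_to_class))) {
    stop("sample_to_class must be a named vector", call. = FALSE)
  }
  dup <- unique(names(sample_to_class)[duplicated(names(sample_to_class))])
  if (length(dup)) {
    stop("sample id(s) listed more than once: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  sample_to_class <- stats::setNames(as.character(sample_to_class),
                                     names(sample_to_class))
  if (!is.null(class_to_color)) {
    bad <- names(class_to_color)[!is_hex_color(class_to_color)]
    if (length(bad)) {
      stop("malformed color for class(es): ", paste(bad, collapse = ", "),
           " (need 6 hex digits)", call. = FALSE)
    }
    class_to_color <- stats::setNames(normalize_hex(as.character(class_to_color)),
                                      names(class_to_color))
    missing_cls <- setdiff(unique(sample_to_class), names(class_to_color))
    if (length(missing_cls)) {
      stop("no color given for class(es): ",
           paste(missing_cls, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(sample_to_class = sample_to_class,
                 class_to_color = class_to_color),
            class = "metadata_table")
}

#' @export
print.metadata_table <- function(x, ...) {
  tab <- table(x$sample_to_class)
  cat(sprintf("<metadata_table> %d samples, %d classes\n",
              length(x$sample_to_class), length(tab)))
  print(tab)
  invisible(x)
}

#' Read sample metadata (classes and optional colors)
#'
#' Expects columns `sample,class[,color]` (matched by position; header names
#' are free). Colors must be 6-hex-digit strings, with or without a leading
#' `#`.
#'
#' @param path Path to a delimited text file.
#' @param sep Field delimiter override (sniffed from the extension otherwise).
#' @return A [metadata_table()].
#' @export
read_metadata <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- sniff_sep(path, sep)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("metadata needs at least sample and class columns",
                           call. = FALSE)
  s2c <- stats::setNames(raw[[2L]], raw[[1L]])
  c2c <- NULL
  if (ncol(raw) >= 3L) {
    per_class <- tapply(raw[[3L]], raw[[2L]], function(v) unique(v))
    multi <- names(per_class)[lengths(per_class) > 1L]
    if (length(multi)) {
      stop("conflicting colors within class(es): ",
           paste(multi, collapse = ", "), call. = FALSE)
    }
    c2c <- vapply(per_class, `[[`, "", 1L)
  }
  metadata_table(s2c, c2c)
}

#' Restrict datasets and metadata to their common samples
#'
#' Every dataset is reduced to the samples present in all datasets and in the
#' metadata, with rows reordered identically (ascending lexicographic sample
#' id) so that downstream cross-validation fold assignment is reproducible.
#'
#' @param datasets List of [omics_dataset()] objects.
#' @param metadata A [metadata_table()].
#' @return A list with `datasets` (the harmonized blocks), `samples` (the
#'   common ordered sample ids) and `classes` (class labels in that order).
#' @export
harmonize <- function(datasets, metadata) {
  stopifnot(length(datasets) >= 1L)
  sets <- c(lapply(datasets, sample_ids), list(names(metadata$sample_to_class)))
  common <- Reduce(intersect, sets)
  if (length(common) == 0L) {
    counts <- vapply(sets, length, 1L)
    labels <- c(vapply(datasets, function(d) d$name, ""), "metadata")
    stop("no sample shared by all inputs (",
         paste(sprintf("%s: %d", labels, counts), collapse = ", "), ")",
         call. = FALSE)
  }
  common <- sort(common, method = "radix")
  datasets <- lapply(datasets, function(ds) {
    ds$values <- ds$values[common, , drop = FALSE]
    validate_omics_dataset(ds)
    ds
  })
  names(datasets) <- vapply(datasets, function(d) d$name, "")
  list(datasets = datasets,
       samples = common,
       classes = unname(metadata$sample_to_class[common]))
}
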