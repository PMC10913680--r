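# End-to-end workflow orchestration from a YAML config: ingest ->
# single-omics feature selection -> pairwise integration -> multiblock
# integration, with machine-readable artifacts and provenance logs.

#' Read a workflow configuration
#'
#' The YAML config holds dataset entries (`path`, `name`, `microbiome`,
#' `transpose`), a `metadata` path, `single`/`pairwise`/`diablo` analysis
#' sections, the CV layout (`folds`, `repeats`, `seed`) and `output_dir`.
#'
#' @param path YAML file.
#' @return The config as a named list (class `workflow_config`).
#' @export
read_workflow_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$datasets)) stop("config lacks a `datasets` section",
                                  call. = FALSE)
  nms <- vapply(cfg$datasets, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("dataset names must be unique", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$repeats <- as.integer(cfg$repeats %||% 10L)
  cfg$output_dir <- cfg$output_dir %||% "omiclink_out"
  structure(cfg, class = "workflow_config")
}

#' Load, pre-filter and harmonize the datasets named in a config
#'
#' @param config A `workflow_config` (or path to one).
#' @param base_dir Directory that relative paths are resolved against.
#' @return List with `datasets` (pre-filtered, harmonized), `classes`,
#'   `metadata` and `filter_reports`.
#' @export
ingest_datasets <- function(config, base_dir = ".") {
  if (is.character(config)) config <- read_workflow_config(config)
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  datasets <- lapply(config$datasets, function(d) {
    read_omics_table(resolve(d$path), d$name,
                     is_microbiome = isTRUE(d$microbiome),
                     transpose = isTRUE(d$transpose))
  })
  metadata <- read_metadata(resolve(config$metadata))
  reports <- list()
  datasets <- lapply(datasets, function(ds) {
    out <- prefilter(ds)
    reports[[ds$name]] <<- out$reports
    out$dataset
  })
  h <- harmonize(datasets, metadata)
  list(datasets = h$datasets, classes = h$classes, samples = h$samples,
       metadata = metadata, filter_reports = reports)
}

model_to_list <- function(model) {
  blocks <- lapply(model$blocks, function(b) {
    list(name = b$name, keep = b$keep,
         scores = as.data.frame(b$scores),
         loadings = as.data.frame(b$loadings))
  })
  list(algorithm = model$algorithm, mode = model$mode, ncomp = model$ncomp,
       class_labels = model$class_labels,
       explained_variance = model$explained_variance,
       design = if (!is.null(model$design)) model$design$values,
       blocks = blocks)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

write_model_artifacts <- function(model, prefix) {
  write_json_artifact(model_to_list(model), paste0(prefix, "_model.json"))
  for (nm in names(model$blocks)) {
    b <- model$blocks[[nm]]
    utils::write.csv(b$loadings,
                     paste0(prefix, "_", nm, "_loadings.csv"))
    utils::write.csv(b$scores, paste0(prefix, "_", nm, "_scores.csv"))
  }
}

tune_to_list <- function(tune) {
  surf <- tune$criterion_surface
  list(selected_ncomp = tune$selected_ncomp,
       selected_keep = tune$selected_keep,
       criterion = tune$criterion,
       criterion_surface = surf,
       folds = tune$folds, repeats = tune$repeats, seed = tune$seed,
       repair_log = tune$repair_log)
}

log_event <- function(log, stage, dataset, message, ...) {
  c(log, list(list(stage = stage, dataset = dataset, message = message, ...)))
}

#' Run the single-omics feature-selection step
#'
#' Per configured dataset: pre-filter, then either the unsupervised path
#' (PCA, number of components from the 80 percent explained-variance rule,
#' sparse PCA keeps tuned by score correlation) or the supervised path
#' (sPLS-DA at the pre-selected components, keeps tuned by cross-validated
#' BER), then reduce the dataset to the selected features and write the
#' reduced table, model JSON, tune JSON and loading/score CSVs. A failing
#' dataset is logged and skipped; the others continue.
#'
#' @param config A `workflow_config` or path to one.
#' @param base_dir Base directory for relative paths.
#' @return Invisibly, a list with the reduced datasets and the event log.
#' @export
run_single <- function(config, base_dir = ".") {
  if (is.character(config)) config <- read_workflow_config(config)
  ing <- ingest_datasets(config, base_dir)
  outdir <- file.path(config$output_dir, "single")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  reduced <- list()
  for (entry in config$single) {
    nm <- entry$dataset
    res <- tryCatch({
      ds <- ing$datasets[[nm]]
      if (is.null(ds)) stop("dataset '", nm, "' not found", call. = FALSE)
      method <- match.arg(entry$method, c("plsda", "pca"))
      prefix <- file.path(outdir, paste0(nm, "_", method))
      if (method == "pca") {
        full <- fit_pca(ds, ncomp = min(nrow(ds$values) - 1L,
                                        ncol(ds$values)))
        H <- select_ncomp_variance(full, entry$variance_threshold %||% 0.80)
        tune <- tune_spca(ds, ncomp = H,
                          grid = entry$grid,
                          folds = config$folds %||% 5L,
                          repeats = config$repeats, seed = config$seed)
        fit <- fit_spca(ds, ncomp = H, keep = tune$selected_keep)
      } else {
        H <- as.integer(entry$ncomp %||% 4L)
        tune <- tune_splsda(ds, ing$classes, ncomp_max = H,
                            grid = entry$grid,
                            folds = config$folds %||%
                              min(5L, min(table(ing$classes))),
                            repeats = config$repeats, seed = config$seed)
        fit <- fit_splsda(ds, ing$classes, ncomp = tune$selected_ncomp,
                          keep = tune$selected_keep)
      }
      red <- reduce_dataset(ds, fit, tune)
      write_omics_table(red, paste0(prefix, "_reduced.csv"))
      write_model_artifacts(fit, prefix)
      write_json_artifact(tune_to_list(tune), paste0(prefix, "_tune.json"))
      reduced[[paste(nm, method, sep = "_")]] <- red
      log <- log_event(log, "single", nm, "completed", method = method,
                       ncomp = tune$selected_ncomp,
                       n_features = ncol(red$values))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      log <- log_event(log, "single", nm, paste("failed:", res))
    }
  }
  write_json_artifact(list(events = log,
                           filter_reports = rapply(ing$filter_reports,
                                                   unclass, how = "list"),
                           seed = config$seed),
                      file.path(outdir, "provenance.json"))
  invisible(list(reduced = reduced, log = log, ingested = ing))
}

#' Run the pairwise two-block integration step
#'
#' Per configured ordered pair: Q-squared component selection, keep tuning by
#' predicted-score correlation (under the near-zero-variance repair loop),
#' the final sparse PLS fit, the cross-block similarity matrix and network
#' exports. With `bidirectional: true` the swapped order runs as well (in
#' regression mode the two orders genuinely differ). A repair abort is
#' recorded and the pair skipped.
#'
#' @inheritParams run_single
#' @param datasets Optional named list of [omics_dataset()] overriding the
#'   config's files (e.g. reduced datasets from [run_single()]).
#' @return Invisibly, a list of per-pair results plus the event log.
#' @export
run_pairwise <- function(config, base_dir = ".", datasets = NULL) {
  if (is.character(config)) config <- read_workflow_config(config)
  if (is.null(datasets)) {
    ing <- ingest_datasets(config, base_dir)
    datasets <- ing$datasets
  }
  outdir <- file.path(config$output_dir, "pairwise")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  results <- list()
  jobs <- list()
  for (pair in config$pairwise) {
    jobs[[length(jobs) + 1L]] <- pair
    if (isTRUE(pair$bidirectional)) {
      swapped <- pair
      swapped$x <- pair$y; swapped$y <- pair$x
      jobs[[length(jobs) + 1L]] <- swapped
    }
  }
  for (pair in jobs) {
    key <- paste(pair$x, pair$y, sep = "_vs_")
    res <- tryCatch({
      X <- datasets[[pair$x]]; Y <- datasets[[pair$y]]
      if (is.null(X) || is.null(Y)) stop("unknown dataset in pair ", key,
                                         call. = FALSE)
      mode <- pair$mode %||% "canonical"
      ncomp_max <- as.integer(pair$ncomp %||% 4L)
      rep_out <- nzv_repair(function(dss) {
        q2 <- q2_scores(dss[[pair$x]], dss[[pair$y]], ncomp = ncomp_max,
                        folds = config$folds %||% 5L,
                        repeats = config$repeats, seed = config$seed)
        H <- select_ncomp_q2(q2)
        tune <- tune_spls_keep(dss[[pair$x]], dss[[pair$y]], ncomp = H,
                               gridX = pair$gridX %||% pair$grid,
                               gridY = pair$gridY %||% pair$grid,
                               folds = config$folds %||% 5L,
                               repeats = config$repeats, seed = config$seed,
                               mode = mode)
        fit <- fit_spls(dss[[pair$x]], dss[[pair$y]], ncomp = H,
                        keepX = tune$selected_keep$X,
                        keepY = tune$selected_keep$Y, mode = mode)
        list(q2 = q2, tune = tune, fit = fit)
      }, stats::setNames(list(X, Y), c(pair$x, pair$y)))
      r <- rep_out$result
      sim <- similarity_matrix(r$fit, pair$x, pair$y)
      net <- build_network(sim, pair$cutoff %||% 0.5)
      prefix <- file.path(outdir, key)
      utils::write.csv(sim, paste0(prefix, "_similarity.csv"))
      export_network(net, paste0(prefix, "_network.graphml"), "graphml")
      export_network(net, paste0(prefix, "_network.json"), "json")
      write_model_artifacts(r$fit, prefix)
      write_json_artifact(c(tune_to_list(r$tune),
                            list(q2 = r$q2,
                                 repair_log = rep_out$repair_log)),
                          paste0(prefix, "_tune.json"))
      results[[key]] <- list(q2 = r$q2, tune = r$tune, fit = r$fit,
                             network = net,
                             repair_log = rep_out$repair_log)
      log <- log_event(log, "pairwise", key, "completed",
                       ncomp = r$tune$selected_ncomp,
                       keepX = r$tune$selected_keep$X,
                       keepY = r$tune$selected_keep$Y)
      NULL
    }, omiclink_repair_abort = function(e) {
      paste("repair aborted:", conditionMessage(e))
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) log <- log_event(log, "pairwise", key,
                                        paste("failed:", res))
  }
  write_json_artifact(list(events = log, seed = config$seed),
                      file.path(outdir, "provenance.json"))
  invisible(list(results = results, log = log))
}

#' Run the multiblock integration step
#'
#' Computes the data-driven design matrix (unless a manual value is given in
#' the config), tunes component count and per-block keeps by cross-validated
#' BER, refits the final multiblock model, and writes circos edges, network
#' exports, per-block loadings/scores and the design value report.
#'
#' @inheritParams run_pairwise
#' @param classes Optional class labels overriding the ingested metadata.
#' @return Invisibly, a list with design, tune, fit, network and the log.
#' @export
run_diablo <- function(config, base_dir = ".", datasets = NULL,
                       classes = NULL) {
  if (is.character(config)) config <- read_workflow_config(config)
  if (is.null(datasets) || is.null(classes)) {
    ing <- ingest_datasets(config, base_dir)
    datasets <- datasets %||% ing$datasets
    classes <- classes %||% ing$classes
  }
  cfgd <- config$diablo
  bn <- unlist(cfgd$blocks)
  if (length(bn) < 2L) {
    stop("multiblock integration needs >= 2 blocks; ",
         "use the single-omics step for one dataset", call. = FALSE)
  }
  blocks <- datasets[bn]
  if (any(vapply(blocks, is.null, TRUE))) {
    stop("unknown block(s): ",
         paste(bn[vapply(blocks, is.null, TRUE)], collapse = ", "),
         call. = FALSE)
  }
  outdir <- file.path(config$output_dir, "diablo")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  design <- if (!is.null(cfgd$design)) {
    design_matrix(bn, as.numeric(cfgd$design))  # manual value overrides
  } else {
    data_driven_design(blocks)
  }
  tune <- tune_diablo(blocks, classes,
                      ncomp_max = as.integer(cfgd$ncomp %||% 4L),
                      grids = cfgd$grids,
                      folds = config$folds %||%
                        min(5L, min(table(classes))),
                      repeats = config$repeats, seed = config$seed,
                      design = design)
  blocks <- tune$datasets %||% blocks  # repair may have dropped columns
  fit <- fit_diablo(blocks, classes, ncomp = tune$selected_ncomp,
                    design = design,
                    keep = lapply(tune$selected_keep, function(k)
                      k[seq_len(tune$selected_ncomp)]))
  net <- circos_edges(fit, cutoff = cfgd$cutoff %||% 0.8)
  prefix <- file.path(outdir, "diablo")
  write_model_artifacts(fit, prefix)
  export_network(net, paste0(prefix, "_network.graphml"), "graphml")
  export_network(net, paste0(prefix, "_network.json"), "json")
  write_json_artifact(c(tune_to_list(tune),
                        list(design_value = design$values[1L, 2L],
                             design_raw_min = design$raw_min,
                             design_pairwise = as.list(design$pairwise %||%
                                                         list()))),
                      paste0(prefix, "_tune.json"))
  log <- log_event(log, "diablo", paste(bn, collapse = "+"), "completed",
                   ncomp = tune$selected_ncomp,
                   design_value = design$values[1L, 2L])
  write_json_artifact(list(events = log, seed = config$seed),
                      file.path(outdir, "provenance.json"))
  invisible(list(design = design, tune = tune, fit = fit, network = net,
                 log = log))
}
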