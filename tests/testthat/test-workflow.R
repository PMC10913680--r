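# End-to-end workflow on a small synthetic experiment written to disk.

make_workflow <- function(dir, seed = 11) {
  spec <- synthetic_spec(
    classes = 3, n_per_class = 4,
    blocks = list(synthetic_block("metab", 20, "continuous", 5, 3),
                  synthetic_block("asv", 120, "counts", 8, 3),
                  synthetic_block("tx", 40, "continuous", 6, 3)),
    seed = seed
  )
  g <- generate_multiomics(spec)
  for (nm in names(g$datasets)) {
    write_omics_table(g$datasets[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  meta <- data.frame(sample = names(g$metadata$sample_to_class),
                     class = unname(g$metadata$sample_to_class))
  meta$color <- unname(g$metadata$class_to_color[meta$class])
  utils::write.csv(meta, file.path(dir, "meta.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- list(
    seed = 5, folds = 3, repeats = 2, output_dir = file.path(dir, "out"),
    metadata = file.path(dir, "meta.csv"),
    datasets = list(
      list(name = "metab", path = file.path(dir, "metab.csv")),
      list(name = "asv", path = file.path(dir, "asv.csv"), microbiome = TRUE),
      list(name = "tx", path = file.path(dir, "tx.csv"))
    ),
    single = list(
      list(dataset = "metab", method = "plsda", ncomp = 2, grid = c(2, 5, 10)),
      list(dataset = "tx", method = "pca", grid = c(2, 5, 10))
    ),
    pairwise = list(
      list(x = "metab", y = "tx", mode = "canonical", ncomp = 2,
           bidirectional = TRUE, grid = c(2, 5, 10), cutoff = 0.5)
    ),
    diablo = list(blocks = c("metab", "asv", "tx"), ncomp = 2,
                  grids = list(metab = c(5, 10), asv = c(8, 16),
                               tx = c(6, 12)),
                  cutoff = 0.7)
  )
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  list(config = path, truth = g$truth, labels = g$labels, data = g)
}

test_that("the single-omics step produces reduced datasets and artifacts", {
  dir <- withr::local_tempdir()
  wf <- make_workflow(dir)
  res <- run_single(wf$config)
  msgs <- vapply(res$log, `[[`, "", "message")
  expect_true(all(msgs == "completed"))
  expect_true(file.exists(file.path(dir, "out/single/metab_plsda_reduced.csv")))
  expect_true(file.exists(file.path(dir, "out/single/tx_pca_reduced.csv")))
  expect_true(file.exists(file.path(dir, "out/single/provenance.json")))
  # reduced datasets re-read as valid datasets with fewer or equal features
  red <- read_omics_table(file.path(dir, "out/single/metab_plsda_reduced.csv"),
                          "metab")
  expect_lte(ncol(red$values), 20L)
  # microbiome block was CLR-transformed during ingest
  ing <- res$ingested
  expect_lt(max(abs(rowSums(ing$datasets$asv$values))), 1e-9)
})

test_that("pipeline artifacts are reproducible bit-for-bit given a seed", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  wf1 <- make_workflow(dir1); wf2 <- make_workflow(dir2)
  run_single(wf1$config); run_single(wf2$config)
  f1 <- file.path(dir1, "out/single/metab_plsda_reduced.csv")
  f2 <- file.path(dir2, "out/single/metab_plsda_reduced.csv")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the pairwise step runs both orders and exports networks", {
  dir <- withr::local_tempdir()
  wf <- make_workflow(dir)
  res <- run_pairwise(wf$config)
  expect_setequal(names(res$results), c("metab_vs_tx", "tx_vs_metab"))
  for (key in names(res$results)) {
    expect_true(file.exists(file.path(dir, "out/pairwise",
                                      paste0(key, "_network.graphml"))))
    expect_true(file.exists(file.path(dir, "out/pairwise",
                                      paste0(key, "_similarity.csv"))))
    expect_gte(res$results[[key]]$tune$selected_ncomp, 1L)
  }
})

test_that("a planted cross-block edge appears in the pairwise network", {
  dir <- withr::local_tempdir()
  wf <- make_workflow(dir, seed = 13)
  res <- run_pairwise(wf$config)
  net <- res$results$metab_vs_tx$network
  truth_pairs <- expand.grid(from = paste0("metab:", wf$truth$metab),
                             to = paste0("tx:", wf$truth$tx))
  found <- paste(net$edges$from, net$edges$to) %in%
    paste(truth_pairs$from, truth_pairs$to)
  expect_gt(sum(found), 0L)
})

test_that("the multiblock step computes a design, tunes, and exports", {
  dir <- withr::local_tempdir()
  wf <- make_workflow(dir)
  res <- run_diablo(wf$config)
  expect_s3_class(res$design, "design_matrix")
  expect_equal(res$design$value, floor_tenth(res$design$raw_min))
  expect_true(file.exists(file.path(dir, "out/diablo/diablo_network.json")))
  expect_true(file.exists(file.path(dir, "out/diablo/diablo_tune.json")))
  pred <- predict_classes(res$fit,
                          lapply(res$tune$datasets, `[[`, "values"))
  expect_lte(ber(wf$labels, pred), 0.25)
})

test_that("a manual design value overrides the data-driven one", {
  dir <- withr::local_tempdir()
  wf <- make_workflow(dir)
  cfg <- read_workflow_config(wf$config)
  cfg$diablo$design <- 0.6
  res <- run_diablo(cfg)
  expect_equal(unname(res$design$values[1, 2]), 0.6)
})

test_that("a single-block multiblock request is rejected with guidance", {
  dir <- withr::local_tempdir()
  wf <- make_workflow(dir)
  cfg <- read_workflow_config(wf$config)
  cfg$diablo$blocks <- "metab"
  expect_error(run_diablo(cfg), "single-omics")
})

test_that("config validation catches duplicate dataset names", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(datasets = list(list(name = "a", path = "a.csv"),
                                        list(name = "a", path = "b.csv")),
                        metadata = "m.csv"), f)
  expect_error(read_workflow_config(f), "unique")
})
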