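test_that("stratified folds balance classes and are seed-deterministic", {
  labels <- rep(paste0("V", 1:4), each = 3)
  fa <- stratified_folds(labels, folds = 3, repeats = 5, seed = 7)
  for (r in seq_along(fa)) {
    tab <- table(labels, fa[[r]])
    expect_true(all(tab == 1))  # one sample per class per fold
  }
  fb <- stratified_folds(labels, folds = 3, repeats = 5, seed = 7)
  expect_identical(fa, fb)
  expect_error(stratified_folds(labels, folds = 4), "smallest class")
})

test_that("balanced error rate follows its definition", {
  expect_equal(ber(c("A", "B"), c("A", "B")), 0)
  expect_equal(ber(c("A", "B"), c("B", "A")), 1)
  tr <- c(rep("A", 4), rep("B", 2))
  pr <- c("B", "A", "A", "A", "A", "B")
  expect_equal(ber(tr, pr), 0.375)
  # equals plain error rate on balanced classes
  set.seed(5)
  for (i in 1:10) {
    tr <- rep(c("A", "B", "C"), each = 4)
    pr <- sample(c("A", "B", "C"), 12, replace = TRUE)
    expect_equal(ber(tr, pr), mean(tr != pr))
  }
})

test_that("80 percent rule and Q2 rule match brute-force oracles", {
  shares <- c(0.85, 0.10, 0.05)
  mk <- function(ev) structure(list(explained_variance_full = ev),
                               class = "latent_model")
  expect_equal(select_ncomp_variance(mk(shares)), 1L)
  expect_equal(select_ncomp_variance(mk(c(0.5, 0.25, 0.15, 0.1))), 3L)
  set.seed(11)
  for (i in 1:20) {
    ev <- prop.table(runif(6))
    oracle <- min(which(cumsum(ev) >= 0.8))
    expect_equal(select_ncomp_variance(mk(ev)), oracle)
  }

  expect_equal(select_ncomp_q2(c(0.3, 0.12, 0.01)), 2L)
  expect_equal(select_ncomp_q2(0.5), 1L)
  expect_equal(select_ncomp_q2(c(-0.2, 0.0)), 1L)
  set.seed(12)
  for (i in 1:20) {
    q2 <- runif(5, -0.5, 0.8)
    pass <- which(q2 > 0.0975)
    oracle <- if (length(pass)) max(pass) else 1L
    expect_equal(select_ncomp_q2(q2), oracle)
  }
})

test_that("floor_tenth and uniqueness_percent match their definitions", {
  expect_equal(floor_tenth(0.87), 0.8)
  expect_equal(floor_tenth(0.90), 0.9)
  expect_equal(floor_tenth(0.999), 0.9)
  set.seed(13)
  for (x in runif(30)) {
    expect_equal(floor_tenth(x), max(seq(0, 1, 0.1)[seq(0, 1, 0.1) <= x + 1e-9]))
  }

  expect_equal(uniqueness_percent(1:8), 100)
  expect_equal(uniqueness_percent(rep(2, 4)), 25)
  expect_equal(uniqueness_percent(c(1, 1, 2, 2)), 50)
})

test_that("Q2 is near 1 for a noiseless linear response and low for noise", {
  set.seed(21)
  n <- 24
  X <- make_matrix(n, 6, seed = 22, prefix = "x")
  # response on the leading principal axis: the first PLS weight vector is
  # then self-consistent and one component carries all of Y
  w <- eigen(cov(scale(X)))$vectors[, 1]
  t1 <- as.vector(scale(X) %*% w)
  Y <- cbind(y1 = 2 * t1, y2 = -t1)
  rownames(Y) <- rownames(X)
  q2 <- q2_scores(X, Y, ncomp = 1, folds = 4, repeats = 2, seed = 1)
  expect_gt(q2[1], 0.9)
  expect_true(all(q2 <= 1))

  # independent noise: mean Q2 over seeds stays below the 0.0975 threshold
  q2n <- vapply(1:10, function(s) {
    Xn <- make_matrix(12, 8, seed = 100 + s, prefix = "x")
    Yn <- make_matrix(12, 5, seed = 200 + s, prefix = "y")
    q2_scores(Xn, Yn, ncomp = 1, folds = 3, repeats = 2, seed = s)[1]
  }, 1)
  expect_lt(mean(q2n), 0.0975)
})

test_that("singleton grids are returned unchanged by the tuners", {
  g <- planted_two_class(seed = 23, p = 20)
  tu <- tune_splsda(g$datasets$blk, g$labels, ncomp_max = 2, grid = 20,
                    folds = 3, repeats = 1, seed = 1)
  expect_equal(unique(tu$keep_per_component), 20L)

  tk <- tune_spls_keep(g$datasets$blk, g$datasets$blk, ncomp = 1,
                       gridX = 7, gridY = 4, folds = 3, repeats = 1,
                       seed = 1, mode = "canonical")
  expect_equal(tk$selected_keep$X, 7L)
  expect_equal(tk$selected_keep$Y, 4L)

  g3 <- planted_three_block(seed = 24, p = 15)
  td <- tune_diablo(g3$datasets, g3$labels, ncomp_max = 1,
                    grids = list(b1 = 5, b2 = 6, b3 = 7),
                    folds = 3, repeats = 1, seed = 1, design = 0.5)
  expect_equal(td$selected_keep, list(b1 = 5, b2 = 6, b3 = 7))
})

test_that("tuning recovers planted features with low BER (spot check)", {
  hits <- 0; bers <- numeric(3)
  for (i in 1:3) {
    g <- planted_two_class(seed = 30 + i)
    tu <- tune_splsda(g$datasets$blk, g$labels, ncomp_max = 1,
                      grid = c(1, 5, 10, 20), folds = 3, repeats = 2,
                      seed = i)
    fit <- fit_splsda(g$datasets$blk, g$labels, ncomp = 1, keep = 5)
    hits <- hits + length(intersect(support_of(fit, "blk"), g$truth$blk))
    surf <- tu$criterion_surface
    bers[i] <- surf$ber[surf$component == 1 & surf$keep == 5]
  }
  expect_gte(hits / 15, 0.8)
  expect_lte(mean(bers), 0.1)
})

test_that("the repair loop removes the planted constant column first and terminates", {
  g <- planted_two_class(seed = 40, p = 20)
  X <- g$datasets$blk
  X$values[, "blk_f3"] <- 7  # constant column: uniqueness 1/n
  Y <- make_ds(12, 8, seed = 41, name = "Y", prefix = "y")
  out <- nzv_repair(function(dss) {
    fit_spls(dss$X, dss$Y, ncomp = 1, mode = "canonical")
    "done"
  }, list(X = X, Y = Y))
  expect_equal(out$result, "done")
  expect_length(out$repair_log, 1L)
  expect_equal(out$repair_log[[1]]$dataset, "X")
  expect_equal(out$repair_log[[1]]$removed_feature_ids, "blk_f3")
  expect_false("blk_f3" %in% colnames(out$datasets$X$values))
})

test_that("repair removes from the dataset with the lower uniqueness minimum", {
  X <- make_ds(8, 5, seed = 42, name = "X")
  X$values[, 2] <- rep(c(1, 2), each = 4)          # uniqueness 25%
  Y <- make_ds(8, 5, seed = 43, name = "Y", prefix = "y")
  Y$values[, 3] <- rep(c(1, 2, 3, 4), each = 2)    # uniqueness 50%
  calls <- 0
  out <- nzv_repair(function(dss) {
    calls <<- calls + 1
    if (calls == 1) omiclink:::stop_tunable("synthetic failure",
                                            c("X", "Y"))
    "ok"
  }, list(X = X, Y = Y))
  expect_equal(out$repair_log[[1]]$dataset, "X")
  expect_equal(out$repair_log[[1]]$removed_feature_ids, "f2")
})

test_that("perpetual failure aborts once a dataset gets too small", {
  X <- make_ds(6, 4, seed = 44, name = "X")
  Y <- make_ds(6, 4, seed = 45, name = "Y", prefix = "y")
  err <- tryCatch(
    nzv_repair(function(dss) omiclink:::stop_tunable("always fails", "X"),
               list(X = X, Y = Y)),
    omiclink_repair_abort = function(e) e
  )
  expect_s3_class(err, "omiclink_repair_abort")
  expect_gt(length(err$repair_log), 0L)
})

test_that("data-driven design uses the floored minimal pairwise correlation", {
  g <- planted_two_class(seed = 50, p = 15)
  twin <- g$datasets$blk
  twin$name <- "twin"
  dd <- data_driven_design(list(blk = g$datasets$blk, twin = twin))
  expect_equal(unname(dd$pairwise), 1, tolerance = 1e-9)
  expect_equal(dd$values["blk", "twin"], 1)

  g3 <- planted_three_block(seed = 51, p = 12)
  d3 <- data_driven_design(g3$datasets)
  expect_equal(d3$value, floor_tenth(d3$raw_min))
  expect_equal(unname(d3$values[1, 2]), d3$value)
  raw <- data_driven_design(g3$datasets, floor_value = FALSE)
  expect_equal(unname(raw$values[1, 2]), raw$raw_min, tolerance = 1e-12)
})

test_that("reduce_dataset keeps the union of per-component supports in order", {
  g <- planted_two_class(seed = 52, p = 15)
  fit <- fit_splsda(g$datasets$blk, g$labels, ncomp = 2, keep = c(3, 4))
  red <- reduce_dataset(g$datasets$blk, fit)
  sup <- union(support_of(fit, "blk", 1),
               setdiff(support_of(fit, "blk", 2), support_of(fit, "blk", 1)))
  expect_setequal(colnames(red$values), support_of(fit, "blk"))
  # original column order preserved
  expect_identical(colnames(red$values),
                   intersect(colnames(g$datasets$blk$values),
                             support_of(fit, "blk")))

  full <- fit_splsda(g$datasets$blk, g$labels, ncomp = 1, keep = 15)
  expect_identical(colnames(reduce_dataset(g$datasets$blk, full)$values),
                   colnames(g$datasets$blk$values))
})

test_that("the tuning stack is a pure function of data, parameters and seed", {
  g <- planted_two_class(seed = 53, p = 20)
  t1 <- tune_splsda(g$datasets$blk, g$labels, ncomp_max = 2,
                    grid = c(2, 5, 10), folds = 3, repeats = 2, seed = 99)
  t2 <- tune_splsda(g$datasets$blk, g$labels, ncomp_max = 2,
                    grid = c(2, 5, 10), folds = 3, repeats = 2, seed = 99)
  expect_identical(t1$criterion_surface, t2$criterion_surface)
  expect_identical(t1$selected_keep, t2$selected_keep)
})
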