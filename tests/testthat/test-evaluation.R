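test_that("negative sampling is exact, disjoint from positives, and seeded", {
  set.seed(2)
  assoc <- matrix(rbinom(200, 1, 0.2), 10, 20,
                  dimnames = list(paste0("c", 1:10), paste0("m", 1:20)))
  n_pos <- sum(assoc)
  negs <- negative_sample(assoc, 2, seed = 5)
  expect_equal(nrow(negs), round(2 * n_pos))
  expect_true(all(assoc[cbind(match(negs$circ_id, rownames(assoc)),
                              match(negs$mi_id, colnames(assoc)))] == 0))
  expect_false(any(duplicated(negs[, c("circ_id", "mi_id")])))
  negs2 <- negative_sample(assoc, 2, seed = 5)
  expect_identical(negs, negs2)
  expect_error(negative_sample(assoc, 100, seed = 1), "unobserved cells")
})

test_that("fold assignment is a stratified balanced partition", {
  labels <- rep(c(1L, 0L), c(100L, 103L))
  fold <- make_folds(labels, 5, seed = 3)
  expect_setequal(unique(fold), 1:5)
  for (cl in 0:1) {
    sizes <- table(fold[labels == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_error(make_folds(rep(c(0L, 1L), c(3L, 50L)), 5), "fewer members")
})

test_that("confusion counts enumerate exactly", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(cc, list(TP = 1L, FP = 1L, TN = 1L, FN = 1L),
               ignore_attr = TRUE)
  perfect <- confusion_counts(c(1, 0), c(1, 0))
  expect_equal(perfect$FP + perfect$FN, 0L)
  allwrong <- confusion_counts(c(0, 0), c(1, 1))
  expect_equal(allwrong$TP + allwrong$TN, 0L)
  expect_error(confusion_counts(1, c(1, 0)), "length")
})

test_that("threshold metrics match hand-derived values and brute force", {
  m <- classification_metrics(list(TP = 3, FP = 2, TN = 4, FN = 1))
  expect_equal(m[["Acc"]], 0.700, tolerance = 1e-3)
  expect_equal(m[["Sen"]], 0.750, tolerance = 1e-3)
  expect_equal(m[["Spe"]], 0.667, tolerance = 1e-3)
  expect_equal(m[["Pre"]], 0.600, tolerance = 1e-3)
  expect_equal(m[["MCC"]], 10 / sqrt(600), tolerance = 1e-12)

  sym <- classification_metrics(list(TP = 25, FP = 25, TN = 25, FN = 25))
  expect_equal(sym[["MCC"]], 0)
  expect_equal(sym[["Acc"]], 0.5)
  perfect <- classification_metrics(list(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_equal(unname(perfect), rep(1, 6), tolerance = 1e-12)

  set.seed(17)
  for (i in 1:50) {
    cts <- as.list(setNames(rpois(4, 6), c("TP", "FP", "TN", "FN")))
    if (sum(unlist(cts)) == 0) next
    got <- suppressWarnings(classification_metrics(cts))
    ref <- metrics_oracle(cts$TP, cts$FP, cts$TN, cts$FN)
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("undefined ratios surface as NA with a warning, never silent zero", {
  w <- capture_warnings(
    m <- classification_metrics(list(TP = 0, FP = 0, TN = 5, FN = 5)))
  expect_true(any(grepl("precision", w)))
  expect_true(any(grepl("MCC", w)))
  expect_true(is.na(m[["Pre"]]))
  expect_false(isTRUE(m[["Pre"]] == 0))
})

test_that("rank metrics match exhaustive enumeration and pROC", {
  rm1 <- rank_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1))
  expect_equal(rm1[["AUC"]], 0.75)
  expect_equal(rank_metrics(c(1, 0), c(1, 0))[["AUC"]], 1.0)
  expect_equal(rank_metrics(c(1, 0), c(1, 0))[["AUPR"]], 1.0)
  expect_equal(rank_metrics(c(1, 0, 1, 0), rep(0.5, 4))[["AUC"]], 0.5)

  set.seed(23)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
    got <- rank_metrics(labels, scores)
    expect_equal(got[["AUC"]], auc_oracle(labels, scores), tolerance = 1e-12)
    expect_equal(got[["AUPR"]], aupr_oracle(labels, scores), tolerance = 1e-12)
    expect_equal(got[["AUC"]],
                 as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-10)
  }
  expect_error(rank_metrics(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("leakage masking removes exactly the test-fold positive edges", {
  set.seed(9)
  assoc <- matrix(rbinom(60, 1, 0.4), 6, 10,
                  dimnames = list(paste0("c", 1:6), paste0("m", 1:10)))
  pos <- which(assoc == 1, arr.ind = TRUE)
  test_pairs <- data.frame(circ_id = c(rownames(assoc)[pos[1:3, 1]], "c1"),
                           mi_id = c(colnames(assoc)[pos[1:3, 2]], "m1"),
                           label = c(1L, 1L, 1L, 0L))
  masked <- mask_test_edges(assoc, test_pairs)
  expect_equal(sum(masked), sum(assoc) - 3)
  expect_true(all(masked[cbind(pos[1:3, 1], pos[1:3, 2])] == 0))
  # negatives in the test fold leave the matrix untouched
  untouched <- setdiff(which(assoc == 1), which(masked == 0))
  expect_true(all(assoc[untouched] == masked[untouched]))
})

test_that("cross-validation reports five folds whose summary equals recomputation", {
  ds <- generate_cmi_dataset(synthetic_config(n_circ = 50L, n_mi = 20L,
                                              circ_len_range = c(100L, 250L),
                                              target_density = 0.1),
                             seed = 6)
  cfg <- cmi_config(sg_epochs = 2L, sae_epochs = 3L, iterations = 150L,
                    leakage_safe = FALSE, patience = 75L)
  cv <- suppressWarnings(cross_validate(ds, cfg, seed = 4))
  expect_equal(nrow(cv$folds), 5L)
  expect_equal(cv$mean, colMeans(cv$folds[names(cv$mean)]), tolerance = 1e-12)
  expect_equal(cv$sd, apply(cv$folds[names(cv$sd)], 2, sd), tolerance = 1e-12)
  expect_setequal(unique(cv$fold_assignment), 1:5)
  expect_equal(length(cv$fold_assignment), nrow(cv$pairs))
  # every positive pair sits in exactly one test fold
  expect_equal(sum(cv$pairs$label), nrow(ds$pairs))
  expect_equal(sum(cv$attention_summary), 1, tolerance = 1e-9)
})
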