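#' Sample negative (non-interacting) pairs
#'
#' Uniformly samples `round(ratio * #positives)` distinct unobserved cells
#' (`A[i, j] == 0`) of the association matrix; the sample is always disjoint
#' from the positive set and reproducible for a fixed seed.
#'
#' @param assoc binary association matrix with id dimnames.
#' @param ratio negatives per positive.
#' @param seed RNG seed.
#' @return pair data.frame (`circ_id`, `mi_id`, `label = 0`) with provenance
#'   `"sampled-negative"`.
#' @export
negative_sample <- function(assoc, ratio = 1, seed = 1L) {
  stopifnot(ratio > 0)
  n_pos <- sum(assoc)
  n_neg <- round(ratio * n_pos)
  zero_cells <- which(assoc == 0)
  if (n_neg > length(zero_cells))
    stop("requested ", n_neg, " negatives but only ", length(zero_cells),
         " unobserved cells exist")
  set.seed(seed)
  cells <- sample(zero_cells, n_neg)
  i <- ((cells - 1L) %% nrow(assoc)) + 1L
  j <- ((cells - 1L) %/% nrow(assoc)) + 1L
  out <- data.frame(circ_id = rownames(assoc)[i], mi_id = colnames(assoc)[j],
                    label = 0L, stringsAsFactors = FALSE)
  attr(out, "provenance") <- "sampled-negative"
  out
}

#' Stratified cross-validation fold assignment
#'
#' Partitions pairs into `n_folds` test folds stratified by label; fold sizes
#' within each class differ by at most one.
#'
#' @param labels 0/1 vector, one per pair.
#' @param n_folds number of folds (>= 2).
#' @param seed RNG seed.
#' @return integer fold id (1..n_folds) per pair.
#' @export
make_folds <- function(labels, n_folds = 5L, seed = 1L) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < n_folds)
      stop("class ", cl, " has fewer members (", length(idx),
           ") than folds (", n_folds, ")")
    fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Confusion counts
#'
#' @param labels true 0/1 labels.
#' @param predicted predicted 0/1 labels.
#' @return named list `(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(labels, predicted) {
  if (length(labels) != length(predicted)) stop("length mismatch")
  list(TP = sum(labels == 1 & predicted == 1),
       FP = sum(labels == 0 & predicted == 1),
       TN = sum(labels == 0 & predicted == 0),
       FN = sum(labels == 1 & predicted == 0))
}

#' Threshold classification metrics
#'
#' Accuracy, sensitivity (recall), specificity, precision, F1 and the
#' Matthews correlation coefficient from confusion counts. Ratios with zero
#' denominators are reported as `NA` with a warning, never silently as zero.
#'
#' @param counts list from [confusion_counts()].
#' @return named numeric vector `(Acc, Sen, Spe, Pre, F1, MCC)`.
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0) stop("no evaluated pairs")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NA_real_)
    }
    num / den
  }
  acc <- (TP + TN) / total
  sen <- safe_div(TP, TP + FN, "sensitivity")
  spe <- safe_div(TN, TN + FP, "specificity")
  pre <- safe_div(TP, TP + FP, "precision")
  f1 <- if (is.na(pre) || is.na(sen) || (pre + sen) == 0) {
    warning("F1 undefined")
    NA_real_
  } else 2 * pre * sen / (pre + sen)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined (zero denominator)")
    NA_real_
  } else (TP * TN - FP * FN) / mcc_den
  c(Acc = acc, Sen = sen, Spe = spe, Pre = pre, F1 = f1, MCC = mcc)
}

#' Ranking metrics: AUC and AUPR
#'
#' AUC is the Mann-Whitney statistic (tied scores contribute 1/2); AUPR is the
#' area under the precision-recall curve with step interpolation over the
#' distinct score thresholds.
#'
#' @param labels true 0/1 labels.
#' @param scores numeric prediction scores.
#' @return named numeric vector `(AUC, AUPR)`.
#' @export
rank_metrics <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("length mismatch")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  aupr <- 0
  prev_recall <- 0
  for (t in thr) {
    called <- scores >= t
    tp <- sum(labels == 1 & called)
    precision <- tp / sum(called)
    recall <- tp / n_pos
    aupr <- aupr + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  c(AUC = auc, AUPR = aupr)
}

#' Remove test-fold positive edges from the association matrix
#'
#' Leakage control for fold-wise graph embedding: zeroes the cells of every
#' positive pair in `test_pairs` so the fold's structural embedding cannot
#' encode its own held-out answers.
#'
#' @param assoc binary association matrix with id dimnames.
#' @param test_pairs pair data.frame (`circ_id`, `mi_id`, `label`).
#' @return the masked association matrix.
#' @export
mask_test_edges <- function(assoc, test_pairs) {
  pos <- test_pairs[test_pairs$label == 1L, , drop = FALSE]
  if (nrow(pos)) {
    assoc[cbind(match(pos$circ_id, rownames(assoc)),
                match(pos$mi_id, colnames(assoc)))] <- 0L
  }
  assoc
}

#' Fivefold cross-validation of the full pipeline
#'
#' Runs sequence embedding, stacked-autoencoder compression, per-fold graph
#' embedding, attention fusion and MLP training end to end, and reports the
#' eight-metric suite per fold with mean and standard deviation rows.
#'
#' Sequence embeddings and the two autoencoders never see interaction labels,
#' so they are fitted once per dataset; the graph embedding is rebuilt for
#' every fold. With `leakage_safe = TRUE` (default) each fold's graph drops
#' that fold's test positives before embedding, so structural features cannot
#' encode the held-out answers; `leakage_safe = FALSE` reproduces the common
#' published protocol of embedding the full association matrix once.
#'
#' @param dataset a `cmi_dataset` (or any list with `circ`, `mi`, `pairs`).
#' @param config a [cmi_config()].
#' @param seed master RNG seed for sampling, folds and training.
#' @param negatives optional pre-sampled negative pair table; sampled at
#'   `config$negative_ratio` when `NULL`.
#' @param permute_labels if `TRUE`, permute the label vector after feature
#'   construction (a permutation null: expected AUC ~ 0.5).
#' @return list of class `cv_report` with `folds` (per-fold metric rows),
#'   `mean`, `sd`, `fold_assignment`, `pairs`, `attention_summary` (mean
#'   stage-2 block weights of the last fold's model on its test pairs),
#'   `config` and `seed`.
#' @export
cross_validate <- function(dataset, config = cmi_config(), seed = 1L,
                           negatives = NULL, permute_labels = FALSE) {
  assoc <- build_association_matrix(dataset$circ, dataset$mi, dataset$pairs)
  if (is.null(negatives))
    negatives <- negative_sample(assoc, config$negative_ratio, seed = seed + 1L)
  pos <- dataset$pairs[, c("circ_id", "mi_id")]
  pos$label <- 1L
  all_pairs <- rbind(pos, negatives[, c("circ_id", "mi_id", "label")])
  rownames(all_pairs) <- NULL

  fold <- make_folds(all_pairs$label, config$n_folds, seed = seed + 2L)
  labels <- all_pairs$label
  if (permute_labels) {
    set.seed(seed + 3L)
    labels <- sample(labels)
  }

  feats <- prepare_molecule_features(dataset, config, seed = seed)

  fold_rows <- vector("list", config$n_folds)
  last_attention <- NULL
  for (f in seq_len(config$n_folds)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    assoc_fold <- if (config$leakage_safe) {
      mask_test_edges(assoc, all_pairs[test_idx, , drop = FALSE])
    } else {
      assoc
    }
    if (sum(assoc_fold) == 0) stop("fold ", f, ": no training edges left")
    struct <- grarep(assoc_fold, K = config$K, d_k = config$d_k,
                     lambda_neg = config$lambda_neg)
    pair_feats <- function(idx) {
      pr <- all_pairs[idx, ]
      list(circ_code = feats$circ_codes[pr$circ_id, , drop = FALSE],
           mi_code = feats$mi_codes[pr$mi_id, , drop = FALSE],
           circ_struct = struct$circ[pr$circ_id, , drop = FALSE],
           mi_struct = struct$mi[pr$mi_id, , drop = FALSE])
    }
    model <- model_fit(pair_feats(train_idx), labels[train_idx],
                       hidden = config$hidden, l2 = config$l2,
                       iterations = config$iterations,
                       batch_size = config$batch_size, lr = config$lr,
                       val_frac = config$val_frac,
                       early_stopping = config$early_stopping,
                       patience = config$patience,
                       eval_every = config$eval_every,
                       fusion_mode = config$fusion_mode,
                       static_ratio = config$static_ratio,
                       seed = seed + 10L + f)
    test_f <- pair_feats(test_idx)
    scores <- predict_scores(model, test_f)
    cm <- classification_metrics(confusion_counts(labels[test_idx],
                                                  predict_labels(scores)))
    rk <- rank_metrics(labels[test_idx], scores)
    fold_rows[[f]] <- c(Fold = f, cm, rk)
    if (f == config$n_folds) {
      fw <- cmi_forward(model$pars, test_f, model$stats, model$fusion_mode,
                        model$static_ratio)
      last_attention <- mean_attention_by_block(fw$fused)
    }
  }
  folds_df <- as.data.frame(do.call(rbind, fold_rows))
  metric_cols <- setdiff(names(folds_df), "Fold")
  structure(list(folds = folds_df,
                 mean = colMeans(folds_df[metric_cols]),
                 sd = apply(folds_df[metric_cols], 2L, sd),
                 fold_assignment = fold, pairs = all_pairs, labels = labels,
                 attention_summary = last_attention,
                 config = config, seed = as.integer(seed)),
            class = "cv_report")
}

#' Class-imbalance evaluation harness
#'
#' Re-samples negatives at each requested negative:positive ratio and runs the
#' full cross-validation per ratio, emitting one row per ratio with all eight
#' metrics.
#'
#' @param dataset a `cmi_dataset`.
#' @param ratios numeric vector of negative:positive ratios (>= 1).
#' @param config a [cmi_config()].
#' @param seed RNG seed.
#' @return data.frame with columns `Ratio`, `Negatives`, and the mean metric
#'   per ratio; per-ratio `cv_report`s attached as attribute `"reports"`.
#' @export
imbalance_experiment <- function(dataset, ratios = 1:5, config = cmi_config(),
                                 seed = 1L) {
  stopifnot(all(ratios >= 1))
  assoc <- build_association_matrix(dataset$circ, dataset$mi, dataset$pairs)
  reports <- vector("list", length(ratios))
  rows <- vector("list", length(ratios))
  for (i in seq_along(ratios)) {
    cfg <- config
    cfg$negative_ratio <- ratios[i]
    negs <- negative_sample(assoc, ratios[i], seed = seed + 100L * i)
    rep_i <- cross_validate(dataset, cfg, seed = seed, negatives = negs)
    reports[[i]] <- rep_i
    rows[[i]] <- c(Ratio = ratios[i], Negatives = nrow(negs), rep_i$mean)
  }
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "reports") <- reports
  out
}
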