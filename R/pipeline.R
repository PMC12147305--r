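#' Pipeline configuration
#'
#' All tunables of the pipeline in one place. Defaults follow the method's
#' published settings where stated (sequence-code and structural dimensions of
#' 64; SAE funnel 256/128/64, 20 epochs, learning rate 1e-3, batch 128; MLP
#' hidden width 100, L2 1e-4, 5000 iterations; pooling cap P = 64) and
#' field-standard choices where the method leaves them open (k-mer length 3,
#' skip-gram window 5 with 5 negative samples, GraRep K = 4 orders of rank 16,
#' lambda = 1).
#'
#' @param k k-mer length.
#' @param dim sequence embedding dimension D.
#' @param window skip-gram context radius c.
#' @param k_neg skip-gram negative samples.
#' @param sg_epochs skip-gram epochs.
#' @param P pooling cap: tokens pooled per sequence.
#' @param sae_sizes stacked-autoencoder layer widths.
#' @param sae_epochs,sae_lr,sae_batch,sae_patience SAE training settings.
#' @param K,d_k,lambda_neg GraRep order count, per-order rank, shift lambda.
#' @param hidden,l2,iterations,batch_size,lr classifier settings.
#' @param early_stopping,patience,eval_every classifier early stopping.
#' @param val_frac validation fraction of the training pool.
#' @param n_folds cross-validation folds.
#' @param negative_ratio negatives per positive.
#' @param leakage_safe drop each fold's test positives from the embedding
#'   graph (`TRUE`, default) or embed the full matrix once (`FALSE`, the
#'   common published protocol).
#' @param fusion_mode `"attention"` or `"static"`.
#' @param static_ratio block ratio for static fusion.
#' @return list of class `cmi_config`.
#' @export
cmi_config <- function(k = 3L, dim = 64L, window = 5L, k_neg = 5L,
                       sg_epochs = 5L, P = 64L,
                       sae_sizes = c(256L, 128L, 64L), sae_epochs = 20L,
                       sae_lr = 1e-3, sae_batch = 128L, sae_patience = 3L,
                       K = 4L, d_k = 16L, lambda_neg = 1,
                       hidden = 100L, l2 = 1e-4, iterations = 5000L,
                       batch_size = 128L, lr = 1e-3, early_stopping = TRUE,
                       patience = 200L, eval_every = 25L, val_frac = 1 / 8,
                       n_folds = 5L, negative_ratio = 1,
                       leakage_safe = TRUE,
                       fusion_mode = c("attention", "static"),
                       static_ratio = c(1, 1, 1)) {
  fusion_mode <- match.arg(fusion_mode)
  cfg <- as.list(environment())
  structure(cfg, class = "cmi_config")
}

#' Label-free molecule features: sequence codes for every molecule
#'
#' Trains the shared k-mer skip-gram space over the union of circRNA and
#' miRNA sequences, pools token vectors per molecule, and compresses each
#' class's pooled embeddings with its own stacked autoencoder. None of these
#' steps sees interaction labels.
#'
#' @param dataset a `cmi_dataset` (elements `circ`, `mi`).
#' @param config a [cmi_config()].
#' @param seed RNG seed.
#' @return list with `circ_codes`, `mi_codes` (molecule x bottleneck
#'   matrices, rownames = ids), the `embedding` table and the two `sae`
#'   models.
#' @export
prepare_molecule_features <- function(dataset, config = cmi_config(),
                                      seed = 1L) {
  corpus <- rbind(dataset$circ[, c("id", "sequence")],
                  dataset$mi[, c("id", "sequence")])
  emb <- train_token_embeddings(corpus, k = config$k, dim = config$dim,
                                window = config$window, k_neg = config$k_neg,
                                epochs = config$sg_epochs, seed = seed)
  circ_emb <- embed_sequences(dataset$circ, emb, P = config$P)
  mi_emb <- embed_sequences(dataset$mi, emb, P = config$P)
  sae_circ <- sae_fit(circ_emb, layer_sizes = config$sae_sizes,
                      epochs = config$sae_epochs, lr = config$sae_lr,
                      batch_size = config$sae_batch,
                      patience = config$sae_patience, seed = seed + 1L)
  sae_mi <- sae_fit(mi_emb, layer_sizes = config$sae_sizes,
                    epochs = config$sae_epochs, lr = config$sae_lr,
                    batch_size = config$sae_batch,
                    patience = config$sae_patience, seed = seed + 2L)
  circ_codes <- sae_encode(sae_circ, circ_emb)
  mi_codes <- sae_encode(sae_mi, mi_emb)
  rownames(circ_codes) <- dataset$circ$id
  rownames(mi_codes) <- dataset$mi$id
  list(circ_codes = circ_codes, mi_codes = mi_codes, embedding = emb,
       sae = list(circ = sae_circ, mi = sae_mi))
}

#' Train a single model on all provided pairs
#'
#' Convenience wrapper for training one deployable model outside
#' cross-validation: samples negatives, embeds the full graph, builds pair
#' features and fits the classifier.
#'
#' @param dataset a `cmi_dataset`.
#' @param config a [cmi_config()].
#' @param seed RNG seed.
#' @return list of class `cmi_trained_pipeline` with the classifier
#'   (`model`), `molecule_features`, `struct` embedding and `config`.
#' @export
train_pipeline <- function(dataset, config = cmi_config(), seed = 1L) {
  assoc <- build_association_matrix(dataset$circ, dataset$mi, dataset$pairs)
  negatives <- negative_sample(assoc, config$negative_ratio, seed = seed + 1L)
  pos <- dataset$pairs[, c("circ_id", "mi_id")]
  pos$label <- 1L
  all_pairs <- rbind(pos, negatives[, c("circ_id", "mi_id", "label")])
  feats <- prepare_molecule_features(dataset, config, seed = seed)
  struct <- grarep(assoc, K = config$K, d_k = config$d_k,
                   lambda_neg = config$lambda_neg)
  pair_features <- list(
    circ_code = feats$circ_codes[all_pairs$circ_id, , drop = FALSE],
    mi_code = feats$mi_codes[all_pairs$mi_id, , drop = FALSE],
    circ_struct = struct$circ[all_pairs$circ_id, , drop = FALSE],
    mi_struct = struct$mi[all_pairs$mi_id, , drop = FALSE])
  model <- model_fit(pair_features, all_pairs$label, hidden = config$hidden,
                     l2 = config$l2, iterations = config$iterations,
                     batch_size = config$batch_size, lr = config$lr,
                     val_frac = config$val_frac,
                     early_stopping = config$early_stopping,
                     patience = config$patience, eval_every = config$eval_every,
                     fusion_mode = config$fusion_mode,
                     static_ratio = config$static_ratio, seed = seed + 5L)
  structure(list(model = model, molecule_features = feats, struct = struct,
                 config = config, seed = as.integer(seed)),
            class = "cmi_trained_pipeline")
}

#' Score candidate pairs with a trained pipeline
#'
#' Pairs whose ids are unknown to the trained pipeline are skipped with a
#' warning listing them.
#'
#' @param pipeline a `cmi_trained_pipeline`.
#' @param pairs data.frame with `circ_id`, `mi_id`.
#' @return data.frame (`circ_id`, `mi_id`, `score`) sorted by descending
#'   score.
#' @export
score_pairs <- function(pipeline, pairs) {
  stopifnot(inherits(pipeline, "cmi_trained_pipeline"))
  feats <- pipeline$molecule_features
  known <- pairs$circ_id %in% rownames(feats$circ_codes) &
    pairs$mi_id %in% rownames(feats$mi_codes)
  if (any(!known)) {
    bad <- pairs[!known, ]
    warning("skipping ", sum(!known), " pair(s) with unknown id(s): ",
            paste(head(paste(bad$circ_id, bad$mi_id, sep = "/"), 5L),
                  collapse = ", "))
    pairs <- pairs[known, , drop = FALSE]
  }
  if (nrow(pairs) == 0L)
    return(data.frame(circ_id = character(0), mi_id = character(0),
                      score = numeric(0)))
  pf <- list(circ_code = feats$circ_codes[pairs$circ_id, , drop = FALSE],
             mi_code = feats$mi_codes[pairs$mi_id, , drop = FALSE],
             circ_struct = pipeline$struct$circ[pairs$circ_id, , drop = FALSE],
             mi_struct = pipeline$struct$mi[pairs$mi_id, , drop = FALSE])
  out <- data.frame(circ_id = pairs$circ_id, mi_id = pairs$mi_id,
                    score = predict_scores(pipeline$model, pf),
                    stringsAsFactors = FALSE)
  out[order(-out$score), , drop = FALSE]
}
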