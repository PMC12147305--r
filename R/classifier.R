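# Forward pass shared by training and prediction. Returns score plus every
# intermediate needed for the backward pass.
cmi_forward <- function(pars, feats, stats, mode = "attention",
                        static_ratio = c(1, 1, 1)) {
  fused <- fuse_pairs(feats$circ_code, feats$mi_code,
                      feats$circ_struct, feats$mi_struct,
                      list(circ1 = list(W = pars$W1c, b = pars$b1c),
                           mi1 = list(W = pars$W1m, b = pars$b1m),
                           circ2 = list(W = pars$W2c, b = pars$b2c),
                           mi2 = list(W = pars$W2m, b = pars$b2m)),
                      mode = mode, static_ratio = static_ratio)
  Ns <- sweep(sweep(fused$N, 2L, stats$mean), 2L, stats$sd, "/")
  preh <- Ns %*% pars$Wh + rep(pars$bh, each = nrow(Ns))
  Hh <- pmax(preh, 0)
  logits <- drop(Hh %*% pars$wo) + pars$bo
  list(fused = fused, Ns = Ns, preh = preh, Hh = Hh, logits = logits,
       p = sigmoid(logits))
}

# Backward through one Hadamard-softmax attention stage.
# G: gradient wrt (X * A); X: stage input; A: stage weights.
# Returns gradients for W, b and the stage input X.
attention_backward <- function(G, X, A, W) {
  dA <- G * X
  dZ <- A * (dA - rowSums(dA * A))
  list(dW = crossprod(X, dZ), db = colSums(dZ),
       dX = dZ %*% t(W) + G * A)
}

#' Train the attention-fusion MLP link classifier
#'
#' Jointly optimizes the four attention stages and a one-hidden-layer MLP
#' (100 ReLU units, sigmoid output) by minimizing binary cross-entropy plus an
#' L2 penalty (1e-4) on every weight matrix, with Adam. "Iterations" are
#' optimizer steps on mini-batches of `batch_size` pairs (set
#' `batch_size = Inf` for full-batch steps). Feature standardization
#' statistics are fitted once on the training pairs (fused with the freshly
#' initialized stages) and kept frozen, so train/validation/test pairs share
#' one affine map.
#'
#' Optional early stopping monitors the binary cross-entropy on a held-out
#' validation slice and restores the best parameters.
#'
#' @param features list with matrices `circ_code`, `mi_code` (pair x d_code)
#'   and `circ_struct`, `mi_struct` (pair x H), one row per pair.
#' @param labels 0/1 vector, one per pair.
#' @param hidden hidden-layer width.
#' @param l2 L2 regularization coefficient.
#' @param iterations maximum optimizer steps.
#' @param batch_size mini-batch size (pairs per step).
#' @param lr Adam learning rate.
#' @param val_frac fraction of pairs held out for early stopping (ignored if
#'   `val_idx` given).
#' @param val_idx optional explicit validation row indices.
#' @param early_stopping monitor validation loss and restore best weights.
#' @param patience iterations without validation improvement before stopping.
#' @param eval_every validation-loss evaluation period, in iterations.
#' @param fusion_mode `"attention"` or `"static"` (fixed-ratio baseline).
#' @param static_ratio block ratio for static fusion.
#' @param seed RNG seed.
#' @return list of class `cmi_model`: parameters, standardization stats,
#'   fusion settings, and `run` (loss trace, final loss, elapsed seconds,
#'   seed).
#' @export
model_fit <- function(features, labels, hidden = 100L, l2 = 1e-4,
                      iterations = 5000L, batch_size = 128L, lr = 1e-3,
                      val_frac = 1 / 8, val_idx = NULL, early_stopping = TRUE,
                      patience = 200L, eval_every = 25L,
                      fusion_mode = c("attention", "static"),
                      static_ratio = c(1, 1, 1), seed = 1L) {
  fusion_mode <- match.arg(fusion_mode)
  labels <- as.numeric(labels)
  n <- length(labels)
  stopifnot(nrow(features$circ_code) == n)
  if (length(unique(labels)) < 2L) stop("need both classes to train")
  if (any(!is.finite(features$circ_code)) || any(!is.finite(features$mi_code)) ||
      any(!is.finite(features$circ_struct)) || any(!is.finite(features$mi_struct)))
    stop("non-finite feature values")
  t0 <- proc.time()[["elapsed"]]
  set.seed(seed)
  d_code <- ncol(features$circ_code)
  H <- ncol(features$circ_struct)
  d_out <- 2L * (d_code + H)

  st <- init_attention_stages(d_code, H, seed = seed)
  pars <- list(W1c = st$circ1$W, b1c = st$circ1$b,
               W1m = st$mi1$W, b1m = st$mi1$b,
               W2c = st$circ2$W, b2c = st$circ2$b,
               W2m = st$mi2$W, b2m = st$mi2$b,
               Wh = glorot_uniform(d_out, hidden), bh = rep(0, hidden),
               wo = drop(glorot_uniform(hidden, 1L)), bo = 0)
  weight_names <- c("W1c", "W1m", "W2c", "W2m", "Wh", "wo")
  attn_names <- c("W1c", "b1c", "W1m", "b1m", "W2c", "b2c", "W2m", "b2m")

  # Frozen standardization stats from the initialized fusion of training pairs.
  init_fused <- fuse_pairs(features$circ_code, features$mi_code,
                           features$circ_struct, features$mi_struct, st,
                           mode = fusion_mode, static_ratio = static_ratio)
  stats <- standardize_features(init_fused$N)$stats

  if (early_stopping && is.null(val_idx)) {
    n_val <- max(2L, round(val_frac * n))
    repeat {
      val_idx <- sample.int(n, n_val)
      if (length(unique(labels[val_idx])) == 2L) break
    }
  }
  train_idx <- if (is.null(val_idx)) seq_len(n) else setdiff(seq_len(n), val_idx)
  sub <- function(idx) list(circ_code = features$circ_code[idx, , drop = FALSE],
                            mi_code = features$mi_code[idx, , drop = FALSE],
                            circ_struct = features$circ_struct[idx, , drop = FALSE],
                            mi_struct = features$mi_struct[idx, , drop = FALSE])
  ftr <- sub(train_idx)
  ytr <- labels[train_idx]
  fval <- if (length(val_idx)) sub(val_idx) else NULL
  yval <- labels[val_idx]

  bce <- function(p, y) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }

  states <- setNames(vector("list", length(pars)), names(pars))
  loss_trace <- numeric(0)
  best <- list(loss = Inf, pars = pars, iter = 0L)
  stall <- 0L
  n_tr <- length(ytr)
  bsz <- min(batch_size, n_tr)

  for (it in seq_len(iterations)) {
    idx <- if (bsz >= n_tr) seq_len(n_tr) else sample.int(n_tr, bsz)
    fb <- sub_features_rows(ftr, idx)
    y <- ytr[idx]
    m <- length(y)
    fw <- cmi_forward(pars, fb, stats, fusion_mode, static_ratio)
    loss <- bce(fw$p, y) +
      l2 * sum(vapply(weight_names, function(nm) sum(pars[[nm]]^2), numeric(1)))
    loss_trace <- c(loss_trace, loss)

    dlogit <- (fw$p - y) / m
    grads <- list()
    grads$wo <- drop(crossprod(fw$Hh, dlogit)) + 2 * l2 * pars$wo
    grads$bo <- sum(dlogit)
    dHh <- outer(dlogit, pars$wo)
    dpreh <- dHh * (fw$preh > 0)
    grads$Wh <- crossprod(fw$Ns, dpreh) + 2 * l2 * pars$Wh
    grads$bh <- colSums(dpreh)
    dNs <- dpreh %*% t(pars$Wh)
    dN <- sweep(dNs, 2L, stats$sd, "/")

    if (fusion_mode == "attention") {
      dcH <- ncol(fw$fused$Cc)
      g2c <- attention_backward(dN[, seq_len(dcH), drop = FALSE],
                                fw$fused$Cc, fw$fused$A2c, pars$W2c)
      g2m <- attention_backward(dN[, dcH + seq_len(dcH), drop = FALSE],
                                fw$fused$Cm, fw$fused$A2m, pars$W2m)
      grads$W2c <- g2c$dW + 2 * l2 * pars$W2c
      grads$b2c <- g2c$db
      grads$W2m <- g2m$dW + 2 * l2 * pars$W2m
      grads$b2m <- g2m$db
      g1c <- attention_backward(g2c$dX[, seq_len(d_code), drop = FALSE],
                                fb$circ_code, fw$fused$A1c, pars$W1c)
      g1m <- attention_backward(g2m$dX[, seq_len(d_code), drop = FALSE],
                                fb$mi_code, fw$fused$A1m, pars$W1m)
      grads$W1c <- g1c$dW + 2 * l2 * pars$W1c
      grads$b1c <- g1c$db
      grads$W1m <- g1m$dW + 2 * l2 * pars$W1m
      grads$b1m <- g1m$db
    }

    upd_names <- if (fusion_mode == "attention") names(grads) else
      setdiff(names(grads), attn_names)
    upd <- adam_step_all(pars[upd_names], grads[upd_names], states[upd_names], lr)
    pars[upd_names] <- upd$pars
    states[upd_names] <- upd$states

    if (early_stopping && !is.null(fval) && it %% eval_every == 0L) {
      vp <- cmi_forward(pars, fval, stats, fusion_mode, static_ratio)$p
      vloss <- bce(vp, yval)
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, pars = pars, iter = it)
        stall <- 0L
      } else {
        stall <- stall + eval_every
        if (stall >= patience) break
      }
    }
  }
  if (early_stopping && !is.null(fval) && is.finite(best$loss)) pars <- best$pars

  structure(list(pars = pars, stats = stats, d_code = d_code, H = H,
                 hidden = as.integer(hidden), l2 = l2,
                 fusion_mode = fusion_mode, static_ratio = static_ratio,
                 run = list(loss_trace = loss_trace,
                            final_loss = loss_trace[length(loss_trace)],
                            iterations_run = length(loss_trace),
                            best_val_loss = if (is.finite(best$loss)) best$loss else NA_real_,
                            seconds = proc.time()[["elapsed"]] - t0,
                            seed = as.integer(seed))),
            class = "cmi_model")
}

sub_features_rows <- function(features, idx) {
  list(circ_code = features$circ_code[idx, , drop = FALSE],
       mi_code = features$mi_code[idx, , drop = FALSE],
       circ_struct = features$circ_struct[idx, , drop = FALSE],
       mi_struct = features$mi_struct[idx, , drop = FALSE])
}

#' Predict interaction scores
#'
#' Deterministic forward pass of a trained model; every score lies in (0, 1).
#'
#' @param model a trained `cmi_model`.
#' @param features feature list as in [model_fit()].
#' @return numeric score vector, one per pair.
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "cmi_model"))
  if (ncol(features$circ_code) != model$d_code ||
      ncol(features$circ_struct) != model$H)
    stop("feature dimensions do not match the trained model")
  cmi_forward(model$pars, features, model$stats, model$fusion_mode,
              model$static_ratio)$p
}

#' Threshold scores into hard labels
#'
#' @param scores numeric vector in `[0, 1]`.
#' @param threshold decision threshold; a pair is called positive when
#'   `score >= threshold`.
#' @return integer 0/1 vector.
#' @export
predict_labels <- function(scores, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  as.integer(scores >= threshold)
}
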