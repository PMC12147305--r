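# Independent reference implementations used as oracles. These deliberately
# re-derive each quantity with explicit loops / dense algebra, separately from
# the package code paths they check.

# Dense step-by-step GraRep reference: explicit block adjacency, explicit
# matrix powers, explicit column sums, explicit log/shift/clamp, full SVD then
# truncation with the largest-|u| sign convention.
grarep_oracle <- function(assoc, K, d_k, lambda_neg = 1) {
  n_c <- nrow(assoc)
  n_m <- ncol(assoc)
  n <- n_c + n_m
  S <- matrix(0, n, n)
  for (i in seq_len(n_c)) for (j in seq_len(n_m)) {
    S[i, n_c + j] <- assoc[i, j]
    S[n_c + j, i] <- assoc[i, j]
  }
  E <- sum(assoc)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    deg <- sum(S[i, ])
    if (deg > 0) A[i, ] <- S[i, ] / deg
  }
  blocks <- list()
  for (k in seq_len(K)) {
    Ak <- diag(n)
    for (s in seq_len(k)) Ak <- Ak %*% A
    X <- matrix(0, n, n)
    for (j in seq_len(n)) {
      gamma_j <- sum(Ak[, j])
      for (i in seq_len(n)) {
        if (Ak[i, j] > 0 && gamma_j > 0) {
          y <- log(Ak[i, j] / gamma_j) - log(lambda_neg / E)
          X[i, j] <- max(y, 0)
        }
      }
    }
    sv <- svd(X)
    dk <- min(d_k, n)
    U <- sv$u[, seq_len(dk), drop = FALSE]
    V <- sv$v[, seq_len(dk), drop = FALSE]
    for (j in seq_len(dk)) {
      piv <- which.max(abs(U[, j]))
      if (U[piv, j] < 0) {
        U[, j] <- -U[, j]
        V[, j] <- -V[, j]
      }
    }
    blocks[[k]] <- U %*% diag(sqrt(sv$d[seq_len(dk)]), dk)
  }
  do.call(cbind, blocks)
}

# Align column signs of b to a (handles residual sign flips from nearly tied
# singular values) before comparing embeddings.
align_signs <- function(a, b) {
  for (j in seq_len(ncol(b))) {
    if (sum(a[, j] * b[, j]) < 0) b[, j] <- -b[, j]
  }
  b
}

# Brute-force confusion-count metrics with plain integer arithmetic.
metrics_oracle <- function(TP, FP, TN, FN) {
  tot <- TP + FP + TN + FN
  acc <- (TP + TN) / tot
  sen <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spe <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  pre <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  f1 <- if (!is.na(pre) && !is.na(sen) && pre + sen > 0)
    2 * pre * sen / (pre + sen) else NA_real_
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den > 0) (TP * TN - FP * FN) / sqrt(den) else NA_real_
  c(Acc = acc, Sen = sen, Spe = spe, Pre = pre, F1 = f1, MCC = mcc)
}

# Exhaustive pairwise AUC: loop over every (positive, negative) score pair.
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Step-curve AUPR by explicit threshold enumeration.
aupr_oracle <- function(labels, scores) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  area <- 0
  r_prev <- 0
  for (t in ths) {
    tp <- 0
    fp <- 0
    for (i in seq_along(scores)) {
      if (scores[i] >= t) {
        if (labels[i] == 1) tp <- tp + 1 else fp <- fp + 1
      }
    }
    prec <- tp / (tp + fp)
    rec <- tp / n_pos
    area <- area + (rec - r_prev) * prec
    r_prev <- rec
  }
  area
}

# Full-gradient ascent on the exact expected skip-gram negative-sampling
# objective (expectation over the noise distribution taken analytically) for
# a tiny corpus; independent of the stochastic C++ trainer.
sgns_expected_oracle <- function(pair_counts, token_counts, dim = 8L,
                                 k_neg = 2L, steps = 2000L, lr = 0.1,
                                 seed = 42L) {
  set.seed(seed)
  V <- length(token_counts)
  noise <- token_counts^0.75
  noise <- noise / sum(noise)
  vin <- matrix(rnorm(V * dim, sd = 0.1), V, dim)
  vout <- matrix(rnorm(V * dim, sd = 0.1), V, dim)
  sig <- function(x) 1 / (1 + exp(-x))
  for (s in seq_len(steps)) {
    gin <- vin * 0
    gout <- vout * 0
    for (c_tok in seq_len(V)) for (o_tok in seq_len(V)) {
      w <- pair_counts[c_tok, o_tok]
      if (w == 0) next
      dot <- sum(vin[c_tok, ] * vout[o_tok, ])
      g <- w * (1 - sig(dot))
      gin[c_tok, ] <- gin[c_tok, ] + g * vout[o_tok, ]
      gout[o_tok, ] <- gout[o_tok, ] + g * vin[c_tok, ]
      for (n_tok in seq_len(V)) {
        gneg <- -w * k_neg * noise[n_tok] * sig(sum(vin[c_tok, ] * vout[n_tok, ]))
        gin[c_tok, ] <- gin[c_tok, ] + gneg * vout[n_tok, ]
        gout[n_tok, ] <- gout[n_tok, ] + gneg * vin[c_tok, ]
      }
    }
    vin <- vin + lr * gin / sum(pair_counts)
    vout <- vout + lr * gout / sum(pair_counts)
  }
  list(input = vin, output = vout)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Small deterministic record data.frame for ingestion tests.
make_records <- function(seqs, class = "circRNA", prefix = "x") {
  data.frame(id = paste0(prefix, seq_along(seqs)), molecule_class = class,
             sequence = seqs, stringsAsFactors = FALSE)
}

# Random small feature set for classifier tests: labels depend only on the
# circ code's first coordinate unless `noise = TRUE`.
make_toy_features <- function(n, d_code = 4L, H = 2L, noise = FALSE,
                              seed = 1L) {
  set.seed(seed)
  f <- list(circ_code = matrix(rnorm(n * d_code), n),
            mi_code = matrix(rnorm(n * d_code), n),
            circ_struct = matrix(rnorm(n * H), n),
            mi_struct = matrix(rnorm(n * H), n))
  y <- if (noise) sample(0:1, n, replace = TRUE) else
    as.integer(f$circ_code[, 1] + 0.3 * f$mi_code[, 1] > 0)
  list(features = f, labels = y)
}
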