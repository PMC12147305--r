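#' Initialize the four attention stages
#'
#' One stage per (modality x level): circRNA sequence and miRNA sequence at
#' stage 1, and the two sequence+structure concatenations at stage 2. Each
#' stage is an affine map to per-feature logits followed by a row-wise softmax.
#' Stage parameters for the circ and mi branches are separate.
#'
#' @param d_code sequence-code dimension (stage-1 input width).
#' @param H structural embedding dimension; stage-2 width is `d_code + H`.
#' @param seed RNG seed for Glorot initialization.
#' @return named list of `attention_stage` lists (`W`, `b`) with names
#'   `circ1`, `mi1`, `circ2`, `mi2`.
#' @export
init_attention_stages <- function(d_code, H, seed = 1L) {
  set.seed(seed)
  mk <- function(d) list(W = glorot_uniform(d, d), b = rep(0, d))
  list(circ1 = mk(d_code), mi1 = mk(d_code),
       circ2 = mk(d_code + H), mi2 = mk(d_code + H))
}

#' Per-sample attention weights
#'
#' `weights = softmax(X W + b)` applied across feature positions within each
#' sample: every row is strictly positive and sums to 1.
#'
#' @param X sample x d matrix.
#' @param stage an attention stage (`W`: d x d, `b`: length d).
#' @return sample x d weight matrix.
#' @export
attention_weights <- function(X, stage) {
  if (any(!is.finite(X))) stop("non-finite values in X")
  if (ncol(X) != nrow(stage$W)) stop("shape mismatch: X has ", ncol(X),
                                     " features, stage expects ", nrow(stage$W))
  softmax_rows(X %*% stage$W + rep(stage$b, each = nrow(X)))
}

#' Re-scale features by attention weights
#'
#' Hadamard product of the feature matrix and its weight matrix.
#'
#' @param X feature matrix.
#' @param weights weight matrix of identical shape.
#' @return `X * weights` elementwise.
#' @export
apply_attention <- function(X, weights) {
  if (!all(dim(X) == dim(weights))) stop("shape mismatch between X and weights")
  X * weights
}

# Fixed stage-2 weight row for static-ratio fusion: block totals proportional
# to (r_seq, r_struct), uniform within each block, summing to 1.
static_stage2_row <- function(d_code, H, r_seq, r_struct) {
  tot <- r_seq + r_struct
  c(rep(r_seq / tot / d_code, d_code), rep(r_struct / tot / H, H))
}

#' Fuse per-pair sequence codes and structural embeddings
#'
#' Two-stage weighted attention: stage 1 re-weights each molecule's sequence
#' code; the attended code is concatenated with the molecule's structural
#' embedding; stage 2 re-weights each concatenation; the two attended
#' concatenations are joined into the final per-pair vector of dimension
#' `2 * (d_code + H)`.
#'
#' In `mode = "static"` the learned attention is replaced by fixed block
#' ratios `static_ratio = c(circ_seq, mi_seq, struct)` (the classical
#' fixed-proportion fusion baseline): stage-1 weights are uniform and stage-2
#' block totals follow the given ratio.
#'
#' @param circ_code,mi_code sample x d_code matrices of sequence codes (one
#'   row per pair).
#' @param circ_struct,mi_struct sample x H matrices of structural embeddings.
#' @param stages list from [init_attention_stages()] (or trained ones).
#' @param mode `"attention"` (default) or `"static"`.
#' @param static_ratio length-3 positive vector used when `mode = "static"`.
#' @return list with `N` (sample x 2(d_code+H) fused matrix) and the
#'   intermediates (`A1c`, `A1m`, `Cc`, `Cm`, `A2c`, `A2m`) needed for
#'   training and attention summaries.
#' @export
fuse_pairs <- function(circ_code, mi_code, circ_struct, mi_struct, stages,
                       mode = c("attention", "static"),
                       static_ratio = c(1, 1, 1)) {
  mode <- match.arg(mode)
  stopifnot(nrow(circ_code) == nrow(mi_code),
            nrow(circ_code) == nrow(circ_struct),
            nrow(circ_code) == nrow(mi_struct))
  n <- nrow(circ_code)
  d_code <- ncol(circ_code)
  H <- ncol(circ_struct)
  if (mode == "attention") {
    A1c <- attention_weights(circ_code, stages$circ1)
    A1m <- attention_weights(mi_code, stages$mi1)
  } else {
    A1c <- matrix(1 / d_code, n, d_code)
    A1m <- matrix(1 / d_code, n, d_code)
  }
  Cc <- cbind(apply_attention(circ_code, A1c), circ_struct)
  Cm <- cbind(apply_attention(mi_code, A1m), mi_struct)
  if (mode == "attention") {
    A2c <- attention_weights(Cc, stages$circ2)
    A2m <- attention_weights(Cm, stages$mi2)
  } else {
    A2c <- matrix(static_stage2_row(d_code, H, static_ratio[1], static_ratio[3]),
                  n, d_code + H, byrow = TRUE)
    A2m <- matrix(static_stage2_row(d_code, H, static_ratio[2], static_ratio[3]),
                  n, d_code + H, byrow = TRUE)
  }
  N <- cbind(apply_attention(Cc, A2c), apply_attention(Cm, A2m))
  list(N = N, A1c = A1c, A1m = A1m, Cc = Cc, Cm = Cm, A2c = A2c, A2m = A2m,
       d_code = d_code, H = H, mode = mode, static_ratio = static_ratio)
}

#' Fuse a single pair
#'
#' Convenience wrapper around [fuse_pairs()] for one (circRNA, miRNA) pair.
#'
#' @param circ_code,mi_code sequence-code vectors.
#' @param circ_struct,mi_struct structural embedding vectors.
#' @param stages attention stages.
#' @inheritParams fuse_pairs
#' @return the fused vector of length `2 * (d_code + H)`.
#' @export
fuse_pair <- function(circ_code, mi_code, circ_struct, mi_struct, stages,
                      mode = "attention", static_ratio = c(1, 1, 1)) {
  drop(fuse_pairs(matrix(circ_code, 1L), matrix(mi_code, 1L),
                  matrix(circ_struct, 1L), matrix(mi_struct, 1L),
                  stages, mode, static_ratio)$N)
}

#' Z-score standardization with reusable statistics
#'
#' Per-feature standardization. Statistics are fitted on training pairs and
#' reused unchanged on validation/test pairs. Zero-variance features pass
#' through unscaled with a warning.
#'
#' @param F pair x d feature matrix.
#' @param stats optional list `(mean, sd)` from a previous fit.
#' @return list with `X` (standardized matrix) and `stats`.
#' @export
standardize_features <- function(F, stats = NULL) {
  if (is.null(stats)) {
    mu <- colMeans(F)
    sdv <- apply(F, 2L, sd)
    if (any(sdv == 0)) {
      warning(sum(sdv == 0), " zero-variance feature(s) left unscaled")
      sdv[sdv == 0] <- 1
    }
    stats <- list(mean = mu, sd = sdv)
  } else if (length(stats$mean) != ncol(F)) {
    stop("standardization stats dimension mismatch")
  }
  X <- sweep(sweep(F, 2L, stats$mean), 2L, stats$sd, "/")
  list(X = X, stats = stats)
}

#' Mean attention weight per feature block
#'
#' Averages the stage-2 attention weights over pairs and sums them within the
#' circRNA-sequence, miRNA-sequence and structural blocks. Each branch's
#' weights sum to 1, so the combined summary (both branches averaged) also
#' sums to 1.
#'
#' @param fused the list returned by [fuse_pairs()].
#' @return named numeric vector `(circ_seq, mi_seq, struct)` summing to 1.
#' @export
mean_attention_by_block <- function(fused) {
  d <- fused$d_code
  H <- fused$H
  mc <- colMeans(fused$A2c)
  mm <- colMeans(fused$A2m)
  c(circ_seq = sum(mc[seq_len(d)]) / 2,
    mi_seq = sum(mm[seq_len(d)]) / 2,
    struct = (sum(mc[d + seq_len(H)]) + sum(mm[d + seq_len(H)])) / 2)
}
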