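#' Fit a stacked autoencoder by greedy layer-wise training
#'
#' A funnel of sigmoid autoencoders (default layer sizes 256, 128, 64) is
#' trained one layer at a time: each layer minimizes the mean squared
#' reconstruction error of its input (decoder weights tied to the transpose of
#' the encoder weights), then is frozen and its codes become the next layer's
#' input. Inputs are min-max scaled to `[0, 1]` per feature first, since a
#' sigmoid decoder cannot reconstruct unbounded values; the scaler is stored
#' in the model and reused at encode time. Optimized with Adam on mini-batches,
#' with early stopping on a held-out validation slice (best weights restored).
#'
#' @param X sample x feature numeric matrix.
#' @param layer_sizes hidden layer widths, outermost first; the last entry is
#'   the bottleneck dimension.
#' @param epochs maximum training epochs per layer.
#' @param lr Adam learning rate.
#' @param val_frac fraction of samples held out for early stopping.
#' @param batch_size mini-batch size.
#' @param patience epochs without validation improvement before stopping.
#' @param tied if `TRUE` (default) the decoder weight is the encoder's
#'   transpose; otherwise a separate decoder matrix is trained.
#' @param seed RNG seed (initialization, shuffling, validation split).
#' @return list of class `sae_model` with `layers` (each `M`, `b`, `b_dec`,
#'   optionally `M_dec`), `scaler`, `history` (per-layer per-epoch validation
#'   loss) and the settings.
#' @export
sae_fit <- function(X, layer_sizes = c(256L, 128L, 64L), epochs = 20L,
                    lr = 1e-3, val_frac = 0.10, batch_size = 128L,
                    patience = 3L, tied = TRUE, seed = 1L) {
  if (!is.matrix(X) || nrow(X) == 0L) stop("X must be a non-empty matrix")
  if (any(!is.finite(X))) stop("non-finite values in X")
  n <- nrow(X)
  n_val <- max(1L, round(val_frac * n))
  if (n - n_val < 1L) stop("too few samples for a ", val_frac, " validation slice")
  set.seed(seed)

  mins <- apply(X, 2L, min)
  rngs <- apply(X, 2L, max) - mins
  rngs[rngs == 0] <- 1
  Z <- sweep(sweep(X, 2L, mins), 2L, rngs, "/")

  val_idx <- sample.int(n, n_val)
  layers <- vector("list", length(layer_sizes))
  history <- vector("list", length(layer_sizes))

  for (l in seq_along(layer_sizes)) {
    h_in <- ncol(Z)
    h_out <- layer_sizes[l]
    # decoder bias starts at the logit of each feature's mean, so the initial
    # reconstruction is already the per-feature-mean baseline
    mu_z <- pmin(pmax(colMeans(Z), 1e-3), 1 - 1e-3)
    pars <- list(M = glorot_uniform(h_out, h_in), b = rep(0, h_out),
                 b_dec = log(mu_z / (1 - mu_z)))
    if (!tied) pars$M_dec <- glorot_uniform(h_out, h_in)
    states <- setNames(vector("list", length(pars)), names(pars))
    Ztr <- Z[-val_idx, , drop = FALSE]
    Zval <- Z[val_idx, , drop = FALSE]

    layer_loss <- function(p, zz) {
      Y <- sigmoid(zz %*% t(p$M) + rep(p$b, each = nrow(zz)))
      dec_w <- if (tied) p$M else p$M_dec
      Zhat <- sigmoid(Y %*% dec_w + rep(p$b_dec, each = nrow(zz)))
      mean(rowSums((zz - Zhat)^2))
    }

    best <- list(pars = pars, loss = layer_loss(pars, Zval), epoch = 0L)
    val_trace <- numeric(0)
    stall <- 0L
    for (ep in seq_len(epochs)) {
      perm <- sample.int(nrow(Ztr))
      starts <- seq(1L, nrow(Ztr), by = batch_size)
      for (s in starts) {
        idx <- perm[s:min(s + batch_size - 1L, nrow(Ztr))]
        zz <- Ztr[idx, , drop = FALSE]
        m <- nrow(zz)
        pre1 <- zz %*% t(pars$M) + rep(pars$b, each = m)
        Y <- sigmoid(pre1)
        dec_w <- if (tied) pars$M else pars$M_dec
        pre2 <- Y %*% dec_w + rep(pars$b_dec, each = m)
        Zhat <- sigmoid(pre2)
        dpre2 <- (2 / m) * (Zhat - zz) * Zhat * (1 - Zhat)
        dY <- dpre2 %*% t(dec_w)
        dpre1 <- dY * Y * (1 - Y)
        grads <- list(M = t(dpre1) %*% zz, b = colSums(dpre1),
                      b_dec = colSums(dpre2))
        if (tied) {
          grads$M <- grads$M + t(Y) %*% dpre2
        } else {
          grads$M_dec <- t(Y) %*% dpre2
        }
        upd <- adam_step_all(pars, grads, states, lr)
        pars <- upd$pars
        states <- upd$states
      }
      vloss <- layer_loss(pars, Zval)
      val_trace <- c(val_trace, vloss)
      if (vloss < best$loss - 1e-9) {
        best <- list(pars = pars, loss = vloss, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
    layers[[l]] <- best$pars
    history[[l]] <- list(val_loss = val_trace, best_epoch = best$epoch,
                         best_loss = best$loss)
    Y_full <- sigmoid(Z %*% t(best$pars$M) + rep(best$pars$b, each = n))
    Z <- Y_full
  }

  structure(list(layers = layers, layer_sizes = as.integer(layer_sizes),
                 scaler = list(min = mins, range = rngs), tied = tied,
                 history = history, epochs = as.integer(epochs), lr = lr,
                 seed = as.integer(seed)),
            class = "sae_model")
}

#' Encode samples through a trained stacked autoencoder
#'
#' @param model a trained `sae_model`.
#' @param X sample x feature matrix on the original (pre-scaling) scale.
#' @param depth number of encoder layers to apply, or `"bottleneck"` for all
#'   of them (the compressed representation used downstream).
#' @return sample x width matrix of codes; every entry lies in (0, 1).
#' @export
sae_encode <- function(model, X, depth = "bottleneck") {
  stopifnot(inherits(model, "sae_model"))
  if (ncol(X) != length(model$scaler$min))
    stop("feature dimension mismatch: ", ncol(X), " vs ",
         length(model$scaler$min))
  if (identical(depth, "bottleneck")) depth <- length(model$layers)
  stopifnot(depth >= 1L, depth <= length(model$layers))
  Z <- sweep(sweep(X, 2L, model$scaler$min), 2L, model$scaler$range, "/")
  for (l in seq_len(depth)) {
    p <- model$layers[[l]]
    Z <- sigmoid(Z %*% t(p$M) + rep(p$b, each = nrow(Z)))
  }
  Z
}

#' Reconstruct samples through the full encoder-decoder stack
#'
#' Encodes to the bottleneck and decodes back through every layer in reverse;
#' useful for measuring how much of the input the compressed code retains.
#'
#' @param model a trained `sae_model`.
#' @param X sample x feature matrix on the original scale.
#' @return reconstruction on the min-max-scaled `[0, 1]` scale, together with
#'   the scaled input, as a list `(X_scaled, X_hat, mse)`.
#' @export
sae_reconstruct <- function(model, X) {
  stopifnot(inherits(model, "sae_model"))
  Z0 <- sweep(sweep(X, 2L, model$scaler$min), 2L, model$scaler$range, "/")
  Z <- Z0
  for (l in seq_along(model$layers)) {
    p <- model$layers[[l]]
    Z <- sigmoid(Z %*% t(p$M) + rep(p$b, each = nrow(Z)))
  }
  for (l in rev(seq_along(model$layers))) {
    p <- model$layers[[l]]
    dec_w <- if (model$tied) p$M else p$M_dec
    Z <- sigmoid(Z %*% dec_w + rep(p$b_dec, each = nrow(Z)))
  }
  list(X_scaled = Z0, X_hat = Z, mse = mean((Z0 - Z)^2))
}
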