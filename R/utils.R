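#' @useDynLib cmipred, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm sd setNames
#' @importFrom utils head read.table write.table
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Row-wise softmax
#'
#' Numerically stable softmax applied independently to each row of a matrix.
#'
#' @param x numeric matrix of logits.
#' @return matrix of the same shape; each row is positive and sums to 1.
#' @keywords internal
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# Glorot (Xavier) uniform initialization for a fan_in x fan_out weight matrix.
glorot_uniform <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

# One Adam update; state holds m, v, t. Returns list(par, state).
adam_step <- function(par, grad, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(state)) state <- list(m = par * 0, v = par * 0, t = 0L)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# Apply adam_step over a named list of parameters.
adam_step_all <- function(pars, grads, states, lr) {
  for (nm in names(pars)) {
    upd <- adam_step(pars[[nm]], grads[[nm]], states[[nm]], lr = lr)
    pars[[nm]] <- upd$par
    states[[nm]] <- upd$state
  }
  list(pars = pars, states = states)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
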