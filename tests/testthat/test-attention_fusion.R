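test_that("attention weights are a proper per-sample softmax", {
  d <- 6L
  stage <- list(W = diag(d) * 0, b = rep(0, d))  # all logits equal
  X <- matrix(rnorm(5 * d), 5)
  w <- attention_weights(X, stage)
  expect_equal(unname(w), matrix(1 / d, 5, d))

  # logits (0, ln 2) -> weights (1/3, 2/3)
  w2 <- softmax_rows(matrix(c(0, log(2)), 1))
  expect_equal(drop(w2), c(1 / 3, 2 / 3), tolerance = 1e-12)

  set.seed(6)
  stage_r <- list(W = matrix(rnorm(d * d), d), b = rnorm(d))
  Xr <- matrix(rnorm(50 * d), 50)
  wr <- attention_weights(Xr, stage_r)
  expect_true(all(wr > 0))
  expect_equal(rowSums(wr), rep(1, 50), tolerance = 1e-6)
  expect_error(attention_weights(matrix(Inf, 2, d), stage_r), "non-finite")
})

test_that("attention application is an elementwise product", {
  X <- matrix(rnorm(12), 3)
  w <- matrix(1 / 4, 3, 4)
  expect_equal(apply_attention(X, w), X / 4)
  onehot <- matrix(0, 3, 4); onehot[, 2] <- 1
  expect_equal(apply_attention(X, onehot)[, 2], X[, 2])
  expect_true(all(apply_attention(X * 0, w) == 0))
  expect_error(apply_attention(X, w[, 1:2]), "mismatch")
})

test_that("fusion output dimension is 2*(d_code + H) across configurations", {
  set.seed(9)
  n <- 7L
  d_code <- 64L
  for (H in c(16L, 64L, 96L)) {
    st <- init_attention_stages(d_code, H, seed = 3)
    out <- fuse_pairs(matrix(rnorm(n * d_code), n), matrix(rnorm(n * d_code), n),
                      matrix(rnorm(n * H), n), matrix(rnorm(n * H), n), st)
    expect_equal(ncol(out$N), 2L * (d_code + H))
    expect_equal(rowSums(out$A2c), rep(1, n), tolerance = 1e-6)
  }
})

test_that("zero inputs fuse to zero and branch swap permutes the halves", {
  d_code <- 8L; H <- 4L
  st <- init_attention_stages(d_code, H, seed = 2)
  zero <- fuse_pair(rep(0, d_code), rep(0, d_code), rep(0, H), rep(0, H), st)
  expect_true(all(zero == 0))

  set.seed(14)
  cc <- rnorm(d_code); mc <- rnorm(d_code); cs <- rnorm(H); ms <- rnorm(H)
  f1 <- fuse_pair(cc, mc, cs, ms, st)
  st_sw <- list(circ1 = st$mi1, mi1 = st$circ1, circ2 = st$mi2, mi2 = st$circ2)
  f2 <- fuse_pair(mc, cc, ms, cs, st_sw)
  half <- d_code + H
  expect_equal(f2, c(f1[(half + 1):(2 * half)], f1[1:half]), tolerance = 1e-12)
})

test_that("standardization fits on training pairs and reuses frozen stats", {
  set.seed(4)
  F1 <- matrix(rnorm(200 * 6, mean = 3, sd = 2), 200)
  s <- standardize_features(F1)
  expect_equal(colMeans(s$X), rep(0, 6), tolerance = 1e-8)
  expect_equal(apply(s$X, 2, sd), rep(1, 6), tolerance = 1e-8)

  F2 <- matrix(rnorm(50 * 6), 50)
  s2 <- standardize_features(F2, stats = s$stats)
  expect_false(isTRUE(all.equal(colMeans(s2$X), rep(0, 6), tolerance = 1e-3)))

  Fc <- cbind(F1[, 1:2], 5)
  expect_warning(sc <- standardize_features(Fc), "zero-variance")
  expect_equal(sc$X[, 3], Fc[, 3] - 5, ignore_attr = TRUE)
})

test_that("block attention summaries conserve mass and follow static ratios", {
  set.seed(5)
  n <- 40L; d_code <- 6L; H <- 3L
  st <- init_attention_stages(d_code, H, seed = 1)
  out <- fuse_pairs(matrix(rnorm(n * d_code), n), matrix(rnorm(n * d_code), n),
                    matrix(rnorm(n * H), n), matrix(rnorm(n * H), n), st)
  blk <- mean_attention_by_block(out)
  expect_equal(sum(blk), 1, tolerance = 1e-9)

  out_s <- fuse_pairs(matrix(rnorm(n * d_code), n), matrix(rnorm(n * d_code), n),
                      matrix(rnorm(n * H), n), matrix(rnorm(n * H), n), st,
                      mode = "static", static_ratio = c(2, 2, 1))
  blk_s <- mean_attention_by_block(out_s)
  expect_equal(unname(blk_s), c(1 / 3, 1 / 3, 1 / 3), tolerance = 1e-12)
})

test_that("attention learns to favor the informative modality", {
  # labels depend only on the sequence codes; structure is pure noise
  set.seed(31)
  n <- 600L; d_code <- 8L; H <- 8L
  f <- list(circ_code = matrix(rnorm(n * d_code), n),
            mi_code = matrix(rnorm(n * d_code), n),
            circ_struct = matrix(rnorm(n * H), n),
            mi_struct = matrix(rnorm(n * H), n))
  y <- as.integer(f$circ_code[, 1] + f$mi_code[, 1] > 0)
  m <- model_fit(f, y, iterations = 1200L, batch_size = 128L,
                 early_stopping = FALSE, seed = 7)
  fw <- cmipred:::cmi_forward(m$pars, f, m$stats)
  blk <- mean_attention_by_block(fw$fused)
  expect_gt(blk[["circ_seq"]] + blk[["mi_seq"]], blk[["struct"]])
})
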