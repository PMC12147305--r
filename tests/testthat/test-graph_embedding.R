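test_that("bipartite block adjacency is assembled correctly", {
  A <- matrix(c(1L), 1, 1, dimnames = list("c1", "m1"))
  g <- build_bipartite_adjacency(A)
  expect_equal(unname(g$S), matrix(c(0, 1, 1, 0), 2))
  expect_equal(g$edge_count, 1L)

  A2 <- matrix(0L, 2, 3)
  A2[1, 1] <- 1L
  g2 <- build_bipartite_adjacency(A2)
  expect_equal(dim(g2$S), c(5L, 5L))
  expect_true(isSymmetric(g2$S))
  expect_error(build_bipartite_adjacency(matrix(0L, 2, 2)), "no interactions")
})

test_that("transition matrix normalizes by degree and warns on isolated nodes", {
  g <- build_bipartite_adjacency(matrix(c(1L), 1, 1))
  expect_equal(unname(transition_matrix(g)), matrix(c(0, 1, 1, 0), 2))

  A <- matrix(c(1L, 1L, 0L, 0L), 2, 2)  # mi2 isolated? col2 has none
  g2 <- build_bipartite_adjacency(A)
  expect_warning(Tm <- transition_matrix(g2), "isolated")
  rs <- rowSums(Tm)
  nondeg <- rowSums(g2$S) > 0
  expect_equal(rs[nondeg], rep(1, sum(nondeg)), ignore_attr = TRUE)
  expect_true(all(rs[!nondeg] == 0))

  # path graph via direct structure: middle node splits mass evenly
  gp <- list(S = matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3), n_circ = 1, n_mi = 2,
             edge_count = 2, node_ids = letters[1:3])
  class(gp) <- "cmi_graph"
  expect_equal(transition_matrix(gp)[2, ], c(0.5, 0, 0.5), ignore_attr = TRUE)
})

test_that("two-node single-edge graph yields an identically zero shifted log matrix", {
  A <- matrix(c(0, 1, 1, 0), 2)
  ord <- shifted_log_matrix(A, k = 1, lambda_neg = 1, E_count = 1)
  expect_equal(ord$A_k, A)
  expect_true(all(ord$X_k == 0))
})

test_that("shifted log matrix matches a dense brute-force computation", {
  set.seed(21)
  assoc <- matrix(rbinom(20, 1, 0.5), 4, 5)
  assoc[1, 1] <- 1L
  g <- build_bipartite_adjacency(assoc)
  A <- suppressWarnings(transition_matrix(g))
  for (k in 1:3) {
    ord <- shifted_log_matrix(A, k, lambda_neg = 2, E_count = g$edge_count)
    Ak <- A
    if (k > 1) for (i in 2:k) Ak <- Ak %*% A
    ref <- matrix(0, nrow(Ak), ncol(Ak))
    for (i in seq_len(nrow(Ak))) for (j in seq_len(ncol(Ak))) {
      if (Ak[i, j] > 0) {
        y <- log(Ak[i, j] / sum(Ak[, j])) - log(2 / g$edge_count)
        ref[i, j] <- max(y, 0)
      }
    }
    expect_equal(unname(ord$X_k), ref, tolerance = 1e-12)
    expect_true(all(ord$X_k >= 0))
  }
})

test_that("raising lambda weakly decreases every shifted-log entry", {
  set.seed(8)
  assoc <- matrix(rbinom(30, 1, 0.4), 5, 6)
  assoc[2, 2] <- 1L
  g <- build_bipartite_adjacency(assoc)
  A <- suppressWarnings(transition_matrix(g))
  x1 <- shifted_log_matrix(A, 2, 1, g$edge_count)$X_k
  x2 <- shifted_log_matrix(A, 2, 4, g$edge_count)$X_k
  expect_true(all(x2 <= x1 + 1e-12))
})

test_that("truncated factorization satisfies Eckart-Young and reconstructs low rank", {
  set.seed(4)
  a <- abs(rnorm(6)); b <- abs(rnorm(5)); c2 <- abs(rnorm(6)); d2 <- abs(rnorm(5))
  X <- a %o% b + c2 %o% d2
  f <- factorize_order(X, 2)
  expect_lt(max(abs(X - f$H_k %*% t(f$Z_k))), 1e-8)

  Xr <- matrix(abs(rnorm(42)), 6, 7)
  f2 <- factorize_order(Xr, 3)
  resid <- norm(Xr - f2$H_k %*% t(f2$Z_k), "F")
  sv <- svd(Xr)$d
  expect_equal(resid, sqrt(sum(sv[-(1:3)]^2)), tolerance = 1e-8)

  expect_warning(fz <- factorize_order(matrix(0, 3, 3), 2), "all-zero")
  expect_true(all(fz$H_k == 0) && all(fz$Z_k == 0))
})

test_that("grarep matches the dense oracle on random small graphs", {
  set.seed(33)
  for (rep in 1:4) {
    n_c <- sample(3:6, 1)
    n_m <- sample(3:6, 1)
    assoc <- matrix(rbinom(n_c * n_m, 1, 0.5), n_c, n_m)
    assoc[1, 1] <- 1L
    emb <- suppressWarnings(grarep(assoc, K = 3, d_k = 4))
    ref <- suppressWarnings(grarep_oracle(assoc, K = 3, d_k = 4))
    got <- rbind(emb$circ, emb$mi)
    expect_lt(max(abs(unname(got) - align_signs(got, ref))), 1e-8)
  }
})

test_that("structurally automorphic nodes share embeddings; dimension is K*d_k", {
  assoc <- matrix(1L, 2, 2)  # the two circ nodes are automorphic, as are the mi
  emb <- grarep(assoc, K = 2, d_k = 2)
  expect_equal(emb$circ[1, ], emb$circ[2, ], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(ncol(emb$circ), 4L)
  emb2 <- suppressWarnings(grarep(matrix(c(1L, 0L, 0L, 1L), 2), K = 4, d_k = 16))
  expect_equal(ncol(emb2$mi), 64L)

  e1 <- grarep(assoc, K = 2, d_k = 2)
  expect_identical(emb$all, e1$all)
})
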