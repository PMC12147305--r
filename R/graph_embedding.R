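#' Build the bipartite adjacency of the CMI graph
#'
#' Stacks the association matrix into the symmetric block adjacency
#' `S = [[0, A], [A', 0]]` over `n_circ + n_mi` nodes (circRNA nodes first).
#'
#' @param assoc binary association matrix from [build_association_matrix()].
#' @return list of class `cmi_graph` with `S` (symmetric 0/1 adjacency),
#'   `n_circ`, `n_mi`, `edge_count` and `node_ids`.
#' @export
build_bipartite_adjacency <- function(assoc) {
  if (sum(assoc) == 0) stop("association matrix has no interactions")
  n_c <- nrow(assoc)
  n_m <- ncol(assoc)
  S <- matrix(0, n_c + n_m, n_c + n_m)
  S[seq_len(n_c), n_c + seq_len(n_m)] <- assoc
  S[n_c + seq_len(n_m), seq_len(n_c)] <- t(assoc)
  ids <- c(rownames(assoc) %||% paste0("circ", seq_len(n_c)),
           colnames(assoc) %||% paste0("mi", seq_len(n_m)))
  dimnames(S) <- list(ids, ids)
  structure(list(S = S, n_circ = n_c, n_mi = n_m,
                 edge_count = sum(assoc), node_ids = ids),
            class = "cmi_graph")
}

#' Degree-normalized transition matrix
#'
#' `A = D^-1 S` with D the diagonal degree matrix. Rows of isolated nodes are
#' left all-zero (with a warning) rather than dividing by zero.
#'
#' @param graph a `cmi_graph`.
#' @return row-stochastic matrix (up to isolated rows).
#' @export
transition_matrix <- function(graph) {
  stopifnot(inherits(graph, "cmi_graph"))
  deg <- rowSums(graph$S)
  if (any(deg == 0))
    warning(sum(deg == 0), " isolated node(s): zero transition row(s)")
  A <- graph$S / ifelse(deg == 0, 1, deg)
  A
}

#' Shifted positive log co-occurrence matrix of order k
#'
#' Computes `A^k`, then `Y_k[i, j] = log(A^k[i, j] / Gamma_k[j]) - log(beta)`
#' with `Gamma_k[j]` the j-th column sum of `A^k` and `beta = lambda / |E|`,
#' and clamps negatives (and the `-Inf` images of zero entries) to zero:
#' `X_k = pmax(Y_k, 0)`.
#'
#' @param A row-stochastic transition matrix.
#' @param k step order (>= 1).
#' @param lambda_neg negative-sample count lambda (> 0).
#' @param E_count number of undirected edges |E| (> 0).
#' @return list with `A_k`, `Y_k` (zero entries carried as `-Inf`), `X_k`,
#'   `beta`.
#' @export
shifted_log_matrix <- function(A, k, lambda_neg = 1, E_count) {
  if (k < 1L) stop("k must be >= 1")
  if (lambda_neg <= 0) stop("lambda_neg must be > 0")
  if (E_count <= 0) stop("E_count must be > 0")
  A_k <- A
  if (k > 1L) for (i in seq_len(k - 1L)) A_k <- A_k %*% A
  gamma <- colSums(A_k)
  beta <- lambda_neg / E_count
  ratio <- sweep(A_k, 2L, ifelse(gamma == 0, 1, gamma), "/")
  Y_k <- suppressWarnings(log(ratio)) - log(beta)
  Y_k[A_k == 0] <- -Inf
  X_k <- pmax(Y_k, 0)
  list(A_k = A_k, Y_k = Y_k, X_k = X_k, beta = beta)
}

#' Rank-d factorization of one order matrix
#'
#' Truncated SVD `X_k ~ U S V'` keeping the `d_k` largest singular values;
#' returns `H_k = U sqrt(S)` and `Z_k = V sqrt(S)`. The sign of each singular
#' vector pair is fixed by making the largest-magnitude component of the left
#' vector positive, so repeated runs are identical.
#'
#' @param X_k nonnegative matrix from [shifted_log_matrix()].
#' @param d_k rank (>= 1).
#' @return list with `H_k`, `Z_k` (node x d_k each) and `d` (singular values).
#' @export
factorize_order <- function(X_k, d_k) {
  if (d_k < 1L) stop("d_k must be >= 1")
  d_k <- min(d_k, nrow(X_k), ncol(X_k))
  if (all(X_k == 0)) {
    warning("all-zero order matrix: zero embeddings")
    return(list(H_k = matrix(0, nrow(X_k), d_k),
                Z_k = matrix(0, ncol(X_k), d_k),
                d = rep(0, d_k)))
  }
  sv <- svd(X_k, nu = d_k, nv = d_k)
  U <- sv$u
  V <- sv$v
  for (j in seq_len(d_k)) {
    pivot <- which.max(abs(U[, j]))
    if (U[pivot, j] < 0) {
      U[, j] <- -U[, j]
      V[, j] <- -V[, j]
    }
  }
  s_half <- sqrt(sv$d[seq_len(d_k)])
  list(H_k = U * rep(s_half, each = nrow(U)),
       Z_k = V * rep(s_half, each = nrow(V)),
       d = sv$d[seq_len(d_k)])
}

#' GraRep node embedding of the CMI network
#'
#' Runs orders `1..K` of the k-step transition factorization and concatenates
#' the per-order source embeddings `H_1..H_K` into one `K * d_k`-dimensional
#' vector per node, split back into circRNA and miRNA sub-tables.
#'
#' @param assoc binary association matrix.
#' @param K maximum step order.
#' @param d_k per-order rank.
#' @param lambda_neg negative-sample count lambda.
#' @return list of class `grarep_embedding` with `circ` and `mi` (node x K*d_k
#'   matrices, rownames = ids), `all` (stacked matrix), and the settings.
#' @export
grarep <- function(assoc, K = 4L, d_k = 16L, lambda_neg = 1) {
  if (K < 1L) stop("K must be >= 1")
  graph <- build_bipartite_adjacency(assoc)
  A <- transition_matrix(graph)
  blocks <- vector("list", K)
  for (k in seq_len(K)) {
    ord <- shifted_log_matrix(A, k, lambda_neg, graph$edge_count)
    H_k <- suppressWarnings(factorize_order(ord$X_k, d_k))$H_k
    if (ncol(H_k) < d_k)  # graphs smaller than the rank: pad so dim is K*d_k
      H_k <- cbind(H_k, matrix(0, nrow(H_k), d_k - ncol(H_k)))
    blocks[[k]] <- H_k
  }
  emb <- do.call(cbind, blocks)
  rownames(emb) <- graph$node_ids
  structure(list(
    circ = emb[seq_len(graph$n_circ), , drop = FALSE],
    mi = emb[graph$n_circ + seq_len(graph$n_mi), , drop = FALSE],
    all = emb, K = as.integer(K), d_k = as.integer(d_k),
    lambda_neg = lambda_neg),
    class = "grarep_embedding")
}
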