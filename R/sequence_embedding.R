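#' Tokenize an RNA sequence into overlapping k-mers
#'
#' Slides a window of length `k` with stride 1 over the sequence; a sequence
#' shorter than `k` yields an empty token list with a warning.
#'
#' @param sequence RNA string over ACGU (a single record's sequence).
#' @param k k-mer length (>= 1).
#' @return character vector of `max(0, nchar(sequence) - k + 1)` tokens.
#' @export
kmer_tokenize <- function(sequence, k = 3L) {
  if (k < 1L) stop("k must be >= 1")
  L <- nchar(sequence)
  if (L < k) {
    warning("sequence shorter than k (", L, " < ", k, "): no tokens")
    return(character(0))
  }
  substring(sequence, 1:(L - k + 1L), k:L)
}

#' Train k-mer token embeddings by skip-gram with negative sampling
#'
#' One shared embedding space is trained over the union of the circRNA and
#' miRNA token streams. For each (center, context) token pair within the
#' window, the training objective maximizes
#' `log sigmoid(<v'_context, v_center>)` plus `k_neg` negative terms
#' `log sigmoid(-<v'_noise, v_center>)` with noise tokens drawn from the
#' unigram distribution smoothed by `noise_exponent`. SGD with a linearly
#' decaying learning rate; single-threaded and bitwise-reproducible for a
#' fixed seed.
#'
#' @param records record data.frame(s) (`id`, `sequence`); pass
#'   `rbind(circ, mi)` to share one vocabulary.
#' @param k k-mer length (vocabulary is the set of observed k-mers).
#' @param dim embedding dimension D.
#' @param window context window radius c.
#' @param k_neg negative samples per positive pair.
#' @param epochs training passes over the corpus.
#' @param lr initial learning rate.
#' @param noise_exponent smoothing power of the unigram noise distribution.
#' @param seed integer seed for the trainer's internal RNG.
#' @return list of class `kmer_embedding` with elements `vocabulary`,
#'   `input` and `output` (token x dim matrices, rownames = tokens), and the
#'   hyperparameters.
#' @export
train_token_embeddings <- function(records, k = 3L, dim = 64L, window = 5L,
                                   k_neg = 5L, epochs = 5L, lr = 0.025,
                                   noise_exponent = 0.75, seed = 1L) {
  if (nrow(records) == 0L) stop("empty corpus")
  if (dim < 1L) stop("dim must be >= 1")
  token_lists <- lapply(records$sequence, function(s)
    suppressWarnings(kmer_tokenize(s, k)))
  vocab <- sort(unique(unlist(token_lists)))
  if (length(vocab) == 0L) stop("no tokens in corpus (all sequences < k?)")
  sentences <- lapply(token_lists, function(tk)
    match(tk, vocab) - 1L)
  sentences <- sentences[lengths(sentences) > 0L]
  fit <- .sgns_train_cpp(sentences, length(vocab), as.integer(dim),
                         as.integer(window), as.integer(k_neg),
                         as.integer(epochs), lr, noise_exponent,
                         as.integer(seed))
  rownames(fit$input) <- vocab
  rownames(fit$output) <- vocab
  structure(list(vocabulary = vocab, input = fit$input, output = fit$output,
                 k = as.integer(k), dim = as.integer(dim),
                 window = as.integer(window), k_neg = as.integer(k_neg),
                 noise_exponent = noise_exponent, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "kmer_embedding")
}

#' Pool token embeddings into one vector per sequence
#'
#' Mean of the input vectors of the first `min(T, P)` tokens of each sequence
#' (truncation length P). A sequence with no in-vocabulary tokens maps to the
#' zero vector with a warning.
#'
#' @param records record data.frame.
#' @param table a trained `kmer_embedding`.
#' @param P maximum token count pooled per sequence.
#' @param oov out-of-vocabulary token policy: `"skip"` (default) or `"error"`.
#' @return numeric matrix (sequence x dim), rownames = record ids.
#' @export
embed_sequences <- function(records, table, P = 64L, oov = c("skip", "error")) {
  stopifnot(inherits(table, "kmer_embedding"))
  oov <- match.arg(oov)
  if (P < 1L) stop("P must be >= 1")
  out <- matrix(0, nrow(records), table$dim,
                dimnames = list(records$id, NULL))
  for (i in seq_len(nrow(records))) {
    tk <- suppressWarnings(kmer_tokenize(records$sequence[i], table$k))
    tk <- tk[seq_len(min(length(tk), P))]
    idx <- match(tk, table$vocabulary)
    if (anyNA(idx)) {
      if (oov == "error") stop("out-of-vocabulary token(s) in ", records$id[i])
      idx <- idx[!is.na(idx)]
    }
    if (length(idx) == 0L) {
      warning("no in-vocabulary tokens for ", records$id[i], ": zero vector")
      next
    }
    out[i, ] <- colMeans(table$input[idx, , drop = FALSE])
  }
  out
}

#' Serialize / load an embedding table as plain text
#'
#' Written as a token-list file plus a delimited dense-matrix file per vector
#' set, so tables survive text-only storage.
#'
#' @param table a `kmer_embedding`.
#' @param prefix path prefix; files `<prefix>_tokens.txt`,
#'   `<prefix>_input.tsv`, `<prefix>_output.tsv` are produced.
#' @return `prefix`, invisibly.
#' @export
write_embedding_table <- function(table, prefix) {
  writeLines(table$vocabulary, paste0(prefix, "_tokens.txt"))
  write.table(table$input, paste0(prefix, "_input.tsv"), sep = "\t",
              quote = FALSE, col.names = FALSE, row.names = FALSE)
  write.table(table$output, paste0(prefix, "_output.tsv"), sep = "\t",
              quote = FALSE, col.names = FALSE, row.names = FALSE)
  invisible(prefix)
}
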