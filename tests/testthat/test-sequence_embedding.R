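test_that("k-mer tokenization follows the sliding-window definition", {
  expect_equal(kmer_tokenize("ACGUACGU", 3),
               c("ACG", "CGU", "GUA", "UAC", "ACG", "CGU"))
  expect_equal(kmer_tokenize("ACG", 3), "ACG")
  expect_warning(tk <- kmer_tokenize("AC", 3), "shorter")
  expect_equal(length(tk), 0L)
  expect_error(kmer_tokenize("ACGU", 0), ">= 1")
})

test_that("token count conservation holds over a random corpus", {
  set.seed(5)
  seqs <- replicate(20, paste(sample(c("A", "C", "G", "U"),
                                     sample(2:30, 1), replace = TRUE),
                              collapse = ""))
  k <- 4L
  total <- sum(vapply(seqs, function(s)
    length(suppressWarnings(kmer_tokenize(s, k))), integer(1)))
  expect_equal(total, sum(pmax(0L, nchar(seqs) - k + 1L)))
})

test_that("training covers the vocabulary and is seed-deterministic", {
  rec <- make_records(c("ACGUACGUACGUACGU", "GGGAGGGAGGGAGGGA",
                        "UUCAUUCAUUCAUUCA"))
  t1 <- train_token_embeddings(rec, k = 3, dim = 16, epochs = 3, seed = 9)
  t2 <- train_token_embeddings(rec, k = 3, dim = 16, epochs = 3, seed = 9)
  tok <- unique(unlist(lapply(rec$sequence, kmer_tokenize, k = 3)))
  expect_setequal(t1$vocabulary, tok)
  expect_equal(dim(t1$input), c(length(tok), 16L))
  expect_identical(t1$input, t2$input)
  expect_identical(t1$output, t2$output)
  expect_true(all(is.finite(t1$input)))
  expect_gt(sum(t1$input^2), 0)
})

test_that("co-occurring tokens align: trainer agrees with the exact-expectation oracle", {
  # Two token cliques with disjoint contexts. Oracle optimizes the exact
  # expected negative-sampling objective; trainer runs stochastic SGD.
  rec <- make_records(rep(c("ACGACGACGACGACGACG", "GUUGUUGUUGUUGUUGUU"), 8))
  tab <- train_token_embeddings(rec, k = 3, dim = 16, window = 2,
                                epochs = 20, seed = 4)
  within_a <- cosine(tab$input["ACG", ], tab$output["CGA", ])
  cross <- cosine(tab$input["ACG", ], tab$output["UUG", ])
  expect_gt(within_a, cross)

  # Oracle on the aggregated co-occurrence counts of the same toy setting:
  # tokens 1-2 co-occur, tokens 3-4 co-occur, no cross pairs.
  pc <- matrix(0, 4, 4)
  pc[1, 2] <- pc[2, 1] <- 50
  pc[3, 4] <- pc[4, 3] <- 50
  orc <- sgns_expected_oracle(pc, token_counts = c(50, 50, 50, 50))
  expect_gt(cosine(orc$input[1, ], orc$output[2, ]),
            cosine(orc$input[1, ], orc$output[4, ]))
})

test_that("planted clique corpora separate in embedding space", {
  set.seed(11)
  clique_a <- c("AAACCC", "CCCAAA")
  clique_b <- c("GGGUUU", "UUUGGG")
  seqs <- c(replicate(10, paste(sample(clique_a, 6, TRUE), collapse = "")),
            replicate(10, paste(sample(clique_b, 6, TRUE), collapse = "")))
  rec <- make_records(seqs)
  tab <- train_token_embeddings(rec, k = 3, dim = 16, window = 3,
                                epochs = 10, seed = 2)
  toks_a <- c("AAA", "ACC", "CCC", "CCA")
  toks_a <- intersect(toks_a, tab$vocabulary)
  toks_b <- intersect(c("GGG", "GUU", "UUU", "UUG"), tab$vocabulary)
  pairs_within <- t(combn(toks_a, 2))
  within <- mean(apply(pairs_within, 1, function(p)
    cosine(tab$input[p[1], ], tab$input[p[2], ])))
  cross <- mean(outer(toks_a, toks_b, Vectorize(function(a, b)
    cosine(tab$input[a, ], tab$input[b, ]))))
  expect_gt(within, cross)
})

test_that("sequence pooling averages, truncates at P and handles empties", {
  rec <- make_records(c("ACGU", "AAAA"))
  tab <- train_token_embeddings(rec, k = 3, dim = 8, epochs = 2, seed = 1)
  one <- make_records("ACG", prefix = "s")
  emb <- embed_sequences(one, tab, P = 10)
  expect_equal(drop(emb), unname(tab$input["ACG", ]))

  # truncation: first min(T, P) tokens only
  long <- make_records(paste(rep("ACGU", 30), collapse = ""), prefix = "l")
  e_p2 <- embed_sequences(long, tab, P = 2)
  tk <- kmer_tokenize(long$sequence, 3)[1:2]
  expect_equal(drop(e_p2), colMeans(tab$input[tk, ]))

  short <- make_records("AC", prefix = "e")
  expect_warning(ez <- embed_sequences(short, tab), "zero vector")
  expect_true(all(ez == 0))
})

test_that("embedding tables serialize to plain text", {
  rec <- make_records(c("ACGUACGU", "GGGGCCCC"))
  tab <- train_token_embeddings(rec, k = 2, dim = 4, epochs = 2, seed = 1)
  pre <- file.path(withr::local_tempdir(), "emb")
  write_embedding_table(tab, pre)
  toks <- readLines(paste0(pre, "_tokens.txt"))
  mat <- as.matrix(read.table(paste0(pre, "_input.tsv"), sep = "\t"))
  expect_equal(toks, tab$vocabulary)
  expect_equal(unname(mat), unname(tab$input), tolerance = 1e-10)
})
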