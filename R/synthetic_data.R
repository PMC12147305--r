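#' Configuration for the synthetic CMI benchmark generator
#'
#' The generator emulates a circRNA/miRNA interaction screen in which binding
#' is driven by seed complementarity: a designated positive pair gets the
#' reverse complement of the miRNA seed region (positions 2-8, the canonical
#' 7-nt seed) embedded at a random position of the circRNA.
#'
#' @param n_circ,n_mi numbers of circRNAs and miRNAs (>= 2 each).
#' @param circ_len_range,mi_len_range inclusive nucleotide length ranges;
#'   defaults 300-1500 nt (circRNA) and 20-24 nt (miRNA).
#' @param seed_region miRNA positions forming the seed; default `2:8`.
#' @param planting_prob probability that a designated positive pair actually
#'   has its motif embedded.
#' @param label_noise probability that a designated positive label is flipped
#'   to negative (creating motif-bearing unlabeled cells).
#' @param target_density positives / (n_circ * n_mi).
#' @param gc_bias probability weight of G/C bases in the background
#'   composition; 0.5 is uniform.
#' @return a list of class `cmi_synth_config`.
#' @export
synthetic_config <- function(n_circ = 300L, n_mi = 100L,
                             circ_len_range = c(300L, 1500L),
                             mi_len_range = c(20L, 24L),
                             seed_region = 2:8,
                             planting_prob = 1, label_noise = 0,
                             target_density = 0.05, gc_bias = 0.5) {
  stopifnot(n_circ >= 2L, n_mi >= 2L,
            all(circ_len_range > 0L), all(mi_len_range > 0L),
            planting_prob >= 0, planting_prob <= 1,
            label_noise >= 0, label_noise <= 1,
            target_density > 0, target_density < 1,
            gc_bias > 0, gc_bias < 1)
  structure(list(n_circ = as.integer(n_circ), n_mi = as.integer(n_mi),
                 circ_len_range = as.integer(circ_len_range),
                 mi_len_range = as.integer(mi_len_range),
                 seed_region = as.integer(seed_region),
                 planting_prob = planting_prob, label_noise = label_noise,
                 target_density = target_density, gc_bias = gc_bias),
            class = "cmi_synth_config")
}

random_rna <- function(n, len_range, gc_bias) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  p <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2, G = gc_bias / 2,
         U = (1 - gc_bias) / 2)
  vapply(lens, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

#' Reverse complement of an RNA string
#' @param x RNA string over ACGU.
#' @return reverse-complemented string.
#' @export
reverse_complement_rna <- function(x) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1]]), collapse = "")
}

#' Generate a synthetic CMI benchmark dataset
#'
#' Draws random miRNA and circRNA sequences, selects positive cells at the
#' target density, embeds the reverse complement of each positive miRNA's seed
#' into the partner circRNA (with probability `planting_prob`), then flips
#' designated positive labels with probability `label_noise`. Fully
#' reproducible for a fixed `seed`.
#'
#' @param config a [synthetic_config()].
#' @param seed integer RNG seed.
#' @return a list of class `cmi_dataset` with elements `circ` and `mi`
#'   (record data.frames), `pairs` (positive pair table, `label = 1`), `truth`
#'   (data.frame of designated cells with a `planted` flag) and `config`.
#' @export
generate_cmi_dataset <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "cmi_synth_config"))
  set.seed(seed)
  n_pos <- round(config$target_density * config$n_circ * config$n_mi)
  if (n_pos < 1L) stop("target_density too low: no positive cells")
  if (n_pos >= config$n_circ * config$n_mi)
    stop("target_density infeasible for the matrix size")

  mi_seq <- random_rna(config$n_mi, config$mi_len_range, config$gc_bias)
  circ_seq <- random_rna(config$n_circ, config$circ_len_range, config$gc_bias)
  circ_id <- sprintf("circ_%04d", seq_len(config$n_circ))
  mi_id <- sprintf("mir_%03d", seq_len(config$n_mi))

  cells <- sample.int(config$n_circ * config$n_mi, n_pos)
  ci <- ((cells - 1L) %% config$n_circ) + 1L
  mj <- ((cells - 1L) %/% config$n_circ) + 1L

  planted <- runif(n_pos) <= config$planting_prob
  # Motifs planted into the same circRNA occupy disjoint windows so that one
  # positive's motif never clobbers another's.
  occupied <- vector("list", config$n_circ)
  for (t in which(planted)) {
    seed_rc <- reverse_complement_rna(
      substr(mi_seq[mj[t]], min(config$seed_region), max(config$seed_region)))
    s <- circ_seq[ci[t]]
    w <- nchar(seed_rc)
    taken <- occupied[[ci[t]]]
    pos <- NA_integer_
    for (try in seq_len(200L)) {
      cand <- sample.int(nchar(s) - w + 1L, 1L)
      if (!length(taken) ||
          all(cand + w - 1L < taken[, 1L] | cand > taken[, 2L])) {
        pos <- cand
        break
      }
    }
    if (is.na(pos))
      stop("cannot place motif for ", circ_id[ci[t]],
           ": sequence too short for its positive pairs")
    substr(s, pos, pos + w - 1L) <- seed_rc
    circ_seq[ci[t]] <- s
    occupied[[ci[t]]] <- rbind(taken, c(pos, pos + w - 1L))
  }

  flipped <- runif(n_pos) < config$label_noise
  truth <- data.frame(circ_id = circ_id[ci], mi_id = mi_id[mj],
                      planted = planted, label = as.integer(!flipped),
                      stringsAsFactors = FALSE)
  pairs <- truth[truth$label == 1L, c("circ_id", "mi_id"), drop = FALSE]
  pairs$label <- 1L
  rownames(pairs) <- NULL
  attr(pairs, "provenance") <- "synthetic"

  structure(list(
    circ = data.frame(id = circ_id, molecule_class = "circRNA",
                      sequence = circ_seq, stringsAsFactors = FALSE),
    mi = data.frame(id = mi_id, molecule_class = "miRNA",
                    sequence = mi_seq, stringsAsFactors = FALSE),
    pairs = pairs, truth = truth, config = config, seed = seed),
    class = "cmi_dataset")
}

#' Rule-based motif oracle
#'
#' For each requested (circRNA, miRNA) pair, checks whether the circRNA
#' contains the reverse complement of the miRNA seed region — the generative
#' interaction rule itself, independent of labels. Chance motif occurrences
#' therefore also return `TRUE`; the oracle bounds attainable pipeline
#' performance from above.
#'
#' @param dataset a `cmi_dataset`.
#' @param pairs data.frame with `circ_id`, `mi_id`; defaults to every cell of
#'   the matrix.
#' @return logical vector, one entry per pair.
#' @export
motif_oracle <- function(dataset, pairs = NULL) {
  stopifnot(inherits(dataset, "cmi_dataset"))
  sr <- dataset$config$seed_region
  if (is.null(pairs)) {
    pairs <- expand.grid(circ_id = dataset$circ$id, mi_id = dataset$mi$id,
                         stringsAsFactors = FALSE)
  }
  seeds_rc <- vapply(dataset$mi$sequence, function(s)
    reverse_complement_rna(substr(s, min(sr), max(sr))), character(1))
  names(seeds_rc) <- dataset$mi$id
  circ_seq <- dataset$circ$sequence
  names(circ_seq) <- dataset$circ$id
  mapply(function(cid, mid) grepl(seeds_rc[[mid]], circ_seq[[cid]], fixed = TRUE),
         pairs$circ_id, pairs$mi_id, USE.NAMES = FALSE)
}

#' Write a synthetic dataset as FASTA + TSV files
#'
#' Emits exactly the formats the ingestion functions consume: two FASTA files,
#' a positive pair table, and the ground-truth rule table, alongside a
#' plain-text copy of the generator configuration and seed.
#'
#' @param dataset a `cmi_dataset`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cmi_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cmi_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_rna_fasta(dataset$circ, file.path(dir, "circRNA.fasta"))
  write_rna_fasta(dataset$mi, file.path(dir, "miRNA.fasta"))
  write.table(dataset$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  writeLines(c(
    paste0("seed = ", dataset$seed),
    paste0(names(cfg), " = ",
           vapply(cfg, function(x) paste(x, collapse = ","), character(1)))),
    file.path(dir, "config.txt"))
  invisible(dir)
}
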