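#' Read RNA records from a FASTA file
#'
#' Loads circRNA or miRNA sequences and normalizes them to the RNA alphabet:
#' sequences are upper-cased and `T` is mapped to `U`, so both DNA-alphabet and
#' RNA-alphabet FASTA files are accepted (public circRNA sequence dumps are
#' frequently DNA-alphabet). Records containing ambiguity codes (`N`, `R`, ...)
#' are handled according to `ambiguity`:
#' \describe{
#'   \item{`"drop"`}{the record is removed with a warning (default);}
#'   \item{`"random"`}{each ambiguous base is replaced by a canonical base
#'     drawn uniformly under the session RNG.}
#' }
#'
#' @param path path to a FASTA file.
#' @param molecule_class `"circRNA"` or `"miRNA"`; stored on every record.
#' @param ambiguity policy for non-ACGU characters after normalization.
#' @return a data.frame with columns `id`, `molecule_class`, `sequence`
#'   (one row per retained record).
#' @export
read_rna_fasta <- function(path, molecule_class = c("circRNA", "miRNA"),
                           ambiguity = c("drop", "random")) {
  molecule_class <- match.arg(molecule_class)
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  sq <- toupper(as.character(seqs))
  sq <- chartr("T", "U", sq)
  has_ambig <- grepl("[^ACGU]", sq)
  if (any(has_ambig)) {
    if (ambiguity == "drop") {
      warning(sum(has_ambig), " record(s) with ambiguous bases dropped: ",
              paste(head(ids[has_ambig], 5L), collapse = ", "))
      sq <- sq[!has_ambig]
      ids <- ids[!has_ambig]
    } else {
      sq[has_ambig] <- vapply(sq[has_ambig], function(s) {
        ch <- strsplit(s, "")[[1]]
        bad <- !(ch %in% c("A", "C", "G", "U"))
        ch[bad] <- sample(c("A", "C", "G", "U"), sum(bad), replace = TRUE)
        paste(ch, collapse = "")
      }, character(1))
    }
  }
  if (length(ids) == 0L) stop("no valid records left in ", path)
  data.frame(id = unname(ids), molecule_class = molecule_class,
             sequence = unname(sq), stringsAsFactors = FALSE)
}

#' Read an interaction pair table
#'
#' Reads a TSV or CSV table with columns (circRNA id, miRNA id) and an optional
#' third 0/1 label column; when the label column is absent all pairs are taken
#' as positives. The delimiter is sniffed from the first line. Duplicate
#' (circ, mi) rows are removed, keeping the first occurrence.
#'
#' @param path path to the delimited file.
#' @param provenance tag stored with the table (`"observed"`,
#'   `"sampled-negative"` or `"synthetic"`).
#' @return a data.frame with columns `circ_id`, `mi_id`, `label` and attribute
#'   `provenance`.
#' @export
read_pair_table <- function(path, provenance = "observed") {
  if (!file.exists(path)) stop("pair table not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("pair table is empty: ", path)
  delim <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else
    stop("cannot resolve column layout in line 1 of ", path,
         " (no tab or comma delimiter found)")
  has_header <- grepl("circ_id|mi_id|\\blabel\\b", first, ignore.case = TRUE)
  tab <- read.table(path, sep = delim, header = has_header,
                    stringsAsFactors = FALSE, comment.char = "")
  if (nrow(tab) == 0L) stop("pair table has no data rows: ", path)
  if (ncol(tab) < 2L) stop("pair table needs >= 2 columns, found ", ncol(tab))
  out <- data.frame(circ_id = as.character(tab[[1]]),
                    mi_id = as.character(tab[[2]]),
                    stringsAsFactors = FALSE)
  out$label <- if (ncol(tab) >= 3L) as.integer(tab[[3]]) else 1L
  if (any(!out$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  ndup <- sum(duplicated(out[, c("circ_id", "mi_id")]))
  out <- out[!duplicated(out[, c("circ_id", "mi_id")]), , drop = FALSE]
  rownames(out) <- NULL
  message("read ", nrow(out), " unique pair(s) from ", path,
          if (ndup) paste0(" (", ndup, " duplicate row(s) removed)") else "")
  attr(out, "provenance") <- provenance
  out
}

#' Build the binary association matrix
#'
#' Assembles the circRNA x miRNA association matrix A with `A[i, j] = 1` when
#' circRNA i is a known interactor of miRNA j and 0 otherwise. Rows follow the
#' order of `records_circ`, columns the order of `records_mi`.
#'
#' @param records_circ,records_mi record data.frames from [read_rna_fasta()].
#' @param pairs pair data.frame from [read_pair_table()]; only rows with
#'   `label == 1` become matrix entries.
#' @return integer matrix with `dimnames` set to the record ids.
#' @export
build_association_matrix <- function(records_circ, records_mi, pairs) {
  stopifnot(!anyDuplicated(records_circ$id), !anyDuplicated(records_mi$id))
  A <- matrix(0L, nrow(records_circ), nrow(records_mi),
              dimnames = list(records_circ$id, records_mi$id))
  pos <- pairs[pairs$label == 1L, , drop = FALSE]
  if (nrow(pos)) {
    i <- match(pos$circ_id, records_circ$id)
    j <- match(pos$mi_id, records_mi$id)
    if (anyNA(i)) stop("unknown circRNA id(s): ",
                       paste(unique(pos$circ_id[is.na(i)]), collapse = ", "))
    if (anyNA(j)) stop("unknown miRNA id(s): ",
                       paste(unique(pos$mi_id[is.na(j)]), collapse = ", "))
    A[cbind(i, j)] <- 1L
  }
  A
}

#' Write a ranked prediction table
#'
#' Writes (circ_id, mi_id, score) rows sorted by descending score as
#' tab-separated text with a header. The file round-trips through
#' [read_prediction_table()].
#'
#' @param pairs data.frame with columns `circ_id`, `mi_id`.
#' @param scores numeric vector in `[0, 1]`, one per pair.
#' @param path output path.
#' @return the output path, invisibly.
#' @export
write_prediction_table <- function(pairs, scores, path) {
  stopifnot(length(scores) == nrow(pairs))
  out <- data.frame(circ_id = pairs$circ_id, mi_id = pairs$mi_id,
                    score = as.numeric(scores), stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prediction table written by [write_prediction_table()]
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `circ_id`, `mi_id`, `score`.
#' @export
read_prediction_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric"))
  tab
}

#' Write RNA records to a FASTA file
#'
#' @param records record data.frame (`id`, `sequence` columns).
#' @param path output path.
#' @return the output path, invisibly.
#' @export
write_rna_fasta <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", records$id, "\n", records$sequence), con)
  invisible(path)
}
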