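#' Sequence record sets
#'
#' Reads and reference sequences are carried as plain data frames of class
#' `"seq_set"` with columns `id`, `seq` and `qual` (`qual` is the raw
#' Phred+33 quality string, or `NA` when absent, e.g. for FASTA input).
#' The internal alphabet is DNA (`A`,`C`,`G`,`T`,`N`); RNA input is
#' converted `U -> T` on ingest when `rna = TRUE` and the conversion is
#' recorded in the `"rna_input"` attribute.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param seq character vector of non-empty nucleotide sequences.
#' @param qual optional character vector of Phred+33 quality strings, one
#'   character per base.
#' @param rna if `TRUE`, accept `U` and convert it to `T`.
#' @return A `seq_set` data frame.
#' @examples
#' seq_set(c("a", "b"), c("ACGT", "TTGA"))
#' @export
seq_set <- function(id, seq, qual = NULL, rna = FALSE) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq))
    stop("id and seq must have equal length")
  if (any(!nzchar(id)) || anyNA(id)) stop("ids must be non-empty")
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1L]
    stop("duplicate sequence id: ", dup)
  }
  had_u <- any(grepl("U", seq, fixed = TRUE))
  if (had_u) {
    if (!rna)
      stop("sequences contain U; pass rna = TRUE to convert U -> T")
    seq <- chartr("U", "T", seq)
  }
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("non-IUPAC characters in sequence for id: ", id[bad][1L])
  if (any(!nzchar(seq))) stop("empty sequence for id: ", id[!nzchar(seq)][1L])
  if (is.null(qual)) {
    qual <- rep(NA_character_, length(seq))
  } else {
    qual <- as.character(qual)
    ok <- is.na(qual) | nchar(qual) == nchar(seq)
    if (!all(ok))
      stop("quality length differs from sequence length for id: ",
           id[!ok][1L])
  }
  out <- data.frame(id = id, seq = seq, qual = qual,
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_set", "data.frame")
  attr(out, "rna_input") <- had_u
  out
}

#' Read a FASTA file
#'
#' Multi-line sequences are concatenated and case is normalised to upper;
#' soft-masking is ignored. Parsing is delegated to
#' [Biostrings::readBStringSet()] after a light syntax check so that a
#' malformed header is reported with its line number.
#'
#' @param path path to a FASTA file.
#' @inheritParams seq_set
#' @return A [seq_set] (no qualities). An empty file yields an empty set
#'   with a warning.
#' @export
read_fasta <- function(path, rna = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    warning("empty FASTA file: ", path)
    return(seq_set(character(), character()))
  }
  first <- nonempty[1L]
  if (!startsWith(lines[first], ">"))
    stop("malformed FASTA header at line ", first, " of ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seq_set(ids, as.character(set), rna = rna)
}

#' Write a FASTA file
#'
#' @param records a [seq_set] (or data frame with `id` and `seq`).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  x <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a 4-line-record FASTQ file (Phred+33)
#'
#' The strict 4-line layout is assumed (no wrapped records). Records whose
#' quality string length differs from the sequence length, and truncated
#' trailing records, are reported by read id.
#'
#' @inheritParams read_fasta
#' @return A [seq_set] with `qual` populated.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L) {
    warning("empty FASTQ file: ", path)
    return(seq_set(character(), character(), character()))
  }
  n <- length(lines)
  heads <- lines[seq(1L, n, by = 4L)]
  if (!all(startsWith(heads, "@")))
    stop("malformed FASTQ record header in ", path)
  if (n %% 4L != 0L) {
    id <- sub("\\s.*$", "", sub("^@", "", heads[length(heads)]))
    stop("truncated FASTQ record for read ", id, " in ", path)
  }
  ids <- sub("\\s.*$", "", sub("^@", "", heads))
  seqs <- lines[seq(2L, n, by = 4L)]
  quals <- lines[seq(4L, n, by = 4L)]
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad))
    stop("sequence/quality length mismatch for read ", ids[bad][1L],
         " in ", path)
  seq_set(ids, seqs, quals)
}

#' Write a 4-line-record FASTQ file (Phred+33)
#'
#' Records without qualities are written with constant quality `I`
#' (Phred 40).
#'
#' @inheritParams write_fasta
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  qual <- records$qual
  miss <- is.na(qual)
  if (any(miss))
    qual[miss] <- vapply(nchar(records$seq[miss]),
                         function(n) strrep("I", n), character(1))
  out <- character(4L * nrow(records))
  out[seq(1L, length(out), by = 4L)] <- paste0("@", records$id)
  out[seq(2L, length(out), by = 4L)] <- records$seq
  out[seq(3L, length(out), by = 4L)] <- "+"
  out[seq(4L, length(out), by = 4L)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qual a quality string, e.g. `"III"`.
#' @return Integer vector of Phred scores.
#' @examples
#' phred_scores("I!") # 40, 0
#' @export
phred_scores <- function(qual) {
  as.integer(charToRaw(qual)) - 33L
}

#' Reverse-complement nucleotide sequences
#'
#' Length-preserving involution over the DNA alphabet. With `rna = TRUE`,
#' `U` is accepted on input (complement partner of `A`) and the result is
#' returned in RNA alphabet.
#'
#' @param x character vector of sequences.
#' @param rna treat sequences as RNA.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("GATC") # palindrome
#' @export
reverse_complement <- function(x, rna = FALSE) {
  x <- toupper(x)
  if (rna) x <- chartr("U", "T", x)
  if (any(grepl("[^ACGTN]", x)))
    stop("non-IUPAC character in sequence")
  out <- as.character(cpp_revcomp(x))
  if (rna) out <- chartr("T", "U", out)
  out
}

#' Write / read a TSV table
#'
#' Tab-separated, header first, UTF-8, newline-terminated; the package's
#' uniform plain-text table format (junction calls, count tables, Ct
#' tables).
#'
#' @param rows a data frame.
#' @param path output path.
#' @return `path` (write) or a data frame (read).
#' @export
write_table_tsv <- function(rows, path) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Reference sequence sets with roles
#'
#' Bundles named references tagged with the role each plays in the
#' pipeline: `host` (genome contigs), `virus` (lentiviral vector) and
#' `target_transcript` (small-RNA target). Roles must not share sequence
#' names.
#'
#' @param host,virus,target_transcript named character vectors of
#'   sequences (or `seq_set`s); any role may be omitted where a stage does
#'   not need it.
#' @return A list of class `"reference_set"`.
#' @export
reference_set <- function(host = NULL, virus = NULL,
                          target_transcript = NULL) {
  norm <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "seq_set") || is.data.frame(x))
      x <- setNames(x$seq, x$id)
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("reference sequences must be named")
    toupper(x)
  }
  out <- list(host = norm(host), virus = norm(virus),
              target_transcript = norm(target_transcript))
  nm <- unlist(lapply(out, names), use.names = FALSE)
  if (anyDuplicated(nm))
    stop("reference names must be disjoint across roles: ",
         nm[duplicated(nm)][1L])
  structure(out, class = "reference_set")
}
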