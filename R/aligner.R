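#' Aligner parameters
#'
#' Defaults used by every alignment decision in the pipeline. The seed
#' length `k = 10` guarantees, by the pigeonhole principle, that every
#' ungapped placement with span >= `min_span` and mismatch rate <=
#' `max_mismatch_rate = 0.05` contains at least one exact 10-mer, so the
#' seeded search provably finds the same hit set as an exhaustive
#' per-diagonal scan (see the methods vignette).
#'
#' @param k seed length in nt (1-31).
#' @param max_mismatch_rate maximum mismatches per aligned base.
#' @param min_span minimum aligned span in nt.
#' @param end_to_end_fraction fraction of the read a hit must cover for
#'   [maps_end_to_end()].
#' @return A list of class `"aligner_params"`.
#' @export
aligner_params <- function(k = 10L, max_mismatch_rate = 0.05,
                           min_span = 15L, end_to_end_fraction = 0.95) {
  stopifnot(k >= 1, k <= 31, max_mismatch_rate >= 0,
            max_mismatch_rate < 1, min_span >= k,
            end_to_end_fraction > 0, end_to_end_fraction <= 1)
  structure(list(k = as.integer(k),
                 max_mismatch_rate = max_mismatch_rate,
                 min_span = as.integer(min_span),
                 end_to_end_fraction = end_to_end_fraction),
            class = "aligner_params")
}

#' Build a k-mer index over one or more reference sequences
#'
#' Indexes every forward-strand k-mer position of each reference (k-mers
#' containing non-ACGT bases are skipped); the reverse strand is handled
#' at query time by aligning the read's reverse complement.
#'
#' @param reference a named character vector of sequences, a [seq_set],
#'   or a single unnamed sequence (named `"ref"`).
#' @param k seed length; must not exceed any reference length.
#' @return An object of class `"kmer_index"`.
#' @examples
#' idx <- build_index(c(chr = "ACGTACGTAA"), k = 4)
#' kmer_positions(idx, "ACGT")
#' @export
build_index <- function(reference, k = aligner_params()$k) {
  if (inherits(reference, "seq_set") || is.data.frame(reference))
    reference <- setNames(reference$seq, reference$id)
  reference <- toupper(reference)
  if (is.null(names(reference))) {
    if (length(reference) == 1L) names(reference) <- "ref"
    else stop("multiple references must be named")
  }
  if (any(nchar(reference) < k))
    stop("k exceeds reference length for: ",
         names(reference)[nchar(reference) < k][1L])
  ptrs <- lapply(unname(reference), cpp_build_index, k = as.integer(k))
  structure(list(ref_ids = names(reference), k = as.integer(k),
                 lengths = unname(nchar(reference)), ptrs = ptrs),
            class = "kmer_index")
}

#' Look up the occurrence positions of a k-mer
#'
#' @param index a [build_index()] object.
#' @param kmer a k-mer (length must equal the index `k`).
#' @param ref_id restrict to one reference (default: all).
#' @return Named list of 0-based position vectors; k-mers absent from the
#'   reference give `integer(0)`.
#' @export
kmer_positions <- function(index, kmer, ref_id = NULL) {
  ids <- index$ref_ids
  keep <- if (is.null(ref_id)) seq_along(ids) else match(ref_id, ids)
  if (anyNA(keep)) stop("unknown ref_id")
  out <- lapply(keep, function(i)
    cpp_index_positions(index$ptrs[[i]], toupper(kmer)))
  setNames(out, ids[keep])
}

#' Count of stored k-mer positions in an index
#' @inheritParams kmer_positions
#' @return Numeric count, summed over references.
#' @export
index_size <- function(index) {
  sum(vapply(index$ptrs, cpp_index_n_positions, numeric(1)))
}

#' Align reads to an indexed reference (ungapped, both strands)
#'
#' A hit is the full overlap of the (possibly reverse-complemented) read
#' with the reference on one diagonal, retained iff its span is at least
#' `min_span` and its mismatch count is at most
#' `max_mismatch_rate * span`. Coordinates are 0-based half-open;
#' minus-strand hits report read coordinates on the reverse-complemented
#' read. Hits are sorted by identity, then span, then
#' (ref_id, ref_start, strand), so output is deterministic.
#'
#' @param reads character vector of read sequences, or a [seq_set].
#' @param index a [build_index()] object.
#' @param params an [aligner_params()] list.
#' @return Data frame with columns `read_id`, `ref_id`, `strand`,
#'   `ref_start`, `ref_end`, `read_start`, `read_end`, `mismatches`,
#'   `identity`.
#' @export
align_reads <- function(reads, index, params = aligner_params()) {
  ids <- NULL
  if (inherits(reads, "seq_set") || is.data.frame(reads)) {
    ids <- reads$id
    reads <- reads$seq
  }
  if (is.null(ids)) ids <- as.character(seq_along(reads))
  parts <- lapply(seq_along(index$ref_ids), function(i) {
    df <- cpp_align_batch(reads, index$ptrs[[i]],
                          params$max_mismatch_rate, params$min_span)
    if (nrow(df)) df$ref_id <- index$ref_ids[i]
    df
  })
  out <- do.call(rbind, parts[vapply(parts, nrow, 1L) > 0])
  if (is.null(out))
    return(data.frame(read_id = character(), ref_id = character(),
                      strand = character(), ref_start = integer(),
                      ref_end = integer(), read_start = integer(),
                      read_end = integer(), mismatches = integer(),
                      identity = numeric(), stringsAsFactors = FALSE))
  span <- out$ref_end - out$ref_start
  ord <- order(out$read, -out$identity, -span, out$ref_id, out$ref_start,
               out$strand)
  out <- out[ord, ]
  data.frame(read_id = ids[out$read], ref_id = out$ref_id,
             strand = out$strand, ref_start = out$ref_start,
             ref_end = out$ref_end, read_start = out$read_start,
             read_end = out$read_end, mismatches = out$mismatches,
             identity = out$identity, stringsAsFactors = FALSE,
             row.names = NULL)
}

# Best hit per read and per reference role; one row per read, NA when no
# hit. Used by the split-read classifier (vectorised over sub-reads).
best_hits <- function(reads, index, params = aligner_params()) {
  best <- NULL
  for (i in seq_along(index$ref_ids)) {
    df <- cpp_best_hits(reads, index$ptrs[[i]],
                        params$max_mismatch_rate, params$min_span)
    df$ref_id <- index$ref_ids[i]
    if (is.null(best)) {
      best <- df
    } else {
      span_new <- df$ref_end - df$ref_start
      span_old <- best$ref_end - best$ref_start
      better <- df$hit & (!best$hit |
        df$identity > best$identity + 1e-12 |
        (abs(df$identity - best$identity) <= 1e-12 &
           !is.na(span_new) & !is.na(span_old) & span_new > span_old))
      better[is.na(better)] <- FALSE
      best[better, ] <- df[better, ]
    }
  }
  best
}

#' Does a read align end-to-end to a reference?
#'
#' `TRUE` iff some hit covers at least `end_to_end_fraction` of the read
#' (default 0.95) within the mismatch tolerance. This is the
#' "aligned to the combined genome" screen used to discard non-chimeric
#' reads before split-read analysis.
#'
#' @inheritParams align_reads
#' @return Logical vector, one element per read.
#' @export
maps_end_to_end <- function(reads, index, params = aligner_params()) {
  if (inherits(reads, "seq_set") || is.data.frame(reads))
    reads <- reads$seq
  out <- rep(FALSE, length(reads))
  for (i in seq_along(index$ref_ids)) {
    todo <- which(!out)
    if (!length(todo)) break
    out[todo] <- cpp_maps_end_to_end(reads[todo], index$ptrs[[i]],
                                     params$max_mismatch_rate,
                                     params$min_span,
                                     params$end_to_end_fraction)
  }
  out
}

#' Dump alignment hits as a TSV mirroring SAM's coordinate fields
#'
#' @param hits output of [align_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  write_table_tsv(hits[, c("read_id", "ref_id", "strand", "ref_start",
                           "ref_end", "read_start", "read_end",
                           "mismatches")], path)
}
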