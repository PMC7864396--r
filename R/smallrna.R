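#' Secondary-siRNA classifier parameters
#'
#' In *N. brasiliensis*, RdRP-derived secondary siRNAs are predominantly
#' 23 nt long and start with a 5' G (the "22G-RNA" class of *C. elegans*,
#' shifted by one nucleotide), hence the defaults.
#'
#' @param required_length read length accepted by the classifier (nt).
#' @param required_first_base required 5' base.
#' @param min_retained_length reads shorter than this are discarded after
#'   trimming (boundary retained).
#' @param antisense_only count only antisense (minus-strand) hits on the
#'   target; by default either strand counts.
#' @param aligner [aligner_params()] used for target mapping; the
#'   end-to-end fraction governs how much of the short read must align.
#' @return A list of class `"classifier_params"`.
#' @export
classifier_params <- function(required_length = 23L,
                              required_first_base = "G",
                              min_retained_length = 15L,
                              antisense_only = FALSE,
                              aligner = aligner_params()) {
  stopifnot(required_length >= min_retained_length,
            nchar(required_first_base) == 1L)
  structure(list(required_length = as.integer(required_length),
                 required_first_base = toupper(required_first_base),
                 min_retained_length = as.integer(min_retained_length),
                 antisense_only = isTRUE(antisense_only),
                 aligner = aligner),
            class = "classifier_params")
}

#' Trim a 3' sequencing adapter from reads
#'
#' Each read is truncated at the leftmost position where a prefix of the
#' adapter (length >= `min_overlap`, or shorter if it covers the full
#' adapter) matches with at most 1 mismatch per 10 nt of overlap;
#' qualities are truncated identically. Reads without a match are
#' returned unchanged; a read that *is* the adapter becomes empty (and is
#' then removed by the length filter).
#'
#' @param reads a [seq_set].
#' @param adapter the 3' adapter sequence (non-empty).
#' @param min_overlap minimum confirmed overlap (>= 5).
#' @return The trimmed [seq_set] (rows preserved; sequences may be
#'   empty).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L) {
  stopifnot(nzchar(adapter), min_overlap >= 5L)
  cut <- cpp_trim_positions(reads$seq, toupper(adapter),
                            as.integer(min_overlap))
  out <- reads
  out$seq <- substr(reads$seq, 1L, cut)
  has_q <- !is.na(reads$qual)
  out$qual[has_q] <- substr(reads$qual[has_q], 1L, cut[has_q])
  out
}

#' Discard reads shorter than a minimum length
#'
#' The boundary is retained: with the default threshold of 15 nt, a
#' 15-nt read survives and a 14-nt read is discarded.
#'
#' @param reads a [seq_set].
#' @param min_retained_length minimum length kept.
#' @return The filtered [seq_set].
#' @export
filter_length <- function(reads, min_retained_length = 15L) {
  reads[nchar(reads$seq) >= min_retained_length, , drop = FALSE]
}

#' Classify reads as target-specific secondary siRNAs
#'
#' A (trimmed, length-filtered) read is a target-specific secondary
#' siRNA iff its length equals `required_length` (23 nt), its first base
#' is `required_first_base` (G) and it aligns end-to-end (per the aligner
#' parameters) to the target transcript -- on either strand by default,
#' antisense only when `antisense_only` is set.
#'
#' @param reads a [seq_set] or character vector of read sequences.
#' @param target_index a [build_index()] over the target transcript.
#' @param params a [classifier_params()] list.
#' @return Logical vector, one element per read.
#' @export
classify_secondary_sirna <- function(reads, target_index,
                                     params = classifier_params()) {
  if (inherits(reads, "seq_set") || is.data.frame(reads))
    reads <- reads$seq
  out <- rep(FALSE, length(reads))
  gate <- nchar(reads) == params$required_length &
    substr(reads, 1L, 1L) == params$required_first_base
  idx <- which(gate)
  if (!length(idx)) return(out)
  ap <- params$aligner
  if (params$antisense_only) {
    hits <- align_reads(reads[idx], target_index, ap)
    span <- hits$read_end - hits$read_start
    ok_ids <- unique(hits$read_id[hits$strand == "-" &
      span >= ap$end_to_end_fraction * params$required_length - 1e-9])
    out[idx[as.integer(ok_ids)]] <- TRUE
  } else {
    out[idx] <- maps_end_to_end(reads[idx], target_index, ap)
  }
  out
}

#' Reads-per-million normalisation
#'
#' @param target_count reads classified as target-specific secondary
#'   siRNAs.
#' @param total_reads library size used as denominator (> 0): all reads
#'   surviving adapter trimming and the length filter.
#' @return `1e6 * target_count / total_reads`.
#' @examples
#' quantify_rpm(10, 1e6) # 10 rpm
#' @export
quantify_rpm <- function(target_count, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  1e6 * target_count / total_reads
}

#' Run the full small-RNA pipeline on one library
#'
#' trim -> length filter -> classify -> normalise. The rpm denominator is
#' the number of reads surviving trimming and the >= 15 nt filter (the
#' "total small RNAs" of the library); this convention is recorded in the
#' output.
#'
#' @param reads a raw [seq_set] as sequenced.
#' @param target_index a [build_index()] over the target transcript.
#' @param adapter the 3' adapter sequence.
#' @param params a [classifier_params()] list.
#' @param library_id label carried into the output.
#' @return A list of class `"smallrna_counts"`: `library_id`,
#'   `total_reads`, `target_22g_count`, `rpm`, `denominator`.
#' @export
process_smallrna_library <- function(reads, target_index, adapter,
                                     params = classifier_params(),
                                     library_id = "library") {
  trimmed <- trim_adapter(reads, adapter)
  kept <- filter_length(trimmed, params$min_retained_length)
  total <- nrow(kept)
  n22g <- sum(classify_secondary_sirna(kept, target_index, params))
  structure(list(library_id = library_id, total_reads = total,
                 target_22g_count = n22g,
                 rpm = quantify_rpm(n22g, total),
                 denominator = "reads surviving trim and length filter"),
            class = "smallrna_counts")
}

#' @export
print.smallrna_counts <- function(x, ...) {
  cat(sprintf("%s: %d / %d reads classified target-specific (%.2f rpm)\n",
              x$library_id, x$target_22g_count, x$total_reads, x$rpm))
  invisible(x)
}

#' Treatment/control fold change of rpm-normalised counts
#'
#' @param treatment,control `smallrna_counts` objects (or lists with an
#'   `rpm` field).
#' @param pseudocount added to both rpm values before the ratio
#'   (default 0; required when the control rpm is zero).
#' @return `(treatment$rpm + pseudocount) / (control$rpm + pseudocount)`.
#' @export
fold_change <- function(treatment, control, pseudocount = 0) {
  if (control$rpm + pseudocount == 0)
    stop("control rpm is zero; supply a positive pseudocount")
  (treatment$rpm + pseudocount) / (control$rpm + pseudocount)
}

#' Write per-library small-RNA counts as TSV
#'
#' @param counts a list of `smallrna_counts` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_smallrna_tsv <- function(counts, path) {
  df <- do.call(rbind, lapply(counts, function(x)
    data.frame(library_id = x$library_id, total_reads = x$total_reads,
               target_22g_count = x$target_22g_count, rpm = x$rpm,
               denominator = x$denominator, stringsAsFactors = FALSE)))
  write_table_tsv(df, path)
}
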