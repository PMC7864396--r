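#' Parameters for split-read integration detection
#'
#' @param aligner an [aligner_params()] list shared by every alignment
#'   decision.
#' @param min_subread minimum length of each sub-read flank at a split
#'   point (nt). Junctions closer than this to a read end cannot be
#'   called; the synthetic truth sets label such reads so the expected
#'   misses are quantifiable.
#' @param margin assignment margin in mismatch equivalents: a sub-read is
#'   attributed to one reference only when its best hit there beats the
#'   best hit to the other reference by at least this many mismatches
#'   (unaligned bases of the shorter hit count as mismatches). Prevents
#'   cross-assignment in homologous stretches.
#' @return A list of class `"integration_params"`.
#' @export
integration_params <- function(aligner = aligner_params(),
                               min_subread = 15L, margin = 2) {
  stopifnot(min_subread >= aligner$k)
  structure(list(aligner = aligner, min_subread = as.integer(min_subread),
                 margin = margin),
            class = "integration_params")
}

#' Select candidate split reads
#'
#' Returns exactly the reads that fail the end-to-end screen against
#' *both* the host and the virus reference ("reads that did not align to
#' the combined genome"): reads wholly from either source are discarded,
#' chimeric junction-spanning reads survive.
#'
#' @param reads a [seq_set] (or data frame with `id`, `seq`).
#' @param host_index,virus_index [build_index()] objects.
#' @param params an [integration_params()] list.
#' @return The subset of `reads` that are split-read candidates.
#' @export
select_candidate_reads <- function(reads, host_index, virus_index,
                                   params = integration_params()) {
  if (nrow(reads) == 0L) return(reads)
  ap <- params$aligner
  keep <- !maps_end_to_end(reads, host_index, ap) &
          !maps_end_to_end(reads, virus_index, ap)
  reads[keep, , drop = FALSE]
}

#' Enumerate prefix/suffix sub-read pairs of a read
#'
#' Every bipartition at a split point `s` with
#' `min_subread <= s <= len - min_subread`, ordered by `s` ascending.
#' A single breakpoint per read is assumed.
#'
#' @param read a single read sequence.
#' @param min_subread minimum flank length.
#' @return Data frame with columns `split` (the 0-based split point),
#'   `prefix`, `suffix`; zero rows when the read is shorter than
#'   `2 * min_subread`.
#' @export
enumerate_subreads <- function(read, min_subread = 15L) {
  n <- nchar(read)
  if (n < 2L * min_subread)
    return(data.frame(split = integer(), prefix = character(),
                      suffix = character(), stringsAsFactors = FALSE))
  s <- seq.int(min_subread, n - min_subread)
  data.frame(split = s,
             prefix = substr(rep(read, length(s)), 1L, s),
             suffix = substr(rep(read, length(s)), s + 1L, n),
             stringsAsFactors = FALSE)
}

# Assign each sub-read to "host"/"virus"/NA by the mismatch-equivalent
# margin rule. h, v: one-row slices of best_hits() output.
.assign_side <- function(h, v, margin) {
  mm_h <- if (h$hit) h$mismatches else Inf
  mm_v <- if (v$hit) v$mismatches else Inf
  span_h <- if (h$hit) h$ref_end - h$ref_start else 0L
  span_v <- if (v$hit) v$ref_end - v$ref_start else 0L
  ms <- max(span_h, span_v)
  eq_h <- mm_h + (ms - span_h)
  eq_v <- mm_v + (ms - span_v)
  if (is.infinite(eq_h) && is.infinite(eq_v)) return(NA_character_)
  if (eq_v - eq_h >= margin) return("host")
  if (eq_h - eq_v >= margin) return("virus")
  NA_character_
}

# Reference coordinate adjacent to the breakpoint for one segment: the
# segment's inner end in read orientation, mapped through its strand.
# part: "prefix" (breakpoint at the segment's right end on the read) or
# "suffix" (left end). 0-based: the returned value is the first reference
# base after the segment when the inner end is the segment's ref_end.
.junction_coord <- function(hit, part) {
  inner_right <- (part == "prefix") == (hit$strand == "+")
  if (inner_right) hit$ref_end else hit$ref_start
}

#' Classify one candidate read as a split read
#'
#' Tries every bipartition of the read; an event is returned iff some
#' split point yields a prefix/suffix pair in which one side aligns
#' (best, by the margin rule) to the virus and the other to the host.
#' Among qualifying split points the one maximising the summed segment
#' identity wins; ties go to the longer host segment, then the smaller
#' split point. Junction coordinates are the reference positions adjacent
#' to the inner ends of the two segments (0-based half-open).
#'
#' @param read one read sequence (assumed to have passed
#'   [select_candidate_reads()]).
#' @param read_id identifier used in the returned event.
#' @inheritParams select_candidate_reads
#' @return A one-row data frame (event) or `NULL`.
#' @export
classify_split_read <- function(read, host_index, virus_index,
                                params = integration_params(),
                                read_id = "read") {
  sub <- enumerate_subreads(read, params$min_subread)
  if (nrow(sub) == 0L) return(NULL)
  ap <- params$aligner
  ph <- best_hits(sub$prefix, host_index, ap)
  pv <- best_hits(sub$prefix, virus_index, ap)
  sh <- best_hits(sub$suffix, host_index, ap)
  sv <- best_hits(sub$suffix, virus_index, ap)
  best <- NULL
  for (i in seq_len(nrow(sub))) {
    side_p <- .assign_side(ph[i, ], pv[i, ], params$margin)
    side_s <- .assign_side(sh[i, ], sv[i, ], params$margin)
    if (is.na(side_p) || is.na(side_s) || side_p == side_s) next
    host_hit <- if (side_p == "host") ph[i, ] else sh[i, ]
    virus_hit <- if (side_p == "virus") pv[i, ] else sv[i, ]
    host_part <- if (side_p == "host") "prefix" else "suffix"
    virus_part <- if (host_part == "prefix") "suffix" else "prefix"
    score <- host_hit$identity + virus_hit$identity
    host_span <- host_hit$ref_end - host_hit$ref_start
    cand <- list(score = score, host_span = host_span, split = sub$split[i],
                 host_hit = host_hit, virus_hit = virus_hit,
                 host_part = host_part, virus_part = virus_part)
    if (is.null(best) ||
        score > best$score + 1e-12 ||
        (abs(score - best$score) <= 1e-12 &&
         (host_span > best$host_span ||
          (host_span == best$host_span && sub$split[i] < best$split))))
      best <- cand
  }
  if (is.null(best)) return(NULL)
  hh <- best$host_hit; vh <- best$virus_hit
  data.frame(
    read_id = read_id,
    split = best$split,
    host_contig = hh$ref_id,
    host_start = hh$ref_start, host_end = hh$ref_end,
    host_strand = hh$strand, host_identity = hh$identity,
    virus_start = vh$ref_start, virus_end = vh$ref_end,
    virus_strand = vh$strand, virus_identity = vh$identity,
    host_part = best$host_part,
    junction_host_pos = .junction_coord(hh, best$host_part),
    junction_virus_pos = .junction_coord(vh, best$virus_part),
    orientation = if (hh$strand == vh$strand) "same" else "opposite",
    stringsAsFactors = FALSE)
}

.empty_events <- function() {
  data.frame(read_id = character(), split = integer(),
             host_contig = character(), host_start = integer(),
             host_end = integer(), host_strand = character(),
             host_identity = numeric(), virus_start = integer(),
             virus_end = integer(), virus_strand = character(),
             virus_identity = numeric(), host_part = character(),
             junction_host_pos = integer(), junction_virus_pos = integer(),
             orientation = character(), stringsAsFactors = FALSE)
}

#' Detect provirus integration events in a WGS read set
#'
#' Orchestrates the full screen: (1) discard reads mapping end-to-end to
#' host or virus, (2) split the survivors into all prefix/suffix
#' sub-read pairs, (3) call an event for reads with one sub-read aligning
#' to the virus and one to the host. Events are deduplicated per read id
#' and the per-million event rate is computed over all screened reads.
#'
#' @param reads a [seq_set] of WGS reads (read pairs are treated as
#'   independent single reads).
#' @param refs a [reference_set()] with `host` and `virus` roles.
#' @param params an [integration_params()] list.
#' @return A list of class `"integration_calls"`: `events` (data frame,
#'   one row per split read), `total_reads_screened`, `rate_per_million`.
#' @export
detect_integrations <- function(reads, refs,
                                params = integration_params()) {
  if (is.null(refs$virus)) stop("reference_set lacks a virus reference")
  if (is.null(refs$host)) stop("reference_set lacks a host reference")
  host_index <- build_index(refs$host, params$aligner$k)
  virus_index <- build_index(refs$virus, params$aligner$k)
  total <- nrow(reads)
  if (total == 0L) stop("no reads to screen")
  cand <- select_candidate_reads(reads, host_index, virus_index, params)
  events <- .empty_events()
  if (nrow(cand)) {
    evs <- lapply(seq_len(nrow(cand)), function(i)
      classify_split_read(cand$seq[i], host_index, virus_index, params,
                          read_id = cand$id[i]))
    evs <- evs[!vapply(evs, is.null, logical(1))]
    if (length(evs)) events <- do.call(rbind, evs)
  }
  events <- events[!duplicated(events$read_id), , drop = FALSE]
  structure(list(events = events, total_reads_screened = total,
                 rate_per_million = 1e6 * nrow(events) / total),
            class = "integration_calls")
}

#' @export
print.integration_calls <- function(x, ...) {
  cat("Integration call set:", nrow(x$events), "split-read event(s) in",
      x$total_reads_screened, "screened reads\n")
  cat(sprintf("rate per million reads: %.4g\n", x$rate_per_million))
  invisible(x)
}

#' Cluster split-read events into integration loci
#'
#' Optional post-processing: events on the same contig whose host
#' junction coordinates lie within `window` bp of each other are merged
#' into one locus (supporting read count retained). The detection stage
#' itself reports raw per-read events.
#'
#' @param events the `events` data frame of an `integration_calls`.
#' @param window merge window in bp.
#' @return Data frame with `host_contig`, `junction_host_pos` (locus
#'   representative: median), `n_reads`, `read_ids`.
#' @export
cluster_events <- function(events, window = 5L) {
  if (nrow(events) == 0L)
    return(data.frame(host_contig = character(),
                      junction_host_pos = integer(), n_reads = integer(),
                      read_ids = character(), stringsAsFactors = FALSE))
  ord <- order(events$host_contig, events$junction_host_pos)
  ev <- events[ord, ]
  cluster <- cumsum(c(TRUE, ev$host_contig[-1] != ev$host_contig[-nrow(ev)] |
    diff(ev$junction_host_pos) > window))
  out <- lapply(split(seq_len(nrow(ev)), cluster), function(ii)
    data.frame(host_contig = ev$host_contig[ii[1]],
               junction_host_pos =
                 as.integer(stats::median(ev$junction_host_pos[ii])),
               n_reads = length(ii),
               read_ids = paste(ev$read_id[ii], collapse = ","),
               stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Export junction calls as a BED-like TSV
#'
#' Columns: host contig, junction position, position + 1, read id,
#' orientation, virus junction position. Coordinates are 0-based
#' half-open, stated in a comment header.
#'
#' @param calls an `integration_calls` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_junctions_tsv <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based, half-open", con)
  ev <- calls$events
  df <- data.frame(host_contig = ev$host_contig,
                   start = ev$junction_host_pos,
                   end = ev$junction_host_pos + 1L,
                   read_id = ev$read_id,
                   orientation = ev$orientation,
                   virus_pos = ev$junction_virus_pos,
                   stringsAsFactors = FALSE)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Downsampling viral-read enrichment test
#'
#' Repeatedly draws `|control|` reads from the exposed library without
#' replacement, counts reads aligning to the virus in each draw, and
#' compares the control library's viral read count to the resulting
#' distribution. The empirical p-value uses the add-one estimator
#' `(1 + #resamples with count <= control count) / (n_resamples + 1)`,
#' so it is never exactly zero.
#'
#' @param exposed_reads,control_reads [seq_set]s (exposed must be the
#'   larger library).
#' @param virus_index a [build_index()] over the viral reference.
#' @param n_resamples number of downsampling draws (default 100).
#' @param seed RNG seed for the resampling (optional).
#' @param params an [aligner_params()] list.
#' @return A list of class `"enrichment_result"`: `control_viral_count`,
#'   `exposed_viral_count`, `downsampled_counts`, `n_resamples`,
#'   `empirical_p`.
#' @export
viral_read_enrichment_test <- function(exposed_reads, control_reads,
                                       virus_index, n_resamples = 100L,
                                       seed = NULL,
                                       params = aligner_params()) {
  n_exp <- nrow(exposed_reads)
  n_ctl <- nrow(control_reads)
  if (n_ctl > n_exp)
    stop("control library is larger than the exposed library; ",
         "swap the roles (the larger library is downsampled)")
  stopifnot(n_resamples >= 1)
  viral_exp <- maps_end_to_end(exposed_reads, virus_index, params)
  viral_ctl <- maps_end_to_end(control_reads, virus_index, params)
  control_viral_count <- sum(viral_ctl)
  counts <- with_seed(seed,
    vapply(seq_len(n_resamples),
           function(i) sum(viral_exp[sample.int(n_exp, n_ctl)]),
           integer(1)))
  structure(list(control_viral_count = control_viral_count,
                 exposed_viral_count = sum(viral_exp),
                 downsampled_counts = counts,
                 n_resamples = as.integer(n_resamples),
                 empirical_p = (1 + sum(counts <= control_viral_count)) /
                               (n_resamples + 1)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Viral read enrichment (downsampling null):\n")
  cat("  control viral reads:", x$control_viral_count, "\n")
  cat(sprintf("  downsampled exposed counts: median %.1f (n = %d)\n",
              stats::median(x$downsampled_counts), x$n_resamples))
  cat(sprintf("  empirical p = %.4g\n", x$empirical_p))
  invisible(x)
}
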