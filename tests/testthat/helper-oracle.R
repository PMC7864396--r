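# Independent brute-force alignment oracle. Evaluates EVERY diagonal
# placement of the read against the reference on both strands via FFT
# cross-correlation of per-base indicator vectors -- no k-mer seeding, no
# shared code with the package's aligner. Matches only count equal
# A/C/G/T pairs, as in the aligner's contract.
oracle_align <- function(read, ref, max_mismatch_rate = 0.05,
                         min_span = 15L) {
  ref_ch <- strsplit(ref, "", fixed = TRUE)[[1L]]
  L <- length(ref_ch)
  one_strand <- function(s, strand) {
    s_ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    rl <- length(s_ch)
    # cross-correlation via FFT: cc[D mod M] = sum_j read[j] == ref[j + D]
    M <- stats::nextn(L + rl)
    cc <- numeric(M)
    for (b in c("A", "C", "G", "T")) {
      xp <- c(as.numeric(s_ch == b), rep(0, M - rl))
      yp <- c(as.numeric(ref_ch == b), rep(0, M - L))
      cc <- cc + Re(fft(fft(yp) * Conj(fft(xp)), inverse = TRUE)) / M
    }
    cc <- round(cc)
    hits <- list()
    for (D in seq.int(1L - rl, L - 1L)) {
      a <- max(0L, -D)
      b <- min(rl, L - D)
      span <- b - a
      if (span < min_span) next
      mm <- span - cc[(D %% M) + 1L]
      if (mm > max_mismatch_rate * span + 1e-9) next
      hits[[length(hits) + 1L]] <- data.frame(
        strand = strand, ref_start = D + a, ref_end = D + b,
        read_start = a, read_end = b, mismatches = as.integer(mm),
        identity = 1 - mm / span, stringsAsFactors = FALSE)
    }
    hits
  }
  hits <- c(one_strand(read, "+"),
            one_strand(lentinema::reverse_complement(read), "-"))
  if (!length(hits))
    return(data.frame(strand = character(), ref_start = integer(),
                      ref_end = integer(), read_start = integer(),
                      read_end = integer(), mismatches = integer(),
                      identity = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(-out$identity, -(out$ref_end - out$ref_start), out$ref_start,
            out$strand), , drop = FALSE]
}

# random DNA string
rand_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# mutate a sequence at given 1-based positions (substitutions)
mutate_at <- function(seq, pos) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# canonical form of a hits data frame for set comparison
hit_key <- function(df) {
  k <- sprintf("%s:%d-%d:%d-%d:%d", df$strand, df$ref_start, df$ref_end,
               df$read_start, df$read_end, df$mismatches)
  sort(k)
}
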