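#' Simulate a host genome
#'
#' I.i.d. bases at a given GC content; deterministic per seed. Contigs
#' are named `contig_1`, `contig_2`, ...
#'
#' @param n_contigs number of contigs.
#' @param lengths contig lengths in bp (recycled; each >= 1 kb
#'   recommended, >= 10 kb for realistic WGS use).
#' @param gc GC content in (0, 1).
#' @param seed RNG seed.
#' @return A named character vector of contig sequences.
#' @export
simulate_genome <- function(n_contigs = 1L, lengths = 1e5, gc = 0.4,
                            seed = NULL) {
  stopifnot(n_contigs >= 1, gc > 0, gc < 1)
  lengths <- rep_len(lengths, n_contigs)
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(lengths, function(L)
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""),
      character(1))
    setNames(seqs, paste0("contig_", seq_len(n_contigs)))
  })
}

#' Simulate a lentiviral vector stand-in
#'
#' A random sequence (default ~8 kb) labelled `virus` plays the
#' lentiviral vector; LTR structure is not modelled.
#'
#' @param length vector length in bp.
#' @param gc GC content.
#' @param seed RNG seed.
#' @return A length-1 named character vector.
#' @export
simulate_virus <- function(length = 8000L, gc = 0.5, seed = NULL) {
  setNames(simulate_genome(1L, length, gc, seed), "virus")
}

#' Inject provirus copies into a host genome
#'
#' Inserts the full virus sequence at `n_events` uniformly drawn,
#' distinct host positions (forward orientation). Each event contributes
#' two truth junctions -- the 5' and 3' provirus boundaries -- recorded
#' both in original host coordinates (`host_pos`: the first host base
#' after the insertion boundary, 0-based) and in modified-genome
#' coordinates (`mod_pos`, for read labelling).
#'
#' Insertion sites are drawn avoiding single-base microhomology at
#' either boundary (the host base at the insertion point must differ
#' from the first virus base, and the preceding host base from the last
#' virus base): with microhomology the junction coordinate is inherently
#' ambiguous -- several split points give identical alignments -- so the
#' truth set would not define a unique expected coordinate. Real
#' integrations can carry microhomology; calls there are exact only up
#' to the homology interval.
#'
#' @param host named character vector of host contigs.
#' @param virus virus sequence (single string; must be shorter than each
#'   contig).
#' @param n_events number of integrations (>= 0).
#' @param seed RNG seed.
#' @return A list: `genome` (modified contigs), `truth` (data frame with
#'   `contig`, `host_pos`, `virus_pos`, `side`, `mod_pos`).
#' @export
inject_provirus <- function(host, virus, n_events, seed = NULL) {
  stopifnot(n_events >= 0)
  virus <- unname(virus[1L])
  lv <- nchar(virus)
  if (any(nchar(host) <= lv))
    stop("virus must be shorter than each host contig")
  empty <- data.frame(contig = character(), host_pos = integer(),
                      virus_pos = integer(), side = character(),
                      mod_pos = integer(), stringsAsFactors = FALSE)
  if (n_events == 0L)
    return(list(genome = host, truth = empty))
  with_seed(seed, {
    lens <- nchar(host)
    contig <- sample(names(host), n_events, replace = TRUE,
                     prob = lens / sum(lens))
    v_first <- substr(virus, 1L, 1L)
    v_last <- substr(virus, lv, lv)
    draw_pos <- function(cn) {
      repeat {
        p <- sample.int(lens[[cn]] - 1L, 1L)  # 0-based point in (0, len)
        if (substr(host[[cn]], p + 1L, p + 1L) != v_first &&
            substr(host[[cn]], p, p) != v_last)
          return(p)
      }
    }
    pos <- vapply(contig, draw_pos, integer(1))
    # distinct positions per contig; redraw collisions
    key <- paste(contig, pos)
    while (anyDuplicated(key)) {
      dup <- duplicated(key)
      pos[dup] <- vapply(contig[dup], draw_pos, integer(1))
      key <- paste(contig, pos)
    }
    genome <- host
    rows <- list()
    for (cn in unique(contig)) {
      pp <- sort(pos[contig == cn])
      offset <- 0L
      for (i in seq_along(pp)) {
        p <- pp[i]
        mod_left <- p + offset
        genome[[cn]] <- paste0(substr(genome[[cn]], 1L, mod_left),
                               virus,
                               substr(genome[[cn]], mod_left + 1L,
                                      nchar(genome[[cn]])))
        rows[[length(rows) + 1L]] <- data.frame(
          contig = cn, host_pos = c(p, p), virus_pos = c(0L, lv),
          side = c("5p", "3p"), mod_pos = c(mod_left, mod_left + lv),
          stringsAsFactors = FALSE)
        offset <- offset + lv
      }
    }
    list(genome = genome, truth = do.call(rbind, rows))
  })
}

# inject substitution errors into reads at a per-base rate
.add_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  nerr <- rbinom(length(seqs), nchar(seqs), error_rate)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(nchar(seqs[i]), nerr[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    for (p in pos) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate whole-genome sequencing reads
#'
#' Uniform single-end reads from a (possibly provirus-carrying) genome,
#' with i.i.d. substitution errors and optional targeted oversampling of
#' junction-spanning windows. Reads overlapping a truth junction by at
#' least 1 nt on each side are labelled junction reads in the returned
#' truth; targeted junction reads are guaranteed
#' `junction_min_flank` nt on each side.
#'
#' @param genome named character vector of contigs (the *modified*
#'   genome when provirus was injected).
#' @param n_reads number of uniformly placed reads.
#' @param read_len read length (<= min contig length).
#' @param error_rate substitution rate in `[0, 0.1)`.
#' @param truth truth data frame from [inject_provirus()] (junction
#'   positions in `mod_pos`), or `NULL`.
#' @param junction_reads_per_site extra reads drawn across each truth
#'   junction.
#' @param junction_min_flank minimum flank of the targeted junction
#'   reads on each side of the junction.
#' @param seed RNG seed.
#' @return A list: `reads` (a [seq_set], qualities constant `I`),
#'   `junction_read_ids` (character vector of labelled reads).
#' @export
simulate_wgs_reads <- function(genome, n_reads, read_len = 150L,
                               error_rate = 0, truth = NULL,
                               junction_reads_per_site = 0L,
                               junction_min_flank = 1L, seed = NULL) {
  stopifnot(error_rate >= 0, error_rate < 0.1,
            read_len <= min(nchar(genome)))
  with_seed(seed, {
    lens <- nchar(genome)
    contig <- sample(names(genome), n_reads, replace = TRUE,
                     prob = lens / sum(lens))
    start <- vapply(lens[contig] - read_len + 1L, sample.int,
                    integer(1), size = 1L) - 1L  # 0-based
    id <- sprintf("read%07d", seq_len(n_reads))
    if (!is.null(truth) && nrow(truth) && junction_reads_per_site > 0L) {
      jr <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
        j <- truth$mod_pos[i]
        lo <- max(0L, j - read_len + junction_min_flank)
        hi <- min(lens[[truth$contig[i]]] - read_len, j - junction_min_flank)
        if (hi < lo) return(NULL)
        data.frame(contig = truth$contig[i],
                   start = lo + sample.int(hi - lo + 1L,
                                           junction_reads_per_site,
                                           replace = TRUE) - 1L,
                   stringsAsFactors = FALSE)
      }))
      contig <- c(contig, jr$contig)
      start <- c(start, jr$start)
      id <- c(id, sprintf("jread%06d", seq_len(nrow(jr))))
    }
    seqs <- substr(genome[contig], start + 1L, start + read_len)
    strand <- sample(c("+", "-"), length(seqs), replace = TRUE)
    seqs[strand == "-"] <- reverse_complement(seqs[strand == "-"])
    seqs <- .add_errors(seqs, error_rate)
    junction_ids <- character()
    if (!is.null(truth) && nrow(truth)) {
      lab <- vapply(seq_along(seqs), function(i) {
        any(truth$contig == contig[i] & truth$mod_pos > start[i] &
            truth$mod_pos < start[i] + read_len)
      }, logical(1))
      junction_ids <- id[lab]
    }
    list(reads = seq_set(id, unname(seqs),
                         strrep("I", rep(read_len, length(seqs)))),
         junction_read_ids = junction_ids)
  })
}

#' Simulate a small-RNA sequencing library
#'
#' Each read is, with probability `p_target22g`, a 23-nt 5'-G
#' subsequence drawn antisense from the target transcript; otherwise a
#' decoy drawn from `decoy_spec`: `wrong_length` (target antisense,
#' 5'-G, length 18-28 but not 23), `wrong_first` (target antisense 23-mer
#' not starting with G), `off_target` (23-nt 5'-G read from an unrelated
#' decoy sequence) or `adapter_only` (empty insert). The 3' adapter is
#' appended to every insert and reads are padded with random bases /
#' truncated to the instrument read length, as on a real run.
#'
#' @param target target transcript sequence (single string).
#' @param n_reads library size.
#' @param p_target22g emission probability of the target-specific
#'   secondary-siRNA class.
#' @param decoy_spec named non-negative weights for the decoy classes
#'   (renormalised to `1 - p_target22g`).
#' @param adapter 3' adapter sequence appended to every insert.
#' @param read_len instrument read length (default 50, single-end).
#' @param seed RNG seed.
#' @return A list: `reads` (a [seq_set]), `truth` (data frame with `id`,
#'   `class`, `insert_len`).
#' @export
simulate_smallrna_library <- function(target, n_reads, p_target22g,
                                      decoy_spec = c(wrong_length = 0.3,
                                                     wrong_first = 0.3,
                                                     off_target = 0.3,
                                                     adapter_only = 0.1),
                                      adapter = "TGGAATTCTCGGGTGCCAAGG",
                                      read_len = 50L, seed = NULL) {
  stopifnot(p_target22g >= 0, p_target22g <= 1, all(decoy_spec >= 0))
  target <- toupper(unname(target[1L]))
  anti <- reverse_complement(target)
  g_at <- function(s, maxlen) {
    p <- which(strsplit(s, "", fixed = TRUE)[[1L]] == "G")
    p[p + maxlen - 1L <= nchar(s)]
  }
  g23 <- g_at(anti, 23L)
  if (!length(g23)) stop("target has no antisense 5'-G 23-mer")
  not_g23 <- setdiff(which(substr(rep(anti, nchar(anti)),
                                  seq_len(nchar(anti)),
                                  seq_len(nchar(anti))) != "G"),
                     seq.int(nchar(anti) - 21L, nchar(anti)))
  with_seed(seed, {
    classes <- c("target22g", names(decoy_spec))
    w <- decoy_spec / sum(decoy_spec)
    probs <- c(p_target22g, (1 - p_target22g) * w)
    cls <- sample(classes, n_reads, replace = TRUE, prob = probs)
    inserts <- character(n_reads)
    i <- cls == "target22g"
    if (any(i)) {
      st <- sample(g23, sum(i), replace = TRUE)
      inserts[i] <- substr(rep(anti, sum(i)), st, st + 22L)
    }
    i <- cls == "wrong_length"
    if (any(i)) {
      len <- sample(setdiff(18:28, 23L), sum(i), replace = TRUE)
      g28 <- g_at(anti, 28L)
      st <- sample(g28, sum(i), replace = TRUE)
      inserts[i] <- substr(rep(anti, sum(i)), st, st + len - 1L)
    }
    i <- cls == "wrong_first"
    if (any(i)) {
      st <- sample(not_g23, sum(i), replace = TRUE)
      inserts[i] <- substr(rep(anti, sum(i)), st, st + 22L)
    }
    i <- cls == "off_target"
    if (any(i)) {
      decoy <- paste(sample(c("A", "C", "G", "T"), 2000L, replace = TRUE),
                     collapse = "")
      dg <- g_at(decoy, 23L)
      st <- sample(dg, sum(i), replace = TRUE)
      inserts[i] <- substr(rep(decoy, sum(i)), st, st + 22L)
    }
    pad <- vapply(pmax(0L, read_len - nchar(inserts) - nchar(adapter)),
                  function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = ""),
                  character(1))
    seqs <- substr(paste0(inserts, adapter, pad), 1L, read_len)
    id <- sprintf("sr%07d", seq_len(n_reads))
    list(reads = seq_set(id, seqs, strrep("I", nchar(seqs))),
         truth = data.frame(id = id, class = cls,
                            insert_len = nchar(inserts),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate an RT-qPCR Ct table
#'
#' Reference-gene Ct values are `baseline + loading + N(0,
#' ref_stability_sd)`; the target Ct is `baseline + loading -
#' log_E(2^true_log2fc) + N(0, ct_noise_sd)`, so the comparative-Ct
#' module recovers `true_log2fc` exactly at zero noise. The per-sample
#' loading offset is shared across genes within a sample and therefore
#' cancels in delta-Ct.
#'
#' @param true_log2fc named numeric vector: groups and their true log2
#'   fold changes (the calibrator group should carry 0).
#' @param reference_genes names of the reference genes.
#' @param target_gene target gene name.
#' @param n_replicates samples per group.
#' @param efficiency target primer efficiency E in (1, 2.2].
#' @param ct_noise_sd Gaussian noise sd on the target Ct.
#' @param ref_stability_sd Gaussian noise sd on reference-gene Ct.
#' @param loading_sd sd of the shared per-sample loading offset.
#' @param baseline_target,baseline_refs baseline Ct values.
#' @param seed RNG seed.
#' @return A Ct table data frame (`sample_id`, `group`, `gene`, `ct`,
#'   `efficiency`).
#' @export
simulate_ct_table <- function(true_log2fc, reference_genes =
                                c("eif-3C", "idhg-1", "rbd-1"),
                              target_gene = "target", n_replicates = 4L,
                              efficiency = 2, ct_noise_sd = 0,
                              ref_stability_sd = 0, loading_sd = 0.5,
                              baseline_target = 24,
                              baseline_refs = c(20, 21, 22),
                              seed = NULL) {
  stopifnot(!is.null(names(true_log2fc)), efficiency > 1,
            efficiency <= 2.2)
  baseline_refs <- rep_len(baseline_refs, length(reference_genes))
  with_seed(seed, {
    rows <- list()
    for (g in names(true_log2fc)) {
      shift <- -log2(2^true_log2fc[[g]]) / log2(efficiency) # -log_E(2^theta)
      for (r in seq_len(n_replicates)) {
        sid <- paste0(g, "_", r)
        load <- rnorm(1, 0, loading_sd)
        for (j in seq_along(reference_genes)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, group = g, gene = reference_genes[j],
            ct = baseline_refs[j] + load + rnorm(1, 0, ref_stability_sd),
            efficiency = NA_real_, stringsAsFactors = FALSE)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = g, gene = target_gene,
          ct = baseline_target + load + shift + rnorm(1, 0, ct_noise_sd),
          efficiency = efficiency, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Assemble and validate a hairpin construct
#'
#' `assembled = stem + loop + reverse_complement(stem)`, the structure of
#' both construct families used for virally delivered RNAi triggers:
#' `shRNAmir` (a 21-nt stem hairpin embedded in a miR-30 backbone,
#' processed by the miRNA pathway) and `lhp` (a long hairpin of >= 100 bp
#' stem, processed into multiple primary siRNAs). Under strict
#' validation an shRNAmir stem must be exactly 21 nt.
#'
#' @param stem sense-arm sequence (RNA accepted; stored as DNA).
#' @param loop loop sequence.
#' @param kind `"shRNAmir"` or `"lhp"`.
#' @param strict enforce the 21-nt shRNAmir stem rule.
#' @return A list of class `"hairpin_design"`: `kind`, `stem`, `loop`,
#'   `assembled`.
#' @export
assemble_hairpin <- function(stem, loop, kind = c("shRNAmir", "lhp"),
                             strict = TRUE) {
  kind <- match.arg(kind)
  stem <- chartr("U", "T", toupper(stem))
  loop <- chartr("U", "T", toupper(loop))
  if (grepl("[^ACGTN]", paste0(stem, loop)))
    stop("non-IUPAC character in stem or loop")
  if (kind == "shRNAmir") {
    if (nchar(stem) < 19L) stop("shRNAmir stem must be >= 19 nt")
    if (strict && nchar(stem) != 21L)
      stop("shRNAmir stem must be exactly 21 nt under strict validation")
  } else {
    if (nchar(stem) < 100L) stop("lhp stem must be >= 100 nt")
  }
  assembled <- paste0(stem, loop, reverse_complement(stem))
  structure(list(kind = kind, stem = stem, loop = loop,
                 assembled = assembled),
            class = "hairpin_design")
}

#' @export
print.hairpin_design <- function(x, ...) {
  cat(sprintf("%s hairpin: %d nt stem + %d nt loop = %d nt assembled\n",
              x$kind, nchar(x$stem), nchar(x$loop), nchar(x$assembled)))
  invisible(x)
}

#' Mature shRNAmir guide sequences used in the transduction experiments
#'
#' The ten mature 21-nt guides targeting *tbb-1*, *tbb-2* and *ache-b*
#' transcripts, as designed (RNA alphabet; the numeric suffix of each
#' name is the 1-based position of the first target nucleotide).
#'
#' @return Data frame with `name`, `target`, `position`, `sequence_rna`,
#'   `sequence_dna`.
#' @export
shrnamir_table <- function() {
  seqs <- c(
    "tbb1-174"  = "AUUGAUUCUUUCCAGCUGCAG",
    "tbb1-180"  = "AUAGACAUUGAUUCUUUCCAG",
    "tbb1-185"  = "UUAUAAUAGACAUUGAUUCUU",
    "tbb1-283"  = "AUAACUGUCCAUAUGGUCCGG",
    "tbb2-130"  = "AUAGACAUUGAUUCGCUCCAA",
    "tbb2-135"  = "UUGUAAUAGACAUUGAUUCGC",
    "tbb2-246"  = "UUGUCCGGUCGGAACAGCUGG",
    "tbb2-444"  = "AUCUUUGCAAUCAACAACGUU",
    "aceb-468"  = "UUGACAUUCACAACUACUGCG",
    "aceb-1653" = "UUGUCUUCGAUCUUUCUCGUU")
  name <- names(seqs)
  data.frame(name = name,
             target = sub("-.*$", "", name),
             position = as.integer(sub("^.*-", "", name)),
             sequence_rna = unname(seqs),
             sequence_dna = chartr("U", "T", unname(seqs)),
             stringsAsFactors = FALSE)
}
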