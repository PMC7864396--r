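# shared fixture: small host + virus with planted integrations
local_int_fixture <- function(seed = 101, n_events = 3,
                              host_len = 4e4, virus_len = 2500) {
  host <- simulate_genome(1, host_len, seed = seed)
  virus <- simulate_virus(virus_len, seed = seed + 1)
  inj <- inject_provirus(host, virus, n_events, seed = seed + 2)
  list(host = host, virus = virus, inj = inj,
       refs = reference_set(host = host, virus = virus),
       hidx = build_index(host), vidx = build_index(virus))
}

test_that("enumerate_subreads yields every bipartition above min_subread", {
  r30 <- rand_seq(30)
  s <- enumerate_subreads(r30, 15)
  expect_equal(nrow(s), 1L)
  expect_equal(s$split, 15L)
  expect_equal(paste0(s$prefix, s$suffix), r30)

  s <- enumerate_subreads(rand_seq(40), 15)
  expect_equal(s$split, 15:25)           # 11 pairs, 22 sub-reads
  expect_equal(nchar(s$prefix) + nchar(s$suffix), rep(40L, 11))
  expect_true(all(nchar(s$prefix) >= 15 & nchar(s$suffix) >= 15))

  expect_equal(nrow(enumerate_subreads(rand_seq(20), 15)), 0L)
})

test_that("candidate screen keeps chimeras, drops pure host/virus reads", {
  set.seed(8)
  fx <- local_int_fixture()
  host_read <- substr(fx$host[[1]], 1001, 1150)
  virus_read <- substr(fx$virus[[1]], 501, 650)
  chimera <- paste0(substr(fx$host[[1]], 2001, 2025),
                    substr(fx$virus[[1]], 301, 325))
  reads <- seq_set(c("h", "v", "c"), c(host_read, virus_read, chimera))
  kept <- select_candidate_reads(reads, fx$hidx, fx$vidx)
  expect_equal(kept$id, "c")
})

test_that("classify_split_read recovers constructed junctions exactly", {
  set.seed(9)
  fx <- local_int_fixture()
  p <- 12345L  # 0-based host breakpoint
  vstart <- 700L
  read <- paste0(substr(fx$host[[1]], p - 69, p),        # host[p-70:p)
                 substr(fx$virus[[1]], vstart + 1, vstart + 80))
  ev <- classify_split_read(read, fx$hidx, fx$vidx, read_id = "jr")
  expect_equal(ev$junction_host_pos, p)
  expect_equal(ev$junction_virus_pos, vstart)
  expect_equal(ev$host_part, "prefix")
  expect_equal(ev$orientation, "same")

  # the same junction read arriving on the minus strand
  ev2 <- classify_split_read(reverse_complement(read), fx$hidx, fx$vidx)
  expect_equal(ev2$junction_host_pos, p)
  expect_equal(ev2$junction_virus_pos, vstart)

  # no junction: host-only read
  expect_null(classify_split_read(substr(fx$host[[1]], 501, 650),
                                  fx$hidx, fx$vidx))
  # virus flank below min_subread cannot be called
  short_flank <- paste0(substr(fx$host[[1]], p - 139, p),
                        substr(fx$virus[[1]], 1, 10))
  expect_null(classify_split_read(short_flank, fx$hidx, fx$vidx))
})

test_that("detect_integrations recovers all planted junction sites exactly", {
  fx <- local_int_fixture(seed = 111, n_events = 3)
  sim <- simulate_wgs_reads(fx$inj$genome, 3000, 150,
                            truth = fx$inj$truth,
                            junction_reads_per_site = 8,
                            junction_min_flank = 20, seed = 117)
  calls <- detect_integrations(sim$reads, fx$refs)
  expect_equal(calls$total_reads_screened, nrow(sim$reads))
  expect_equal(calls$rate_per_million,
               1e6 * nrow(calls$events) / calls$total_reads_screened)
  expect_false(any(duplicated(calls$events$read_id)))
  # every truth junction coordinate is found, and no spurious coordinate is
  expect_setequal(unique(calls$events$junction_host_pos),
                  unique(fx$inj$truth$host_pos))
  # events come only from truth-labelled junction-spanning reads
  expect_true(all(calls$events$read_id %in% sim$junction_read_ids))
})

test_that("virus-free libraries yield zero events", {
  host <- simulate_genome(1, 3e4, seed = 31)
  virus <- simulate_virus(2000, seed = 32)
  sim <- simulate_wgs_reads(host, 5000, 150, seed = 33)
  calls <- detect_integrations(sim$reads,
                               reference_set(host = host, virus = virus))
  expect_equal(nrow(calls$events), 0L)
  expect_equal(calls$rate_per_million, 0)
})

test_that("junction table export states the coordinate convention", {
  fx <- local_int_fixture(seed = 121, n_events = 1)
  sim <- simulate_wgs_reads(fx$inj$genome, 200, 150, truth = fx$inj$truth,
                            junction_reads_per_site = 5,
                            junction_min_flank = 25, seed = 122)
  calls <- detect_integrations(sim$reads, fx$refs)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_junctions_tsv(calls, f)
  lines <- readLines(f)
  expect_match(lines[1], "0-based")
  expect_equal(length(lines), nrow(calls$events) + 2L)
})

test_that("cluster_events merges nearby junctions", {
  ev <- .mapply(function(pos, id)
    data.frame(read_id = id, host_contig = "c1", junction_host_pos = pos,
               stringsAsFactors = FALSE),
    list(c(100L, 103L, 105L, 300L), c("a", "b", "c", "d")), NULL)
  ev <- do.call(rbind, ev)
  cl <- cluster_events(ev, window = 5)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$n_reads, c(3L, 1L))
})

test_that("enrichment test matches the hypergeometric oracle", {
  set.seed(10)
  virus <- simulate_virus(2000, seed = 41)
  vidx <- build_index(virus)
  viral_reads <- vapply(sample(1800, 100), function(st)
    substr(virus[[1]], st, st + 99), character(1))
  junk <- vapply(rep(100, 9900), rand_seq, character(1))
  exposed <- seq_set(paste0("e", 1:10000), c(viral_reads, junk))
  control <- seq_set(paste0("c", 1:1000), vapply(rep(100, 1000), rand_seq,
                                                 character(1)))
  res <- viral_read_enrichment_test(exposed, control, vidx,
                                    n_resamples = 100, seed = 42)
  expect_equal(res$control_viral_count, 0L)
  expect_equal(res$exposed_viral_count, 100L)
  expect_length(res$downsampled_counts, 100L)
  # oracle: each downsampled count is Hypergeometric(10000, 100, 1000);
  # P(count <= 0) = phyper(0, 100, 9900, 1000) ~ 2.6e-5, so across 100
  # draws the probability of any zero is < 0.3% and empirical_p = 1/101
  expect_lt(stats::phyper(0, 100, 9900, 1000), 1e-4)
  expect_equal(res$empirical_p, 1 / 101)
  # and the resample mean sits near the hypergeometric mean (10)
  hyper_mean <- 1000 * 100 / 10000
  hyper_sd <- sqrt(1000 * (100 / 10000) * (9900 / 10000) *
                   (9000 / 9999))
  expect_lt(abs(mean(res$downsampled_counts) - hyper_mean),
            3 * hyper_sd / sqrt(100))
})

test_that("enrichment test is deterministic per seed and null-calibrated", {
  set.seed(11)
  virus <- simulate_virus(1500, seed = 51)
  vidx <- build_index(virus)
  mk <- function(n, vfrac, prefix) {
    nv <- round(n * vfrac)
    vr <- vapply(sample(1400, nv, replace = TRUE), function(st)
      substr(virus[[1]], st, st + 79), character(1))
    seq_set(paste0(prefix, seq_len(n)),
            c(vr, vapply(rep(80, n - nv), rand_seq, character(1))))
  }
  exposed <- mk(2000, 0.05, "e")
  control <- mk(1000, 0.05, "c")
  r1 <- viral_read_enrichment_test(exposed, control, vidx, seed = 7)
  r2 <- viral_read_enrichment_test(exposed, control, vidx, seed = 7)
  expect_identical(r1$downsampled_counts, r2$downsampled_counts)
  # same viral fraction in both libraries: not significant
  expect_gt(r1$empirical_p, 0.05)
  # control larger than exposed is a usage error
  expect_error(viral_read_enrichment_test(control, exposed, vidx),
               "swap")
})

test_that("empirical p is non-increasing in the exposed viral fraction", {
  set.seed(12)
  virus <- simulate_virus(1500, seed = 61)
  vidx <- build_index(virus)
  control <- seq_set(paste0("c", 1:400),
                     c(vapply(sample(1400, 8, replace = TRUE), function(st)
                         substr(virus[[1]], st, st + 79), character(1)),
                       vapply(rep(80, 392), rand_seq, character(1))))
  ps <- vapply(c(0.02, 0.05, 0.10, 0.20), function(vfrac) {
    nv <- round(1200 * vfrac)
    vr <- vapply(sample(1400, nv, replace = TRUE), function(st)
      substr(virus[[1]], st, st + 79), character(1))
    exposed <- seq_set(paste0("e", 1:1200),
                       c(vr, vapply(rep(80, 1200 - nv), rand_seq,
                                    character(1))))
    viral_read_enrichment_test(exposed, control, vidx, seed = 9)$empirical_p
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})
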