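# small Ct-table builder used across cases
ct_rows <- function(group, sample, target_ct, ref_cts,
                    ref_genes = c("ref1", "ref2", "ref3"),
                    target = "tgt", eff = 2) {
  rbind(
    data.frame(sample_id = sample, group = group, gene = target,
               ct = target_ct, efficiency = eff, stringsAsFactors = FALSE),
    data.frame(sample_id = sample, group = group, gene = ref_genes,
               ct = ref_cts, efficiency = NA_real_,
               stringsAsFactors = FALSE))
}

test_that("reference_geomean is the geometric mean of raw Ct values", {
  expect_equal(reference_geomean(c(20, 20, 20)), 20)
  expect_equal(reference_geomean(c(18, 20, 22.5)), 8100^(1 / 3))
  expect_equal(reference_geomean(c(22.5, 18, 20)),
               reference_geomean(c(18, 20, 22.5)))
  expect_error(reference_geomean(numeric(0)), "finite")
})

test_that("relative_expression implements the comparative-Ct method", {
  tab <- rbind(ct_rows("WT", "w1", 22, c(20, 20, 20)),
               ct_rows("WT", "w2", 22, c(20, 20, 20)),
               ct_rows("KD", "k1", 23.737, c(20, 20, 20)),
               ct_rows("KD", "k2", 23, c(20, 20, 20)))
  res <- relative_expression(tab, "tgt", c("ref1", "ref2", "ref3"), "WT")
  # self-calibration: calibrator group mean ddCt = 0, mean rel_expr = 1
  expect_equal(mean(res$delta_delta_ct[res$group == "WT"]), 0)
  expect_equal(mean(res$rel_expr[res$group == "WT"]), 1)
  # ddCt = 1.737 at E = 2 -> 2^-1.737 = 0.2999 (a 70% decrease)
  expect_equal(res$rel_expr[res$sample_id == "k1"], 2^-1.737)
  expect_equal(round(100 * (1 - res$rel_expr[res$sample_id == "k1"])), 70)
  # ddCt = 1 at E = 2 halves expression
  expect_equal(res$rel_expr[res$sample_id == "k2"], 0.5)
  expect_equal(res$log2_fc[res$sample_id == "k2"], -1)
})

test_that("per-primer efficiencies are honoured and validated", {
  tab <- rbind(ct_rows("WT", "w1", 22, c(20, 20, 20), eff = 2.1),
               ct_rows("KD", "k1", 23, c(20, 20, 20), eff = 2.1))
  res <- relative_expression(tab, "tgt", c("ref1", "ref2", "ref3"), "WT")
  expect_equal(res$rel_expr[res$group == "KD"], 1 / 2.1)
  bad <- tab
  bad$efficiency[bad$gene == "tgt"] <- 2.5
  expect_error(relative_expression(bad, "tgt", c("ref1", "ref2", "ref3"),
                                   "WT"), "outside \\(1, 2.2\\]")
  warn <- tab
  warn$efficiency[warn$gene == "tgt"] <- 1.7
  expect_warning(relative_expression(warn, "tgt",
                                     c("ref1", "ref2", "ref3"), "WT"),
                 "1.9-2.1")
})

test_that("samples missing a reference gene are excluded with a warning", {
  tab <- rbind(ct_rows("WT", "w1", 22, c(20, 20, 20)),
               ct_rows("WT", "w2", 22, c(20, 20, 20)),
               ct_rows("KD", "k1", 23, c(20, 20, 20)))
  tab <- rbind(tab, data.frame(sample_id = "k2", group = "KD",
                               gene = "tgt", ct = 23,
                               efficiency = 2, stringsAsFactors = FALSE))
  expect_warning(res <- relative_expression(tab, "tgt",
                                            c("ref1", "ref2", "ref3"),
                                            "WT"), "k2")
  expect_false("k2" %in% res$sample_id)
})

test_that("equal-loading shifts cancel in delta-Ct", {
  # a constant added to every Ct of one sample leaves that sample's dCt
  # unchanged; exact whenever the reference Cts are equal (the geometric
  # mean of raw Ct values commutes with a constant shift only then)
  tab <- rbind(ct_rows("WT", "w1", 22, c(20, 20, 20)),
               ct_rows("WT", "w2", 22, c(20, 20, 20)),
               ct_rows("KD", "k1", 24, c(20, 20, 20)))
  shifted <- tab
  k1 <- shifted$sample_id == "k1"
  shifted$ct[k1] <- shifted$ct[k1] + 1.6
  a <- relative_expression(tab, "tgt", c("ref1", "ref2", "ref3"), "WT")
  b <- relative_expression(shifted, "tgt", c("ref1", "ref2", "ref3"), "WT")
  expect_equal(b$delta_ct, a$delta_ct)
  expect_equal(b$rel_expr, a$rel_expr)
})

test_that("summarize_group reports mean log2, SEM and percent knockdown", {
  res <- data.frame(sample_id = paste0("s", 1:3), group = "g",
                    log2_fc = rep(-0.72, 3), stringsAsFactors = FALSE)
  s <- summarize_group(res)
  expect_equal(s$mean_log2, -0.72)
  expect_equal(s$sem_log2, 0)
  expect_equal(s$percent_knockdown, 100 * (1 - 2^-0.72))
  expect_equal(round(s$percent_knockdown / 10) * 10, 40)  # reported as ~40%

  expect_equal(summarize_group(data.frame(group = "g", log2_fc = 0,
                                          sample_id = "s"))$percent_knockdown,
               0)
  expect_equal(summarize_group(data.frame(group = "g", log2_fc = -1,
                                          sample_id = "s"))$percent_knockdown,
               50)
  one <- summarize_group(data.frame(group = "g", log2_fc = -0.5,
                                    sample_id = "s"))
  expect_true(is.na(one$sem_log2))
  # per-sample percent mode
  res2 <- data.frame(group = "g", sample_id = paste0("s", 1:2),
                     log2_fc = c(0, -1))
  expect_equal(summarize_group(res2, per_sample_percent = TRUE)$percent_knockdown,
               mean(c(0, 50)))
})

test_that("Kruskal-Wallis H matches stats::kruskal.test, including ties", {
  set.seed(19)
  for (i in 1:5) {
    x <- round(rnorm(15), 1)      # rounding induces ties
    g <- sample(rep(c("a", "b", "c"), each = 5))
    got <- compare_groups(x, g, "a", exact_max = 0)  # force chi-square
    ref <- stats::kruskal.test(x, factor(g))
    expect_equal(got$H, unname(ref$statistic))
    expect_equal(got$p, ref$p.value)
  }
})

test_that("exact permutation p agrees with a Monte-Carlo oracle", {
  set.seed(20)
  x <- c(1.2, 0.8, 1.0, 2.2, 2.5, 2.1, 0.9, 1.1, 1.3)
  g <- rep(c("a", "b", "c"), each = 3)
  got <- compare_groups(x, g, "a")
  expect_equal(got$p_method, "exact permutation")
  # independent oracle: random relabellings of the same data
  kw <- function(xx, gg) {
    r <- rank(xx); n <- length(xx)
    rb <- tapply(r, gg, mean); ni <- tapply(r, gg, length)
    12 / (n * (n + 1)) * sum(ni * (rb - (n + 1) / 2)^2)
  }
  h_obs <- kw(x, g)
  mc <- mean(replicate(20000, kw(x, sample(g)) >= h_obs - 1e-12))
  expect_lt(abs(got$p - mc), 3 * sqrt(mc * (1 - mc) / 20000))
})

test_that("identical groups are not significant; H = 0 degenerate case", {
  x <- rep(5, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  got <- compare_groups(x, g, "a")
  expect_equal(got$H, 0)
  expect_equal(got$p, 1)
  expect_true(all(got$pairwise$stars == "ns"))
  # same distribution in all groups: p above 0.05
  set.seed(21)
  x2 <- rnorm(12)
  g2 <- rep(c("a", "b", "c"), each = 4)
  expect_gt(compare_groups(x2, g2, "a")$p, 0.05)
})

test_that("Dunn pairs, Bonferroni adjustment and stars behave", {
  set.seed(22)
  x <- c(rnorm(6), rnorm(6, 5), rnorm(6, -5))
  g <- rep(c("ctl", "up", "down"), each = 6)
  got <- compare_groups(x, g, "ctl")
  expect_equal(nrow(got$pairwise), 2L)
  expect_equal(sort(got$pairwise$treatment), c("down", "up"))
  expect_true(all(got$pairwise$p_adj ==
                  pmin(1, got$pairwise$p_raw * 2)))
  z_up <- got$pairwise$z[got$pairwise$treatment == "up"]
  z_dn <- got$pairwise$z[got$pairwise$treatment == "down"]
  expect_gt(z_up, 0)
  expect_lt(z_dn, 0)
  # star thresholds
  expect_equal(lentinema:::.stars(c(0.2, 0.04, 0.009, 9e-4, 9e-5)),
               c("ns", "*", "**", "***", "****"))
})

test_that("closed loop: simulated Ct tables recover the truth", {
  refs <- c("eif-3C", "idhg-1", "rbd-1")
  # zero noise (including loading): exact recovery
  tab <- simulate_ct_table(c(WT = 0, KD = -0.72), reference_genes = refs,
                           n_replicates = 4, ct_noise_sd = 0,
                           ref_stability_sd = 0, loading_sd = 0, seed = 23)
  res <- relative_expression(tab, "target", refs, "WT")
  s <- summarize_group(res)
  expect_equal(s$mean_log2[s$group == "KD"], -0.72)
  expect_equal(s$mean_log2[s$group == "WT"], 0)
  expect_equal(s$percent_knockdown[s$group == "WT"], 0)
  # with noise: recovered mean within 3 standard errors of the estimate
  # for >= 9 of 10 seeds. The estimator's error combines the treatment
  # group's SEM with the calibrator-mean uncertainty (calibration
  # subtracts the mean calibrator dCt, whose noise the group SEM alone
  # does not see), so the correct SE is sqrt(sem_KD^2 + sem_WT^2).
  ok <- vapply(1:10, function(sd_seed) {
    tab <- simulate_ct_table(c(WT = 0, KD = -0.72), reference_genes = refs,
                             n_replicates = 12, ct_noise_sd = 0.2,
                             ref_stability_sd = 0, loading_sd = 0,
                             seed = 400 + sd_seed)
    res <- relative_expression(tab, "target", refs, "WT")
    s <- summarize_group(res)
    se <- sqrt(s$sem_log2[s$group == "KD"]^2 +
               s$sem_log2[s$group == "WT"]^2)
    abs(s$mean_log2[s$group == "KD"] + 0.72) <= 3 * se
  }, logical(1))
  expect_gte(sum(ok), 9L)
})
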