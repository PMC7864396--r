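#' Geometric mean of reference-gene Ct values
#'
#' Multi-reference normalisation takes the geometric mean over the raw
#' (positive) Ct values of the reference genes for one sample.
#'
#' @param ct numeric vector of reference-gene Ct values (>= 1 value, all
#'   finite and positive).
#' @return The geometric mean.
#' @examples
#' reference_geomean(c(18, 20, 22.5)) # (18*20*22.5)^(1/3)
#' @export
reference_geomean <- function(ct) {
  if (length(ct) < 1L || any(!is.finite(ct)) || any(ct <= 0))
    stop("reference Ct values must be finite and positive")
  exp(mean(log(ct)))
}

.validate_efficiency <- function(e, gene) {
  if (any(e <= 1 | e > 2.2))
    stop("amplification efficiency for ", gene, " outside (1, 2.2]")
  if (any(e < 1.9 | e > 2.1))
    warning("amplification efficiency for ", gene,
            " outside the expected 1.9-2.1 range")
  e
}

#' Comparative-Ct (delta-delta-Ct) relative expression
#'
#' Per sample: `dCt = Ct_target - geomean(Ct_refs)`;
#' `ddCt = dCt - mean(dCt over calibrator samples)`;
#' `rel_expr = E^(-ddCt)` with `E` the target primer efficiency
#' (default 2, i.e. perfect doubling); `log2_fc = log2(rel_expr)`.
#' Calibration uses the arithmetic mean of the calibrator samples' dCt,
#' so the calibrator group's mean ddCt is 0 and its mean log2 fold
#' change is 0 by construction.
#'
#' @param ct_table data frame with columns `sample_id`, `group`, `gene`,
#'   `ct` and optionally `efficiency` (per-primer E for the target; rows
#'   for reference genes may carry their own E but it is not used, per
#'   the raw-Ct geometric-mean convention). Each (sample, gene) pair must
#'   appear once.
#' @param target_gene name of the target gene.
#' @param reference_genes character vector of reference gene names;
#'   samples missing any reference gene are excluded with a warning.
#' @param calibrator_group group defining relative expression 1 (>= 1
#'   sample).
#' @param efficiency default target efficiency when the table has no
#'   `efficiency` column; values outside (1, 2.2] are errors, values
#'   outside 1.9-2.1 raise a warning (the empirically acceptable
#'   window).
#' @return Data frame with one row per sample: `sample_id`, `group`,
#'   `delta_ct`, `delta_delta_ct`, `rel_expr`, `log2_fc`.
#' @export
relative_expression <- function(ct_table, target_gene, reference_genes,
                                calibrator_group, efficiency = 2) {
  need <- c("sample_id", "group", "gene", "ct")
  if (!all(need %in% names(ct_table)))
    stop("ct_table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(ct_table[, c("sample_id", "gene")]))
    stop("each (sample, gene) pair must appear once")
  if (any(!is.finite(ct_table$ct))) stop("Ct values must be finite")
  tgt <- ct_table[ct_table$gene == target_gene, ]
  if (nrow(tgt) == 0L) stop("no rows for target gene ", target_gene)
  e <- if ("efficiency" %in% names(ct_table) &&
           any(!is.na(tgt$efficiency))) {
    unique(tgt$efficiency[!is.na(tgt$efficiency)])[1L]
  } else efficiency
  .validate_efficiency(e, target_gene)

  refs <- ct_table[ct_table$gene %in% reference_genes, ]
  n_refs <- tapply(refs$gene, refs$sample_id,
                   function(g) length(unique(g)))
  complete <- names(n_refs)[n_refs == length(reference_genes)]
  dropped <- setdiff(unique(tgt$sample_id), complete)
  if (length(dropped))
    warning("excluding sample(s) missing reference genes: ",
            paste(dropped, collapse = ", "))
  tgt <- tgt[tgt$sample_id %in% complete, ]
  if (nrow(tgt) == 0L) stop("no samples with complete reference panels")
  geo <- vapply(tgt$sample_id, function(s)
    reference_geomean(refs$ct[refs$sample_id == s]), numeric(1))
  delta_ct <- tgt$ct - geo
  cal <- tgt$group == calibrator_group
  if (!any(cal)) stop("calibrator group ", calibrator_group, " absent")
  ddct <- delta_ct - mean(delta_ct[cal])
  rel <- e^(-ddct)
  data.frame(sample_id = tgt$sample_id, group = tgt$group,
             delta_ct = delta_ct, delta_delta_ct = ddct, rel_expr = rel,
             log2_fc = log2(rel), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Group summary: mean log2 fold change, SEM, percent knockdown
#'
#' Percent knockdown is derived from the group-mean log2 fold change as
#' `100 * (1 - 2^mean_log2)` (default); averaging the per-sample
#' percentages instead is available via `per_sample_percent = TRUE`.
#'
#' @param results [relative_expression()] rows for one group (or more:
#'   summarised per group).
#' @param per_sample_percent average per-sample percent decreases rather
#'   than transforming the group-mean log2.
#' @return Data frame with `group`, `n`, `mean_log2`, `sem_log2` (`NA`
#'   for a single sample), `percent_knockdown`.
#' @export
summarize_group <- function(results, per_sample_percent = FALSE) {
  out <- lapply(split(results, results$group), function(g) {
    n <- nrow(g)
    m <- mean(g$log2_fc)
    pk <- if (per_sample_percent) mean(100 * (1 - 2^g$log2_fc))
          else 100 * (1 - 2^m)
    data.frame(group = g$group[1L], n = n, mean_log2 = m,
               sem_log2 = if (n > 1L) sd(g$log2_fc) / sqrt(n) else NA_real_,
               percent_knockdown = pk, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Kruskal-Wallis H with midranks and tie correction (the classical
# tie-corrected statistic; agreement with stats::kruskal.test is asserted
# in the test suite, and the same H feeds the permutation null).
.kw_stat <- function(x, g) {
  r <- rank(x)
  n <- length(x)
  rb <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  h <- 12 / (n * (n + 1)) * sum(ni * (rb - (n + 1) / 2)^2)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) return(0)
  h / corr
}

# all distinct assignments of n items into groups of sizes ns (list of
# index vectors); used for the exact permutation null at small n
.group_assignments <- function(n, ns) {
  recurse <- function(avail, sizes) {
    if (length(sizes) == 0L) return(list(list()))
    if (length(sizes) == 1L) return(list(list(avail)))
    first <- avail[1L]
    rest_combos <- utils::combn(avail[-1L], sizes[1L] - 1L,
                                simplify = FALSE)
    out <- list()
    for (cmb in rest_combos) {
      grp <- c(first, cmb)
      sub <- recurse(setdiff(avail, grp), sizes[-1L])
      out <- c(out, lapply(sub, function(s) c(list(grp), s)))
    }
    out
  }
  recurse(seq_len(n), ns)
}

.stars <- function(p) {
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 1e-2, "**",
  ifelse(p < 0.05, "*", "ns"))))
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Global Kruskal-Wallis H (tie-corrected midranks) with a chi-square
#' p-value, or the exact permutation p-value when the total sample size
#' is at most `exact_max` (all distinct relabellings are enumerated).
#' Dunn's pairwise z statistics are computed for each treatment group
#' against each control group, with Bonferroni adjustment over the pairs
#' actually tested, and significance stars at 0.05 / 0.01 / 0.001 /
#' 0.0001.
#'
#' @param values numeric vector (e.g. per-sample log2 fold changes).
#' @param groups group labels, parallel to `values` (at least 2 groups
#'   with at least 2 samples each).
#' @param control_groups labels of the control group(s); every other
#'   group is tested against each of these.
#' @param exact_max largest total n for which the exact permutation null
#'   replaces the chi-square approximation.
#' @param adjust multiplicity adjustment for Dunn's p-values
#'   (see [stats::p.adjust()]; default Bonferroni).
#' @return A list of class `"group_comparison"`: `H`, `p`, `p_method`,
#'   `pairwise` (data frame with `control`, `treatment`, `z`, `p_raw`,
#'   `p_adj`, `stars`).
#' @export
compare_groups <- function(values, groups, control_groups,
                           exact_max = 10L, adjust = "bonferroni") {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  ni <- table(groups)
  if (length(ni) < 2L || any(ni < 2L))
    stop("need >= 2 groups with >= 2 samples each")
  if (!all(control_groups %in% names(ni)))
    stop("control group(s) absent from data")
  n <- length(values)
  h <- .kw_stat(values, groups)
  if (n <= exact_max) {
    sizes <- as.integer(ni)
    labs <- names(ni)
    assigns <- .group_assignments(n, sizes)
    hs <- vapply(assigns, function(a) {
      g <- character(n)
      for (i in seq_along(a)) g[a[[i]]] <- labs[i]
      .kw_stat(values, g)
    }, numeric(1))
    p <- mean(hs >= h - 1e-12)
    p_method <- "exact permutation"
  } else {
    p <- pchisq(h, df = length(ni) - 1L, lower.tail = FALSE)
    p_method <- "chi-square"
  }

  # Dunn's z: difference of mean ranks over the pooled standard error,
  # with the tie correction term
  r <- rank(values)
  rb <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- expand.grid(control = control_groups,
                       treatment = setdiff(names(ni), control_groups),
                       stringsAsFactors = FALSE)
  z <- mapply(function(ctl, trt) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
               (1 / ni[[ctl]] + 1 / ni[[trt]]))
    if (se == 0) 0 else (rb[[trt]] - rb[[ctl]]) / se
  }, pairs$control, pairs$treatment)
  p_raw <- 2 * pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = adjust)
  pairwise <- data.frame(control = pairs$control,
                         treatment = pairs$treatment, z = as.numeric(z),
                         p_raw = p_raw, p_adj = p_adj,
                         stars = .stars(p_adj), stringsAsFactors = FALSE)
  structure(list(H = h, p = p, p_method = p_method, pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4g, p = %.4g (%s)\n",
              x$H, x$p, x$p_method))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
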