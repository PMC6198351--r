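# Pair-wise case-control 3'UTR switching: linear-by-linear trend test on
# each gene's 2 x k site-count table, BH FDR within each pair, and
# frequency aggregation across all case x control pairs.

#' Linear-by-linear trend test on a 2 x k poly(A)-site count table
#'
#' Tests for a linear trend in site usage between two samples. With group
#' scores 0 (control) and 1 (case) and column scores `scores` (3'UTR
#' lengths), `r` is the Pearson correlation between group and score over
#' the N individual reads, the statistic is M2 = (N - 1) r^2, and the
#' p-value is the upper tail of a 1-df chi-square at M2. A positive `r`
#' means case reads sit at longer 3'UTRs (lengthening); negative means
#' shortening. Degenerate margins (all reads in one group, or all reads at
#' one site) give r = 0, p = 1.
#'
#' @param case_counts,control_counts non-negative integer read counts per
#'   ordered site.
#' @param scores strictly increasing column scores, one per site (3'UTR
#'   lengths in nt by default; any affine transform with positive slope
#'   gives identical results).
#' @return list with `r`, `m2`, `p` and `n` (total reads).
#' @export
linear_trend_test <- function(case_counts, control_counts, scores) {
  k <- length(scores)
  if (k < 2L) stop("at least 2 ordered sites are required")
  if (length(case_counts) != k || length(control_counts) != k)
    stop("counts and scores must have equal length")
  if (any(case_counts < 0) || any(control_counts < 0))
    stop("negative counts")
  if (any(diff(scores) <= 0)) stop("scores must be strictly increasing")
  n1 <- sum(case_counts)
  n0 <- sum(control_counts)
  N <- n1 + n0
  if (N < 1L) stop("empty table")
  col <- case_counts + control_counts
  if (n1 == 0L || n0 == 0L || sum(col > 0) < 2L)
    return(list(r = 0, m2 = 0, p = 1, n = N))
  sum_s <- sum(col * scores)
  sum_s2 <- sum(col * scores^2)
  sum_gs <- sum(case_counts * scores)
  num <- N * sum_gs - n1 * sum_s
  var_g <- N * n1 - n1^2
  var_s <- N * sum_s2 - sum_s^2
  r <- num / sqrt(var_g * var_s)
  m2 <- (N - 1) * r^2
  list(r = r, m2 = m2, p = stats::pchisq(m2, df = 1, lower.tail = FALSE), n = N)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p numeric p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pair-wise case-control switching scan
#'
#' For every (case, control) sample pair and every profiled gene with at
#' least `min_pair_reads` reads in both samples of the pair, runs the
#' linear trend test on the pair's two count rows, then BH-adjusts within
#' the pair across its tested genes. A gene/pair is significant when its
#' q-value falls below `fdr_threshold`.
#'
#' @param profiles a `tandem_profiles` list.
#' @param case_samples,control_samples sample identifiers (must be rows of
#'   every profile count matrix).
#' @param fdr_threshold per-pair BH FDR cutoff.
#' @param min_pair_reads per-sample read floor for testing a gene in a
#'   pair (0 disables).
#' @param scores either "utr_length" (default) or "rank" column scores.
#' @return data frame of pair results: gene_id, case_sample,
#'   control_sample, r, m2, p, q, significant.
#' @export
pairwise_switch_scan <- function(profiles, case_samples, control_samples,
                                 fdr_threshold = 0.01, min_pair_reads = 10L,
                                 scores = c("utr_length", "rank")) {
  scores <- match.arg(scores)
  if (!length(case_samples) || !length(control_samples))
    stop("both sample lists must be nonempty")
  if (length(profiles)) {
    have <- rownames(profiles[[1]]$counts)
    missing <- setdiff(c(case_samples, control_samples), have)
    if (length(missing))
      stop("sample(s) absent from profiles: ", paste(missing, collapse = ", "))
  }
  res <- list()
  for (ca in case_samples) {
    for (co in control_samples) {
      rows <- lapply(profiles, function(p) {
        x <- p$counts[ca, ]
        y <- p$counts[co, ]
        if (sum(x) < min_pair_reads || sum(y) < min_pair_reads) return(NULL)
        s <- if (scores == "utr_length") p$utr_lengths else seq_along(p$utr_lengths)
        tt <- linear_trend_test(x, y, s)
        data.table::data.table(gene_id = p$gene_id, case_sample = ca,
                               control_sample = co, r = tt$r, m2 = tt$m2,
                               p = tt$p, n = tt$n)
      })
      rows <- rows[!vapply(rows, is.null, TRUE)]
      if (!length(rows)) next
      pair <- data.table::rbindlist(rows)
      pair[, q := bh_fdr(p)]
      pair[, significant := q < fdr_threshold]
      res[[length(res) + 1L]] <- pair
    }
  }
  if (!length(res)) {
    return(data.frame(gene_id = character(), case_sample = character(),
                      control_sample = character(), r = numeric(),
                      m2 = numeric(), p = numeric(), n = integer(),
                      q = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  as.data.frame(data.table::rbindlist(res))
}

#' Aggregate pair results into gene-level switching calls
#'
#' A gene is called switching when it is significant in at least
#' `min_significant_pairs` pairs. Direction is the strict majority sign of
#' r among its significant pairs: positive majority = lengthened in cases,
#' negative = shortened, tie = ambiguous.
#'
#' @param results data frame from [pairwise_switch_scan()].
#' @param min_significant_pairs pair-count threshold for a call.
#' @return data frame: gene_id, n_pairs_tested, n_significant_pairs,
#'   direction, mean_r (over significant pairs), called.
#' @export
aggregate_gene_calls <- function(results, min_significant_pairs = 10L) {
  dt <- data.table::as.data.table(results)
  if (nrow(dt) == 0L) {
    return(data.frame(gene_id = character(), n_pairs_tested = integer(),
                      n_significant_pairs = integer(), direction = character(),
                      mean_r = numeric(), called = logical(),
                      stringsAsFactors = FALSE))
  }
  agg <- dt[, {
    sig <- significant
    npos <- sum(sig & r > 0)
    nneg <- sum(sig & r < 0)
    dir <- if (npos > nneg) "lengthened" else if (nneg > npos) "shortened"
           else "ambiguous"
    list(n_pairs_tested = .N, n_significant_pairs = sum(sig),
         direction = if (sum(sig) > 0L) dir else "ambiguous",
         mean_r = if (sum(sig) > 0L) mean(r[sig]) else NA_real_)
  }, by = gene_id]
  agg[, called := n_significant_pairs >= min_significant_pairs]
  data.table::setorder(agg, gene_id)
  as.data.frame(agg)
}

#' Proximal-to-distal supersite expression ratio
#'
#' Pools a gene's sites into a proximal supersite (site indexes
#' `1..split_index`) and a distal supersite (the rest) and returns their
#' count ratio for one sample. A zero distal count gives an
#' infinite-flagged result.
#'
#' @param profile a `tandem_profile`.
#' @param split_index last site index (1-based) of the proximal supersite;
#'   must satisfy 1 <= split_index < number of sites.
#' @param sample sample identifier.
#' @return list with `ratio`, `proximal`, `distal` and `infinite`.
#' @export
supersite_ratio <- function(profile, split_index = 1L, sample) {
  k <- length(profile$utr_lengths)
  if (split_index < 1L || split_index >= k)
    stop("split_index must satisfy 1 <= split_index < ", k)
  cnt <- profile$counts[sample, ]
  proximal <- sum(cnt[seq_len(split_index)])
  distal <- sum(cnt[(split_index + 1L):k])
  if (distal == 0) {
    list(ratio = Inf, proximal = proximal, distal = distal, infinite = TRUE)
  } else {
    list(ratio = proximal / distal, proximal = proximal, distal = distal,
         infinite = FALSE)
  }
}
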