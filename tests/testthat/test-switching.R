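test_that("trend test reproduces hand-computable tables", {
  # complete separation: all control reads proximal, all case reads distal
  tt <- linear_trend_test(c(0, 10), c(10, 0), c(0, 1))
  expect_equal(tt$r, 1)
  expect_equal(tt$m2, 19)
  expect_equal(tt$p, pchisq(19, 1, lower.tail = FALSE))
  # identical distributions: no trend
  tt0 <- linear_trend_test(c(5, 5), c(5, 5), c(0, 1))
  expect_equal(tt0$r, 0)
  expect_equal(tt0$m2, 0)
  expect_equal(tt0$p, 1)
})

test_that("trend test matches the expanded-vector oracle on random tables", {
  set.seed(505)
  for (i in 1:1000) {
    tab <- random_2xk_table()
    got <- linear_trend_test(tab$case, tab$control, tab$scores)
    want <- oracle_trend(tab$case, tab$control, tab$scores)
    expect_equal(got$r, want$r, tolerance = 1e-9)
    expect_equal(got$m2, want$m2, tolerance = 1e-9)
    expect_equal(got$p, want$p, tolerance = 1e-9)
  }
})

test_that("swapping groups negates r and preserves m2 and p", {
  set.seed(506)
  for (i in 1:100) {
    tab <- random_2xk_table()
    a <- linear_trend_test(tab$case, tab$control, tab$scores)
    b <- linear_trend_test(tab$control, tab$case, tab$scores)
    expect_equal(a$r, -b$r)
    expect_equal(a$m2, b$m2)
    expect_equal(a$p, b$p)
  }
})

test_that("affine score transforms preserve the test; negative slope flips r", {
  set.seed(507)
  for (i in 1:100) {
    tab <- random_2xk_table()
    a <- linear_trend_test(tab$case, tab$control, tab$scores)
    b <- linear_trend_test(tab$case, tab$control, 3.7 * tab$scores + 11)
    expect_equal(a$r, b$r, tolerance = 1e-12)
    expect_equal(a$m2, b$m2, tolerance = 1e-9)
    # reversing column order with negated scores mirrors the table
    d <- linear_trend_test(rev(tab$case), rev(tab$control), sort(-2 * tab$scores))
    expect_equal(a$r, -d$r, tolerance = 1e-12)
  }
})

test_that("degenerate margins and invalid tables are handled", {
  expect_equal(linear_trend_test(c(0, 0), c(5, 5), c(0, 1))$p, 1)
  expect_equal(linear_trend_test(c(4, 0), c(6, 0), c(0, 1))$p, 1)
  expect_error(linear_trend_test(c(3), c(4), c(0)), "at least 2")
  expect_error(linear_trend_test(c(-1, 2), c(1, 1), c(0, 1)), "negative")
  expect_error(linear_trend_test(c(1, 2), c(1, 1), c(1, 1)), "increasing")
})

test_that("BH adjustment matches the textbook step-up computation", {
  expect_equal(bh_fdr(c(0.001, 0.02, 0.04, 0.9)),
               c(0.004, 0.04, 0.04 * 4 / 3, 0.9))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(508)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("every case-control combination yields one tested pair per gene", {
  counts <- matrix(50L, nrow = 12, ncol = 2,
                   dimnames = list(c(sprintf("case%02d", 1:6),
                                     sprintf("ctrl%02d", 1:6)), NULL))
  prof <- list(g1 = fixture_profile("g1", c(100L, 400L), counts))
  res <- pairwise_switch_scan(prof, sprintf("case%02d", 1:6),
                              sprintf("ctrl%02d", 1:6))
  expect_equal(nrow(res), 36L)
  expect_equal(length(unique(paste(res$case_sample, res$control_sample))), 36L)
  expect_error(pairwise_switch_scan(prof, "nosuch", "ctrl01"), "absent")
  expect_error(pairwise_switch_scan(prof, character(), "ctrl01"), "nonempty")
})

test_that("the per-pair read floor excludes a gene from that pair's FDR family", {
  counts <- matrix(50L, nrow = 4, ncol = 2,
                   dimnames = list(c("caseA", "caseB", "ctrlA", "ctrlB"), NULL))
  counts["caseB", ] <- c(4L, 5L)   # 9 reads < floor of 10
  prof <- list(g1 = fixture_profile("g1", c(100L, 400L), counts))
  res <- pairwise_switch_scan(prof, c("caseA", "caseB"), c("ctrlA", "ctrlB"),
                              min_pair_reads = 10L)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$case_sample == "caseA"))
  res0 <- pairwise_switch_scan(prof, c("caseA", "caseB"), c("ctrlA", "ctrlB"),
                               min_pair_reads = 0L)
  expect_equal(nrow(res0), 4L)
})

test_that("gene calls follow the pair-count threshold and majority direction", {
  mk_results <- function(n_sig, r_signs, gene = "g1") {
    n <- max(n_sig, 12L)
    data.frame(gene_id = gene, case_sample = sprintf("c%02d", seq_len(n)),
               control_sample = "x",
               r = c(r_signs, rep(0.5, n - length(r_signs))),
               m2 = 1, p = 0.001, n = 100L,
               q = c(rep(0.001, n_sig), rep(0.5, n - n_sig)),
               significant = c(rep(TRUE, n_sig), rep(FALSE, n - n_sig)),
               stringsAsFactors = FALSE)
  }
  # 12 significant pairs, all positive r -> called, lengthened
  calls <- aggregate_gene_calls(mk_results(12L, rep(0.8, 12)))
  expect_true(calls$called)
  expect_equal(calls$direction, "lengthened")
  expect_equal(calls$mean_r, 0.8)
  # 9 pairs: below the threshold
  expect_false(aggregate_gene_calls(mk_results(9L, rep(0.8, 9)))$called)
  # 10 pairs, 5 positive / 5 negative: called but ambiguous
  calls3 <- aggregate_gene_calls(mk_results(10L, c(rep(0.5, 5), rep(-0.5, 5))))
  expect_true(calls3$called)
  expect_equal(calls3$direction, "ambiguous")
  # majority negative -> shortened
  calls4 <- aggregate_gene_calls(mk_results(11L, c(rep(-0.5, 6), rep(0.5, 5))))
  expect_equal(calls4$direction, "shortened")
})

test_that("supersite ratios divide proximal by distal pooled counts", {
  counts <- matrix(c(30L, 10L), nrow = 1, dimnames = list("s1", NULL))
  prof <- fixture_profile("g1", c(100L, 400L), counts)
  expect_equal(supersite_ratio(prof, 1L, "s1")$ratio, 3.0)
  counts2 <- matrix(c(0L, 10L), nrow = 1, dimnames = list("s1", NULL))
  expect_equal(supersite_ratio(fixture_profile("g1", c(100L, 400L), counts2),
                               1L, "s1")$ratio, 0)
  counts3 <- matrix(c(10L, 0L), nrow = 1, dimnames = list("s1", NULL))
  res <- supersite_ratio(fixture_profile("g1", c(100L, 400L), counts3), 1L, "s1")
  expect_true(res$infinite)
  expect_error(supersite_ratio(prof, 2L, "s1"), "split_index")
})

test_that("null p-values are approximately uniform", {
  cfg <- simulation_config(n_genes = 150L, switch_fraction = 0,
                           ip_artifact_rate = 0,
                           n_sites_per_gene = c(3L, 3L), seed = 31L)
  sim <- simulate_genome(cfg)
  rec <- simulate_reads(cfg, sim)
  sites <- cluster_cleavage_sites(rec)
  ann <- mark_tandem_sites(annotate_sites(sites, sim$genes, sim$known_ends,
                                          sim$polyadb), sim$genes)
  prof <- build_profiles(ann)
  smp <- sim_sample_names(cfg)
  res <- pairwise_switch_scan(prof, smp$case, smp$control)
  n <- nrow(res)
  ks <- max(abs(sort(res$p) - seq_len(n) / n))
  # 1% critical value of the one-sample KS statistic
  expect_lt(ks, 1.628 / sqrt(n))
})
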