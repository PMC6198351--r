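test_that("identical configs give byte-identical simulated experiments", {
  cfg <- small_sim_config(n_genes = 8L)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  suppressWarnings({
    simulate_apa_experiment(cfg, d1)
    simulate_apa_experiment(cfg, d2)
  })
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("fixed site count is honored and spacing stays in range", {
  cfg <- simulation_config(n_genes = 12L, n_sites_per_gene = c(3L, 3L), seed = 5L)
  sim <- simulate_genome(cfg)
  expect_true(all(sim$truth$n_sites == 3L))
  for (g in sim$truth$gene_id) {
    s <- sim$sites$utr_length[sim$sites$gene_id == g]
    expect_length(s, 3L)
    expect_true(all(diff(s) >= 150L & diff(s) <= 600L))
    expect_true(s[1] >= 150L && s[1] <= 600L)
  }
})

test_that("a_rich_tract_prob = 1 plants a >= 8-nt A tract in every gene body", {
  cfg <- simulation_config(n_genes = 10L, a_rich_tract_prob = 1, seed = 2L)
  sim <- simulate_genome(cfg)
  p <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(sim$genome, p)
  seqc <- paste(readLines(p)[-1], collapse = "")
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    body <- substr(seqc, tr$gene_start + 1L, tr$gene_start + tr$gene_length)
    # the transcript-sense tract reads as T's on the genome for - genes
    pat <- if (tr$strand == "+") "AAAAAAAA" else "TTTTTTTT"
    expect_true(grepl(pat, body, fixed = TRUE), label = tr$gene_id)
  }
})

test_that("null configuration gives identical case and control usage", {
  cfg <- simulation_config(n_genes = 30L, switch_fraction = 0, seed = 7L)
  sim <- simulate_genome(cfg)
  expect_true(all(sim$truth$programmed_direction == "none"))
  expect_identical(sim$truth$usage_control, sim$truth$usage_case)
  for (u in sim$usage) {
    expect_equal(sum(u$control), 1, tolerance = 1e-9)
    expect_identical(u$control, u$case)
  }
})

test_that("degenerate usage (1,0) puts all reads at the proximal site", {
  cfg <- simulation_config(n_genes = 2L, n_sites_per_gene = c(2L, 2L),
                           switch_fraction = 0, ip_artifact_rate = 0, seed = 3L)
  sim <- simulate_genome(cfg)
  for (i in seq_along(sim$usage)) sim$usage[[i]] <- list(control = c(1, 0),
                                                         case = c(1, 0))
  rec <- simulate_reads(cfg, sim)
  for (g in sim$truth$gene_id) {
    prox <- sim$sites$genomic_pos[sim$sites$gene_id == g][1]
    gr <- rec[rec$position >= sim$truth$gene_start[match(g, sim$truth$gene_id)] &
                rec$position < sim$truth$gene_start[match(g, sim$truth$gene_id)] +
                sim$truth$gene_length[match(g, sim$truth$gene_id)], ]
    expect_true(all(abs(gr$position - prox) <= 8L), label = g)
  }
})

test_that("total emitted reads per sample follow the negative binomial scale", {
  cfg <- simulation_config(n_genes = 100L, reads_per_gene_mean = 200,
                           reads_per_gene_dispersion = 10,
                           ip_artifact_rate = 0, switch_fraction = 0, seed = 7L)
  sim <- simulate_genome(cfg)
  rec <- simulate_reads(cfg, sim)
  per_sample <- table(rec$sample_id)
  mu <- 100 * 200
  sd_tot <- sqrt(100 * (200 + 200^2 / 10))
  expect_true(all(abs(as.numeric(per_sample) - mu) <= 3 * sd_tot))
})

test_that("control-group proximal usage is calibrated to the Dirichlet mean", {
  cfg <- simulation_config(n_genes = 120L, n_sites_per_gene = c(2L, 2L),
                           switch_fraction = 0, ip_artifact_rate = 0, seed = 11L)
  sim <- simulate_genome(cfg)
  rec <- simulate_reads(cfg, sim)
  ctrl <- rec[grepl("^ctrl", rec$sample_id), ]
  prox_frac <- vapply(seq_len(nrow(sim$truth)), function(i) {
    tr <- sim$truth[i, ]
    gr <- ctrl$position[ctrl$position >= tr$gene_start &
                          ctrl$position < tr$gene_start + tr$gene_length]
    prox <- sim$sites$genomic_pos[sim$sites$gene_id == tr$gene_id][1]
    mean(abs(gr - prox) <= 8L)
  }, numeric(1))
  # symmetric Dirichlet over 2 sites: expected proximal usage 0.5
  se <- stats::sd(prox_frac) / sqrt(length(prox_frac))
  expect_lt(abs(mean(prox_frac) - 0.5), 2 * se)
})

test_that("artifact windows carry priming motifs and true-site windows never do", {
  cfg <- simulation_config(n_genes = 40L, a_rich_tract_prob = 1,
                           ip_artifact_rate = 5, seed = 13L)
  sim <- simulate_genome(cfg)
  rec <- simulate_reads(cfg, sim)
  w <- downstream_windows(rec, sim$genome)
  art <- rec$origin == "artifact"
  expect_true(all(vapply(w[art], oracle_ip_decision, logical(1))))
  true_w <- unique(w[!art])
  expect_false(any(vapply(true_w, oracle_ip_decision, logical(1))))
})

test_that("the FASTQ emitter writes reads whose 3' end is the cleavage base", {
  cfg <- simulation_config(n_genes = 3L, seed = 21L, ip_artifact_rate = 0)
  sim <- simulate_genome(cfg)
  rec <- head(simulate_reads(cfg, sim), 25)
  p <- tempfile(fileext = ".fastq")
  write_synthetic_fastq(sim$genome, rec, p, read_length = 58L)
  lines <- readLines(p)
  expect_equal(length(lines), 4 * nrow(rec))
  seqs <- lines[seq(2, length(lines), by = 4)]
  seqc <- as.character(sim$genome[["chrS"]])
  for (i in seq_len(nrow(rec))) {
    last <- substr(seqs[i], nchar(seqs[i]), nchar(seqs[i]))
    genomic_base <- substr(seqc, rec$position[i] + 1L, rec$position[i] + 1L)
    expected <- if (rec$strand[i] == "+") genomic_base else
      chartr("ACGT", "TGCA", genomic_base)
    expect_identical(last, expected)
  }
})
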