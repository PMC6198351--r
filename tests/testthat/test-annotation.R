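# shared fixture: the two-gene GTF plus catalogs and hand-placed sites
annot_fixture <- function() {
  gm <- read_gene_models(fixture_gtf())
  known_ends <- data.frame(chrom = "chr1", strand = "+", pos = 1280L,
                           site_name = "gplus", stringsAsFactors = FALSE)
  polyadb <- data.frame(chrom = "chr1", strand = "+", pos = 1100L,
                        site_name = "gplus", stringsAsFactors = FALSE)
  list(gm = gm, known_ends = known_ends, polyadb = polyadb)
}

mk_sites <- function(rep_pos, strand = "+", chrom = "chr1",
                     counts = list(a = 2L)) {
  n <- length(rep_pos)
  df <- data.frame(site_id = sprintf("S%d", seq_len(n)), chrom = chrom,
                   strand = strand, start = as.integer(rep_pos),
                   end = as.integer(rep_pos + 1L),
                   representative_pos = as.integer(rep_pos),
                   total_reads = 2L, stringsAsFactors = FALSE)
  for (s in names(counts)) df[[s]] <- counts[[s]]
  structure(df, samples = names(counts),
            class = c("polya_sites", "data.frame"))
}

test_that("annotation categories resolve by distance and priority", {
  fx <- annot_fixture()
  sites <- mk_sites(c(
    1304,   # 24 nt from the known end at 1280 -> ucsc_known_end
    1124,   # 24 nt from the polyadb entry at 1100 -> known_polyadb
    1200,   # 25+ nt from both, inside the annotated 3'UTR -> novel_3utr
    1400,   # past the gene end (1299), within 1 kb -> novel_downstream_1kb
    800,    # inside the CDS -> novel_cds
    50000)) # nowhere near anything -> novel_intergenic
  # move the boundary cases away from closer features
  ann <- annotate_sites(sites, fx$gm, fx$known_ends, fx$polyadb)
  expect_equal(as.character(ann$category)[c(1, 2, 5, 6)],
               c("ucsc_known_end", "known_polyadb", "novel_cds",
                 "novel_intergenic"))
  # 25 nt past the known end but still in the 3'UTR: one past the threshold
  s2 <- mk_sites(1255)   # |1255-1280|=25 and |1255-1100|>24
  ann2 <- annotate_sites(s2, fx$gm, fx$known_ends, fx$polyadb)
  expect_equal(as.character(ann2$category), "novel_3utr")
  # downstream window on the plus strand
  s3 <- mk_sites(1400)
  ann3 <- annotate_sites(s3, fx$gm, NULL, NULL)
  expect_equal(as.character(ann3$category), "novel_downstream_1kb")
  # more than 1 kb past the end is intergenic
  s4 <- mk_sites(2400)
  expect_equal(as.character(annotate_sites(s4, fx$gm, NULL, NULL)$category),
               "novel_intergenic")
})

test_that("every site gets exactly one category and the partition is complete", {
  fx <- annot_fixture()
  set.seed(404)
  sites <- mk_sites(sample.int(60000, 300))
  ann <- annotate_sites(sites, fx$gm, fx$known_ends, fx$polyadb)
  expect_false(any(is.na(ann$category)))
  expect_equal(sum(table(ann$category)), 300L)
})

test_that("intron and noncoding-gene sites are recognized", {
  p <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "t", "exon", 101, 200, ".", "+", ".",
          'gene_id "spl"; transcript_id "spl.t1";', sep = "\t"),
    paste("chr1", "t", "exon", 501, 700, ".", "+", ".",
          'gene_id "spl"; transcript_id "spl.t1";', sep = "\t"),
    paste("chr1", "t", "CDS", 121, 200, ".", "+", "0",
          'gene_id "spl"; transcript_id "spl.t1";', sep = "\t"),
    paste("chr1", "t", "CDS", 501, 680, ".", "+", "0",
          'gene_id "spl"; transcript_id "spl.t1";', sep = "\t"),
    paste("chr1", "t", "exon", 5001, 5400, ".", "+", ".",
          'gene_id "linc"; transcript_id "linc.t1"; gene_biotype "lincRNA";',
          sep = "\t")), p)
  gm <- read_gene_models(p)
  ann <- annotate_sites(mk_sites(c(300, 5100)), gm, NULL, NULL)
  expect_equal(as.character(ann$category),
               c("novel_intron", "novel_noncoding"))
})

test_that("3'UTR lengths are strand-oriented distances from the stop codon", {
  fx <- annot_fixture()
  expect_equal(utr3_length(1299L, 999L, "+"), 300L)
  expect_equal(utr3_length(1700L, 2000L, "-"), 300L)
  expect_equal(utr3_length(1000L, 999L, "+"), 1L)  # base right after the stop
  # through the annotation path
  sites <- mk_sites(1299)
  ann <- mark_tandem_sites(annotate_sites(sites, fx$gm, NULL, NULL), fx$gm)
  expect_true(ann$is_tandem)
  expect_equal(ann$gene_id, "gplus")
  expect_equal(ann$utr_length, 300L)
  sm <- mk_sites(1700, strand = "-")
  annm <- mark_tandem_sites(annotate_sites(sm, fx$gm, NULL, NULL), fx$gm)
  expect_equal(annm$utr_length, 300L)
  expect_equal(annm$gene_id, "gminus")
})

test_that("tandem marking needs a same-strand 3'UTR overlap", {
  fx <- annot_fixture()
  # gplus 3'UTR is [1000,1300)+; gminus 3'UTR is [1700,2000)-
  ann <- mark_tandem_sites(
    annotate_sites(mk_sites(c(1100, 1800, 300), strand = "+"), fx$gm, NULL, NULL),
    fx$gm)
  expect_equal(ann$is_tandem, c(TRUE, FALSE, FALSE))
  # the same positions on the minus strand flip the assignment
  annm <- mark_tandem_sites(
    annotate_sites(mk_sites(c(1100, 1800), strand = "-"), fx$gm, NULL, NULL),
    fx$gm)
  expect_equal(annm$is_tandem, c(FALSE, TRUE))
  expect_equal(annm$gene_id[2], "gminus")
})

test_that("profiles require two tandem sites and order by UTR length", {
  fx <- annot_fixture()
  sites <- mk_sites(c(1250, 1050), counts = list(a = c(5L, 2L), b = c(1L, 7L)))
  ann <- mark_tandem_sites(annotate_sites(sites, fx$gm, NULL, NULL), fx$gm)
  prof <- build_profiles(ann)
  expect_length(prof, 1L)
  p <- prof[["gplus"]]
  expect_equal(p$utr_lengths, c(51L, 251L))
  expect_equal(unname(p$counts["a", ]), c(2L, 5L))
  expect_equal(unname(p$counts["b", ]), c(7L, 1L))
  # one tandem site only -> no profile
  prof1 <- build_profiles(mark_tandem_sites(
    annotate_sites(mk_sites(1050), fx$gm, NULL, NULL), fx$gm))
  expect_length(prof1, 0L)
})

test_that("duplicate UTR lengths within a gene are merged with a warning", {
  fx <- annot_fixture()
  sites <- mk_sites(c(1050, 1050, 1250),
                    counts = list(a = c(2L, 3L, 4L)))
  ann <- mark_tandem_sites(annotate_sites(sites, fx$gm, NULL, NULL), fx$gm)
  expect_warning(prof <- build_profiles(ann), "merged")
  expect_equal(unname(prof[["gplus"]]$counts["a", ]), c(5L, 4L))
})

test_that("profiles round-trip through the TSV format", {
  fx <- annot_fixture()
  sites <- mk_sites(c(1050, 1250), counts = list(a = c(5L, 2L), b = c(1L, 7L)))
  ann <- mark_tandem_sites(annotate_sites(sites, fx$gm, NULL, NULL), fx$gm)
  prof <- build_profiles(ann)
  p <- tempfile(fileext = ".tsv")
  write_profiles(prof, p)
  back <- read_profiles(p)
  expect_equal(back[["gplus"]]$utr_lengths, prof[["gplus"]]$utr_lengths)
  expect_equal(back[["gplus"]]$counts, prof[["gplus"]]$counts)
})

test_that("known-site fraction is recovered on synthetic data", {
  cfg <- simulation_config(n_genes = 100L, ip_artifact_rate = 0,
                           known_site_fraction = 0.6, seed = 23L)
  sim <- simulate_genome(cfg)
  rec <- simulate_reads(cfg, sim)
  sites <- cluster_cleavage_sites(rec)
  ann <- annotate_sites(sites, sim$genes, sim$known_ends, sim$polyadb)
  known <- ann$category %in% c("ucsc_known_end", "known_polyadb")
  # expected known fraction: distal ends always + 60% of the rest
  n <- nrow(sim$sites)
  n_distal <- nrow(sim$truth)
  p_exp <- (n_distal + 0.6 * (n - n_distal)) / n
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(mean(known) - p_exp), 3 * se)
})
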