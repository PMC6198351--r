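# Small fixtures built in code at test time.

# two single-exon genes, one per strand, with known coordinates:
#   plus:  exon [500,1300), CDS [700,1000)  -> stop codon base 999,
#          3'UTR [1000,1300)
#   minus: exon [1500,2300), CDS [2000,2300) -> stop codon base 2000,
#          3'UTR [1700,2000) after trimming to the exon
fixture_gtf <- function(path = tempfile(fileext = ".gtf")) {
  lines <- c(
    paste("chr1", "test", "exon", 501, 1300, ".", "+", ".",
          'gene_id "gplus"; transcript_id "gplus.t1";', sep = "\t"),
    paste("chr1", "test", "CDS", 701, 1000, ".", "+", "0",
          'gene_id "gplus"; transcript_id "gplus.t1";', sep = "\t"),
    paste("chr1", "test", "exon", 1701, 2300, ".", "-", ".",
          'gene_id "gminus"; transcript_id "gminus.t1";', sep = "\t"),
    paste("chr1", "test", "CDS", 2001, 2300, ".", "-", "0",
          'gene_id "gminus"; transcript_id "gminus.t1";', sep = "\t"))
  writeLines(lines, path)
  path
}

fixture_bed6 <- function(rows, path = tempfile(fileext = ".bed")) {
  writeLines(vapply(rows, function(r)
    paste(r$chrom, r$start, r$end, r$name %||% ".", r$score %||% 0, r$strand,
          sep = "\t"), ""), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# an in-memory genome with a single chromosome from an explicit string
fixture_genome <- function(seq, name = "chrT") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- name
  g
}

# hand-built tandem profile
fixture_profile <- function(gene_id, utr_lengths, counts) {
  structure(list(gene_id = gene_id,
                 site_ids = paste0("S", seq_along(utr_lengths)),
                 utr_lengths = utr_lengths, counts = counts),
            class = "tandem_profile")
}

small_sim_config <- function(...) {
  args <- list(n_genes = 20L, reads_per_gene_mean = 100, seed = 42L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}
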