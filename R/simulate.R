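# Synthetic 3'-end sequencing experiment generator.
#
# Every gene is laid out in transcript orientation as
#   [5' pad][CDS ending in TAA][3'UTR with k tandem poly(A) sites][tail]
# and placed on a single synthetic chromosome, alternating strands.
# Guarantees used by downstream tests:
#   * the 20-nt strand-oriented window downstream of every position a true
#     read can take (site +/- jitter) is free of A (drawn from {C,G,T}), so
#     no true read is ever caught by the internal-priming filter;
#   * internal-priming artifact reads are placed immediately upstream of a
#     15-nt genomic A tract, so their downstream window always contains
#     AAAAAAAA and the filter must remove them;
#   * when a miRNA is planted, its seed core is scrubbed from every 3'UTR
#     and exactly one 8mer site is written into the extended region
#     (between the proximal and distal poly(A) sites) of each programmed
#     lengthened gene.

GENE_PAD5 <- 100L
GENE_CDS_LEN <- 300L
GENE_UTR_TAIL <- 60L
GENE_GAP <- 200L
A_TRACT_LEN <- 15L
SITE_ZONE_UP <- 8L     # jitter radius
SITE_ZONE_DOWN <- 28L  # jitter radius + 20-nt filter window

#' Parameterize a synthetic 3'-end sequencing experiment
#'
#' Defaults describe a 6-versus-6 case-control study with 2-4 tandem
#' poly(A) sites per gene spaced 150-600 nt apart, negative-binomial read
#' counts, and a programmed subset of genes whose proximal-site usage
#' shifts from 0.7 to 0.3 (lengthening in cases) or 0.3 to 0.7
#' (shortening).
#'
#' @param n_genes number of genes.
#' @param n_sites_per_gene integer range (min, max) of tandem sites per gene.
#' @param utr_site_spacing nt range between consecutive sites.
#' @param n_case,n_control group sizes.
#' @param reads_per_gene_mean negative-binomial mean reads per gene per sample.
#' @param reads_per_gene_dispersion NB size parameter (variance =
#'   mean + mean^2/size).
#' @param usage_concentration symmetric Dirichlet concentration for baseline
#'   site-usage vectors.
#' @param switch_fraction fraction of genes programmed to switch.
#' @param switch_high,switch_low proximal-site usage probability in the
#'   high- and low-usage group of a programmed gene.
#' @param switch_direction_mix fraction of programmed genes that lengthen
#'   (the rest shorten).
#' @param ip_artifact_rate Poisson mean of artifact records per gene per
#'   sample (genes carrying an A tract only).
#' @param a_rich_tract_prob probability a gene body carries a 15-nt A tract.
#' @param known_site_fraction fraction of true sites included in the
#'   known-poly(A)-DB catalog.
#' @param plant_mirna mature miRNA sequence (RNA or DNA); if set, one 8mer
#'   seed site is planted in the extended 3'UTR region of every programmed
#'   lengthened gene and chance seed cores are scrubbed from all 3'UTRs.
#' @param read_length read length (nt) used by the optional FASTQ emitter.
#' @param cleavage_jitter half-width (nt) of the uniform cleavage-position
#'   jitter around each true site.
#' @param seed RNG seed; identical configs give byte-identical outputs.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 100L,
                              n_sites_per_gene = c(2L, 4L),
                              utr_site_spacing = c(150L, 600L),
                              n_case = 6L, n_control = 6L,
                              reads_per_gene_mean = 200,
                              reads_per_gene_dispersion = 10,
                              usage_concentration = 5,
                              switch_fraction = 0.1,
                              switch_high = 0.7, switch_low = 0.3,
                              switch_direction_mix = 0.5,
                              ip_artifact_rate = 2,
                              a_rich_tract_prob = 0.2,
                              known_site_fraction = 0.6,
                              plant_mirna = NULL,
                              read_length = 58L,
                              cleavage_jitter = 8L,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_sites_per_gene = as.integer(n_sites_per_gene),
              utr_site_spacing = as.integer(utr_site_spacing),
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              reads_per_gene_mean = reads_per_gene_mean,
              reads_per_gene_dispersion = reads_per_gene_dispersion,
              usage_concentration = usage_concentration,
              switch_fraction = switch_fraction,
              switch_high = switch_high, switch_low = switch_low,
              switch_direction_mix = switch_direction_mix,
              ip_artifact_rate = ip_artifact_rate,
              a_rich_tract_prob = a_rich_tract_prob,
              known_site_fraction = known_site_fraction,
              plant_mirna = plant_mirna,
              read_length = as.integer(read_length),
              cleavage_jitter = as.integer(cleavage_jitter),
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  probs <- c(cfg$switch_fraction, cfg$switch_high, cfg$switch_low,
             cfg$switch_direction_mix, cfg$a_rich_tract_prob,
             cfg$known_site_fraction)
  stopifnot(
    cfg$n_genes >= 1L,
    length(cfg$n_sites_per_gene) == 2L, cfg$n_sites_per_gene[1] >= 2L,
    cfg$n_sites_per_gene[2] >= cfg$n_sites_per_gene[1],
    length(cfg$utr_site_spacing) == 2L, cfg$utr_site_spacing[1] >= 50L,
    cfg$utr_site_spacing[2] >= cfg$utr_site_spacing[1],
    cfg$n_case >= 1L, cfg$n_control >= 1L,
    cfg$reads_per_gene_mean > 0, cfg$reads_per_gene_dispersion > 0,
    cfg$usage_concentration > 0,
    all(probs >= 0 & probs <= 1),
    cfg$ip_artifact_rate >= 0,
    cfg$cleavage_jitter >= 0L,
    cfg$cleavage_jitter <= SITE_ZONE_UP)
  cfg
}

# transcript offset (0-based) -> genomic 0-based position
tx_to_genomic <- function(t, strand, g0, len) {
  if (strand == "+") g0 + t else g0 + len - 1L - t
}

#' Sample names used by the synthetic experiment
#' @param config a [simulation_config()].
#' @return list with character vectors `case` and `control`.
#' @export
sim_sample_names <- function(config) {
  list(case = sprintf("case%02d", seq_len(config$n_case)),
       control = sprintf("ctrl%02d", seq_len(config$n_control)))
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# remove every occurrence of `core` from tx[rng] except occurrences lying
# entirely inside `protect` (transcript 1-based indices); a single base of
# each stray occurrence is rewritten (A -> G, G -> C, else -> G)
scrub_core <- function(tx, rng, core, protect = integer()) {
  nc <- nchar(core)
  for (iter in 1:100) {
    s <- paste(tx[rng], collapse = "")
    hits <- gregexpr(core, s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) break
    changed <- FALSE
    for (h in as.integer(hits)) {
      idx <- rng[1] + h - 1L + 0:(nc - 1L)   # transcript indices of the match
      if (all(idx %in% protect)) next       # the deliberately planted site
      cand <- setdiff(idx, protect)
      if (!length(cand)) next
      a_pos <- cand[tx[cand] == "A"]
      p <- if (length(a_pos)) a_pos[1] else cand[1]
      tx[p] <- if (tx[p] == "A") "G" else if (tx[p] == "G") "C" else "G"
      changed <- TRUE
    }
    if (!changed) break
  }
  tx
}

#' Generate the synthetic genome, gene models and site catalogs
#'
#' @param config a [simulation_config()].
#' @return an `apa_simulation` list: `genome` (DNAStringSet), `genes`
#'   (gene_models), `known_ends` and `polyadb` (site catalogs), `truth`
#'   (per-gene truth table), `sites` (long table of true sites), `usage`
#'   (per-gene control/case usage vectors) and the config.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  k_rng <- config$n_sites_per_gene
  sp_rng <- config$utr_site_spacing

  n_prog <- as.integer(round(config$switch_fraction * n))
  prog_idx <- if (n_prog > 0) sort(sample.int(n, n_prog)) else integer()
  n_len <- as.integer(round(config$switch_direction_mix * n_prog))
  len_idx <- if (n_len > 0) sort(sample(prog_idx, n_len)) else integer()
  direction <- rep("none", n)
  direction[prog_idx] <- "shortened"
  direction[len_idx] <- "lengthened"

  plant_patterns <- NULL
  core <- NULL
  if (!is.null(config$plant_mirna)) {
    plant_patterns <- seed_patterns(config$plant_mirna)
    core <- substr(plant_patterns[["7mer-A1"]], 1L, 6L)  # revcomp of seed 2-7
  }

  gene_seqs <- character(n)
  strands <- ifelse(seq_len(n) %% 2L == 1L, "+", "-")
  lens <- integer(n)
  truth_rows <- vector("list", n)
  site_rows <- vector("list", n)
  usage <- vector("list", n)
  bases <- c("A", "C", "G", "T")
  utr0 <- GENE_PAD5 + GENE_CDS_LEN        # 0-based transcript offset of first UTR base
  stop0 <- utr0 - 1L                      # last base of the stop codon

  for (i in seq_len(n)) {
    k <- if (k_rng[1] == k_rng[2]) k_rng[1] else sample(k_rng[1]:k_rng[2], 1L)
    spac <- if (sp_rng[1] == sp_rng[2]) rep(sp_rng[1], k) else
      sample(sp_rng[1]:sp_rng[2], k, replace = TRUE)
    s <- cumsum(spac)                     # site utr_lengths (nt from stop codon)
    L <- utr0 + s[k] + GENE_UTR_TAIL
    tx <- sample(bases, L, replace = TRUE)
    tx[(utr0 - 2L):utr0] <- c("T", "A", "A")  # stop codon (1-based idx utr0-2..utr0)
    # A-free zones covering every jittered read's downstream filter window
    site_tx0 <- stop0 + s                 # 0-based transcript offset of each site
    for (t0 in site_tx0) {
      zone <- (t0 - SITE_ZONE_UP):(t0 + SITE_ZONE_DOWN) + 1L  # 1-based
      tx[zone] <- sample(c("C", "G", "T"), length(zone), replace = TRUE)
    }
    # internal-priming A tract in the CDS, with its artifact cleavage base
    has_tract <- stats::runif(1) < config$a_rich_tract_prob
    tract_idx <- integer()
    artifact_tx0 <- NA_integer_
    if (has_tract) {
      t_start <- GENE_PAD5 + 50L          # 0-based
      tract_idx <- (t_start:(t_start + A_TRACT_LEN - 1L)) + 1L
      tx[tract_idx] <- "A"
      artifact_tx0 <- t_start - 1L
    }
    # optional miRNA seed planting / scrubbing over the whole 3'UTR
    plant_tx0 <- NA_integer_
    if (!is.null(core)) {
      utr_rng <- (utr0 + 1L):L            # 1-based indices of UTR bases
      tx <- scrub_core(tx, utr_rng, core, protect = tract_idx)
      if (direction[i] == "lengthened") {
        u_plant <- s[1] + (s[2] - s[1]) %/% 2L   # utr offset of 8mer start
        plant_tx0 <- stop0 + u_plant
        p8 <- strsplit(plant_patterns[["8mer"]], "")[[1]]
        plant_idx <- plant_tx0 + seq_along(p8)   # 1-based (tx0+1 .. tx0+8)
        tx[plant_idx] <- p8
        tx <- scrub_core(tx, utr_rng, core, protect = c(tract_idx, plant_idx))
      }
    }
    gene_seqs[i] <- paste(tx, collapse = "")
    lens[i] <- L

    base_u <- stats::rgamma(k, shape = config$usage_concentration)
    base_u <- base_u / sum(base_u)
    if (direction[i] == "none") {
      uc <- ua <- base_u
    } else {
      distal_w <- if (k > 1L) base_u[-1] / sum(base_u[-1]) else numeric()
      hi <- c(config$switch_high, (1 - config$switch_high) * distal_w)
      lo <- c(config$switch_low, (1 - config$switch_low) * distal_w)
      if (direction[i] == "lengthened") { uc <- hi; ua <- lo } else { uc <- lo; ua <- hi }
    }
    usage[[i]] <- list(control = uc, case = ua)

    truth_rows[[i]] <- data.frame(
      gene_id = sprintf("G%04d", i), strand = strands[i], n_sites = k,
      programmed_direction = direction[i],
      utr_lengths = paste(s, collapse = ","),
      usage_control = paste(signif(uc, 8), collapse = ","),
      usage_case = paste(signif(ua, 8), collapse = ","),
      has_tract = has_tract, artifact_tx_offset = artifact_tx0,
      plant_tx_offset = plant_tx0, stringsAsFactors = FALSE)
    site_rows[[i]] <- data.frame(
      gene_id = sprintf("G%04d", i), site_index = seq_len(k),
      utr_length = s, tx_offset = site_tx0, stringsAsFactors = FALSE)
  }

  # lay the genes on one chromosome, alternating strands, GENE_GAP apart
  gap_seq <- vapply(seq_len(n + 1L), function(j)
    paste(sample(bases, GENE_GAP, replace = TRUE), collapse = ""), "")
  g0 <- GENE_GAP + cumsum(c(0L, head(lens, -1) + GENE_GAP))
  placed <- ifelse(strands == "+", gene_seqs, revcomp_chr(gene_seqs))
  chrom_seq <- paste0(paste0(gap_seq[seq_len(n)], placed, collapse = ""),
                      gap_seq[n + 1L])
  genome <- Biostrings::DNAStringSet(chrom_seq)
  names(genome) <- "chrS"

  truth <- do.call(rbind, truth_rows)
  sites <- do.call(rbind, site_rows)
  gi <- match(sites$gene_id, truth$gene_id)
  sites$chrom <- "chrS"
  sites$strand <- truth$strand[gi]
  sites$genomic_pos <- mapply(tx_to_genomic, sites$tx_offset, sites$strand,
                              g0[gi], lens[gi])
  truth$gene_start <- g0
  truth$gene_length <- lens
  truth$artifact_pos <- ifelse(
    truth$has_tract,
    mapply(tx_to_genomic, truth$artifact_tx_offset, truth$strand, g0, lens),
    NA_integer_)
  truth$stop_codon_pos <- mapply(tx_to_genomic, stop0, truth$strand, g0, lens)

  gm <- sim_gene_models(truth, g0, lens, stop0, utr0)
  distal <- sites[!duplicated(sites$gene_id, fromLast = TRUE), ]
  known_ends <- data.frame(chrom = "chrS", strand = distal$strand,
                           pos = distal$genomic_pos, site_name = distal$gene_id,
                           stringsAsFactors = FALSE)
  in_db <- stats::runif(nrow(sites)) < config$known_site_fraction
  polyadb <- data.frame(chrom = "chrS", strand = sites$strand[in_db],
                        pos = sites$genomic_pos[in_db],
                        site_name = sites$gene_id[in_db],
                        stringsAsFactors = FALSE)

  out <- list(genome = genome, genes = gm, known_ends = known_ends,
              polyadb = polyadb, truth = truth, sites = sites,
              usage = usage, config = config)
  class(out) <- "apa_simulation"
  out
}

sim_gene_models <- function(truth, g0, lens, stop0, utr0) {
  n <- nrow(truth)
  plus <- truth$strand == "+"
  genes <- data.frame(
    gene_id = truth$gene_id, chrom = "chrS",
    start = g0, end = g0 + lens, strand = truth$strand,
    stop_codon_pos = truth$stop_codon_pos,
    terminal_end = ifelse(plus, g0 + lens - 1L, g0),
    is_noncoding = FALSE, stringsAsFactors = FALSE)
  utr3 <- data.frame(
    gene_id = truth$gene_id, chrom = "chrS",
    start = ifelse(plus, truth$stop_codon_pos + 1L, g0),
    end = ifelse(plus, g0 + lens, truth$stop_codon_pos),
    strand = truth$strand, stringsAsFactors = FALSE)
  cds <- data.frame(
    gene_id = truth$gene_id, chrom = "chrS",
    start = ifelse(plus, g0 + GENE_PAD5, g0 + lens - utr0),
    end = ifelse(plus, g0 + utr0, g0 + lens - GENE_PAD5),
    strand = truth$strand, stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = truth$gene_id, chrom = "chrS", start = g0, end = g0 + lens,
    strand = truth$strand, stringsAsFactors = FALSE)
  new_gene_models(genes, utr3, cds, exons, empty_iv())
}

#' Simulate per-sample cleavage records from a synthetic genome
#'
#' Reads per gene per sample are negative-binomial, allocated to the gene's
#' sites by a multinomial draw from the group-specific usage vector, and
#' jittered uniformly within +/- `cleavage_jitter` nt of the site. Genes
#' carrying an A tract additionally emit Poisson-distributed
#' internal-priming artifact records immediately upstream of the tract.
#'
#' @param config the [simulation_config()] used for [simulate_genome()].
#' @param sim the `apa_simulation` object.
#' @return data frame of cleavage records (chrom, strand, position,
#'   sample_id) with an extra `origin` column ("true" or "artifact").
#' @export
simulate_reads <- function(config, sim) {
  stopifnot(inherits(sim, "apa_simulation"))
  set.seed((config$seed %% 1000000000L) + 77003L)
  samples <- sim_sample_names(config)
  truth <- sim$truth
  n <- nrow(truth)
  jit <- config$cleavage_jitter
  site_off <- split(sim$sites$tx_offset, sim$sites$gene_id)[truth$gene_id]
  out <- vector("list", 0L)
  for (grp in c("control", "case")) {
    for (smp in samples[[if (grp == "case") "case" else "control"]]) {
      n_reads <- stats::rnbinom(n, mu = config$reads_per_gene_mean,
                                size = config$reads_per_gene_dispersion)
      for (i in seq_len(n)) {
        if (n_reads[i] > 0L) {
          alloc <- as.integer(stats::rmultinom(1L, n_reads[i], sim$usage[[i]][[grp]]))
          tx <- rep(site_off[[i]], alloc)
          if (jit > 0L) tx <- tx + sample((-jit):jit, length(tx), replace = TRUE)
          pos <- if (truth$strand[i] == "+") truth$gene_start[i] + tx else
            truth$gene_start[i] + truth$gene_length[i] - 1L - tx
          out[[length(out) + 1L]] <- data.table::data.table(
            chrom = "chrS", strand = truth$strand[i], position = pos,
            sample_id = smp, origin = "true")
        }
        if (truth$has_tract[i] && config$ip_artifact_rate > 0) {
          na <- stats::rpois(1L, config$ip_artifact_rate)
          if (na > 0L) out[[length(out) + 1L]] <- data.table::data.table(
            chrom = "chrS", strand = truth$strand[i],
            position = rep(truth$artifact_pos[i], na),
            sample_id = smp, origin = "artifact")
        }
      }
    }
  }
  if (!length(out))
    return(cbind(new_cleavage_records(character(), character(), integer(),
                                      character()),
                 origin = character()))
  as.data.frame(data.table::rbindlist(out))
}

#' Run the generator and write every artifact to disk
#'
#' Writes genome FASTA, gene models (GTF and BED12), known-end and
#' poly(A)-DB catalogs (BED), one cleavage BED per sample, the truth table
#' (TSV) and the resolved config (YAML). Output is byte-identical for
#' identical configs.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @param fastq also emit synthetic FASTQ reads per sample.
#' @return the `apa_simulation` object, with the emitted records in
#'   `$records` and file paths in `$files`.
#' @export
simulate_apa_experiment <- function(config, out_dir, fastq = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(config)
  records <- simulate_reads(config, sim)
  files <- list(
    genome = file.path(out_dir, "genome.fa"),
    gtf = file.path(out_dir, "genes.gtf"),
    bed12 = file.path(out_dir, "genes.bed12"),
    known_ends = file.path(out_dir, "known_ends.bed"),
    polyadb = file.path(out_dir, "polyadb.bed"),
    truth = file.path(out_dir, "truth.tsv"),
    config = file.path(out_dir, "sim_config.yaml"))
  Biostrings::writeXStringSet(sim$genome, files$genome)
  write_gene_models_gtf(sim$genes, files$gtf)
  write_gene_models_bed12(sim$genes, files$bed12)
  write_site_catalog(sim$known_ends, files$known_ends)
  write_site_catalog(sim$polyadb, files$polyadb)
  write_tsv(sim$truth, files$truth)
  cfg <- unclass(config)
  cfg$plant_mirna <- if (is.null(cfg$plant_mirna)) "" else cfg$plant_mirna
  yaml::write_yaml(cfg, files$config)
  files$reads <- character()
  for (smp in unlist(sim_sample_names(config))) {
    p <- file.path(out_dir, paste0("reads_", smp, ".bed"))
    write_cleavage_records(records[records$sample_id == smp, , drop = FALSE], p)
    files$reads[smp] <- p
    if (fastq) {
      fq <- file.path(out_dir, paste0("reads_", smp, ".fastq"))
      write_synthetic_fastq(sim$genome,
                            records[records$sample_id == smp, , drop = FALSE],
                            fq, read_length = config$read_length)
      files$fastq[smp] <- fq
    }
  }
  sim$records <- records
  sim$files <- files
  sim
}

#' Emit synthetic FASTQ reads ending at each cleavage position
#'
#' Each read is the `read_length`-nt strand-oriented genomic sequence whose
#' 3'-most base is the record's cleavage position (truncated at contig
#' edges), with uniform quality.
#'
#' @param genome DNAStringSet.
#' @param records cleavage record data frame.
#' @param path output FASTQ file.
#' @param read_length read length in nt.
#' @export
write_synthetic_fastq <- function(genome, records, path, read_length = 58L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in unique(records$chrom)) {
    seqc <- as.character(genome[[chrom]])
    clen <- nchar(seqc)
    rec <- records[records$chrom == chrom, , drop = FALSE]
    plus <- rec$strand == "+"
    s <- ifelse(plus, pmax(rec$position - read_length + 2L, 1L), rec$position + 1L)
    e <- ifelse(plus, rec$position + 1L, pmin(rec$position + read_length, clen))
    seqs <- substring(seqc, s, e)
    if (any(!plus)) seqs[!plus] <- revcomp_chr(seqs[!plus])
    ids <- sprintf("@%s_%s_%d_%s", rec$sample_id, chrom, rec$position, rec$strand)
    writeLines(paste(ids, seqs, "+", strvapply_qual(seqs), sep = "\n"), con)
  }
  invisible(path)
}

strvapply_qual <- function(seqs) {
  vapply(nchar(seqs), function(n) paste(rep("I", n), collapse = ""), "")
}
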