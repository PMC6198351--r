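# miRNA seed-match scanning of common vs extended 3'UTR regions of
# switching genes, with the three canonical site types:
#   7mer-m8: reverse complement of miRNA positions 2-8
#   8mer:    7mer-m8 followed by A
#   7mer-A1: reverse complement of positions 2-7 followed by A
# Matches are counted on the DNA alphabet, overlapping occurrences
# included; at one locus only the longest matching type is reported (an
# 8mer suppresses the 7mers it contains).

#' Read mature miRNA sequences from FASTA
#'
#' RNA sequences are transliterated to DNA (U to T).
#'
#' @param path FASTA file of mature miRNA sequences.
#' @return named character vector of DNA-alphabet sequences.
#' @export
read_mirnas <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- chartr("Uu", "Tt", toupper(as.character(ss)))
  stats::setNames(seqs, sub("\\s.*$", "", names(ss)))
}

#' Seed-match patterns for a mature miRNA
#'
#' @param mirna mature miRNA sequence (RNA or DNA alphabet), length >= 8.
#' @return named character vector with elements `8mer`, `7mer-m8` and
#'   `7mer-A1` (DNA-alphabet target-site patterns).
#' @export
seed_patterns <- function(mirna) {
  s <- chartr("Uu", "Tt", toupper(mirna))
  if (nchar(s) < 8L) stop("miRNA sequence must be at least 8 nt")
  if (grepl("[^ACGT]", s)) stop("miRNA sequence has non-nucleotide characters")
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  m8 <- rc(substr(s, 2L, 8L))
  c(`8mer` = paste0(m8, "A"),
    `7mer-m8` = m8,
    `7mer-A1` = paste0(rc(substr(s, 2L, 7L)), "A"))
}

# all (overlapping) 0-based match offsets of a fixed pattern
match_offsets <- function(pattern, subject) {
  if (!nzchar(subject) || nchar(subject) < nchar(pattern)) return(integer())
  hits <- gregexpr(sprintf("(?=%s)", pattern), subject, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer())
  as.integer(hits) - 1L
}

# strand-oriented 3'UTR sequence, utr positions 1..len (base after stop
# codon first)
extract_utr_sequence <- function(genome, gene, len) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  seqc <- as.character(genome[[gene$chrom]])
  stop0 <- gene$stop_codon_pos
  if (gene$strand == "+") {
    s1 <- stop0 + 2L; e1 <- stop0 + 1L + len      # 1-based
    if (e1 > nchar(seqc)) stop("3'UTR region off contig for ", gene$gene_id)
    substring(seqc, s1, e1)
  } else {
    s1 <- stop0 - len + 1L; e1 <- stop0           # 1-based
    if (s1 < 1L) stop("3'UTR region off contig for ", gene$gene_id)
    revcomp_chr(substring(seqc, s1, e1))
  }
}

#' Scan a gene's 3'UTR for miRNA seed sites, split by region
#'
#' The scanned sequence runs from the base after the stop codon to the
#' distal poly(A) site (inclusive). The common region ends at the proximal
#' site (inclusive); the extended region is the remainder. A hit belongs
#' to the region containing its 5'-most base. At one locus only the
#' longest matching site type is reported.
#'
#' @param genome DNAStringSet or FASTA path.
#' @param gene one row of `gene_models$genes` (or an equivalent list with
#'   gene_id, chrom, strand, stop_codon_pos).
#' @param proximal_len,distal_len 3'UTR lengths (nt) of the proximal and
#'   distal poly(A) sites; `proximal_len < distal_len`.
#' @param mirnas named character vector of mature miRNA sequences.
#' @return data frame: mirna_id, gene_id, site_type, position (0-based
#'   offset in the 3'UTR), region ("common"/"extended").
#' @export
scan_utr_regions <- function(genome, gene, proximal_len, distal_len, mirnas) {
  if (!(proximal_len < distal_len))
    stop("proximal 3'UTR length must be smaller than distal")
  utr <- extract_utr_sequence(genome, gene, distal_len)
  out <- list()
  for (mid in names(mirnas)) {
    pat <- seed_patterns(mirnas[[mid]])
    o8 <- match_offsets(pat[["8mer"]], utr)
    hits <- data.frame(site_type = rep("8mer", length(o8)), position = o8,
                       len = rep(8L, length(o8)), stringsAsFactors = FALSE)
    for (ty in c("7mer-m8", "7mer-A1")) {
      o7 <- match_offsets(pat[[ty]], utr)
      # subsumption: drop 7mers contained in an 8mer locus
      if (length(o8) && length(o7)) {
        inside <- vapply(o7, function(o)
          any(o >= o8 & (o + 7L) <= (o8 + 8L)), logical(1))
        o7 <- o7[!inside]
      }
      hits <- rbind(hits, data.frame(site_type = rep(ty, length(o7)),
                                     position = o7, len = rep(7L, length(o7)),
                                     stringsAsFactors = FALSE))
    }
    if (nrow(hits) == 0L) next
    hits$mirna_id <- mid
    out[[length(out) + 1L]] <- hits
  }
  if (!length(out)) {
    return(data.frame(mirna_id = character(), gene_id = character(),
                      site_type = character(), position = integer(),
                      region = character(), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  # 5'-most base at 0-based offset o has utr position o + 1
  hits$region <- ifelse(hits$position < proximal_len, "common", "extended")
  data.frame(mirna_id = hits$mirna_id, gene_id = gene$gene_id,
             site_type = hits$site_type, position = hits$position,
             region = hits$region, stringsAsFactors = FALSE)
}

#' Scan all called switching genes for miRNA seed sites
#'
#' For every called gene with a lengthened or shortened direction, scans
#' its 3'UTR from the shortest to the longest tandem isoform.
#'
#' @param genome DNAStringSet or FASTA path.
#' @param genes a `gene_models` object.
#' @param profiles a `tandem_profiles` list.
#' @param calls data frame from [aggregate_gene_calls()].
#' @param mirnas named character vector of mature miRNA sequences.
#' @return combined hit data frame (see [scan_utr_regions()]).
#' @export
scan_switch_genes <- function(genome, genes, profiles, calls, mirnas) {
  sel <- calls[calls$called & calls$direction %in% c("lengthened", "shortened"), ,
               drop = FALSE]
  out <- list()
  for (g in sel$gene_id) {
    p <- profiles[[g]]
    if (is.null(p)) next
    grow <- genes$genes[genes$genes$gene_id == g, , drop = FALSE]
    if (nrow(grow) == 0L) next
    out[[length(out) + 1L]] <- scan_utr_regions(
      genome, as.list(grow[1, ]), min(p$utr_lengths), max(p$utr_lengths), mirnas)
  }
  if (!length(out)) {
    return(data.frame(mirna_id = character(), gene_id = character(),
                      site_type = character(), position = integer(),
                      region = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' miRNA target sites gained and lost through 3'UTR switching
#'
#' Lengthened genes gain their extended-region hits; shortened genes lose
#' theirs; ambiguous-direction genes are excluded.
#'
#' @param hits hit data frame from [scan_switch_genes()].
#' @param calls data frame from [aggregate_gene_calls()].
#' @return list with `per_gene` (gene_id, direction, extended_hits,
#'   gained, lost) and `totals` (named vector gained/lost).
#' @export
mirna_gain_loss <- function(hits, calls) {
  sel <- calls[calls$called & calls$direction %in% c("lengthened", "shortened"), ,
               drop = FALSE]
  ext <- hits[hits$region == "extended", , drop = FALSE]
  n_ext <- vapply(sel$gene_id, function(g) sum(ext$gene_id == g), integer(1))
  per_gene <- data.frame(
    gene_id = sel$gene_id, direction = sel$direction, extended_hits = n_ext,
    gained = ifelse(sel$direction == "lengthened", n_ext, 0L),
    lost = ifelse(sel$direction == "shortened", n_ext, 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_gene = per_gene,
       totals = c(gained = sum(per_gene$gained), lost = sum(per_gene$lost)))
}
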