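# Read-level filters: raw-read trimming (convenience path for FASTQ
# input), the internal-priming genomic filter, and singleton-site removal.

#' Trim raw 3'-end reads
#'
#' Strips a trailing run of >= 8 A's (the oligo-dT anchor remnant) and
#' rejects reads shorter than `min_length` after trimming or with more
#' than `max_n_frac` N's.
#'
#' @param reads character vector over the alphabet ACGTN.
#' @param min_length minimum accepted length after trimming.
#' @param min_tail_a minimum trailing-A run length that is stripped.
#' @param max_n_frac maximum tolerated fraction of N's.
#' @return data frame with columns `read` (trimmed) and `accepted`.
#' @export
trim_raw_reads <- function(reads, min_length = 20L, min_tail_a = 8L,
                           max_n_frac = 0.10) {
  reads <- toupper(reads)
  if (any(grepl("[^ACGTN]", reads)))
    stop("non-nucleotide characters in reads")
  tail_re <- sprintf("A{%d,}$", min_tail_a)
  trimmed <- sub(tail_re, "", reads)
  n_count <- nchar(trimmed) - nchar(gsub("N", "", trimmed, fixed = TRUE))
  len <- nchar(trimmed)
  accepted <- len >= min_length & (len == 0L | n_count / pmax(len, 1L) <= max_n_frac)
  data.frame(read = trimmed, accepted = accepted, stringsAsFactors = FALSE)
}

# internal-priming motif decision on ready-made window strings
# (strand-oriented, 5'->3'); TRUE means the window shows priming evidence
ip_window_is_artifact <- function(windows) {
  a_count <- nchar(windows) - nchar(gsub("A", "", windows, fixed = TRUE))
  grepl("AAAAAAAA", windows, fixed = TRUE) |
    grepl("GA{4,}GA{3,}G", windows) |
    a_count > 12L
}

#' Extract strand-oriented downstream windows for cleavage records
#'
#' For a record cleaved at 0-based position p, the window covers downstream
#' offsets `window[1]..window[2]` in strand orientation: genomic
#' `p+window[1] .. p+window[2]` on `+`, `p-window[2] .. p-window[1]`
#' reverse-complemented on `-`. Windows truncated at contig edges are
#' returned as-is; records whose window lies entirely off-contig get an
#' empty string.
#'
#' @param records cleavage record data frame.
#' @param genome DNAStringSet (or path to a FASTA file).
#' @param window integer pair of downstream offsets (default 1..20).
#' @return character vector of windows, one per record.
#' @export
downstream_windows <- function(records, genome, window = c(1L, 20L)) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  out <- character(nrow(records))
  for (chrom in unique(records$chrom)) {
    if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
    seqc <- as.character(genome[[chrom]])
    clen <- nchar(seqc)
    idx <- which(records$chrom == chrom)
    p <- records$position[idx]
    plus <- records$strand[idx] == "+"
    s0 <- ifelse(plus, p + window[1], p - window[2])   # 0-based inclusive
    e0 <- ifelse(plus, p + window[2], p - window[1])
    s1 <- pmax(s0 + 1L, 1L)                            # 1-based, clamped
    e1 <- pmin(e0 + 1L, clen)
    w <- ifelse(s1 <= e1, substring(seqc, s1, e1), "")
    minus <- which(!plus & nzchar(w))
    if (length(minus)) w[minus] <- revcomp_chr(w[minus])
    out[idx] <- w
  }
  out
}

#' Internal-priming filter on cleavage records
#'
#' A record is an internal-priming artifact if the genomic sequence 1-20 nt
#' downstream of its cleavage position (strand-oriented) contains
#' `AAAAAAAA`, matches `GA{4,}GA{3,}G`, or contains more than 12 A's in
#' total. Records whose window cannot be extracted at all (off-contig) are
#' kept with a warning.
#'
#' @param records cleavage record data frame.
#' @param genome DNAStringSet or FASTA path.
#' @param window downstream offset pair (default 1..20).
#' @return logical vector, TRUE where the record is KEPT.
#' @export
internal_priming_keep <- function(records, genome, window = c(1L, 20L)) {
  if (nrow(records) == 0L) return(logical(0))
  w <- downstream_windows(records, genome, window)
  empty <- !nzchar(w)
  if (any(empty))
    warning(sum(empty), " record(s) with no extractable downstream window; kept")
  keep <- !ip_window_is_artifact(w)
  keep[empty] <- TRUE
  keep
}

#' Split cleavage records by the internal-priming filter
#'
#' @inheritParams internal_priming_keep
#' @return list with elements `kept` and `filtered` (record data frames)
#'   and the logical `keep` vector.
#' @export
filter_internal_priming <- function(records, genome, window = c(1L, 20L)) {
  keep <- internal_priming_keep(records, genome, window)
  list(kept = records[keep, , drop = FALSE],
       filtered = records[!keep, , drop = FALSE],
       keep = keep)
}

#' Drop poly(A) sites below the read-support threshold
#'
#' Sites supported by fewer than `min_reads` pooled reads (all samples
#' together) are removed; with the default this is singleton removal.
#'
#' @param sites a `polya_sites` table.
#' @param min_reads minimum pooled read count.
#' @return the filtered `polya_sites` table.
#' @export
remove_singleton_sites <- function(sites, min_reads = 2L) {
  keep <- sites$total_reads >= min_reads
  out <- sites[keep, , drop = FALSE]
  attr(out, "samples") <- attr(sites, "samples")
  class(out) <- class(sites)
  out
}
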