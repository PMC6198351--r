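# Cleavage records: one row per sequenced read 3' end. `position` is the
# 0-based genomic coordinate of the base at which the transcript is cleaved
# (the last transcribed base). For a BED interval this is end-1 on the +
# strand and start on the - strand, so records may be stored either as
# full-read intervals or as 1-bp intervals.

new_cleavage_records <- function(chrom, strand, position, sample_id) {
  data.frame(chrom = as.character(chrom), strand = as.character(strand),
             position = as.integer(position),
             sample_id = as.character(sample_id), stringsAsFactors = FALSE)
}

#' Read cleavage records from a BED file
#'
#' The cleavage position of each record is the strand-oriented 3'-most
#' aligned base: interval end - 1 on `+`, interval start on `-`.
#'
#' @param path BED file with a strand column (BED6).
#' @param sample_id sample identity attached to every record.
#' @return data frame with columns chrom, strand, position, sample_id.
#' @export
read_cleavage_records <- function(path, sample_id) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0)
    return(new_cleavage_records(character(), character(), integer(), character()))
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop("BED record without strand in ", path, " (strand column required)")
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  if (any(end0 <= start0))
    stop("zero-length interval in ", path)
  pos <- ifelse(strand == "+", end0 - 1L, start0)
  new_cleavage_records(as.character(GenomicRanges::seqnames(gr)),
                       strand, pos, sample_id)
}

#' Write cleavage records as BED6 (1-bp intervals)
#'
#' Re-reading the file with [read_cleavage_records()] reproduces positions
#' and strands exactly. The name column carries the sample id.
#'
#' @param records cleavage record data frame.
#' @param path output BED file.
#' @export
write_cleavage_records <- function(records, path) {
  gr <- GenomicRanges::GRanges(
    records$chrom,
    IRanges::IRanges(records$position + 1L, records$position + 1L),
    strand = records$strand)
  S4Vectors::mcols(gr)$name <- records$sample_id
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a poly(A) site catalog from BED
#'
#' Each entry is reduced to its strand-oriented 3' position, the same
#' convention as cleavage records.
#'
#' @param path BED6 file; the name column, if informative, is kept as
#'   `site_name`.
#' @return data frame chrom, strand, pos, site_name.
#' @export
read_site_catalog <- function(path) {
  recs <- read_cleavage_records(path, sample_id = "catalog")
  gr <- rtracklayer::import(path, format = "bed")
  nm <- if (!is.null(S4Vectors::mcols(gr)$name)) as.character(S4Vectors::mcols(gr)$name)
        else rep(NA_character_, length(gr))
  data.frame(chrom = recs$chrom, strand = recs$strand, pos = recs$position,
             site_name = nm, stringsAsFactors = FALSE)
}

write_site_catalog <- function(cat, path) {
  gr <- GenomicRanges::GRanges(
    cat$chrom, IRanges::IRanges(cat$pos + 1L, cat$pos + 1L), strand = cat$strand)
  S4Vectors::mcols(gr)$name <- if (!is.null(cat$site_name)) cat$site_name else "."
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

# plain TSV helpers shared by the stage writers
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA"))
}
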