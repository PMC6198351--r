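# 24-nt single-linkage clustering of cleavage positions into poly(A) sites.

#' Cluster cleavage records into poly(A) sites
#'
#' Single-linkage chaining per (chromosome, strand): consecutive sorted
#' cleavage positions at most `max_gap` nt apart join one cluster, so the
#' "within 24 nt of each other" relation is applied transitively and a
#' cluster may span more than 24 nt. Clusters with at least `min_reads`
#' pooled reads become poly(A) sites; with the default of 2 this removes
#' singleton sites. The representative position is the modal cleavage
#' position, ties broken toward the strand-oriented proximal (5') end.
#'
#' @param records cleavage record data frame (chrom, strand, position,
#'   sample_id).
#' @param max_gap maximum joining gap in nt.
#' @param min_reads minimum pooled read support.
#' @param samples sample ordering for the count columns; defaults to the
#'   sorted samples present.
#' @return a `polya_sites` data frame: site_id, chrom, strand, start, end
#'   (0-based half-open span of member positions), representative_pos,
#'   total_reads, then one count column per sample (attribute `samples`).
#' @export
cluster_cleavage_sites <- function(records, max_gap = 24L, min_reads = 2L,
                                   samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(records$sample_id))
  samples <- as.character(unname(samples))
  if (nrow(records) && !all(records$sample_id %in% samples))
    stop("records carry sample ids absent from `samples`")
  dt <- data.table::as.data.table(records[, c("chrom", "strand", "position",
                                              "sample_id")])
  if (nrow(dt) == 0L) return(empty_polya_sites(samples))
  data.table::setorder(dt, chrom, strand, position)
  dt[, cl := cumsum(c(1L, as.integer(diff(position) > max_gap))),
     by = .(chrom, strand)]
  per <- dt[, {
    tab <- table(position)
    m <- as.integer(names(tab)[tab == max(tab)])
    rep_pos <- if (strand[1] == "+") min(m) else max(m)
    c(list(start = min(position), end = max(position) + 1L,
           representative_pos = rep_pos, total_reads = .N),
      as.list(stats::setNames(vapply(samples, function(s) sum(sample_id == s),
                                     integer(1), USE.NAMES = FALSE), samples)))
  }, by = .(chrom, strand, cl)]
  per <- per[total_reads >= min_reads]
  data.table::setorder(per, chrom, start, strand)
  out <- as.data.frame(per[, !"cl"])
  out <- cbind(site_id = sprintf("PAS%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  structure(out, samples = samples, class = c("polya_sites", "data.frame"))
}

empty_polya_sites <- function(samples) {
  out <- data.frame(site_id = character(), chrom = character(),
                    strand = character(), start = integer(), end = integer(),
                    representative_pos = integer(), total_reads = integer(),
                    stringsAsFactors = FALSE)
  for (s in samples) out[[s]] <- integer()
  structure(out, samples = samples, class = c("polya_sites", "data.frame"))
}

#' Samples-by-sites count matrix
#'
#' @param sites a `polya_sites` (or annotated sites) table.
#' @param samples ordered sample identifiers; must all be known to the
#'   table.
#' @return integer matrix, rows = samples, columns = sites (site_id).
#' @export
site_count_matrix <- function(sites, samples = attr(sites, "samples")) {
  known <- attr(sites, "samples")
  bad <- setdiff(samples, known)
  if (length(bad)) stop("unknown sample id(s): ", paste(bad, collapse = ", "))
  m <- t(as.matrix(as.data.frame(sites)[, samples, drop = FALSE]))
  storage.mode(m) <- "integer"
  rownames(m) <- samples
  colnames(m) <- sites$site_id
  m
}

#' Write/read poly(A) site tables
#'
#' `write_sites`/`read_sites` use a TSV with per-sample count columns (the
#' inter-stage format); `write_sites_bed` emits BED6 with the pooled read
#' count as score.
#'
#' @param sites a `polya_sites` table.
#' @param path file path.
#' @export
write_sites <- function(sites, path) {
  write_tsv(as.data.frame(sites), path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path) {
  df <- read_tsv(path)
  fixed <- c("site_id", "chrom", "strand", "start", "end",
             "representative_pos", "total_reads")
  extra <- setdiff(names(df), c(fixed, "category", "gene_id", "is_tandem",
                                "utr_length"))
  structure(df, samples = extra, class = c("polya_sites", "data.frame"))
}

#' @rdname write_sites
#' @export
write_sites_bed <- function(sites, path) {
  gr <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(sites$representative_pos + 1L, sites$representative_pos + 1L),
    strand = sites$strand)
  S4Vectors::mcols(gr)$name <- sites$site_id
  S4Vectors::mcols(gr)$score <- sites$total_reads
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
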