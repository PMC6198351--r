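# Gene models: genes with stop-codon position, 3'UTR / CDS / intron
# intervals, all in 0-based half-open coordinates. The stop codon position
# is the 0-based coordinate of the LAST base of the stop codon in strand
# orientation (largest CDS coordinate on +, smallest on -); the CDS is
# taken to include the stop codon.

new_gene_models <- function(genes, utr3, cds, exons, introns) {
  obj <- list(genes = genes, utr3 = utr3, cds = cds,
              exons = exons, introns = introns)
  class(obj) <- "gene_models"
  obj
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes (%d noncoding), %d 3'UTR intervals\n",
              nrow(x$genes), sum(x$genes$is_noncoding), nrow(x$utr3)))
  invisible(x)
}

empty_iv <- function() {
  data.frame(gene_id = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

check_intervals <- function(iv, what) {
  if (nrow(iv) == 0) return(invisible(iv))
  bad <- which(!(iv$start < iv$end))
  if (length(bad)) stop(what, ": start must be < end (row ", bad[1], ")")
  if (!all(iv$strand %in% c("+", "-")))
    stop(what, ": strand must be '+' or '-'")
  invisible(iv)
}

#' Read gene models from GTF/GFF2 or BED12
#'
#' Builds one model per gene: span, strand, stop-codon position (0-based,
#' last stop-codon base in strand orientation, derived from the CDS end),
#' 3'UTR exon intervals (annotated `three_prime_utr` features when present,
#' otherwise exon sequence downstream of the stop codon), CDS intervals and
#' introns (gaps between exons). Genes with no CDS are treated as noncoding
#' with a warning unless flagged (`gene_biotype` not protein_coding).
#'
#' @param path GTF/GFF2 or BED12 file.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed12"`.
#' @return a `gene_models` object: list of data frames `genes` (gene_id,
#'   chrom, start, end, strand, stop_codon_pos, terminal_end, is_noncoding),
#'   `utr3`, `cds`, `exons`, `introns` (gene_id, chrom, start, end, strand).
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bed12?$", path, ignore.case = TRUE)) "bed12" else "gtf"
  }
  if (format == "gtf") read_gene_models_gtf(path) else read_gene_models_bed12(path)
}

read_gene_models_gtf <- function(path) {
  if (length(readLines(path, n = 1L)) == 0L) {
    return(new_gene_models(
      genes = data.frame(gene_id = character(), chrom = character(),
                         start = integer(), end = integer(), strand = character(),
                         stop_codon_pos = integer(), terminal_end = integer(),
                         is_noncoding = logical(), stringsAsFactors = FALSE),
      utr3 = empty_iv(), cds = empty_iv(), exons = empty_iv(), introns = empty_iv()))
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("malformed GTF ", path, ": ",
                                          conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id)) stop("GTF has no gene_id attribute: ", path)
  feat <- data.frame(
    gene_id = as.character(md$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    stringsAsFactors = FALSE)
  if (any(feat$strand == "*"))
    stop("GTF record without strand in ", path)
  biotype <- rep(NA_character_, nrow(feat))
  if (!is.null(md$gene_biotype)) biotype <- as.character(md$gene_biotype)
  build_gene_models(feat, biotype)
}

build_gene_models <- function(feat, biotype = NULL) {
  feat <- feat[feat$type %in% c("exon", "CDS", "three_prime_utr", "stop_codon"), ,
               drop = FALSE]
  ids <- unique(feat$gene_id)
  genes <- vector("list", length(ids))
  utr3 <- list(); cds <- list(); exons <- list(); introns <- list()
  for (i in seq_along(ids)) {
    g <- ids[i]
    f <- feat[feat$gene_id == g, , drop = FALSE]
    ex <- f[f$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0) ex <- f  # tolerate exon-less GTFs: use all features
    chrom <- ex$chrom[1]; strand <- ex$strand[1]
    g_start <- min(ex$start); g_end <- max(ex$end)
    cd <- f[f$type == "CDS", , drop = FALSE]
    sc <- f[f$type == "stop_codon", , drop = FALSE]
    noncoding <- nrow(cd) == 0 && nrow(sc) == 0
    if (noncoding && (is.null(biotype) ||
                      is.na(biotype[match(g, feat$gene_id)]) ||
                      biotype[match(g, feat$gene_id)] == "protein_coding")) {
      warning("gene ", g, " has no CDS; treated as noncoding")
    }
    stop_pos <- NA_integer_
    if (!noncoding) {
      # stop codon = strand-orientation end of the CDS (stop_codon feature wins)
      src <- if (nrow(sc)) sc else cd
      stop_pos <- if (strand == "+") max(src$end) - 1L else min(src$start)
    }
    terminal_end <- if (strand == "+") g_end - 1L else g_start
    genes[[i]] <- data.frame(
      gene_id = g, chrom = chrom, start = g_start, end = g_end,
      strand = strand, stop_codon_pos = stop_pos, terminal_end = terminal_end,
      is_noncoding = noncoding, stringsAsFactors = FALSE)
    u <- f[f$type == "three_prime_utr", , drop = FALSE]
    if (nrow(u) == 0 && !noncoding) {
      # derive: exon territory strictly downstream of the stop codon
      u <- derive_utr3(ex, stop_pos, strand)
      if (nrow(u)) u$gene_id <- g
    }
    if (!noncoding && nrow(u)) {
      utr3[[length(utr3) + 1L]] <-
        u[, c("gene_id", "chrom", "start", "end", "strand")]
    }
    if (nrow(cd)) {
      cds[[length(cds) + 1L]] <-
        cd[, c("gene_id", "chrom", "start", "end", "strand")]
    }
    exons[[length(exons) + 1L]] <-
      ex[, c("gene_id", "chrom", "start", "end", "strand")]
    introns[[length(introns) + 1L]] <- derive_introns(ex, g)
  }
  cat_iv <- function(l) if (length(l)) do.call(rbind, l) else empty_iv()
  gm <- new_gene_models(
    genes = do.call(rbind, genes),
    utr3 = check_intervals(cat_iv(utr3), "3'UTR"),
    cds = check_intervals(cat_iv(cds), "CDS"),
    exons = check_intervals(cat_iv(exons), "exon"),
    introns = cat_iv(introns))
  validate_gene_models(gm)
  gm
}

derive_utr3 <- function(ex, stop_pos, strand) {
  out <- list()
  for (j in seq_len(nrow(ex))) {
    s <- ex$start[j]; e <- ex$end[j]
    if (strand == "+") {
      s2 <- max(s, stop_pos + 1L)
      if (s2 < e) out[[length(out) + 1L]] <-
          data.frame(gene_id = ex$gene_id[j], chrom = ex$chrom[j],
                     start = s2, end = e, strand = strand,
                     stringsAsFactors = FALSE)
    } else {
      e2 <- min(e, stop_pos)
      if (s < e2) out[[length(out) + 1L]] <-
          data.frame(gene_id = ex$gene_id[j], chrom = ex$chrom[j],
                     start = s, end = e2, strand = strand,
                     stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else empty_iv()
}

derive_introns <- function(ex, g) {
  if (nrow(ex) < 2) return(empty_iv())
  o <- order(ex$start)
  s <- ex$start[o]; e <- ex$end[o]
  gaps <- which(s[-1] > e[-length(e)])
  if (!length(gaps)) return(empty_iv())
  data.frame(gene_id = g, chrom = ex$chrom[1],
             start = e[gaps], end = s[gaps + 1L], strand = ex$strand[1],
             stringsAsFactors = FALSE)
}

validate_gene_models <- function(gm) {
  g <- gm$genes
  if (nrow(gm$utr3)) {
    # 3'UTR must lie downstream of the stop codon in strand orientation
    m <- match(gm$utr3$gene_id, g$gene_id)
    plus <- gm$utr3$strand == "+"
    ok <- ifelse(plus,
                 gm$utr3$start > g$stop_codon_pos[m],
                 gm$utr3$end <= g$stop_codon_pos[m])
    if (!all(ok)) stop("3'UTR interval upstream of stop codon for gene ",
                       gm$utr3$gene_id[which(!ok)[1]])
  }
  nc <- g$gene_id[g$is_noncoding]
  if (length(nc) && (any(gm$utr3$gene_id %in% nc) || any(gm$cds$gene_id %in% nc)))
    stop("noncoding gene carries CDS/3'UTR intervals")
  invisible(gm)
}

read_gene_models_bed12 <- function(path) {
  n1 <- readLines(path, n = 1L)
  if (length(n1) == 0L) return(read_gene_models_gtf_empty())
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 12L) stop("not BED12 (", ncol(dt), " columns): ", path)
  data.table::setnames(dt, 1:12, c("chrom", "start", "end", "name", "score",
                                   "strand", "thickStart", "thickEnd",
                                   "itemRgb", "blockCount", "blockSizes",
                                   "blockStarts"))
  feat <- list()
  for (j in seq_len(nrow(dt))) {
    sizes <- as.integer(strsplit(sub(",$", "", dt$blockSizes[j]), ",")[[1]])
    offs <- as.integer(strsplit(sub(",$", "", dt$blockStarts[j]), ",")[[1]])
    if (length(sizes) != dt$blockCount[j])
      stop("malformed BED12 blocks at line ", j, " of ", path)
    es <- dt$start[j] + offs
    ee <- es + sizes
    feat[[length(feat) + 1L]] <- data.frame(
      gene_id = dt$name[j], chrom = dt$chrom[j], start = es, end = ee,
      strand = dt$strand[j], type = "exon", stringsAsFactors = FALSE)
    if (dt$thickEnd[j] > dt$thickStart[j]) {
      cs <- pmax(es, dt$thickStart[j]); ce <- pmin(ee, dt$thickEnd[j])
      keep <- cs < ce
      if (any(keep)) feat[[length(feat) + 1L]] <- data.frame(
        gene_id = dt$name[j], chrom = dt$chrom[j], start = cs[keep],
        end = ce[keep], strand = dt$strand[j], type = "CDS",
        stringsAsFactors = FALSE)
    }
  }
  build_gene_models(do.call(rbind, feat))
}

read_gene_models_gtf_empty <- function() {
  new_gene_models(
    genes = data.frame(gene_id = character(), chrom = character(),
                       start = integer(), end = integer(), strand = character(),
                       stop_codon_pos = integer(), terminal_end = integer(),
                       is_noncoding = logical(), stringsAsFactors = FALSE),
    utr3 = empty_iv(), cds = empty_iv(), exons = empty_iv(), introns = empty_iv())
}

#' Write gene models as GTF
#' @param gm a `gene_models` object.
#' @param path output GTF file.
#' @export
write_gene_models_gtf <- function(gm, path) {
  rows <- function(iv, type) {
    if (nrow(iv) == 0) return(NULL)
    GenomicRanges::GRanges(
      iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end), strand = iv$strand,
      type = type, source = "apatrend", gene_id = iv$gene_id,
      transcript_id = paste0(iv$gene_id, ".t1"),
      phase = if (type == "CDS") 0L else NA_integer_)
  }
  gr <- suppressWarnings(c(rows(gm$exons, "exon"), rows(gm$cds, "CDS"),
                           rows(gm$utr3, "three_prime_utr")))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write gene models as BED12 (one transcript per gene)
#' @param gm a `gene_models` object.
#' @param path output BED12 file.
#' @export
write_gene_models_bed12 <- function(gm, path) {
  lines <- character(nrow(gm$genes))
  for (i in seq_len(nrow(gm$genes))) {
    g <- gm$genes[i, ]
    ex <- gm$exons[gm$exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cd <- gm$cds[gm$cds$gene_id == g$gene_id, , drop = FALSE]
    thick <- if (nrow(cd)) c(min(cd$start), max(cd$end)) else c(g$start, g$start)
    lines[i] <- paste(
      g$chrom, g$start, g$end, g$gene_id, 0L, g$strand,
      thick[1], thick[2], "0", nrow(ex),
      paste0(paste(ex$end - ex$start, collapse = ","), ","),
      paste0(paste(ex$start - g$start, collapse = ","), ","),
      sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
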