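# Annotation of poly(A) sites against gene models and known-site catalogs,
# tandem-site marking, 3'UTR lengths, and per-gene tandem 3'UTR profiles.

ANNOT_CATEGORIES <- c("ucsc_known_end", "known_polyadb", "novel_3utr",
                      "novel_downstream_1kb", "novel_cds", "novel_noncoding",
                      "novel_intron", "novel_intergenic")

# minimum |pos - catalog pos| per record over same-chrom same-strand entries
nearest_catalog <- function(chrom, strand, pos, cat) {
  dist <- rep(Inf, length(pos))
  hit <- rep(NA_character_, length(pos))
  if (is.null(cat) || nrow(cat) == 0L) return(list(dist = dist, name = hit))
  for (key in unique(paste(chrom, strand))) {
    idx <- which(paste(chrom, strand) == key)
    cidx <- which(paste(cat$chrom, cat$strand) == key)
    if (!length(cidx)) next
    cp <- sort(cat$pos[cidx])
    cn <- cat$site_name[cidx][order(cat$pos[cidx])]
    j <- findInterval(pos[idx], cp)
    lo <- pmax(j, 1L); hi <- pmin(j + 1L, length(cp))
    dlo <- abs(pos[idx] - cp[lo]); dhi <- abs(pos[idx] - cp[hi])
    dist[idx] <- pmin(dlo, dhi)
    hit[idx] <- ifelse(dlo <= dhi, cn[lo], cn[hi])
  }
  list(dist = dist, name = hit)
}

iv_granges <- function(iv) {
  GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end),
                         strand = iv$strand)
}

# first strand-aware overlap of 1-bp site positions with an interval set;
# returns the gene_id (or NA), warning on ambiguity
overlap_gene <- function(gr_pos, iv, what) {
  out <- rep(NA_character_, length(gr_pos))
  if (nrow(iv) == 0L) return(out)
  ov <- GenomicRanges::findOverlaps(gr_pos, iv_granges(iv))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  if (anyDuplicated(qh)) {
    warning("site overlapping multiple same-strand ", what,
            " features; nearest-listed gene assigned")
  }
  first <- !duplicated(qh)
  out[qh[first]] <- iv$gene_id[sh[first]]
  out
}

#' Annotate poly(A) sites
#'
#' Each site receives exactly one category, resolved in priority order:
#' within `max_dist` nt of a known transcript end (`ucsc_known_end`), then
#' of a known poly(A)-DB entry (`known_polyadb`); otherwise a novel site
#' located in an annotated 3'UTR, at most `downstream` nt past a gene's
#' annotated end (strand-oriented), in a CDS, in a noncoding gene, in an
#' intron, or intergenic. Distance tests use the representative position;
#' all tests are strand-aware.
#'
#' @param sites a `polya_sites` table.
#' @param genes a `gene_models` object.
#' @param known_ends,polyadb site catalogs (data frames from
#'   [read_site_catalog()]), or NULL.
#' @param max_dist nt distance for the known-site categories.
#' @param downstream nt length of the downstream region.
#' @return the sites table with columns `category` and `gene_id` added
#'   (class `annotated_sites`).
#' @export
annotate_sites <- function(sites, genes, known_ends = NULL, polyadb = NULL,
                           max_dist = 24L, downstream = 1000L) {
  n <- nrow(sites)
  category <- rep(NA_character_, n)
  gene_id <- rep(NA_character_, n)
  rep_pos <- sites$representative_pos

  ke <- nearest_catalog(sites$chrom, sites$strand, rep_pos, known_ends)
  idx <- which(ke$dist <= max_dist)
  category[idx] <- "ucsc_known_end"; gene_id[idx] <- ke$name[idx]

  db <- nearest_catalog(sites$chrom, sites$strand, rep_pos, polyadb)
  idx <- which(is.na(category) & db$dist <= max_dist)
  category[idx] <- "known_polyadb"; gene_id[idx] <- db$name[idx]

  gr_pos <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(rep_pos + 1L, rep_pos + 1L),
    strand = sites$strand)

  g <- genes$genes
  plus <- g$strand == "+"
  down_iv <- data.frame(
    gene_id = g$gene_id, chrom = g$chrom,
    start = ifelse(plus, g$terminal_end + 1L, g$terminal_end - downstream),
    end = ifelse(plus, g$terminal_end + 1L + downstream, g$terminal_end),
    strand = g$strand, stringsAsFactors = FALSE)
  down_iv$start <- pmax(down_iv$start, 0L)
  nc_iv <- g[g$is_noncoding, c("gene_id", "chrom", "start", "end", "strand")]

  steps <- list(novel_3utr = genes$utr3, novel_downstream_1kb = down_iv,
                novel_cds = genes$cds, novel_noncoding = nc_iv,
                novel_intron = genes$introns)
  for (catname in names(steps)) {
    open <- which(is.na(category))
    if (!length(open)) break
    hit <- overlap_gene(gr_pos[open], steps[[catname]], catname)
    got <- !is.na(hit)
    category[open[got]] <- catname
    gene_id[open[got]] <- hit[got]
  }
  category[is.na(category)] <- "novel_intergenic"

  out <- as.data.frame(sites)
  out$category <- factor(category, levels = ANNOT_CATEGORIES)
  out$gene_id <- gene_id
  structure(out, samples = attr(sites, "samples"),
            class = c("annotated_sites", "polya_sites", "data.frame"))
}

#' 3'UTR length of a poly(A) site
#'
#' Strand-oriented distance from the base after the stop codon to the
#' site's representative position, inclusive: the shortest possible value
#' (site immediately after the stop codon) is 1 nt.
#'
#' @param rep_pos representative position(s), 0-based.
#' @param stop_codon_pos 0-based position of the last stop-codon base.
#' @param strand "+" or "-".
#' @return integer nt length(s).
#' @export
utr3_length <- function(rep_pos, stop_codon_pos, strand) {
  as.integer(ifelse(strand == "+", rep_pos - stop_codon_pos,
                    stop_codon_pos - rep_pos))
}

#' Mark tandem poly(A) sites and compute their 3'UTR lengths
#'
#' A site is tandem if its span overlaps an annotated 3'UTR interval of a
#' same-strand gene, or if it is a known-category site within `max_dist` nt
#' of a gene's annotated transcript end. Tandem sites get the owning
#' `gene_id` and a `utr_length`; sites resolving to a non-positive length
#' are left non-tandem.
#'
#' @param annotated an `annotated_sites` table.
#' @param genes a `gene_models` object.
#' @param max_dist nt distance for the known-end fallback.
#' @return the table with `is_tandem` and `utr_length` columns.
#' @export
mark_tandem_sites <- function(annotated, genes, max_dist = 24L) {
  n <- nrow(annotated)
  gr_span <- GenomicRanges::GRanges(
    annotated$chrom, IRanges::IRanges(annotated$start + 1L, annotated$end),
    strand = annotated$strand)
  owner <- overlap_gene(gr_span, genes$utr3, "3'UTR")

  # known-category fallback: near a gene's annotated transcript end
  need <- which(is.na(owner) &
                  annotated$category %in% c("ucsc_known_end", "known_polyadb"))
  if (length(need)) {
    ends <- data.frame(chrom = genes$genes$chrom, strand = genes$genes$strand,
                       pos = genes$genes$terminal_end,
                       site_name = genes$genes$gene_id, stringsAsFactors = FALSE)
    nr <- nearest_catalog(annotated$chrom[need], annotated$strand[need],
                          annotated$representative_pos[need], ends)
    ok <- nr$dist <= max_dist
    owner[need[ok]] <- nr$name[ok]
  }

  is_tandem <- !is.na(owner)
  utr_length <- rep(NA_integer_, n)
  if (any(is_tandem)) {
    gi <- match(owner[is_tandem], genes$genes$gene_id)
    ul <- utr3_length(annotated$representative_pos[is_tandem],
                      genes$genes$stop_codon_pos[gi],
                      genes$genes$strand[gi])
    drop <- is.na(ul) | ul < 1L
    utr_length[is_tandem] <- ul
    if (any(drop)) {
      bad <- which(is_tandem)[drop]
      is_tandem[bad] <- FALSE
      utr_length[bad] <- NA_integer_
      owner[bad] <- NA_character_
    }
  }
  out <- annotated
  out$gene_id <- ifelse(is_tandem, owner, out$gene_id)
  out$is_tandem <- is_tandem
  out$utr_length <- utr_length
  structure(out, samples = attr(annotated, "samples"), class = class(annotated))
}

#' Build per-gene tandem 3'UTR profiles
#'
#' One profile per gene with at least two tandem sites, ordered by
#' ascending 3'UTR length. Sites with identical lengths within a gene are
#' merged (counts summed) with a warning.
#'
#' @param annotated an `annotated_sites` table with tandem marks.
#' @param samples ordered sample identifiers.
#' @return a named list of class `tandem_profiles`; each element has
#'   `gene_id`, `site_ids`, `utr_lengths` and a samples-by-sites `counts`
#'   matrix.
#' @export
build_profiles <- function(annotated, samples = attr(annotated, "samples")) {
  tand <- annotated[annotated$is_tandem, , drop = FALSE]
  profiles <- list()
  for (g in unique(tand$gene_id)) {
    rows <- tand[tand$gene_id == g, , drop = FALSE]
    rows <- rows[order(rows$utr_length), , drop = FALSE]
    counts <- t(as.matrix(rows[, samples, drop = FALSE]))
    rownames(counts) <- samples
    colnames(counts) <- rows$site_id
    if (anyDuplicated(rows$utr_length)) {
      warning("gene ", g, ": sites with identical 3'UTR length merged")
      grp <- match(rows$utr_length, unique(rows$utr_length))
      counts <- t(rowsum(t(counts), grp))
      colnames(counts) <- vapply(split(rows$site_id, grp), paste,
                                 "", collapse = "+")
      rows <- rows[!duplicated(rows$utr_length), , drop = FALSE]
    }
    if (nrow(rows) < 2L) next
    profiles[[g]] <- structure(
      list(gene_id = g, site_ids = colnames(counts),
           utr_lengths = rows$utr_length, counts = counts),
      class = "tandem_profile")
  }
  structure(profiles, class = "tandem_profiles")
}

#' Write/read tandem profiles as TSV
#'
#' Long-by-site layout: gene_id, site_id, utr_length, then one count
#' column per sample.
#'
#' @param profiles a `tandem_profiles` list.
#' @param path file path.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    df <- data.frame(gene_id = p$gene_id, site_id = p$site_ids,
                     utr_length = p$utr_lengths, stringsAsFactors = FALSE)
    cbind(df, as.data.frame(t(p$counts)))
  })
  write_tsv(data.table::rbindlist(rows), path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- read_tsv(path)
  samples <- setdiff(names(df), c("gene_id", "site_id", "utr_length"))
  profiles <- list()
  for (g in unique(df$gene_id)) {
    rows <- df[df$gene_id == g, , drop = FALSE]
    rows <- rows[order(rows$utr_length), , drop = FALSE]
    counts <- t(as.matrix(rows[, samples, drop = FALSE]))
    rownames(counts) <- samples
    colnames(counts) <- rows$site_id
    profiles[[g]] <- structure(
      list(gene_id = g, site_ids = rows$site_id,
           utr_lengths = rows$utr_length, counts = counts),
      class = "tandem_profile")
  }
  structure(profiles, class = "tandem_profiles")
}
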