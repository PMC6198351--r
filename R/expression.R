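# Gene-level expression accumulated over poly(A) sites, a pooled-count
# exact test for differential expression, and the DE x switching
# cross-tabulation. The DE test is this package's own defined stand-in:
# per-sample total-count normalization and a two-sided Fisher exact test
# on pooled case/control counts, BH-adjusted across genes.

#' Accumulate gene expression from annotated poly(A) sites
#'
#' Per gene and sample, sums the read counts of every site assigned to the
#' gene (any category with a gene id). Genes with no sites are absent.
#'
#' @param annotated an `annotated_sites` table.
#' @param samples ordered sample identifiers.
#' @return data frame: gene_id plus one count column per sample (class
#'   `gene_expression`, attribute `samples`).
#' @export
accumulate_expression <- function(annotated, samples = attr(annotated, "samples")) {
  rows <- annotated[!is.na(annotated$gene_id), , drop = FALSE]
  if (nrow(rows) == 0L) {
    out <- data.frame(gene_id = character(), stringsAsFactors = FALSE)
    for (s in samples) out[[s]] <- integer()
  } else {
    m <- rowsum(as.matrix(rows[, samples, drop = FALSE]), rows$gene_id)
    out <- data.frame(gene_id = rownames(m), stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(m, row.names = NULL))
  }
  structure(out, samples = samples,
            class = c("gene_expression", "data.frame"))
}

#' Pooled-count exact test for differential expression
#'
#' For each gene, pools counts within the case and control groups and
#' tests the 2 x 2 table (gene count vs library remainder per group) with
#' a two-sided Fisher exact test; q-values are BH-adjusted across genes.
#' The log2 fold change compares pooled counts normalized by pooled
#' library size, with a 0.5 pseudocount on each pooled count. Status is
#' `up`/`down` only when q falls below `fdr_threshold`, `ns` otherwise.
#'
#' @param expr a `gene_expression` table.
#' @param case_samples,control_samples sample identifiers.
#' @param fdr_threshold BH FDR cutoff for up/down status.
#' @return data frame: gene_id, case_count, control_count, log2fc, p, q,
#'   status.
#' @export
exact_de_test <- function(expr, case_samples, control_samples,
                          fdr_threshold = 0.05) {
  missing <- setdiff(c(case_samples, control_samples), attr(expr, "samples"))
  if (length(missing))
    stop("sample(s) absent from expression table: ",
         paste(missing, collapse = ", "))
  cc <- rowSums(as.data.frame(expr)[, case_samples, drop = FALSE])
  tc <- rowSums(as.data.frame(expr)[, control_samples, drop = FALSE])
  Lc <- sum(cc); Lt <- sum(tc)
  if (Lc == 0 || Lt == 0) stop("zero library size in one group")
  p <- vapply(seq_along(cc), function(i) {
    tab <- matrix(c(cc[i], Lc - cc[i], tc[i], Lt - tc[i]), nrow = 2)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  q <- bh_fdr(p)
  log2fc <- log2(((cc + 0.5) / Lc) / ((tc + 0.5) / Lt))
  status <- ifelse(q < fdr_threshold, ifelse(log2fc > 0, "up", "down"), "ns")
  data.frame(gene_id = expr$gene_id, case_count = cc, control_count = tc,
             log2fc = log2fc, p = p, q = q, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-tabulate DE status against switching direction
#'
#' Counts called switching genes by direction (lengthened/shortened) and
#' DE status (up/down/ns).
#'
#' @param de data frame from [exact_de_test()].
#' @param calls data frame from [aggregate_gene_calls()].
#' @return 2 x 3 integer matrix (direction x status).
#' @export
crosstab_de_switching <- function(de, calls) {
  out <- matrix(0L, nrow = 2, ncol = 3,
                dimnames = list(c("lengthened", "shortened"),
                                c("up", "down", "ns")))
  called <- calls[calls$called & calls$direction %in% rownames(out), ,
                  drop = FALSE]
  if (nrow(called) == 0L) return(out)
  st <- de$status[match(called$gene_id, de$gene_id)]
  st[is.na(st)] <- "ns"
  for (i in seq_len(nrow(called)))
    out[called$direction[i], st[i]] <- out[called$direction[i], st[i]] + 1L
  out
}
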