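#' Pipeline run configuration
#'
#' Assembles the thresholds used across the pipeline stages into a single
#' validated list. Defaults follow the analysis conventions of 3'-end
#' sequencing APA studies: poly(A) sites are cleavage clusters joined at a
#' maximum gap of 24 nt and supported by at least 2 reads; internal-priming
#' evidence is looked for 1-20 nt downstream of the cleavage base; per-pair
#' switching calls are kept below an FDR of 0.01 and a gene is called when
#' significant in at least 10 case-control pairs.
#'
#' @param cluster_distance maximum gap (nt) joining cleavage positions into
#'   one cluster.
#' @param min_cluster_reads minimum pooled read support for a poly(A) site.
#' @param ip_window integer pair: first and last downstream offset (nt,
#'   strand-relative, 1-based offsets from the cleavage base) of the window
#'   scanned for internal-priming motifs.
#' @param annotation_distance maximum distance (nt) between a site and a
#'   catalog entry / transcript end for a "known" annotation.
#' @param downstream_window length (nt) of the region past a gene's
#'   annotated end in which novel sites are labelled downstream.
#' @param fdr_threshold per-pair Benjamini-Hochberg FDR cutoff.
#' @param min_significant_pairs pairs a gene must be significant in to be
#'   called a switching gene.
#' @param min_pair_reads minimum reads a gene needs in each sample of a
#'   pair to be tested there (0 disables the floor).
#' @param de_fdr_threshold FDR cutoff for the differential-expression
#'   stand-in.
#' @param supersite_split site index (1-based) at which a gene's sites are
#'   split into proximal/distal supersites; sites `1..split` are proximal.
#' @param seed integer seed logged with every run.
#' @return a named list of class `apa_config`.
#' @export
apa_config <- function(cluster_distance = 24L,
                       min_cluster_reads = 2L,
                       ip_window = c(1L, 20L),
                       annotation_distance = 24L,
                       downstream_window = 1000L,
                       fdr_threshold = 0.01,
                       min_significant_pairs = 10L,
                       min_pair_reads = 10L,
                       de_fdr_threshold = 0.05,
                       supersite_split = 1L,
                       seed = 1L) {
  cfg <- list(
    cluster_distance = as.integer(cluster_distance),
    min_cluster_reads = as.integer(min_cluster_reads),
    ip_window = as.integer(ip_window),
    annotation_distance = as.integer(annotation_distance),
    downstream_window = as.integer(downstream_window),
    fdr_threshold = as.numeric(fdr_threshold),
    min_significant_pairs = as.integer(min_significant_pairs),
    min_pair_reads = as.integer(min_pair_reads),
    de_fdr_threshold = as.numeric(de_fdr_threshold),
    supersite_split = as.integer(supersite_split),
    seed = as.integer(seed)
  )
  class(cfg) <- "apa_config"
  validate_apa_config(cfg)
  cfg
}

validate_apa_config <- function(cfg) {
  stopifnot(
    cfg$cluster_distance > 0L,
    cfg$min_cluster_reads > 0L,
    length(cfg$ip_window) == 2L,
    cfg$ip_window[1] >= 1L,
    cfg$ip_window[2] >= cfg$ip_window[1],
    cfg$annotation_distance > 0L,
    cfg$downstream_window > 0L,
    cfg$fdr_threshold > 0, cfg$fdr_threshold < 1,
    cfg$min_significant_pairs > 0L,
    cfg$min_pair_reads >= 0L,
    cfg$de_fdr_threshold > 0, cfg$de_fdr_threshold < 1,
    cfg$supersite_split >= 1L
  )
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Keys absent from the file keep their `apa_config()` defaults; entries in
#' `overrides` (e.g. parsed command-line flags) take precedence over both.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list overriding file values.
#' @return an `apa_config` list.
#' @export
read_apa_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(apa_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
    vals <- vals[intersect(names(vals), known)]
  }
  do.call(apa_config, vals)
}

#' Write a run configuration to YAML
#' @param cfg an `apa_config` list.
#' @param path output file.
#' @export
write_apa_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
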