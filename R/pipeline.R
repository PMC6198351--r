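# End-to-end orchestration: simulate (optional) -> filter -> cluster ->
# annotate -> switch -> de -> mirna, every stage re-loadable from its
# plain-text artifact, with a JSON run manifest.

#' Run the full APA switching pipeline
#'
#' Executes all stages into `out_dir`, writing plain TSV/BED artifacts so
#' any stage can be re-run or replaced externally, plus a `manifest.json`
#' recording the resolved configuration, input digests and per-stage
#' record counts. With `sim_config` set, a synthetic experiment is first
#' generated under `out_dir/sim` and used as input.
#'
#' @param out_dir output directory.
#' @param config an [apa_config()].
#' @param sim_config optional [simulation_config()]; when given, inputs
#'   are simulated.
#' @param inputs when not simulating, a named list: `genome` (FASTA),
#'   `genes` (GTF/BED12), `reads` (named vector of per-sample cleavage
#'   BEDs), `case_samples`, `control_samples`, optional `known_ends`,
#'   `polyadb` (BED catalogs) and `mirnas` (FASTA).
#' @return invisible list with the stage results and the manifest.
#' @export
run_apa_pipeline <- function(out_dir, config = apa_config(),
                             sim_config = NULL, inputs = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages$failed_stage <<- name
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, force = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (!is.null(sim_config)) {
    sim <- stage("simulate",
                 simulate_apa_experiment(sim_config, file.path(out_dir, "sim")))
    smp <- sim_sample_names(sim_config)
    inputs <- list(genome = sim$files$genome, genes = sim$files$gtf,
                   known_ends = sim$files$known_ends,
                   polyadb = sim$files$polyadb,
                   reads = sim$files$reads,
                   case_samples = smp$case, control_samples = smp$control)
    if (!is.null(sim_config$plant_mirna)) {
      mf <- file.path(out_dir, "sim", "mirnas.fa")
      writeLines(c(">planted_mirna", sim_config$plant_mirna), mf)
      inputs$mirnas <- mf
    }
    manifest$stages$simulate <- list(
      n_genes = sim_config$n_genes,
      records_emitted = nrow(sim$records),
      artifact_records = sum(sim$records$origin == "artifact"))
  }

  for (req in c("genome", "genes", "reads", "case_samples", "control_samples")) {
    if (is.null(inputs[[req]])) stop("missing input: ", req)
  }
  for (f in c(inputs$genome, inputs$genes, unname(inputs$reads),
              inputs$known_ends, inputs$polyadb, inputs$mirnas)) {
    if (!file.exists(f)) stop("missing input file: ", f)
  }
  digestible <- c(genome = inputs$genome, genes = inputs$genes,
                  inputs$reads, known_ends = inputs$known_ends,
                  polyadb = inputs$polyadb, mirnas = inputs$mirnas)
  manifest$inputs <- as.list(tools::md5sum(digestible))

  genome <- Biostrings::readDNAStringSet(inputs$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genes <- stage("load", read_gene_models(inputs$genes))
  known_ends <- if (!is.null(inputs$known_ends))
    read_site_catalog(inputs$known_ends) else NULL
  polyadb <- if (!is.null(inputs$polyadb))
    read_site_catalog(inputs$polyadb) else NULL
  samples <- c(inputs$case_samples, inputs$control_samples)
  records <- stage("load", do.call(rbind, lapply(samples, function(s)
    read_cleavage_records(inputs$reads[[s]], s))))
  manifest$stages$load <- list(records_in = nrow(records))

  flt <- stage("filter", filter_internal_priming(records, genome,
                                                 window = config$ip_window))
  write_cleavage_records(flt$kept, file.path(out_dir, "kept.bed"))
  write_cleavage_records(flt$filtered, file.path(out_dir, "filtered.bed"))
  manifest$stages$filter <- list(records_in = nrow(records),
                                 records_kept = nrow(flt$kept),
                                 records_filtered = nrow(flt$filtered))

  sites <- stage("cluster", cluster_cleavage_sites(
    flt$kept, max_gap = config$cluster_distance,
    min_reads = config$min_cluster_reads, samples = samples))
  write_sites(sites, file.path(out_dir, "sites.tsv"))
  write_sites_bed(sites, file.path(out_dir, "sites.bed"))
  manifest$stages$cluster <- list(sites_called = nrow(sites))

  annotated <- stage("annotate", mark_tandem_sites(
    annotate_sites(sites, genes, known_ends, polyadb,
                   max_dist = config$annotation_distance,
                   downstream = config$downstream_window),
    genes, max_dist = config$annotation_distance))
  write_sites(as.data.frame(annotated), file.path(out_dir, "annotated.tsv"))
  profiles <- stage("annotate", build_profiles(annotated, samples))
  write_profiles(profiles, file.path(out_dir, "profiles.tsv"))
  manifest$stages$annotate <- list(
    tandem_sites = sum(annotated$is_tandem),
    genes_profiled = length(profiles))

  pairs <- stage("switch", pairwise_switch_scan(
    profiles, inputs$case_samples, inputs$control_samples,
    fdr_threshold = config$fdr_threshold,
    min_pair_reads = config$min_pair_reads))
  write_tsv(pairs, file.path(out_dir, "pairs.tsv"))
  calls <- stage("switch", aggregate_gene_calls(
    pairs, min_significant_pairs = config$min_significant_pairs))
  write_tsv(calls, file.path(out_dir, "calls.tsv"))
  manifest$stages$switch <- list(
    pairs_tested = length(unique(paste(pairs$case_sample, pairs$control_sample))),
    gene_pair_tests = nrow(pairs),
    genes_called = sum(calls$called))

  expr <- stage("de", accumulate_expression(annotated, samples))
  write_tsv(as.data.frame(expr), file.path(out_dir, "expression.tsv"))
  de <- stage("de", exact_de_test(expr, inputs$case_samples,
                                  inputs$control_samples,
                                  fdr_threshold = config$de_fdr_threshold))
  write_tsv(de, file.path(out_dir, "de.tsv"))
  xtab <- crosstab_de_switching(de, calls)
  write_tsv(cbind(direction = rownames(xtab), as.data.frame(xtab)),
            file.path(out_dir, "de_switching_crosstab.tsv"))
  manifest$stages$de <- list(genes_tested = nrow(de),
                             genes_up = sum(de$status == "up"),
                             genes_down = sum(de$status == "down"))

  hits <- NULL; gain_loss <- NULL
  if (!is.null(inputs$mirnas)) {
    mirnas <- read_mirnas(inputs$mirnas)
    hits <- stage("mirna", scan_switch_genes(genome, genes, profiles, calls,
                                             mirnas))
    write_tsv(hits, file.path(out_dir, "mirna_hits.tsv"))
    gain_loss <- mirna_gain_loss(hits, calls)
    write_tsv(gain_loss$per_gene, file.path(out_dir, "mirna_gain_loss.tsv"))
    manifest$stages$mirna <- list(hits = nrow(hits),
                                  sites_gained = unname(gain_loss$totals["gained"]),
                                  sites_lost = unname(gain_loss$totals["lost"]))
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(sites = sites, annotated = annotated, profiles = profiles,
                 pairs = pairs, calls = calls, expr = expr, de = de,
                 crosstab = xtab, hits = hits, gain_loss = gain_loss,
                 manifest = manifest))
}
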