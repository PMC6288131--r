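# End-to-end orchestration: QC -> locus definition -> gene mapping ->
# prioritization -> enrichment -> liability conversion -> drug
# connectivity, driven by one configuration with one seed, emitting a
# JSON report that embeds the configuration for provenance.

#' Default pipeline configuration
#'
#' All thresholds default to the standard values of the analysis this
#' pipeline implements: genome-wide significance `5e-8`, locus
#' membership `p < 1e-4` at `r2 > 0.2`, positional window 250 kb,
#' interaction FDR `1e-6`, minimum prioritization score 2, universe of
#' 19180 protein-coding genes, 100 permutations at `alpha = 0.05` for
#' the connectivity null, and `1e6` iterations for drug-set permutation
#' p-values. Every default is overridable; the configuration used is
#' serialized into the run report. One seed governs all stochastic
#' stages (per-stage substreams are derived from it).
#'
#' @param ... Overrides of the defaults, by name. Input paths
#'   (`sumstats`, `ld`, `genes`, `interactions`, `criteria`,
#'   `target_set`, `disease_z`, `profiles`, `profile_meta`) and stage
#'   toggles (`run_connectivity`, logical) are set the same way.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sumstats = NULL, ld = NULL, genes = NULL, interactions = NULL,
    criteria = NULL, target_set = NULL, disease_z = NULL,
    profiles = NULL, profile_meta = NULL,
    r2_filter = 0.4, het_p = 1e-8,
    p_gw = 5e-8, p_member = 1e-4, r2_locus = 0.2,
    window_bp = 250000L, fdr_max = 1e-6,
    min_score = 2L, universe_n = 19180L, weight = NULL,
    h2_observed = NULL, prevalence = NULL, case_proportion = NULL,
    top_fraction = 0.1, n_perm = 100L, alpha = 0.05, n_iter = 1e6,
    run_connectivity = TRUE,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with fields as in [pipeline_config()].
#' @return Named configuration list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

require_input <- function(cfg, field, stage) {
  path <- cfg[[field]]
  if (is.null(path)) {
    stop(sprintf("stage '%s' requires input '%s'", stage, field))
  }
  if (!file.exists(path)) {
    stop(sprintf("stage '%s': input file not found: %s", stage, path))
  }
  path
}

#' Run the post-GWAS pipeline end to end
#'
#' Executes summary-statistic QC, locus definition, locus-to-gene
#' mapping, gene prioritization, gene-set enrichment of the mapped and
#' prioritized gene lists, optional liability-scale conversion and
#' optional drug connectivity mapping, writing tab-separated stage
#' outputs plus a JSON report (including the full configuration) under
#' `out_dir`.
#'
#' @param config Configuration from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   file output.
#' @return The report as a named list, invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  t0 <- Sys.time()
  report <- list(config = config[!vapply(config, is.null, TRUE)])

  ## stage: qc
  ss <- read_sumstats(require_input(config, "sumstats", "qc"))
  ld <- read_ld_pairs(require_input(config, "ld", "qc"))
  qc <- qc_sumstats(ss, ld, r2_min = config$r2_filter)
  report$qc <- list(
    n_input = nrow(ss),
    n_removed_ld_filter = length(qc$removed_ld_filter),
    lambda_gc = qc$inflation$lambda_gc,
    lambda_1000 = qc$lambda_1000,
    mean_chi2 = qc$inflation$mean_chi2
  )
  ss <- qc$sumstats

  ## stage: loci
  loci <- define_loci(ss, ld, p_gw = config$p_gw,
                      p_member = config$p_member,
                      r2_min = config$r2_locus)
  report$loci <- list(n_loci = nrow(loci),
                      lead_variants = loci$lead_variant)

  ## stage: gene mapping
  genes <- read_gene_bed(require_input(config, "genes", "map"))
  interactions <- if (!is.null(config$interactions)) {
    read_interactions(config$interactions)
  } else NULL
  mapping <- map_genes(loci, genes, interactions,
                       window_bp = config$window_bp,
                       fdr_max = config$fdr_max)
  mapped_genes <- pooled_gene_list(mapping)
  report$mapping <- list(n_mapped_genes = length(mapped_genes))

  ## stage: prioritization
  prioritized <- character(0)
  pri_table <- NULL
  if (!is.null(config$criteria)) {
    criteria <- read_criteria(require_input(config, "criteria",
                                            "prioritize"))
    scores <- score_genes(criteria)
    pri_table <- suppressWarnings(
      prioritization_table(scores, mapping, min_score = config$min_score))
    prioritized <- sort(unique(pri_table[prioritized == TRUE, gene_id]))
    report$prioritization <- list(
      n_prioritized = length(prioritized),
      prioritized_genes = prioritized)
  }

  ## stage: enrichment
  if (!is.null(config$target_set)) {
    target <- read_gene_set(require_input(config, "target_set", "enrich"))
    enr <- function(drawn) {
      central <- test_enrichment(drawn, target, config$universe_n)
      out <- list(
        table = unclass(central$table),
        odds_ratio = central$odds_ratio,
        p_strict = central$p_strict,
        p_inclusive = central$p_inclusive
      )
      if (!is.null(config$weight)) {
        wal <- test_enrichment(drawn, target, config$universe_n,
                               weight = config$weight)
        out$wallenius <- list(weight = config$weight,
                              p_strict = wal$p_strict,
                              p_inclusive = wal$p_inclusive)
      }
      out
    }
    report$enrichment <- list(mapped = enr(mapped_genes))
    if (length(prioritized)) {
      report$enrichment$prioritized <- enr(prioritized)
    }
  }

  ## stage: liability conversion
  if (!is.null(config$h2_observed)) {
    report$heritability <- list(
      h2_observed = config$h2_observed,
      h2_liability = liability_transform(config$h2_observed,
                                         config$prevalence,
                                         config$case_proportion),
      sensitivity = as.list(prevalence_sensitivity(
        config$h2_observed, config$prevalence, config$case_proportion))
    )
  }

  ## stage: connectivity
  conn_scores <- NULL
  if (isTRUE(config$run_connectivity) && !is.null(config$disease_z)) {
    z <- read_gene_z(require_input(config, "disease_z", "connect"))
    prof <- read_drug_profiles(
      require_input(config, "profiles", "connect"),
      require_input(config, "profile_meta", "connect"))
    sig <- build_disease_signature(z, top_fraction = config$top_fraction)
    conn_scores <- score_perturbagens(sig, prof$profiles, prof$meta)
    null <- permutation_null(z, prof$profiles, prof$meta,
                             n_perm = config$n_perm,
                             alpha = config$alpha,
                             top_fraction = config$top_fraction,
                             seed = config$seed + 10L)
    sig_drugs <- significant_reversers(conn_scores, null)
    report$connectivity <- list(
      n_drugs = nrow(conn_scores),
      signature_size = length(sig),
      pooled_null_size = length(null$pooled_null),
      threshold = null$threshold,
      n_significant = length(sig_drugs),
      significant = sig_drugs
    )
  }

  report$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(loci[, !"members"], file.path(out_dir, "loci.tsv"))
    write_tsv(mapping, file.path(out_dir, "gene_mapping.tsv"))
    if (!is.null(pri_table)) {
      write_tsv(pri_table, file.path(out_dir, "prioritization.tsv"))
    }
    if (!is.null(conn_scores)) {
      write_tsv(conn_scores, file.path(out_dir, "connectivity.tsv"))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}
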