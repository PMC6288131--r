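# Synthetic-data generator: summary statistics with planted causal loci
# propagated through block LD, gene annotations with size-inflated
# target sets and planted top-scoring genes, and perturbagen profiles
# with planted signature reversers. Everything is driven by one seeded
# configuration so the full pipeline is testable without external data.

#' Simulation configuration
#'
#' All counts, effect sizes and rates for the synthetic-data generator,
#' with one mandatory seed (no implicit randomness). Defaults describe a
#' compact GWAS-like study: z-scores exchangeably correlated within LD
#' blocks, ten planted risk loci at non-centrality 8 (association power
#' about 0.995 at genome-wide significance), lognormal gene sizes with
#' mean about 62 kb, a curated target set inflated in size by the factor
#' 2.44 observed for monogenic disease genes, and a perturbagen library
#' with a handful of planted signature reversers at strength 0.8.
#'
#' @param seed Mandatory integer seed.
#' @param n_snps Number of variants.
#' @param n_loci Number of planted risk loci.
#' @param ld_block_size Variants per exchangeable LD block.
#' @param within_block_r2 Squared correlation between variants of one
#'   block, in \\[0, 1).
#' @param causal_effect_z Non-centrality added to each planted lead
#'   (block partners receive `r * causal_effect_z` with
#'   `r = sqrt(within_block_r2)`); 0 gives a null study.
#' @param n_cases,n_controls Case-control counts written into the
#'   summary statistics (defaults 15212 and 29677).
#' @param n_genes Number of genes.
#' @param gene_size_meanlog,gene_size_sdlog Lognormal gene-size
#'   parameters (defaults give mean size 62.2 kb).
#' @param target_set_size Size of the curated target gene set.
#' @param target_set_size_factor Mean-size inflation of target genes
#'   relative to the rest (default 2.44).
#' @param n_drugs,n_conditions Perturbagen library dimensions.
#' @param reverser_count Number of planted signature reversers.
#' @param reverser_strength Reversal strength in (0, 1]; 1 gives exact
#'   sign-flipped signatures.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_snps = 10000L,
                       n_loci = 10L,
                       ld_block_size = 20L,
                       within_block_r2 = 0.5,
                       causal_effect_z = 8,
                       n_cases = 15212L,
                       n_controls = 29677L,
                       n_genes = 2000L,
                       gene_size_meanlog = log(62200) - 0.5,
                       gene_size_sdlog = 1,
                       target_set_size = 102L,
                       target_set_size_factor = 2.44,
                       n_drugs = 2000L,
                       n_conditions = 3L,
                       reverser_count = 15L,
                       reverser_strength = 0.8) {
  if (missing(seed) || !is.finite(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  counts <- c("n_snps", "n_loci", "ld_block_size", "n_genes", "n_drugs",
              "n_conditions", "n_cases", "n_controls")
  for (nm in counts) {
    if (cfg[[nm]] < 1) stop(nm, " must be positive")
  }
  if (within_block_r2 < 0 || within_block_r2 >= 1) {
    stop("within_block_r2 must lie in [0, 1)")
  }
  if (ld_block_size > n_snps) stop("block size exceeds n_snps")
  if (n_loci > floor(n_snps / ld_block_size)) {
    stop("more planted loci than LD blocks")
  }
  if (reverser_strength <= 0 || reverser_strength > 1) {
    stop("reverser_strength must lie in (0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate GWAS summary statistics with planted loci
#'
#' Null z-scores are drawn with exchangeable correlation
#' `r = sqrt(within_block_r2)` within contiguous LD blocks (one-factor
#' construction). Planted loci add `causal_effect_z` to the block's lead
#' variant and `r * causal_effect_z` to its partners, the expected
#' propagation of an association signal through LD. Variants sit every
#' 5 kb on one chromosome; p-values follow the two-sided normal map.
#'
#' @param config A [sim_config()].
#' @return List with `sumstats` (standard summary-statistic table),
#'   `ld` (within-block pair table with `R2 = within_block_r2`), and
#'   `truth` (`data.table` of planted loci: block index, lead variant id,
#'   member ids, lead position).
#' @export
simulate_sumstats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_snps
  bs <- config$ld_block_size
  block <- rep(seq_len(ceiling(n / bs)), each = bs)[seq_len(n)]
  r <- sqrt(config$within_block_r2)
  f <- rnorm(max(block))[block]
  z <- sqrt(r) * f + sqrt(1 - r) * rnorm(n)

  full_blocks <- which(tabulate(block) == bs)
  # space planted blocks so that 250 kb positional windows of distinct
  # loci cannot overlap: planted genes then identify their locus uniquely
  block_span <- bs * 5000L
  gap <- ceiling(700000 / block_span)
  candidates <- full_blocks[seq(1, length(full_blocks), by = gap)]
  if (length(candidates) < config$n_loci) {
    stop("n_snps too small to plant ", config$n_loci,
         " well-separated loci")
  }
  planted <- sort(sample(candidates, config$n_loci))
  lead_idx <- integer(0)
  if (config$causal_effect_z != 0 || config$n_loci > 0) {
    for (b in planted) {
      idx <- which(block == b)
      lead <- idx[ceiling(length(idx) / 2)]
      z[idx] <- z[idx] + r * config$causal_effect_z
      z[lead] <- z[lead] + (1 - r) * config$causal_effect_z
      lead_idx <- c(lead_idx, lead)
    }
  }

  snp <- sprintf("rs%06d", seq_len(n))
  alleles <- c("A", "C", "G", "T")
  a1 <- sample(alleles, n, replace = TRUE)
  a2 <- vapply(a1, function(a) sample(setdiff(alleles, a), 1), "")
  ss <- data.table(
    SNP = snp, CHR = "1", BP = seq_len(n) * 5000L,
    A1 = a1, A2 = a2,
    FREQ = runif(n, 0.05, 0.5),
    Z = z, P = 2 * pnorm(-abs(z)),
    N_CASES = config$n_cases, N_CONTROLS = config$n_controls
  )

  ld <- rbindlist(lapply(split(seq_len(n), block), function(idx) {
    if (length(idx) < 2L) return(NULL)
    pairs <- t(utils::combn(idx, 2L))
    data.table(SNP_A = snp[pairs[, 1]], SNP_B = snp[pairs[, 2]],
               R2 = config$within_block_r2)
  }))

  truth <- data.table(
    planted_locus = seq_along(planted),
    block = planted,
    lead_snp = snp[lead_idx],
    lead_bp = as.integer(lead_idx * 5000L),
    members = lapply(planted, function(b) snp[block == b])
  )
  list(sumstats = ss, ld = ld, truth = truth)
}

#' Simulate gene annotations, target sets and a criteria matrix
#'
#' Gene sizes are lognormal; genes in the curated target set have their
#' sizes multiplied by `target_set_size_factor`, so the recovered
#' [size_bias_weight()] is that factor in expectation. One planted gene
#' per planted locus is placed at the locus lead position with at least
#' three true criteria; all other genes carry at most one. Gene
#' intervals are 0-based half-open on the simulated chromosome.
#'
#' @param config A [sim_config()].
#' @param truth Optional truth table from [simulate_sumstats()]; when
#'   supplied, planted genes are anchored at the planted lead positions.
#' @return List with `genes` (BED-convention table incl. `size_bp`),
#'   `target_set` (gene ids), `criteria` (gene-by-six 0/1 table) and
#'   `truth` (planted gene per locus).
#' @export
simulate_genes_and_sets <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ng <- config$n_genes
  sizes <- rlnorm(ng, config$gene_size_meanlog, config$gene_size_sdlog)
  gene_id <- sprintf("GENE%05d", seq_len(ng))
  target <- sample(gene_id, config$target_set_size)
  sizes[gene_id %in% target] <- sizes[gene_id %in% target] *
    config$target_set_size_factor
  genome_bp <- config$n_snps * 5000L
  start <- sample.int(genome_bp, ng, replace = TRUE)

  planted_genes <- character(0)
  if (!is.null(truth) && nrow(truth) > 0L) {
    planted_genes <- gene_id[seq_len(nrow(truth))]
    start[seq_len(nrow(truth))] <- truth$lead_bp
    # planted genes stay compact (<= 200 kb) so they cannot reach the
    # positional window of a different planted locus
    sizes[seq_len(nrow(truth))] <- pmin(sizes[seq_len(nrow(truth))],
                                        200000)
  }
  genes <- data.table(chrom = "1", start = start - 1L,
                      end = as.integer(start - 1L + ceiling(sizes)),
                      gene_id = gene_id)
  genes[, size_bp := end - start]

  crit_names <- c("twas_significant", "eqtl_in_locus", "brain_preferential",
                  "missense_in_locus", "ppi_prioritized",
                  "ko_mouse_phenotype")
  cm <- matrix(0L, nrow = ng, ncol = 6L,
               dimnames = list(NULL, crit_names))
  # background genes: at most one criterion
  bg_hit <- rbinom(ng, 1L, 0.3)
  bg_col <- sample.int(6L, ng, replace = TRUE)
  cm[cbind(seq_len(ng), bg_col)] <- bg_hit
  # planted genes: 3 to 6 criteria met
  for (g in planted_genes) {
    i <- match(g, gene_id)
    cm[i, ] <- 0L
    k <- sample(3:6, 1L)
    cm[i, sample.int(6L, k)] <- 1L
  }
  criteria <- data.table(gene_id = gene_id)
  criteria <- cbind(criteria, as.data.table(cm))

  truth_genes <- if (length(planted_genes)) {
    data.table(planted_locus = seq_along(planted_genes),
               gene_id = planted_genes,
               lead_bp = truth$lead_bp[seq_along(planted_genes)])
  } else {
    data.table(planted_locus = integer(), gene_id = character(),
               lead_bp = integer())
  }
  list(genes = genes, target_set = target, criteria = criteria,
       truth = truth_genes)
}

#' Simulate perturbagen expression profiles with planted reversers
#'
#' Null profiles are independent standard normal per gene and condition.
#' Planted reversers follow
#' `-strength * z_std + sqrt(1 - strength^2) * noise` on the disease
#' z-score scale, so at strength 1 (no noise) a reverser scores exactly
#' -1 against the disease signature.
#'
#' @param config A [sim_config()].
#' @param disease_z Named numeric gene-level z-scores defining the gene
#'   universe of the profiles.
#' @return List with `profiles` (gene-by-condition matrix), `meta`
#'   (condition-to-perturbagen table) and `truth` (reverser ids).
#' @export
simulate_drug_profiles <- function(config, disease_z) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(names(disease_z))) stop("disease_z must be named by gene")
  set.seed(config$seed + 2L)
  genes <- names(disease_z)
  ng <- length(genes)
  nd <- config$n_drugs
  nc <- config$n_conditions
  drug_ids <- sprintf("DRUG%05d", seq_len(nd))
  cond_ids <- as.vector(outer(drug_ids, seq_len(nc),
                              function(d, k) paste0(d, "_c", k)))
  meta <- data.table(
    condition_id = cond_ids,
    perturbagen_id = rep(drug_ids, times = nc),
    cell_line = paste0("CL", rep(seq_len(nc), each = nd)),
    dose = "10uM", time = "24h"
  )
  m <- matrix(rnorm(ng * length(cond_ids)), nrow = ng,
              dimnames = list(genes, cond_ids))
  reversers <- sort(sample(drug_ids, config$reverser_count))
  s <- config$reverser_strength
  z_std <- disease_z / sd(disease_z)
  for (d in reversers) {
    cols <- meta[perturbagen_id == d, condition_id]
    for (cc in cols) {
      m[, cc] <- -s * z_std + sqrt(1 - s^2) * rnorm(ng)
    }
  }
  list(profiles = m, meta = meta, truth = reversers)
}

#' Write a full set of simulated pipeline inputs
#'
#' Generates all inputs (summary statistics, LD, genes, interactions,
#' criteria, target set, disease z-scores, drug profiles and metadata)
#' and writes them as plain-text tables under `dir`, with the planted
#' truth under `dir/truth` for assertions.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of written file paths, invisibly.
#' @export
simulate_inputs <- function(config, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  sim <- simulate_sumstats(config)
  gs <- simulate_genes_and_sets(config, sim$truth)
  # gene-level z for connectivity: reuse per-gene standard normals with
  # planted-gene inflation so a signature exists
  set.seed(config$seed + 3L)
  disease_z <- setNames(rnorm(nrow(gs$genes)), gs$genes$gene_id)
  drugs <- simulate_drug_profiles(config, disease_z)

  p <- list(
    sumstats = file.path(dir, "sumstats.tsv"),
    ld = file.path(dir, "ld.tsv"),
    genes = file.path(dir, "genes.bed"),
    criteria = file.path(dir, "criteria.tsv"),
    target_set = file.path(dir, "target_set.txt"),
    disease_z = file.path(dir, "disease_z.tsv"),
    profiles = file.path(dir, "profiles.tsv"),
    meta = file.path(dir, "profile_meta.tsv"),
    truth_loci = file.path(dir, "truth", "loci.tsv"),
    truth_genes = file.path(dir, "truth", "genes.tsv"),
    truth_reversers = file.path(dir, "truth", "reversers.txt")
  )
  write_tsv(sim$sumstats, p$sumstats)
  write_tsv(sim$ld, p$ld)
  fwrite(gs$genes[, .(chrom, start, end, gene_id)], p$genes,
         sep = "\t", col.names = FALSE)
  write_tsv(gs$criteria, p$criteria)
  writeLines(gs$target_set, p$target_set)
  write_tsv(data.table(gene_id = names(disease_z), z = disease_z),
            p$disease_z)
  prof_dt <- data.table(gene_id = rownames(drugs$profiles))
  prof_dt <- cbind(prof_dt, as.data.table(drugs$profiles))
  write_tsv(prof_dt, p$profiles)
  write_tsv(drugs$meta, p$meta)
  write_tsv(sim$truth[, .(planted_locus, block, lead_snp, lead_bp)],
            p$truth_loci)
  write_tsv(gs$truth, p$truth_genes)
  writeLines(drugs$truth, p$truth_reversers)
  invisible(p)
}
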