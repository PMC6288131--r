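# Locus definition from genome-wide significant variants and LD, and
# locus-to-gene mapping by position and by promoter chromatin
# interaction.

#' Define genome-wide significant loci
#'
#' Greedy locus construction: the lowest-p unassigned variant with
#' `p < p_gw` becomes the lead; its locus is the region encompassing all
#' unassigned variants with `p < p_member` in LD (`r2 > r2_min`) with
#' the lead (lead included). Assigned variants cannot seed or join later
#' loci. Loci with intersecting spans on the same chromosome are merged,
#' keeping the lead with the smaller p, so member sets are disjoint and
#' genes cannot be double-counted downstream.
#'
#' @param sumstats Summary statistics with `SNP`, `CHR`, `BP`, `P`.
#' @param ld LD pairs with `SNP_A`, `SNP_B`, `R2` (unordered).
#' @param p_gw Genome-wide significance threshold for leads
#'   (default `5e-8`).
#' @param p_member Membership p-value threshold (default `1e-4`).
#' @param r2_min LD threshold with the lead (default 0.2, strict `>`).
#' @return `data.table` with one row per locus, ordered by (chrom,
#'   start): `locus_id`, `lead_variant`, `lead_p`, `chrom`, `start`,
#'   `end` (1-based inclusive), `n_members` and a `members` list column.
#'   Zero rows when no variant reaches `p_gw`.
#' @export
define_loci <- function(sumstats, ld, p_gw = 5e-8, p_member = 1e-4,
                        r2_min = 0.2) {
  ss <- as.data.table(sumstats)[!is.na(P)]
  need <- c("SNP", "CHR", "BP", "P")
  if (!all(need %in% names(ss))) {
    stop("sumstats needs ", paste(need, collapse = ", "))
  }
  # deterministic order: by p then id, so output is row-order invariant
  setorder(ss, P, SNP)
  ld <- as.data.table(ld)
  partners <- rbind(
    ld[, .(snp = SNP_A, other = SNP_B, r2 = R2)],
    ld[, .(snp = SNP_B, other = SNP_A, r2 = R2)]
  )[r2 > r2_min]
  setkey(partners, snp)

  pos <- setNames(ss$BP, ss$SNP)
  chr <- setNames(ss$CHR, ss$SNP)
  pval <- setNames(ss$P, ss$SNP)
  assigned <- new.env(hash = TRUE, parent = emptyenv())

  loci <- list()
  for (i in seq_len(nrow(ss))) {
    lead <- ss$SNP[i]
    if (ss$P[i] >= p_gw) break
    if (!is.null(assigned[[lead]])) next
    cand <- partners[.(lead), other, nomatch = NULL]
    cand <- cand[cand %in% names(pos)]
    cand <- cand[vapply(cand, function(s) is.null(assigned[[s]]), TRUE)]
    members <- cand[pval[cand] < p_member & chr[cand] == chr[[lead]]]
    members <- sort(unique(c(lead, members)))
    for (s in members) assigned[[s]] <- TRUE
    loci[[length(loci) + 1L]] <- list(
      lead_variant = lead,
      lead_p = pval[[lead]],
      chrom = chr[[lead]],
      start = min(pos[members]),
      end = max(pos[members]),
      members = members
    )
  }
  if (length(loci) == 0L) {
    return(data.table(locus_id = character(), lead_variant = character(),
                      lead_p = numeric(), chrom = character(),
                      start = integer(), end = integer(),
                      n_members = integer(), members = list()))
  }
  out <- rbindlist(lapply(loci, function(l) {
    data.table(lead_variant = l$lead_variant, lead_p = l$lead_p,
               chrom = l$chrom, start = l$start, end = l$end,
               n_members = length(l$members), members = list(l$members))
  }))
  out <- merge_overlapping_loci(out)
  setorder(out, chrom, start, end)
  out[, locus_id := sprintf("%s:%d-%d", chrom, as.integer(start),
                            as.integer(end))]
  setcolorder(out, c("locus_id", "lead_variant", "lead_p", "chrom",
                     "start", "end", "n_members", "members"))
  out[]
}

# Merge loci with intersecting [start, end] on one chromosome; the
# merged locus keeps the lead with the smaller p and the union of
# members.
merge_overlapping_loci <- function(loci) {
  setorder(loci, chrom, start, end)
  merged <- list()
  cur <- NULL
  for (i in seq_len(nrow(loci))) {
    row <- loci[i]
    if (!is.null(cur) && row$chrom == cur$chrom && row$start <= cur$end) {
      cur$end <- max(cur$end, row$end)
      cur$members <- list(sort(unique(c(cur$members[[1]],
                                       row$members[[1]]))))
      if (row$lead_p < cur$lead_p) {
        cur$lead_p <- row$lead_p
        cur$lead_variant <- row$lead_variant
      }
      cur$n_members <- length(cur$members[[1]])
    } else {
      if (!is.null(cur)) merged[[length(merged) + 1L]] <- cur
      cur <- row
    }
  }
  merged[[length(merged) + 1L]] <- cur
  rbindlist(merged)
}

loci_granges <- function(loci, window_bp = 0L) {
  GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, loci$start - window_bp),
                              end = loci$end + window_bp)
  )
}

#' Positional locus-to-gene mapping
#'
#' Maps each locus to the genes whose interval lies within `window_bp`
#' of the locus span (default 250 kb, measured from the locus edges).
#' Gene annotations follow the 0-based half-open BED convention; locus
#' coordinates are 1-based inclusive; the overlap test converts
#' internally. Strand is ignored.
#'
#' @param loci Output of [define_loci()] (or any table with `locus_id`,
#'   `chrom`, `start`, `end`).
#' @param genes Gene table from [read_gene_bed()].
#' @param window_bp Flanking window in bp (default 250000).
#' @return `data.table` with `locus_id`, `gene_id`,
#'   `evidence = "positional"`.
#' @export
positional_map <- function(loci, genes, window_bp = 250000L) {
  loci <- as.data.table(loci)
  genes <- as.data.table(genes)
  if (nrow(loci) == 0L || nrow(genes) == 0L) {
    return(data.table(locus_id = character(), gene_id = character(),
                      evidence = character()))
  }
  lr <- loci_granges(loci, window_bp)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end)
  )
  hits <- GenomicRanges::findOverlaps(lr, gr)
  out <- data.table(
    locus_id = loci$locus_id[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    evidence = "positional"
  )
  unique(out)
}

#' Chromatin-interaction locus-to-gene mapping
#'
#' Maps a locus to a gene when a significant promoter interaction
#' (`fdr < fdr_max`, strict) has its anchor overlapping the locus span.
#' Anchors follow the 0-based half-open convention.
#'
#' @param loci Output of [define_loci()].
#' @param interactions Table from [read_interactions()].
#' @param fdr_max Interaction FDR threshold (default `1e-6`, strict `<`).
#' @return `data.table` with `locus_id`, `gene_id`,
#'   `evidence = "chromatin"`.
#' @export
chromatin_map <- function(loci, interactions, fdr_max = 1e-6) {
  loci <- as.data.table(loci)
  ia <- as.data.table(interactions)[fdr < fdr_max]
  if (nrow(loci) == 0L || nrow(ia) == 0L) {
    return(data.table(locus_id = character(), gene_id = character(),
                      evidence = character()))
  }
  lr <- loci_granges(loci)
  ar <- GenomicRanges::GRanges(
    seqnames = ia$anchor_chrom,
    ranges = IRanges::IRanges(start = ia$anchor_start + 1L,
                              end = ia$anchor_end)
  )
  hits <- GenomicRanges::findOverlaps(lr, ar)
  out <- data.table(
    locus_id = loci$locus_id[S4Vectors::queryHits(hits)],
    gene_id = ia$gene_id[S4Vectors::subjectHits(hits)],
    evidence = "chromatin"
  )
  unique(out)
}

#' Combined locus-to-gene mapping
#'
#' Union of the positional and chromatin-interaction maps; genes mapped
#' by both routes carry `evidence = "both"`.
#'
#' @inheritParams positional_map
#' @inheritParams chromatin_map
#' @param interactions Optional; when `NULL` only positional mapping is
#'   performed.
#' @return `data.table` with `locus_id`, `gene_id`, `evidence` in
#'   `{"positional", "chromatin", "both"}`.
#' @export
map_genes <- function(loci, genes, interactions = NULL,
                      window_bp = 250000L, fdr_max = 1e-6) {
  pm <- positional_map(loci, genes, window_bp = window_bp)
  cm <- if (is.null(interactions)) {
    data.table(locus_id = character(), gene_id = character(),
               evidence = character())
  } else {
    chromatin_map(loci, interactions, fdr_max = fdr_max)
  }
  both <- rbind(pm, cm)
  if (nrow(both) == 0L) return(both)
  both[, .(evidence = if (uniqueN(evidence) > 1L) "both" else evidence[1]),
       by = .(locus_id, gene_id)]
}

#' Pooled, de-duplicated mapped gene list
#'
#' Genes mapped to multiple loci (or multiple phenotype analyses) are
#' counted once in the pooled list used for enrichment.
#'
#' @param ... One or more mapping tables from [map_genes()].
#' @return Sorted character vector of unique gene ids.
#' @export
pooled_gene_list <- function(...) {
  maps <- list(...)
  sort(unique(unlist(lapply(maps, function(m) as.data.table(m)$gene_id))))
}
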