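# Readers and writers for the plain-text exchange formats used across
# the pipeline. All tables are tab-separated with headers (except BED),
# positions in summary statistics are 1-based, gene/anchor intervals
# follow the 0-based half-open BED convention, missing token "NA".

#' Read GWAS summary statistics
#'
#' Tab-separated with header columns `SNP`, `CHR`, `BP`, `A1`, `A2`,
#' `FREQ`, `Z`, `P`, `N_CASES`, `N_CONTROLS`. `BP` is 1-based; `Z` is
#' signed with respect to the minor allele; `FREQ` is the minor-allele
#' frequency.
#'
#' @param path File path.
#' @param validate Check p/z consistency and frequency bounds
#'   (default `TRUE`).
#' @return A `data.table`.
#' @export
read_sumstats <- function(path, validate = TRUE) {
  ss <- fread(path, sep = "\t", na.strings = "NA")
  required <- c("SNP", "CHR", "BP", "A1", "A2", "FREQ", "Z", "P")
  missing_cols <- setdiff(required, names(ss))
  if (length(missing_cols)) {
    stop("summary statistics missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  ss[, CHR := as.character(CHR)]
  if (validate) validate_sumstats(ss)
  ss
}

#' Validate summary-statistic invariants
#'
#' Checks that stored p-values are consistent with the two-sided normal
#' map of the z-scores (1e-6 relative tolerance; stored `P` takes
#' precedence and is not overwritten) and that minor-allele frequencies
#' lie in (0, 0.5].
#'
#' @param sumstats Table as returned by [read_sumstats()].
#' @return The input, invisibly. Inconsistencies raise an error.
#' @export
validate_sumstats <- function(sumstats) {
  ss <- as.data.table(sumstats)
  both <- !is.na(ss$P) & !is.na(ss$Z)
  if (any(both)) {
    p_from_z <- 2 * pnorm(-abs(ss$Z[both]))
    bad <- abs(p_from_z - ss$P[both]) > 1e-6 * pmax(ss$P[both], p_from_z)
    if (any(bad)) {
      stop(sum(bad), " variant(s) with P inconsistent with |Z| ",
           "(first: ", ss$SNP[both][which(bad)[1]], ")")
    }
  }
  if ("FREQ" %in% names(ss)) {
    f <- ss$FREQ[!is.na(ss$FREQ)]
    if (any(f <= 0 | f > 0.5)) {
      stop("minor-allele frequencies must lie in (0, 0.5]")
    }
  }
  if (any(!is.na(ss$P) & (ss$P <= 0 | ss$P > 1))) {
    stop("p-values must lie in (0, 1]")
  }
  invisible(sumstats)
}

#' Read an LD pair table
#'
#' Tab-separated with header `SNP_A`, `SNP_B`, `R2`. Pairs are
#' unordered; `R2` must lie in \\[0, 1\\].
#'
#' @param path File path.
#' @return A `data.table`.
#' @export
read_ld_pairs <- function(path) {
  ld <- fread(path, sep = "\t", na.strings = "NA")
  if (!all(c("SNP_A", "SNP_B", "R2") %in% names(ld))) {
    stop("LD table needs SNP_A, SNP_B, R2")
  }
  if (any(ld$R2 < 0 | ld$R2 > 1, na.rm = TRUE)) stop("R2 outside [0, 1]")
  ld
}

#' Read gene annotations from BED
#'
#' Four-column BED (`chrom`, `start`, `end`, `name`), 0-based half-open,
#' no header. Gene size in bp is `end - start`.
#'
#' @param path File path.
#' @return `data.table` with `chrom`, `start`, `end`, `gene_id`,
#'   `size_bp`.
#' @export
read_gene_bed <- function(path) {
  genes <- fread(path, sep = "\t", header = FALSE,
                 col.names = c("chrom", "start", "end", "gene_id"))
  if (any(genes$end <= genes$start)) stop("gene end must exceed start")
  genes[, chrom := as.character(chrom)]
  genes[, size_bp := end - start]
  genes
}

#' Read a promoter-locus chromatin interaction table
#'
#' Tab-separated with header `anchor_chrom`, `anchor_start`,
#' `anchor_end`, `gene_id`, `fdr`. Anchor intervals are 0-based
#' half-open; `fdr` is the precomputed interaction FDR.
#'
#' @param path File path.
#' @return A `data.table`.
#' @export
read_interactions <- function(path) {
  x <- fread(path, sep = "\t", na.strings = "NA")
  need <- c("anchor_chrom", "anchor_start", "anchor_end", "gene_id", "fdr")
  if (!all(need %in% names(x))) {
    stop("interaction table needs ", paste(need, collapse = ", "))
  }
  if (any(x$fdr < 0 | x$fdr > 1, na.rm = TRUE)) stop("fdr outside [0, 1]")
  x[, anchor_chrom := as.character(anchor_chrom)]
  x
}

#' Read a gene criteria table
#'
#' Tab-separated: `gene_id` plus one 0/1 column per prioritization
#' criterion, named in the header. The standard scheme has six criteria
#' (TWAS, eQTL in locus, brain-preferential expression, missense in
#' locus, protein-interaction prioritization, knockout-mouse phenotype).
#'
#' @param path File path.
#' @return A `data.table`.
#' @export
read_criteria <- function(path) {
  x <- fread(path, sep = "\t", na.strings = "NA")
  if (!"gene_id" %in% names(x)) stop("criteria table needs gene_id")
  crit <- setdiff(names(x), "gene_id")
  for (cc in crit) {
    v <- x[[cc]]
    if (!all(v %in% c(0, 1, NA))) stop("criterion column not 0/1: ", cc)
  }
  x
}

#' Read a gene set (one id per line)
#' @param path File path.
#' @return Character vector of unique ids.
#' @export
read_gene_set <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  unique(lines[nzchar(lines)])
}

#' Read a perturbagen profile matrix and its metadata
#'
#' The profile matrix is tab-separated with a `gene_id` first column and
#' one column per profiled condition; the metadata table maps each
#' condition column to its perturbagen (`condition_id`,
#' `perturbagen_id`, plus free annotation columns such as cell line,
#' dose, time).
#'
#' @param profiles_path,meta_path File paths.
#' @return List with `profiles` (numeric matrix, genes in rows) and
#'   `meta` (`data.table`).
#' @export
read_drug_profiles <- function(profiles_path, meta_path) {
  prof <- fread(profiles_path, sep = "\t")
  if (!"gene_id" %in% names(prof)) stop("profile matrix needs gene_id")
  m <- as.matrix(prof[, !"gene_id"])
  rownames(m) <- prof$gene_id
  meta <- fread(meta_path, sep = "\t")
  if (!all(c("condition_id", "perturbagen_id") %in% names(meta))) {
    stop("metadata needs condition_id and perturbagen_id")
  }
  if (!all(colnames(m) %in% meta$condition_id)) {
    stop("profile columns missing from metadata")
  }
  list(profiles = m, meta = meta)
}

#' Read a gene-to-z table (two columns: gene_id, z)
#' @param path File path.
#' @return Named numeric vector of signed z-scores.
#' @export
read_gene_z <- function(path) {
  x <- fread(path, sep = "\t")
  if (!all(c("gene_id", "z") %in% names(x))) stop("needs gene_id and z")
  setNames(x$z, x$gene_id)
}

#' Write a table as tab-separated text
#' @param x Table.
#' @param path Destination.
#' @export
write_tsv <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
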