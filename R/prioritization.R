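# Multi-criteria biological gene prioritization: score mapped genes on
# boolean evidence criteria and select the top-scoring gene(s) per
# locus.

#' Score genes on boolean evidence criteria
#'
#' Each gene's score is the number of criteria met, with equal weight 1
#' per criterion. The standard scheme has six criteria (significant
#' TWAS association, cis-eQTL in the locus, brain-preferential
#' expression, missense variant in the locus, protein-interaction
#' network prioritization, nervous-system/behavioural knockout-mouse
#' phenotype), giving scores in 0-6; the scorer accepts any number of
#' boolean columns.
#'
#' @param criteria `data.frame` with a `gene_id` column and one logical
#'   or 0/1 column per criterion. `NA` (missing evidence) counts as
#'   `FALSE`.
#' @return `data.table` with `gene_id` and integer `score`.
#' @export
score_genes <- function(criteria) {
  x <- as.data.table(criteria)
  if (!"gene_id" %in% names(x)) stop("criteria needs gene_id")
  crit_cols <- setdiff(names(x), "gene_id")
  if (length(crit_cols) == 0L) stop("no criterion columns")
  m <- as.matrix(x[, ..crit_cols])
  if (!(is.logical(m) || all(m %in% c(0, 1, NA)))) {
    stop("criterion entries must be boolean (0/1)")
  }
  storage.mode(m) <- "numeric"
  m[is.na(m)] <- 0
  data.table(gene_id = x$gene_id, score = as.integer(rowSums(m)))
}

#' Prioritize genes per locus
#'
#' Per locus, returns every gene attaining the maximum score, provided
#' that maximum reaches `min_score`; otherwise the locus gets no
#' prioritized gene (an empty set, conventionally reported as "none").
#' Genes mapped to several loci are scored once but can be prioritized
#' in each locus independently.
#'
#' @param scores Output of [score_genes()].
#' @param mappings Locus-to-gene table with `locus_id`, `gene_id`
#'   (see [map_genes()]). Mapped genes absent from `scores` are treated
#'   as all-criteria-false (score 0) with a warning.
#' @param min_score Minimum qualifying score (default 2).
#' @return Named list: one character vector of prioritized gene ids per
#'   locus (possibly empty), names = locus ids.
#' @export
prioritize_genes <- function(scores, mappings, min_score = 2L) {
  sc <- as.data.table(scores)
  mp <- unique(as.data.table(mappings)[, .(locus_id, gene_id)])
  missing_genes <- setdiff(mp$gene_id, sc$gene_id)
  if (length(missing_genes)) {
    warning(length(missing_genes),
            " mapped gene(s) absent from criteria; scored 0")
    sc <- rbind(sc, data.table(gene_id = missing_genes, score = 0L))
  }
  mp <- sc[mp, on = "gene_id"]
  out <- lapply(split(mp, by = "locus_id", sorted = TRUE), function(d) {
    top <- max(d$score)
    if (top >= min_score) sort(d$gene_id[d$score == top]) else character(0)
  })
  out
}

#' Flat prioritization table
#'
#' Tabular form of [prioritize_genes()] for writing: one row per
#' mapped gene with its score and a prioritized flag.
#'
#' @inheritParams prioritize_genes
#' @return `data.table` with `locus_id`, `gene_id`, `score`,
#'   `prioritized`.
#' @export
prioritization_table <- function(scores, mappings, min_score = 2L) {
  pri <- prioritize_genes(scores, mappings, min_score = min_score)
  sc <- as.data.table(scores)
  mp <- unique(as.data.table(mappings)[, .(locus_id, gene_id)])
  mp <- sc[mp, on = "gene_id"]
  mp[is.na(score), score := 0L]
  mp[, prioritized := mapply(function(l, g) g %in% pri[[l]],
                             locus_id, gene_id)]
  setorder(mp, locus_id, -score, gene_id)
  setcolorder(mp, c("locus_id", "gene_id", "score", "prioritized"))
  mp[]
}

#' Brain-preferential expression flag
#'
#' A gene is flagged brain-preferential when its average expression over
#' all brain tissues strictly exceeds its average over non-brain
#' tissues.
#'
#' @param expr Numeric gene-by-tissue matrix with gene row names and
#'   tissue column names.
#' @param brain_tissues Tissue ids forming the brain group; the
#'   remaining columns form the non-brain group. Both groups must be
#'   non-empty.
#' @return Named logical vector per gene. Genes with all-missing
#'   expression are `FALSE` with a warning.
#' @export
brain_preferential_expression <- function(expr, brain_tissues) {
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expr needs gene row names and tissue column names")
  }
  brain <- intersect(colnames(expr), brain_tissues)
  other <- setdiff(colnames(expr), brain_tissues)
  if (length(brain) == 0L || length(other) == 0L) {
    stop("need at least one brain and one non-brain tissue")
  }
  mb <- rowMeans(expr[, brain, drop = FALSE], na.rm = TRUE)
  mo <- rowMeans(expr[, other, drop = FALSE], na.rm = TRUE)
  out <- mb > mo
  all_missing <- !is.finite(mb) | !is.finite(mo)
  if (any(all_missing)) {
    warning(sum(all_missing),
            " gene(s) with all-missing expression flagged FALSE")
    out[all_missing] <- FALSE
  }
  out
}
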