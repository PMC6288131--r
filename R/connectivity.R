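# Connectivity mapping: disease expression signature from gene-level
# association z-scores, cosine reversal scores against perturbagen
# profiles, per-drug condition collapse, permutation null thresholds,
# and drug-set enrichment by overlap and median rank.

#' Build a disease expression signature
#'
#' Selects the top fraction of scored genes by absolute association
#' z-score (default the top decile), retaining the signs. Ties at the
#' cutoff are broken by gene id lexicographic order so the signature is
#' deterministic.
#'
#' @param z_by_gene Named numeric vector of signed gene-level z-scores.
#' @param top_fraction Fraction of genes to keep (default 0.1); the
#'   signature size is `ceiling(top_fraction * length(z_by_gene))`.
#' @return Named numeric vector: the signature genes and their signed
#'   z-scores.
#' @export
build_disease_signature <- function(z_by_gene, top_fraction = 0.1) {
  if (length(z_by_gene) == 0L) stop("z_by_gene is empty")
  if (is.null(names(z_by_gene)) || anyNA(names(z_by_gene))) {
    stop("z_by_gene must be named by gene")
  }
  n_keep <- ceiling(top_fraction * length(z_by_gene))
  ord <- order(-abs(z_by_gene), names(z_by_gene))
  z_by_gene[ord[seq_len(n_keep)]]
}

#' Cosine connectivity between a signature and one profile
#'
#' Cosine similarity over the genes common to the signature and the
#' profile, reported under the reversal sign convention: negative scores
#' mean the perturbagen shifts expression opposite to the disease
#' (candidate therapeutic), positive scores mean mimicry.
#'
#' @param signature Named numeric disease signature
#'   (see [build_disease_signature()]).
#' @param profile Named numeric expression-change vector.
#' @return Cosine score in \\[-1, 1\\], or `NA` when fewer than 2 genes
#'   are shared or a vector has zero norm.
#' @export
cosine_connectivity <- function(signature, profile) {
  common <- intersect(names(signature), names(profile))
  if (length(common) < 2L) return(NA_real_)
  x <- signature[common]
  y <- profile[common]
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  sum(x * y) / (nx * ny)
}

# Cosine of one signature against every column of a profile matrix,
# restricted to the genes shared between signature and matrix rows.
cosine_columns <- function(signature, profiles) {
  common <- intersect(rownames(profiles), names(signature))
  if (length(common) < 2L) {
    return(setNames(rep(NA_real_, ncol(profiles)), colnames(profiles)))
  }
  s <- signature[common]
  m <- profiles[common, , drop = FALSE]
  num <- as.vector(crossprod(m, s))
  den <- sqrt(colSums(m^2)) * sqrt(sum(s^2))
  out <- num / den
  out[den == 0] <- NA_real_
  setNames(out, colnames(profiles))
}

#' Collapse per-condition scores to one score per perturbagen
#'
#' A perturbagen profiled in several conditions (cell line, dose, time)
#' keeps the score with the largest absolute value, whether positive or
#' negative, as that extreme is least likely under chance. Ties on
#' absolute value are broken toward the negative score, then by
#' condition id.
#'
#' @param scores Numeric scores for one perturbagen's conditions.
#' @param conditions Condition ids parallel to `scores`.
#' @return List with `score` and `best_condition`; `NULL` when no
#'   condition is scorable.
#' @export
collapse_conditions <- function(scores, conditions = seq_along(scores)) {
  ok <- !is.na(scores)
  if (!any(ok)) return(NULL)
  scores <- scores[ok]
  conditions <- conditions[ok]
  ord <- order(-abs(scores), scores, conditions)
  list(score = scores[ord[1L]],
       best_condition = as.character(conditions[ord[1L]]))
}

#' Score and rank all perturbagens against a disease signature
#'
#' Computes the cosine connectivity of every profiled condition, then
#' collapses conditions per perturbagen ([collapse_conditions()]) and
#' ranks perturbagens by ascending score (rank 1 = strongest reverser;
#' ties share the mean rank).
#'
#' @param signature Named numeric disease signature.
#' @param profiles Numeric matrix, genes in rows (row names = gene ids),
#'   one column per profiled condition (column names = condition ids).
#' @param meta Optional `data.frame` with `condition_id` and
#'   `perturbagen_id` mapping columns to perturbagens; when `NULL` each
#'   column is its own perturbagen.
#' @return `data.table` with `perturbagen_id`, `score`,
#'   `best_condition`, `rank`. Perturbagens with no scorable condition
#'   are dropped with a warning.
#' @export
score_perturbagens <- function(signature, profiles, meta = NULL) {
  cond_scores <- cosine_columns(signature, profiles)
  if (is.null(meta)) {
    meta <- data.table(condition_id = colnames(profiles),
                       perturbagen_id = colnames(profiles))
  }
  meta <- as.data.table(meta)[, .(condition_id, perturbagen_id)]
  meta <- meta[condition_id %in% names(cond_scores)]
  meta[, score := cond_scores[condition_id]]
  scored <- meta[!is.na(score)]
  # vectorized collapse: per perturbagen keep the largest |score|,
  # ties toward the negative score, then by condition id
  scored <- scored[order(perturbagen_id, -abs(score), score, condition_id)]
  collapsed <- scored[!duplicated(perturbagen_id),
                      .(perturbagen_id, score, best_condition = condition_id)]
  dropped <- setdiff(unique(meta$perturbagen_id), collapsed$perturbagen_id)
  if (length(dropped)) {
    warning(length(dropped),
            " perturbagen(s) with no scorable condition dropped")
  }
  collapsed[, rank := rank(score, ties.method = "average")]
  setorder(collapsed, rank)
  collapsed[]
}

#' Permutation null distribution and significance threshold
#'
#' For each permutation the gene-level z-scores are randomly permuted
#' across gene labels, the disease signature is rebuilt from the
#' permuted scores, and every perturbagen is scored and collapsed as in
#' the observed analysis. The pooled null therefore holds
#' `n_perm * N_drugs` cosine values; the significance threshold is its
#' empirical lower `alpha`-quantile (inverse-ECDF; `alpha = 0` gives the
#' minimum).
#'
#' @param z_by_gene Named numeric gene-level z-scores (all scored
#'   genes, not just the signature).
#' @param profiles,meta As in [score_perturbagens()].
#' @param n_perm Number of permutations (default 100).
#' @param alpha Lower-tail significance level (default 0.05).
#' @param top_fraction Signature fraction (default 0.1).
#' @param seed Optional integer seed for reproducibility.
#' @return A `null_threshold`: list with `pooled_null`, `alpha`,
#'   `threshold`, `n_perm`, `n_drugs`.
#' @export
permutation_null <- function(z_by_gene, profiles, meta = NULL,
                             n_perm = 100L, alpha = 0.05,
                             top_fraction = 0.1, seed = NULL) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  genes <- names(z_by_gene)
  pooled <- vector("list", n_perm)
  n_drugs <- NA_integer_
  for (b in seq_len(n_perm)) {
    z_perm <- setNames(sample(unname(z_by_gene)), genes)
    sig <- build_disease_signature(z_perm, top_fraction = top_fraction)
    sc <- suppressWarnings(score_perturbagens(sig, profiles, meta))
    n_drugs <- nrow(sc)
    pooled[[b]] <- sc$score
  }
  pooled <- unlist(pooled)
  threshold <- unname(quantile(pooled, probs = alpha, type = 1))
  structure(list(pooled_null = pooled, alpha = alpha,
                 threshold = threshold, n_perm = n_perm,
                 n_drugs = n_drugs),
            class = "null_threshold")
}

#' @export
print.null_threshold <- function(x, ...) {
  cat(sprintf(
    "Permutation null: %d x %d = %d values; alpha = %g -> threshold %.4f\n",
    x$n_perm, x$n_drugs, length(x$pooled_null), x$alpha, x$threshold))
  invisible(x)
}

#' Perturbagens significantly reversing the disease signature
#'
#' @param scores Output of [score_perturbagens()].
#' @param threshold Cosine threshold from [permutation_null()] (its
#'   `threshold` element is extracted automatically).
#' @return Character vector of perturbagen ids with score strictly below
#'   the threshold.
#' @export
significant_reversers <- function(scores, threshold) {
  if (inherits(threshold, "null_threshold")) threshold <- threshold$threshold
  scores <- as.data.table(scores)
  scores[score < threshold, perturbagen_id]
}

#' Permutation p-value for overlap with a reference drug set
#'
#' Draws `n_iter` random drug sets of the same size as the significant
#' set and counts how many contain at least the observed number of
#' reference drugs. The add-one estimator
#' `(count + 1) / (n_iter + 1)` keeps the p-value positive, so a zero
#' count is reported as below `1 / (n_iter + 1)`.
#'
#' @param significant Significant perturbagen ids (subset of
#'   `all_drugs`).
#' @param reference Reference set ids (subset of `all_drugs`).
#' @param all_drugs All scored perturbagen ids.
#' @param n_iter Monte-Carlo iterations (default 1e6).
#' @param seed Optional integer seed.
#' @return Permutation p-value in (0, 1]; 1 when the significant set is
#'   empty.
#' @export
set_overlap_permutation_p <- function(significant, reference, all_drugs,
                                      n_iter = 1e6, seed = NULL) {
  significant <- unique(significant)
  reference <- unique(reference)
  all_drugs <- unique(all_drugs)
  if (!all(significant %in% all_drugs) || !all(reference %in% all_drugs)) {
    stop("significant and reference must be subsets of all_drugs")
  }
  if (length(significant) == 0L) return(1)
  if (!is.null(seed)) set.seed(seed)
  observed <- length(intersect(significant, reference))
  if (observed == 0L) return(1)
  is_ref <- all_drugs %in% reference
  n_all <- length(all_drugs)
  m <- length(significant)
  count <- 0L
  for (i in seq_len(n_iter)) {
    if (sum(is_ref[sample.int(n_all, m)]) >= observed) count <- count + 1L
  }
  (count + 1) / (n_iter + 1)
}

#' Median-rank enrichment of a drug set
#'
#' Tests whether a reference drug set ranks higher (more strongly
#' signature-reversing, i.e. smaller ranks) than random sets of the same
#' size: the p-value is the add-one-corrected fraction of `n_iter`
#' random same-size sets whose median rank is at most the observed
#' median rank. Ranks are ascending in score (rank 1 = most negative);
#' the median of an even count is the mean of the two central values.
#'
#' @param scores Output of [score_perturbagens()] (must carry `rank`).
#' @param drug_set Reference perturbagen ids; must intersect the scored
#'   drugs.
#' @param n_iter Monte-Carlo iterations (default 1e6).
#' @param seed Optional integer seed.
#' @return List with `median_rank_all`, `median_rank_set`, `shift`
#'   (`all - set`; positive when the set ranks better than average) and
#'   the permutation `p`.
#' @export
median_rank_enrichment <- function(scores, drug_set, n_iter = 1e6,
                                   seed = NULL) {
  scores <- as.data.table(scores)
  in_set <- scores$perturbagen_id %in% drug_set
  if (!any(in_set)) stop("drug_set does not intersect the scored drugs")
  if (!is.null(seed)) set.seed(seed)
  ranks <- scores$rank
  m <- sum(in_set)
  med_all <- median(ranks)
  med_set <- median(ranks[in_set])
  count <- 0L
  for (i in seq_len(n_iter)) {
    if (median(ranks[sample.int(length(ranks), m)]) <= med_set) {
      count <- count + 1L
    }
  }
  list(median_rank_all = med_all,
       median_rank_set = med_set,
       shift = med_all - med_set,
       p = (count + 1) / (n_iter + 1))
}
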