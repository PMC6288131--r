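# Summary-statistic level QC: effective sample size, genomic inflation,
# LD-aware chi-square outlier filtering, heterogeneity filtering and
# sample-size-weighted fixed-effects meta-analysis.

#' Effective sample size of a case-control stratum
#'
#' Computes the balanced-design sample size with equivalent power,
#' `4 / (1/n_cases + 1/n_controls)`, the quantity used to weight
#' sample-size-based fixed-effects meta-analyses of unbalanced
#' case-control strata.
#'
#' @param n_cases,n_controls Positive case and control counts. Vectorized.
#' @return Numeric effective sample size, at most `n_cases + n_controls`
#'   with equality iff the design is balanced.
#' @examples
#' effective_sample_size(1000, 1000)   # 2000
#' effective_sample_size(15212, 29677) # about 40228
#' @export
effective_sample_size <- function(n_cases, n_controls) {
  if (any(!is.finite(n_cases)) || any(!is.finite(n_controls)) ||
      any(n_cases <= 0) || any(n_controls <= 0)) {
    stop("n_cases and n_controls must be positive")
  }
  4 / (1 / n_cases + 1 / n_controls)
}

#' Genomic inflation factor
#'
#' The genomic inflation factor lambda is the median of the observed
#' association chi-square statistics divided by the median of the
#' 1-df chi-square distribution (0.4549...). Values above 1 indicate
#' polygenicity or confounding.
#'
#' @param chi2_values Non-empty numeric vector of non-negative 1-df
#'   chi-square statistics (z-squared).
#' @return An object of class `inflation_report`: a list with
#'   `lambda_gc` and `mean_chi2`.
#' @seealso [lambda_1000()] for the sample-size-standardized version.
#' @export
genomic_inflation <- function(chi2_values) {
  chi2_values <- chi2_values[!is.na(chi2_values)]
  if (length(chi2_values) == 0L) stop("chi2_values must be non-empty")
  if (any(chi2_values < 0)) stop("chi-square statistics must be non-negative")
  out <- list(
    lambda_gc = median(chi2_values) / qchisq(0.5, df = 1),
    mean_chi2 = mean(chi2_values)
  )
  class(out) <- "inflation_report"
  out
}

#' @export
print.inflation_report <- function(x, ...) {
  cat(sprintf("Genomic inflation: lambda = %.4f, mean chi2 = %.4f\n",
              x$lambda_gc, x$mean_chi2))
  invisible(x)
}

#' Inflation rescaled to 1000 cases and 1000 controls
#'
#' Lambda scales with sample size, so studies are compared after
#' rescaling to an equivalent study of 1000 cases and 1000 controls:
#' `1 + (lambda - 1) * 500 * (1/n_cases + 1/n_controls)`.
#'
#' @param lambda_gc Genomic inflation factor (> 0).
#' @param n_cases,n_controls Positive sample counts.
#' @return The rescaled inflation factor; equals `lambda_gc` when the
#'   study already has 1000 cases and 1000 controls.
#' @export
lambda_1000 <- function(lambda_gc, n_cases, n_controls) {
  if (any(lambda_gc <= 0)) stop("lambda_gc must be positive")
  if (any(n_cases <= 0) || any(n_controls <= 0)) {
    stop("sample sizes must be positive")
  }
  1 + (lambda_gc - 1) * 500 * (1 / n_cases + 1 / n_controls)
}

#' Flag LD pairs with extreme chi-square differences
#'
#' Compares association chi-square statistics (z-squared) between all
#' pairs of variants in high LD. A pair is flagged when the absolute
#' chi-square difference exceeds a cutoff that scales exponentially with
#' the magnitude of the statistics and the LD between the pair:
#' `3 * sqrt((chi2_1 + chi2_2) / 2) / (r2)^2`. A large, isolated
#' statistic unsupported by its LD partners is the signature of a
#' spurious signal, so the larger-chi-square member of a flagged pair is
#' marked for removal.
#'
#' @param sumstats `data.frame` with columns `SNP` and `Z`.
#' @param ld `data.frame` of LD pairs with columns `SNP_A`, `SNP_B`,
#'   `R2`. Pairs are treated as unordered; duplicated orientations are
#'   collapsed.
#' @param r2_min Only pairs with `R2 > r2_min` are evaluated (default
#'   0.4). Pairs with `R2 == 0` are skipped (cutoff undefined).
#' @return A `data.table` with one row per evaluated pair: the two
#'   variant ids, their chi-squares, `r2`, `cutoff`, `flagged`, and
#'   `remove_variant` (the larger-chi-square member, `NA` when not
#'   flagged). Row order follows (snp_a, snp_b) lexicographic order so
#'   the result is invariant to input row order.
#' @export
chi2_ld_pair_filter <- function(sumstats, ld, r2_min = 0.4) {
  ss <- as.data.table(sumstats)
  if (!all(c("SNP", "Z") %in% names(ss))) stop("sumstats needs SNP and Z")
  ld <- as.data.table(ld)
  if (!all(c("SNP_A", "SNP_B", "R2") %in% names(ld))) {
    stop("ld needs SNP_A, SNP_B, R2")
  }
  chi2 <- setNames(ss$Z^2, ss$SNP)
  # canonical unordered pair, drop duplicates and self-pairs
  a <- pmin(ld$SNP_A, ld$SNP_B)
  b <- pmax(ld$SNP_A, ld$SNP_B)
  pairs <- unique(data.table(snp_a = a, snp_b = b, r2 = ld$R2))
  pairs <- pairs[snp_a != snp_b & r2 > r2_min & r2 > 0]
  pairs <- pairs[snp_a %in% names(chi2) & snp_b %in% names(chi2)]
  setkey(pairs, snp_a, snp_b)
  if (nrow(pairs) == 0L) {
    return(pairs[, `:=`(chi2_a = numeric(), chi2_b = numeric(),
                        cutoff = numeric(), flagged = logical(),
                        remove_variant = character())][])
  }
  pairs[, chi2_a := chi2[snp_a]]
  pairs[, chi2_b := chi2[snp_b]]
  pairs[, cutoff := 3 * sqrt((chi2_a + chi2_b) / 2) / r2^2]
  pairs[, flagged := abs(chi2_a - chi2_b) > cutoff]
  pairs[, remove_variant := fifelse(
    flagged, fifelse(chi2_a >= chi2_b, snp_a, snp_b), NA_character_)]
  pairs[]
}

#' Cochran's Q heterogeneity test for one variant across strata
#'
#' Fixed-effects heterogeneity: `Q = sum w_i (beta_i - beta_bar)^2` with
#' inverse-variance weights `w_i = 1/se_i^2`, referred to a chi-square
#' distribution with `k - 1` degrees of freedom. Variants with
#' significant heterogeneity of effect across cohort clusters
#' (`p < p_threshold`) are marked for removal.
#'
#' @param beta Per-stratum effect estimates.
#' @param se Per-stratum standard errors (finite, positive).
#' @param p_threshold Removal threshold on the heterogeneity p-value
#'   (default `1e-8`).
#' @return List with `Q`, `df`, `p` and logical `remove`. With a single
#'   stratum `Q` and `p` are `NA` and the variant is kept.
#' @export
heterogeneity_test <- function(beta, se, p_threshold = 1e-8) {
  if (length(beta) != length(se)) stop("beta and se lengths differ")
  if (length(beta) < 1L) stop("at least one stratum required")
  if (length(beta) == 1L) {
    return(list(Q = NA_real_, df = 0L, p = NA_real_, remove = FALSE))
  }
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("standard errors must be finite and positive")
  }
  w <- 1 / se^2
  beta_bar <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - beta_bar)^2)
  df <- length(beta) - 1L
  p <- pchisq(Q, df = df, lower.tail = FALSE)
  list(Q = Q, df = df, p = p, remove = p < p_threshold)
}

#' Fixed-effects meta-analysis of one variant across strata
#'
#' Default scheme is the sample-size-weighted z-score combination,
#' `z_meta = sum(z_i * w_i) / sqrt(sum(w_i^2))` with
#' `w_i = sqrt(n_eff_i)`, the scheme for which per-stratum effective
#' sample sizes are computed. An inverse-variance alternative on
#' (beta, se) is available via `method = "ivw"`.
#'
#' @param z Per-stratum signed z-scores (sample-size scheme).
#' @param n_eff Per-stratum effective sample sizes (sample-size scheme).
#' @param beta,se Per-stratum effects and standard errors (`"ivw"` only).
#' @param method `"sample_size"` (default) or `"ivw"`.
#' @return List with `z_meta` and two-sided `p_meta` (and `beta_meta`,
#'   `se_meta` under `"ivw"`).
#' @export
meta_analyze <- function(z = NULL, n_eff = NULL, beta = NULL, se = NULL,
                         method = c("sample_size", "ivw")) {
  method <- match.arg(method)
  if (method == "sample_size") {
    if (is.null(z) || is.null(n_eff)) stop("z and n_eff required")
    if (length(z) == 0L) stop("at least one stratum required")
    if (length(z) != length(n_eff)) stop("z and n_eff lengths differ")
    if (any(n_eff <= 0)) stop("n_eff must be positive")
    w <- sqrt(n_eff)
    z_meta <- sum(z * w) / sqrt(sum(w^2))
  } else {
    if (is.null(beta) || is.null(se)) stop("beta and se required for ivw")
    if (length(beta) == 0L) stop("at least one stratum required")
    w <- 1 / se^2
    beta_meta <- sum(w * beta) / sum(w)
    se_meta <- sqrt(1 / sum(w))
    z_meta <- beta_meta / se_meta
  }
  out <- list(z_meta = z_meta, p_meta = 2 * pnorm(-abs(z_meta)))
  if (method == "ivw") {
    out$beta_meta <- beta_meta
    out$se_meta <- se_meta
  }
  out
}

#' Summary-statistic QC: filters plus an inflation report
#'
#' Applies the LD-aware chi-square pair filter and (optionally) the
#' per-variant heterogeneity filter, then reports genomic inflation on
#' the retained variants.
#'
#' @param sumstats Summary-statistic table (see [read_sumstats()]).
#' @param ld Optional LD pair table for [chi2_ld_pair_filter()].
#' @param r2_min LD threshold for the pair filter.
#' @param het Optional heterogeneity table: one row per variant and
#'   stratum with columns `SNP`, `beta`, `se`.
#' @param het_p Heterogeneity removal threshold.
#' @return List with the filtered `sumstats`, the per-filter removal id
#'   sets, the flagged-pair table, and the `inflation` report (with
#'   `lambda_1000` when per-variant sample sizes are present).
#' @export
qc_sumstats <- function(sumstats, ld = NULL, r2_min = 0.4,
                        het = NULL, het_p = 1e-8) {
  ss <- as.data.table(sumstats)
  removed_ld <- character()
  pair_table <- NULL
  if (!is.null(ld)) {
    pair_table <- chi2_ld_pair_filter(ss, ld, r2_min = r2_min)
    removed_ld <- unique(pair_table$remove_variant[pair_table$flagged])
  }
  removed_het <- character()
  if (!is.null(het)) {
    het <- as.data.table(het)
    removed_het <- het[, heterogeneity_test(beta, se, het_p)$remove,
                       by = SNP][V1 == TRUE, SNP]
  }
  keep <- !(ss$SNP %in% c(removed_ld, removed_het))
  out <- ss[keep]
  infl <- genomic_inflation(out$Z^2)
  l1000 <- if (all(c("N_CASES", "N_CONTROLS") %in% names(out)) &&
               nrow(out) > 0L) {
    lambda_1000(infl$lambda_gc, max(out$N_CASES), max(out$N_CONTROLS))
  } else NA_real_
  list(sumstats = out,
       removed_ld_filter = removed_ld,
       removed_het_filter = removed_het,
       flagged_pairs = pair_table,
       inflation = infl,
       lambda_1000 = l1000)
}
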