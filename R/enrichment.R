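# Gene-set enrichment: 2x2 overlap tables, sample odds ratios, exact
# central hypergeometric tails, and a gene-length-bias-corrected
# Wallenius noncentral hypergeometric test.

#' Build a gene-set enrichment table
#'
#' Overlap configuration for testing whether a drawn gene list (e.g.
#' genes mapped to significant loci) is enriched for a curated target
#' set (e.g. monogenic disease genes or drug targets) against a universe
#' of protein-coding genes. The universe total counts all protein-coding
#' genes, with the drawn genes inside it.
#'
#' @param drawn Character vector of drawn gene ids.
#' @param target Character vector of target-set gene ids.
#' @param universe_n Total number of genes in the universe.
#' @return An `enrichment_table`: list with `universe_n`, `target_k`,
#'   `drawn_n`, `overlap_a`.
#' @seealso [enrichment_counts()] to build a table directly from counts.
#' @export
enrichment_table <- function(drawn, target, universe_n) {
  drawn <- unique(drawn)
  target <- unique(target)
  enrichment_counts(universe_n = universe_n,
                    target_k = length(target),
                    drawn_n = length(drawn),
                    overlap_a = length(intersect(drawn, target)))
}

#' Enrichment table from counts
#'
#' @param universe_n Universe size N (all protein-coding genes,
#'   drawn genes included).
#' @param target_k Target-set size K.
#' @param drawn_n Number of drawn genes n.
#' @param overlap_a Observed overlap a.
#' @return An `enrichment_table`.
#' @export
enrichment_counts <- function(universe_n, target_k, drawn_n, overlap_a) {
  stopifnot(universe_n >= 0, target_k >= 0, drawn_n >= 0, overlap_a >= 0)
  if (drawn_n > universe_n) stop("drawn_n exceeds universe_n")
  if (target_k > universe_n) stop("target_k exceeds universe_n")
  if (overlap_a > min(target_k, drawn_n)) {
    stop("overlap exceeds min(target_k, drawn_n)")
  }
  if (drawn_n + target_k - overlap_a > universe_n) {
    stop("counts exceed universe")
  }
  structure(list(universe_n = universe_n, target_k = target_k,
                 drawn_n = drawn_n, overlap_a = overlap_a),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("Enrichment table: N = %d, K = %d, n = %d, a = %d\n",
              x$universe_n, x$target_k, x$drawn_n, x$overlap_a))
  invisible(x)
}

#' Sample odds ratio of an enrichment table
#'
#' Cross-product odds ratio `(a*d)/(b*c)` of the 2x2 table with
#' `b = n - a`, `c = K - a`, `d = N - n - K + a`. Returns 0 when
#' `a = 0` and `Inf` when a off-diagonal margin is exhausted with
#' `a*d > 0`.
#'
#' @param table An `enrichment_table`.
#' @return Non-negative numeric odds ratio.
#' @export
enrichment_odds_ratio <- function(table) {
  a <- table$overlap_a
  b <- table$drawn_n - a
  cc <- table$target_k - a
  d <- table$universe_n - table$drawn_n - table$target_k + a
  if (a == 0) return(0)
  if (b * cc == 0) return(if (a * d > 0) Inf else NaN)
  (a * d) / (b * cc)
}

#' Exact central hypergeometric enrichment test
#'
#' Upper-tail probabilities of the overlap under random sampling without
#' replacement: `p_strict = P(X > a)` and `p_inclusive = P(X >= a)`.
#' Both conventions are returned because published single-number
#' "hypergeometric p" values differ in which tail they report.
#'
#' @param table An `enrichment_table`.
#' @return List with `p_strict` and `p_inclusive`.
#' @export
hypergeom_test <- function(table) {
  a <- table$overlap_a
  K <- table$target_k
  N <- table$universe_n
  n <- table$drawn_n
  list(
    p_strict = phyper(a, K, N - K, n, lower.tail = FALSE),
    p_inclusive = phyper(a - 1, K, N - K, n, lower.tail = FALSE)
  )
}

#' Gene-size sampling bias weight
#'
#' Ratio of mean gene lengths, target over non-target. Because longer
#' genes are proportionally more likely to be hit by positional mapping,
#' this ratio is used as the sampling odds of the bias-corrected
#' Wallenius test.
#'
#' @param target_sizes,other_sizes Non-empty numeric vectors of gene
#'   lengths in bp.
#' @return `mean(target_sizes) / mean(other_sizes)`.
#' @export
size_bias_weight <- function(target_sizes, other_sizes) {
  if (length(target_sizes) == 0L || length(other_sizes) == 0L) {
    stop("both size lists must be non-empty")
  }
  denom <- mean(other_sizes)
  if (denom == 0) stop("zero mean in denominator")
  mean(target_sizes) / denom
}

#' Wallenius noncentral hypergeometric probability mass function
#'
#' Biased-urn sampling without replacement: `n` balls are drawn one at a
#' time from an urn with `target_k` target and `universe_n - target_k`
#' non-target balls, each remaining target ball having odds `weight`
#' per draw. The pmf over the number of target balls drawn is computed
#' by the exact sequential-draw recursion (the defining chain of the
#' distribution), which is numerically stable for the table sizes used
#' here (`n` in the hundreds). `weight = 1` reduces exactly to the
#' central hypergeometric distribution.
#'
#' @param universe_n,target_k,drawn_n Urn configuration N, K, n.
#' @param weight Sampling odds of a target ball (> 0).
#' @return Numeric vector of probabilities over the support
#'   `0:min(drawn_n, target_k)`; sums to 1.
#' @export
wallenius_pmf <- function(universe_n, target_k, drawn_n, weight) {
  if (weight <= 0 || !is.finite(weight)) stop("weight must be positive")
  N <- as.integer(universe_n)
  K <- as.integer(target_k)
  n <- as.integer(drawn_n)
  if (n > N) stop("drawn_n exceeds universe_n")
  if (K > N) stop("target_k exceeds universe_n")
  xmax <- min(n, K)
  p <- c(1, rep(0, xmax))
  for (j in seq_len(n)) {
    pnew <- numeric(xmax + 1L)
    upper <- min(j - 1L, xmax)
    for (x in 0:upper) {
      px <- p[x + 1L]
      if (px == 0) next
      k_left <- K - x
      o_left <- (N - K) - (j - 1L - x)
      tot <- weight * k_left + o_left
      if (tot <= 0) stop("urn exhausted; invalid configuration")
      if (k_left > 0 && x < xmax) {
        pnew[x + 2L] <- pnew[x + 2L] + px * weight * k_left / tot
      }
      if (o_left > 0) {
        pnew[x + 1L] <- pnew[x + 1L] + px * o_left / tot
      }
    }
    p <- pnew
  }
  tot <- sum(p)
  if (!is.finite(tot) || abs(tot - 1) > 1e-8) {
    stop("Wallenius recursion failed to conserve probability: sum = ", tot)
  }
  p
}

#' Wallenius noncentral hypergeometric enrichment test
#'
#' Upper-tail probabilities of the observed overlap under biased-urn
#' sampling with the given odds favouring the target category, used to
#' correct gene-set enrichment for gene-length sampling bias: a weight
#' above 1 makes large overlaps more probable under the null, so
#' enrichment is harder to call.
#'
#' @param table An `enrichment_table`.
#' @param weight Sampling odds of target genes (> 0), typically the
#'   [size_bias_weight()] ratio of mean gene lengths.
#' @return List with `p_strict` (`P(X > a)`) and `p_inclusive`
#'   (`P(X >= a)`).
#' @export
wallenius_test <- function(table, weight) {
  pmf <- wallenius_pmf(table$universe_n, table$target_k, table$drawn_n,
                       weight)
  a <- table$overlap_a
  xmax <- length(pmf) - 1L
  p_incl <- if (a <= 0) 1 else sum(pmf[(a + 1L):(xmax + 1L)])
  p_strict <- if (a >= xmax) 0 else sum(pmf[(a + 2L):(xmax + 1L)])
  list(p_strict = p_strict, p_inclusive = min(1, p_incl))
}

#' Gene-set enrichment test
#'
#' Convenience wrapper: builds the table from gene sets (or accepts an
#' existing `enrichment_table`), computes the sample odds ratio and both
#' upper tails of the central test, and, when a size-bias `weight` is
#' supplied, of the Wallenius bias-corrected test.
#'
#' @param drawn Drawn gene ids, or an `enrichment_table`.
#' @param target Target gene ids (ignored when `drawn` is a table).
#' @param universe_n Universe size (ignored when `drawn` is a table).
#' @param weight Optional Wallenius sampling odds; `NULL` for the
#'   central test only.
#' @return An `enrichment_result`: list with the table, `odds_ratio`,
#'   `p_strict`, `p_inclusive`, `method` (`"central"` or
#'   `"wallenius"`) and `weight`.
#' @export
test_enrichment <- function(drawn, target = NULL, universe_n = NULL,
                            weight = NULL) {
  tab <- if (inherits(drawn, "enrichment_table")) {
    drawn
  } else {
    enrichment_table(drawn, target, universe_n)
  }
  if (is.null(weight)) {
    tails <- hypergeom_test(tab)
    method <- "central"
    w <- 1
  } else {
    tails <- wallenius_test(tab, weight)
    method <- "wallenius"
    w <- weight
  }
  structure(list(table = tab,
                 odds_ratio = enrichment_odds_ratio(tab),
                 p_strict = tails$p_strict,
                 p_inclusive = tails$p_inclusive,
                 method = method,
                 weight = w),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  t <- x$table
  cat(sprintf(
    "%s enrichment (N=%d, K=%d, n=%d, a=%d%s)\n  OR = %.4g, P(X>a) = %.3g, P(X>=a) = %.3g\n",
    if (x$method == "wallenius") "Wallenius" else "Hypergeometric",
    t$universe_n, t$target_k, t$drawn_n, t$overlap_a,
    if (x$method == "wallenius") sprintf(", w=%.3g", x$weight) else "",
    x$odds_ratio, x$p_strict, x$p_inclusive))
  invisible(x)
}
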