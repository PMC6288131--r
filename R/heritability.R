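# Observed-scale to liability-scale heritability conversion under the
# liability threshold model, with a prevalence sensitivity sweep.

#' Convert heritability from the observed to the liability scale
#'
#' Under the liability threshold model of binary disease, an
#' observed-scale (0/1) SNP-heritability estimate from an ascertained
#' case-control sample is rescaled to the liability scale by
#' `h2_L = h2_o * K^2 (1-K)^2 / (p (1-p) Z^2)`, where `K` is the
#' population prevalence, `p` the proportion of cases in the sample and
#' `Z` the standard normal density at the liability threshold
#' `qnorm(1 - K)`. The transform is strictly linear in `h2_observed`, so
#' confidence interval endpoints convert endpoint-wise.
#'
#' @param h2_observed Observed-scale heritability (vectorized, e.g. an
#'   estimate with its CI endpoints).
#' @param prevalence Disease prevalence K in (0, 1).
#' @param case_proportion Sample case proportion p in (0, 1).
#' @return Liability-scale heritability, same length as `h2_observed`.
#' @examples
#' liability_transform(0.1, prevalence = 0.01, case_proportion = 0.5)
#' @export
liability_transform <- function(h2_observed, prevalence, case_proportion) {
  K <- prevalence
  p <- case_proportion
  if (length(K) != 1L || length(p) != 1L) {
    stop("prevalence and case_proportion must be scalars")
  }
  if (!is.finite(K) || K <= 0 || K >= 1) {
    stop("prevalence must lie strictly in (0, 1)")
  }
  if (!is.finite(p) || p <= 0 || p >= 1) {
    stop("case_proportion must lie strictly in (0, 1)")
  }
  z <- dnorm(qnorm(1 - K))
  h2_observed * K^2 * (1 - K)^2 / (p * (1 - p) * z^2)
}

#' Prevalence sensitivity of the liability-scale estimate
#'
#' Re-evaluates the liability transform at scaled prevalences
#' (conventionally half and double the base estimate) to show how
#' sensitive the liability-scale heritability is to the assumed
#' prevalence.
#'
#' @inheritParams liability_transform
#' @param h2_observed Scalar observed-scale heritability.
#' @param factors Multiplicative prevalence factors (default
#'   `c(0.5, 1, 2)`). Factors pushing `K` outside (0, 1) are skipped
#'   with a warning.
#' @return `data.table` with `factor`, `prevalence`, `h2_liability`.
#' @export
prevalence_sensitivity <- function(h2_observed, prevalence,
                                   case_proportion,
                                   factors = c(0.5, 1, 2)) {
  K <- prevalence * factors
  ok <- K > 0 & K < 1
  if (any(!ok)) {
    warning("skipping prevalence factor(s) outside (0, 1): ",
            paste(factors[!ok], collapse = ", "))
  }
  data.table(
    factor = factors[ok],
    prevalence = K[ok],
    h2_liability = vapply(K[ok], function(k) {
      liability_transform(h2_observed, k, case_proportion)
    }, numeric(1))
  )
}
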