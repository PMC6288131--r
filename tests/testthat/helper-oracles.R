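# Independent oracles used across the suite. These deliberately avoid
# the code paths they check: exhaustive enumeration, explicit binomial
# coefficients, and direct biased-urn simulation.

# Exhaustive hypergeometric upper tails by enumerating every possible
# draw of size n from a universe of N labelled genes (tiny N only).
hyper_enum_tails <- function(N, K, n, a) {
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K) # genes 1..K are the target set
  c(p_strict = mean(overlaps > a), p_inclusive = mean(overlaps >= a))
}

# Hypergeometric pmf from explicit binomial coefficients (N <= 60).
hyper_choose_pmf <- function(N, K, n) {
  x <- 0:min(n, K)
  p <- choose(K, x) * choose(N - K, n - x) / choose(N, n)
  setNames(p, x)
}

# Direct biased-urn simulation of Wallenius sampling: draw n balls one
# at a time, each remaining target ball having odds w.
wallenius_sim <- function(N, K, n, w, reps, seed = 1) {
  set.seed(seed)
  counts <- integer(min(n, K) + 1L)
  for (r in seq_len(reps)) {
    k_left <- K
    o_left <- N - K
    x <- 0L
    for (j in seq_len(n)) {
      p_target <- w * k_left / (w * k_left + o_left)
      if (runif(1) < p_target) {
        x <- x + 1L
        k_left <- k_left - 1L
      } else {
        o_left <- o_left - 1L
      }
    }
    counts[x + 1L] <- counts[x + 1L] + 1L
  }
  counts / reps
}

# Brute-force interval overlap: does gene [gs, ge) (0-based half-open)
# intersect the 1-based inclusive window [ws, we]?
interval_overlaps <- function(gs, ge, ws, we) {
  (gs + 1) <= we && ge >= ws
}
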