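# Independent statistical oracles used against the package implementations.

# Minimum-likelihood two-sided binomial p by direct enumeration of the
# outcome probabilities.
enum_binom_p <- function(k, n, p0 = 0.5) {
  probs <- choose(n, 0:n) * p0^(0:n) * (1 - p0)^(n - (0:n))
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# Fisher two-sided p for a 2x2 table by hypergeometric enumeration over all
# tables with the observed margins.
enum_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n):min(k, m)
  probs <- vapply(xs, function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, numeric(1))
  obs <- probs[xs == tab[1, 1]]
  sum(probs[probs <= obs * (1 + 1e-7)])
}
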