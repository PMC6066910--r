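# Shared hypergeometric machinery: regulon and GO category scoring call the
# same two functions, so identical (universe, set, members, overlap) tuples
# give identical probabilities by construction.

# Upper-tail over-representation probability P(X >= k) for drawing `n`
# members from a universe of `N` genes containing `K` successes.
#' @noRd
.hyperEnrich <- function(k, K, N, n) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= max(K, n), k <= min(K, n))
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# Lower-tail depletion probability P(X <= k).
#' @noRd
.hyperDeplete <- function(k, K, N, n) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= max(K, n), k <= min(K, n))
  phyper(k, K, N - K, n, lower.tail = TRUE)
}

# Sample odds ratio of the 2x2 overlap table, with a Haldane-Anscombe 0.5
# correction when any cell is zero. a = overlap, within set of size n drawn
# against K successes in a universe of N.
#' @noRd
.overlapOddsRatio <- function(k, K, N, n) {
  a <- k; b <- n - k; c <- K - k; d <- N - n - K + k
  if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5
                              c <- c + 0.5; d <- d + 0.5 }
  (a * d) / (b * c)
}

# -log10 with a floor so q = 0 (numerical underflow) stays finite.
#' @noRd
.negLog10 <- function(q) -log10(pmax(q, 1e-300))
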