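# Karlin-Altschul statistics for ungapped local alignment scores of DNA
# with a two-valued (match/mismatch) scoring scheme.  lambda is the unique
# positive root of E[e^{lambda * S}] = 1; K is obtained from an exact
# excursion analysis of the score random walk: the stationary rate of
# score excursions (Lindley chain) times the first-passage probability that
# an excursion peaks at or above x, scaled by e^{lambda x} and averaged
# over one lattice period.  For +1/-2 at uniform base composition this
# reproduces the classical ungapped values (lambda 1.333, K 0.621).

#' Karlin-Altschul parameters for a match/mismatch scheme
#'
#' @param match Match score (positive integer).
#' @param mismatch Mismatch score (negative integer).
#' @param p_match Probability two random background letters match (for
#'   uniform base composition, 0.25).
#' @return List with `lambda` and `K`.
#' @export
karlin_params <- function(match = 1L, mismatch = -2L, p_match = 0.25) {
  stopifnot(match > 0, mismatch < 0, p_match > 0, p_match < 1)
  key <- paste("ka", match, mismatch, signif(p_match, 10), sep = "_")
  if (!is.null(.oscache[[key]])) return(.oscache[[key]])
  a <- as.integer(match); b <- -as.integer(mismatch); p <- p_match
  lambda <- uniroot(function(l) p * exp(l * a) + (1 - p) * exp(-l * b) - 1,
                    c(1e-9, 10), tol = 1e-14)$root

  # stationary distribution of the reflected score walk, truncated
  H <- 2000L
  piw <- c(1, rep(0, H))
  for (it in seq_len(5000L)) {
    np <- rep(0, H + 1L)
    # up step +a (capped at H)
    np[(a + 1L):(H + 1L)] <- np[(a + 1L):(H + 1L)] + p * piw[1:(H + 1L - a)]
    np[H + 1L] <- np[H + 1L] + p * sum(piw[(H + 2L - a):(H + 1L)])
    # down step -b (floored at 0; states 0..b-1 hit the floor)
    np[1L] <- np[1L] + (1 - p) * sum(piw[1:b])
    np[1:(H + 1L - b)] <- np[1:(H + 1L - b)] +
      (1 - p) * piw[(b + 1L):(H + 1L)]
    if (max(abs(np - piw)) < 1e-15) { piw <- np; break }
    piw <- np
  }
  pi0 <- piw[1]

  span <- a + b  # lattice period of the two-valued step distribution
  xwin <- 25:(24 + max(span, 4L))
  Ks <- vapply(xwin, function(x) {
    n <- x - 1L
    A <- diag(n); rhs <- rep(0, n)
    for (h in seq_len(n)) {
      hu <- h + a
      if (hu >= x) rhs[h] <- rhs[h] + p else A[h, hu] <- A[h, hu] - p
      hd <- h - b
      if (hd >= 1) A[h, hd] <- A[h, hd] - (1 - p)
    }
    u <- solve(A, rhs)
    ua <- if (a >= x) 1 else u[a]
    pi0 * p * ua * exp(lambda * x)
  }, numeric(1))
  out <- list(lambda = lambda, K = mean(Ks))
  .oscache[[key]] <- out
  out
}

#' Bit score and e-value of a raw alignment score
#'
#' `bit = (lambda * S - log K) / log 2`; `evalue = K * m * n * exp(-lambda * S)`
#' with `m` the query length and `n` the total database length.
#'
#' @param score Raw alignment score(s).
#' @param m Query length.
#' @param n Total database length.
#' @param ka List from [karlin_params()].
#' @return data.frame with columns `bit_score` and `evalue`.
#' @export
karlin_evalue <- function(score, m, n, ka) {
  data.frame(bit_score = (ka$lambda * score - log(ka$K)) / log(2),
             evalue = ka$K * as.numeric(m) * as.numeric(n) *
               exp(-ka$lambda * score))
}
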