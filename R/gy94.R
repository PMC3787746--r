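# GY94 codon substitution model: F3x4 frequencies, rate matrices, transition
# probabilities (C++ kernel) and stochastic simulation of the jump process.

#' F3x4 codon frequencies
#'
#' Computes equilibrium codon frequencies from position-specific nucleotide
#' frequencies (the F3x4 convention of codon-model software), normalized over
#' the 61 sense codons.
#'
#' @param x Either a character vector of in-frame nucleotide sequences or a
#'   3 x 4 matrix of position-specific nucleotide counts (columns in order
#'   T, C, A, G).
#' @return Numeric vector of length 61 summing to 1, in the codon order of
#'   [codon_tables()].
#' @export
f3x4_frequencies <- function(x) {
  bases <- c("T", "C", "A", "G")
  if (is.matrix(x)) {
    stopifnot(nrow(x) == 3L, ncol(x) == 4L)
    cnt <- x
  } else {
    cnt <- matrix(0, 3, 4, dimnames = list(NULL, bases))
    for (s in x) {
      cods <- split_codons(toupper(s))
      for (pos in 1:3) {
        tb <- table(factor(substring(cods, pos, pos), levels = bases))
        cnt[pos, ] <- cnt[pos, ] + as.numeric(tb)
      }
    }
  }
  rs <- rowSums(cnt)
  stopifnot(all(rs > 0))
  f <- cnt / rs
  tab <- codon_tables()
  cmat <- do.call(rbind, strsplit(tab$codons, ""))
  pi <- f[1, match(cmat[, 1], bases)] *
        f[2, match(cmat[, 2], bases)] *
        f[3, match(cmat[, 3], bases)]
  pi <- pmax(pi, 1e-8)  # guard absent codons so log-likelihoods stay finite
  pi / sum(pi)
}

#' GY94 rate matrix
#'
#' Builds the 61 x 61 Goldman-Yang codon rate matrix with transition /
#' transversion ratio `kappa` and nonsynonymous / synonymous rate ratio
#' `omega`, scaled so that one unit of branch length equals one expected
#' substitution per codon at stationarity.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param pi Codon frequencies (length 61, summing to 1).
#' @param scale_omega Omega at which the matrix is normalized to one
#'   expected substitution per codon per unit time (default `omega`, the
#'   codeml convention).  Simulating a set of genes with a shared
#'   mutational clock uses the genome-average omega here, so that
#'   synonymous divergence is constant across genes while realized total
#'   divergence grows with omega.
#' @return 61 x 61 rate matrix with rows summing to zero.
#' @export
gy94_rate_matrix <- function(kappa, omega, pi, scale_omega = omega) {
  stopifnot(kappa > 0, omega >= 0, scale_omega >= 0, length(pi) == 61L)
  tab <- codon_tables()
  e <- tab$edge
  Q <- matrix(0, 61, 61, dimnames = list(tab$codons, tab$codons))
  base <- pi[e$j]
  base[e$ts] <- base[e$ts] * kappa
  r <- base
  r[!e$syn] <- r[!e$syn] * omega
  Q[cbind(e$i, e$j)] <- r
  diag(Q) <- -rowSums(Q)
  flux_syn <- sum(pi[e$i[e$syn]] * base[e$syn])
  flux_nonsyn <- sum(pi[e$i[!e$syn]] * base[!e$syn])
  scale <- flux_syn + scale_omega * flux_nonsyn
  if (scale > 0) Q <- Q / scale
  Q
}

#' GY94 transition probability matrix
#'
#' @param t Branch length in expected substitutions per codon.
#' @inheritParams gy94_rate_matrix
#' @return 61 x 61 stochastic matrix P(t).
#' @export
gy94_pmatrix <- function(t, kappa, omega, pi) {
  stopifnot(t >= 0, kappa > 0, omega >= 0, length(pi) == 61L)
  tab <- codon_tables()
  e <- tab$edge
  P <- .gy94_pmat_cpp(t, kappa, omega, pi,
                      as.integer(e$i) - 1L, as.integer(e$j) - 1L,
                      as.integer(e$ts), as.integer(e$syn))
  dimnames(P) <- list(tab$codons, tab$codons)
  P
}

# Simulate the GY94 jump process along one branch for a vector of codon
# states (1..61).  Returns the end states and the number of synonymous /
# nonsynonymous substitution events.  Vectorized over sites in rounds of
# exponential waiting times, with target draws grouped by current state so
# the cost is bounded by 61 categorical draws per round.
simulate_gy94_branch <- function(states, t, kappa, omega, pi,
                                 scale_omega = omega) {
  tab <- codon_tables()
  if (t <= 0 || length(states) == 0L)
    return(list(states = states, n_syn = 0L, n_nonsyn = 0L))
  Q <- gy94_rate_matrix(kappa, omega, pi, scale_omega = scale_omega)
  rates <- -diag(Q)
  aa <- tab$aa
  n_syn <- 0L; n_nonsyn <- 0L
  remaining <- rep(t, length(states))
  active <- which(rates[states] > 0)
  while (length(active) > 0L) {
    lam <- rates[states[active]]
    dt <- rexp(length(active), lam)
    jump <- dt < remaining[active]
    idx <- active[jump]
    cur <- states[idx]  # snapshot: one jump per site per round
    for (from in unique(cur)) {
      sites <- idx[cur == from]
      p <- Q[from, ]; p[from] <- 0
      to <- sample.int(61L, length(sites), replace = TRUE, prob = p)
      ns <- sum(aa[to] == aa[from])
      n_syn <- n_syn + ns
      n_nonsyn <- n_nonsyn + (length(sites) - ns)
      states[sites] <- to
    }
    remaining[active] <- remaining[active] - dt
    active <- idx[rates[states[idx]] > 0]
  }
  list(states = states, n_syn = as.integer(n_syn),
       n_nonsyn = as.integer(n_nonsyn))
}

# Expected fraction of substitution events that are nonsynonymous under the
# generator matrix at stationarity (used in generator self-checks).
gy94_expected_nonsyn_fraction <- function(kappa, omega, pi) {
  tab <- codon_tables()
  e <- tab$edge
  r <- pi[e$j]
  r[e$ts] <- r[e$ts] * kappa
  r[!e$syn] <- r[!e$syn] * omega
  flux <- pi[e$i] * r
  sum(flux[!e$syn]) / sum(flux)
}
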