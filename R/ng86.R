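# Nei-Gojobori (1986) counting estimator of dN/dS with pathway averaging and
# Jukes-Cantor correction.  Serves both as a fast per-gene estimator and as
# the initialization / cross-check for the GY94 maximum-likelihood fits.

#' NG86 synonymous/nonsynonymous counting
#'
#' Counts synonymous and nonsynonymous sites and differences between the two
#' rows of a pairwise codon alignment, averaging multi-nucleotide codon
#' differences over all minimal substitution pathways (pathways through stop
#' codons excluded), and applies the Jukes-Cantor correction
#' `d = -(3/4) log(1 - (4/3) p)`.
#'
#' @param pair A two-row [codon_aln].
#' @return A list of class `ng_counts`: `S`, `N` (site counts averaged over
#'   the two sequences; `S + N` = 3 x codons), `Sd`, `Nd` (pathway-averaged
#'   difference counts), `pS`, `pN`, `dS`, `dN`, `omega`, and flag
#'   `dS_zero` (TRUE when `Sd` is 0 or a correction is undefined, in which
#'   case `omega` is `NA`).
#' @export
ng86 <- function(pair) {
  stopifnot(inherits(pair, "codon_aln"))
  if (nrow(pair$codon_idx) != 2L)
    stop("ng86 requires a two-row codon alignment")
  tab <- codon_tables()
  a <- pair$codon_idx[1, ]
  b <- pair$codon_idx[2, ]
  S <- (sum(tab$syn_sites[a]) + sum(tab$syn_sites[b])) / 2
  ncod <- length(a)
  N <- 3 * ncod - S
  Sd <- sum(tab$sd_pair[cbind(a, b)])
  Nd <- sum(tab$nd_pair[cbind(a, b)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  dS <- jc(pS)
  dN <- jc(pN)
  dS_zero <- Sd == 0 || is.na(dS) || dS == 0
  omega <- if (!dS_zero && !is.na(dN)) dN / dS else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, omega = omega, dS_zero = dS_zero),
            class = "ng_counts")
}

#' @export
print.ng_counts <- function(x, ...) {
  cat(sprintf("NG86: S=%.2f N=%.2f Sd=%.2f Nd=%.2f dS=%s dN=%s omega=%s\n",
              x$S, x$N, x$Sd, x$Nd, format(x$dS), format(x$dN),
              format(x$omega)))
  invisible(x)
}
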