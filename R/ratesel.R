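# Rate estimation: GY94 maximum-likelihood pairwise omega, 3-taxon
# branch-model likelihood-ratio tests, multiple-testing correction and the
# bootstrap-concatenation estimator of genome-wide omega.

# 0-based edge arrays for the C++ kernels, cached
.edge_args <- function() {
  if (is.null(.oscache$edge_args)) {
    e <- codon_tables()$edge
    .oscache$edge_args <- list(ei = as.integer(e$i) - 1L,
                               ej = as.integer(e$j) - 1L,
                               ts = as.integer(e$ts),
                               syn = as.integer(e$syn))
  }
  .oscache$edge_args
}

.PAR_LOWER <- c(t = 1e-6, kappa = 0.1, omega = 1e-4)
.PAR_UPPER <- c(t = 50, kappa = 99, omega = 99)

# Maximize the pairwise GY94 likelihood over (t, kappa, omega) in log space
# with multiple starts; ties on lnL resolved to the smallest omega.
.fit_gy94_pair <- function(pat, pi, starts) {
  ea <- .edge_args()
  i0 <- as.integer(pat$i) - 1L
  j0 <- as.integer(pat$j) - 1L
  f <- function(lp) .gy94_pair_nll_cpp(exp(lp[1]), exp(lp[2]), exp(lp[3]),
                                       pi, ea$ei, ea$ej, ea$ts, ea$syn,
                                       i0, j0, pat$w)
  lo <- log(.PAR_LOWER); up <- log(.PAR_UPPER)
  best <- NULL
  for (s in starts) {
    p0 <- log(pmin(pmax(s, .PAR_LOWER), .PAR_UPPER))
    fit <- tryCatch(
      optim(p0, f, method = "L-BFGS-B", lower = lo, upper = up,
            control = list(factr = 1e7, maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cand <- list(par = exp(fit$par), nll = fit$value)
    if (is.null(best) || cand$nll < best$nll - 1e-6 ||
        (abs(cand$nll - best$nll) <= 1e-6 && cand$par[3] < best$par[3]))
      best <- cand
  }
  if (is.null(best)) stop("pairwise likelihood optimization failed")
  names(best$par) <- c("t", "kappa", "omega")
  best$boundary <- any(abs(best$par - .PAR_LOWER) < 1e-3) ||
    any(abs(best$par - .PAR_UPPER) < 1e-3)
  best
}

# model-based dN and dS: expected substitutions per site class, with site
# proportions taken at omega = 1 (mutational opportunity), so dN/dS = omega
.model_dnds <- function(t, kappa, omega, pi) {
  fN <- gy94_expected_nonsyn_fraction(kappa, omega, pi)
  fN1 <- gy94_expected_nonsyn_fraction(kappa, 1, pi)
  list(dN = t * fN / (3 * fN1), dS = t * (1 - fN) / (3 * (1 - fN1)))
}

.ng86_t_per_codon <- function(ng, ncod) {
  if (is.na(ng$dS) || is.na(ng$dN)) return(0.5)
  (ng$S * ng$dS + ng$N * ng$dN) / ncod
}

#' Maximum-likelihood pairwise dN/dS (GY94)
#'
#' Fits the Goldman-Yang codon model with F3x4 frequencies to a two-species
#' codon alignment by maximizing the likelihood over branch length `t`
#' (expected substitutions per codon), `kappa` and `omega`, from three
#' starting points (NG86-based, omega = 0.1 and omega = 1).
#'
#' @param pair A two-row [codon_aln].
#' @param pi Optional codon frequencies; defaults to F3x4 computed from the
#'   alignment itself.
#' @param min_codons Minimum alignment length in codons (default 30); shorter
#'   alignments are refused as insufficient data.
#' @return A list of class `rate_result`: `gene_id`, `method = "ml"`,
#'   `omega`, `dN`, `dS`, `t`, `kappa`, `lnL` and flags `dS_zero`,
#'   `boundary`.
#' @export
ml_pairwise <- function(pair, pi = NULL, min_codons = 30L) {
  stopifnot(inherits(pair, "codon_aln"), nrow(pair$codon_idx) == 2L)
  ncod <- ncol(pair$codon_idx)
  if (ncod < min_codons)
    stop(sprintf("insufficient data: %d codons < %d", ncod, min_codons))
  if (is.null(pi)) pi <- f3x4_frequencies(codon_aln_f3x4_counts(pair))
  pat <- codon_aln_pair_patterns(pair)
  ng <- ng86(pair)
  t0 <- max(0.01, .ng86_t_per_codon(ng, ncod))
  w0 <- if (is.na(ng$omega)) 0.2 else min(max(ng$omega, 0.01), 20)
  starts <- list(c(t0, 2, w0), c(t0, 2, 0.1), c(t0, 2, 1.0))
  fit <- .fit_gy94_pair(pat, pi, starts)
  d <- .model_dnds(fit$par["t"], fit$par["kappa"], fit$par["omega"], pi)
  structure(list(gene_id = pair$gene_id, method = "ml",
                 omega = unname(fit$par["omega"]), dN = d$dN, dS = d$dS,
                 t = unname(fit$par["t"]), kappa = unname(fit$par["kappa"]),
                 lnL = -fit$nll, dS_zero = FALSE, boundary = fit$boundary),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("rate_result '%s' (%s): omega=%.4g dN=%.4g dS=%.4g t=%.4g kappa=%.3g lnL=%.3f%s\n",
              x$gene_id, x$method, x$omega, x$dN, x$dS, x$t, x$kappa, x$lnL,
              if (isTRUE(x$boundary)) " [boundary]" else ""))
  invisible(x)
}

#' NG86 counting as a rate result
#'
#' Convenience wrapper returning [ng86()] counts in the same record layout
#' as [ml_pairwise()] (`method = "counting"`; `t` is the NG86 estimate of
#' substitutions per codon, `lnL` is `NA`).
#'
#' @inheritParams ml_pairwise
#' @return A `rate_result` list.
#' @export
counting_pairwise <- function(pair) {
  stopifnot(inherits(pair, "codon_aln"))
  ng <- ng86(pair)
  structure(list(gene_id = pair$gene_id, method = "counting",
                 omega = ng$omega, dN = ng$dN, dS = ng$dS,
                 t = .ng86_t_per_codon(ng, ncol(pair$codon_idx)),
                 kappa = NA_real_, lnL = NA_real_,
                 dS_zero = ng$dS_zero, boundary = FALSE),
            class = "rate_result")
}

# NG86-based branch length initialization for a trio (star decomposition of
# the three pairwise distances)
.trio_init <- function(trio) {
  ncod <- ncol(trio$codon_idx)
  d <- numeric(3)
  omg <- numeric(0)
  combs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (k in 1:3) {
    p <- codon_aln(trio$codon_idx[combs[[k]], , drop = FALSE],
                   trio$species[combs[[k]]], trio$gene_id)
    ng <- ng86(p)
    d[k] <- .ng86_t_per_codon(ng, ncod)
    if (!is.na(ng$omega)) omg <- c(omg, ng$omega)
  }
  t1 <- max(0.005, (d[1] + d[2] - d[3]) / 2)
  t2 <- max(0.005, (d[1] + d[3] - d[2]) / 2)
  t3 <- max(0.005, (d[2] + d[3] - d[1]) / 2)
  w <- if (length(omg)) min(max(mean(omg), 0.01), 10) else 0.2
  list(t = c(t1, t2, t3), omega = w)
}

.fit_gy94_trio <- function(pat, pi, focal_branch, starts, fixed_null = TRUE) {
  ea <- .edge_args()
  i1 <- as.integer(pat$i1) - 1L
  i2 <- as.integer(pat$i2) - 1L
  i3 <- as.integer(pat$i3) - 1L
  npar <- if (fixed_null) 5L else 6L
  lo <- log(c(rep(.PAR_LOWER["t"], 3), .PAR_LOWER["kappa"],
              rep(.PAR_LOWER["omega"], npar - 4L)))
  up <- log(c(rep(.PAR_UPPER["t"], 3), .PAR_UPPER["kappa"],
              rep(.PAR_UPPER["omega"], npar - 4L)))
  f <- function(lp) {
    p <- exp(lp)
    wf <- if (fixed_null) p[5] else p[6]
    .gy94_trio_nll_cpp(p[1], p[2], p[3], p[4], p[5], wf,
                       if (fixed_null) 0L else focal_branch,
                       pi, ea$ei, ea$ej, ea$ts, ea$syn, i1, i2, i3, pat$w)
  }
  best <- NULL
  for (s in starts) {
    p0 <- log(pmin(pmax(s, exp(lo)), exp(up)))
    fit <- tryCatch(
      optim(p0, f, method = "L-BFGS-B", lower = lo, upper = up,
            control = list(factr = 1e7, maxit = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cand <- list(par = exp(fit$par), nll = fit$value)
    if (is.null(best) || cand$nll < best$nll - 1e-6 ||
        (abs(cand$nll - best$nll) <= 1e-6 && cand$par[5] < best$par[5]))
      best <- cand
  }
  if (is.null(best)) stop("trio likelihood optimization failed")
  best
}

#' Branch-model likelihood-ratio test on a 3-taxon star
#'
#' Tests whether the focal lineage evolves at a different dN/dS than the
#' other two: the null model shares one omega across all three branches
#' (free parameters t1, t2, t3, kappa, omega); the alternative gives the
#' focal branch its own omega.  The statistic 2(lnL_alt - lnL_null) is
#' referred to a chi-square distribution with one degree of freedom.
#'
#' @param trio A three-row [codon_aln].
#' @param focal Species identifier of the focal branch (must be a row of
#'   `trio`).
#' @param pi Optional codon frequencies; default F3x4 from the alignment.
#' @return A list of class `branch_test_result`: `gene_id`, `focal`,
#'   `lnL_null`, `lnL_alt`, `lrt`, `df = 1`, `p`, `omega_background`,
#'   `omega_focal`, `direction` ("accelerated" or "decelerated").
#' @export
branch_test <- function(trio, focal, pi = NULL) {
  stopifnot(inherits(trio, "codon_aln"), nrow(trio$codon_idx) == 3L)
  fb <- match(focal, trio$species)
  if (is.na(fb)) stop(sprintf("focal species '%s' not in trio", focal))
  if (is.null(pi)) pi <- f3x4_frequencies(codon_aln_f3x4_counts(trio))
  pat <- codon_aln_trio_patterns(trio)
  ini <- .trio_init(trio)
  null_starts <- list(c(ini$t, 2, ini$omega), c(ini$t, 2, 0.1),
                      c(ini$t, 2, 1.0))
  fit0 <- .fit_gy94_trio(pat, pi, fb, null_starts, fixed_null = TRUE)
  p0 <- fit0$par
  alt_starts <- list(c(p0, p0[5]), c(p0, min(p0[5] * 3, 50)),
                     c(p0, p0[5] / 3))
  fit1 <- .fit_gy94_trio(pat, pi, fb, alt_starts, fixed_null = FALSE)
  lnL0 <- -fit0$nll
  lnL1 <- -fit1$nll
  lrt <- 2 * (lnL1 - lnL0)
  p <- pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  dir <- if (fit1$par[6] >= fit1$par[5]) "accelerated" else "decelerated"
  structure(list(gene_id = trio$gene_id, focal = focal,
                 lnL_null = lnL0, lnL_alt = lnL1, lrt = lrt, df = 1L, p = p,
                 omega_background = unname(fit1$par[5]),
                 omega_focal = unname(fit1$par[6]), direction = dir),
            class = "branch_test_result")
}

#' @export
print.branch_test_result <- function(x, ...) {
  cat(sprintf("branch_test '%s' focal=%s: lrt=%.3f p=%.3g (%s)\n",
              x$gene_id, x$focal, x$lrt, x$p, x$direction))
  invisible(x)
}

#' False-discovery-rate adjustment
#'
#' Benjamini-Hochberg step-up q-values, optionally rescaled by the Storey
#' null-proportion estimate `pi0 = min(1, #\{p > 0.5\} / (0.5 m))`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"bh"` or `"storey"`.
#' @return q-values in input order.
#' @export
adjust_fdr <- function(p, method = c("bh", "storey")) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, sum(p > 0.5) / (0.5 * length(p)))
    q <- pmin(1, pi0 * q)
  }
  q
}

#' Bootstrap-concatenation estimate of genome-wide omega
#'
#' For each bootstrap replicate, a fixed number of pairwise codon alignments
#' is sampled (without replacement within the replicate), concatenated, and
#' a single GY94 omega estimated on the concatenation by [ml_pairwise()]'s
#' fitting machinery.  Long concatenated alignments give robust genome-wide
#' estimates; the spread over replicates is the sampling uncertainty.
#'
#' @param alignments List of two-row [codon_aln] objects (one per gene).
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param genes_per_rep Alignments concatenated per replicate (default 150).
#' @param seed Optional RNG seed for reproducibility.
#' @return A list of class `bootstrap_summary`: `species_pair`, `n_reps`,
#'   `genes_per_rep`, `omega` (per-replicate estimates), `mean`, `sd`,
#'   `ci` (2.5/97.5 percentiles) and `seed`.
#' @export
bootstrap_genome_omega <- function(alignments, n_reps = 1000L,
                                   genes_per_rep = 150L, seed = NULL) {
  npool <- length(alignments)
  if (npool < genes_per_rep)
    stop(sprintf("alignment pool (%d) smaller than genes_per_rep (%d)",
                 npool, genes_per_rep))
  stopifnot(all(vapply(alignments, function(a)
    inherits(a, "codon_aln") && nrow(a$codon_idx) == 2L, logical(1))))
  if (!is.null(seed)) set.seed(seed)
  # per-gene sufficient statistics: sparse pattern counts and F3x4 counts
  patmat <- matrix(0, npool, 61L * 61L)
  f3mat <- matrix(0, npool, 12L)
  for (g in seq_len(npool)) {
    pat <- codon_aln_pair_patterns(alignments[[g]])
    patmat[g, (pat$i - 1L) * 61L + pat$j] <- pat$w
    f3mat[g, ] <- as.numeric(codon_aln_f3x4_counts(alignments[[g]]))
  }
  sp <- alignments[[1]]$species
  omega <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    pick <- sample.int(npool, genes_per_rep, replace = FALSE)
    w <- colSums(patmat[pick, , drop = FALSE])
    nz <- which(w > 0)
    pat <- list(i = ((nz - 1L) %/% 61L) + 1L, j = ((nz - 1L) %% 61L) + 1L,
                w = w[nz])
    pi <- f3x4_frequencies(matrix(colSums(f3mat[pick, , drop = FALSE]), 3, 4))
    starts <- list(c(0.3, 2, 0.15), c(0.3, 2, 0.5))
    fit <- .fit_gy94_pair(pat, pi, starts)
    omega[r] <- fit$par["omega"]
  }
  structure(list(species_pair = paste(sp, collapse = "-"),
                 n_reps = as.integer(n_reps),
                 genes_per_rep = as.integer(genes_per_rep), omega = omega,
                 mean = mean(omega), sd = sd(omega),
                 ci = unname(quantile(omega, c(0.025, 0.975))),
                 seed = seed),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("bootstrap omega (%s): mean=%.4f sd=%.4f [%.4f, %.4f] (%d reps x %d genes)\n",
              x$species_pair, x$mean, x$sd, x$ci[1], x$ci[2], x$n_reps,
              x$genes_per_rep))
  invisible(x)
}
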