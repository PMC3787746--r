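# Downstream statistics: rate-class gene lists, term over/under-
# representation (Fisher / hypergeometric with BH adjustment), chromosome-
# level rate contrasts, cross-depth correlation and assembly summary
# statistics.

#' Gene lists by evolutionary-rate class
#'
#' From a per-gene omega table, builds the three canonical fast-gene lists:
#' omega > 1 (the traditional positive-selection benchmark), omega > 0.8,
#' and the top decile (threshold = 90th percentile of usable omega values,
#' ties included).
#'
#' @param rates data.frame with columns `gene_id` and `omega` (one row per
#'   gene; NA omega allowed and excluded with a count).
#' @return List of class `gene_lists`: `lists` (named list of gene-id
#'   vectors `omega_gt_1`, `omega_gt_0.8`, `top_decile`), `thresholds`,
#'   `n_undefined`, `universe`.
#' @export
select_rate_classes <- function(rates) {
  if (nrow(rates) == 0L) stop("empty rate table")
  usable <- rates[!is.na(rates$omega), , drop = FALSE]
  if (nrow(usable) == 0L) stop("no usable estimates")
  q90 <- unname(quantile(usable$omega, 0.9, type = 7))
  lists <- list(omega_gt_1 = usable$gene_id[usable$omega > 1],
                omega_gt_0.8 = usable$gene_id[usable$omega > 0.8],
                top_decile = usable$gene_id[usable$omega >= q90])
  structure(list(lists = lists,
                 thresholds = c(omega_gt_1 = 1, omega_gt_0.8 = 0.8,
                                top_decile = q90),
                 n_undefined = nrow(rates) - nrow(usable),
                 universe = usable$gene_id),
            class = "gene_lists")
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum of all table probabilities <= the observed table's probability
.fisher2x2_p <- function(obs, list_size, term_size, universe) {
  supp <- max(0L, list_size + term_size - universe):min(list_size, term_size)
  pr <- stats::dhyper(supp, term_size, universe - term_size, list_size)
  p_obs <- stats::dhyper(obs, term_size, universe - term_size, list_size)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

#' Term over/under-representation
#'
#' For every term in the map, tests the 2x2 table (in list / not in list x
#' has term / not) with a two-sided Fisher exact test (hypergeometric
#' enumeration) and a one-sided hypergeometric test in the observed
#' direction, then adjusts the Fisher p-values across terms with
#' Benjamini-Hochberg.
#'
#' @param gene_list Character vector of gene ids (subset of `universe`).
#' @param universe Character vector of all gene ids considered.
#' @param term_map data.frame with columns `gene_id`, `term_id` and
#'   optionally `term_desc`; memberships outside `universe` are ignored.
#' @return data.frame sorted by p: `term_id`, `term_desc`, `total`
#'   (universe genes with the term), `expected` (total x |list|/|universe|),
#'   `observed`, `p` (Fisher two-sided), `p_hyper` (one-sided), `p_adjusted`
#'   (BH), `direction` ("over"/"under").
#' @export
term_enrichment <- function(gene_list, universe, term_map) {
  stopifnot(all(gene_list %in% universe))
  term_map <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  terms <- unique(term_map$term_id)
  nu <- length(universe); nl <- length(gene_list)
  rows <- lapply(terms, function(tm) {
    tg <- unique(term_map$gene_id[term_map$term_id == tm])
    total <- length(tg)
    obs <- length(intersect(tg, gene_list))
    expd <- total * nl / nu
    dirn <- if (obs >= expd) "over" else "under"
    p_hyp <- if (dirn == "over")
      stats::phyper(obs - 1L, total, nu - total, nl, lower.tail = FALSE)
    else
      stats::phyper(obs, total, nu - total, nl, lower.tail = TRUE)
    desc <- term_map$term_desc[match(tm, term_map$term_id)]
    data.frame(term_id = tm,
               term_desc = if (is.null(desc)) NA_character_ else desc,
               total = total, expected = expd, observed = obs,
               p = .fisher2x2_p(obs, nl, total, nu), p_hyper = p_hyp,
               direction = dirn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(0), term_desc = character(0),
                      total = integer(0), expected = numeric(0),
                      observed = integer(0), p = numeric(0),
                      p_hyper = numeric(0), p_adjusted = numeric(0),
                      direction = character(0)))
  out$p_adjusted <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term_id),
             c("term_id", "term_desc", "total", "expected", "observed",
               "p", "p_hyper", "p_adjusted", "direction")]
  rownames(out) <- NULL
  out
}

#' Chromosome-level rate statistics
#'
#' One-way ANOVA of per-gene omega across chromosomes, plus one-tailed
#' Welch t-tests for requested ordered contrasts (e.g. Z evolving faster
#' than chromosome 4, or 4A slower than 12).  A contrast may use the
#' pseudo-group "autosomes" meaning all chromosomes except Z and 4A.
#'
#' @param rates data.frame with columns `omega` and `chrom` (undefined
#'   omega rows dropped).
#' @param contrasts List of `c(group_a, direction, group_b)` triplets with
#'   direction ">" or "<", e.g. `list(c("Z", ">", "autosomes"))`.
#' @return List of class `chrom_rate_stats`: `anova` (F, df1, df2, p),
#'   `contrasts` (data.frame group_a, direction, group_b, t, p), and
#'   `group_means`.
#' @export
omega_chromosome_stats <- function(rates, contrasts = list()) {
  rates <- rates[!is.na(rates$omega), , drop = FALSE]
  tb <- table(rates$chrom)
  if (length(tb) < 2L || sum(tb >= 2L) < 2L)
    stop("need >= 2 chromosomes with >= 2 genes each")
  fit <- lm(omega ~ chrom, data = rates)
  an <- anova(fit)
  pick <- function(grp) {
    if (grp == "autosomes") rates$omega[!(rates$chrom %in% c("Z", "4A"))]
    else rates$omega[rates$chrom == grp]
  }
  crows <- lapply(contrasts, function(ct) {
    stopifnot(length(ct) == 3L, ct[2] %in% c(">", "<"))
    xa <- pick(ct[1]); xb <- pick(ct[3])
    if (!length(xa)) stop("contrast chromosome absent: ", ct[1])
    if (!length(xb)) stop("contrast chromosome absent: ", ct[3])
    if (sd(xa) == 0 && sd(xb) == 0 && mean(xa) == mean(xb)) {
      tt <- list(statistic = c(t = 0), p.value = 0.5)
    } else {
      tt <- t.test(xa, xb, alternative =
                     if (ct[2] == ">") "greater" else "less")
    }
    data.frame(group_a = ct[1], direction = ct[2], group_b = ct[3],
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  structure(list(anova = list(F = an$`F value`[1], df1 = an$Df[1],
                              df2 = an$Df[2], p = an$`Pr(>F)`[1]),
                 contrasts = if (length(crows)) do.call(rbind, crows)
                             else NULL,
                 group_means = tapply(rates$omega, rates$chrom, mean)),
            class = "chrom_rate_stats")
}

#' @export
print.chrom_rate_stats <- function(x, ...) {
  cat(sprintf("ANOVA omega ~ chromosome: F(%d,%d)=%.3f p=%.4g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  if (!is.null(x$contrasts)) print(x$contrasts)
  invisible(x)
}

#' Correlation of omega across divergence depths
#'
#' Pearson correlation between per-gene omega estimated at a shallow
#' divergence and omega for the same genes at a deeper divergence (e.g. a
#' reference-vs-outgroup table supplied externally).
#'
#' @param omega_shallow,omega_deep data.frames with columns `gene_id` and
#'   `omega`.
#' @return List: `r`, `p`, `n_genes` (pairs used), `n_dropped` (shared
#'   genes lost to undefined omega).
#' @export
depth_correlation <- function(omega_shallow, omega_deep) {
  m <- merge(omega_shallow[, c("gene_id", "omega")],
             omega_deep[, c("gene_id", "omega")],
             by = "gene_id", suffixes = c("_shallow", "_deep"))
  ok <- !is.na(m$omega_shallow) & !is.na(m$omega_deep)
  if (sum(ok) < 3L) stop("fewer than 3 shared genes with defined omega")
  ct <- cor.test(m$omega_shallow[ok], m$omega_deep[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_genes = sum(ok),
       n_dropped = sum(!ok))
}

#' Assembly summary statistics
#'
#' @param lengths Positive integer vector of sequence lengths.
#' @return List of class `assembly_stats`: `n_sequences`, `total_bp`,
#'   `mean_length`, `n50` (the length at which the descending cumulative
#'   sum first reaches half the total).
#' @export
assembly_stats <- function(lengths) {
  if (length(lengths) == 0L) stop("no sequence lengths")
  stopifnot(all(lengths > 0))
  sl <- sort(lengths, decreasing = TRUE)
  n50 <- sl[which(cumsum(as.numeric(sl)) >= sum(as.numeric(sl)) / 2)[1]]
  structure(list(n_sequences = length(lengths),
                 total_bp = sum(as.numeric(lengths)),
                 mean_length = mean(lengths), n50 = n50),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("%d sequences, %.0f bp total, mean %.1f bp, N50 %d bp\n",
              x$n_sequences, x$total_bp, x$mean_length, x$n50))
  invisible(x)
}
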