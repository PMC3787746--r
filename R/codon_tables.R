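# Codon bookkeeping shared by the simulator, NG86 counting and the GY94
# likelihood machinery.  All tables are built once per session and cached.

.oscache <- new.env(parent = emptyenv())

#' Codon model tables
#'
#' Internal tables for the standard genetic code over the 61 sense codons:
#' codon strings, amino-acid translations, the single-nucleotide neighbour
#' structure used to build GY94 rate matrices, NG86 synonymous-site counts,
#' and pathway-averaged synonymous/nonsynonymous difference counts for every
#' ordered codon pair.
#'
#' @return A list with elements `codons` (61 sense codon strings), `aa`
#'   (their amino acids), `stops`, `edge` (data.frame of single-nucleotide
#'   sense-codon changes with columns `i`, `j`, `ts`, `syn`), `syn_sites`
#'   (NG86 synonymous sites per codon, changes into stops counted as
#'   nonsynonymous), `ndiff`, `sd_pair`, `nd_pair` (61 x 61 matrices of
#'   nucleotide differences and pathway-averaged synonymous / nonsynonymous
#'   differences).
#' @keywords internal
codon_tables <- function() {
  if (!is.null(.oscache$tab)) return(.oscache$tab)

  bases <- c("T", "C", "A", "G")
  gc <- Biostrings::GENETIC_CODE
  all64 <- names(gc)
  stops <- all64[gc == "*"]
  codons <- all64[gc != "*"]
  aa <- unname(gc[codons])
  n <- length(codons)
  stopifnot(n == 61L)

  cmat <- do.call(rbind, strsplit(codons, ""))
  is_transition <- function(a, b) {
    (a == "A" & b == "G") | (a == "G" & b == "A") |
      (a == "C" & b == "T") | (a == "T" & b == "C")
  }

  # single-nucleotide neighbour structure among sense codons
  ei <- integer(0); ej <- integer(0); ets <- logical(0); esyn <- logical(0)
  idx <- seq_len(n); names(idx) <- codons
  for (i in idx) {
    for (pos in 1:3) {
      for (b in bases) {
        if (b == cmat[i, pos]) next
        tgt <- cmat[i, ]; tgt[pos] <- b
        tgt <- paste(tgt, collapse = "")
        j <- idx[tgt]
        if (is.na(j)) next  # stop codon: rate zero, excluded
        ei <- c(ei, i); ej <- c(ej, unname(j))
        ets <- c(ets, is_transition(cmat[i, pos], b))
        esyn <- c(esyn, aa[i] == aa[unname(j)])
      }
    }
  }
  edge <- data.frame(i = ei, j = ej, ts = ets, syn = esyn)

  # NG86 synonymous sites per codon; a change creating a stop codon counts
  # as nonsynonymous so that S + N = 3 x codons
  syn_sites <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (pos in 1:3) {
      for (b in bases) {
        if (b == cmat[i, pos]) next
        tgt <- cmat[i, ]; tgt[pos] <- b
        tgt <- paste(tgt, collapse = "")
        if (tgt %in% codons && gc[tgt] == aa[i]) s <- s + 1 / 3
      }
    }
    syn_sites[i] <- s
  }

  # pathway-averaged difference counts for every ordered sense-codon pair;
  # minimal substitution pathways passing through a stop codon are excluded
  ndiff <- matrix(0L, n, n)
  sd_pair <- matrix(0, n, n)
  nd_pair <- matrix(0, n, n)
  perms <- list(`1` = list(1L), `2` = list(1:2, 2:1),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dpos <- which(cmat[i, ] != cmat[j, ])
      d <- length(dpos)
      ndiff[i, j] <- d
      tot_s <- 0; tot_n <- 0; nvalid <- 0
      for (ord in perms[[as.character(d)]]) {
        cur <- cmat[i, ]; s <- 0; nn <- 0; ok <- TRUE
        for (pos in dpos[ord]) {
          nxt <- cur; nxt[pos] <- cmat[j, pos]
          cfrom <- paste(cur, collapse = ""); cto <- paste(nxt, collapse = "")
          if (gc[cto] == "*") { ok <- FALSE; break }
          if (gc[cfrom] == gc[cto]) s <- s + 1 else nn <- nn + 1
          cur <- nxt
        }
        if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + nn; nvalid <- nvalid + 1 }
      }
      stopifnot(nvalid > 0)  # holds for all sense-codon pairs
      sd_pair[i, j] <- tot_s / nvalid
      nd_pair[i, j] <- tot_n / nvalid
    }
  }

  .oscache$tab <- list(codons = codons, aa = aa, stops = stops, edge = edge,
                       syn_sites = syn_sites, ndiff = ndiff,
                       sd_pair = sd_pair, nd_pair = nd_pair)
  .oscache$tab
}

# map codon strings to 1..61 sense indices (NA for stops/ambiguous)
codon_index <- function(codon_strings) {
  tab <- codon_tables()
  match(codon_strings, tab$codons)
}

# split an in-frame nucleotide string into codon strings
split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3 == 0)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

is_stop_codon <- function(codon_strings) {
  codon_strings %in% codon_tables()$stops
}
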