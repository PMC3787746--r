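# The codon alignment container: a gap-free, in-frame, stop-free matrix of
# sense-codon indices, one row per species.  This is the unit of all rate
# analyses.

#' Construct a codon alignment
#'
#' @param codon_idx Integer matrix (species x codons) of sense-codon indices
#'   (1..61 in the order of [codon_tables()]).
#' @param species Character vector of row (species) identifiers.
#' @param gene_id Gene identifier.
#' @param ref_codon_index Optional integer vector mapping alignment columns
#'   to codon positions of the reference CDS.
#' @return An object of class `codon_aln`.
#' @export
codon_aln <- function(codon_idx, species, gene_id = "gene",
                      ref_codon_index = NULL) {
  codon_idx <- as.matrix(codon_idx)
  stopifnot(is.numeric(codon_idx), nrow(codon_idx) == length(species),
            !anyNA(codon_idx), all(codon_idx >= 1), all(codon_idx <= 61))
  storage.mode(codon_idx) <- "integer"
  rownames(codon_idx) <- species
  structure(list(gene_id = gene_id, species = species, codon_idx = codon_idx,
                 bp = 3L * ncol(codon_idx),
                 ref_codon_index = ref_codon_index),
            class = "codon_aln")
}

#' Build a codon alignment from in-frame sequences
#'
#' Stacks equal-length, in-frame nucleotide sequences, removes the terminal
#' stop codon (if the first sequence ends in one) and drops every codon
#' column containing a gap, an ambiguity code or a stop codon in any row.
#'
#' @param seqs Named character vector (or `Biostrings::DNAStringSet`) of
#'   equal-length in-frame sequences.
#' @param gene_id Gene identifier.
#' @return A `codon_aln`, or `NULL` if no columns survive.
#' @export
codon_aln_from_seqs <- function(seqs, gene_id = "gene") {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("sequences must have equal length")
  if (len %% 3L != 0L) stop("sequence length must be a multiple of 3")
  cods <- lapply(toupper(seqs), split_codons)
  ncod <- len / 3L
  if (is_stop_codon(cods[[1]][ncod])) {
    cods <- lapply(cods, function(x) x[-ncod])
    ncod <- ncod - 1L
  }
  if (ncod == 0L) return(NULL)
  idx <- do.call(rbind, lapply(cods, codon_index))
  keep <- colSums(is.na(idx)) == 0L
  if (!any(keep)) return(NULL)
  codon_aln(idx[, keep, drop = FALSE], names(seqs), gene_id,
            ref_codon_index = which(keep))
}

#' @export
print.codon_aln <- function(x, ...) {
  cat(sprintf("codon_aln '%s': %d species x %d codons (%d bp)\n",
              x$gene_id, length(x$species), ncol(x$codon_idx), x$bp))
  invisible(x)
}

#' Extract two species of a codon alignment as a pairwise alignment
#'
#' @param aln A [codon_aln].
#' @param sp1,sp2 Species (row) identifiers to keep, in order.
#' @return A two-row `codon_aln`.
#' @export
codon_aln_pair <- function(aln, sp1, sp2) {
  stopifnot(all(c(sp1, sp2) %in% aln$species))
  codon_aln(aln$codon_idx[c(sp1, sp2), , drop = FALSE], c(sp1, sp2),
            aln$gene_id, aln$ref_codon_index)
}

# position-specific nucleotide counts (3 x 4, TCAG) over all rows; the
# sufficient statistic for F3x4 and cheap to sum across genes when
# concatenating
codon_aln_f3x4_counts <- function(aln) {
  tab <- codon_tables()
  bases <- c("T", "C", "A", "G")
  cmat <- do.call(rbind, strsplit(tab$codons, ""))
  cnt <- matrix(0, 3, 4, dimnames = list(NULL, bases))
  codcount <- tabulate(aln$codon_idx, nbins = 61L)
  for (pos in 1:3) {
    b <- match(cmat[, pos], bases)
    for (k in 1:4) cnt[pos, k] <- sum(codcount[b == k])
  }
  cnt
}

# pairwise site-pattern counts: data.frame(i, j, w) of codon index pairs
codon_aln_pair_patterns <- function(aln) {
  stopifnot(nrow(aln$codon_idx) == 2L)
  key <- (aln$codon_idx[1, ] - 1L) * 61L + aln$codon_idx[2, ]
  tb <- table(key)
  k <- as.integer(names(tb))
  list(i = ((k - 1L) %/% 61L) + 1L, j = ((k - 1L) %% 61L) + 1L,
       w = as.numeric(tb))
}

# trio site-pattern counts
codon_aln_trio_patterns <- function(aln) {
  stopifnot(nrow(aln$codon_idx) == 3L)
  key <- ((aln$codon_idx[1, ] - 1L) * 61L + (aln$codon_idx[2, ] - 1L)) * 61L +
    aln$codon_idx[3, ]
  tb <- table(key)
  k <- as.numeric(names(tb))
  i3 <- ((k - 1) %% 61) + 1
  r <- (k - 1) %/% 61
  i2 <- (r %% 61) + 1
  i1 <- (r %/% 61) + 1
  list(i1 = as.integer(i1), i2 = as.integer(i2), i3 = as.integer(i3),
       w = as.numeric(tb))
}
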