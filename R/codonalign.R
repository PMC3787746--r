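# Codon-aware alignment refinement: align fragments to the reference CDS,
# repair frame-disrupting insertions, build per-species consensus sequences
# on the CDS grid, and assemble gap-free in-frame codon alignments.

#' Semi-global affine alignment of a fragment to a CDS
#'
#' Aligns the whole fragment to the best-matching internal window of the
#' CDS (no end penalties on the CDS side) with affine gap costs, and
#' returns the alignment as a column table pairing fragment and CDS
#' positions (0-based; NA marks a gap on that side).
#'
#' @param fragment Nucleotide sequence (character scalar), already oriented
#'   to the CDS strand.
#' @param cds Reference CDS sequence.
#' @param match,mismatch,gap_open,gap_extend Scoring scheme (defaults
#'   +2/-3, gap open 5, extend 2).
#' @param fragment_id,gene_id Identifiers carried in the result.
#' @return List of class `coord_alignment`: `fragment_id`, `gene_id`,
#'   `score`, and `columns` (data.frame `frag_pos`, `cds_pos`, `base`).
#' @export
align_affine <- function(fragment, cds, match = 2, mismatch = -3,
                         gap_open = 5, gap_extend = 2,
                         fragment_id = "fragment", gene_id = "gene") {
  fragment <- toupper(as.character(fragment)[1])
  cds <- toupper(as.character(cds)[1])
  if (is.na(fragment) || nchar(fragment) == 0L) stop("empty fragment")
  if (is.na(cds) || nchar(cds) == 0L) stop("empty CDS")
  al <- .affine_align_cpp(fragment, cds, match, mismatch, gap_open,
                          gap_extend, "glocal")
  fb <- strsplit(fragment, "")[[1]]
  base <- ifelse(is.na(al$frag_pos), "-", fb[al$frag_pos + 1L])
  cols <- data.frame(frag_pos = al$frag_pos, cds_pos = al$cds_pos,
                     base = base, stringsAsFactors = FALSE)
  structure(list(fragment_id = fragment_id, gene_id = gene_id,
                 score = al$score, columns = cols),
            class = "coord_alignment")
}

#' @export
print.coord_alignment <- function(x, ...) {
  cat(sprintf("coord_alignment %s -> %s: %d columns, score %.1f\n",
              x$fragment_id, x$gene_id, nrow(x$columns), x$score))
  invisible(x)
}

#' Repair frame-disrupting insertions
#'
#' Deletes every alignment column where the fragment has a base but the CDS
#' has a gap — extra nucleotides relative to the reference reading frame are
#' treated as sequencing errors and discarded.  Deletions relative to the
#' CDS are retained (as CDS positions with a fragment gap) and dealt with at
#' the codon stage.
#'
#' @param alignment A [align_affine()] result.
#' @return The repaired `coord_alignment`.
#' @export
repair_frame <- function(alignment) {
  stopifnot(inherits(alignment, "coord_alignment"))
  keep <- !is.na(alignment$columns$cds_pos)
  alignment$columns <- alignment$columns[keep, , drop = FALSE]
  rownames(alignment$columns) <- NULL
  alignment
}

#' Per-species consensus on the CDS grid
#'
#' Stacks frame-repaired fragment alignments of one gene and species and
#' calls, at every CDS position, the majority base among covering fragments
#' (a fragment gap at a covered position votes '-').  Ties are broken by
#' the base carried by the highest-scoring fragment, then lexicographically.
#' Uncovered positions are '-'.
#'
#' @param alignments List of frame-repaired [coord_alignment]s for one gene.
#' @param cds_len Reference CDS length in bp.
#' @param gene_id,species_id Identifiers carried in the result.
#' @return List of class `species_consensus`: `gene_id`, `species_id`,
#'   `seq` (character vector over A,C,G,T,-, length `cds_len`), `support`
#'   (covering-fragment count per position).
#' @export
build_consensus <- function(alignments, cds_len, gene_id = "gene",
                            species_id = "species") {
  if (length(alignments) == 0L) stop("no alignments to build consensus from")
  letters5 <- c("A", "C", "G", "T", "-")
  votes <- matrix(0L, 5, cds_len, dimnames = list(letters5, NULL))
  bestsc <- matrix(-Inf, 5, cds_len)
  for (al in alignments) {
    stopifnot(inherits(al, "coord_alignment"))
    cc <- al$columns
    cc <- cc[!is.na(cc$cds_pos), , drop = FALSE]
    b <- ifelse(is.na(cc$frag_pos), "-", cc$base)
    b[!(b %in% letters5)] <- "-"  # ambiguity codes never vote a base
    i <- match(b, letters5)
    j <- cc$cds_pos + 1L
    ij <- cbind(i, j)  # unique within one alignment, so safe to vectorize
    votes[ij] <- votes[ij] + 1L
    bestsc[ij] <- pmax(bestsc[ij], al$score)
  }
  support <- colSums(votes)
  seq <- rep("-", cds_len)
  cov <- which(support > 0L)
  for (j in cov) {
    v <- votes[, j]
    top <- which(v == max(v))
    if (length(top) > 1L) {
      sc <- bestsc[top, j]
      top <- top[sc == max(sc)]
      top <- top[order(letters5[top])]
    }
    seq[j] <- letters5[top[1]]
  }
  structure(list(gene_id = gene_id, species_id = species_id, seq = seq,
                 support = as.integer(support)),
            class = "species_consensus")
}

#' @export
print.species_consensus <- function(x, ...) {
  cat(sprintf("species_consensus %s/%s: %d bp, %.1f%% covered\n",
              x$gene_id, x$species_id, length(x$seq),
              100 * mean(x$seq != "-")))
  invisible(x)
}

#' Assemble a gap-free in-frame codon alignment
#'
#' Stacks the reference CDS and the species consensuses on the CDS codon
#' grid, removes the terminal stop codon of the reference frame, then drops
#' every codon column containing a gap, an ambiguity code or a stop codon in
#' any row.  Genes whose surviving alignment is shorter than `min_len` bp
#' are rejected.
#'
#' @param consensuses List of [build_consensus()] results (1 or more
#'   species) sharing a gene.
#' @param ref_cds Reference CDS sequence (with terminal stop codon).
#' @param min_len Minimum surviving alignment length in bp (default 300).
#' @param ref_name Row name used for the reference species.
#' @return A [codon_aln] with the reference as first row, or `NULL` when
#'   the gene is rejected.
#' @export
build_codon_alignment <- function(consensuses, ref_cds, min_len = 300L,
                                  ref_name = "reference") {
  stopifnot(length(consensuses) >= 1L)
  ref_cds <- toupper(as.character(ref_cds)[1])
  gene_id <- consensuses[[1]]$gene_id
  for (cs in consensuses) {
    stopifnot(inherits(cs, "species_consensus"))
    if (length(cs$seq) != nchar(ref_cds))
      stop(sprintf("consensus length (%d) does not match CDS length (%d) for %s",
                   length(cs$seq), nchar(ref_cds), gene_id))
  }
  seqs <- c(setNames(ref_cds, ref_name),
            vapply(consensuses, function(cs)
              paste(cs$seq, collapse = ""), "",
              USE.NAMES = FALSE))
  names(seqs) <- c(ref_name, vapply(consensuses, `[[`, "", "species_id"))
  aln <- codon_aln_from_seqs(seqs, gene_id = gene_id)
  if (is.null(aln) || aln$bp < min_len) return(NULL)
  aln
}
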