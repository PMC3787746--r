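# Ortholog assignment: k-mer-seeded local alignment of transcript fragments
# against the reference cDNA set, Karlin-Altschul e-values, and the
# best-hit filters (e-value <= 1e-5, aligned length >= 300 bp).

#' Matching parameters
#'
#' @param k Seed word length (>= 8; default 11, a blastn-like regime for
#'   90-98% identity).
#' @param max_evalue Hit e-value ceiling (default 1e-5).
#' @param min_hit_len Minimum aligned hit length in bp (default 300).
#' @param match,mismatch Match/mismatch scores (default +1/-2).
#' @param gap_open,gap_extend Affine gap penalties (positive; default 5/2).
#' @param max_candidates Seeded subjects extended per strand (default 25).
#' @return List of class `match_params`.
#' @export
match_params <- function(k = 11L, max_evalue = 1e-5, min_hit_len = 300L,
                         match = 1L, mismatch = -2L, gap_open = 5,
                         gap_extend = 2, max_candidates = 25L) {
  stopifnot(k >= 8L, max_evalue > 0, min_hit_len > 0, match > 0,
            mismatch < 0, gap_open >= 0, gap_extend >= 0)
  structure(list(k = as.integer(k), max_evalue = max_evalue,
                 min_hit_len = as.integer(min_hit_len),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = gap_open, gap_extend = gap_extend,
                 max_candidates = as.integer(max_candidates)),
            class = "match_params")
}

.as_char_seqs <- function(x) {
  if (methods::is(x, "DNAStringSet")) x <- setNames(as.character(x), names(x))
  stopifnot(is.character(x))
  toupper(x)
}

.seq_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1L), k:L)
}

#' Index a reference cDNA set for seeded search
#'
#' Records every k-mer occurrence of the database (k-mers containing N are
#' skipped), the database composition and the Karlin-Altschul parameters of
#' the scoring scheme at that composition.
#'
#' @param cdna_set Named character vector or `DNAStringSet` of reference
#'   cDNA sequences (alphabet ACGTN).
#' @param params A [match_params()].
#' @return List of class `kmer_index`.
#' @export
index_reference <- function(cdna_set, params = match_params()) {
  seqs <- .as_char_seqs(cdna_set)
  if (length(seqs) == 0L) stop("empty reference set")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("reference sequences must be named")
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup)) stop("duplicate sequence id: ", dup[1])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("non-ACGTN characters in sequence ",
                     names(seqs)[bad][1])
  short <- nchar(seqs) < params$k
  if (any(short)) {
    warning("skipping ", sum(short), " sequence(s) shorter than k")
    seqs_idx <- seqs[!short]
  } else seqs_idx <- seqs
  tabs <- lapply(names(seqs_idx), function(id) {
    km <- .seq_kmers(seqs_idx[[id]], params$k)
    keep <- !grepl("N", km, fixed = TRUE)
    if (!any(keep)) return(NULL)
    data.table::data.table(kmer = km[keep], seq_id = id,
                           pos = which(keep))
  })
  dt <- data.table::rbindlist(tabs)
  data.table::setkey(dt, kmer)
  # background composition of the database for the score statistics
  cnt <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(seqs), baseOnly = TRUE))[c("A", "C", "G", "T")]
  freq <- cnt / sum(cnt)
  ka <- karlin_params(params$match, params$mismatch,
                      p_match = sum(freq^2))
  structure(list(dt = dt, seqs = seqs, db_len = sum(nchar(seqs)),
                 params = params, base_freq = freq, ka = ka),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: %d sequences, %d bp, k=%d, %d indexed k-mer positions\n",
              length(x$seqs), x$db_len, x$params$k, nrow(x$dt)))
  invisible(x)
}

.empty_hits <- function() {
  data.frame(fragment_id = character(0), gene_id = character(0),
             raw_score = numeric(0), bit_score = numeric(0),
             evalue = numeric(0), q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0), pident = numeric(0),
             length = integer(0), mismatches = integer(0),
             gap_opens = integer(0), strand = character(0),
             stringsAsFactors = FALSE)
}

#' Seeded local search of one fragment against the index
#'
#' Finds candidate subjects sharing seed words with the fragment (both
#' strands), extends each candidate by affine-gap local alignment, and
#' scores hits with Karlin-Altschul bit scores and e-values
#' (`E = K m n exp(-lambda S)`, `m` = fragment length, `n` = database
#' length).  Hits are returned sorted by ascending e-value.
#'
#' @param fragment Nucleotide sequence (character scalar), length >= k.
#' @param index A [index_reference()] result.
#' @param params Matching parameters; default those stored in the index.
#' @param fragment_id Identifier used in the output table.
#' @return data.frame of hits with 1-based inclusive coordinates; minus
#'   strand hits have `s_start > s_end`.
#' @export
search <- function(fragment, index, params = index$params,
                   fragment_id = "fragment") {
  stopifnot(inherits(index, "kmer_index"))
  fragment <- toupper(as.character(fragment)[1])
  if (is.na(fragment) || nchar(fragment) == 0L)
    stop("empty fragment")
  m <- nchar(fragment)
  if (m < params$k) stop("fragment shorter than seed length k")
  hits <- list()
  for (strand in c("+", "-")) {
    fr <- if (strand == "+") fragment else .revcomp(fragment)
    km <- .seq_kmers(fr, params$k)
    km <- unique(km[!grepl("N", km, fixed = TRUE)])
    if (!length(km)) next
    seed <- index$dt[data.table::data.table(kmer = km), nomatch = NULL]
    if (nrow(seed) == 0L) next
    counts <- seed[, .N, by = "seq_id"]
    data.table::setorderv(counts, c("N", "seq_id"), order = c(-1L, 1L))
    # two-hit heuristic: once any subject has two seed words, single-seed
    # subjects are almost surely spurious and not worth extending
    if (counts$N[1] >= 2L) counts <- counts[counts$N >= 2L, ]
    cand <- head(counts$seq_id, params$max_candidates)
    for (sid in cand) {
      al <- .affine_align_cpp(fr, index$seqs[[sid]], params$match,
                              params$mismatch, params$gap_open,
                              params$gap_extend, "local")
      sc <- al$score
      if (sc <= 0) next
      ke <- karlin_evalue(sc, m, index$db_len, index$ka)
      alen <- length(al$frag_pos)
      go <- sum(diff(c(FALSE, is.na(al$frag_pos))) == 1L) +
        sum(diff(c(FALSE, is.na(al$cds_pos))) == 1L)
      p1 <- al$p_start + 1L; p2 <- al$p_end + 1L
      s1 <- al$s_start + 1L; s2 <- al$s_end + 1L
      if (strand == "+") {
        qs <- p1; qe <- p2; ss <- s1; se <- s2
      } else {  # report on the original fragment; subject descending
        qs <- m - p2 + 1L; qe <- m - p1 + 1L; ss <- s2; se <- s1
      }
      hits[[length(hits) + 1L]] <- data.frame(
        fragment_id = fragment_id, gene_id = sid, raw_score = sc,
        bit_score = ke$bit_score, evalue = ke$evalue, q_start = qs,
        q_end = qe, s_start = ss, s_end = se,
        pident = 100 * al$nmatch / alen, length = alen,
        mismatches = al$nmismatch, gap_opens = go,
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(.empty_hits())
  out <- do.call(rbind, hits)
  out[order(out$evalue, -out$raw_score, out$gene_id), , drop = FALSE]
}

#' Search a set of fragments
#'
#' @param fragments Named character vector or `DNAStringSet`.
#' @inheritParams search
#' @return Combined hit data.frame (see [search()]).
#' @export
search_fragments <- function(fragments, index, params = index$params) {
  seqs <- .as_char_seqs(fragments)
  stopifnot(!is.null(names(seqs)))
  res <- lapply(names(seqs), function(id) {
    if (nchar(seqs[[id]]) < params$k) return(.empty_hits())
    search(seqs[[id]], index, params, fragment_id = id)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Best-hit ortholog assignment
#'
#' Applies the hit filters (aligned length >= `min_hit_len`, e-value <=
#' `max_evalue`) and keeps the single best surviving hit per fragment
#' (ascending e-value; ties broken by higher raw score, then lexicographic
#' gene id).  Fragments with no surviving hit are recorded unassigned.
#'
#' @param hits Hit data.frame from [search_fragments()].
#' @param params A [match_params()].
#' @param fragment_ids Optional universe of fragment ids (so fragments with
#'   no hits at all appear as unassigned rows).
#' @return data.frame with one row per fragment: `fragment_id`, `gene_id`
#'   (NA if unassigned), `strand`, `evalue`, `raw_score`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `length`, `pident`.
#' @export
assign_orthologs <- function(hits, params = match_params(),
                             fragment_ids = NULL) {
  if (is.null(fragment_ids)) fragment_ids <- unique(hits$fragment_id)
  keep <- hits$length >= params$min_hit_len & hits$evalue <= params$max_evalue
  surv <- hits[keep, , drop = FALSE]
  surv <- surv[order(surv$evalue, -surv$raw_score, surv$gene_id), ,
               drop = FALSE]
  best <- surv[!duplicated(surv$fragment_id), , drop = FALSE]
  cols <- c("gene_id", "strand", "evalue", "raw_score", "q_start", "q_end",
            "s_start", "s_end", "length", "pident")
  out <- data.frame(fragment_id = fragment_ids, stringsAsFactors = FALSE)
  mi <- match(fragment_ids, best$fragment_id)
  for (cl in cols) out[[cl]] <- best[[cl]][mi]
  out
}

#' Write hits in the conventional 12-column tabular format
#'
#' Columns: query, subject, \% identity, alignment length, mismatches, gap
#' opens, qstart, qend, sstart, send, evalue, bitscore (1-based inclusive).
#'
#' @param hits Hit data.frame.
#' @param path Output file.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- hits[, c("fragment_id", "gene_id", "pident", "length", "mismatches",
                  "gap_opens", "q_start", "q_end", "s_start", "s_end",
                  "evalue", "bit_score")]
  out$pident <- sprintf("%.3f", out$pident)
  out$evalue <- format(out$evalue, digits = 3, scientific = TRUE)
  out$bit_score <- sprintf("%.1f", out$bit_score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
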