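# Reference-free heterozygous SNP discovery from single-individual reads:
# read filters, a depth-based diploid heterozygote caller on the species
# consensus, compartment classification against gene models, and
# per-chromosome SNP density.

#' SNP-calling parameters
#'
#' @param min_read_len Minimum read length in bp (default 100; shorter
#'   reads are filtered).
#' @param homopolymer_frac Reads with any single nucleotide making up at
#'   least this fraction of the read are filtered (default 0.60).
#' @param min_allele_depth Minimum reads supporting each allele (default 2).
#' @param min_total_depth Minimum total depth at a called site (default 4).
#' @param end_mask Bases ignored at each read end (default 5).
#' @param indel_mask Consensus positions within this distance of an
#'   alignment gap are ignored for that read (default 3).
#' @param flank_bp Width of the 5'/3' flanking compartments (default 1000).
#' @return List of class `snp_params`.
#' @export
snp_params <- function(min_read_len = 100L, homopolymer_frac = 0.60,
                       min_allele_depth = 2L, min_total_depth = 4L,
                       end_mask = 5L, indel_mask = 3L, flank_bp = 1000L) {
  stopifnot(min_read_len > 0, homopolymer_frac > 0, homopolymer_frac <= 1,
            min_allele_depth > 0, min_total_depth > 0, end_mask >= 0,
            indel_mask >= 0, flank_bp > 0)
  structure(list(min_read_len = as.integer(min_read_len),
                 homopolymer_frac = homopolymer_frac,
                 min_allele_depth = as.integer(min_allele_depth),
                 min_total_depth = as.integer(min_total_depth),
                 end_mask = as.integer(end_mask),
                 indel_mask = as.integer(indel_mask),
                 flank_bp = as.integer(flank_bp)),
            class = "snp_params")
}

#' Filter reads by length and homopolymer content
#'
#' Drops reads shorter than `min_read_len` and reads in which one
#' nucleotide represents at least `homopolymer_frac` of the entire read.
#'
#' @param reads Named character vector or `DNAStringSet`.
#' @param params A [snp_params()].
#' @return List: `reads` (kept, named character vector), `n_short`,
#'   `n_homopolymer` (counts dropped per rule; a read failing both rules
#'   counts as short).
#' @export
filter_reads <- function(reads, params = snp_params()) {
  seqs <- .as_char_seqs(reads)
  len <- nchar(seqs)
  short <- len < params$min_read_len
  maxfrac <- vapply(seqs, function(s) {
    tb <- table(strsplit(s, "")[[1]])
    max(tb) / nchar(s)
  }, numeric(1), USE.NAMES = FALSE)
  homo <- !short & maxfrac >= params$homopolymer_frac
  list(reads = seqs[!short & !homo], n_short = sum(short),
       n_homopolymer = sum(homo))
}

#' Depth-based heterozygous SNP calling
#'
#' Builds a pileup of read alignments on each gene's species consensus and
#' calls a heterozygous site where exactly two alleles each reach
#' `min_allele_depth` and the total depth reaches `min_total_depth`.
#' Bases within `end_mask` of a read end, and consensus positions within
#' `indel_mask` of an alignment gap in that read, are excluded from the
#' pileup; positions where three or more alleles reach `min_allele_depth`
#' are skipped as error-rich.
#'
#' @param read_alignments Named list (gene id -> list of
#'   [coord_alignment]s of reads against that gene's consensus, reads
#'   oriented to the consensus strand).
#' @param cons_len Named integer vector of consensus lengths per gene.
#' @param params A [snp_params()].
#' @return data.frame of calls: `gene_id`, `pos` (0-based consensus
#'   position), `allele1`, `allele2` (allele1 has the higher depth; ties
#'   alphabetical), `depth1`, `depth2`.
#' @export
call_het_snps <- function(read_alignments, cons_len, params = snp_params()) {
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (g in names(read_alignments)) {
    alns <- read_alignments[[g]]
    L <- cons_len[[g]]
    if (is.null(L)) stop("no consensus length for gene ", g)
    if (length(alns) == 0L) next
    counts <- matrix(0L, 4, L, dimnames = list(bases, NULL))
    for (al in alns) {
      cc <- al$columns
      gapcols <- which(is.na(cc$frag_pos) | is.na(cc$cds_pos))
      masked <- rep(FALSE, nrow(cc))
      if (length(gapcols) && params$indel_mask > 0) {
        for (gc in gapcols) {
          lo <- max(1L, gc - params$indel_mask)
          hi <- min(nrow(cc), gc + params$indel_mask)
          masked[lo:hi] <- TRUE
        }
      }
      read_len <- sum(!is.na(cc$frag_pos))
      use <- !masked & !is.na(cc$cds_pos) & !is.na(cc$frag_pos) &
        cc$base %in% bases
      if (params$end_mask > 0) {
        rp <- cc$frag_pos - min(cc$frag_pos, na.rm = TRUE)
        use <- use & !is.na(rp) & rp >= params$end_mask &
          rp < (read_len - params$end_mask)
      }
      if (!any(use)) next
      ij <- cbind(match(cc$base[use], bases), cc$cds_pos[use] + 1L)
      counts[ij] <- counts[ij] + 1L  # unique positions within one read
    }
    tot <- colSums(counts)
    nallele <- colSums(counts >= params$min_allele_depth)
    cand <- which(nallele == 2L & tot >= params$min_total_depth)
    for (j in cand) {
      v <- counts[, j]
      al <- order(-v, bases)[1:2]
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, pos = j - 1L, allele1 = bases[al[1]],
        allele2 = bases[al[2]], depth1 = v[al[1]], depth2 = v[al[2]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), pos = integer(0),
                      allele1 = character(0), allele2 = character(0),
                      depth1 = integer(0), depth2 = integer(0)))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$gene_id, res$pos), , drop = FALSE]
}

# flanking intervals (0-based half-open) of every gene, strand-aware
.gene_flanks <- function(annotation, flank_bp) {
  g <- annotation$genes
  up <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                   type = ifelse(g$strand == "+", "flank5", "flank3"),
                   start = pmax(0L, g$tx_start - flank_bp),
                   end = g$tx_start, stringsAsFactors = FALSE)
  dn <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                   type = ifelse(g$strand == "+", "flank3", "flank5"),
                   start = g$tx_end, end = g$tx_end + flank_bp,
                   stringsAsFactors = FALSE)
  rbind(up, dn)
}

#' Classify SNP positions into genomic compartments
#'
#' Assigns each chromosome position to CDS, UTR5, UTR3, intron, flank5,
#' flank3 (within `flank_bp` of the transcript, strand-aware) or
#' intergenic, with that precedence when annotations overlap.
#'
#' @param calls data.frame with columns `chrom` and `genome_pos` (0-based).
#' @param annotation A [build_reference()] bundle (or any list with
#'   `chromosomes`, `genes`, `features` in the same layout).
#' @param params A [snp_params()] (for `flank_bp`).
#' @return `calls` with added columns `compartment` and `compartment_gene`.
#' @export
classify_snp <- function(calls, annotation, params = snp_params()) {
  prec <- c("CDS", "UTR5", "UTR3", "intron", "flank5", "flank3")
  chrlen <- setNames(annotation$chromosomes$length,
                     annotation$chromosomes$name)
  bad <- calls$genome_pos < 0 | calls$genome_pos >= chrlen[calls$chrom] |
    is.na(chrlen[calls$chrom])
  if (any(bad)) stop("SNP position beyond chromosome length")
  fe <- annotation$features
  fe <- merge(fe, annotation$genes[, c("gene_id", "chrom")], by = "gene_id")
  fl <- .gene_flanks(annotation, params$flank_bp)
  allf <- rbind(fe[, c("gene_id", "chrom", "type", "start", "end")], fl)
  comp <- rep("intergenic", nrow(calls))
  gene <- rep(NA_character_, nrow(calls))
  for (ch in unique(calls$chrom)) {
    ci <- which(calls$chrom == ch)
    cf <- allf[allf$chrom == ch, , drop = FALSE]
    if (!nrow(cf)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = calls$genome_pos[ci] + 1L, width = 1L),
      IRanges::IRanges(start = cf$start + 1L, end = cf$end))
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    pr <- match(cf$type[sh], prec)
    o <- order(qh, pr, cf$gene_id[sh])
    first <- !duplicated(qh[o])
    comp[ci[qh[o][first]]] <- cf$type[sh[o][first]]
    gene[ci[qh[o][first]]] <- cf$gene_id[sh[o][first]]
  }
  calls$compartment <- comp
  calls$compartment_gene <- gene
  calls
}

#' Per-chromosome SNP density and size scaling
#'
#' Counts calls per chromosome (rows for SNP-free chromosomes included),
#' computes SNPs per kb, and fits the least-squares line of count versus
#' chromosome length.
#'
#' @param calls data.frame with a `chrom` column.
#' @param chromosomes data.frame with `name` and `length` (bp).
#' @return List of class `chrom_density`: `table` (chromosome, length,
#'   snp_count, snps_per_kb), `slope`, `intercept`, `r_squared`.
#' @export
chromosome_density <- function(calls, chromosomes) {
  if (any(chromosomes$length <= 0)) stop("zero-length chromosome")
  cnt <- table(factor(calls$chrom, levels = chromosomes$name))
  tabd <- data.frame(chromosome = chromosomes$name,
                     length = chromosomes$length,
                     snp_count = as.integer(cnt),
                     snps_per_kb = 1000 * as.integer(cnt) /
                       chromosomes$length,
                     stringsAsFactors = FALSE)
  fit <- lm(snp_count ~ length, data = tabd)
  structure(list(table = tabd,
                 slope = unname(coef(fit)["length"]),
                 intercept = unname(coef(fit)["(Intercept)"]),
                 r_squared = summary(fit)$r.squared),
            class = "chrom_density")
}

#' @export
print.chrom_density <- function(x, ...) {
  print(x$table)
  cat(sprintf("count ~ length: slope=%.3g r^2=%.3f\n", x$slope,
              x$r_squared))
  invisible(x)
}
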