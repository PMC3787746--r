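# File formats: FASTA/FASTQ via Biostrings; minimal GFF3 and site-only VCF
# writers/readers with exact round-trips.  Internal coordinates are 0-based
# half-open; GFF3 and VCF are written 1-based inclusive.

#' Read and write FASTA
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector or `DNAStringSet`.
#' @param width Line-wrap width (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read FASTQ (qualities ignored)
#'
#' The SNP caller is depth-based, so base qualities are accepted but
#' ignored.
#'
#' @param path File path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Write a reference annotation as GFF3
#'
#' Emits gene, mRNA, CDS, five_prime_UTR, three_prime_UTR and intron
#' features (1-based inclusive coordinates) plus `##sequence-region`
#' pragmas for the chromosomes.
#'
#' @param bundle A [build_reference()] bundle (or annotation list with
#'   `chromosomes`, `genes`, `features`).
#' @param path Output file.
#' @export
write_gff3 <- function(bundle, path) {
  type_map <- c(CDS = "CDS", UTR5 = "five_prime_UTR",
                UTR3 = "three_prime_UTR", intron = "intron")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(bundle$chromosomes)))
    writeLines(sprintf("##sequence-region %s 1 %d",
                       bundle$chromosomes$name[i],
                       bundle$chromosomes$length[i]), con)
  g <- bundle$genes
  fe <- bundle$features
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    writeLines(sprintf("%s\tomegascan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom[i], g$tx_start[i] + 1L, g$tx_end[i],
                       g$strand[i], gid), con)
    writeLines(sprintf("%s\tomegascan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                       g$chrom[i], g$tx_start[i] + 1L, g$tx_end[i],
                       g$strand[i], gid, gid), con)
    fg <- fe[fe$gene_id == gid, , drop = FALSE]
    fg <- fg[order(fg$start), , drop = FALSE]
    for (j in seq_len(nrow(fg))) {
      ph <- if (fg$type[j] == "CDS") "0" else "."
      writeLines(sprintf("%s\tomegascan\t%s\t%d\t%d\t.\t%s\t%s\tParent=%s.t1",
                         g$chrom[i], type_map[[fg$type[j]]],
                         fg$start[j] + 1L, fg$end[j], g$strand[i], ph, gid),
                 con)
    }
  }
  invisible(path)
}

#' Read a GFF3 annotation written by [write_gff3()]
#'
#' @param path GFF3 file.
#' @return Annotation list with `chromosomes`, `genes`, `features`
#'   (0-based half-open internally).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  sr <- grep("^##sequence-region", lines, value = TRUE)
  srf <- do.call(rbind, strsplit(sr, "\\s+"))
  chromosomes <- data.frame(name = srf[, 2],
                            length = as.integer(srf[, 4]),
                            stringsAsFactors = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body))
    stop("no feature records in ", path)
  f <- strsplit(body, "\t")
  bad <- which(lengths(f) != 9L)
  if (length(bad))
    stop("malformed GFF3 record at line ",
         which(lines == body[bad[1]])[1])
  f <- do.call(rbind, f)
  type_map <- c(CDS = "CDS", five_prime_UTR = "UTR5",
                three_prime_UTR = "UTR3", intron = "intron")
  att <- f[, 9]
  is_gene <- f[, 3] == "gene"
  genes <- data.frame(gene_id = sub("^ID=", "", att[is_gene]),
                      chrom = f[is_gene, 1], strand = f[is_gene, 7],
                      tx_start = as.integer(f[is_gene, 4]) - 1L,
                      tx_end = as.integer(f[is_gene, 5]),
                      stringsAsFactors = FALSE)
  is_feat <- f[, 3] %in% names(type_map)
  features <- data.frame(
    type = unname(type_map[f[is_feat, 3]]),
    start = as.integer(f[is_feat, 4]) - 1L,
    end = as.integer(f[is_feat, 5]),
    gene_id = sub("\\.t1$", "", sub("^Parent=", "", att[is_feat])),
    stringsAsFactors = FALSE)
  list(chromosomes = chromosomes, genes = genes,
       features = features[, c("type", "start", "end", "gene_id")])
}

#' Write heterozygous SNP calls as a minimal VCF
#'
#' Site-only VCF 4.2 with INFO keys DP1, DP2 (allele depths), GENE and
#' CMP (compartment).  Positions are written 1-based.
#'
#' @param calls data.frame with columns `chrom`, `genome_pos` (0-based),
#'   `allele1`, `allele2`, `depth1`, `depth2` and optionally
#'   `compartment_gene`, `compartment`.
#' @param chromosomes data.frame with `name`, `length` for contig headers.
#' @param path Output file.
#' @export
write_vcf <- function(calls, chromosomes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", chromosomes$name,
                       chromosomes$length),
               "##INFO=<ID=DP1,Number=1,Type=Integer,Description=\"Depth of allele 1\">",
               "##INFO=<ID=DP2,Number=1,Type=Integer,Description=\"Depth of allele 2\">",
               "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
               "##INFO=<ID=CMP,Number=1,Type=String,Description=\"Genomic compartment\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls)) {
    gene <- if ("compartment_gene" %in% names(calls))
      ifelse(is.na(calls$compartment_gene), ".", calls$compartment_gene)
    else "."
    cmp <- if ("compartment" %in% names(calls)) calls$compartment else "."
    info <- sprintf("DP1=%d;DP2=%d;GENE=%s;CMP=%s", calls$depth1,
                    calls$depth2, gene, cmp)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", calls$chrom,
                       calls$genome_pos + 1L, calls$allele1, calls$allele2,
                       info), con)
  }
  invisible(path)
}

#' Read a VCF written by [write_vcf()]
#'
#' @param path VCF file.
#' @return data.frame with `chrom`, `genome_pos` (0-based), `allele1`,
#'   `allele2`, `depth1`, `depth2`, `compartment_gene`, `compartment`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.frame(chrom = character(0), genome_pos = integer(0),
                      allele1 = character(0), allele2 = character(0),
                      depth1 = integer(0), depth2 = integer(0),
                      compartment_gene = character(0),
                      compartment = character(0)))
  f <- strsplit(body, "\t")
  bad <- which(lengths(f) != 8L)
  if (length(bad))
    stop("malformed VCF record at line ", which(lines == body[bad[1]])[1])
  f <- do.call(rbind, f)
  getinfo <- function(info, key) {
    vapply(info, function(s) {
      m <- regmatches(s, regexpr(paste0(key, "=[^;]*"), s))
      if (length(m)) sub(paste0(key, "="), "", m) else NA_character_
    }, "", USE.NAMES = FALSE)
  }
  info <- f[, 8]
  data.frame(chrom = f[, 1], genome_pos = as.integer(f[, 2]) - 1L,
             allele1 = f[, 4], allele2 = f[, 5],
             depth1 = as.integer(getinfo(info, "DP1")),
             depth2 = as.integer(getinfo(info, "DP2")),
             compartment_gene = getinfo(info, "GENE"),
             compartment = getinfo(info, "CMP"),
             stringsAsFactors = FALSE)
}

#' Tab-separated table helpers
#'
#' Plain TSV with a header, no quoting and no row names — the interchange
#' format of every pipeline table.
#'
#' @param x data.frame.
#' @param path File path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
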