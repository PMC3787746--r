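# Read filters, the depth-based heterozygote caller, compartment
# classification and per-chromosome density.

mkread_aln <- function(bases, start, id = "r") {
  # ungapped read alignment covering consensus positions start..start+n-1
  n <- length(bases)
  cols <- data.frame(frag_pos = seq_len(n) - 1L,
                     cds_pos = start + seq_len(n) - 1L, base = bases,
                     stringsAsFactors = FALSE)
  structure(list(fragment_id = id, gene_id = "g", score = n,
                 columns = cols), class = "coord_alignment")
}

test_that("read filters drop short and homopolymer reads", {
  reads <- c(
    short = paste(rep("ACGT", 24), collapse = ""),            # 96 bp
    keep = paste(rep("ACGT", 40), collapse = ""),             # 160 bp, 25% max
    homo = paste(c(rep("A", 130), rep("CGT", 23)), collapse = ""),  # 65% A
    edge = paste(rep("A", 99), collapse = ""))                # short wins
  f <- filter_reads(reads, snp_params())
  expect_identical(names(f$reads), "keep")
  expect_equal(f$n_short, 2L)
  expect_equal(f$n_homopolymer, 1L)
  # exactly at 60%: filtered (rule is >=)
  r60 <- c(x = paste(c(rep("A", 60), rep("C", 20), rep("G", 20)),
                     collapse = ""))
  expect_equal(length(filter_reads(r60, snp_params())$reads), 0L)
})

test_that("het calls require two alleles at depth with masks applied", {
  p <- snp_params(end_mask = 0, min_total_depth = 4)
  L <- 50L
  base <- rep("A", L)
  alt <- base; alt[20] <- "G"
  alns <- c(replicate(3, mkread_aln(base, 0), simplify = FALSE),
            replicate(3, mkread_aln(alt, 0), simplify = FALSE))
  calls <- call_het_snps(list(g = alns), c(g = L), p)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 19L)
  expect_identical(c(calls$allele1, calls$allele2), c("A", "G"))
  expect_equal(c(calls$depth1, calls$depth2), c(3L, 3L))

  # 5 vs 1: minor allele below min_allele_depth, no call
  alns2 <- c(replicate(5, mkread_aln(base, 0), simplify = FALSE),
             list(mkread_aln(alt, 0)))
  expect_equal(nrow(call_het_snps(list(g = alns2), c(g = L), p)), 0L)

  # homozygous error-free input: zero calls
  alns3 <- replicate(6, mkread_aln(base, 0), simplify = FALSE)
  expect_equal(nrow(call_het_snps(list(g = alns3), c(g = L), p)), 0L)

  # three alleles at depth: error-rich position skipped
  alt2 <- base; alt2[20] <- "T"
  alns4 <- c(replicate(2, mkread_aln(base, 0), simplify = FALSE),
             replicate(2, mkread_aln(alt, 0), simplify = FALSE),
             replicate(2, mkread_aln(alt2, 0), simplify = FALSE))
  expect_equal(nrow(call_het_snps(list(g = alns4), c(g = L), p)), 0L)
})

test_that("end and indel masks suppress unreliable pileup columns", {
  L <- 60L
  base <- rep("A", L)
  alt <- base; alt[3] <- "G"   # within the 5 bp end mask of every read
  p <- snp_params()
  alns <- c(replicate(3, mkread_aln(base, 0), simplify = FALSE),
            replicate(3, mkread_aln(alt, 0), simplify = FALSE))
  expect_equal(nrow(call_het_snps(list(g = alns), c(g = L), p)), 0L)

  # a gap column masks indel_mask positions on both sides
  gapaln <- function(bases) {
    cols <- data.frame(frag_pos = c(0:19, NA, 20:(length(bases) - 1)),
                       cds_pos = c(0:20, 21:(length(bases))),
                       base = c(bases[1:20], "-", bases[21:length(bases)]),
                       stringsAsFactors = FALSE)
    structure(list(fragment_id = "r", gene_id = "g", score = 1,
                   columns = cols), class = "coord_alignment")
  }
  alt22 <- base; alt22[23] <- "G"  # cds_pos 23: within 3 of the gap column
  p0 <- snp_params(end_mask = 0)
  alns2 <- c(replicate(3, list(gapaln(alt22))),
             replicate(3, mkread_aln(base, 0), simplify = FALSE))
  calls <- call_het_snps(list(g = alns2), c(g = L + 1L), p0)
  expect_false(23L %in% calls$pos)
})

test_that("planted heterozygous sites are recovered from deep reads", {
  # recall and precision against the generator truth at depth >= 8
  cfg <- sim_config(seed = 33, n_genes = 12, codons_per_gene = 300,
                    read_coverage = 12)
  ref <- build_reference(cfg)
  tr <- evolve_orthologs(ref, cfg)
  dip <- make_diploid_and_reads(tr, ref, cfg)
  p <- snp_params()
  filt <- filter_reads(dip$reads, p)
  rt <- dip$read_truth[dip$read_truth$id %in% names(filt$reads), ]
  alns <- list(); cons_len <- integer(0)
  for (g in ref$genes$gene_id) {
    ids <- rt$id[rt$gene_id == g]
    alns[[g]] <- lapply(ids, function(id) {
      s <- filt$reads[[id]]
      if (rt$strand[rt$id == id] == "-") s <- omegascan:::.revcomp(s)
      align_affine(s, tr$seqs$ingroupA[[g]], fragment_id = id, gene_id = g)
    })
    cons_len[g] <- nchar(tr$seqs$ingroupA[[g]])
  }
  calls <- call_het_snps(alns, cons_len, p)
  truth_keys <- paste(dip$sites$gene_id, dip$sites$cds_pos)
  call_keys <- paste(calls$gene_id, calls$pos)
  # condition on adequate coverage: reads fall inside the transcript, so
  # the last ~read-length of each gene has linearly decaying depth
  depth_at <- function(g, pos) {
    rg <- rt[rt$gene_id == g, ]
    sum(rg$start + p$end_mask <= pos & pos < rg$start + rg$len - p$end_mask)
  }
  covered <- mapply(depth_at, dip$sites$gene_id, dip$sites$cds_pos) >= 8
  recall <- mean(truth_keys[covered] %in% call_keys)
  precision <- mean(call_keys %in% truth_keys)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.95)
})

test_that("compartment classification matches an interval-membership oracle", {
  cfg <- sim_config(seed = 44, n_genes = 20, codons_per_gene = 150)
  ref <- build_reference(cfg)
  p <- snp_params()
  set.seed(45)
  chrom <- sample(ref$chromosomes$name, 400, TRUE)
  pos <- vapply(chrom, function(ch)
    sample.int(ref$chromosomes$length[ref$chromosomes$name == ch], 1) - 1L,
    1L)
  calls <- data.frame(chrom = chrom, genome_pos = pos,
                      stringsAsFactors = FALSE)
  got <- classify_snp(calls, ref, p)
  fe <- merge(ref$features, ref$genes[, c("gene_id", "chrom")],
              by = "gene_id")
  oracle_one <- function(ch, x) {
    hit <- fe[fe$chrom == ch & fe$start <= x & x < fe$end, ]
    for (ty in c("CDS", "UTR5", "UTR3", "intron"))
      if (ty %in% hit$type) return(ty)
    g <- ref$genes[ref$genes$chrom == ch, ]
    fl5 <- with(g, ifelse(strand == "+",
                          x >= tx_start - p$flank_bp & x < tx_start,
                          x >= tx_end & x < tx_end + p$flank_bp))
    fl3 <- with(g, ifelse(strand == "+",
                          x >= tx_end & x < tx_end + p$flank_bp,
                          x >= tx_start - p$flank_bp & x < tx_start))
    if (any(fl5) && any(fl3)) {
      # overlapping flanks of different genes: precedence flank5 first
      return("flank5")
    }
    if (any(fl5)) return("flank5")
    if (any(fl3)) return("flank3")
    "intergenic"
  }
  want <- mapply(oracle_one, chrom, pos)
  expect_identical(got$compartment, unname(want))
})

test_that("classification flags positions beyond the chromosome", {
  cfg <- sim_config(seed = 46, n_genes = 10, codons_per_gene = 150)
  ref <- build_reference(cfg)
  bad <- data.frame(chrom = ref$chromosomes$name[1],
                    genome_pos = ref$chromosomes$length[1] + 5L)
  expect_error(classify_snp(bad, ref, snp_params()), "beyond chromosome")
})

test_that("chromosome density arithmetic, zero rows and linear scaling", {
  chroms <- data.frame(name = c("c1", "c2"), length = c(5000L, 8000L))
  calls <- data.frame(chrom = rep("c1", 10))
  d <- chromosome_density(calls, chroms)
  expect_equal(d$table$snps_per_kb, c(2.0, 0.0))
  expect_equal(d$table$snp_count, c(10L, 0L))
  expect_error(chromosome_density(calls, data.frame(name = "c", length = 0L)),
               "zero-length")

  # uniform rate across 10 chromosomes: near-perfect linearity
  set.seed(47)
  lens <- seq(2e5, 2e6, length.out = 10)
  cnts <- rbinom(10, lens, 5e-4)
  calls2 <- data.frame(chrom = rep(sprintf("c%02d", 1:10), cnts))
  d2 <- chromosome_density(calls2,
                           data.frame(name = sprintf("c%02d", 1:10),
                                      length = lens))
  expect_gte(sum(d2$table$snp_count), 1000)
  expect_gte(d2$r_squared, 0.98)
})
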