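# Fragment-to-CDS alignment, frame repair, consensus and codon-alignment
# assembly.

test_that("exact substrings align gaplessly with full score", {
  set.seed(1)
  cds <- random_cds(400)
  frag <- substr(cds, 301, 700)
  al <- align_affine(frag, cds, match = 1, mismatch = -1, gap_open = 1,
                     gap_extend = 1)
  expect_equal(nrow(al$columns), 400L)
  expect_equal(al$score, 400)
  expect_false(anyNA(al$columns$frag_pos))
  expect_false(anyNA(al$columns$cds_pos))
  expect_equal(al$columns$cds_pos, 300:699)
})

test_that("alignment scores match an exhaustive DP oracle", {
  al <- align_affine("ACGT", "ACGGT", match = 1, mismatch = -1,
                     gap_open = 1, gap_extend = 1)
  expect_equal(al$score,
               oracle_affine_score("ACGT", "ACGGT", 1, -1, 1, 1, "glocal"))
  expect_equal(sum(is.na(al$columns$frag_pos)), 1L)  # one CDS-side gap

  set.seed(14)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:25) {
    p <- paste(sample(bases, sample(5:30, 1), TRUE), collapse = "")
    s <- paste(sample(bases, sample(5:40, 1), TRUE), collapse = "")
    for (mode in c("glocal", "local")) {
      got <- omegascan:::.affine_align_cpp(p, s, 2, -3, 5, 2, mode)$score
      want <- oracle_affine_score(p, s, 2, -3, 5, 2, mode)
      expect_equal(got, want, info = paste(mode, p, s))
    }
  }
})

test_that("alignment columns advance monotonically on both sequences", {
  set.seed(15)
  cds <- random_cds(300)
  frag <- substr(cds, 50, 649)
  # inject noise: substitutions and a deletion
  fb <- strsplit(frag, "")[[1]]
  fb[sample(length(fb), 20)] <- sample(c("A", "C", "G", "T"), 20, TRUE)
  frag <- paste(fb[-c(100, 300)], collapse = "")
  al <- align_affine(frag, cds)
  expect_true(all(diff(al$columns$frag_pos[!is.na(al$columns$frag_pos)]) == 1))
  cp <- al$columns$cds_pos[!is.na(al$columns$cds_pos)]
  expect_true(all(diff(cp) == 1))
})

test_that("repair_frame deletes fragment insertions and nothing else", {
  cds <- "ATGAAACCCGGGTTTTAA"
  # fragment with one extra base after position 8
  frag <- paste0(substr(cds, 1, 9), "T", substr(cds, 10, 18))
  al <- align_affine(frag, cds, match = 2, mismatch = -3, gap_open = 6,
                     gap_extend = 3)
  expect_equal(sum(is.na(al$columns$cds_pos)), 1L)
  rep1 <- repair_frame(al)
  expect_equal(nrow(rep1$columns), nchar(cds))
  expect_false(anyNA(rep1$columns$cds_pos))
  # repaired fragment restores the reading frame
  restored <- paste(rep1$columns$base, collapse = "")
  expect_identical(restored, cds)

  # no insertions: repair is the identity
  al2 <- align_affine(substr(cds, 1, 15), cds)
  expect_identical(repair_frame(al2)$columns, al2$columns)

  # two consecutive extra bases: both removed
  frag3 <- paste0(substr(cds, 1, 9), "TT", substr(cds, 10, 18))
  al3 <- align_affine(frag3, cds, match = 2, mismatch = -3, gap_open = 6,
                      gap_extend = 3)
  rep3 <- repair_frame(al3)
  expect_equal(nrow(rep3$columns), nchar(cds))
  expect_identical(paste(rep3$columns$base, collapse = ""), cds)
})

test_that("consensus follows majority with score- and letter-based tie breaks", {
  cds <- paste(rep("ACGT", 30), collapse = "")
  mkaln <- function(seq, start, score) {
    cols <- data.frame(frag_pos = seq_len(nchar(seq)) - 1L,
                       cds_pos = start + seq_len(nchar(seq)) - 1L,
                       base = strsplit(seq, "")[[1]],
                       stringsAsFactors = FALSE)
    structure(list(fragment_id = "f", gene_id = "g", score = score,
                   columns = cols), class = "coord_alignment")
  }
  # three agreeing fragments
  cs <- build_consensus(list(mkaln("ACGT", 0, 10), mkaln("ACGT", 0, 9),
                             mkaln("ACGT", 0, 8)), nchar(cds))
  expect_identical(cs$seq[1:4], c("A", "C", "G", "T"))
  expect_equal(cs$support[1:4], rep(3L, 4))
  # 2 vs 1 disagreement: majority wins
  cs2 <- build_consensus(list(mkaln("TCGT", 0, 1), mkaln("ACGT", 0, 10),
                              mkaln("TCGT", 0, 2)), nchar(cds))
  expect_identical(cs2$seq[1], "T")
  # 1 vs 1 tie: base of the higher-scoring fragment
  cs3 <- build_consensus(list(mkaln("ACGT", 0, 5), mkaln("TCGT", 0, 7)),
                         nchar(cds))
  expect_identical(cs3$seq[1], "T")
  # uncovered interior positions are '-'
  cs4 <- build_consensus(list(mkaln("ACGT", 0, 5), mkaln("ACGT", 116, 5)),
                         nchar(cds))
  expect_true(all(cs4$seq[5:116] == "-"))
  expect_true(all(cs4$support[5:116] == 0L))
  expect_error(build_consensus(list(), 10), "no alignments")
})

test_that("codon alignment drops stop and deficient columns and enforces min_len", {
  set.seed(16)
  cds <- random_cds(150)  # 453 bp including the stop
  L <- nchar(cds)
  full <- function(seqchars) {
    structure(list(gene_id = "g", species_id = "sp",
                   seq = seqchars, support = rep(1L, L)),
              class = "species_consensus")
  }
  perfect <- strsplit(cds, "")[[1]]
  aln <- build_codon_alignment(list(full(perfect)), cds, min_len = 300)
  # terminal stop removed, everything else kept (150 codons + stop in cds)
  expect_equal(ncol(aln$codon_idx), 150L)
  expect_equal(aln$bp, 450L)
  tab <- omegascan:::codon_tables()
  expect_false(any(tab$codons[aln$codon_idx] %in% tab$stops))

  # a gap anywhere in a codon deletes exactly that codon column
  gapped <- perfect; gapped[10] <- "-"
  aln2 <- build_codon_alignment(list(full(gapped)), cds, min_len = 300)
  expect_equal(ncol(aln2$codon_idx), 149L)
  expect_false(4L %in% aln2$ref_codon_index)

  # internal stop codon in the consensus removes that column too
  stopped <- perfect
  stopped[13:15] <- c("T", "A", "A")
  aln3 <- build_codon_alignment(list(full(stopped)), cds, min_len = 300)
  expect_equal(ncol(aln3$codon_idx), 149L)

  # surviving length below min_len rejects the gene
  sparse <- perfect
  sparse[seq(1, 200, by = 3)] <- "-"
  expect_null(build_codon_alignment(list(full(sparse)), cds,
                                    min_len = 300))
  # 99 complete codons = 297 bp < 300 rejected; >= 300 retained
  mostly <- rep("-", L)
  mostly[1:297] <- perfect[1:297]
  expect_null(build_codon_alignment(list(full(mostly)), cds, min_len = 300))
  mostly[1:300] <- perfect[1:300]
  expect_s3_class(build_codon_alignment(list(full(mostly)), cds,
                                        min_len = 300), "codon_aln")

  # consensus/CDS length mismatch is an internal-consistency error
  expect_error(build_codon_alignment(list(full(perfect[-1])), cds),
               "does not match")
})

test_that("error-free full-coverage fragments reconstruct the evolved CDS", {
  cfg <- sim_config(seed = 22, n_genes = 10, codons_per_gene = 150,
                    fragment_coverage = 6, read_error_sub = 0,
                    read_error_homopolymer_indel = 0)
  ref <- build_reference(cfg)
  tr <- evolve_orthologs(ref, cfg)
  dip <- make_diploid_and_reads(tr, ref, cfg)
  ft <- dip$fragment_truth
  tab <- omegascan:::codon_tables()
  checked <- 0L
  for (g in ref$genes$gene_id) {
    ids <- ft$id[ft$gene_id == g]
    cov <- rep(FALSE, nchar(ref$cds[[g]]))
    for (i in which(ft$gene_id == g))
      cov[(ft$start[i] + 1):(ft$start[i] + ft$len[i])] <- TRUE
    if (!all(cov)) next  # needs full fragment coverage for exactness
    sites <- dip$sites$cds_pos[dip$sites$gene_id == g]
    if (length(sites)) next  # heterozygous genes differ at planted sites
    alns <- lapply(ids, function(id) {
      s <- dip$fragments[[id]]
      if (ft$strand[ft$id == id] == "-") s <- omegascan:::.revcomp(s)
      repair_frame(align_affine(s, ref$cds[[g]], fragment_id = id,
                                gene_id = g))
    })
    cs <- build_consensus(alns, nchar(ref$cds[[g]]), g, "ingroupA")
    aln <- build_codon_alignment(list(cs), ref$cds[[g]], min_len = 300,
                                 ref_name = "ingroupB")
    true_a <- tr$seqs$ingroupA[[g]]
    got <- paste(tab$codons[aln$codon_idx["ingroupA", ]], collapse = "")
    want <- substr(true_a, 1, nchar(true_a) - 3)  # minus terminal stop
    expect_identical(got, want)
    checked <- checked + 1L
  }
  expect_gte(checked, 3L)
})
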