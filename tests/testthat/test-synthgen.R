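# Synthetic study generator: reference annotation, ortholog evolution,
# diploid individual, fragments and reads.

small_plan <- function() {
  data.frame(name = c("1", "2", "3"), length = c(40000L, 40000L, 40000L),
             n_genes = c(4L, 3L, 3L), omega_multiplier = 1,
             het_rate = 0.003, stringsAsFactors = FALSE)
}

test_that("reference bundle honors the plan and its invariants", {
  cfg <- sim_config(seed = 3, chromosome_plan = small_plan(),
                    codons_per_gene = 120)
  ref <- build_reference(cfg)
  expect_equal(nrow(ref$genes), 10L)
  expect_equal(as.vector(table(ref$genes$chrom)[c("1", "2", "3")]),
               c(4L, 3L, 3L))
  for (g in ref$genes$gene_id) {
    cds <- ref$cds[[g]]
    expect_equal(nchar(cds) %% 3, 0)
    expect_identical(substr(cds, 1, 3), "ATG")
    cods <- omegascan:::split_codons(cds)
    st <- omegascan:::is_stop_codon(cods)
    expect_true(st[length(cods)])
    expect_false(any(st[-length(cods)]))
    # cDNA embeds the CDS
    expect_true(grepl(cds, ref$cdna[[g]], fixed = TRUE))
  }
  # same seed twice: byte-identical bundles
  expect_identical(ref, build_reference(cfg))
})

test_that("plans without Z still run, and sizing errors name the chromosome", {
  cfg <- sim_config(seed = 4, chromosome_plan = small_plan())
  expect_false("Z" %in% build_reference(cfg)$chromosomes$name)

  tight <- small_plan()
  tight$length <- c(9000L, 40000L, 40000L)
  cfg2 <- sim_config(seed = 4, chromosome_plan = tight,
                     codons_per_gene = 500)
  expect_error(build_reference(cfg2), "chromosome 1 too short")
})

test_that("config validation rejects absurd settings", {
  expect_error(sim_config(codons_per_gene = 50), ">= 100")
  bad <- small_plan(); bad$het_rate <- 0.5
  expect_error(sim_config(chromosome_plan = bad), "absurd")
  expect_error(sim_config(tree = c(ingroupA = -0.1, ingroupB = 0.1,
                                   outgroup = 0.2)), ">= 0")
})

test_that("ortholog evolution preserves genes, lengths and degenerate limits", {
  cfg <- sim_config(seed = 6, chromosome_plan = small_plan(),
                    codons_per_gene = 120)
  ref <- build_reference(cfg)
  tr <- evolve_orthologs(ref, cfg)
  expect_equal(nrow(tr$genes), cfg$n_genes)
  for (tx in c("ingroupA", "ingroupB", "outgroup"))
    expect_equal(unname(nchar(tr$seqs[[tx]])), unname(nchar(ref$cds)))
  expect_identical(tr, evolve_orthologs(ref, cfg))
  expect_identical(unname(tr$seqs$ingroupB), unname(ref$cds))

  # zero branch lengths: all taxa identical to the reference
  cfg0 <- sim_config(seed = 6, chromosome_plan = small_plan(),
                     codons_per_gene = 120,
                     tree = c(ingroupA = 0, ingroupB = 0, outgroup = 0))
  tr0 <- evolve_orthologs(ref, cfg0)
  for (tx in c("ingroupA", "ingroupB", "outgroup"))
    expect_identical(unname(tr0$seqs[[tx]]), unname(ref$cds))
  expect_true(all(tr0$genes[, grepl("^n_", names(tr0$genes))] == 0))

  # omega 0: no nonsynonymous events on any branch
  cfgw <- sim_config(seed = 8, chromosome_plan = small_plan(),
                     codons_per_gene = 120, omega_mean = 0)
  trw <- evolve_orthologs(ref, cfgw)
  expect_true(all(trw$genes$n_nonsyn_ingroupA == 0L &
                  trw$genes$n_nonsyn_ingroupB == 0L &
                  trw$genes$n_nonsyn_outgroup == 0L))
})

test_that("focal branch multipliers raise the nonsynonymous event count", {
  plan <- small_plan(); plan$n_genes <- c(2L, 0L, 0L)
  cfg <- sim_config(seed = 16, chromosome_plan = plan,
                    codons_per_gene = 400, omega_mean = 0.2,
                    branch_multipliers = c(g0001 = 8))
  ref <- build_reference(cfg)
  tr <- evolve_orthologs(ref, cfg)
  expect_equal(tr$genes$mult_ingroupA, c(8, 1))
})

test_that("diploid truth, fragments and reads behave as configured", {
  cfg <- sim_config(seed = 10, chromosome_plan = small_plan(),
                    codons_per_gene = 400, read_coverage = 20,
                    read_error_sub = 0, read_error_homopolymer_indel = 0)
  ref <- build_reference(cfg)
  tr <- evolve_orthologs(ref, cfg)
  dip <- make_diploid_and_reads(tr, ref, cfg)
  # haplotypes differ exactly at the planted sites, alleles distinct
  expect_true(all(dip$sites$allele1 != dip$sites$allele2))
  for (g in unique(dip$sites$gene_id)) {
    h1 <- strsplit(dip$haplotypes$hap1[[g]], "")[[1]]
    h2 <- strsplit(dip$haplotypes$hap2[[g]], "")[[1]]
    expect_identical(which(h1 != h2) - 1L,
                     dip$sites$cds_pos[dip$sites$gene_id == g])
  }
  # genome positions lie in CDS features of the right chromosome
  expect_true(all(dip$sites$genome_pos >= 0))
  # read count near Poisson expectation for one gene
  L <- nchar(ref$cds[[1]])
  lambda <- cfg$read_coverage * L / cfg$read_mean_len
  n1 <- sum(dip$read_truth$gene_id == ref$genes$gene_id[1])
  expect_lt(abs(n1 - lambda), 3 * sqrt(lambda))
  # error-free reads match their source haplotype exactly
  rt <- dip$read_truth[1, ]
  src <- dip$haplotypes[[rt$hap]][[rt$gene_id]]
  rd <- dip$reads[[rt$id]]
  if (rt$strand == "-") rd <- omegascan:::.revcomp(rd)
  expect_identical(rd, substr(src, rt$start + 1, rt$start + rt$len))

  # het_rate 0: no sites, identical haplotypes
  plan0 <- small_plan(); plan0$het_rate <- 0
  cfg0 <- sim_config(seed = 10, chromosome_plan = plan0,
                     codons_per_gene = 120)
  dip0 <- make_diploid_and_reads(evolve_orthologs(build_reference(cfg0),
                                                  cfg0),
                                 build_reference(cfg0), cfg0)
  expect_equal(nrow(dip0$sites), 0L)
  expect_identical(dip0$haplotypes$hap1, dip0$haplotypes$hap2)
})

test_that("CDS-to-genome maps are consistent with strand and features", {
  cfg <- sim_config(seed = 13, chromosome_plan = small_plan(),
                    codons_per_gene = 150)
  ref <- build_reference(cfg)
  fe <- ref$features
  for (g in ref$genes$gene_id) {
    gm <- omegascan:::cds_genome_positions(ref, g)
    expect_equal(length(gm), nchar(ref$cds[[g]]))
    cdsiv <- fe[fe$gene_id == g & fe$type == "CDS", ]
    inside <- vapply(gm, function(p)
      any(p >= cdsiv$start & p < cdsiv$end), TRUE)
    expect_true(all(inside))
    strand <- ref$genes$strand[ref$genes$gene_id == g]
    expect_true(if (strand == "+") all(diff(gm) > 0) else all(diff(gm) < 0))
  }
})

test_that("synthetic term map covers reference genes", {
  cfg <- sim_config(seed = 2, chromosome_plan = small_plan(),
                    codons_per_gene = 120)
  ref <- build_reference(cfg)
  tm <- synth_term_map(ref, n_terms = 10, seed = 2)
  expect_true(all(tm$gene_id %in% ref$genes$gene_id))
  expect_equal(length(unique(tm$term_id)), 10L)
  expect_identical(tm, synth_term_map(ref, n_terms = 10, seed = 2))
})
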