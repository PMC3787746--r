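# omegascan

Comparative molecular-evolution analysis for de novo avian (songbird)
transcriptomes, built for the common study design in which a newly
sequenced species' brain transcriptome — assembled transcript fragments
and single-individual reads — is analyzed against an annotated relative
(reference) and an outgroup:

* **Ortholog assignment**: k-mer-seeded affine-gap local search of
  fragments against the reference cDNA set, with Karlin–Altschul
  e-values and the classical filters (e ≤ 1e−5, hit ≥ 300 bp, best hit
  per fragment).
* **Codon-aware alignment refinement**: semi-global alignment of each
  fragment to its gene's CDS, deletion of frame-disrupting insertions
  (treated as sequencing errors), per-species majority consensus on the
  CDS grid, stop-codon and gapped/ambiguous-column removal, 300-bp
  minimum alignment length.
* **Rates of protein evolution**: Nei–Gojobori (NG86) counting with
  pathway averaging and Jukes–Cantor correction, and Goldman–Yang (GY94,
  F3x4) maximum-likelihood pairwise ω = dN/dS; three-taxon branch-model
  likelihood-ratio tests (χ², 1 df) with Benjamini–Hochberg / Storey FDR
  control; genome-wide ω by bootstrap concatenation (1000 replicates of
  150 alignments by default).
* **Heterozygous SNP discovery**: reference-free, depth-based calling
  from one diploid individual's reads (length and homopolymer read
  filters, end/indel masking, two alleles at depth ≥ 2, total ≥ 4),
  chromosomal mapping, compartment classification (CDS/UTR/intron/1-kb
  flank/intergenic) and per-chromosome density with its linear size
  scaling.
* **Downstream statistics**: fast-gene lists (ω > 1, ω > 0.8, top
  decile), Fisher/hypergeometric term enrichment, chromosome ANOVA and
  one-tailed contrasts (Z fast, 4A slow), cross-depth ω correlation,
  assembly N50.
* **A synthetic-study generator** that simulates the whole design — a
  reference annotation with chromosomes, gene models and CDS; three
  orthologous sequence sets evolved on a 3-taxon star under GY94;
  a diploid focal individual; error-bearing fragments and 454-style
  reads — with truth tables for every downstream stage, so the entire
  pipeline is testable against known answers.

In the model, ω < 1 indicates purifying selection, ω = 1 neutrality and
ω > 1 positive selection; the GY94 rate from codon *i* to *j* is
π_j·κ^[transition]·ω^[nonsynonymous] for single-nucleotide changes, and
branch lengths count expected substitutions per codon.

## Worked example

Simulate a 40-gene study under the default scenario (per-gene ω drawn
from a gamma law with mean 0.13, κ = 2, ingroup species 0.3
substitutions/codon apart) and estimate rates:

```r
library(omegascan)

cfg   <- sim_config(seed = 1, n_genes = 40, codons_per_gene = 300)
ref   <- build_reference(cfg)
truth <- evolve_orthologs(ref, cfg)

aln <- codon_aln_from_seqs(c(zf = truth$seqs$ingroupB[["g0001"]],
                             wx = truth$seqs$ingroupA[["g0001"]]), "g0001")
ml_pairwise(aln)
#> rate_result 'g0001' (ml): omega=0.09174 dN=0.01983 dS=0.2161 t=0.21
#>   kappa=1.93 lnL=-1446.631
ng86(aln)
#> NG86: S=202.33 N=697.67 Sd=41.50 Nd=13.50 dS=0.2396129 dN=0.01960421
#>   omega=0.08181617

pairs <- lapply(ref$genes$gene_id, function(g)
  codon_aln_from_seqs(c(zf = truth$seqs$ingroupB[[g]],
                        wx = truth$seqs$ingroupA[[g]]), g))
bootstrap_genome_omega(pairs, n_reps = 100, genes_per_rep = 30, seed = 2)
#> bootstrap omega (zf-wx): mean=0.1710 sd=0.0142 [0.1457, 0.1968]
#>   (100 reps x 30 genes)
```

The two estimators agree on the example gene (ML ω = 0.092, NG86
ω = 0.082; this gene's true simulated ω is 0.039, within estimation
noise at 300 codons — across the 40 genes the estimates track truth with
r = 0.95).  The bootstrap mean of 0.171 matches this particular 40-gene
draw, whose true mean ω is 0.161; at the 300-gene scale the estimate
centers on the configured genome-wide mean of 0.13.

The full pipeline — simulation, matching, alignment, rates, branch
tests, SNP calling, enrichment, report — runs from one seeded
configuration and writes deterministic outputs:

```r
res <- run_pipeline(pipeline_config(list(seed = 11,
         simulate = list(n_genes = 30, codons_per_gene = 200),
         rates = list(bootstrap = list(n_reps = 50, genes_per_rep = 10)))),
       out_dir = "run1")
names(res$report)
#> [1] "assembly" "ortholog_assignment" "gene_rates" "branch_tests"
#> [5] "bootstrap" "snp_compartments" "chromosome_density"
#> [9] "chromosome_stats" "enrichment"
```

A thin command-line wrapper with `simulate` and `run-all` subcommands is
installed at `inst/scripts/omegascan-cli.R`.

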