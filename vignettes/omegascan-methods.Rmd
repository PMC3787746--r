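---
title: "omegascan: models and methods"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`omegascan` re-implements, as one tested pipeline, the comparative
molecular-evolution analysis of a de novo songbird brain transcriptome
against an annotated relative and an outgroup: ortholog assignment of
assembled transcript fragments, codon-aware alignment refinement,
counting (NG86) and maximum-likelihood (GY94) estimation of dN/dS,
three-taxon branch-model likelihood-ratio tests, bootstrap-concatenation
estimates of genome-wide omega, reference-free heterozygous SNP discovery
from single-individual reads, and the downstream enrichment and
per-chromosome statistics.  A synthetic-study generator produces complete
inputs with truth tables, so every stage can be validated end to end on
data whose answer is known.

# The codon substitution model

All rate estimation rests on the Goldman–Yang (GY94) codon model over the
61 sense codons.  The instantaneous rate from codon $i$ to $j$ is zero
unless they differ at exactly one position, and otherwise

$$q_{ij} = \pi_j \cdot \kappa^{[\text{transition}]} \cdot
          \omega^{[\text{nonsynonymous}]},$$

with $\pi$ the F3x4 codon frequencies (products of position-specific
nucleotide frequencies, renormalized over sense codons), $\kappa$ the
transition/transversion rate ratio and $\omega = dN/dS$.  Substitutions
into stop codons have rate zero.  The matrix is scaled so that branch
length $t$ counts expected substitutions per codon.  Transition
probabilities come from the symmetric eigendecomposition
$P(t) = \Pi^{-1/2} U e^{\Lambda t} U^\top \Pi^{1/2}$, which is exact for a
reversible matrix and lets one decomposition serve every branch length —
the C++ kernel caches decompositions by $(\kappa, \omega)$ because the
optimizer's finite-difference gradients mostly perturb branch lengths.

**Pairwise estimation** (`ml_pairwise`) maximizes
$\sum_{\text{sites}} \log \pi_{x_1} P_{x_1 x_2}(t)$ over
$(t, \kappa, \omega)$ in log space (L-BFGS-B; bounds $t \in [10^{-6},
50]$, $\kappa \in [0.1, 99]$, $\omega \in [10^{-4}, 99]$), from three
starts (NG86-based, $\omega = 0.1$, $\omega = 1$); ties on likelihood
resolve to the smaller $\omega$, and estimates within $10^{-3}$ of a
bound set a `boundary` flag.  Site patterns are collapsed before
optimization, so concatenated alignments cost no more than single genes.
Model-based $dN$ and $dS$ use site proportions evaluated at $\omega = 1$
(mutational opportunity), which makes $dN/dS$ equal the $\omega$
parameter exactly.

**The NG86 counting estimator** (`ng86`) is the independent cross-check:
synonymous site counts per codon (changes creating a stop count as
nonsynonymous so that $S + N = 3 \times$ codons), pathway averaging over
all minimal substitution orders excluding paths through stops, and the
Jukes–Cantor correction $d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$.
`dS_zero` flags alignments where $\omega$ is undefined.  NG86 is unbiased
for the GY94 process at $\kappa = 1$; at $\kappa = 2$ it carries the
classical transition bias, which the tests acknowledge with a looser
concordance band.

**Branch tests** (`branch_test`) use the unrooted 3-taxon star, the only
identifiable topology for three sequences.  The null model shares one
$\omega$ over the three branches (free $t_1, t_2, t_3, \kappa, \omega$);
the alternative frees the focal branch's $\omega$.  The site likelihood
sums over the internal-node state (one-node pruning).  Branch lengths and
$\kappa$ are re-optimized under both models.  Because the alternative
optimization starts from the null optimum (plus perturbed focal-omega
starts), the nesting inequality $\ell_1 \ge \ell_0$ holds by
construction up to optimizer tolerance.  $2(\ell_1 - \ell_0)$ is
referred to $\chi^2_1$; `adjust_fdr` offers Benjamini–Hochberg and the
Storey variant $\pi_0 = \min(1, \#\{p > 0.5\}/(0.5m))$, $q = \pi_0
\times q_{\text{BH}}$.

**Genome-wide omega** (`bootstrap_genome_omega`) concatenates, per
replicate, a without-replacement sample of `genes_per_rep` pairwise
alignments (defaults 1000 replicates of 150, the study design) and fits a
single GY94 $\omega$ to each concatenation; per-gene pattern counts and
F3x4 sufficient statistics are precomputed once, so a replicate costs one
optimization.

# The synthetic study generator

The generator emulates the study design: an annotated reference species
(zebra-finch-like), a focal ingroup sequenced as error-bearing 454-style
reads and assembled fragments (waxbill-like), and an outgroup
(tit-like).  Defaults, chosen once as the study conditions:

* `tree = c(ingroupA = 0.15, ingroupB = 0.15, outgroup = 0.45)`
  substitutions/codon — the two ingroups symmetric and 0.3 apart, the
  outgroup about three times deeper, matching the recent
  ingroup-divergence / older-outgroup geometry of the study system.
* `omega_mean = 0.13` (the genome-wide purifying regime), gamma shape 2 —
  a right-skewed per-gene distribution whose spread is realistic for
  brain-expressed genes while keeping $\omega > 1$ genes rare.
* `kappa = 2`, avian-like transition bias.
* Chromosome classes: Z carries $\omega \times 1.5$ and heterozygosity
  $\times 0.3$; 4A carries $\omega \times 0.6$ and heterozygosity
  $\times 5$; six autosomes are neutral.  Magnitudes are free parameters
  of the generator chosen to make the qualitative contrasts recoverable
  at desk scale, not published estimates.
* Baseline heterozygosity 0.002/bp.  The study does not report the
  sequenced individual's heterozygosity; this default is synthetic and
  labeled as such.
* Reads: mean 350 bp (sd 60), per-base substitution error 0.001,
  per-homopolymer-run indel error 0.003, coverage 12; fragments: mean
  600 bp (sd 100), coverage 3, error rates halved/quartered
  ("error-light" assemblies).  No base qualities are simulated — the
  caller is depth-based, as the 454-era workflow was.

**Rooting and the reference.**  The reference bundle is the observed tip
of the reference species: the pipeline aligns fragments against the
reference annotation, so the annotation row of every codon alignment must
be that species' own sequence.  The internal-node state is obtained by
evolving the reference tip along its own branch — equivalent in
distribution under the reversible model — after which the other two tips
evolve from the internal node.  The terminal stop codon is held fixed
(the codon process has no stop states).

**Shared mutational clock.**  Every gene's rate matrix is normalized at
the genome-average $\omega$, not its own: synonymous divergence is then
constant across genes while realized total divergence grows with
$\omega$, as in real transcriptomes where genes share divergence time and
mutation rate and selection modulates only the nonsynonymous flux.
Normalizing each gene at its own $\omega$ (the estimator's convention)
would force every gene to the same total divergence and deflate pooled
$\omega$ estimates below the gamma mean by Jensen's inequality — a
generator artifact, not a property of the data being emulated.  The
estimators are unaffected; they always rescale internally.

**What the generator does not emulate:** alternative splicing and
isoform mixtures, paralogy, intergenic transcription, coverage biases of
library normalization, quality-score structure, assembly chimerism, and
base-composition heterogeneity along chromosomes.  Passing tests
therefore demonstrate correctness of the algorithms under the stated
model, not robustness to every artifact of real 454 data.

# Ortholog assignment

Fragments are assigned by a k-mer-seeded (k = 11), affine-gap local
aligner over both strands with blastn-like scores (+1/−2, gap open 5,
extend 2, gap of length $L$ costing $\mathrm{open} + \mathrm{extend}
\times (L-1)$).  Once any subject shares two seed words, single-seed
subjects are not extended (a two-hit heuristic).  Significance follows
Karlin–Altschul: $E = K m n e^{-\lambda S}$ with $m$ the fragment length
and $n$ the total database length.  $\lambda$ is the positive root of
$\sum p_i p_j e^{\lambda s_{ij}} = 1$ at the database composition; $K$
is computed exactly from the score random walk — the stationary rate of
score excursions (power iteration of the reflected Lindley chain,
truncated at height 2000) times the first-passage probability that an
excursion peaks at or above $x$, scaled by $e^{\lambda x}$ and averaged
over one lattice period.  For +1/−2 at uniform composition this yields
$\lambda = 1.333$, $K = 0.621$, the classical ungapped values; gapped
statistics are approximated by the ungapped pair, which suffices because
the e-value's role here is a filter at $10^{-5}$ with orders of magnitude
of separation between true and spurious hits.  Hits shorter than 300 bp
or with $E > 10^{-5}$ are discarded and the best surviving e-value wins
(ties: higher raw score, then lexicographic gene id).

# Alignment refinement

Each assigned fragment is aligned to its gene's CDS semi-globally (whole
fragment, free CDS ends) with affine gaps and a deterministic traceback
that prefers, at equal score, match/mismatch over a gap in the fragment
over a gap in the CDS.  `repair_frame` deletes columns where the
fragment has a base against a CDS gap — extra nucleotides that would
disrupt the annotated reading frame are treated as sequencing errors —
while fragment deletions survive to the codon stage as gaps.
`build_consensus` stacks repaired fragments on the CDS grid: majority
base per position, ties to the highest-scoring fragment then
lexicographic (a deliberate resolution-to-a-base rule: ambiguity codes
would be removed later anyway, and determinism is preferred).
`build_codon_alignment` removes the reference's terminal stop codon,
drops every codon column containing a gap, an ambiguity or a stop in any
row, and rejects genes shorter than 300 bp after filtering.  Conflicting
fragments (possible paralogs or isoforms) are reconciled by majority
rule; this is the package's choice where the original workflow is
unspecified.

# SNP discovery

Reads shorter than 100 bp, or with one nucleotide making up at least 60%
of the read, are filtered.  Surviving reads are assigned to genes by the
same seeded search (minimum hit length 50 bp for reads), oriented, and
aligned to the focal species' consensus.  The caller is depth-based in
the reference-free, single-individual tradition: per consensus position
it counts alleles, ignoring the 5 terminal bases of each read and
positions within 3 of an alignment gap (homopolymer indel shadows), and
calls a heterozygous site where exactly two alleles each have depth ≥ 2
and total depth ≥ 4; positions with three alleles at depth are skipped as
error-rich.  Single-individual discovery sees only heterozygous sites and
is biased toward high-frequency polymorphisms; at default error rates the
two-reads-per-allele rule keeps the false-positive rate per site around
$10^{-4}$.  Calls are lifted to genome coordinates through the gene
model and classified CDS > UTR5/UTR3 > intron > 1-kb flank (strand-aware)
> intergenic.  A telomere compartment is not modeled; such positions
fall into intergenic.  Transcript ends have linearly decaying read depth
(reads fall inside the transcript), so sites within roughly a read length
of a gene end are undercalled — accuracy statements are conditioned on
depth ≥ 8.

# Downstream statistics

Gene lists use $\omega > 1$, $\omega > 0.8$ and the top decile
(90th-percentile threshold, ties included).  Term enrichment tests each
term's 2×2 table with a two-sided Fisher exact test computed by
hypergeometric enumeration (all tables with probability not exceeding the
observed table's, with a $1 + 10^{-7}$ relative guard against ties lost
to floating point) plus a one-sided hypergeometric p in the observed
direction, BH-adjusted across terms; the `expected` column is
$\text{total} \times |\text{list}|/|\text{universe}|$.  Annotation is
flat term membership — no ontology-graph propagation.  Chromosome-level
rate variation uses classical one-way ANOVA, and directional contrasts
(Z faster than autosomes, 4A slower) use one-tailed Welch t-tests —
unequal variances are the norm when chromosome gene counts differ by an
order of magnitude.  Cross-depth comparison is a Pearson correlation of
per-gene $\omega$ between the shallow (ingroup) and deep (outgroup)
tables.  N50 is the length at which the descending cumulative sum first
reaches half the total.

# Pipeline and reproducibility

`run_pipeline` executes simulate → match → align → rates → snps → enrich
→ report from a single configuration in which every named threshold of
the analysis is a key (e-value $10^{-5}$, minimum hit 300 bp, minimum
alignment 300 bp, 1000 × 150 bootstrap, 1-kb flanks, 100-bp/60% read
filters).  All randomness derives from the single top-level seed (the
generator uses seed, seed+1, seed+2, seed+3 for its stages; the two
bootstraps use seed+11 and seed+12), so identical configurations produce
byte-identical outputs — checked by checksum in the tests.  Every stage
reads and writes plain files (FASTA, GFF3, VCF, TSV, YAML, JSON) with
exact round-trips; coordinates are 0-based half-open internally, 1-based
inclusive on disk.

# Validation scale

The shipped checks run at desk scale, chosen to finish in minutes on one
core while leaving clear statistical margins: genome-wide omega recovery
and LRT calibration on 300 genes × 500 codons; bootstrap scaled to 200
replicates × 50 genes (100 × 50 per lineage for the symmetry check);
omega recovery at $\omega \in \{0.05, 0.13, 0.5, 1, 2\}$ with 50 genes
each; chromosome-class patterns over 20 seeds (600 genes × 300 codons for
the rate contrast; 48 genes with coverage-9 reads for SNP density); the
NG86 and Fisher oracles exhaustively on their small domains.  The full
study-scale settings (thousands of genes, 1000 × 150 bootstrap) are the
defaults of the corresponding functions.

# Known limitations

NG86 and GY94 here assume no rate variation among sites and no
branch-site effects (deliberately — the study design stops at branch
models); the aligner's gapped statistics reuse ungapped Karlin–Altschul
parameters; the SNP caller has no genotype likelihoods and cannot see
homozygous differences from the (absent) reference; enrichment treats
terms as flat sets.  The printed e-value constants depend on database
composition, so identical fragments can receive slightly different
e-values against different databases — the filtering decision, not the
absolute value, is the contract.
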