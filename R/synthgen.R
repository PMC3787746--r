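# Synthetic study generator: reference annotation, three evolved ortholog
# sets on a 3-taxon star, a diploid focal individual, transcript fragments
# and error-bearing reads, with truth tables for every downstream stage.
#
# The scenario emulated is a songbird brain-transcriptome study: an
# annotated reference species (zebra-finch-like), a focal ingroup
# (waxbill-like) sequenced as fragments and 454-style reads, and an
# outgroup (tit-like).  Chromosome classes carry the avian contrasts of
# interest: elevated omega and reduced heterozygosity on Z, reduced omega
# and elevated heterozygosity on 4A.

#' Default chromosome plan
#'
#' Distributes `n_genes` over eight chromosomes (six autosomes, Z and 4A)
#' with chromosome-class effects: Z gets a 1.5x omega multiplier and 0.3x
#' heterozygosity, 4A a 0.6x omega multiplier and 5x heterozygosity.
#' The base heterozygosity is `het_rate` per bp.
#'
#' @param n_genes Total gene count to apportion.
#' @param het_rate Baseline heterozygous-site rate per bp (default 0.002).
#' @return data.frame with columns `name`, `length`, `n_genes`,
#'   `omega_multiplier`, `het_rate`.
#' @export
default_chromosome_plan <- function(n_genes, het_rate = 0.002) {
  name <- c("1", "2", "3", "4", "5", "12", "Z", "4A")
  frac <- c(0.20, 0.17, 0.14, 0.13, 0.10, 0.07, 0.12, 0.07)
  cnt <- floor(frac * n_genes)
  cnt <- pmax(cnt, 1L)
  # largest-remainder top-up to hit n_genes exactly
  while (sum(cnt) < n_genes) {
    i <- which.max(frac * n_genes - cnt)
    cnt[i] <- cnt[i] + 1L
  }
  while (sum(cnt) > n_genes) {
    i <- which.max(cnt)
    cnt[i] <- cnt[i] - 1L
  }
  data.frame(name = name, length = cnt * 6000L + 10000L, n_genes = cnt,
             omega_multiplier = c(1, 1, 1, 1, 1, 1, 1.5, 0.6),
             het_rate = het_rate * c(1, 1, 1, 1, 1, 1, 0.3, 5),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic study.  Branch lengths
#' are expected substitutions per codon; the default tree (ingroups 0.15
#' each, outgroup 0.45) puts the two ingroup species 0.3 substitutions per
#' codon apart.  Per-gene omega is drawn from a gamma law with mean
#' `omega_mean` (default 0.13, a genome-wide purifying-selection regime)
#' and shape `omega_shape`.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of genes (ignored if `chromosome_plan` supplied).
#' @param codons_per_gene Codons per CDS excluding the stop codon (>= 100).
#' @param chromosome_plan data.frame as from [default_chromosome_plan()].
#' @param tree Named numeric: branch lengths `ingroupA`, `ingroupB`,
#'   `outgroup`.
#' @param kappa Transition/transversion ratio.
#' @param omega_mean,omega_shape Gamma law for per-gene omega.
#' @param branch_multipliers Optional named numeric (gene id -> multiplier)
#'   applied to omega on the focal (ingroupA) branch.
#' @param fragment_mean_len,fragment_len_sd,fragment_coverage Assembled
#'   transcript fragment ("isotig") length model and coverage.
#' @param read_mean_len,read_len_sd,read_coverage Read length model and
#'   per-gene coverage.
#' @param read_error_sub Per-base substitution error rate of reads.
#' @param read_error_homopolymer_indel Per-homopolymer-run indel error rate
#'   of reads (454-style).
#' @param n_terms Number of annotation terms in the synthetic gene-term map.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 30L, codons_per_gene = 500L,
                       chromosome_plan = NULL,
                       tree = c(ingroupA = 0.15, ingroupB = 0.15,
                                outgroup = 0.45),
                       kappa = 2, omega_mean = 0.13, omega_shape = 2,
                       branch_multipliers = NULL,
                       fragment_mean_len = 600, fragment_len_sd = 100,
                       fragment_coverage = 3,
                       read_mean_len = 350, read_len_sd = 60,
                       read_coverage = 12, read_error_sub = 0.001,
                       read_error_homopolymer_indel = 0.003,
                       n_terms = 40L) {
  if (is.null(chromosome_plan))
    chromosome_plan <- default_chromosome_plan(n_genes)
  else
    n_genes <- sum(chromosome_plan$n_genes)
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              codons_per_gene = as.integer(codons_per_gene),
              chromosome_plan = chromosome_plan,
              tree = tree, kappa = kappa, omega_mean = omega_mean,
              omega_shape = omega_shape,
              branch_multipliers = branch_multipliers,
              fragment_mean_len = fragment_mean_len,
              fragment_len_sd = fragment_len_sd,
              fragment_coverage = fragment_coverage,
              read_mean_len = read_mean_len, read_len_sd = read_len_sd,
              read_coverage = read_coverage,
              read_error_sub = read_error_sub,
              read_error_homopolymer_indel = read_error_homopolymer_indel,
              n_terms = as.integer(n_terms))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config A `sim_config` to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$chromosome_plan
  req <- c("name", "length", "n_genes", "omega_multiplier", "het_rate")
  if (!all(req %in% names(p)))
    stop("chromosome_plan must have columns ", paste(req, collapse = ", "))
  if (anyDuplicated(p$name)) stop("duplicate chromosome names in plan")
  if (config$codons_per_gene < 100L)
    stop("codons_per_gene must be >= 100")
  if (any(config$tree < 0)) stop("branch lengths must be >= 0")
  if (!setequal(names(config$tree), c("ingroupA", "ingroupB", "outgroup")))
    stop("tree must name branches ingroupA, ingroupB, outgroup")
  rates <- c(config$kappa, config$omega_mean, config$omega_shape,
             config$fragment_coverage, config$read_coverage,
             config$read_error_sub, config$read_error_homopolymer_indel,
             p$het_rate, p$omega_multiplier)
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (any(p$het_rate > 0.1))
    stop("het_rate above 0.1 sites/bp is biologically absurd")
  if (any(p$length <= 0) || any(p$n_genes < 0))
    stop("chromosome lengths must be positive and gene counts non-negative")
  invisible(config)
}

# base composition used for reference sequence simulation (TCAG order,
# mildly AT-rich as in avian transcripts)
.REF_BASE_FREQ <- c(T = 0.28, C = 0.22, A = 0.28, G = 0.22)

.rand_bases <- function(n) {
  sample(names(.REF_BASE_FREQ), n, replace = TRUE, prob = .REF_BASE_FREQ)
}

# random sense codons (no stops), ATG start, one sampled stop appended
.rand_cds <- function(n_codons) {
  tab <- codon_tables()
  out <- character(0)
  while (length(out) < n_codons) {
    need <- n_codons - length(out)
    m <- need + ceiling(0.1 * need) + 4L
    cand <- paste0(.rand_bases(m), .rand_bases(m), .rand_bases(m))
    cand <- cand[!(cand %in% tab$stops)]
    out <- c(out, head(cand, need))
  }
  out[1] <- "ATG"
  paste0(paste(out, collapse = ""), sample(tab$stops, 1))
}

#' Build a synthetic reference annotation
#'
#' Places genes on the chromosomes of the plan, each with a 5' UTR, a CDS of
#' `codons_per_gene` codons plus one stop codon (split by 0-3 introns), and
#' a 3' UTR, on a random strand with intergenic spacing.  Coordinates are
#' 0-based half-open internally.
#'
#' @param config A [sim_config()].
#' @return A list of class `reference_bundle`: `chromosomes` (name, length),
#'   `genes` (gene_id, chrom, strand, tx_start, tx_end), `features`
#'   (gene_id, type in CDS/UTR5/UTR3/intron, start, end), `cds` and `cdna`
#'   (named character vectors, transcript orientation).
#' @export
build_reference <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  plan <- config$chromosome_plan
  genes <- list(); feats <- list(); cds <- character(0); cdna <- character(0)
  gid <- 0L
  for (ci in seq_len(nrow(plan))) {
    cursor <- 0L
    for (k in seq_len(plan$n_genes[ci])) {
      gid <- gid + 1L
      gene_id <- sprintf("g%04d", gid)
      utr5 <- sample(50:200, 1)
      utr3 <- sample(150:400, 1)
      cds_len <- config$codons_per_gene * 3L + 3L
      n_intron <- sample(0:3, 1)
      intron_len <- if (n_intron > 0) sample(80:300, n_intron, replace = TRUE)
                    else integer(0)
      tx_len <- utr5 + cds_len + utr3
      span <- tx_len + sum(intron_len)
      gap <- sample(2200:3500, 1)
      tx_start <- cursor + gap
      tx_end <- tx_start + span
      if (tx_end > plan$length[ci])
        stop(sprintf("chromosome %s too short to host its %d genes",
                     plan$name[ci], plan$n_genes[ci]))
      cursor <- tx_end
      strand <- sample(c("+", "-"), 1)

      # intron insertion points in transcript coordinates, strictly inside
      # the CDS and pairwise >= 30 bp apart
      if (n_intron > 0) {
        repeat {
          pts <- sort(sample((utr5 + 10L):(utr5 + cds_len - 10L), n_intron))
          if (n_intron == 1 || min(diff(pts)) >= 30L) break
        }
      } else pts <- integer(0)

      # walk the transcript, inserting introns, to get genomic features in
      # transcript-forward layout (0-based offsets within the gene span)
      segs <- data.frame(type = character(0), t0 = integer(0), t1 = integer(0))
      bounds <- c(0L, utr5, utr5 + cds_len, tx_len)
      types <- c("UTR5", "CDS", "UTR3")
      cuts <- sort(unique(c(bounds, pts)))
      piece_type <- function(a) types[findInterval(a, bounds[-4],
                                                   rightmost.closed = FALSE)]
      off <- 0L
      for (s in seq_len(length(cuts) - 1L)) {
        a <- cuts[s]; b <- cuts[s + 1L]
        if (a %in% pts) {  # intron before this piece
          il <- intron_len[match(a, pts)]
          segs <- rbind(segs, data.frame(type = "intron", t0 = off,
                                         t1 = off + il))
          off <- off + il
        }
        segs <- rbind(segs, data.frame(type = piece_type(a), t0 = off,
                                       t1 = off + (b - a)))
        off <- off + (b - a)
      }
      stopifnot(off == span)
      if (strand == "-") {  # mirror within the span
        tmp <- segs
        segs$t0 <- span - tmp$t1
        segs$t1 <- span - tmp$t0
      }
      segs$start <- tx_start + segs$t0
      segs$end <- tx_start + segs$t1
      segs <- segs[order(segs$start), c("type", "start", "end")]
      segs$gene_id <- gene_id

      cds_seq <- .rand_cds(config$codons_per_gene)
      cdna_seq <- paste0(paste(.rand_bases(utr5), collapse = ""), cds_seq,
                         paste(.rand_bases(utr3), collapse = ""))
      cds[gene_id] <- cds_seq
      cdna[gene_id] <- cdna_seq
      genes[[gene_id]] <- data.frame(gene_id = gene_id, chrom = plan$name[ci],
                                     strand = strand, tx_start = tx_start,
                                     tx_end = tx_end,
                                     stringsAsFactors = FALSE)
      feats[[gene_id]] <- segs
    }
  }
  out <- list(chromosomes = data.frame(name = plan$name,
                                       length = plan$length,
                                       stringsAsFactors = FALSE),
              genes = do.call(rbind, c(genes, list(make.row.names = FALSE))),
              features = do.call(rbind, c(feats, list(make.row.names = FALSE))),
              cds = cds, cdna = cdna)
  class(out) <- "reference_bundle"
  validate_reference_bundle(out)
  out
}

#' @rdname build_reference
#' @param bundle A `reference_bundle` to validate against its invariants
#'   (CDS length multiple of 3, ATG start, single terminal stop, no internal
#'   stops, features within gene intervals).
#' @export
validate_reference_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "reference_bundle"))
  for (g in names(bundle$cds)) {
    s <- bundle$cds[[g]]
    stopifnot(nchar(s) %% 3 == 0)
    cods <- split_codons(s)
    if (substr(s, 1, 3) != "ATG") stop("CDS of ", g, " does not begin ATG")
    st <- is_stop_codon(cods)
    if (!st[length(cods)] || any(st[-length(cods)]))
      stop("CDS of ", g, " must end with its only stop codon")
  }
  fe <- merge(bundle$features, bundle$genes, by = "gene_id")
  if (any(fe$start < fe$tx_start | fe$end > fe$tx_end))
    stop("feature outside its transcript interval")
  ge <- merge(bundle$genes,
              setNames(bundle$chromosomes, c("chrom", "chrom_len")),
              by = "chrom")
  if (any(ge$tx_start < 0 | ge$tx_end > ge$chrom_len))
    stop("gene outside its chromosome")
  invisible(bundle)
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat(sprintf("reference_bundle: %d chromosomes, %d genes\n",
              nrow(x$chromosomes), nrow(x$genes)))
  invisible(x)
}

# genomic position (0-based) of every CDS base of a gene, in CDS order
cds_genome_positions <- function(bundle, gene_id) {
  fe <- bundle$features
  cdsiv <- fe[fe$gene_id == gene_id & fe$type == "CDS", , drop = FALSE]
  strand <- bundle$genes$strand[bundle$genes$gene_id == gene_id]
  if (strand == "+") {
    cdsiv <- cdsiv[order(cdsiv$start), ]
    unlist(Map(function(a, b) seq.int(a, b - 1L), cdsiv$start, cdsiv$end),
           use.names = FALSE)
  } else {
    cdsiv <- cdsiv[order(-cdsiv$start), ]
    unlist(Map(function(a, b) seq.int(b - 1L, a), cdsiv$start, cdsiv$end),
           use.names = FALSE)
  }
}

#' Evolve orthologs on the 3-taxon star
#'
#' Draws a per-gene omega from the gamma law (times the chromosome-class
#' multiplier), then evolves each gene on the unrooted 3-taxon star under
#' the GY94 process (F3x4 frequencies from the reference CDS set).  The
#' reference bundle is the observed tip of the reference species
#' (ingroupB); the internal-node state is obtained by evolving the
#' reference along its own branch (equivalent in distribution under the
#' reversible model), after which ingroupA and the outgroup are evolved
#' from the internal node along their branches.  The terminal stop codon is
#' held fixed.  Records synonymous and nonsynonymous substitution events
#' per branch.
#'
#' @param reference A [build_reference()] bundle.
#' @param config The matching [sim_config()].
#' @return A list of class `ortholog_truth`: `genes` (per-gene truth table:
#'   omega_true, focal multiplier, chromosome, event counts per branch),
#'   `seqs` (list of named character vectors `ingroupA`, `ingroupB`,
#'   `outgroup`), `pi` (simulation codon frequencies).
#' @export
evolve_orthologs <- function(reference, config) {
  validate_sim_config(config)
  stopifnot(inherits(reference, "reference_bundle"))
  set.seed(config$seed + 1L)
  pi <- f3x4_frequencies(unname(reference$cds))
  plan <- config$chromosome_plan
  bm <- config$branch_multipliers
  gene_ids <- reference$genes$gene_id
  seqs <- list(ingroupA = character(0), ingroupB = character(0),
               outgroup = character(0))
  rows <- vector("list", length(gene_ids))
  for (k in seq_along(gene_ids)) {
    g <- gene_ids[k]
    chrom <- reference$genes$chrom[k]
    cmult <- plan$omega_multiplier[match(chrom, plan$name)]
    w <- if (config$omega_mean > 0)
      rgamma(1, shape = config$omega_shape,
             rate = config$omega_shape / config$omega_mean) * cmult
    else 0
    multA <- if (!is.null(bm) && g %in% names(bm)) unname(bm[g]) else 1
    cods <- split_codons(reference$cds[[g]])
    ncod <- length(cods) - 1L
    refstate <- codon_index(cods[seq_len(ncod)])
    stop_cod <- cods[ncod + 1L]
    # Genes share a mutational clock: every gene's process is normalized
    # at the genome-average omega, so synonymous divergence is constant
    # across genes and realized total divergence grows with omega.
    s_w <- config$omega_mean
    # internal node by evolving the reference tip backwards along its branch
    evB <- simulate_gy94_branch(refstate, config$tree[["ingroupB"]],
                                config$kappa, w, pi, scale_omega = s_w)
    anc <- evB$states
    ev <- list(
      ingroupA = simulate_gy94_branch(anc, config$tree[["ingroupA"]],
                                      config$kappa, w * multA, pi,
                                      scale_omega = s_w),
      ingroupB = evB,
      outgroup = simulate_gy94_branch(anc, config$tree[["outgroup"]],
                                      config$kappa, w, pi,
                                      scale_omega = s_w))
    tabc <- codon_tables()$codons
    seqs$ingroupA[g] <- paste0(paste(tabc[ev$ingroupA$states],
                                     collapse = ""), stop_cod)
    seqs$ingroupB[g] <- reference$cds[[g]]
    seqs$outgroup[g] <- paste0(paste(tabc[ev$outgroup$states],
                                     collapse = ""), stop_cod)
    rows[[k]] <- data.frame(
      gene_id = g, chrom = chrom, omega_true = w, mult_ingroupA = multA,
      n_syn_ingroupA = ev$ingroupA$n_syn,
      n_nonsyn_ingroupA = ev$ingroupA$n_nonsyn,
      n_syn_ingroupB = ev$ingroupB$n_syn,
      n_nonsyn_ingroupB = ev$ingroupB$n_nonsyn,
      n_syn_outgroup = ev$outgroup$n_syn,
      n_nonsyn_outgroup = ev$outgroup$n_nonsyn,
      stringsAsFactors = FALSE)
  }
  out <- list(genes = do.call(rbind, c(rows, list(make.row.names = FALSE))),
              seqs = seqs, pi = pi)
  class(out) <- "ortholog_truth"
  out
}

#' @export
print.ortholog_truth <- function(x, ...) {
  cat(sprintf("ortholog_truth: %d genes, 3 taxa; mean true omega %.3f\n",
              nrow(x$genes), mean(x$genes$omega_true)))
  invisible(x)
}

# apply substitution errors and 454-style homopolymer indels to a sequence
.sequencing_errors <- function(seq, sub_rate, hp_indel_rate) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  if (sub_rate > 0) {
    hit <- which(runif(n) < sub_rate)
    for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  }
  if (hp_indel_rate > 0 && n > 1) {
    r <- rle(b)
    runs <- which(r$lengths >= 2)
    if (length(runs)) {
      hit <- runs[runif(length(runs)) < hp_indel_rate]
      if (length(hit)) {
        ends <- cumsum(r$lengths)
        out <- character(0)
        prev <- 0L
        for (k in seq_along(r$lengths)) {
          seg <- b[(prev + 1L):ends[k]]
          if (k %in% hit) {
            if (runif(1) < 0.5) seg <- seg[-1] else seg <- c(seg, seg[1])
          }
          out <- c(out, seg)
          prev <- ends[k]
        }
        b <- out
      }
    }
  }
  paste(b, collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate the diploid focal individual, fragments and reads
#'
#' Plants heterozygous sites on the focal (ingroupA) CDS at the
#' chromosome-class rate, forms the two haplotypes, and draws (i) error-light
#' assembled transcript fragments from single haplotypes and (ii) 454-style
#' reads evenly from both haplotypes with substitution and
#' homopolymer-indel errors.  Fragment and read strands are randomized.
#'
#' @param truth An [evolve_orthologs()] result.
#' @param reference The matching [build_reference()] bundle.
#' @param config The matching [sim_config()].
#' @return A list of class `diploid_truth`: `sites` (gene_id, chrom,
#'   cds_pos, genome_pos, allele1, allele2), `haplotypes` (list of two named
#'   character vectors), `fragments`, `reads` (named character vectors),
#'   `fragment_truth`, `read_truth` (source tables).
#' @export
make_diploid_and_reads <- function(truth, reference, config) {
  validate_sim_config(config)
  stopifnot(inherits(truth, "ortholog_truth"),
            inherits(reference, "reference_bundle"))
  set.seed(config$seed + 2L)
  plan <- config$chromosome_plan
  h1 <- truth$seqs$ingroupA
  h2 <- h1
  sites <- list()
  for (g in names(h1)) {
    chrom <- reference$genes$chrom[reference$genes$gene_id == g]
    hr <- plan$het_rate[match(chrom, plan$name)]
    L <- nchar(h1[[g]])
    nsite <- rbinom(1, L, hr)
    if (nsite == 0) next
    pos <- sort(sample.int(L, nsite))
    gmap <- cds_genome_positions(reference, g)
    a1 <- substring(h1[[g]], pos, pos)
    a2 <- vapply(a1, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    s2 <- strsplit(h2[[g]], "")[[1]]
    s2[pos] <- a2
    h2[g] <- paste(s2, collapse = "")
    sites[[g]] <- data.frame(gene_id = g, chrom = chrom, cds_pos = pos - 1L,
                             genome_pos = gmap[pos], allele1 = unname(a1),
                             allele2 = unname(a2), stringsAsFactors = FALSE)
  }
  sites <- if (length(sites))
    do.call(rbind, c(sites, list(make.row.names = FALSE)))
  else data.frame(gene_id = character(0), chrom = character(0),
                  cds_pos = integer(0), genome_pos = integer(0),
                  allele1 = character(0), allele2 = character(0))

  draw_pieces <- function(prefix, mean_len, sd_len, coverage, sub_rate,
                          hp_rate, even_haplotypes) {
    seqs <- character(0)
    rows <- list()
    counter <- 0L
    for (g in names(h1)) {
      L <- nchar(h1[[g]])
      n <- rpois(1, coverage * L / mean_len)
      if (prefix == "frag") n <- max(n, 1L)  # every gene gets some assembly
      if (n == 0) next
      hap <- if (even_haplotypes) sample(rep(1:2, length.out = n))
             else sample(1:2, n, replace = TRUE)
      for (i in seq_len(n)) {
        counter <- counter + 1L
        len <- min(L, max(60L, round(rnorm(1, mean_len, sd_len))))
        start <- sample.int(L - len + 1L, 1) - 1L
        src <- if (hap[i] == 1) h1[[g]] else h2[[g]]
        s <- substr(src, start + 1L, start + len)
        s <- .sequencing_errors(s, sub_rate, hp_rate)
        strand <- sample(c("+", "-"), 1)
        if (strand == "-") s <- .revcomp(s)
        id <- sprintf("%s%06d", prefix, counter)
        seqs[id] <- s
        rows[[counter]] <- data.frame(id = id, gene_id = g, hap = hap[i],
                                      start = start, len = len,
                                      strand = strand,
                                      stringsAsFactors = FALSE)
      }
    }
    list(seqs = seqs,
         truth = if (length(rows))
           do.call(rbind, c(rows, list(make.row.names = FALSE)))
         else data.frame(id = character(0), gene_id = character(0),
                         hap = integer(0), start = integer(0),
                         len = integer(0), strand = character(0)))
  }

  frags <- draw_pieces("frag", config$fragment_mean_len,
                       config$fragment_len_sd, config$fragment_coverage,
                       config$read_error_sub / 2,
                       config$read_error_homopolymer_indel / 4,
                       even_haplotypes = FALSE)
  reads <- draw_pieces("read", config$read_mean_len, config$read_len_sd,
                       config$read_coverage, config$read_error_sub,
                       config$read_error_homopolymer_indel,
                       even_haplotypes = TRUE)

  out <- list(sites = sites, haplotypes = list(hap1 = h1, hap2 = h2),
              fragments = frags$seqs, reads = reads$seqs,
              fragment_truth = frags$truth, read_truth = reads$truth)
  class(out) <- "diploid_truth"
  out
}

#' @export
print.diploid_truth <- function(x, ...) {
  cat(sprintf("diploid_truth: %d planted sites, %d fragments, %d reads\n",
              nrow(x$sites), length(x$fragments), length(x$reads)))
  invisible(x)
}

#' Synthetic gene-to-term annotation map
#'
#' Random flat term membership over the reference genes, with log-uniform
#' term sizes, standing in for a GO-style annotation table.
#'
#' @param reference A [build_reference()] bundle.
#' @param n_terms Number of terms.
#' @param seed RNG seed.
#' @return data.frame with columns `gene_id`, `term_id`, `term_desc`.
#' @export
synth_term_map <- function(reference, n_terms = 40L, seed = 1L) {
  set.seed(seed + 3L)
  genes <- reference$genes$gene_id
  rows <- list()
  for (k in seq_len(n_terms)) {
    sz <- max(2L, round(exp(runif(1, log(2), log(max(3, length(genes) / 3))))))
    sz <- min(sz, length(genes))
    rows[[k]] <- data.frame(gene_id = sort(sample(genes, sz)),
                            term_id = sprintf("T%04d", k),
                            term_desc = sprintf("synthetic term %d", k),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
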