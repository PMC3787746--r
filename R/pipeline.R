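# Pipeline orchestration: simulate -> match -> align -> rates -> snps ->
# enrich -> report, driven by a single (YAML-serializable) configuration
# with every threshold of the analysis exposed as a config key.

.modify_defaults <- function(defaults, override) {
  if (is.null(override)) return(defaults)
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && is.list(override[[nm]]))
      defaults[[nm]] <- .modify_defaults(defaults[[nm]], override[[nm]])
    else defaults[[nm]] <- override[[nm]]
  }
  defaults
}

#' Pipeline configuration
#'
#' Builds the full pipeline configuration with the analysis defaults
#' (e-value 1e-5, minimum hit 300 bp, minimum alignment 300 bp, 1000
#' bootstrap replicates of 150 alignments, 1 kb flanks, read filters
#' 100 bp / 60% homopolymer), overridden by the entries of `override`
#' (a nested list or a YAML file path).
#'
#' @param override Nested list or YAML file path with overrides.
#' @param seed Top-level seed (used when `override` carries none).
#' @return Nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(override = NULL, seed = 1L) {
  if (is.character(override)) override <- yaml::read_yaml(override)
  defaults <- list(
    seed = as.integer(seed),
    simulate = list(n_genes = 30L, codons_per_gene = 200L),
    match = list(k = 11L, max_evalue = 1e-5, min_hit_len = 300L),
    read_match = list(min_hit_len = 50L),
    align = list(min_len = 300L),
    rates = list(focal = "ingroupA", fdr_method = "storey",
                 run_branch_tests = TRUE,
                 bootstrap = list(n_reps = 1000L, genes_per_rep = 150L)),
    snps = list(min_read_len = 100L, homopolymer_frac = 0.60,
                min_allele_depth = 2L, min_total_depth = 4L,
                end_mask = 5L, indel_mask = 3L, flank_bp = 1000L),
    enrich = list(n_terms = 40L, q_cut = 0.05))
  cfg <- .modify_defaults(defaults, override)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
}

.log_stage <- function(name, fmt, ...) {
  message(sprintf("[%s] %s", name, sprintf(fmt, ...)))
}

# orient a sequence to the reference strand given the assignment strand
.orient <- function(seq, strand) if (strand == "-") .revcomp(seq) else seq

# consensus sequences for one species: named list of species_consensus per
# gene, from assigned pieces
.consensus_by_gene <- function(pieces, assign, reference, species_id) {
  out <- list()
  assigned <- assign[!is.na(assign$gene_id), , drop = FALSE]
  for (g in unique(assigned$gene_id)) {
    rows <- assigned[assigned$gene_id == g, , drop = FALSE]
    alns <- lapply(seq_len(nrow(rows)), function(i) {
      s <- .orient(pieces[[rows$fragment_id[i]]], rows$strand[i])
      repair_frame(align_affine(s, reference$cds[[g]],
                                fragment_id = rows$fragment_id[i],
                                gene_id = g))
    })
    out[[g]] <- build_consensus(alns, nchar(reference$cds[[g]]),
                                gene_id = g, species_id = species_id)
  }
  out
}

#' Run the full analysis pipeline on a simulated study
#'
#' Executes simulate -> assembly stats -> ortholog match -> codon-aware
#' alignment -> rate estimation (pairwise ML, branch LRTs with FDR,
#' bootstrap genome-wide omega) -> SNP discovery (filter, call, classify,
#' density) -> enrichment and chromosome statistics, writing every
#' intermediate artifact and a report to `out_dir`.  Identical
#' configuration and seed produce byte-identical outputs.
#'
#' @param config A [pipeline_config()], nested list, or YAML file path.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `report` (the 9-section result list) and
#'   `manifest` (paths, seeds, per-stage record counts).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, ...)
  manifest <- list(seed = config$seed, counts = list(), files = list())

  ## simulate ---------------------------------------------------------------
  sim <- .stage("simulate", {
    cfg_sim <- do.call(sim_config, c(list(seed = config$seed),
                                     config$simulate))
    ref <- build_reference(cfg_sim)
    truth <- evolve_orthologs(ref, cfg_sim)
    dip <- make_diploid_and_reads(truth, ref, cfg_sim)
    term_map <- synth_term_map(ref, config$enrich$n_terms, cfg_sim$seed)
    write_fasta(ref$cds, pth("reference_cds.fasta"))
    write_fasta(ref$cdna, pth("reference_cdna.fasta"))
    write_gff3(ref, pth("reference.gff3"))
    write_fasta(dip$fragments, pth("fragments.fasta"))
    write_fasta(dip$reads, pth("reads.fasta"))
    write_fasta(truth$seqs$outgroup, pth("outgroup_transcripts.fasta"))
    write_tsv(truth$genes, pth("truth_genes.tsv"))
    write_tsv(dip$sites, pth("truth_snps.tsv"))
    write_tsv(term_map, pth("term_map.tsv"))
    cfg_echo <- config
    class(cfg_echo) <- NULL
    yaml::write_yaml(cfg_echo, pth("config.yaml"))
    list(cfg = cfg_sim, ref = ref, truth = truth, dip = dip,
         term_map = term_map)
  })
  manifest$config_hash <- unname(tools::md5sum(pth("config.yaml")))
  .log_stage("simulate", "%d genes, %d fragments, %d reads",
             nrow(sim$ref$genes), length(sim$dip$fragments),
             length(sim$dip$reads))

  ## assembly stats ---------------------------------------------------------
  asm <- .stage("assembly", assembly_stats(nchar(sim$dip$fragments)))

  ## ortholog match ---------------------------------------------------------
  mt <- .stage("match", {
    params <- do.call(match_params, config$match)
    idx <- index_reference(sim$ref$cdna, params)
    hits <- search_fragments(sim$dip$fragments, idx, params)
    write_hits_tsv(hits, pth("fragment_hits.tsv"))
    assign <- assign_orthologs(hits, params, names(sim$dip$fragments))
    og_hits <- search_fragments(sim$truth$seqs$outgroup, idx, params)
    og_assign <- assign_orthologs(og_hits, params,
                                  names(sim$truth$seqs$outgroup))
    write_tsv(assign, pth("fragment_assignment.tsv"))
    list(params = params, idx = idx, assign = assign,
         og_assign = og_assign)
  })
  n_assigned <- sum(!is.na(mt$assign$gene_id))
  manifest$counts$fragments_assigned <- n_assigned
  .log_stage("match", "%d/%d fragments assigned", n_assigned,
             nrow(mt$assign))

  ## codon-aware alignment --------------------------------------------------
  al <- .stage("align", {
    consA <- .consensus_by_gene(sim$dip$fragments, mt$assign, sim$ref,
                                "ingroupA")
    consO <- .consensus_by_gene(sim$truth$seqs$outgroup, mt$og_assign,
                                sim$ref, "outgroup")
    min_len <- config$align$min_len
    pair <- list(); trio <- list()
    for (g in names(consA)) {
      p <- build_codon_alignment(list(consA[[g]]), sim$ref$cds[[g]],
                                 min_len = min_len, ref_name = "ingroupB")
      if (!is.null(p)) pair[[g]] <- p
      if (!is.null(consO[[g]])) {
        t3 <- build_codon_alignment(list(consA[[g]], consO[[g]]),
                                    sim$ref$cds[[g]], min_len = min_len,
                                    ref_name = "ingroupB")
        if (!is.null(t3)) trio[[g]] <- t3
      }
    }
    manifest_aln <- data.frame(
      gene_id = names(pair),
      bp = vapply(pair, `[[`, 0L, "bp"),
      in_trio = names(pair) %in% names(trio), stringsAsFactors = FALSE)
    write_tsv(manifest_aln, pth("alignment_manifest.tsv"))
    list(consA = consA, pair = pair, trio = trio)
  })
  manifest$counts$genes_aligned <- length(al$pair)
  manifest$counts$genes_rejected_minlen <-
    length(al$consA) - length(al$pair)
  .log_stage("align", "%d pairwise, %d trio alignments (%d genes rejected)",
             length(al$pair), length(al$trio),
             manifest$counts$genes_rejected_minlen)

  ## rates ------------------------------------------------------------------
  rt <- .stage("rates", {
    chrom_of <- setNames(sim$ref$genes$chrom, sim$ref$genes$gene_id)
    rows <- lapply(al$pair, function(a) {
      r <- ml_pairwise(a)
      c <- counting_pairwise(a)
      data.frame(gene_id = a$gene_id, chrom = chrom_of[[a$gene_id]],
                 omega = r$omega, dN = r$dN, dS = r$dS, t = r$t,
                 kappa = r$kappa, lnL = r$lnL, boundary = r$boundary,
                 omega_ng = c$omega, stringsAsFactors = FALSE)
    })
    rates_tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    write_tsv(rates_tab, pth("gene_rates.tsv"))

    branch_tab <- NULL
    if (isTRUE(config$rates$run_branch_tests) && length(al$trio)) {
      brows <- lapply(al$trio, function(a) {
        b <- branch_test(a, config$rates$focal)
        data.frame(gene_id = b$gene_id, focal = b$focal,
                   lnL0 = b$lnL_null, lnL1 = b$lnL_alt, lrt = b$lrt,
                   p = b$p, direction = b$direction,
                   stringsAsFactors = FALSE)
      })
      branch_tab <- do.call(rbind, c(brows, list(make.row.names = FALSE)))
      branch_tab$q <- adjust_fdr(branch_tab$p, config$rates$fdr_method)
      write_tsv(branch_tab, pth("branch_tests.tsv"))
    }

    # bootstrap genome-wide omega for each ingroup against the outgroup
    bs <- list()
    if (length(al$trio)) {
      pools <- list(
        `ingroupB-outgroup` = lapply(al$trio, codon_aln_pair,
                                     sp1 = "ingroupB", sp2 = "outgroup"),
        `ingroupA-outgroup` = lapply(al$trio, codon_aln_pair,
                                     sp1 = "ingroupA", sp2 = "outgroup"))
      for (k in seq_along(pools)) {
        bs[[names(pools)[k]]] <- bootstrap_genome_omega(
          unname(pools[[k]]), n_reps = config$rates$bootstrap$n_reps,
          genes_per_rep = config$rates$bootstrap$genes_per_rep,
          seed = config$seed + 10L + k)
      }
      bs_tab <- do.call(rbind, lapply(names(bs), function(nm)
        data.frame(pair = nm, rep = seq_along(bs[[nm]]$omega),
                   omega = bs[[nm]]$omega, stringsAsFactors = FALSE)))
      write_tsv(bs_tab, pth("bootstrap_omega.tsv"))
    }

    # deep-divergence per-gene omega (reference vs outgroup, counting)
    deep <- NULL
    if (length(al$trio)) {
      drows <- lapply(al$trio, function(a) {
        cg <- counting_pairwise(codon_aln_pair(a, "ingroupB", "outgroup"))
        data.frame(gene_id = a$gene_id, omega = cg$omega,
                   stringsAsFactors = FALSE)
      })
      deep <- do.call(rbind, c(drows, list(make.row.names = FALSE)))
    }
    list(rates = rates_tab, branch = branch_tab, bootstrap = bs,
         deep = deep)
  })
  manifest$counts$genes_tested <-
    if (is.null(rt$branch)) 0L else nrow(rt$branch)
  .log_stage("rates", "%d pairwise omega, %d branch tests",
             nrow(rt$rates), manifest$counts$genes_tested)

  ## snps -------------------------------------------------------------------
  sn <- .stage("snps", {
    sp <- do.call(snp_params, config$snps)
    filt <- filter_reads(sim$dip$reads, sp)
    rparams <- do.call(match_params,
                       .modify_defaults(config$match, config$read_match))
    rhits <- search_fragments(filt$reads, mt$idx, rparams)
    rassign <- assign_orthologs(rhits, rparams, names(filt$reads))
    rassign <- rassign[!is.na(rassign$gene_id), , drop = FALSE]
    # align reads to the focal-species consensus of their gene
    cons_seq <- vapply(al$consA, function(cs)
      paste(gsub("-", "N", cs$seq, fixed = TRUE), collapse = ""), "")
    read_alns <- list()
    for (i in seq_len(nrow(rassign))) {
      g <- rassign$gene_id[i]
      if (!g %in% names(cons_seq)) next
      s <- .orient(filt$reads[[rassign$fragment_id[i]]], rassign$strand[i])
      read_alns[[g]] <- c(read_alns[[g]], list(
        align_affine(s, cons_seq[[g]],
                     fragment_id = rassign$fragment_id[i], gene_id = g)))
    }
    cons_len <- vapply(al$consA, function(cs) length(cs$seq), 0L)
    calls <- call_het_snps(read_alns, cons_len, sp)
    # lift consensus (CDS) coordinates to the genome
    if (nrow(calls)) {
      calls$chrom <- sim$ref$genes$chrom[match(calls$gene_id,
                                               sim$ref$genes$gene_id)]
      calls$genome_pos <- NA_integer_
      for (g in unique(calls$gene_id)) {
        gmap <- cds_genome_positions(sim$ref, g)
        gi <- calls$gene_id == g
        calls$genome_pos[gi] <- gmap[calls$pos[gi] + 1L]
      }
      calls <- classify_snp(calls, sim$ref, sp)
    } else {
      calls$chrom <- character(0); calls$genome_pos <- integer(0)
      calls$compartment <- character(0)
      calls$compartment_gene <- character(0)
    }
    write_vcf(calls, sim$ref$chromosomes, pth("het_snps.vcf"))
    dens <- chromosome_density(calls, sim$ref$chromosomes)
    write_tsv(dens$table, pth("snp_density.tsv"))
    comp <- table(factor(calls$compartment,
                         levels = c("CDS", "UTR5", "UTR3", "intron",
                                    "flank5", "flank3", "intergenic")))
    list(params = sp, filt = filt, calls = calls, density = dens,
         compartment_pct = 100 * as.numeric(comp) / max(1, nrow(calls)),
         compartment_names = names(comp))
  })
  manifest$counts$reads_filtered <- sn$filt$n_short + sn$filt$n_homopolymer
  manifest$counts$snps_called <- nrow(sn$calls)
  .log_stage("snps", "%d heterozygous SNPs called", nrow(sn$calls))

  ## enrichment and chromosome statistics -----------------------------------
  en <- .stage("enrich", {
    classes <- select_rate_classes(rt$rates)
    uni <- classes$universe
    enr <- lapply(classes$lists, function(gl)
      term_enrichment(gl, uni, sim$term_map))
    if (!is.null(rt$branch)) {
      sig <- rt$branch[rt$branch$q < config$enrich$q_cut, , drop = FALSE]
      acc <- sig$gene_id[sig$direction == "accelerated"]
      dec <- sig$gene_id[sig$direction == "decelerated"]
      enr$accelerated_focal <- term_enrichment(intersect(acc, uni), uni,
                                               sim$term_map)
      enr$decelerated_focal <- term_enrichment(intersect(dec, uni), uni,
                                               sim$term_map)
    }
    for (nm in names(enr))
      write_tsv(enr[[nm]], pth(sprintf("enrichment_%s.tsv", nm)))
    cnt <- table(rt$rates$chrom[!is.na(rt$rates$omega)])
    n_of <- function(grp) {
      if (grp == "autosomes")
        sum(cnt[setdiff(names(cnt), c("Z", "4A"))])
      else if (grp %in% names(cnt)) cnt[[grp]] else 0L
    }
    want <- list(c("Z", ">", "autosomes"), c("4A", "<", "autosomes"),
                 c("Z", ">", "4"), c("4A", "<", "4"), c("4A", "<", "12"))
    want <- Filter(function(ct) n_of(ct[1]) >= 2L && n_of(ct[3]) >= 2L,
                   want)
    cstats <- omega_chromosome_stats(rt$rates, want)
    corr <- if (!is.null(rt$deep))
      tryCatch(depth_correlation(rt$rates, rt$deep), error = function(e)
        list(r = NA_real_, p = NA_real_, n_genes = 0L, n_dropped = 0L))
    else NULL
    list(classes = classes, enrichment = enr, chrom_stats = cstats,
         depth_corr = corr)
  })

  ## report -----------------------------------------------------------------
  report <- list(
    assembly = list(n_sequences = asm$n_sequences, total_bp = asm$total_bp,
                    mean_length = asm$mean_length, n50 = asm$n50),
    ortholog_assignment = list(
      n_fragments = nrow(mt$assign), n_assigned = n_assigned,
      rate = n_assigned / max(1, nrow(mt$assign))),
    gene_rates = rt$rates,
    branch_tests = rt$branch,
    bootstrap = lapply(rt$bootstrap, function(b)
      list(pair = b$species_pair, mean = b$mean, sd = b$sd,
           ci = b$ci, n_reps = b$n_reps,
           genes_per_rep = b$genes_per_rep)),
    snp_compartments = setNames(as.list(sn$compartment_pct),
                                sn$compartment_names),
    chromosome_density = list(table = sn$density$table,
                              slope = sn$density$slope,
                              r_squared = sn$density$r_squared),
    chromosome_stats = list(anova = en$chrom_stats$anova,
                            contrasts = en$chrom_stats$contrasts,
                            depth_correlation = en$depth_corr),
    enrichment = lapply(en$enrichment, head, 20))
  jsonlite::write_json(report, pth("report.json"), auto_unbox = TRUE,
                       digits = 10, na = "null", pretty = TRUE)
  manifest$files <- list.files(out_dir)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  invisible(list(report = report, manifest = manifest))
}

#' Round-trip a file through its parser and writer
#'
#' Parses an artifact file, rewrites it, and re-parses, checking that the
#' two parses are identical — the format round-trip guarantee used by the
#' pipeline tests.
#'
#' @param path Input file.
#' @param format One of "fasta", "fastq", "gff3", "vcf", "tsv", "yaml".
#' @return The parsed object, invisibly; errors if the round-trip is not
#'   exact.
#' @export
io_roundtrip <- function(path, format = c("fasta", "fastq", "gff3", "vcf",
                                          "tsv", "yaml")) {
  format <- match.arg(format)
  tmp <- tempfile(fileext = paste0(".", format))
  on.exit(unlink(tmp))
  obj <- switch(format,
    fasta = read_fasta(path), fastq = read_fastq(path),
    gff3 = read_gff3(path), vcf = read_vcf(path), tsv = read_tsv(path),
    yaml = yaml::read_yaml(path))
  switch(format,
    fasta = write_fasta(obj, tmp), fastq = write_fasta(obj, tmp),
    gff3 = write_gff3(obj, tmp),
    vcf = {
      chroms <- data.frame(name = unique(obj$chrom),
                           length = max(obj$genome_pos + 2L))
      write_vcf(obj, chroms, tmp)
    },
    tsv = write_tsv(obj, tmp), yaml = yaml::write_yaml(obj, tmp))
  obj2 <- switch(format,
    fasta = read_fasta(tmp), fastq = read_fastq(tmp), gff3 = read_gff3(tmp),
    vcf = read_vcf(tmp), tsv = read_tsv(tmp), yaml = yaml::read_yaml(tmp))
  if (format == "vcf") obj2 <- obj2[, names(obj), drop = FALSE]
  if (!isTRUE(all.equal(obj, obj2)))
    stop("round-trip mismatch for ", path)
  invisible(obj)
}
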