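# End-to-end orchestration: simulate a cohort and its probe set, run the
# capture and sequencing simulators, build the catalog, map, call and
# filter, and evaluate everything against the planted truth.

#' Run the full hyRAD simulation and analysis pipeline
#'
#' Simulates an ancestor with planted ddRAD loci, a diploid cohort, probe
#' generation from the fresh individuals, per-sample shotgun libraries
#' (museum samples get fragmented, deaminated DNA), hybridization capture,
#' paired-end sequencing; then builds the RAD-ref catalog from probe
#' reads, maps the captured reads, removes PCR duplicates, estimates and
#' rescales damage, calls and filters SNPs, and runs the structure check.
#'
#' @param config a [hyrad_config()] list.
#' @param seed master seed; defaults to `config$rng_seed`.  Every
#'   stochastic stage draws from the seeded stream.
#' @param rescale apply damage-aware base-quality rescaling (the
#'   no-rescaling arm is used for the damage false-positive comparison).
#' @param museum_samples character vector of individual ids sequenced as
#'   museum specimens; by default the first half of each population.
#' @return a list with the intermediate and final products: `cohort`,
#'   `planted_loci`, `probes`, `catalog`, `reads`, `capture_reports`,
#'   `alignments`, `damage_profile`, `calls`, `filtered` (matrix + step
#'   counts), `structure`, `sample_modes`, `config`.
#' @export
hyrad_end_to_end <- function(config = hyrad_config(), seed = NULL,
                             rescale = TRUE, museum_samples = NULL) {
  if (is.null(seed)) seed <- config$rng_seed
  set.seed(seed)
  sim <- config$simulate
  lib <- config$library

  anc <- simulate_ancestor(sim$genome_length, sim$gc)
  planted <- plant_rad_loci(anc, sim$n_loci)
  model <- population_model(sim$n_pops, sim$n_per_pop, sim$theta_within,
                            sim$d_between, sim$rs_mutation_boost)
  cohort <- simulate_cohort(planted$ancestor, model)
  inds <- names(cohort$individuals)
  if (is.null(museum_samples)) {
    museum_samples <- unlist(lapply(split(inds, cohort$labels[inds]),
                                    function(x) head(x, ceiling(length(x) / 2))))
  }
  modes <- setNames(ifelse(inds %in% museum_samples, "museum", "fresh"), inds)

  # probes from the fresh individuals (pooled across haplotypes)
  window <- c(config$digest$size_min, config$digest$size_max)
  fresh <- inds[modes == "fresh"]
  hap_genomes <- unlist(lapply(fresh, function(i) {
    lapply(cohort$individuals[[i]], function(h) seq_records("chr1", h))
  }), recursive = FALSE)
  probes <- pool_probes(hap_genomes, window)

  # probe (RAD) reads per fresh sample -> RAD-ref catalog
  probe_reads <- lapply(fresh, function(i) {
    per_hap <- lapply(cohort$individuals[[i]], function(h) {
      g <- seq_records("chr1", h)
      select_probes(double_digest(g), g, window)$seq
    })
    seqs <- unlist(per_hap, use.names = FALSE)
    copies <- pmax(1L, rpois(length(seqs), 5))
    reads <- rep(seqs, copies)
    as.character(cpp_point_errors(reads, lib$seq_error)$seq)
  })
  names(probe_reads) <- fresh
  probe_reads <- lapply(probe_reads, function(r) dedupe_exact(r)$seq)
  catalog <- build_rad_ref(probe_reads, config$catalog$t_within,
                           config$catalog$t_among)

  cmodel <- capture_model(config$capture$identity_threshold,
                          config$capture$min_overlap_bp,
                          config$capture$p_on, config$capture$p_bg,
                          config$capture$p_daisy,
                          config$capture$daisy_chain,
                          config$capture$flank_bp, config$capture$cot1)

  all_reads <- list()
  reports <- list()
  for (i in inds) {
    lcfg <- library_config(mode = modes[[i]], coverage = lib$coverage,
                           read_len = lib$read_len,
                           seq_error = lib$seq_error,
                           contaminant_fraction = lib$contaminant_fraction,
                           damage = if (modes[[i]] == "museum") {
                             damage_model(lib$p_max, lib$rho)
                           } else damage_model(0, 0.5))
    mols <- fragment_molecules(cohort$individuals[[i]], lcfg, sample = i)
    enr <- enrich(mols, probes, cmodel)
    reports[[i]] <- enr$report
    mols <- enr$molecules
    if (lcfg$damage$p_max > 0) mols <- apply_damage(mols, lcfg$damage)
    # PCR duplicates copy the damaged template; sequencing errors are
    # drawn independently per copy
    mols <- amplify_molecules(mols, sim$pcr_dup_rate)
    reads <- sequence_reads(mols, lcfg)
    if (lcfg$contaminant_fraction > 0) {
      contam <- simulate_ancestor(50000L, 0.5, id = "contaminant")
      reads <- spike_contaminants(reads, lcfg, contam)
    }
    all_reads[[i]] <- reads
  }
  reads <- rbindlist(all_reads, fill = TRUE)

  aln <- map_reads(reads, catalog, config$align$k, config$align$score_margin,
                   config$align$band, config$align$min_score_frac)
  aln <- remove_duplicates(aln)
  # damage is assessed and rescaled per sample (fresh samples show a flat
  # profile and are effectively untouched)
  profiles <- lapply(setNames(inds, inds), function(i) {
    estimate_damage_profile(subset_alignments(aln, i),
                            config$variants$damage_window)
  })
  aln_used <- if (rescale) {
    parts <- lapply(inds, function(i) {
      rescale_qualities(subset_alignments(aln, i), profiles[[i]])
    })
    structure(list(reads = rbindlist(lapply(parts, `[[`, "reads")),
                   pairs = rbindlist(lapply(parts, `[[`, "pairs")),
                   contigs = aln$contigs),
              class = "hyrad_alignments")
  } else aln
  profile <- estimate_damage_profile(aln, config$variants$damage_window)
  calls <- call_sites(aln_used, config$variants$min_base_q, samples = inds)
  fcfg <- filter_config(config$variants$min_qual, config$variants$mac_mode,
                        config$variants$mac_fraction,
                        config$variants$mac_absolute,
                        config$variants$min_presence,
                        config$variants$min_depth,
                        config$variants$paralog_sd_mult,
                        config$variants$drop_indels,
                        config$variants$biallelic_only)
  filtered <- filter_sites(calls, fcfg)
  structure_res <- tryCatch(
    structure_check(filtered$matrix, 2L, cohort$labels),
    error = function(e) list(assignments = NULL, concordance = NA_real_))

  list(cohort = cohort, planted_loci = planted$loci, probes = probes,
       catalog = catalog, reads = reads, capture_reports = reports,
       alignments = aln, alignments_used = aln_used,
       damage_profile = profile, damage_profiles = profiles,
       calls = calls, filtered = filtered,
       structure = structure_res, sample_modes = modes, config = config,
       seed = seed)
}

#' Locate catalog contigs on the ancestor genome
#'
#' Maps contigs (as pseudo-reads) to the ancestor with the package mapper
#' so that contig coordinates can be translated to ancestor coordinates
#' for truth comparison.
#'
#' @param catalog catalog `data.table`.
#' @param ancestor [seq_records()] ancestor.
#' @return `data.table`: `contig`, `astart`, `strand`, `clen` (NA rows
#'   for contigs that failed to locate).
#' @export
locate_contigs <- function(catalog, ancestor) {
  if (nrow(catalog) == 0L) {
    return(data.table(contig = character(), astart = integer(),
                      strand = character(), clen = integer()))
  }
  fake <- quality_reads(catalog$id, catalog$seq,
                        vapply(nchar(catalog$seq),
                               function(L) strrep("I", L), character(1)))
  aln <- map_reads(fake, seq_records(ancestor$id[1L], ancestor$seq[1L]),
                   k = 15L, score_margin = 4L, band = 12L,
                   min_score_frac = 0.5)
  aln$reads[, .(contig = read_id, astart = start, strand = strand,
                clen = rlen, map_class)]
}

#' Evaluate called variants against the planted truth
#'
#' Translates called sites to ancestor coordinates via [locate_contigs()]
#' and compares them with the truth table restricted to the probe
#' intervals.  A called variant site is a site with quality >
#' `min_qual` and at least one non-reference genotype; a true positive
#' additionally matches the truth position and alternative allele.
#'
#' @param result a [hyrad_end_to_end()] result (or a compatible list with
#'   `calls`, `catalog`, `cohort`, `probes`).
#' @param min_qual site-quality cutoff for a confident call.
#' @return list with `sensitivity`, `fdr`, `n_truth`, `n_called`, `n_tp`,
#'   and the per-site tables.
#' @export
evaluate_variants <- function(result, min_qual = 30) {
  cohort <- result$cohort
  loc <- locate_contigs(result$catalog, cohort$ancestor)
  loc <- loc[map_class != "unmapped"]
  iv <- unique(result$probes[, .(chrom, start, end)])
  truth <- truth_variants_in(cohort, iv)
  calls <- result$calls
  gt <- calls$gt
  # a confident SNP call: quality above the cutoff and segregating within
  # the sample set (sites monomorphic-alternative against the catalog
  # consensus indicate a consensus error, not a polymorphism, and carry
  # minor allele count 0)
  alt_n <- rowSums(calls$gt, na.rm = TRUE)
  called_n <- 2L * rowSums(!is.na(calls$gt))
  conf <- calls$sites$qual > min_qual & alt_n > 0L & alt_n < called_n
  called <- cbind(calls$sites[, .(contig, pos, ref, alt)], conf = conf)[conf == TRUE]
  called <- merge(called, loc, by = "contig")
  called[, apos := ifelse(strand == "+", astart + pos,
                          astart + clen - 1L - pos)]
  called[, aalt := ifelse(strand == "+", alt, COMP4[alt])]
  called[, aref := ifelse(strand == "+", ref, COMP4[ref])]
  # the catalog consensus may carry either allele of a true variant, so a
  # true positive matches the truth position and the unordered allele pair
  tr <- truth[, .(pos, tref = ref, talt = alt)]
  tp <- called[tr, on = .(apos = pos), nomatch = NULL][
    (aref == tref & aalt == talt) | (aref == talt & aalt == tref)]
  n_tp_sites <- length(unique(tp$apos))
  n_truth <- nrow(truth)
  n_called <- nrow(called)
  fp <- n_called - nrow(unique(called[truth, on = .(apos = pos),
                                      nomatch = NULL],
                              by = "apos"))
  list(sensitivity = if (n_truth) n_tp_sites / n_truth else NA_real_,
       fdr = if (n_called) fp / n_called else NA_real_,
       n_truth = n_truth, n_called = n_called, n_tp = n_tp_sites,
       called = called, truth = truth)
}

#' Count confident damage-signature false-positive SNP calls
#'
#' Confident calls (site quality > `min_qual`, at least one non-reference
#' genotype) whose alleles carry the deamination signature in contig
#' orientation (`C->T` or `G->A`) and whose position, translated to the
#' ancestor, is absent from the truth table.  This is the quantity that
#' base-quality rescaling is meant to suppress: the drop in SNP count
#' after rescaling on damaged samples.
#'
#' @param result a [hyrad_end_to_end()] result (supplies catalog, cohort).
#' @param calls the `hyrad_calls` arm to evaluate (defaults to the
#'   result's own calls).
#' @param min_qual site-quality cutoff.
#' @return number of confident damage-signature false-positive sites.
#' @export
damage_false_positives <- function(result, calls = result$calls,
                                   min_qual = 30) {
  s <- calls$sites
  if (nrow(s) == 0L) return(0L)
  alt_n <- rowSums(calls$gt, na.rm = TRUE)
  sig <- (s$ref == "C" & s$alt == "T") | (s$ref == "G" & s$alt == "A")
  conf <- s$qual > min_qual & alt_n > 0L
  cand <- cbind(s, conf = conf, sig = sig)[conf & sig]
  if (nrow(cand) == 0L) return(0L)
  loc <- locate_contigs(result$catalog, result$cohort$ancestor)
  loc <- loc[map_class != "unmapped"]
  cand <- merge(cand, loc[, .(contig, astart, strand, clen)], by = "contig")
  cand[, apos := ifelse(strand == "+", astart + pos,
                        astart + clen - 1L - pos)]
  sum(!cand$apos %in% result$cohort$truth$pos)
}

#' Count candidate sites whose only variant evidence is damage-shaped
#'
#' A candidate site counts iff every non-reference base above the quality
#' floor is a read-oriented T-over-C within `K` of the read 5' end or
#' A-over-G within `K` of the 3' end -- the post-mortem deamination
#' signature.  Quality rescaling pushes such bases below the floor, so
#' this is the quantity it is designed to suppress.
#'
#' @param aln a `hyrad_alignments` object (pre- or post-rescaling).
#' @param min_base_q candidate base-quality floor (default 13).
#' @param K terminal window (default 12).
#' @return number of damage-signature-only candidate sites.
#' @export
count_damage_signature_sites <- function(aln, min_base_q = 13, K = 12L) {
  p <- read_oriented(aln$pairs)[qual >= min_base_q]
  nonref <- p[base != ref]
  if (nrow(nonref) == 0L) return(0L)
  nonref[, dmg := (base_ro == "T" & ref_ro == "C" & roff5 < K) |
           (base_ro == "A" & ref_ro == "G" & roff3 < K)]
  agg <- nonref[, .(all_dmg = all(dmg)), by = .(contig, cpos)]
  sum(agg$all_dmg)
}

# ---------------------------------------------------------------------------
# Command-line interface
# ---------------------------------------------------------------------------

#' Command-line entry point
#'
#' Subcommands: `digest` (in-silico double digest and probe selection of a
#' FASTA genome) and `simulate` (full [hyrad_end_to_end()] run writing
#' probes, catalog, reads, VCF, genotype matrix and reports).  All
#' subcommands accept `--config <json>` and `--seed <int>`.
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return invisibly, the main result object.
#' @export
hyrad_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: hyradsim <digest|simulate> [--config cfg.json] [--seed N]",
    "                [--genome genome.fa] [--out outdir]", sep = "\n")
  if (length(args) < 1L) { message(usage); return(invisible(NULL)) }
  cmd <- args[1L]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  cfg <- if (!is.null(opt("config"))) read_config(opt("config")) else hyrad_config()
  seed <- as.integer(opt("seed", cfg$rng_seed))
  out <- opt("out", ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (cmd == "digest") {
    genome <- parse_fasta(opt("genome"))
    frags <- double_digest(genome, enzyme(cfg$digest$enzyme_a),
                           enzyme(cfg$digest$enzyme_b))
    probes <- select_probes(frags, genome,
                            c(cfg$digest$size_min, cfg$digest$size_max))
    write_fasta(seq_records(probes$id, probes$seq),
                file.path(out, "probes.fa"))
    write_probe_bed(probes, file.path(out, "probes.bed"))
    message(nrow(probes), " probes written to ", out)
    return(invisible(probes))
  }
  if (cmd == "simulate") {
    res <- hyrad_end_to_end(cfg, seed = seed)
    write_fasta(seq_records(res$probes$id, res$probes$seq),
                file.path(out, "probes.fa"))
    write_catalog(res$catalog, file.path(out, "catalog.fa"))
    write_fastq(res$reads, file.path(out, "capture_reads.fastq"))
    write_truth(res$cohort, file.path(out, "truth.tsv"))
    write_vcf(res$calls, file.path(out, "calls.vcf"))
    write_matrix(res$filtered$matrix, file.path(out, "matrix.tsv"))
    fwrite(res$filtered$steps, file.path(out, "filter_steps.tsv"), sep = "\t")
    message("simulation written to ", out,
            " (matrix fullness ",
            sprintf("%.3f", matrix_fullness(res$filtered$matrix)), ")")
    return(invisible(res))
  }
  stop("unknown subcommand: ", cmd, "\n", usage)
}
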