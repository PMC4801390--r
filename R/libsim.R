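# Shotgun library read simulator for fresh, sonicated and museum samples:
# lognormal fragmentation, terminal cytosine deamination, paired-end
# sequencing with i.i.d. substitution errors, and contaminant spike-ins.

#' Post-mortem deamination damage model
#'
#' Geometric damage profile: a C at 5' offset `i` converts to T with
#' probability `p_max * rho^i`; a G at 3' offset `j` converts to A with
#' probability `p_max * rho^j`.  A two-parameter simplification of the
#' overhang-deamination model that reproduces the monotone terminal
#' mismatch enrichment seen in degraded museum DNA.
#'
#' @param p_max maximal per-base deamination probability at the terminus.
#' @param rho per-position geometric decay in (0, 1).
#' @return list with class `hyrad_damage_model`.
#' @export
damage_model <- function(p_max = 0.3, rho = 0.5) {
  stopifnot(p_max >= 0, p_max <= 1, rho > 0, rho < 1)
  structure(list(p_max = p_max, rho = rho), class = "hyrad_damage_model")
}

#' Map specimen age to a damage intensity
#'
#' Linear interpolation between configurable endpoints (ages at or below
#' `age_min` get `p_range[1]`, at or above `age_max` get `p_range[2]`); no
#' quantitative age-damage curve is assumed beyond monotonicity.
#'
#' @param age specimen age in years.
#' @param age_min,age_max interpolation endpoints (years).
#' @param p_range `p_max` at the two endpoints.
#' @return `p_max` value(s).
#' @export
age_to_pmax <- function(age, age_min = 10, age_max = 100,
                        p_range = c(0.05, 0.3)) {
  f <- pmin(1, pmax(0, (age - age_min) / (age_max - age_min)))
  p_range[1L] + f * (p_range[2L] - p_range[1L])
}

#' Library configuration
#'
#' @param mode `fresh`, `sonicated` or `museum`; sets the fragment-length
#'   regime and (for museum) the damage default.
#' @param frag_mean,frag_sd lognormal fragment-length mean and SD in bp
#'   (defaults by mode: fresh/sonicated 300, museum 80).
#' @param coverage mean sequencing depth over the genome (and hence over
#'   probe space, since fragment starts are uniform).
#' @param read_len read length in bp (>= 30).
#' @param seq_error per-base substitution error probability.
#' @param contaminant_fraction expected fraction of contaminant reads.
#' @param damage a [damage_model()]; NULL gives the mode default
#'   (museum: p_max 0.3, rho 0.5; otherwise no damage).
#' @return list with class `hyrad_library_config`.
#' @export
library_config <- function(mode = c("fresh", "sonicated", "museum"),
                           frag_mean = NULL, frag_sd = NULL,
                           coverage = 30, read_len = 150L,
                           seq_error = 0.001, contaminant_fraction = 0,
                           damage = NULL) {
  mode <- match.arg(mode)
  defaults <- list(fresh = c(300, 75), sonicated = c(300, 60),
                   museum = c(80, 30))
  if (is.null(frag_mean)) frag_mean <- defaults[[mode]][1L]
  if (is.null(frag_sd)) frag_sd <- defaults[[mode]][2L]
  if (is.null(damage)) {
    damage <- if (mode == "museum") damage_model(0.3, 0.5) else damage_model(0, 0.5)
  }
  stopifnot(coverage > 0, read_len >= 30L,
            contaminant_fraction >= 0, contaminant_fraction < 1)
  structure(list(mode = mode, frag_mean = frag_mean, frag_sd = frag_sd,
                 coverage = coverage, read_len = as.integer(read_len),
                 seq_error = seq_error,
                 contaminant_fraction = contaminant_fraction,
                 damage = damage),
            class = "hyrad_library_config")
}

#' Fragment a diploid genome into library molecules
#'
#' Fragment starts are uniform over the genome, lengths lognormal with the
#' configured mean/SD truncated to >= 30 bp, and the molecule count is
#' chosen so expected depth is about `coverage` over the diploid genome.
#'
#' @param haplotypes named list/character vector of haplotype sequences
#'   (e.g. `cohort$individuals[[i]]`).
#' @param config a [library_config()].
#' @param seed integer seed or NULL.
#' @param sample sample id recorded on the molecules.
#' @param chrom chromosome name of the haplotypes.
#' @return `data.table` of molecules: `id`, `sample`, `chrom`, `start`,
#'   `end` (0-based half-open), `hap` (haplotype index), `seq`,
#'   `provenance`, `damage` (list column, empty until [apply_damage()]).
#' @export
fragment_molecules <- function(haplotypes, config, seed = NULL,
                               sample = "s1", chrom = "chr1") {
  if (!is.null(seed)) set.seed(seed)
  haplotypes <- as.list(haplotypes)
  L <- nchar(haplotypes[[1L]])
  n_hap <- length(haplotypes)
  n <- max(1L, round(config$coverage * L / config$frag_mean))
  hap <- sample.int(n_hap, n, replace = TRUE)
  if (config$frag_sd <= 0) {
    len <- rep(round(config$frag_mean), n)
  } else {
    sigma2 <- log(1 + (config$frag_sd / config$frag_mean)^2)
    len <- round(rlnorm(n, log(config$frag_mean) - sigma2 / 2, sqrt(sigma2)))
  }
  len <- pmax(30L, as.integer(len))
  start <- as.integer(floor(runif(n, 0, L)))
  end <- pmin(L, start + len)
  keep <- end - start >= 30L
  start <- start[keep]; end <- end[keep]; hap <- hap[keep]
  seqs <- character(length(start))
  for (h in seq_len(n_hap)) {
    sel <- hap == h
    seqs[sel] <- substring(haplotypes[[h]], start[sel] + 1L, end[sel])
  }
  data.table(id = sprintf("%s_m%06d", sample, seq_along(start)),
             sample = sample, chrom = chrom, start = start, end = end,
             hap = hap, seq = seqs, provenance = "endogenous",
             damage = rep(list(integer(0)), length(start)))
}

#' Apply post-mortem deamination damage to molecules
#'
#' Independently per base: a C at 5' offset `i` becomes T with probability
#' `p_max * rho^i`; a G at 3' offset `j` (counted from the 3' end) becomes
#' A with probability `p_max * rho^j`.  Converted offsets are recorded.
#'
#' @param molecules molecule `data.table` from [fragment_molecules()], or a
#'   character vector of sequences.
#' @param model a [damage_model()].
#' @param seed integer seed or NULL.
#' @return same shape as the input, with damaged `seq` and 0-based damaged
#'   offsets in `damage` (for a character input: a list with `seq` and
#'   `positions`).
#' @export
apply_damage <- function(molecules, model = damage_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(molecules)) {
    res <- cpp_apply_damage(molecules, model$p_max, model$rho)
    return(list(seq = as.character(res$seq), positions = res$positions))
  }
  if (model$p_max == 0 || nrow(molecules) == 0L) return(molecules)
  res <- cpp_apply_damage(molecules$seq, model$p_max, model$rho)
  out <- copy(molecules)
  out[, seq := as.character(res$seq)]
  out[, damage := res$positions]
  out[]
}

#' Sequence molecules into paired reads
#'
#' Read 1 is the first `read_len` bases of the molecule, read 2 the
#' reverse complement of the last `read_len` bases; molecules shorter than
#' `read_len` are read through entirely (fully overlapping mates).
#' Substitution errors are i.i.d. at `seq_error`; per-base qualities are
#' drawn so the mean PHRED matches `-10*log10(seq_error)`.  Provenance and
#' damaged offsets are propagated into read coordinates.
#'
#' @param molecules molecule `data.table` (optionally damaged).
#' @param config a [library_config()].
#' @param seed integer seed or NULL.
#' @return reads `data.table` ([quality_reads()] columns plus `molecule`,
#'   `src_chrom`, `src_start`, `src_end`, `hap`).
#' @export
sequence_reads <- function(molecules, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(molecules) == 0L) {
    return(cbind(quality_reads(character(), character(), character())[0L],
                 data.table(molecule = character(), src_chrom = character(),
                            src_start = integer(), src_end = integer(),
                            hap = integer())))
  }
  rl <- config$read_len
  mlen <- nchar(molecules$seq)
  r1 <- substr(molecules$seq, 1L, rl)
  r2 <- revcomp(substring(molecules$seq, pmax(1L, mlen - rl + 1L)))
  e1 <- cpp_point_errors(r1, config$seq_error)
  e2 <- cpp_point_errors(r2, config$seq_error)
  q0 <- -10 * log10(max(config$seq_error, 1e-4))
  q1 <- cpp_phred_strings(nchar(r1), q0, 3)
  q2 <- cpp_phred_strings(nchar(r2), q0, 3)
  dmg1 <- lapply(seq_len(nrow(molecules)), function(i) {
    d <- molecules$damage[[i]]
    d[d < rl]
  })
  dmg2 <- lapply(seq_len(nrow(molecules)), function(i) {
    d <- molecules$damage[[i]]
    off <- mlen[i] - 1L - d
    sort(off[off < rl])
  })
  mk <- function(mate, seqs, quals, dmg) {
    quality_reads(paste0(molecules$id, "/", mate), as.character(seqs),
                  as.character(quals), sample = molecules$sample,
                  mate = mate, provenance = molecules$provenance,
                  damage = dmg)
  }
  reads <- rbind(mk(1L, e1$seq, q1, dmg1), mk(2L, e2$seq, q2, dmg2))
  extra <- data.table(molecule = molecules$id, src_chrom = molecules$chrom,
                      src_start = molecules$start, src_end = molecules$end,
                      hap = molecules$hap)
  cbind(reads, rbind(extra, extra))
}

#' Spike contaminant reads into a read set
#'
#' Contaminant reads are generated from the contaminant genome by the same
#' fragment/read model and interleaved so the final contaminant fraction
#' is approximately `config$contaminant_fraction`; they carry
#' `provenance = "contaminant"` so downstream contamination accounting is
#' exact.
#'
#' @param reads endogenous reads `data.table`.
#' @param config a [library_config()] with `contaminant_fraction` set.
#' @param contaminant_genome [seq_records()] of the contaminant source.
#' @param seed integer seed or NULL.
#' @return combined, shuffled reads `data.table`.
#' @export
spike_contaminants <- function(reads, config, contaminant_genome = NULL,
                               seed = NULL) {
  f <- config$contaminant_fraction
  if (f == 0) return(reads)
  if (is.null(contaminant_genome)) {
    stop("contaminant_fraction > 0 requires a contaminant genome")
  }
  if (!is.null(seed)) set.seed(seed)
  n_e <- nrow(reads)
  n_c <- rbinom(1L, round(n_e / (1 - f)), f)
  if (n_c == 0L) return(reads)
  ccfg <- config
  ccfg$coverage <- 1 # placeholder; molecule count set below
  n_mol <- ceiling(n_c / 2)
  L <- nchar(contaminant_genome$seq[1L])
  ccfg$coverage <- n_mol * ccfg$frag_mean / L
  mols <- fragment_molecules(setNames(list(contaminant_genome$seq[1L]),
                                      "h1"),
                             ccfg,
                             sample = reads$sample[1L],
                             chrom = contaminant_genome$id[1L])
  mols[, `:=`(provenance = "contaminant",
              id = sub("_m", "_c", id))]
  creads <- sequence_reads(mols, ccfg)
  creads <- creads[sample.int(nrow(creads), min(n_c, nrow(creads)))]
  out <- rbind(reads, creads)
  out[sample.int(nrow(out))]
}

#' Duplicate molecules to emulate PCR amplification
#'
#' Each molecule is duplicated with probability `rate` (duplicates share
#' coordinates and sequence; sequencing errors are drawn independently
#' later, as for real PCR duplicates).  Duplicates keep the parent
#' molecule id with a `.dupN` suffix so duplicate-removal can be verified
#' against truth.
#'
#' @param molecules molecule `data.table`.
#' @param rate per-molecule duplication probability.
#' @param seed integer seed or NULL.
#' @return molecule `data.table` with duplicates appended.
#' @export
amplify_molecules <- function(molecules, rate = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (rate <= 0 || nrow(molecules) == 0L) return(molecules)
  dup <- molecules[runif(.N) < rate]
  if (nrow(dup) == 0L) return(molecules)
  dup[, id := paste0(id, ".dup1")]
  rbind(molecules, dup)
}
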