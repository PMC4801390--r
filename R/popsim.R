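# Synthetic diploid cohorts from diverged populations, with a complete
# truth table of planted variants.  Substitution-only by default; an indel
# planting switch exists solely to exercise the indel-removal filter.

#' Population model parameters
#'
#' @param n_pops number of populations (>= 1).
#' @param n_per_pop diploid individuals per population.
#' @param theta_within per-bp probability that an individual is
#'   heterozygous at a site.
#' @param d_between per-bp rate of fixed differences private to one
#'   population.
#' @param rs_mutation_boost multiplier applied to both rates at positions
#'   inside a restriction-site occurrence (models restriction-site
#'   polymorphism causing ddRAD locus dropout).
#' @return a list with class `hyrad_popmodel`.
#' @export
population_model <- function(n_pops = 2L, n_per_pop = 4L,
                             theta_within = 0.003, d_between = 0.01,
                             rs_mutation_boost = 1) {
  stopifnot(n_pops >= 1L, n_per_pop >= 1L,
            theta_within >= 0, theta_within <= 1,
            d_between >= 0, d_between <= 1, rs_mutation_boost >= 0)
  structure(list(n_pops = as.integer(n_pops),
                 n_per_pop = as.integer(n_per_pop),
                 theta_within = theta_within, d_between = d_between,
                 rs_mutation_boost = rs_mutation_boost),
            class = "hyrad_popmodel")
}

#' Simulate an ancestral genome sequence
#'
#' I.i.d. bases with `P(G) + P(C) = gc`; deterministic given `seed`.
#'
#' @param length sequence length (>= 1).
#' @param gc GC fraction in (0, 1]; 1.0 gives a G/C-only sequence.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param id chromosome name.
#' @return [seq_records()] with one record.
#' @export
simulate_ancestor <- function(length, gc = 0.42, seed = NULL, id = "chr1") {
  stopifnot(length >= 1, gc > 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(p), length, replace = TRUE, prob = p)
  seq_records(id, paste(bases, collapse = ""))
}

#' Plant ddRAD-compatible loci into an ancestor
#'
#' Embeds `n_loci` SbfI..MseI motif pairs at evenly spaced positions so
#' that the digest yields size-selectable SbfI-MseI fragments.  The insert
#' between the motifs keeps the local ancestor bases, scrubbed of any
#' accidental recognition sites.  Sequence length is unchanged.
#'
#' @param ancestor [seq_records()] with one record.
#' @param n_loci number of loci to plant.
#' @param insert_range range of insert lengths between the two motifs; the
#'   resulting fragment length is insert + 3 bp.
#' @param seed integer seed or NULL.
#' @return list with `ancestor` (modified) and `loci`
#'   (`data.table(chrom, start, end)` of the expected probe fragments,
#'   0-based half-open).
#' @export
plant_rad_loci <- function(ancestor, n_loci, insert_range = c(140L, 180L),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- ancestor$seq[1L]
  L <- nchar(s)
  sbfi <- enzyme("SbfI")$recognition
  msei <- enzyme("MseI")$recognition
  span_max <- 12L + insert_range[2L]
  margin <- 500L
  stopifnot(L > 2L * margin + n_loci * (span_max + 50L))
  starts <- round(seq(margin, L - margin - span_max, length.out = n_loci))
  loci <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    ins_len <- sample(insert_range[1L]:insert_range[2L], 1L)
    a <- starts[i] # 0-based start of the SbfI motif
    insert <- substr(s, a + 9L, a + 8L + ins_len)
    insert <- scrub_motifs(insert, c(sbfi, msei))
    region <- paste0(sbfi, insert, msei)
    # scrub any motif occurrence created at the junctions with the context
    for (iter in 1:20) {
      ctx_lo <- max(0L, a - 7L)
      ctx <- paste0(substr(s, ctx_lo + 1L, a),
                    region,
                    substr(s, a + nchar(region) + 1L,
                           min(L, a + nchar(region) + 7L)))
      occ <- c(find_sites(ctx, enzyme("SbfI")), find_sites(ctx, enzyme("MseI")))
      want <- c(a - ctx_lo, a - ctx_lo + 8L + ins_len) # planted motif starts
      stray <- setdiff(occ, want)
      if (length(stray) == 0L) break
      # mutate one base of the stray site that lies outside planted motifs
      pos_ctx <- stray[1L]
      cand <- pos_ctx + 0:3
      cand <- cand[!(cand %in% c(want[1L] + 0:7, want[2L] + 0:3))]
      p <- cand[1L] + ctx_lo # back to 0-based genome coordinate
      old <- substr(s, p + 1L, p + 1L)
      new <- setdiff(c("A", "C", "G", "T"), old)[sample.int(3L, 1L)]
      if (p >= a && p < a + nchar(region)) {
        substr(region, p - a + 1L, p - a + 1L) <- new
      } else {
        substr(s, p + 1L, p + 1L) <- new
      }
    }
    substr(s, a + 1L, a + nchar(region)) <- region
    # expected fragment: SbfI cut at a+6, MseI cut at (a+8+ins_len)+1
    loci[[i]] <- data.table(chrom = ancestor$id[1L],
                            start = a + 6L, end = a + 9L + ins_len)
  }
  list(ancestor = seq_records(ancestor$id[1L], s), loci = rbindlist(loci))
}

scrub_motifs <- function(x, motifs) {
  for (iter in 1:50) {
    hit <- FALSE
    for (m in motifs) {
      p <- regexpr(m, x, fixed = TRUE)
      if (p > 0) {
        hit <- TRUE
        old <- substr(x, p, p)
        substr(x, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1L]
      }
    }
    if (!hit) break
  }
  x
}

#' Simulate a diploid cohort with a variant truth table
#'
#' Fixed differences are population-private and homozygous; heterozygous
#' sites are drawn independently per individual.  Positions inside any
#' SbfI/MseI recognition occurrence mutate at `rate * rs_mutation_boost`.
#' Alternative alleles never create a new recognition site (violating
#' draws are re-drawn, and dropped if no allele is admissible).
#'
#' @param ancestor [seq_records()] with one record.
#' @param model a [population_model()].
#' @param seed integer seed or NULL.
#' @return object of class `hyrad_cohort`: list with `ancestor`,
#'   `individuals` (named list of `list(h1, h2)` haplotype strings),
#'   `labels` (named population vector), `truth` (`data.table` with
#'   `chrom`, `pos` (0-based), `ref`, `alt` and one 0/1/2 genotype column
#'   per individual), and `model`.
#' @export
simulate_cohort <- function(ancestor, model = population_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- ancestor$seq[1L]
  L <- nchar(s)
  chrom <- ancestor$id[1L]
  n_ind <- model$n_pops * model$n_per_pop
  ind_ids <- paste0("p", rep(seq_len(model$n_pops), each = model$n_per_pop),
                    "_i", rep(seq_len(model$n_per_pop), model$n_pops))
  labels <- setNames(rep(paste0("pop", seq_len(model$n_pops)),
                         each = model$n_per_pop), ind_ids)

  boost <- rep(1, L)
  for (enz in list(enzyme("SbfI"), enzyme("MseI"))) {
    for (st in find_sites(s, enz)) {
      boost[(st + 1L):(st + nchar(enz$recognition))] <- model$rs_mutation_boost
    }
  }

  # population-private fixed differences
  p_fix <- pmin(1, model$d_between * boost)
  fix_pos <- which(runif(L) < p_fix) # 1-based
  fix_pop <- sample.int(model$n_pops, length(fix_pos), replace = TRUE)

  # per-individual heterozygous sites (excluding fixed-difference positions)
  p_het <- pmin(1, model$theta_within * boost)
  het <- vector("list", n_ind)
  for (j in seq_len(n_ind)) {
    hp <- which(runif(L) < p_het)
    het[[j]] <- setdiff(hp, fix_pos)
  }
  all_pos <- sort(unique(c(fix_pos, unlist(het))))
  if (length(all_pos) == 0L) {
    truth <- data.table(chrom = character(), pos = integer(),
                        ref = character(), alt = character())
    for (id in ind_ids) truth[, (id) := integer()]
    haps <- lapply(ind_ids, function(i) list(h1 = s, h2 = s))
    names(haps) <- ind_ids
    return(structure(list(ancestor = ancestor, individuals = haps,
                          labels = labels, truth = truth, model = model),
                     class = "hyrad_cohort"))
  }
  ref <- substring(s, all_pos, all_pos)
  alt <- draw_alt_alleles(s, all_pos, ref)
  ok <- !is.na(alt)
  all_pos <- all_pos[ok]; ref <- ref[ok]; alt <- alt[ok]

  gt <- matrix(0L, nrow = length(all_pos), ncol = n_ind,
               dimnames = list(NULL, ind_ids))
  fix_keep <- fix_pos %in% all_pos
  if (any(fix_keep)) {
    ridx <- match(fix_pos[fix_keep], all_pos)
    for (k in seq_along(ridx)) {
      members <- which(labels == paste0("pop", fix_pop[fix_keep][k]))
      gt[ridx[k], members] <- 2L
    }
  }
  which_hap <- matrix(0L, nrow = length(all_pos), ncol = n_ind)
  for (j in seq_len(n_ind)) {
    hj <- het[[j]][het[[j]] %in% all_pos]
    ridx <- match(hj, all_pos)
    gt[ridx, j] <- 1L
    which_hap[ridx, j] <- sample(c(1L, 2L), length(ridx), replace = TRUE)
  }

  anc_chars <- strsplit(s, "")[[1L]]
  haps <- vector("list", n_ind)
  for (j in seq_len(n_ind)) {
    h1 <- anc_chars; h2 <- anc_chars
    hom <- which(gt[, j] == 2L)
    if (length(hom)) {
      h1[all_pos[hom]] <- alt[hom]
      h2[all_pos[hom]] <- alt[hom]
    }
    hz <- which(gt[, j] == 1L)
    if (length(hz)) {
      on1 <- which_hap[hz, j] == 1L
      h1[all_pos[hz][on1]] <- alt[hz][on1]
      h2[all_pos[hz][!on1]] <- alt[hz][!on1]
    }
    haps[[j]] <- list(h1 = paste(h1, collapse = ""),
                      h2 = paste(h2, collapse = ""))
  }
  names(haps) <- ind_ids

  truth <- data.table(chrom = chrom, pos = all_pos - 1L, ref = ref, alt = alt)
  truth <- cbind(truth, as.data.table(gt))
  structure(list(ancestor = ancestor, individuals = haps, labels = labels,
                 truth = truth, model = model),
            class = "hyrad_cohort")
}

# Draw one alternative allele per position such that the substitution does
# not create a new SbfI/MseI occurrence in its 15-bp context; NA if no
# admissible allele exists.
draw_alt_alleles <- function(s, pos, ref) {
  L <- nchar(s)
  lo <- pmax(1L, pos - 7L)
  hi <- pmin(L, pos + 7L)
  win <- substring(s, lo, hi)
  rel <- pos - lo + 1L
  n_before <- stringi::stri_count_fixed(win, "CCTGCAGG") +
    stringi::stri_count_fixed(win, "TTAA")
  alt <- rep(NA_character_, length(pos))
  remaining <- seq_along(pos)
  bases <- c("A", "C", "G", "T")
  # candidate order randomized once per position
  cand_order <- vapply(ref, function(r) sample(setdiff(bases, r)),
                       character(3))
  for (k in 1:3) {
    if (length(remaining) == 0L) break
    cand <- cand_order[k, remaining]
    w <- win[remaining]
    r <- rel[remaining]
    trial <- paste0(substr(w, 1L, r - 1L), cand,
                    substring(w, r + 1L))
    n_after <- stringi::stri_count_fixed(trial, "CCTGCAGG") +
      stringi::stri_count_fixed(trial, "TTAA")
    ok <- n_after <= n_before[remaining]
    alt[remaining[ok]] <- cand[ok]
    remaining <- remaining[!ok]
  }
  alt
}

#' Subset the truth table to variants inside intervals
#'
#' @param cohort a [simulate_cohort()] result.
#' @param intervals `data.table`/data.frame with `chrom`, `start`, `end`
#'   (0-based half-open on ancestor coordinates).
#' @return the truth rows whose `pos` falls in any interval.
#' @export
truth_variants_in <- function(cohort, intervals) {
  tr <- cohort$truth
  if (nrow(tr) == 0L || NROW(intervals) == 0L) return(tr[0L])
  iv <- as.data.table(intervals)[, .(chrom, start, end)]
  hit <- rep(FALSE, nrow(tr))
  for (ch in unique(iv$chrom)) {
    sel <- tr$chrom == ch
    if (!any(sel)) next
    ivc <- iv[chrom == ch]
    hit[sel] <- hit[sel] | data.table::inrange(tr$pos[sel], ivc$start,
                                               ivc$end - 1L)
  }
  tr[hit]
}

#' Apply the truth table to the ancestor to rebuild a haplotype
#'
#' Reconstruction helper used by the invariant tests: a cohort haplotype
#' must equal the ancestor with the individual's truth alleles applied.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param individual individual id.
#' @param hap 1 or 2.
#' @return haplotype string.
#' @export
reconstruct_haplotype <- function(cohort, individual, hap = 1L) {
  chars <- strsplit(cohort$ancestor$seq[1L], "")[[1L]]
  tr <- cohort$truth
  g <- tr[[individual]]
  hom <- which(g == 2L)
  chars[tr$pos[hom] + 1L] <- tr$alt[hom]
  hz <- which(g == 1L)
  if (length(hz)) {
    actual <- substring(cohort$individuals[[individual]][[hap]],
                        tr$pos[hz] + 1L, tr$pos[hz] + 1L)
    carried <- actual == tr$alt[hz]
    chars[tr$pos[hz][carried] + 1L] <- tr$alt[hz][carried]
  }
  paste(chars, collapse = "")
}

#' Write the truth table as a VCF-like TSV with a population sidecar
#' @param cohort a [simulate_cohort()] result.
#' @param path output TSV; the sidecar is written to `<path>.pops`.
#' @export
write_truth <- function(cohort, path) {
  fwrite(cohort$truth, path, sep = "\t")
  fwrite(data.table(individual = names(cohort$labels),
                    population = unname(cohort$labels)),
         paste0(path, ".pops"), sep = "\t")
  invisible(path)
}
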