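# Damage-aware SNP calling and filtering: damage profile estimation and
# base-quality rescaling, a diploid genotype-likelihood caller, the filter
# cascade (indels, biallelic, quality, depth, presence, minor allele
# count, paralogs), matrix summaries, a lightweight k=2 structure check,
# and the ddRAD-vs-hyRAD locus dropout comparator.

COMP4 <- c(A = "T", C = "G", G = "C", T = "A")

# read-oriented base/ref for a pairs table (minus-strand rows complemented)
read_oriented <- function(pairs) {
  p <- copy(pairs)
  minus <- p$strand == "-"
  p[, `:=`(base_ro = base, ref_ro = ref)]
  p[minus == TRUE, `:=`(base_ro = COMP4[base], ref_ro = COMP4[ref])]
  p
}

#' Estimate a terminal deamination damage profile from alignments
#'
#' `r5[i]` is the C->T mismatch rate at 5' read offset `i` minus the
#' baseline C->T rate at offsets >= `K`, floored at 0; `r3` is the G->A
#' mirror from the 3' end.  Bases are compared in read orientation
#' (minus-strand alignments complemented), so damage appears as T-over-C
#' near the 5' end and A-over-G near the 3' end on both strands.
#'
#' @param aln a `hyrad_alignments` object (unique reads contribute).
#' @param K profile window length (default 12).
#' @return object of class `hyrad_damage_profile`: list with `r5`, `r3`
#'   (length `K`), `K` and the two baselines.
#' @export
estimate_damage_profile <- function(aln, K = 12L) {
  p <- read_oriented(aln$pairs)
  if (nrow(p) < 1000L) {
    warning("fewer than 1,000 aligned bases; damage profile will be noisy")
  }
  ct <- p[ref_ro == "C"][, mismatch := base_ro == "T"]
  ga <- p[ref_ro == "G"][, mismatch := base_ro == "A"]
  prof <- function(dt, offcol) {
    inwin <- dt[get(offcol) < K]
    r <- numeric(K)
    if (nrow(inwin)) {
      agg <- inwin[, .(rate = mean(mismatch)), keyby = c(offcol)]
      r[agg[[offcol]] + 1L] <- agg$rate
    }
    base_rows <- dt[get(offcol) >= K]
    baseline <- if (nrow(base_rows)) mean(base_rows$mismatch) else 0
    list(r = pmax(0, r - baseline), baseline = baseline)
  }
  p5 <- prof(ct, "roff5")
  p3 <- prof(ga, "roff3")
  structure(list(r5 = p5$r, r3 = p3$r, K = as.integer(K),
                 baseline5 = p5$baseline, baseline3 = p3$baseline),
            class = "hyrad_damage_profile")
}

#' Rescale base qualities of putatively damaged bases
#'
#' For an aligned base showing the damage signature (read-oriented T over
#' reference C at 5' offset `i < K`, or A over G at 3' offset `j < K`)
#' with estimated excess rate `r > 0`, the quality becomes
#' `Q' = min(Q, -10*log10(r + eps - r*eps))` with `eps = max(10^(-Q/10),
#' 1e-4)`.  All other bases are untouched.
#'
#' @param aln a `hyrad_alignments` object.
#' @param profile a [estimate_damage_profile()] result.
#' @return a `hyrad_alignments` object with rescaled pair qualities.
#' @export
rescale_qualities <- function(aln, profile) {
  p <- read_oriented(aln$pairs)
  K <- profile$K
  r <- rep(0, nrow(p))
  is5 <- p$ref_ro == "C" & p$base_ro == "T" & p$roff5 < K
  r[is5] <- profile$r5[p$roff5[is5] + 1L]
  is3 <- p$ref_ro == "G" & p$base_ro == "A" & p$roff3 < K
  r[is3] <- pmax(r[is3], profile$r3[p$roff3[is3] + 1L])
  hit <- r > 0
  if (any(hit)) {
    eps <- pmax(10^(-p$qual[hit] / 10), 1e-4)
    rr <- r[hit]
    qnew <- -10 * log10(rr + eps - rr * eps)
    p[hit, qual := pmin(qual, qnew)]
  }
  p[, c("base_ro", "ref_ro") := NULL]
  structure(list(reads = aln$reads, pairs = p[], contigs = aln$contigs),
            class = "hyrad_alignments")
}

#' Construct a site-call object
#'
#' Container used by [call_sites()] and accepted by [filter_sites()]; it
#' can also be built directly for constructed filter-test tables.
#'
#' @param sites `data.table` with `contig`, `pos` (0-based), `ref`, `alt`
#'   (comma-separated if multiallelic), `qual`, `is_indel`.
#' @param gt integer matrix sites x samples with values 0/1/2/NA.
#' @param dp,gq numeric matrices, same shape.
#' @param samples sample names (columns).
#' @return object of class `hyrad_calls`.
#' @export
site_calls <- function(sites, gt, dp, gq = NULL, samples = colnames(gt)) {
  stopifnot(nrow(sites) == nrow(gt), all(dim(gt) == dim(dp)))
  if (is.null(gq)) gq <- matrix(99, nrow(gt), ncol(gt))
  if (!"is_indel" %in% names(sites)) sites$is_indel <- FALSE
  colnames(gt) <- colnames(dp) <- colnames(gq) <- samples
  structure(list(sites = as.data.table(sites), gt = gt, dp = dp, gq = gq,
                 samples = samples),
            class = "hyrad_calls")
}

#' Call SNP sites with a diploid genotype-likelihood model
#'
#' Every contig position carrying at least one non-reference base with
#' quality >= `min_base_q` becomes a candidate site.  Per sample, diploid
#' genotype likelihoods use the standard pileup model
#' `P(b | g) = (c_b/2)(1-e) + ((2-c_b)/2)(e/3)` with `e` from the base
#' quality and `c_b` the copies of `b` in `g`; the genotype is the
#' argmax under a flat prior; `site_qual` is the PHRED-scaled probability
#' that all samples are homozygous reference.  Bases below `min_base_q`
#' are excluded from the pileup entirely.  Only unique alignments
#' contribute (multi-mapping reads carry no pileup).
#'
#' @param aln a deduplicated `hyrad_alignments` object.
#' @param min_base_q minimal base quality (default 13).
#' @param samples sample universe; defaults to the samples seen in `aln`.
#' @return a `hyrad_calls` object (biallelic by construction: the alt is
#'   the most frequent non-reference base).
#' @export
call_sites <- function(aln, min_base_q = 13, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(aln$reads$sample))
  p <- aln$pairs[qual >= min_base_q]
  empty <- site_calls(
    data.table(contig = character(), pos = integer(), ref = character(),
               alt = character(), qual = numeric(), is_indel = logical()),
    matrix(NA_integer_, 0L, length(samples)),
    matrix(0, 0L, length(samples)), samples = samples)
  if (nrow(p) == 0L) return(empty)
  cand <- unique(p[base != ref, .(contig, cpos)])
  if (nrow(cand) == 0L) return(empty)
  pc <- p[cand, on = .(contig, cpos)]
  altdt <- pc[base != ref, .N, by = .(contig, cpos, base)]
  setorder(altdt, contig, cpos, -N, base)
  altdt <- altdt[!duplicated(paste(contig, cpos))][
    , .(contig, cpos, alt = base)]
  pc <- pc[altdt, on = .(contig, cpos)]
  dp_dt <- pc[, .(dp = .N), by = .(contig, cpos, sample)]
  pg <- pc[base == ref | base == alt]
  pg[, e := pmin(0.75, 10^(-qual / 10))]
  ll <- pg[, {
    isalt <- base == alt
    l_rr <- sum(log10(ifelse(isalt, e / 3, 1 - e)))
    l_aa <- sum(log10(ifelse(isalt, 1 - e, e / 3)))
    l_ra <- sum(log10(0.5 * (1 - e) + e / 6))
    list(l_rr = l_rr, l_ra = l_ra, l_aa = l_aa)
  }, by = .(contig, cpos, sample)]
  m <- pmax(ll$l_rr, ll$l_ra, ll$l_aa)
  post <- cbind(10^(ll$l_rr - m), 10^(ll$l_ra - m), 10^(ll$l_aa - m))
  post <- post / rowSums(post)
  ll[, `:=`(gt = max.col(post, ties.method = "first") - 1L,
            p_rr = post[, 1L],
            gq = pmin(99, -10 * log10(pmax(1e-10, 1 - apply(post, 1L, max)))))]
  key <- ll[, .(site_qual = pmin(9999, -10 * sum(log10(pmax(p_rr, 1e-300))))),
            by = .(contig, cpos)]
  sites <- altdt[key, on = .(contig, cpos)]
  refs <- unique(pc[, .(contig, cpos, ref)])
  sites <- sites[refs, on = .(contig, cpos), nomatch = NULL]
  setorder(sites, contig, cpos)
  n_sites <- nrow(sites)
  gt <- matrix(NA_integer_, n_sites, length(samples),
               dimnames = list(NULL, samples))
  dp <- matrix(0, n_sites, length(samples), dimnames = list(NULL, samples))
  gq <- matrix(NA_real_, n_sites, length(samples),
               dimnames = list(NULL, samples))
  skey <- paste(sites$contig, sites$cpos)
  ridx <- match(paste(ll$contig, ll$cpos), skey)
  cidx <- match(ll$sample, samples)
  gt[cbind(ridx, cidx)] <- ll$gt
  gq[cbind(ridx, cidx)] <- ll$gq
  dpr <- match(paste(dp_dt$contig, dp_dt$cpos), skey)
  dpc <- match(dp_dt$sample, samples)
  dp[cbind(dpr, dpc)] <- dp_dt$dp
  site_calls(
    sites[, .(contig, pos = cpos, ref, alt, qual = site_qual,
              is_indel = FALSE)],
    gt, dp, gq, samples = samples)
}

#' Filter configuration for the SNP cascade
#'
#' Defaults follow the reference filter set: biallelic sites with quality
#' PHRED > 30, minor allele count larger than 1/6 of all called alleles
#' (or, in `absolute` mode, at least 6), present in at least 50% of the
#' samples, per-genotype depth of at least 6, indels removed, and
#' high-coverage paralogs removed at mean + 3 SD.
#'
#' @param min_qual minimal site quality (strict `>`).
#' @param mac_mode `fraction` (MAC > `mac_fraction` of called alleles) or
#'   `absolute` (MAC >= `mac_absolute`).
#' @param mac_fraction,mac_absolute the two MAC thresholds.
#' @param min_presence minimal fraction of samples with a called genotype.
#' @param min_depth minimal per-sample genotype depth; genotypes below it
#'   become missing before presence counting.
#' @param paralog_sd_mult SD multiplier of the paralog depth filter.
#' @param drop_indels,biallelic_only cascade switches.
#' @return list with class `hyrad_filter_config`.
#' @export
filter_config <- function(min_qual = 30, mac_mode = c("fraction", "absolute"),
                          mac_fraction = 1 / 6, mac_absolute = 6L,
                          min_presence = 0.5, min_depth = 6L,
                          paralog_sd_mult = 3, drop_indels = TRUE,
                          biallelic_only = TRUE) {
  mac_mode <- match.arg(mac_mode)
  stopifnot(min_qual > 0, mac_fraction > 0, mac_fraction < 1,
            min_presence > 0, min_depth > 0)
  structure(list(min_qual = min_qual, mac_mode = mac_mode,
                 mac_fraction = mac_fraction,
                 mac_absolute = as.integer(mac_absolute),
                 min_presence = min_presence,
                 min_depth = as.integer(min_depth),
                 paralog_sd_mult = paralog_sd_mult,
                 drop_indels = drop_indels,
                 biallelic_only = biallelic_only),
            class = "hyrad_filter_config")
}

#' Apply the SNP filter cascade
#'
#' Fixed order: (1) drop indels; (2) biallelic only; (3) site quality >
#' `min_qual`; (4) genotypes with depth < `min_depth` set missing; (5)
#' site present in >= `min_presence` of samples; (6) minor allele count
#' criterion over called alleles; (7) paralog depth filter.  Each step
#' only removes; per-step retention counts are reported.
#'
#' @param calls a `hyrad_calls` object.
#' @param config a [filter_config()].
#' @return list with `matrix` (a `hyrad_matrix`: genotype matrix with
#'   site metadata), and `steps` (`data.table` of per-step site counts).
#' @export
filter_sites <- function(calls, config = filter_config()) {
  gt <- calls$gt
  dp <- calls$dp
  sites <- copy(calls$sites)
  steps <- list(data.table(step = "input", n_sites = nrow(sites)))
  keep <- rep(TRUE, nrow(sites))
  if (config$drop_indels) keep <- keep & !sites$is_indel
  steps <- c(steps, list(data.table(step = "drop_indels", n_sites = sum(keep))))
  if (config$biallelic_only) {
    keep <- keep & !grepl(",", sites$alt, fixed = TRUE)
  }
  steps <- c(steps, list(data.table(step = "biallelic", n_sites = sum(keep))))
  keep <- keep & sites$qual > config$min_qual
  steps <- c(steps, list(data.table(step = "site_quality", n_sites = sum(keep))))
  gt[dp < config$min_depth] <- NA_integer_
  # (4) removes no site by itself; presence counting sees the masking
  steps <- c(steps, list(data.table(step = "depth_mask", n_sites = sum(keep))))
  presence <- rowMeans(!is.na(gt))
  keep <- keep & presence >= config$min_presence
  steps <- c(steps, list(data.table(step = "presence", n_sites = sum(keep))))
  alt_count <- rowSums(gt, na.rm = TRUE)
  called <- 2 * rowSums(!is.na(gt))
  mac <- pmin(alt_count, called - alt_count)
  mac_ok <- if (config$mac_mode == "fraction") {
    mac > called * config$mac_fraction
  } else {
    mac >= config$mac_absolute
  }
  keep <- keep & mac_ok
  steps <- c(steps, list(data.table(step = "mac", n_sites = sum(keep))))
  site_depth <- rowMeans(dp)
  kept_idx <- which(keep)
  mat <- new_matrix(gt[kept_idx, , drop = FALSE], sites[kept_idx],
                    calls$samples)
  mat <- paralog_filter(mat, site_depth[kept_idx], config$paralog_sd_mult)
  steps <- c(steps, list(data.table(step = "paralog",
                                    n_sites = nrow(mat$sites))))
  list(matrix = mat, steps = rbindlist(steps))
}

new_matrix <- function(gt, sites, samples) {
  structure(list(gt = gt, sites = as.data.table(sites), samples = samples),
            class = "hyrad_matrix")
}

#' Remove putative paralogs by the depth outlier rule
#'
#' A site is removed iff its mean depth exceeds
#' `mean(site depths) + sd_mult * SD(site depths)` (population SD, strict
#' inequality), computed over the sites in the matrix.
#'
#' @param matrix a `hyrad_matrix` (or plain genotype matrix).
#' @param site_depths per-site mean depths, aligned with the matrix rows.
#' @param sd_mult SD multiplier (default 3).
#' @return the filtered matrix, with the logical keep vector in
#'   `attr(, "kept")`.
#' @export
paralog_filter <- function(matrix, site_depths, sd_mult = 3) {
  x <- site_depths
  n <- length(x)
  if (n == 0L) return(matrix)
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  keep <- !(x > mu + sd_mult * sdev)
  if (inherits(matrix, "hyrad_matrix")) {
    out <- new_matrix(matrix$gt[keep, , drop = FALSE], matrix$sites[keep],
                      matrix$samples)
  } else {
    out <- matrix[keep, , drop = FALSE]
  }
  attr(out, "kept") <- keep
  out
}

#' Genotype-matrix fullness
#'
#' @param matrix a `hyrad_matrix` or plain genotype matrix.
#' @return fraction of non-missing cells.
#' @export
matrix_fullness <- function(matrix) {
  gt <- if (inherits(matrix, "hyrad_matrix")) matrix$gt else matrix
  if (length(gt) == 0L) stop("empty genotype matrix")
  mean(!is.na(gt))
}

#' Lightweight population-structure check (PCA + 2-means)
#'
#' Missing genotypes are mean-imputed per site, samples are projected onto
#' the top two principal axes and clustered by k-means with seeded
#' restarts.  When true labels are supplied, concordance is the maximal
#' agreement over label permutations.
#'
#' @param matrix a `hyrad_matrix` or sites x samples genotype matrix.
#' @param k number of groups (2 supported).
#' @param truth_labels optional named vector of true population labels.
#' @param seed integer seed or NULL.
#' @param n_restarts k-means restarts.
#' @return list with `assignments` (named integer vector) and
#'   `concordance` (NA without truth labels).
#' @export
structure_check <- function(matrix, k = 2L, truth_labels = NULL, seed = NULL,
                            n_restarts = 20L) {
  stopifnot(k == 2L)
  if (!is.null(seed)) set.seed(seed)
  gt <- if (inherits(matrix, "hyrad_matrix")) matrix$gt else matrix
  if (matrix_fullness(gt) <= 0.2) {
    warning("matrix fullness below 0.2; structure check unreliable")
  }
  X <- t(gt) # samples x sites
  for (j in seq_len(ncol(X))) {
    m <- mean(X[, j], na.rm = TRUE)
    if (is.nan(m)) m <- 0
    X[is.na(X[, j]), j] <- m
  }
  X <- X[, apply(X, 2L, function(v) length(unique(v)) > 1L), drop = FALSE]
  if (ncol(X) == 0L) stop("degenerate matrix: no variable sites")
  pc <- prcomp(X, rank. = 2L, center = TRUE, scale. = FALSE)
  proj <- pc$x
  if (ncol(proj) < 2L) proj <- cbind(proj, 0)
  km <- kmeans(proj, centers = k, nstart = n_restarts)
  assignments <- setNames(km$cluster, rownames(X))
  concordance <- NA_real_
  if (!is.null(truth_labels)) {
    tl <- as.integer(factor(truth_labels[names(assignments)]))
    a <- assignments
    concordance <- max(mean(a == tl), mean((3L - a) == tl))
  }
  list(assignments = assignments, concordance = concordance)
}

#' Compare in-silico ddRAD locus presence against hyRAD matrix fullness
#'
#' A ddRAD locus is present for an individual iff, on both haplotypes,
#' both flanking recognition sites are intact and the fragment length
#' stays inside the size window (strict diploid accounting: losing either
#' allele loses the locus).  `ddrad_fullness` is the mean presence over
#' individuals x loci; `hyrad_fullness` is the realized genotype-matrix
#' fullness of the hyRAD pipeline on the same cohort, if supplied.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param size_window insert-length window in bp.
#' @param hyrad_matrix optional `hyrad_matrix` from the hyRAD pipeline.
#' @param enzA,enzB [enzyme()]s.
#' @return list with `ddrad_fullness`, `hyrad_fullness` (NA if no matrix),
#'   `presence` (individuals x loci logical matrix) and `loci`.
#' @export
ddrad_dropout_compare <- function(cohort, size_window = c(130L, 190L),
                                  hyrad_matrix = NULL,
                                  enzA = enzyme("SbfI"),
                                  enzB = enzyme("MseI")) {
  frags <- double_digest(cohort$ancestor, enzA, enzB)
  len <- frags$end - frags$start
  ends_ok <- (frags$left_end == enzA$name & frags$right_end == enzB$name) |
    (frags$left_end == enzB$name & frags$right_end == enzA$name)
  loci <- frags[ends_ok & len >= size_window[1L] & len <= size_window[2L]]
  enzymes <- setNames(list(enzA, enzB), c(enzA$name, enzB$name))
  site_of <- function(boundary, label, is_left) {
    enz <- enzymes[[label]]
    start <- boundary - enz$cut_offset
    c(start, start + nchar(enz$recognition))
  }
  inds <- names(cohort$individuals)
  presence <- matrix(FALSE, length(inds), nrow(loci),
                     dimnames = list(inds, NULL))
  for (li in seq_len(nrow(loci))) {
    ls <- site_of(loci$start[li], loci$left_end[li], TRUE)
    rs <- site_of(loci$end[li], loci$right_end[li], FALSE)
    lmotif <- enzymes[[loci$left_end[li]]]$recognition
    rmotif <- enzymes[[loci$right_end[li]]]$recognition
    for (ii in seq_along(inds)) {
      haps <- cohort$individuals[[ii]]
      ok <- vapply(haps, function(h) {
        substr(h, ls[1L] + 1L, ls[2L]) == lmotif &&
          substr(h, rs[1L] + 1L, rs[2L]) == rmotif
      }, logical(1))
      presence[ii, li] <- all(ok)
    }
  }
  hyf <- if (is.null(hyrad_matrix)) NA_real_ else matrix_fullness(hyrad_matrix)
  list(ddrad_fullness = mean(presence), hyrad_fullness = hyf,
       presence = presence, loci = loci)
}

#' Write filtered calls as VCF 4.2
#'
#' Biallelic SNP records with `GT:DP:GQ` per sample; positions converted
#' to 1-based at emission.
#'
#' @param calls a `hyrad_calls` object.
#' @param path output path.
#' @param keep optional logical vector of sites to write.
#' @export
write_vcf <- function(calls, path, keep = NULL) {
  if (is.null(keep)) keep <- rep(TRUE, nrow(calls$sites))
  s <- calls$sites[keep]
  gt <- calls$gt[keep, , drop = FALSE]
  dp <- calls$dp[keep, , drop = FALSE]
  gq <- calls$gq[keep, , drop = FALSE]
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow(gt), ncol(gt))
  gt_str[is.na(gt_str)] <- "./."
  fmt <- matrix(sprintf("%s:%d:%d", gt_str, as.integer(dp),
                        as.integer(round(ifelse(is.na(gq), 0, gq)))),
                nrow(gt), ncol(gt))
  header <- c("##fileformat=VCFv4.2",
              "##source=hyradsim",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
              '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", calls$samples), collapse = "\t"))
  body <- if (nrow(s)) {
    paste(s$contig, s$pos + 1L, ".", s$ref, s$alt,
          sprintf("%.1f", s$qual), "PASS", ".", "GT:DP:GQ",
          apply(fmt, 1L, paste, collapse = "\t"), sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a genotype matrix as TSV
#' @param matrix a `hyrad_matrix`.
#' @param path output path.
#' @export
write_matrix <- function(matrix, path) {
  out <- cbind(matrix$sites[, .(contig, pos, ref, alt)],
               as.data.table(matrix$gt))
  fwrite(out, path, sep = "\t")
  invisible(path)
}
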