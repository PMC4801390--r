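# Fixture builders and independent oracles used across the suite.

random_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# naive substring scan: all 0-based positions where motif occurs
naive_find_sites <- function(seq, motif) {
  k <- nchar(motif)
  L <- nchar(seq)
  if (L < k) return(integer(0))
  starts <- 1:(L - k + 1L)
  which(substring(seq, starts, starts + k - 1L) == motif) - 1L
}

# brute-force cut-and-split double digest: returns fragments with end labels
naive_digest <- function(seq, chrom = "c") {
  sb <- naive_find_sites(seq, "CCTGCAGG") + 6L
  ms <- naive_find_sites(seq, "TTAA") + 1L
  cuts <- c(sb, ms)
  lab <- c(rep("SbfI", length(sb)), rep("MseI", length(ms)))
  keep <- cuts > 0L & cuts < nchar(seq)
  o <- order(cuts[keep])
  cuts <- cuts[keep][o]; lab <- lab[keep][o]
  d <- duplicated(cuts); cuts <- cuts[!d]; lab <- lab[!d]
  b <- c(0L, cuts, nchar(seq))
  bl <- c("chrom_end", lab, "chrom_end")
  data.frame(chrom = chrom, start = b[-length(b)], end = b[-1L],
             left_end = bl[-length(bl)], right_end = bl[-1L],
             stringsAsFactors = FALSE)
}

# exhaustive 3-genotype diploid likelihood oracle for one sample pileup;
# bases/quals vectors, returns argmax genotype code 0/1/2 (RR first on tie)
genotype_oracle <- function(bases, quals, ref, alt) {
  e <- pmin(0.75, 10^(-quals / 10))
  use <- bases %in% c(ref, alt)
  bases <- bases[use]; e <- e[use]
  if (!length(bases)) return(NA_integer_)
  pb <- function(copies_b) (copies_b / 2) * (1 - e) + ((2 - copies_b) / 2) * (e / 3)
  ll <- vapply(0:2, function(g) {
    cb <- ifelse(bases == alt, g, 2 - g)
    sum(log(pb(cb)))
  }, numeric(1))
  which.max(ll) - 1L
}

# build a hyrad_alignments object directly from pileup row vectors
make_pileup_aln <- function(contig, cpos, base, ref, qual, sample,
                            roff5 = NULL, roff3 = NULL, strand = "+",
                            read_id = NULL) {
  n <- length(base)
  if (is.null(roff5)) roff5 <- rep(20L, n)
  if (is.null(roff3)) roff3 <- rep(20L, n)
  if (is.null(read_id)) read_id <- sprintf("r%04d", seq_len(n))
  pairs <- data.table::data.table(
    read_id = read_id, sample = sample, contig = contig, cpos = cpos,
    base = base, ref = ref, qual = as.numeric(qual),
    roff5 = roff5, roff3 = roff3, strand = strand)
  reads <- data.table::data.table(
    read_id = unique(read_id), sample = sample[match(unique(read_id), read_id)],
    contig = contig[match(unique(read_id), read_id)],
    strand = "+", start = 0L, end = 1L, score = 1L, second = NA_integer_,
    map_class = "unique", nm = 0L, rlen = 41L)
  structure(list(reads = reads, pairs = pairs, contigs = unique(contig)),
            class = "hyrad_alignments")
}

# reads tiling a locus at fixed stride, error free
tiling_reads <- function(locus, read_len, stride) {
  L <- nchar(locus)
  last <- max(1L, L - read_len + 1L)
  starts <- unique(c(seq(1L, last, by = stride), last))
  substring(locus, starts, pmin(L, starts + read_len - 1L))
}

# point substitutions at a fixed per-base rate (R-side, independent of the
# C++ error model)
mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1L]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

small_cohort_config <- function(...) {
  hyrad_config(simulate = list(genome_length = 60000, n_loci = 10L,
                               n_per_pop = 2L),
               library = list(coverage = 20), ...)
}
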