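# Read mapping onto a locus catalog, uniqueness classification, and PCR
# duplicate removal on aligned fragments.

BASES4 <- c("A", "C", "G", "T")

#' Map reads to a locus catalog
#'
#' Seed-and-extend: candidate contigs are located via exact k-mer seeds on
#' both strands; each candidate is scored by a banded alignment (match +1,
#' mismatch -1, gap -2) that is global in the read.  `map_class` is
#' `unique` iff the best score beats the second-best by at least
#' `score_margin`, `multi` if a second candidate is within the margin, and
#' `unmapped` if the best score is below `min_score_frac * read_len`.
#' Mates are aligned independently.
#'
#' @param reads reads `data.table`.
#' @param catalog catalog `data.table` (`id`, `seq`).
#' @param k seed length (default 15).
#' @param score_margin score gap defining a unique best hit (default 4).
#' @param band alignment band half-width (default 12).
#' @param min_score_frac minimal best score as a fraction of read length.
#' @return object of class `hyrad_alignments`: list with
#'   `reads` (per-read `data.table`: `read_id`, `sample`, `contig`,
#'   `strand`, `start`, `end`, `score`, `second`, `map_class`, `nm`,
#'   `rlen`) and `pairs` (per aligned base of unique reads: `read_id`,
#'   `sample`, `contig`, `cpos`, `base`, `ref`, `qual`, `roff5`, `roff3`,
#'   `strand`), plus the catalog contig ids.
#' @export
map_reads <- function(reads, catalog, k = 15L, score_margin = 4L,
                      band = 12L, min_score_frac = 0.5) {
  stopifnot(nrow(catalog) > 0L)
  quals <- phred_decode(reads$qual)
  res <- cpp_map_reads(reads$seq, quals, catalog$seq, k, score_margin,
                       band, min_score_frac)
  cls <- c("unmapped", "unique", "multi")[res$map_class + 1L]
  # 0 = unmapped: indexing with a 0-containing vector would drop entries
  contig_id <- rep(NA_character_, length(res$contig))
  mapped <- res$contig > 0L
  contig_id[mapped] <- catalog$id[res$contig[mapped]]
  rtab <- data.table(
    read_id = reads$id, sample = reads$sample,
    contig = contig_id,
    strand = ifelse(res$strand >= 0L, "+", "-"),
    start = ifelse(res$contig > 0L, res$start, NA_integer_),
    end = ifelse(res$contig > 0L, res$end, NA_integer_),
    score = ifelse(res$contig > 0L, res$score, NA_integer_),
    second = res$second, map_class = cls, nm = res$nm,
    rlen = nchar(reads$seq)
  )
  rtab[map_class == "unmapped", strand := NA_character_]
  pr <- res$pair_read
  pairs <- data.table(
    read_id = reads$id[pr], sample = reads$sample[pr],
    contig = catalog$id[res$contig[pr]],
    cpos = res$pair_cpos,
    base = BASES4[res$pair_rbase + 1L],
    ref = BASES4[res$pair_refbase + 1L],
    qual = as.numeric(res$pair_qual),
    roff5 = res$pair_roff5,
    roff3 = nchar(reads$seq)[pr] - 1L - res$pair_roff5,
    strand = ifelse(res$strand[pr] >= 0L, "+", "-")
  )
  structure(list(reads = rtab[], pairs = pairs[], contigs = catalog$id),
            class = "hyrad_alignments")
}

#' Remove PCR duplicates from alignments
#'
#' Aligned read pairs are grouped by fragment coordinates -- both fragment
#' ends (`sample`, `contig`, outer start/end) when both mates map to the
#' same contig, else the single-end coordinates plus strand -- and only
#' the fragment with the highest summed base quality is kept per group
#' (approximating Picard MarkDuplicates).  Idempotent.
#'
#' @param aln a `hyrad_alignments` object.
#' @return a `hyrad_alignments` object with duplicate fragments removed.
#' @export
remove_duplicates <- function(aln) {
  rt <- copy(aln$reads)
  mapped <- rt[map_class != "unmapped"]
  if (nrow(mapped) == 0L) return(aln)
  mapped[, stem := sub("/[12]$", "", read_id)]
  qsum <- aln$pairs[, .(qs = sum(qual)), by = read_id]
  mapped <- merge(mapped, qsum, by = "read_id", all.x = TRUE)
  mapped[is.na(qs), qs := 0]
  frag <- mapped[, {
    if (.N == 2L && uniqueN(contig) == 1L) {
      list(contig = contig[1L], fs = min(start), fe = max(end),
           fstrand = "*", qs = sum(qs))
    } else {
      list(contig = contig, fs = start, fe = end, fstrand = strand, qs = qs)
    }
  }, by = .(sample, stem)]
  frag_best <- frag[, .(keep_stem = stem[which.max(qs)]),
                    by = .(sample, contig, fs, fe, fstrand)]
  keep_ids <- rt[map_class == "unmapped", read_id]
  keep_stems <- unique(frag_best$keep_stem)
  kept_mapped <- mapped[stem %in% keep_stems, read_id]
  keep <- c(keep_ids, kept_mapped)
  structure(list(reads = rt[read_id %in% keep],
                 pairs = aln$pairs[read_id %in% keep],
                 contigs = aln$contigs),
            class = "hyrad_alignments")
}

#' Subset alignments to one sample
#' @param aln a `hyrad_alignments` object.
#' @param sample sample id.
#' @return a `hyrad_alignments` object restricted to the sample.
#' @export
subset_alignments <- function(aln, sample) {
  s <- sample
  structure(list(reads = aln$reads[sample == s],
                 pairs = aln$pairs[sample == s],
                 contigs = aln$contigs),
            class = "hyrad_alignments")
}

#' Per-sample mapping-class fractions
#'
#' @param aln a `hyrad_alignments` object.
#' @return `data.table` with `sample`, `n_reads` and fractions `unmapped`,
#'   `unique`, `multi` (summing to 1 per sample); zero rows for empty
#'   input.
#' @export
mapping_stats <- function(aln) {
  rt <- aln$reads
  if (nrow(rt) == 0L) {
    return(data.table(sample = character(), n_reads = integer(),
                      unmapped = numeric(), unique = numeric(),
                      multi = numeric()))
  }
  rt[, .(n_reads = .N,
         unmapped = mean(map_class == "unmapped"),
         unique = mean(map_class == "unique"),
         multi = mean(map_class == "multi")),
     by = sample]
}

#' Export alignments as TSV
#' @param aln a `hyrad_alignments` object.
#' @param path output path.
#' @export
write_alignments <- function(aln, path) {
  fwrite(aln$reads, path, sep = "\t")
  invisible(path)
}
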