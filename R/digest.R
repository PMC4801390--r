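# In-silico double restriction digestion and probe size selection.

#' Restriction enzyme definition
#'
#' Built-ins use the standard REBASE definitions: SbfI cuts CCTGCA^GG
#' (top-strand cut offset 6), MseI cuts T^TAA (offset 1).  Overhang
#' chemistry is not modeled; a cut is a single coordinate.
#'
#' @param name enzyme name; `"SbfI"` and `"MseI"` are built in.
#' @param recognition recognition sequence over `{A,C,G,T}` (exact match
#'   only, IUPAC ambiguity codes unsupported).
#' @param cut_offset 0-based offset of the top-strand cut within the site.
#' @return a list with class `hyrad_enzyme`.
#' @export
enzyme <- function(name, recognition = NULL, cut_offset = NULL) {
  builtins <- list(
    SbfI = list(recognition = "CCTGCAGG", cut_offset = 6L),
    MseI = list(recognition = "TTAA", cut_offset = 1L)
  )
  if (is.null(recognition)) {
    if (!name %in% names(builtins)) stop("unknown built-in enzyme: ", name)
    recognition <- builtins[[name]]$recognition
    cut_offset <- builtins[[name]]$cut_offset
  }
  recognition <- toupper(recognition)
  if (grepl("[^ACGT]", recognition)) stop("recognition must be over {A,C,G,T}")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(recognition)) {
    stop("cut_offset outside recognition site")
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset), class = "hyrad_enzyme")
}

#' Find exact recognition-site occurrences
#'
#' All and only exact occurrences, overlaps allowed; `N` never matches.
#'
#' @param seq a single DNA sequence.
#' @param enz an [enzyme()].
#' @return sorted integer vector of 0-based match start positions.
#' @export
find_sites <- function(seq, enz) {
  hits <- stringi::stri_locate_all_fixed(
    toupper(seq), enz$recognition,
    overlap = TRUE)[[1L]]
  if (is.na(hits[1L, 1L])) return(integer(0))
  as.integer(hits[, 1L]) - 1L
}

#' Double-digest a genome
#'
#' Cut coordinates are `site_start + cut_offset` for every site of both
#' enzymes; fragments are the intervals between consecutive cuts plus the
#' chromosome ends, labeled by the cutting enzyme at each boundary.  Per
#' chromosome the fragments partition the sequence exactly.
#'
#' @param genome sequence records ([seq_records()]).
#' @param enzA,enzB the two [enzyme()]s.
#' @return `data.table` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `left_end`, `right_end` (enzyme name or `"chrom_end"`).
#' @export
double_digest <- function(genome, enzA = enzyme("SbfI"), enzB = enzyme("MseI")) {
  res <- vector("list", nrow(genome))
  for (i in seq_len(nrow(genome))) {
    s <- genome$seq[i]
    L <- nchar(s)
    cutsA <- find_sites(s, enzA) + enzA$cut_offset
    cutsB <- find_sites(s, enzB) + enzB$cut_offset
    cuts <- c(cutsA, cutsB)
    lab <- c(rep(enzA$name, length(cutsA)), rep(enzB$name, length(cutsB)))
    keep <- cuts > 0L & cuts < L
    cuts <- cuts[keep]; lab <- lab[keep]
    o <- order(cuts)
    cuts <- cuts[o]; lab <- lab[o]
    # a coincident cut by both enzymes keeps the first label (enzyme A)
    dup <- duplicated(cuts)
    cuts <- cuts[!dup]; lab <- lab[!dup]
    bounds <- c(0L, cuts, L)
    blab <- c("chrom_end", lab, "chrom_end")
    nfrag <- length(bounds) - 1L
    res[[i]] <- data.table(
      chrom = genome$id[i],
      start = bounds[seq_len(nfrag)],
      end = bounds[seq_len(nfrag) + 1L],
      left_end = blab[seq_len(nfrag)],
      right_end = blab[seq_len(nfrag) + 1L]
    )
  }
  rbindlist(res)
}

#' Size-select double-digest fragments into a probe set
#'
#' Keeps exactly the fragments carrying one SbfI-type and one MseI-type end
#' (either orientation) whose insert length lies within the size window.
#' Probe sequences are genome substrings; genomic provenance is recorded.
#'
#' @param fragments output of [double_digest()].
#' @param genome the digested genome ([seq_records()]).
#' @param size_window `c(min_len, max_len)` in bp.
#' @param enzA,enzB end labels counted as the two required end types.
#' @return `data.table` of probes: `id`, `seq`, `chrom`, `start`, `end`,
#'   with the size window stored in `attr(, "size_window")`.
#' @export
select_probes <- function(fragments, genome, size_window = c(130L, 190L),
                          enzA = "SbfI", enzB = "MseI") {
  stopifnot(size_window[1L] >= 1L, size_window[2L] >= size_window[1L])
  len <- fragments$end - fragments$start
  ends_ok <- (fragments$left_end == enzA & fragments$right_end == enzB) |
    (fragments$left_end == enzB & fragments$right_end == enzA)
  keep <- fragments[ends_ok & len >= size_window[1L] & len <= size_window[2L]]
  if (nrow(keep) == 0L) {
    warning("no fragments pass size selection")
    probes <- data.table(id = character(), seq = character(),
                         chrom = character(), start = integer(),
                         end = integer())
    setattr(probes, "size_window", as.integer(size_window))
    return(probes)
  }
  gseq <- setNames(genome$seq, genome$id)
  probes <- keep[, .(
    id = sprintf("%s:%d-%d", chrom, start, end),
    seq = substr(gseq[chrom], start + 1L, end),
    chrom = chrom, start = start, end = end
  )]
  setattr(probes, "size_window", as.integer(size_window))
  probes[]
}

#' Digest one or more individual genomes and pool the probes
#'
#' Emulates generating the ddRAD probe set from several fresh individuals:
#' each haplotype is digested and size-selected independently and the union
#' of distinct probe sequences is kept (first provenance wins).
#'
#' @param genomes list of [seq_records()] (one per haplotype/individual).
#' @param size_window insert-length window in bp.
#' @param enzA,enzB [enzyme()]s.
#' @return pooled probe `data.table` as in [select_probes()].
#' @export
pool_probes <- function(genomes, size_window = c(130L, 190L),
                        enzA = enzyme("SbfI"), enzB = enzyme("MseI")) {
  all <- rbindlist(lapply(genomes, function(g) {
    select_probes(double_digest(g, enzA, enzB), g, size_window,
                  enzA$name, enzB$name)
  }))
  pooled <- all[!duplicated(seq)]
  setattr(pooled, "size_window", as.integer(size_window))
  pooled[]
}

#' Write probe intervals as BED
#' @param probes probe `data.table` from [select_probes()].
#' @param path output path.
#' @export
write_probe_bed <- function(probes, path) {
  fwrite(probes[, .(chrom, start, end, id)], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}
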