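#' @useDynLib hyradsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats prcomp kmeans rbinom rlnorm rpois runif sd setNames
#' @importFrom utils head tail
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a set of sequence records
#'
#' The basic carrier for genomes, probes and catalog contigs: a
#' `data.table` with columns `id` and `seq`.  Sequences are uppercased and
#' restricted to the alphabet `A,C,G,T,N`.
#'
#' @param id character vector of identifiers.
#' @param seq character vector of sequences (same length as `id`).
#' @return a `data.table` with columns `id`, `seq`.
#' @export
seq_records <- function(id, seq) {
  stopifnot(length(id) == length(seq))
  seq <- toupper(seq)
  if (any(nchar(seq) == 0L)) stop("empty sequence not allowed")
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N}: record ",
         id[which(bad)[1L]])
  }
  data.table(id = as.character(id), seq = seq)
}

#' Reverse complement
#' @param seq character vector of DNA sequences.
#' @return character vector.
#' @export
revcomp <- function(seq) cpp_revcomp(toupper(seq))

# ---------------------------------------------------------------------------
# PHRED arithmetic (Sanger PHRED+33 only)
# ---------------------------------------------------------------------------

#' Convert a PHRED quality to an error probability
#'
#' @param q non-negative PHRED score(s).
#' @return `10^(-q/10)`.
#' @export
phred_error <- function(q) {
  if (any(q < 0)) stop("negative PHRED quality")
  10^(-q / 10)
}

#' Decode a PHRED+33 quality string to integer qualities
#' @param qual character vector of quality strings.
#' @return list of integer vectors.
#' @export
phred_decode <- function(qual) {
  lapply(qual, function(x) utf8ToInt(x) - 33L)
}

#' Encode integer qualities as a PHRED+33 string
#' @param q integer vector (0-93).
#' @return single quality string.
#' @export
phred_encode <- function(q) {
  if (any(q < 0 | q > 93)) stop("PHRED quality out of range 0-93")
  intToUtf8(as.integer(q) + 33L)
}

# ---------------------------------------------------------------------------
# Reads
# ---------------------------------------------------------------------------

#' Construct a table of quality-scored reads
#'
#' Reads are a `data.table` with columns `id`, `seq`, `qual` (PHRED+33
#' string), `sample`, `mate` (1, 2 or NA), `provenance` (`endogenous`,
#' `contaminant` or `unknown`) and `damage` (list column of 0-based damaged
#' offsets; truth metadata for simulated reads only).
#'
#' @param id,seq,qual,sample,mate,provenance,damage column values; scalars
#'   are recycled.
#' @return a `data.table` of reads.
#' @export
quality_reads <- function(id, seq, qual, sample = NA_character_,
                          mate = NA_integer_,
                          provenance = "unknown", damage = NULL) {
  seq <- toupper(seq)
  if (any(nchar(seq) != nchar(qual))) {
    bad <- which(nchar(seq) != nchar(qual))[1L]
    stop("seq/qual length mismatch in read ", id[bad])
  }
  dt <- data.table(id = as.character(id), seq = seq, qual = qual,
                   sample = sample, mate = as.integer(mate),
                   provenance = provenance)
  if (is.null(damage)) damage <- rep(list(integer(0)), nrow(dt))
  dt[, damage := damage]
  dt[]
}

# ---------------------------------------------------------------------------
# FASTA
# ---------------------------------------------------------------------------

#' Parse FASTA text into sequence records
#'
#' @param text a single string of FASTA text, a character vector of lines,
#'   or a path to a file.
#' @return `data.table` of records (possibly empty), order preserved;
#'   wrapped sequence lines are concatenated and uppercased.
#' @export
parse_fasta <- function(text) {
  lines <- as_lines(text)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(data.table(id = character(), seq = character()))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    stop("malformed FASTA: line 1 does not start with '>'")
  }
  grp <- cumsum(is_hdr)
  ids <- sub("^>", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]), paste0,
                 character(1), collapse = "")
  full <- rep("", length(ids))
  full[as.integer(names(seqs))] <- seqs
  if (any(full == "")) {
    stop("malformed FASTA: record '", ids[which(full == "")[1L]],
         "' has no sequence")
  }
  seq_records(ids, full)
}

#' Write sequence records as FASTA
#' @param records a `data.table` with `id` and `seq`.
#' @param path output file, or NULL to return the text.
#' @param width line-wrap width (0 = no wrap).
#' @return invisibly, the text written.
#' @export
write_fasta <- function(records, path = NULL, width = 0L) {
  seqs <- records$seq
  if (width > 0L) {
    seqs <- vapply(seqs, function(s) {
      starts <- seq(1L, nchar(s), by = width)
      paste(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
            collapse = "\n")
    }, character(1))
  }
  txt <- paste0(">", records$id, "\n", seqs, collapse = "\n")
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

# ---------------------------------------------------------------------------
# FASTQ
# ---------------------------------------------------------------------------

#' Parse 4-line FASTQ text (PHRED+33) into reads
#'
#' @inheritParams parse_fasta
#' @return a reads `data.table` (see [quality_reads()]).
#' @export
parse_fastq <- function(text) {
  lines <- as_lines(text)
  if (length(lines) > 0L && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) return(quality_reads(character(), character(), character())[0])
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ: line count not a multiple of 4")
  ids <- lines[seq(1L, length(lines), by = 4L)]
  if (!all(startsWith(ids, "@"))) stop("malformed FASTQ: missing '@' header")
  ids <- sub("^@", "", ids)
  ids <- sub("\\s.*$", "", ids)
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  quals <- lines[seq(4L, length(lines), by = 4L)]
  mism <- nchar(seqs) != nchar(quals)
  if (any(mism)) stop("seq/qual length mismatch in read ", ids[which(mism)[1L]])
  mate <- rep(NA_integer_, length(ids))
  mate[endsWith(ids, "/1")] <- 1L
  mate[endsWith(ids, "/2")] <- 2L
  quality_reads(ids, seqs, quals, mate = mate)
}

#' Write reads as 4-line FASTQ (PHRED+33)
#' @param reads a reads `data.table`.
#' @param path output file, or NULL to return the text.
#' @return invisibly, the text written.
#' @export
write_fastq <- function(reads, path = NULL) {
  txt <- paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual,
                collapse = "\n")
  if (nrow(reads) == 0L) txt <- ""
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    return(readLines(text))
  }
  if (length(text) == 1L) return(strsplit(text, "\n", fixed = TRUE)[[1L]])
  text
}

# ---------------------------------------------------------------------------
# Demultiplexing
# ---------------------------------------------------------------------------

#' Demultiplex reads by inline 5' barcode on read 1
#'
#' Barcodes are inline at the 5' end of read 1 and are stripped from both
#' `seq` and `qual` on assignment.  Mate-2 reads inherit the assignment of
#' their mate (read ids `<stem>/1`, `<stem>/2`).  Reads matching no barcode
#' within `max_mismatch`, or more than one, go to the `unassigned` bin.
#'
#' @param reads reads `data.table`.
#' @param barcode_map named character vector: `barcode -> sample`.
#' @param max_mismatch maximal Hamming distance for a barcode match.
#' @return list with `assigned` (reads, `sample` filled in, barcode
#'   stripped) and `unassigned`.
#' @export
demultiplex <- function(reads, barcode_map, max_mismatch = 0L) {
  bcs <- names(barcode_map)
  bl <- unique(nchar(bcs))
  if (length(bl) != 1L) stop("barcodes must have equal length")
  dmin <- min_pairwise_hamming(bcs)
  if (length(bcs) > 1L && dmin < 2L * max_mismatch + 1L) {
    stop("barcode collision: minimal pairwise distance ", dmin,
         " < ", 2L * max_mismatch + 1L)
  }
  reads <- copy(reads)
  is_r1 <- is.na(reads$mate) | reads$mate == 1L
  pre <- substr(reads$seq, 1L, bl)
  dist <- vapply(bcs, function(b) {
    bs <- strsplit(b, "")[[1L]]
    ps <- matrix(unlist(strsplit(pre, "")), nrow = bl)
    colSums(ps != bs)
  }, numeric(length(pre)))
  if (is.null(dim(dist))) dist <- matrix(dist, nrow = 1L)
  n_ok <- rowSums(dist <= max_mismatch)
  best <- max.col(-dist, ties.method = "first")
  hit <- is_r1 & n_ok == 1L
  sample_assign <- rep(NA_character_, nrow(reads))
  sample_assign[hit] <- unname(barcode_map[best[hit]])
  # mate 2 inherits mate 1 assignment via the read-pair stem
  stem <- sub("/[12]$", "", reads$id)
  r1_map <- sample_assign[is_r1]
  names(r1_map) <- stem[is_r1]
  is_r2 <- !is.na(reads$mate) & reads$mate == 2L
  sample_assign[is_r2] <- r1_map[stem[is_r2]]
  assigned_idx <- !is.na(sample_assign)
  reads[, sample := sample_assign]
  strip <- assigned_idx & is_r1
  reads[strip, `:=`(seq = substr(seq, bl + 1L, nchar(seq)),
                    qual = substr(qual, bl + 1L, nchar(qual)))]
  list(assigned = reads[assigned_idx], unassigned = reads[!assigned_idx])
}

min_pairwise_hamming <- function(x) {
  if (length(x) < 2L) return(Inf)
  m <- do.call(rbind, strsplit(x, ""))
  best <- Inf
  for (i in seq_len(nrow(m) - 1L)) {
    for (j in (i + 1L):nrow(m)) {
      best <- min(best, sum(m[i, ] != m[j, ]))
    }
  }
  best
}

# ---------------------------------------------------------------------------
# Quality and adapter trimming
# ---------------------------------------------------------------------------

#' Quality- and adapter-trim reads
#'
#' 3' bases are removed from the first sliding window (scanning 5' to 3')
#' whose mean quality falls below `min_q`; then any read suffix that
#' exactly matches a prefix (>= 8 bases) of an adapter is removed; reads
#' shorter than `min_len` are dropped.
#'
#' @param reads reads `data.table`.
#' @param window sliding window size (>= 1).
#' @param min_q minimal mean window quality.
#' @param adapters character vector of adapter sequences.
#' @param min_len minimal surviving read length.
#' @return trimmed reads `data.table` (possibly empty).
#' @export
quality_trim <- function(reads, window = 4L, min_q = 15,
                         adapters = default_adapters(), min_len = 30L) {
  stopifnot(window >= 1L)
  if (nrow(reads) == 0L) return(reads)
  reads <- copy(reads)
  n <- nrow(reads)
  newlen <- integer(n)
  seqs <- reads$seq
  quals <- reads$qual
  for (i in seq_len(n)) {
    q <- utf8ToInt(quals[i]) - 33L
    L <- length(q)
    cut <- L
    if (L >= window) {
      cs <- cumsum(c(0L, q))
      wmeans <- (cs[(window + 1L):(L + 1L)] - cs[1L:(L - window + 1L)]) / window
      first_bad <- which(wmeans < min_q)
      if (length(first_bad)) {
        # cut at the first sub-threshold base inside the failing window, so
        # a high-quality base leading the window is kept
        ws <- first_bad[1L]
        inwin <- ws:min(L, ws + window - 1L)
        low <- inwin[q[inwin] < min_q]
        cut <- if (length(low)) low[1L] - 1L else ws - 1L
      }
    }
    s <- substr(seqs[i], 1L, cut)
    # adapter: longest read suffix equal to an adapter prefix, >= 8 bases
    sl <- nchar(s)
    for (ad in adapters) {
      maxo <- min(sl, nchar(ad))
      if (maxo < 8L) next
      for (o in maxo:8L) {
        if (substr(s, sl - o + 1L, sl) == substr(ad, 1L, o)) {
          s <- substr(s, 1L, sl - o)
          sl <- nchar(s)
          break
        }
      }
    }
    newlen[i] <- nchar(s)
  }
  reads[, `:=`(seq = substr(seq, 1L, newlen), qual = substr(qual, 1L, newlen))]
  reads[nchar(seq) >= min_len]
}

#' Default adapter sequences (Illumina read-through)
#' @return character vector.
#' @export
default_adapters <- function() {
  c(P1 = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT",
    P2 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC")
}

# ---------------------------------------------------------------------------
# Run configuration
# ---------------------------------------------------------------------------

#' Default run configuration
#'
#' Named parameter groups for every pipeline stage plus the RNG seed.
#' Serializes losslessly to JSON via [write_config()] / [read_config()].
#'
#' @param ... named overrides of the form `group$name`, e.g.
#'   `hyrad_config(capture = list(p_bg = 0.1))` replaces listed fields only.
#' @return nested named list.
#' @export
hyrad_config <- function(...) {
  cfg <- list(
    rng_seed = 1L,
    digest = list(
      enzyme_a = "SbfI", enzyme_b = "MseI",
      size_min = 130L, size_max = 190L
    ),
    simulate = list(
      genome_length = 1e6, gc = 0.42, n_loci = 30L,
      n_pops = 2L, n_per_pop = 4L,
      theta_within = 0.003, d_between = 0.01, rs_mutation_boost = 1,
      pcr_dup_rate = 0.05
    ),
    library = list(
      fresh = list(frag_mean = 300, frag_sd = 75),
      sonicated = list(frag_mean = 300, frag_sd = 60),
      museum = list(frag_mean = 80, frag_sd = 30),
      coverage = 30, read_len = 150L, seq_error = 0.001,
      contaminant_fraction = 0, p_max = 0.3, rho = 0.5
    ),
    capture = list(
      identity_threshold = 0.8, min_overlap_bp = 40L,
      p_on = 0.9, p_bg = 0.02, p_daisy = 0.3,
      daisy_chain = TRUE, flank_bp = 500L, cot1 = TRUE
    ),
    catalog = list(
      t_within = 0.91, t_among = 0.71,
      grid_within = c(0.51, 0.61, 0.71, 0.81, 0.83, 0.91, 0.93, 0.96, 0.98),
      grid_among = c(0.51, 0.61, 0.71, 0.81, 0.85, 0.88),
      extend_cycles = 30L, extend_min_overlap = 30L,
      extend_min_identity = 0.9, extend_min_support = 2L,
      extend_trim_bp = 60L,
      assembly_k = 31L, assembly_min_cov = 2L
    ),
    align = list(k = 15L, score_margin = 4L, band = 12L, min_score_frac = 0.5),
    variants = list(
      min_base_q = 13L, damage_window = 12L,
      min_qual = 30, mac_mode = "fraction", mac_fraction = 1 / 6,
      mac_absolute = 6L, min_presence = 0.5, min_depth = 6L,
      paralog_sd_mult = 3, drop_indels = TRUE, biallelic_only = TRUE
    )
  )
  mods <- list(...)
  for (grp in names(mods)) {
    if (!grp %in% names(cfg)) stop("unknown config group: ", grp)
    if (is.list(cfg[[grp]]) && is.list(mods[[grp]])) {
      for (nm in names(mods[[grp]])) cfg[[grp]][[nm]] <- mods[[grp]][[nm]]
    } else {
      cfg[[grp]] <- mods[[grp]]
    }
  }
  cfg
}

#' Write a run configuration to JSON
#' @param config nested list as from [hyrad_config()].
#' @param path output path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path JSON file written by [write_config()].
#' @return nested list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  # integers come back as numeric; coerce whole numbers for stable round-trip
  rapply(cfg, function(x) {
    if (is.numeric(x) && all(x == round(x)) && all(abs(x) < 2^31)) {
      as.integer(x)
    } else x
  }, how = "replace")
}
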