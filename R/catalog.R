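# Locus catalog construction: PCR-duplicate collapse, greedy identity
# clustering with threshold optimization (RAD-ref), read-based contig
# extension (RAD-ref-ext), and a minimal de Bruijn unitig assembler
# (assembly-ref).

#' Collapse exact duplicate sequences
#'
#' First occurrence kept, multiplicity recorded (the in-silico analog of
#' PCR-duplicate removal on unaligned reads).
#'
#' @param seqs character vector of sequences.
#' @return `data.table` with `seq`, `count`, `first` (index of the first
#'   occurrence), in first-occurrence order.
#' @export
dedupe_exact <- function(seqs) {
  if (length(seqs) == 0L) {
    return(data.table(seq = character(), count = integer(), first = integer()))
  }
  dt <- data.table(seq = seqs, idx = seq_along(seqs))
  out <- dt[, .(count = .N, first = min(idx)), by = seq][order(first)]
  out[]
}

#' Greedy identity clustering (cluster_fast emulation)
#'
#' Sequences are processed in decreasing-length order (ties lexicographic)
#' and joined to the FIRST existing centroid (in creation order) with
#' global identity >= `t`, else they found a new cluster.  Identity is
#' matches / alignment columns of an end-gap-free banded global alignment
#' (band 20% of length).  The cluster consensus is the per-column majority
#' of members star-aligned to the centroid, ties keeping the centroid
#' base.
#'
#' @param seqs character vector of sequences.
#' @param t identity threshold in (0, 1].
#' @param ids optional per-sequence identifiers carried into `members`.
#' @return list with `clusters` (`data.table`: `cluster`, `centroid`,
#'   `consensus`, `size`) and `members` (`data.table`: `seq`, `id`,
#'   `cluster`).
#' @export
greedy_cluster <- function(seqs, t, ids = NULL) {
  stopifnot(t > 0, t <= 1)
  if (length(seqs) == 0L) {
    return(list(clusters = data.table(cluster = integer(),
                                      centroid = character(),
                                      consensus = character(),
                                      size = integer()),
                members = data.table(seq = character(), id = character(),
                                     cluster = integer())))
  }
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  o <- order(-nchar(seqs), seqs)
  sorted <- seqs[o]
  cl <- cpp_greedy_cluster(sorted, t)
  members <- data.table(seq = sorted, id = ids[o], cluster = cl)
  clusters <- members[, .(centroid = seq[1L], size = .N), by = cluster]
  clusters[, consensus := vapply(cluster, function(k) {
    cpp_consensus(centroid[cluster == k], members$seq[members$cluster == k])
  }, character(1))]
  setcolorder(clusters, c("cluster", "centroid", "consensus", "size"))
  list(clusters = clusters[], members = members[])
}

#' Build a locus catalog by two-iteration clustering (RAD-ref)
#'
#' Iteration 1 clusters each sample's probe reads independently at
#' `t_within` and takes cluster consensi; iteration 2 clusters the pooled
#' consensi at `t_among`; the catalog is the iteration-2 consensus
#' sequences.
#'
#' @param per_sample_reads named list of character vectors (probe reads
#'   per sample).
#' @param t_within within-sample identity threshold (default 0.91, the
#'   optimum of the threshold scan).
#' @param t_among among-sample identity threshold (default 0.71).
#' @return a catalog: `data.table` with `id`, `seq`, `support` (iteration-2
#'   member count) and `n_reads` (total reads behind the contig); method
#'   stored in `attr(, "method")`.
#' @export
build_rad_ref <- function(per_sample_reads, t_within = 0.91, t_among = 0.71) {
  stopifnot(length(per_sample_reads) >= 1L)
  cons <- list()
  nreads <- list()
  for (s in names(per_sample_reads)) {
    reads <- per_sample_reads[[s]]
    if (length(reads) == 0L) next
    cl1 <- greedy_cluster(reads, t_within)
    cons[[s]] <- cl1$clusters$consensus
    nreads[[s]] <- cl1$clusters$size
  }
  pooled <- unlist(cons, use.names = FALSE)
  pooled_n <- unlist(nreads, use.names = FALSE)
  if (length(pooled) == 0L) {
    warning("no reads: empty catalog")
    cat <- data.table(id = character(), seq = character(),
                      support = integer(), n_reads = integer())
    setattr(cat, "method", "rad_ref")
    return(cat)
  }
  cl2 <- greedy_cluster(pooled, t_among, ids = as.character(seq_along(pooled)))
  reads_per <- cl2$members[, .(n_reads = sum(pooled_n[as.integer(id)])),
                           by = cluster]
  cat <- cl2$clusters[reads_per, on = "cluster"][
    , .(id = sprintf("locus%05d", cluster), seq = consensus,
        support = size, n_reads = n_reads)]
  cat <- cat[nchar(seq) > 0L]
  setattr(cat, "method", "rad_ref")
  cat[]
}

#' Scan clustering identity thresholds
#'
#' For each threshold, counts clusters with >= `min_cov` and
#' >= `min_cov + 1` members; the chosen threshold maximizes the first
#' count, ties broken by the second count, then by the larger threshold.
#'
#' @param seqs character vector of sequences.
#' @param grid thresholds to scan (defaults: the within-sample grid; use
#'   `grid_among()` for the among-sample grid).
#' @param min_cov primary coverage level (default 2, i.e. 2x/3x counts).
#' @return list with `scan` (`data.table`: `t`, `n_ge2`, `n_ge3`) and
#'   `chosen`.
#' @export
optimize_threshold <- function(seqs, grid = grid_within(), min_cov = 2L) {
  stopifnot(length(grid) >= 1L)
  scan <- rbindlist(lapply(grid, function(t) {
    sizes <- greedy_cluster(seqs, t)$clusters$size
    data.table(t = t, n_ge2 = sum(sizes >= min_cov),
               n_ge3 = sum(sizes >= min_cov + 1L))
  }))
  best <- scan[order(-n_ge2, -n_ge3, -t)][1L]
  if (best$n_ge2 == 0L) {
    warning("no cluster reaches the coverage level at any threshold")
  }
  list(scan = scan[], chosen = best$t)
}

#' @rdname optimize_threshold
#' @export
grid_within <- function() c(0.51, 0.61, 0.71, 0.81, 0.83, 0.91, 0.93, 0.96, 0.98)

#' @rdname optimize_threshold
#' @export
grid_among <- function() c(0.51, 0.61, 0.71, 0.81, 0.85, 0.88)

#' Extend catalog contigs with capture reads (RAD-ref-ext)
#'
#' Per contig and cycle, reads whose prefix matches the contig's 3' end
#' (or suffix the 5' end; both read orientations tried) with ungapped
#' overlap >= `min_overlap` and identity >= `min_identity` vote on the
#' overhang columns; the contig grows by the per-column majority while
#' column support >= `min_support` (majority ties freeze extension).
#' After all cycles, `trim_bp` is removed from each end and contigs of
#' length <= `2 * trim_bp` are dropped.
#'
#' @param catalog catalog `data.table` (`id`, `seq`).
#' @param capture_reads character vector of capture-library read sequences
#'   (pooled across samples).
#' @param cycles extension cycles (default 30).
#' @param min_overlap minimal ungapped overlap in bp (default 30).
#' @param min_identity minimal overlap identity (default 0.9).
#' @param min_support minimal votes per extended column (default 2).
#' @param trim_bp bases trimmed from each contig end afterwards
#'   (default 60, removing putatively low-quality ends).
#' @return extended catalog with method `rad_ref_ext`.
#' @export
extend_catalog <- function(catalog, capture_reads, cycles = 30L,
                           min_overlap = 30L, min_identity = 0.9,
                           min_support = 2L, trim_bp = 60L) {
  stopifnot(cycles >= 0L)
  reads <- c(capture_reads, revcomp(capture_reads))
  seqs <- catalog$seq
  for (ci in seq_along(seqs)) {
    contig <- seqs[ci]
    for (cyc in seq_len(cycles)) {
      grew <- FALSE
      if (length(reads)) {
        # right end
        ov <- cpp_best_overlap(contig, reads, min_overlap, min_identity, 1L)
        over <- which(ov > 0L & nchar(reads) > ov)
        if (length(over)) {
          ext <- vote_extension(substring(reads[over], ov[over] + 1L),
                                min_support)
          if (nchar(ext)) { contig <- paste0(contig, ext); grew <- TRUE }
        }
        # left end (overhang columns counted from the contig outward)
        ov <- cpp_best_overlap(contig, reads, min_overlap, min_identity, 0L)
        over <- which(ov > 0L & nchar(reads) > ov)
        if (length(over)) {
          overhang <- substr(reads[over], 1L, nchar(reads[over]) - ov[over])
          ext <- vote_extension(stringi::stri_reverse(overhang), min_support)
          if (nchar(ext)) {
            contig <- paste0(stringi::stri_reverse(ext), contig)
            grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
    seqs[ci] <- contig
  }
  out <- data.table(id = catalog$id, seq = seqs, support = catalog$support)
  if (trim_bp > 0L) {
    out <- out[nchar(seq) > 2L * trim_bp]
    out[, seq := substr(seq, trim_bp + 1L, nchar(seq) - trim_bp)]
  }
  setattr(out, "method", "rad_ref_ext")
  out[]
}

# majority vote over overhang strings aligned at column 1; stops at the
# first column with support < min_support or a tied majority
vote_extension <- function(overhangs, min_support) {
  maxlen <- max(nchar(overhangs))
  ext <- character(0)
  for (j in seq_len(maxlen)) {
    b <- substr(overhangs, j, j)
    b <- b[b %in% c("A", "C", "G", "T")]
    if (length(b) < min_support) break
    tab <- sort(table(b), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) break
    ext <- c(ext, names(tab)[1L])
  }
  paste(ext, collapse = "")
}

#' Minimal de Bruijn unitig assembly (assembly-ref)
#'
#' k-mers (from both read strands) below `min_kmer_cov` are discarded;
#' unitigs are maximal non-branching paths; contigs shorter than `k + 10`
#' are dropped.  Branching nodes terminate unitigs; no bubble popping.
#' Reverse-complement mirror unitigs are collapsed to a canonical
#' orientation.
#'
#' @param reads character vector of read sequences.
#' @param k odd k-mer size in [15, 63] (default 31).
#' @param min_kmer_cov minimal k-mer multiplicity (default 2).
#' @return catalog `data.table` (`id`, `seq`, `support` = mean k-mer
#'   coverage) with method `assembly_ref`.
#' @export
assemble_denovo <- function(reads, k = 31L, min_kmer_cov = 2L) {
  stopifnot(k %% 2L == 1L, k >= 15L, k <= 63L)
  empty <- data.table(id = character(), seq = character(), support = numeric())
  setattr(empty, "method", "assembly_ref")
  if (length(reads) == 0L) return(empty)
  reads <- c(reads, revcomp(reads))
  reads <- reads[nchar(reads) >= k]
  if (length(reads) == 0L) return(empty)
  kmers <- unlist(lapply(reads, function(s) {
    substring(s, 1L:(nchar(s) - k + 1L), k:nchar(s))
  }))
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  tab <- data.table(kmer = kmers)[, .(cov = .N), by = kmer]
  tab <- tab[cov >= min_kmer_cov]
  if (nrow(tab) == 0L) return(empty)
  km <- tab$kmer
  cov <- setNames(tab$cov, km)
  kset <- new.env(hash = TRUE, parent = emptyenv(), size = length(km) * 2L)
  for (x in km) assign(x, TRUE, envir = kset)
  has <- function(x) exists(x, envir = kset, inherits = FALSE)
  succ <- function(x) {
    sfx <- substr(x, 2L, k)
    cand <- paste0(sfx, c("A", "C", "G", "T"))
    cand[vapply(cand, has, logical(1))]
  }
  pred <- function(x) {
    pfx <- substr(x, 1L, k - 1L)
    cand <- paste0(c("A", "C", "G", "T"), pfx)
    cand[vapply(cand, has, logical(1))]
  }
  visited <- new.env(hash = TRUE, parent = emptyenv(), size = length(km) * 2L)
  contigs <- character(0)
  supports <- numeric(0)
  starts <- km[vapply(km, function(x) {
    p <- pred(x)
    length(p) != 1L || length(succ(p)) > 1L
  }, logical(1))]
  walk <- function(x) {
    path <- x
    assign(x, TRUE, envir = visited)
    repeat {
      nx <- succ(x)
      if (length(nx) != 1L) break
      if (length(pred(nx)) != 1L) break
      if (exists(nx, envir = visited, inherits = FALSE)) break
      path <- c(path, nx)
      assign(nx, TRUE, envir = visited)
      x <- nx
    }
    path
  }
  for (x in starts) {
    if (exists(x, envir = visited, inherits = FALSE)) next
    path <- walk(x)
    contigs <- c(contigs, paste0(path[1L],
                                 paste(substr(path[-1L], k, k), collapse = "")))
    supports <- c(supports, mean(cov[path]))
  }
  # isolated cycles (no branching start): walk from any unvisited k-mer
  for (x in km) {
    if (exists(x, envir = visited, inherits = FALSE)) next
    path <- walk(x)
    contigs <- c(contigs, paste0(path[1L],
                                 paste(substr(path[-1L], k, k), collapse = "")))
    supports <- c(supports, mean(cov[path]))
  }
  keep <- nchar(contigs) >= k + 10L
  contigs <- contigs[keep]; supports <- supports[keep]
  # collapse reverse-complement mirrors
  rc <- revcomp(contigs)
  canon <- ifelse(contigs <= rc, contigs, rc)
  first <- !duplicated(canon)
  out <- data.table(id = sprintf("ctg%05d", seq_len(sum(first))),
                    seq = contigs[first], support = supports[first])
  setattr(out, "method", "assembly_ref")
  out[]
}

#' Write a catalog as FASTA
#' @param catalog catalog `data.table`.
#' @param path output path.
#' @export
write_catalog <- function(catalog, path) {
  write_fasta(seq_records(catalog$id, catalog$seq), path)
  invisible(path)
}

#' Write a threshold scan as TSV
#' @param scan result of [optimize_threshold()].
#' @param path output path.
#' @export
write_threshold_scan <- function(scan, path) {
  fwrite(scan$scan, path, sep = "\t")
  invisible(path)
}
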