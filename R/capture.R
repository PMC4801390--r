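# In-solution hybridization capture: which library molecules survive
# enrichment.  On-target molecules hybridize to a probe directly;
# "daisy-chain" molecules overlap a probe's source locus (+- flank) and
# are pulled down via already-captured molecules; everything else is
# background carryover.

#' Capture enrichment model
#'
#' Hybridization stringency (temperature, SSC washes) is abstracted into
#' an identity/overlap threshold and per-class retention probabilities.
#' The `cot1` flag emulates adding Cot-1 blocking DNA, which suppresses
#' background carryover (`p_bg` 0.02 with, 0.1 without).
#'
#' @param identity_threshold minimal fractional identity of the best
#'   molecule-probe local alignment to count as on-target.
#' @param min_overlap_bp minimal alignment overlap in bp.
#' @param p_on,p_daisy,p_bg retention probabilities for on-target,
#'   flanking (daisy-chain) and off-target molecules; must satisfy
#'   `p_bg <= p_daisy <= p_on`.
#' @param daisy_chain enable the flanking class.
#' @param flank_bp flank width around a probe's source locus.
#' @param cot1 model Cot-1 blocking DNA (lowers `p_bg`).
#' @return list with class `hyrad_capture_model`.
#' @export
capture_model <- function(identity_threshold = 0.8, min_overlap_bp = 40L,
                          p_on = 0.9, p_bg = NULL, p_daisy = 0.3,
                          daisy_chain = TRUE, flank_bp = 500L, cot1 = TRUE) {
  if (is.null(p_bg)) p_bg <- if (cot1) 0.02 else 0.1
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            p_bg >= 0, p_bg <= p_daisy, p_daisy <= p_on, p_on <= 1)
  structure(list(identity_threshold = identity_threshold,
                 min_overlap_bp = as.integer(min_overlap_bp),
                 p_on = p_on, p_bg = p_bg, p_daisy = p_daisy,
                 daisy_chain = daisy_chain, flank_bp = as.integer(flank_bp),
                 cot1 = cot1),
            class = "hyrad_capture_model")
}

#' Classify library molecules against the probe set
#'
#' A molecule is `on_target` iff its best local alignment to a probe has
#' overlap >= `min_overlap_bp` and identity >= `identity_threshold`;
#' otherwise `flanking` iff daisy-chaining is enabled and the molecule's
#' source interval overlaps a probe interval +- `flank_bp` (simulated
#' molecules only); otherwise `off_target`.
#'
#' With `use_provenance = TRUE` (simulator path), alignment candidates are
#' pre-screened by source-interval overlap with the probe intervals, which
#' is exact for non-repetitive simulated genomes; with `FALSE`, candidates
#' are found by an exact k-mer screen against the probe sequences, so the
#' classifier also works on reads of unknown origin.
#'
#' @param molecules molecule `data.table` from [fragment_molecules()].
#' @param probes probe `data.table` from [select_probes()].
#' @param model a [capture_model()].
#' @param use_provenance use simulator source intervals for candidate
#'   pre-screening and the flanking class.
#' @return factor vector (`on_target`, `flanking`, `off_target`), one per
#'   molecule.
#' @export
classify_molecules <- function(molecules, probes, model = capture_model(),
                               use_provenance = TRUE) {
  n <- nrow(molecules)
  cls <- rep("off_target", n)
  if (n == 0L || nrow(probes) == 0L) {
    return(factor(cls, levels = c("on_target", "flanking", "off_target")))
  }
  has_prov <- use_provenance && all(c("chrom", "start", "end") %in%
                                      names(molecules))
  if (has_prov) {
    endo <- which(molecules$provenance == "endogenous")
    cand <- integer(0)
    cand_probe <- integer(0)
    if (length(endo)) {
      ov <- interval_overlap(molecules[endo], probes)
      cand <- endo[ov$query]
      cand_probe <- ov$subject
    }
  } else {
    hit <- cpp_kmer_screen(molecules$seq, probes$seq, 16L, 2L)
    cand <- which(hit > 0L)
    cand_probe <- hit[cand]
  }
  if (length(cand)) {
    on <- logical(length(cand))
    for (i in seq_along(cand)) {
      a <- cpp_local_align(molecules$seq[cand[i]], probes$seq[cand_probe[i]])
      on[i] <- a[["columns"]] >= model$min_overlap_bp &&
        a[["columns"]] > 0 &&
        a[["matches"]] / a[["columns"]] >= model$identity_threshold
    }
    cls[cand[on]] <- "on_target"
  }
  if (model$daisy_chain && has_prov) {
    flanked <- probes[, .(chrom, start = pmax(0L, start - model$flank_bp),
                          end = end + model$flank_bp)]
    endo <- which(molecules$provenance == "endogenous" & cls == "off_target")
    if (length(endo)) {
      ov <- interval_overlap(molecules[endo], flanked)
      cls[endo[unique(ov$query)]] <- "flanking"
    }
  }
  factor(cls, levels = c("on_target", "flanking", "off_target"))
}

# best-overlap interval join; returns query/subject index pairs, one row
# per query (the subject with maximal overlap)
interval_overlap <- function(query, subject) {
  q <- data.table(qi = seq_len(nrow(query)), chrom = query$chrom,
                  qstart = query$start, qend = query$end)
  s <- data.table(si = seq_len(nrow(subject)), chrom = subject$chrom,
                  sstart = subject$start, send = subject$end)
  setkey(s, chrom, sstart, send)
  j <- foverlaps(setnames(copy(q), c("qstart", "qend"), c("sstart", "send")),
                 s, type = "any", nomatch = NULL)
  if (nrow(j) == 0L) return(list(query = integer(0), subject = integer(0)))
  j[, ov := pmin(i.send, send) - pmax(i.sstart, sstart)]
  j <- j[order(qi, -ov)][!duplicated(qi)]
  list(query = j$qi, subject = j$si)
}

#' Enrich molecules by hybridization capture
#'
#' Each molecule is retained independently with the probability of its
#' capture class (`p_on` / `p_daisy` / `p_bg`); deterministic given
#' `seed`.
#'
#' @inheritParams classify_molecules
#' @param seed integer seed or NULL.
#' @return list with `molecules` (retained rows plus a `capture_class`
#'   column) and `report` (per-class input/retained counts).
#' @export
enrich <- function(molecules, probes, model = capture_model(), seed = NULL,
                   use_provenance = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  cls <- classify_molecules(molecules, probes, model, use_provenance)
  p <- c(on_target = model$p_on, flanking = model$p_daisy,
         off_target = model$p_bg)[as.integer(cls)]
  keep <- runif(nrow(molecules)) < p
  out <- copy(molecules)[, capture_class := cls][keep]
  report <- data.table(class = levels(cls))[
    , .(class, n_input = as.integer(table(cls)[class]),
        n_retained = as.integer(table(cls[keep])[class]))]
  report[is.na(n_retained), n_retained := 0L]
  list(molecules = out[], report = report[])
}

#' Write a capture report as TSV
#' @param report the `report` element of an [enrich()] result.
#' @param path output path.
#' @export
write_capture_report <- function(report, path) {
  fwrite(report, path, sep = "\t")
  invisible(path)
}
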