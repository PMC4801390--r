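test_that("FASTA parsing handles wrapping, order and malformed input", {
  expect_equal(parse_fasta(">a\nACGT\n")$seq, "ACGT")
  two <- parse_fasta(">a\nAC\nGT\n>b\nTT\n")
  expect_equal(two$id, c("a", "b"))
  expect_equal(two$seq, c("ACGT", "TT"))
  expect_equal(nrow(parse_fasta("")), 0L)
  expect_error(parse_fasta("ACGT\n>a\nAC"), "line 1")
  expect_error(parse_fasta(">a\n>b\nAC"), "'a' has no sequence")
})

test_that("FASTA round-trip is the identity on 1,000 seeded records", {
  set.seed(101)
  recs <- seq_records(sprintf("rec%04d", 1:1000),
                      vapply(sample(20:200, 1000, replace = TRUE),
                             random_seq, character(1)))
  for (w in c(0L, 60L)) {
    txt <- write_fasta(recs, width = w)
    back <- parse_fasta(txt)
    expect_identical(back$id, recs$id)
    expect_identical(back$seq, recs$seq)
  }
})

test_that("FASTQ decodes PHRED+33 and round-trips", {
  r <- parse_fastq("@r\nAC\n+\nII\n")
  expect_equal(phred_decode(r$qual)[[1]], c(40L, 40L))
  r0 <- parse_fastq("@r\nAC\n+\n!!\n")
  expect_equal(phred_decode(r0$qual)[[1]], c(0L, 0L))
  expect_error(parse_fastq("@r\nACG\n+\nII\n"), "read r")
  set.seed(102)
  n <- 500
  seqs <- vapply(sample(30:150, n, replace = TRUE), random_seq, character(1))
  quals <- vapply(nchar(seqs), function(L) {
    phred_encode(sample(0:41, L, replace = TRUE))
  }, character(1))
  reads <- quality_reads(sprintf("rd%03d/1", 1:n), seqs, quals, mate = 1L)
  back <- parse_fastq(write_fastq(reads))
  expect_identical(back$id, reads$id)
  expect_identical(back$seq, reads$seq)
  expect_identical(back$qual, reads$qual)
  expect_identical(back$mate, reads$mate)
})

test_that("phred_error follows the definition and rejects negatives", {
  expect_equal(phred_error(20), 0.01)
  expect_equal(phred_error(30), 0.001)
  expect_equal(phred_error(0), 1.0)
  expect_error(phred_error(-1))
})

test_that("demultiplex assigns, strips and conserves reads", {
  bc <- c(AAAAAA = "s1", CCCCCC = "s2", GGGGGG = "s3")
  reads <- quality_reads(c("x/1", "y/1", "z/1"),
                         c("AAAAAACGT", "CAAAAACGT", "TTTTTTCGT"),
                         c("IIIIIIIII", "IIIIIIIII", "IIIIIIIII"), mate = 1L)
  res <- demultiplex(reads, bc, max_mismatch = 0L)
  expect_equal(res$assigned$sample, "s1")
  expect_equal(res$assigned$seq, "CGT")
  expect_equal(res$assigned$qual, "III")
  expect_equal(nrow(res$unassigned), 2L) # Hamming-1 read and no-match read
  res1 <- demultiplex(reads, bc, max_mismatch = 1L)
  expect_setequal(res1$assigned$sample, c("s1", "s1"))
  expect_error(demultiplex(reads, c(AAAAAA = "s1", AAAAAC = "s2"),
                           max_mismatch = 1L), "collision")
})

test_that("demultiplex recovers generator truth counts on 2,000 reads", {
  set.seed(103)
  bases <- c("A", "C", "G", "T")
  repeat {
    bcs <- unique(vapply(1:20, function(i) random_seq(6), character(1)))
    bcs <- bcs[seq_len(min(8, length(bcs)))]
    ok <- TRUE
    for (i in seq_along(bcs)) for (j in seq_len(i - 1L)) {
      d <- sum(strsplit(bcs[i], "")[[1]] != strsplit(bcs[j], "")[[1]])
      if (d < 3L) ok <- FALSE
    }
    if (ok && length(bcs) == 8L) break
  }
  bc_map <- setNames(paste0("s", 1:8), bcs)
  truth_sample <- sample(paste0("s", 1:8), 2000, replace = TRUE)
  truth_bc <- names(bc_map)[match(truth_sample, bc_map)]
  payload <- vapply(1:2000, function(i) random_seq(40), character(1))
  reads <- quality_reads(sprintf("m%04d/1", 1:2000),
                         paste0(truth_bc, payload),
                         strrep("I", 46L), mate = 1L)
  res <- demultiplex(reads, bc_map, max_mismatch = 1L)
  expect_equal(nrow(res$assigned) + nrow(res$unassigned), 2000L)
  got <- table(res$assigned$sample)
  expect_equal(as.integer(got[paste0("s", 1:8)]),
               as.integer(table(truth_sample)[paste0("s", 1:8)]))
})

test_that("quality_trim implements the sliding-window and adapter rules", {
  # all-Q40, no adapter: unchanged
  r <- quality_reads("a/1", random_seq(60), strrep("I", 60L), mate = 1L)
  expect_identical(quality_trim(r)$seq, r$seq)
  # 10 trailing Q2 bases, window 4, min_q 15: removed at the window start
  q <- phred_encode(c(rep(40L, 50), rep(2L, 10)))
  r2 <- quality_reads("b/1", random_seq(60), q, mate = 1L)
  out <- quality_trim(r2, window = 4L, min_q = 15)
  expect_equal(nchar(out$seq), 50L)
  # 3' suffix equal to an adapter prefix is removed
  ad <- default_adapters()[["P2"]]
  body <- random_seq(50)
  r3 <- quality_reads("c/1", paste0(body, substr(ad, 1, 20)),
                      strrep("I", 70L), mate = 1L)
  out3 <- quality_trim(r3)
  expect_equal(out3$seq, body)
  # reads shorter than min_len are dropped
  r4 <- quality_reads("d/1", random_seq(40),
                      phred_encode(c(rep(40L, 5), rep(2L, 35))), mate = 1L)
  expect_equal(nrow(quality_trim(r4, min_len = 30L)), 0L)
})

test_that("quality_trim never lengthens reads and is idempotent", {
  set.seed(104)
  seqs <- vapply(1:200, function(i) random_seq(sample(40:150, 1)), character(1))
  quals <- vapply(nchar(seqs), function(L) {
    phred_encode(pmax(2L, pmin(41L, round(rnorm(L, 30, 12)))))
  }, character(1))
  reads <- quality_reads(sprintf("t%03d/1", 1:200), seqs, quals, mate = 1L)
  once <- quality_trim(reads)
  expect_true(all(nchar(once$seq) <=
                    nchar(reads$seq[match(once$id, reads$id)])))
  twice <- quality_trim(once)
  expect_identical(twice$seq, once$seq)
  expect_identical(twice$qual, once$qual)
})

test_that("run configuration round-trips through JSON", {
  cfg <- hyrad_config(capture = list(p_bg = 0.07),
                      simulate = list(n_loci = 17L))
  path <- tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  norm <- function(x) rapply(x, function(v) {
    if (is.numeric(v)) as.numeric(v) else v
  }, how = "replace")
  expect_equal(norm(back), norm(cfg))
  expect_equal(back$capture$p_bg, 0.07)
  expect_equal(back$simulate$n_loci, 17L)
})
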