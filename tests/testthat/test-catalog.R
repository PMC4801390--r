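test_that("dedupe_exact keeps first occurrences with multiplicities", {
  d <- dedupe_exact(c("AAA", "AAA", "BBB"))
  expect_equal(d$seq, c("AAA", "BBB"))
  expect_equal(d$count, c(2L, 1L))
  all_distinct <- dedupe_exact(c("A", "C", "G"))
  expect_equal(all_distinct$count, rep(1L, 3))
  set.seed(501)
  pool <- vapply(1:300, function(i) random_seq(60), character(1))
  mult <- sample(1:5, 300, replace = TRUE)
  reads <- sample(rep(pool, mult))
  d2 <- dedupe_exact(reads)
  expect_equal(sort(d2$count), sort(mult))
  expect_equal(sum(d2$count), length(reads))
})

test_that("greedy_cluster trivial cases", {
  same <- greedy_cluster(rep("ACGTACGTACGT", 5), 0.91)
  expect_equal(nrow(same$clusters), 1L)
  expect_equal(same$clusters$consensus, "ACGTACGTACGT")
  expect_equal(same$clusters$size, 5L)
  a <- strrep("AC", 20)
  b <- paste0(strrep("AC", 10), strrep("GT", 10))
  expect_lt(hyradsim:::cpp_identity(a, b), 0.91)
  two <- greedy_cluster(c(a, b), 0.91)
  expect_equal(nrow(two$clusters), 2L)
})

test_that("clustering at t = 1 on deduplicated input is exact grouping", {
  set.seed(502)
  seqs <- unique(vapply(1:100, function(i) random_seq(50), character(1)))
  cl <- greedy_cluster(seqs, 1.0)
  expect_equal(nrow(cl$clusters), length(seqs))
})

test_that("greedy_cluster recovers planted locus counts within 5%", {
  set.seed(503)
  loci <- vapply(1:100, function(i) random_seq(sample(150:180, 1)),
                 character(1))
  reads <- unlist(lapply(loci, function(l) {
    vapply(1:5, function(i) mutate_seq(l, 0.01), character(1))
  }))
  cl <- greedy_cluster(sample(reads), 0.91)
  expect_lte(abs(nrow(cl$clusters) - 100), 5)
  # consensus recovers the planted sequence for large clusters
  big <- cl$clusters[size >= 4]
  hits <- sum(big$consensus %in% loci)
  expect_gt(hits / nrow(big), 0.8)
})

test_that("build_rad_ref merges homologous loci across samples", {
  set.seed(504)
  loci <- vapply(1:100, function(i) random_seq(sample(150:180, 1)),
                 character(1))
  per_sample <- lapply(setNames(1:2, c("s1", "s2")), function(s) {
    variant <- vapply(loci, function(l) mutate_seq(l, 0.025), character(1))
    unlist(lapply(variant, function(l) {
      vapply(1:4, function(i) mutate_seq(l, 0.01), character(1))
    }))
  })
  cat2 <- build_rad_ref(per_sample, t_within = 0.91, t_among = 0.71)
  expect_lte(abs(nrow(cat2) - 100), 5)
  # t_among = 1.0 keeps the per-sample loci separate (oversplitting)
  cat_split <- build_rad_ref(per_sample, t_within = 0.91, t_among = 1.0)
  expect_gt(nrow(cat_split), 1.8 * nrow(cat2))
  # single sample, one locus, clean reads
  cat1 <- build_rad_ref(list(s1 = rep(loci[1L], 5)))
  expect_equal(nrow(cat1), 1L)
  expect_equal(cat1$seq, loci[1L])
  expect_warning(build_rad_ref(list(s1 = character(0))), "empty")
})

test_that("two-iteration clustering merges loci that one level splits", {
  # between-sample divergence just above the within-sample threshold's
  # tolerance: single-level clustering at t_within splits homologs, the
  # second iteration at t_among re-merges them
  set.seed(505)
  loci <- vapply(1:60, function(i) random_seq(160), character(1))
  mk <- function() {
    v <- vapply(loci, function(l) mutate_seq(l, 0.025), character(1))
    unlist(lapply(v, function(l) rep(l, 3)))
  }
  per_sample <- list(s1 = mk(), s2 = mk())
  two_it <- build_rad_ref(per_sample, 0.96, 0.71)
  one_it <- greedy_cluster(unlist(per_sample, use.names = FALSE), 0.96)
  expect_lte(abs(nrow(two_it) - 60), 3)
  expect_gt(nrow(one_it$clusters), 1.5 * nrow(two_it))
})

test_that("optimize_threshold follows the argmax and tie-break rules", {
  # one locus, 5 identical reads: every threshold gives one >=2x cluster;
  # ties resolve to the largest threshold
  one <- optimize_threshold(rep(strrep("ACGT", 40), 5), grid_within())
  expect_true(all(one$scan$n_ge2 == 1L))
  expect_equal(one$chosen, 0.98)
  # pure singletons: all counts zero, chosen = max(grid), with a warning
  set.seed(506)
  singles <- vapply(1:20, function(i) random_seq(100), character(1))
  expect_warning(res <- optimize_threshold(singles, grid_among()),
                 "no cluster")
  expect_true(all(res$scan$n_ge2 == 0L))
  expect_equal(res$chosen, 0.88)
})

test_that("threshold scan recovers planted loci under 8% noise", {
  set.seed(507)
  loci <- vapply(1:50, function(i) random_seq(160), character(1))
  reads <- unlist(lapply(loci, function(l) {
    vapply(1:5, function(i) mutate_seq(l, 0.04), character(1))
  }))
  res <- optimize_threshold(reads, grid_within())
  # recovered loci = clusters at >= 2x coverage at the chosen threshold
  sizes <- greedy_cluster(reads, res$chosen)$clusters$size
  expect_lte(abs(sum(sizes >= 2L) - 50), 5)
})

test_that("extend_catalog obeys the overlap floor and reaches flanks", {
  set.seed(508)
  source_locus <- random_seq(300)
  contig <- substr(source_locus, 101L, 200L)
  catalog <- data.table::data.table(id = "c1", seq = contig, support = 1L)
  # no reads: unchanged at trim 0
  same <- extend_catalog(catalog, character(0), trim_bp = 0L)
  expect_equal(same$seq, contig)
  # reads overlapping by exactly 29 bases never extend
  r29 <- paste0(substring(source_locus, 172L, 200L), # 29-base overlap
                substring(source_locus, 201L, 260L))
  no_ext <- extend_catalog(catalog, rep(r29, 5), cycles = 5L,
                           min_overlap = 30L, trim_bp = 0L)
  expect_equal(no_ext$seq, contig)
  # but 30 bases do extend
  r30 <- paste0(substring(source_locus, 171L, 200L),
                substring(source_locus, 201L, 260L))
  ext1 <- extend_catalog(catalog, rep(r30, 5), cycles = 5L,
                         min_overlap = 30L, trim_bp = 0L)
  expect_gt(nchar(ext1$seq), nchar(contig))
  # error-free tiling reads, trim 0: contains the seed and reaches flanks
  reads <- tiling_reads(source_locus, 60L, 7L)
  reads <- rep(reads, 3)
  full <- extend_catalog(catalog, reads, cycles = 30L, min_overlap = 30L,
                         min_identity = 1, trim_bp = 0L)
  expect_true(grepl(contig, full$seq, fixed = TRUE))
  expect_true(grepl(full$seq, source_locus, fixed = TRUE))
  expect_gt(nchar(full$seq), 250L)
  # end trimming drops short contigs entirely
  trimmed <- extend_catalog(catalog, character(0), cycles = 0L,
                            trim_bp = 60L)
  expect_equal(nrow(trimmed), 0L)
})

test_that("assemble_denovo reconstructs planted loci exactly", {
  set.seed(509)
  locus <- random_seq(500)
  reads <- rep(tiling_reads(locus, 80L, 8L), 2) # ~10x
  asm <- assemble_denovo(reads, k = 31L, min_kmer_cov = 2L)
  expect_equal(nrow(asm), 1L)
  expect_true(asm$seq == locus || asm$seq == revcomp(locus))
  # two unrelated loci -> two contigs
  locus2 <- random_seq(400)
  reads2 <- c(reads, rep(tiling_reads(locus2, 80L, 8L), 2))
  asm2 <- assemble_denovo(reads2, k = 31L, min_kmer_cov = 2L)
  expect_equal(nrow(asm2), 2L)
  recovered <- vapply(asm2$seq, function(s) {
    s %in% c(locus, locus2) || revcomp(s) %in% c(locus, locus2)
  }, logical(1))
  expect_true(all(recovered))
  # empty input
  expect_equal(nrow(assemble_denovo(character(0))), 0L)
  expect_error(assemble_denovo("ACGT", k = 30L))
})
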