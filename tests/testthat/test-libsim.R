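test_that("fragment count matches target coverage and degenerate sd", {
  set.seed(301)
  anc <- simulate_ancestor(100000, 0.42)
  haps <- list(h1 = anc$seq, h2 = anc$seq)
  cfg <- library_config("fresh", coverage = 10)
  mols <- fragment_molecules(haps, cfg, seed = 302)
  depth <- sum(mols$end - mols$start) / 100000
  expect_lt(abs(depth - 10) / 10, 0.2)
  cfg0 <- library_config("fresh", frag_sd = 0, coverage = 2)
  mols0 <- fragment_molecules(haps, cfg0, seed = 303)
  inner <- mols0[end < 100000] # end-clipped fragments excluded
  expect_true(all(inner$end - inner$start == 300L))
})

test_that("museum fragments are shorter than fresh ones", {
  set.seed(304)
  anc <- simulate_ancestor(50000, 0.42)
  haps <- list(h1 = anc$seq, h2 = anc$seq)
  mus <- fragment_molecules(haps, library_config("museum", coverage = 5))
  fre <- fragment_molecules(haps, library_config("fresh", coverage = 5))
  expect_lt(median(mus$end - mus$start), median(fre$end - fre$start))
})

test_that("apply_damage follows the geometric terminal model", {
  # p_max = 0: identity
  res0 <- apply_damage(c("CCCGGG", "ACGTACGT"), damage_model(0, 0.5),
                       seed = 305)
  expect_equal(res0$seq, c("CCCGGG", "ACGTACGT"))
  expect_true(all(lengths(res0$positions) == 0L))
  # p_max = 1, tiny rho: first C always converted
  res1 <- apply_damage(rep("CAAAAAAA", 20), damage_model(1, 1e-9), seed = 306)
  expect_true(all(startsWith(res1$seq, "T")))
  # offset rates: 10,000 molecules, p_max 0.3, rho 0.5
  set.seed(307)
  mols <- vapply(1:10000, function(i) paste0("CC", random_seq(30, 0.5), "GG"),
                 character(1))
  res <- apply_damage(mols, damage_model(0.3, 0.5))
  first <- substr(res$seq, 1L, 1L)
  secondC <- substr(res$seq, 2L, 2L)
  r0 <- mean(first == "T")
  r1 <- mean(secondC == "T")
  expect_lt(abs(r0 - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
  expect_lt(abs(r1 - 0.15), 3 * sqrt(0.15 * 0.85 / 10000))
  # 3' mirror: last base G -> A at p_max
  last <- substring(res$seq, nchar(res$seq))
  expect_lt(abs(mean(last == "A") - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("damage is strand-symmetric in aggregate", {
  set.seed(308)
  mols <- vapply(1:5000, function(i) random_seq(60, 0.5), character(1))
  res <- apply_damage(mols, damage_model(0.3, 0.5))
  ch_before <- strsplit(mols, "")
  ch_after <- strsplit(res$seq, "")
  ct0 <- ga0 <- c(num = 0, den = 0)
  for (i in seq_along(mols)) {
    b <- ch_before[[i]]; a <- ch_after[[i]]; L <- length(b)
    if (b[1] == "C") ct0 <- ct0 + c(a[1] == "T", 1)
    if (b[L] == "G") ga0 <- ga0 + c(a[L] == "A", 1)
  }
  r5 <- ct0[1] / ct0[2]; r3 <- ga0[1] / ga0[2]
  se <- sqrt(0.3 * 0.7 * (1 / ct0[2] + 1 / ga0[2]))
  expect_lt(abs(r5 - r3), 3 * se)
})

test_that("sequence_reads is exact without errors and reads through", {
  set.seed(309)
  anc <- simulate_ancestor(20000, 0.42)
  cfg <- library_config("fresh", coverage = 2, seq_error = 0)
  mols <- fragment_molecules(list(h1 = anc$seq, h2 = anc$seq), cfg)
  reads <- sequence_reads(mols, cfg)
  r1 <- reads[mate == 1L][match(mols$id, molecule)]
  r2 <- reads[mate == 2L][match(mols$id, molecule)]
  src <- substring(anc$seq, mols$start + 1L, mols$end)
  expect_identical(r1$seq, substr(src, 1L, 150L))
  expect_identical(r2$seq,
                   revcomp(substring(src, pmax(1L, nchar(src) - 149L))))
  # a molecule shorter than read_len: mates overlap fully
  short <- mols[end - start < 150L][1L]
  expect_equal(nchar(reads[molecule == short$id & mate == 1L, seq]),
               short$end - short$start)
  expect_identical(reads[molecule == short$id & mate == 2L, seq],
                   revcomp(reads[molecule == short$id & mate == 1L, seq]))
})

test_that("sequencing error count is within 3 binomial SDs", {
  set.seed(310)
  src <- vapply(1:500, function(i) random_seq(100, 0.5), character(1))
  mols <- data.table::data.table(
    id = sprintf("m%03d", 1:500), sample = "s", chrom = "c",
    start = 0L, end = 100L, hap = 1L, seq = src,
    provenance = "endogenous", damage = rep(list(integer(0)), 500))
  cfg <- library_config("fresh", coverage = 1, seq_error = 0.001,
                        read_len = 50L)
  reads <- sequence_reads(mols, cfg)
  r1 <- reads[mate == 1L][match(mols$id, molecule)]
  mism <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, r1$seq, substr(src, 1, 50)))
  expect_lt(abs(mism - 25), 3 * sqrt(25) + 3)
})

test_that("damage offsets propagate into both mates' coordinates", {
  mol <- data.table::data.table(
    id = "m1", sample = "s", chrom = "c", start = 0L, end = 60L, hap = 1L,
    seq = strrep("A", 60), provenance = "endogenous",
    damage = list(c(0L, 5L, 59L)))
  cfg <- library_config("museum", coverage = 1, seq_error = 0, read_len = 40L)
  reads <- sequence_reads(mol, cfg)
  expect_equal(reads[mate == 1L, damage][[1]], c(0L, 5L))  # within read 1
  expect_equal(reads[mate == 2L, damage][[1]], c(0L))      # 59 -> offset 0
})

test_that("spike_contaminants hits the configured fraction with truth tags", {
  set.seed(311)
  anc <- simulate_ancestor(100000, 0.42)
  cfg <- library_config("fresh", coverage = 15, contaminant_fraction = 0)
  mols <- fragment_molecules(list(h1 = anc$seq, h2 = anc$seq), cfg)
  reads <- sequence_reads(mols, cfg)[1:5000]
  expect_identical(spike_contaminants(reads, cfg), reads) # fraction 0
  cfg5 <- library_config("fresh", coverage = 15, contaminant_fraction = 0.5)
  contam <- simulate_ancestor(20000, 0.5, id = "cont")
  out <- spike_contaminants(reads, cfg5, contam, seed = 312)
  n_c <- sum(out$provenance == "contaminant")
  expect_lt(abs(n_c - 5000), 3 * sqrt(10000 * 0.25))
  expect_equal(sum(out$provenance == "endogenous"), 5000L)
  expect_error(spike_contaminants(reads, cfg5, NULL), "contaminant genome")
})

test_that("error-free undamaged reads map back exactly (round trip)", {
  set.seed(313)
  pl <- plant_rad_loci(simulate_ancestor(60000, 0.42), 6L)
  probes <- select_probes(double_digest(pl$ancestor), pl$ancestor,
                          c(130L, 190L))
  catalog <- data.table::data.table(id = probes$id, seq = probes$seq)
  cfg <- library_config("fresh", coverage = 3, seq_error = 0)
  mols <- fragment_molecules(list(h1 = pl$ancestor$seq), cfg)
  cls <- classify_molecules(mols, probes)
  on <- mols[cls == "on_target"]
  reads <- sequence_reads(on, cfg)
  aln <- map_reads(reads, catalog)
  mapped <- aln$reads[map_class != "unmapped"]
  expect_gt(nrow(mapped), 0L)
  expect_true(all(aln$pairs$base == aln$pairs$ref))
})

test_that("age maps linearly onto damage intensity", {
  expect_equal(age_to_pmax(10), 0.05)
  expect_equal(age_to_pmax(100), 0.3)
  expect_equal(age_to_pmax(55), 0.175)
  expect_equal(age_to_pmax(500), 0.3)
})
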