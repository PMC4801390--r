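test_that("rescaling formula matches the closed form and its scope", {
  # profile all zeros: untouched
  prof0 <- structure(list(r5 = rep(0, 12), r3 = rep(0, 12), K = 12L,
                          baseline5 = 0, baseline3 = 0),
                     class = "hyrad_damage_profile")
  aln <- make_pileup_aln("c", 5L, base = "T", ref = "C", qual = 40,
                         sample = "s1", roff5 = 0L, roff3 = 40L)
  same <- rescale_qualities(aln, prof0)
  expect_equal(same$pairs$qual, 40)
  # r5[0] = 0.3, T over C at offset 0, Q40 -> about 5.2
  prof <- prof0
  prof$r5[1] <- 0.3
  resc <- rescale_qualities(aln, prof)
  expect_equal(resc$pairs$qual,
               -10 * log10(0.3 + 1e-4 - 0.3 * 1e-4), tolerance = 1e-6)
  expect_lt(abs(resc$pairs$qual - 5.2), 0.1)
  # A over C is not a damage signature: untouched
  aln2 <- make_pileup_aln("c", 5L, base = "A", ref = "C", qual = 40,
                          sample = "s1", roff5 = 0L, roff3 = 40L)
  expect_equal(rescale_qualities(aln2, prof)$pairs$qual, 40)
  # offsets beyond K untouched
  aln3 <- make_pileup_aln("c", 5L, base = "T", ref = "C", qual = 40,
                          sample = "s1", roff5 = 15L, roff3 = 40L)
  expect_equal(rescale_qualities(aln3, prof)$pairs$qual, 40)
  # minus strand: contig A-over-G at 5' offset is the same signature
  aln4 <- make_pileup_aln("c", 5L, base = "A", ref = "G", qual = 40,
                          sample = "s1", roff5 = 0L, roff3 = 40L,
                          strand = "-")
  expect_lt(rescale_qualities(aln4, prof)$pairs$qual, 6)
})

test_that("damage profile recovers generator parameters", {
  set.seed(701)
  pl <- plant_rad_loci(simulate_ancestor(60000, 0.42), 8L)
  probes <- select_probes(double_digest(pl$ancestor), pl$ancestor,
                          c(130L, 190L))
  catalog <- data.table::data.table(id = probes$id, seq = probes$seq)
  cfg <- library_config("museum", coverage = 40, seq_error = 0.001)
  mols <- fragment_molecules(list(h1 = pl$ancestor$seq, h2 = pl$ancestor$seq),
                             cfg)
  mols <- mols[classify_molecules(mols, probes) == "on_target"]
  mols <- apply_damage(mols, damage_model(0.3, 0.5))
  reads <- sequence_reads(mols, cfg)
  aln <- map_reads(reads, catalog)
  prof <- estimate_damage_profile(aln)
  expect_lt(abs(prof$r5[1] - 0.3), 0.05)
  expect_lt(abs(prof$r5[2] - 0.15), 0.05)
  expect_lt(abs(prof$r3[1] - 0.3), 0.05)
  # strand symmetry of the two profiles
  expect_lt(max(abs(prof$r5[1:4] - prof$r3[1:4])), 0.05)
  # undamaged libraries show no signal above noise
  set.seed(702)
  mols0 <- fragment_molecules(list(h1 = pl$ancestor$seq), cfg)
  mols0 <- mols0[classify_molecules(mols0, probes) == "on_target"]
  reads0 <- sequence_reads(mols0, cfg)
  prof0 <- estimate_damage_profile(map_reads(reads0, catalog))
  expect_lt(max(prof0$r5), 0.01)
  expect_lt(max(prof0$r3), 0.01)
})

test_that("call_sites matches the brute-force genotype oracle", {
  # hand case: 10 ref + 10 alt reads at Q30 give a confident heterozygote
  aln <- make_pileup_aln("c", rep(3L, 20), base = rep(c("A", "G"), each = 10),
                         ref = "A", qual = rep(30, 20), sample = "s1")
  calls <- call_sites(aln)
  expect_equal(nrow(calls$sites), 1L)
  expect_equal(calls$sites$alt, "G")
  expect_equal(unname(calls$gt[1, "s1"]), 1L)
  expect_gt(calls$sites$qual, 30)
  # all-reference pileups produce no site
  ref_only <- make_pileup_aln("c", rep(4L, 8), base = "T", ref = "T",
                              qual = 35, sample = "s1")
  expect_equal(nrow(call_sites(ref_only)$sites), 0L)
})

test_that("caller equals exhaustive enumeration on 500 seeded pileups", {
  set.seed(703)
  bases4 <- c("A", "C", "G", "T")
  for (i in 1:500) {
    ref <- sample(bases4, 1)
    alt <- sample(setdiff(bases4, ref), 1)
    n <- sample(1:12, 1)
    pr <- runif(1, 0.2, 0.8)
    b <- sample(c(ref, alt), n, replace = TRUE, prob = c(pr, 1 - pr))
    q <- sample(13:40, n, replace = TRUE)
    if (!any(b != ref)) next # no candidate site
    aln <- make_pileup_aln("c", rep(7L, n), base = b, ref = ref, qual = q,
                           sample = "sX")
    calls <- call_sites(aln)
    expect_equal(nrow(calls$sites), 1L)
    oracle <- genotype_oracle(b, q, ref, alt)
    expect_identical(unname(calls$gt[1, "sX"]), oracle)
    expect_equal(unname(calls$dp[1, "sX"]), n)
  }
})

test_that("the filter cascade reproduces hand-enumerated counts", {
  samples <- paste0("s", 1:4)
  # 8 sites: 2 indels, 1 triallelic, 1 low-qual, 1 low-depth, 1 low-MAC,
  # 2 passing
  sites <- data.table::data.table(
    contig = "c", pos = 0:7, ref = "A",
    alt = c("T", "T", "C,G", "G", "T", "C", "G", "T"),
    qual = c(99, 99, 99, 10, 99, 99, 99, 99),
    is_indel = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  gt <- rbind(
    c(1L, 1L, 0L, 0L), # indel
    c(1L, 1L, 0L, 0L), # indel
    c(1L, 1L, 0L, 0L), # triallelic
    c(1L, 1L, 0L, 0L), # low qual
    c(1L, 1L, 1L, 1L), # low depth -> masked -> fails presence
    c(1L, 0L, 0L, 0L), # MAC 1 of 8 alleles: fails MAC > 8/6
    c(1L, 1L, 1L, 0L), # passes (MAC 3 > 1.33)
    c(2L, 2L, 0L, 0L)) # passes (MAC 4 == min(4,4) > 1.33)
  dp <- matrix(10, 8, 4)
  dp[5, ] <- c(10, 3, 2, 1) # three genotypes below min_depth 6
  calls <- site_calls(sites, gt, dp, samples = samples)
  res <- filter_sites(calls, filter_config())
  expect_equal(res$steps$n_sites,
               c(8L, 6L, 5L, 4L, 4L, 3L, 2L, 2L))
  expect_equal(res$matrix$sites$pos, c(6L, 7L))
  # an all-passing table is unchanged with flat counts
  ok <- site_calls(sites[7:8], gt[7:8, , drop = FALSE],
                   dp[7:8, , drop = FALSE], samples = samples)
  res_ok <- filter_sites(ok, filter_config())
  expect_true(all(res_ok$steps$n_sites == 2L))
  # absolute MAC mode: both survivors fail MAC >= 6
  res_abs <- filter_sites(calls, filter_config(mac_mode = "absolute"))
  expect_equal(res_abs$matrix$sites[, .N], 0L)
})

test_that("paralog filter honors the mean + 3 SD boundary algebra", {
  mk <- function(n) {
    site_calls(data.table::data.table(contig = "c", pos = seq_len(n) - 1L,
                                      ref = "A", alt = "T", qual = 99,
                                      is_indel = FALSE),
               matrix(1L, n, 2), matrix(10, n, 2),
               samples = c("s1", "s2"))
  }
  # uniform depths: nothing removed
  u <- paralog_filter(new_mat <- filter_sites(mk(5))$matrix, rep(10, 5))
  expect_equal(nrow(u$sites), 5L)
  # 19 sites at 10 and 1 at 100: threshold 10 + 3 * SD < 100 -> removed
  d20 <- c(rep(10, 19), 100)
  m20 <- filter_sites(mk(20))$matrix
  out20 <- paralog_filter(m20, d20)
  expect_equal(nrow(out20$sites), 19L)
  expect_false(attr(out20, "kept")[20])
  thr <- mean(d20) + 3 * sqrt(mean((d20 - mean(d20))^2))
  expect_lt(thr, 100)
  # 9 sites at 10 and 1 at 100: mean + 3 SD equals exactly 100; strict
  # inequality keeps the site
  d10 <- c(rep(10, 9), 100)
  thr10 <- mean(d10) + 3 * sqrt(mean((d10 - mean(d10))^2))
  expect_equal(thr10, 100)
  out10 <- paralog_filter(filter_sites(mk(10))$matrix, d10)
  expect_equal(nrow(out10$sites), 10L)
})

test_that("matrix fullness is the non-missing fraction", {
  gt <- matrix(c(0L, 1L, NA, 2L), 2, 2)
  expect_equal(matrix_fullness(gt), 0.75)
  expect_equal(matrix_fullness(matrix(1L, 3, 3)), 1)
  expect_error(matrix_fullness(matrix(integer(0), 0, 0)), "empty")
  set.seed(704)
  m <- matrix(sample(0:2, 2000, replace = TRUE), 100, 20)
  mask <- runif(2000) < 0.3
  m[mask] <- NA
  expect_equal(matrix_fullness(m), mean(!mask))
})

test_that("structure check separates populations and not panmixia", {
  set.seed(705)
  # two fully differentiated populations
  gt <- rbind(matrix(rep(c(0L, 2L), each = 5), 40, 10, byrow = TRUE))
  colnames(gt) <- paste0("i", 1:10)
  labels <- setNames(rep(c("A", "B"), each = 5), colnames(gt))
  res <- structure_check(gt, 2L, labels, seed = 706)
  expect_equal(res$concordance, 1)
  # panmictic: concordance stays near chance over 20 seeds
  labels20 <- setNames(rep(c("A", "B"), each = 10), paste0("j", 1:20))
  conc <- vapply(1:20, function(s) {
    g <- matrix(sample(0:2, 800, replace = TRUE, prob = c(.25, .5, .25)),
                40, 20)
    colnames(g) <- paste0("j", 1:20)
    structure_check(g, 2L, labels20, seed = s)$concordance
  }, numeric(1))
  expect_lte(mean(conc), 0.7)
  expect_error(structure_check(matrix(1L, 5, 4,
                                      dimnames = list(NULL, paste0("i", 1:4))),
                               2L),
               "degenerate")
})

test_that("ddRAD dropout accounting matches intact-site logic", {
  set.seed(707)
  pl <- plant_rad_loci(simulate_ancestor(60000, 0.42), 8L)
  # no polymorphism: every locus present in every individual
  co0 <- simulate_cohort(pl$ancestor, population_model(2, 2, 0, 0))
  dd0 <- ddrad_dropout_compare(co0)
  expect_equal(dd0$ddrad_fullness, 1)
  # with polymorphism, fullness matches the closed-form expectation
  model <- population_model(2, 2, theta_within = 0.004, d_between = 0.008,
                            rs_mutation_boost = 8)
  reps <- 12L
  obs <- numeric(reps)
  n_trials <- 0L
  for (r in seq_len(reps)) {
    co <- simulate_cohort(pl$ancestor, model, seed = 7000 + r)
    dd <- ddrad_dropout_compare(co)
    obs[r] <- dd$ddrad_fullness
    n_trials <- n_trials + length(dd$presence)
  }
  d_eff <- min(1, model$d_between * model$rs_mutation_boost)
  t_eff <- min(1, model$theta_within * model$rs_mutation_boost)
  p_clean <- (1 - d_eff) * (1 - t_eff) + d_eff * (1 / 2) # other pop's fix
  expected <- p_clean^12 # 8 SbfI + 4 MseI site positions per locus
  se <- sqrt(expected * (1 - expected) / n_trials)
  expect_lt(abs(mean(obs) - expected), 3 * se + 0.02)
})

test_that("VCF output is well-formed and 1-based", {
  sites <- data.table::data.table(contig = "c1", pos = c(4L, 9L), ref = "A",
                                  alt = "T", qual = c(50, 60),
                                  is_indel = FALSE)
  gt <- rbind(c(0L, NA), c(1L, 2L))
  calls <- site_calls(sites, gt, matrix(8, 2, 2), samples = c("s1", "s2"))
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  lines <- readLines(path)
  expect_true(any(startsWith(lines, "##fileformat=VCFv4.2")))
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 2L)
  f1 <- strsplit(body[1], "\t")[[1]]
  expect_equal(f1[2], "5") # 0-based 4 -> 1-based 5
  expect_equal(f1[10], "0/0:8:99")
  expect_equal(f1[11], "./.:8:99")
  f2 <- strsplit(body[2], "\t")[[1]]
  expect_equal(f2[10], "0/1:8:99")
  expect_equal(f2[11], "1/1:8:99")
})
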