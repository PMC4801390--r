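---
title: "hyradsim: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hyradsim: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package models

hyRAD is a reduced-representation sequencing strategy for degraded
(museum) DNA: double-digest RAD fragments from a few fresh specimens are
biotinylated and used as hybridization-capture baits to enrich shotgun
libraries from many specimens, including old, fragmented ones. Because
the *captured* molecules need not carry intact restriction sites, hyRAD
avoids the locus/allele dropout that restriction-site polymorphism causes
in classical ddRAD.

`hyradsim` implements both halves of that story as testable software:

* a **wet-lab simulator** — in-silico SbfI+MseI double digestion and size
  selection (`double_digest()`, `select_probes()`), diploid cohorts from
  diverged populations with a complete variant truth table
  (`simulate_cohort()`), shotgun fragmentation, post-mortem cytosine
  deamination, paired-end sequencing with errors, contaminant spike-ins
  (`fragment_molecules()`, `apply_damage()`, `sequence_reads()`,
  `spike_contaminants()`), and capture enrichment with on-target,
  daisy-chain and background classes (`classify_molecules()`,
  `enrich()`);
* a **native analysis pipeline** — locus catalogs by two-iteration greedy
  clustering (`build_rad_ref()`), read-based contig extension
  (`extend_catalog()`) and de-novo unitig assembly (`assemble_denovo()`);
  seed-and-extend read mapping with unique/multi classes (`map_reads()`);
  PCR duplicate removal; damage-profile estimation and base-quality
  rescaling (`estimate_damage_profile()`, `rescale_qualities()`); a
  diploid genotype-likelihood caller (`call_sites()`); the filter cascade
  (`filter_sites()`); and population-structure and dropout summaries
  (`structure_check()`, `ddrad_dropout_compare()`).

Everything is verifiable against planted ground truth: every simulated
variant, damaged base, contaminant read and PCR duplicate is recorded.

# The generative model

## Cohort

An ancestral chromosome is i.i.d. with a configurable GC fraction
(default 0.42, a typical insect nuclear composition). `plant_rad_loci()`
embeds SbfI..MseI motif pairs so that a digest yields a predictable
number of size-selectable loci; on purely random 1-Mb sequence the
expected SbfI density (~15 sites/Mb) would leave too few loci for
controlled experiments.

Variation is substitution-only, in two layers:

* **fixed differences** at per-bp rate `d_between` (default 0.01),
  private to one randomly chosen population and homozygous in all its
  members — this is what creates recoverable k = 2 structure;
* **heterozygous sites** at per-bp rate `theta_within` (default 0.003,
  within the range of insect nuclear diversity), independent per
  individual, one haplotype chosen at random.

There is no coalescent, recombination or demography: two layers are the
minimal structure the downstream statistics (PCA/k-means concordance,
allele counts) respond to. Positions inside any SbfI/MseI recognition
occurrence mutate at `rate * rs_mutation_boost`, which is how
restriction-site-disrupting polymorphism — the cause of ddRAD dropout —
is dialed in. Substitutions are re-drawn if they would *create* a new
recognition site (and dropped if no admissible base exists), so the site
census can only shrink; this keeps the closed-form dropout expectation
exact.

## Libraries, damage, capture

Fragment lengths are lognormal with mode-specific defaults: fresh and
sonicated 300 bp (the Covaris peak), museum 80 bp with SD 30 bp — the
literature gives no quantitative museum length distribution, so this is
a declared assumption exposed in `library_config()`. Fragment starts are
uniform; the molecule count is chosen so expected depth equals
`coverage` (default 30x per sample).

Deamination is a two-parameter geometric profile: a C at 5' offset *i*
becomes T with probability `p_max * rho^i`, mirrored as G→A from the 3'
end (both strands are ligated). Defaults `p_max = 0.3`, `rho = 0.5`
reproduce the monotone terminal enrichment that mapDamage detects,
without the full overhang model. `age_to_pmax()` maps specimen age
linearly between configurable endpoints (0.05 at 10 y to 0.30 at 100 y);
no quantitative age-damage curve is claimed beyond monotonicity.

Capture assigns each molecule a class and retains it with a per-class
probability: `on_target` (best local alignment to a probe with >= 40 bp
overlap and >= 0.8 identity; retained at `p_on` = 0.9), `flanking`
(source interval within 500 bp of a probe locus, the "daisy-chain"
effect; `p_daisy` = 0.3) and `off_target` (`p_bg` = 0.02 with Cot-1
blocking, 0.1 without). These probabilities are stand-ins for
hybridization stringency, chosen so default simulations sit in the
qualitative regime the protocol produces — most retained reads
off-target — not to match any printed number. Reads are 150 bp
paired-end; museum molecules shorter than the read length are read
through entirely, so mates overlap fully — which doubles the effective
observation count and is why terminal damage appears at both read ends.

# Analysis-side numerical choices

**Clustering identity.** Identity is matches / alignment columns of a
banded global alignment with terminal-gap columns excluded (the vsearch
`iddef 2` convention). Alignment scores are deliberately gap-averse
(match +2, mismatch −4, flat gap −16, comparable to vsearch's gap-open
20): with cheap gaps, score-optimal paths on *unrelated* sequences reach
~55% identity, above the lowest grid threshold (0.51), and unrelated
loci would co-cluster. The simulator plants no indels, so true cluster
members never need internal gaps. `cluster_fast` emulation is
length-sorted, first-match (not best-match) assignment; consensus is a
star alignment to the centroid with ties kept as the centroid base.

**Threshold optimization.** For each grid threshold the scan counts
clusters with >= 2 and >= 3 members; the chosen threshold maximizes the
first count, breaking ties by the second and then by the larger
threshold. How the two coverage curves combine is not specified by the
protocol literature; this argmax/tie-break rule is a package decision.
"Recovered loci" at a threshold means clusters with >= 2x coverage — the
same quantity the scan maximizes; a total count including singletons
would over-count split remnants at high thresholds.

**Two-iteration robustness.** The second clustering iteration (pooled
per-sample consensi at `t_among` = 0.71) merges homologous loci whose
between-sample divergence exceeds what `t_within` tolerates. Note the
contrast only exists when divergence > 1 − `t_within`: at the default
`t_within` = 0.91 a 3% divergence is merged by single-level clustering
too; the property tests therefore demonstrate the split/merge contrast
at `t_within` = 0.96 with 5% divergence.

**Mapping.** Candidates come from exact 15-mer seeds on both strands;
each candidate diagonal is scored by a banded alignment (match +1,
mismatch −1, gap −2) that is *global in the read*, with soft clipping
allowed only where the read runs off a contig end. This is a deliberate
middle course: fully local alignment would clip terminal damage
mismatches (destroying the damage profile that rescaling depends on),
while strict end-to-end alignment would reject the many reads
overhanging the short (~160 bp) RAD contigs and starve fresh-sample
depth. A read maps `unique` when the best score beats the second-best by
>= 4 (the "close scores" margin; the source protocol states no MAPQ
cutoff), `multi` when a second candidate is within the margin, and
`unmapped` below half the read length in score. Mates are mapped
independently; pairing is used for duplicate grouping and as a
diagnostic only.

**Damage estimation and rescaling.** The profile is the excess C→T rate
per 5' offset (and G→A per 3' offset) over the baseline rate at offsets
>= K = 12, floored at zero, computed in read orientation so both strands
contribute. The pipeline estimates and rescales per sample, as
mapDamage2.0 is run per sample; fresh samples show a flat profile and
are untouched. A damage-signature base with excess rate r is rescaled to
`Q' = min(Q, -10 log10(r + eps - r*eps))` with `eps = max(10^(-Q/10),
1e-4)`; the floor prevents `Q' > Q` at tiny rates, and bases with r = 0
are never touched. Rescaled damage bases fall below the caller's
base-quality floor (13) and stop generating candidate sites — the
mechanism behind the >= 5-fold reduction in damage-shaped false
positives the acceptance suite asserts.

**Calling.** Diploid genotype likelihoods use
`P(b | g) = (c_b/2)(1−e) + ((2−c_b)/2)(e/3)` with a flat prior; site
quality is the PHRED probability that every sample is homozygous
reference. The caller is deliberately simple (no allele-frequency prior,
no haplotype model) so that an exhaustive 3-genotype enumeration can
serve as an oracle on every pileup.

**Filter cascade.** Fixed order: indels; biallelic; site quality > 30
(strict); per-genotype depth < 6 set missing (the vcftools `minDP`
reading of "minimum depth of 6" — site-level depth is available as a
config alternative); presence >= 50%; minor allele count > 1/6 of called
alleles (or >= 6 in `absolute` mode, the grasshopper variant); paralog
removal at site mean depth > mean + 3 SD (population SD, strict
inequality — at n = 10 with a single outlier the threshold equals the
outlier exactly and the strict inequality keeps it, an algebraic
boundary the tests pin down).

**Dropout accounting.** A ddRAD locus is present for an individual only
if both flanking recognition sites are intact on *both* haplotypes
(losing one allele corrupts the genotype, so strict diploid accounting
is used); under the generator the per-individual presence probability is
`((1−d_eff)(1−t_eff) + d_eff (n_pops−1)/n_pops)^12` over the 12 site
positions, which the tests check within sampling error. hyRAD fullness
on the same cohort is the realized genotype-matrix fullness of the full
pipeline; it exceeds ddRAD presence in every seeded replicate because
capture does not require intact sites.

# What a green test does and does not establish

The generator's world is favorable in known ways: no repeats (the paper
explicitly could not separate background carryover from repeat-driven
capture, and neither can a simulator without repeats), no indels by
default, no coverage biases beyond uniform sampling, no coalescent
structure, and contaminants from an unrelated random genome rather than
real fungal/bacterial sequence. Green end-to-end tests therefore
establish internal correctness — the pipeline recovers what the
simulator planted, damage handling suppresses exactly the artifact class
it targets, capture accounting is monotone in its parameters — not
concordance with any particular empirical dataset. The printed results
of the original study depend on undeposited reads and are out of scope
by design.

# Reproducibility

Every stochastic operation accepts a seed or draws from R's seeded
stream; `hyrad_end_to_end()` is bit-reproducible for a given config and
seed. The C++ kernels use R's RNG, so `set.seed()` governs them too.
Configurations round-trip through JSON (`write_config()` /
`read_config()`).
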