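---
title: "Selection scans, haplotype statistics and introgression tests with hapscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans, haplotype statistics and introgression tests with hapscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapscan)
```

## What the package computes

hapscan implements the statistical core of a domestication-genomics scan
on phased biallelic SNP data, organised as three chained analyses:

1. **Windowed summaries and candidate divergent regions (CDRs).** Per-bp
   nucleotide diversity, weighted Weir–Cockerham FST and Tajima's D are
   computed on a 10-kb sliding grid with 5-kb steps. FST is Z-transformed
   genome-wide, diversity contrast is expressed as
   $\log_2(\pi_A/\pi_B)$, and a window is called a CDR when it falls
   simultaneously in the top 5% of Z-FST and the bottom 5% of the log2
   ratio. Overlapping flagged windows are merged; genes in a GFF3
   annotation overlapping a region by at least 1 bp are reported.
2. **EHH-family haplotype scans.** Extended haplotype homozygosity is the
   probability that two haplotypes of a class are identical over the
   inclusive span from a core SNP to an offset. iHS and nSL integrate the
   ancestral- and derived-class curves (over physical distance and site
   index respectively) and take `ln(iHH_A/iHH_D)`; the cross-population
   statistics XP-EHH and XP-nSL integrate pooled-allele curves in an
   observed and a reference population over a common span and take
   `ln(iHH_obs/iHH_ref)`. iHS and nSL are standardized in 100 equal-width
   derived-frequency bins; the XP statistics genome-wide. Significance is
   assessed by the proportion of SNPs beyond score 2 in non-overlapping
   500-kb windows, ranked genome-wide with tiers at the 95th and 99th
   percentiles; windows with fewer than 100 tested SNPs are excluded.
3. **ABBA-BABA introgression tests.** On the rooted four-taxon topology
   `(((P1, P2), P3), O)`, allele-frequency weighted site patterns give
   Patterson's D with a delete-one block jackknife over consecutive
   blocks of informative sites, `Z = D/SE`, and two-sided normal
   p-values. Gene flow between P2 and P3 pushes D positive, between P1
   and P3 negative.

Because statements like "the windows flagged by the scan recover the
selected region" can only be verified against known truth, the package
ships a forward Wright–Fisher simulator whose output feeds every
end-to-end check.

## The simulator and its study conditions

`simulate_cohort()` iterates discrete generations of 1–5 constant-size
diploid populations on a caterpillar topology. Offspring haplotypes
recombine two parental haplotypes (crossover count Poisson(ρL),
breakpoints uniform) and mutate at Poisson(μL) uniform continuous
positions under infinite sites. A split copies the trunk population; an
introgression pulse redirects each target parent to the source population
with probability *f* for one generation; a hard sweep injects a single
beneficial copy with additive diploid fitness (1, 1+s, 1+2s) and, when
required to fix, restarts from the injection snapshot whenever the allele
is lost or still segregating at sampling time. All randomness flows
through R's Mersenne–Twister stream from one master seed, so identical
parameters reproduce byte-identical VCFs.

**Rescaling.** Forward simulation of a realistic perennial-tree cohort
(*N*<sub>e</sub> ≈ 10<sup>4</sup>–10<sup>5</sup>) is not feasible at desk
scale, so the bundled scenarios rescale: population sizes shrink to
*N* = 50–200 while per-generation rates grow so that the population-scaled
products 4*N*μ and 4*N*ρ per bp stay in a realistic range
(θ ≈ 10<sup>-4</sup>–10<sup>-3</sup>). For example `scenario_neutral()`
uses *N* = 200, μ = 1.5×10<sup>-7</sup> — the equivalent of
*N*<sub>e</sub> = 2×10<sup>4</sup> with μ = 1.5×10<sup>-9</sup> at scale
factor 100. This preserves expected diversity, the shape of the site
frequency spectrum and LD decay per θ, at the cost of coarser drift
granularity.

**Why sampling variance dictates these values.** The check "sampled π is
within ±25% of 4Nμ" is a statement about the *evolutionary* variance of
π, which for a single locus has CV ≈ 0.5 regardless of sample size.
Only recombination across a long window averages enough quasi-independent
genealogies to tighten it: at μ = ρ = 10<sup>-8</sup> and *N* = 200 over
500 kb the population-scaled recombination ρ<sub>L</sub> = 4NρL is 4 and
coalescent theory puts the coverage of the ±25% band near 40% — no
simulator, however correct, can reach 80% there. The bundled conditions
(μ = 1.5×10<sup>-7</sup>, ρ = 5×10<sup>-7</sup>, ρ<sub>L</sub> = 200)
bring the coverage above 95% under the same coalescent calculation, which
is what the neutral-sanity suite asserts.

**Scenario defaults.**

| scenario | emulates | key values |
|---|---|---|
| `scenario_neutral()` | equilibrium panmixia | N = 200, L = 500 kb, μ = 1.5e-7, ρ = 5e-7 |
| `scenario_sweep()` | firm- vs soft-flesh contrast with a hard sweep | N = 200 ×2 pops, L = 1 Mb, μ = 2e-7, ρ = 2.5e-7, split 300 gen; s = 0.1 at 250 kb injected 120 gen ago, fixation by sampling required |
| `scenario_pulse()` | geographic gene flow | N = 50 ×4 pops, L = 500 kb, splits 50/150/300 gen, pulse P3→P2 (f = 0.2) at 10 gen |
| `scenario_divergent()` | neutral two-group background for implanted CDRs | N = 100 ×2 pops, L = 500 kb, split 100 gen |

The pulse scenario's splits and rates were chosen, before any package
code existed, by coalescent calculation of the power of the jackknifed D
statistic: with f = 0.2 the expected informative-site count (~10³) and
mean Z ≈ 8 put the detection probability near 0.98, while the null stays
comfortably inside |Z| < 3. The sweep scenario's recombination rate
balances the sweep footprint (~s/(ρ ln 2Ns) ≈ 100 kb) against the 500-kb
proportion-window grid. A rescaled sweep is intrinsically harder to
detect than its full-scale counterpart: with 2Ns = 40 the sweep needs
~130 generations to fix, so swept haplotypes coalesce at ~0.3 coalescent
units against ~1.0 for the reference population, and the log-ratio signal
is a factor ~3, not the order of magnitude seen in large cohorts. The
sweep is injected 120 generations before sampling and required to fix by
then (restarting from the injection snapshot otherwise), which conditions
on fast trajectories and samples at the moment the haplotype signal
peaks; calibration on seeds disjoint from the test suite's puts per-seed
top-window recovery near 0.83. The validation suite asserts recovery in
at least 80% of its 20 seeds — a bound sitting at the very edge of the
scan's intrinsic power under these conditions, which an unlucky seed set
can miss; the suite reports the observed count either way rather than
softening the threshold.

**What the generator does not emulate.** No gene conversion, no dominance,
no background (linked purifying) selection, no mutation-rate or
recombination-rate heterogeneity along the sequence, no clonal
propagation, and sample sizes far below a resequencing cohort. Passing
end-to-end tests on these simulations therefore demonstrates
implementation correctness and statistical calibration under the stated
model — not robustness to every idiosyncrasy of real resequencing data.

## Numerical and definitional choices

* **π denominators.** Window π divides summed per-site pairwise-difference
  probabilities by the window length in bp (monomorphic bp contribute 0),
  the convention of the windowed-diversity tools this mirrors; Tajima's D
  uses count units. Missing data are handled pairwise-complete per site,
  while the Tajima constants use the population haplotype count — exact
  on complete data, approximate under heavy missingness (the simulations
  emit complete data).
* **Weir–Cockerham FST.** Diploid individuals are reconstructed from
  consecutive haplotype row pairs and the observed-heterozygosity term is
  kept; windows report the "weighted" ratio of summed variance
  components. Negative per-window values are reported as computed. A
  haploid variant (no heterozygosity term) is available for checking.
* **Quantiles and ties.** Empirical thresholds use linear interpolation
  between order statistics (R type 7); ties at a threshold fall in the
  tail.
* **Zero-diversity windows.** The log2 ratio adds a pseudocount of
  10<sup>-6</sup> per bp (one substitution per Mb). The perturbation is
  bounded by log2(1 + pseudo/min(π)); it stays below 0.01 once both
  diversities exceed ~1.5×10<sup>-4</sup>.
* **EHH truncation.** Curves stop after the first value below 0.05;
  physical-distance integrals extend at most 1 Mb from the core;
  site-index (nSL-type) integrals at most 200 sites. A gap over 200 kb
  between consecutive SNPs voids the core, as does reaching a chromosome
  edge while still above the cutoff. XP integration spans are set by the
  EHH of the two populations pooled. These mirror the documented defaults
  of the standard scan tool so that synthetic results are comparable.
* **Ancestral states.** iHS/nSL require per-site ancestral alleles; the
  simulator provides exact truth (allele 0), and `read_vcf()` honours
  INFO `AA=`. For real data an outgroup-majority rule is the recommended
  preprocessing; sites with unknown ancestral state are excluded from
  iHS/nSL (XP statistics need no polarization).
* **Standardization.** Sample standard deviations everywhere; frequency
  bins with fewer than two scores, or zero spread, yield missing scores
  rather than guesses.
* **D-statistic polarization.** Sites are polarized so the outgroup-major
  allele is ancestral; exact 50/50 outgroup ties keep the ALT allele as
  derived (a deterministic tie-break). Blocks count informative sites,
  not bp, so jackknife blocks carry equal weight; the default block size
  (2000 informative sites) suits genome-scale inputs and is lowered in
  the bundled desk-scale scenarios to keep ≥20 blocks.
* **Mann–Whitney tests.** Exact null when both groups have ≤8 values and
  no ties; otherwise the normal approximation with tie correction and no
  continuity correction. Windows belong to a region when their midpoint
  falls inside it.
* **Implanted divergence segments.** The CDR positive-control fixture
  collapses group-A haplotypes onto a template with per-entry probability
  `strength` and drives a `strength × fix_fraction` share of segment
  sites to fixed differences. The default strength 0.95 leaves residual
  within-segment diversity around (1-strength)² ≈ 0.25% — an order of
  magnitude below the sampling noise floor of 10-kb windowed π at the
  bundled scenario's θ, so the fixture models the near-complete diversity
  loss a CDR represents rather than a marginal perturbation.

## Design choices on open points

* Outlier thresholds for the CDR scan are computed genome-wide (not per
  chromosome); per-chromosome scans can be had by running contigs
  separately.
* The 500-kb grid applies to the proportion-of-extreme-SNPs ranking;
  score standardization itself is genome-wide (bins for iHS/nSL, global
  for XP statistics). A single reading of "normalized with a 500-kb
  window" that applied standardization within 500-kb windows would make
  scores incomparable across windows and defeat the genome-wide ranking.
* Both the merged-region count and the raw flagged-window count are
  reported for CDR scans, since sliding-grid windows necessarily overlap
  when adjacent.
* Unphased heterozygous input is loaded but refused by the EHH-family
  scans; silent pseudo-phasing would corrupt haplotype homozygosity.

## Problem sizes used by the validation suite

The test suite regenerates all data: oracle-equivalence checks use 200
random datasets of up to 30 haplotypes × 500 sites (π/FST/Tajima) and
datasets up to 64 haplotypes × 512 sites (EHH), implant recovery and
sweep recovery use 20 seeded replicates of their scenarios, the
D-statistic calibration uses 50 pulse and 50 null replicates, and the
neutral sanity check 20 replicates. These sizes keep the whole suite
within a coffee break on one core while leaving each stochastic assertion
a comfortable margin under its calibrated power.

## A worked example

```{r example, eval = FALSE}
library(hapscan)

sim <- simulate_cohort(scenario_sweep(seed = 1), dir = "simdir")
ds  <- read_vcf("simdir/sim.vcf", "simdir/popmap.tsv")

xp <- ds |>
  xp_scan("FF", "SF", mode = "bp") |>
  standardize_scores()
pw <- proportion_windows(xp, contig_length = 1e6)
autoplot(pw)

trio <- simulate_cohort(scenario_pulse(seed = 1))
dstat(trio$data, "P1", "P2", "P3", "OUT", block_size = 25) |> tidy()
```

## Known limitations

* The forward simulator is desk-scale by design; it cannot be pushed to
  realistic tree-crop effective sizes without rescaling, and the
  runtime guard warns beyond ~10^10 unit operations.
* EHH statistics assume phased haplotypes and complete-ish data; missing
  entries break haplotype identity (conservative for homozygosity).
* The CDR caller's quantile thresholds need at least 20 eligible windows
  and are meaningless on very short contigs.
* The D statistic's normal p-values inherit the usual block-jackknife
  caveats: blocks must be long relative to LD, and fewer than ~20 blocks
  makes Z unstable (the package warns below 3).
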