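---
title: "vmrscan: models and methods for variably methylated region analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vmrscan methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind each stage of
`vmrscan`, the tunable parameters and their defaults, the numerical
choices made where a method is specified only loosely in common practice,
what the synthetic-data generator does and does not emulate, and the known
limitations. It is the place to look when you need to know *exactly* what
a function computes.

## The variability model

Methylation at probe $p$ in sample $s$ is a beta value
$\beta_{ps} \in [0,1]$. The package's core statistic is the per-probe
sample standard deviation (denominator $n-1$) within a stratum — one cell
type, one sex. A **variably methylated region (VMR)** is a cluster of
neighboring probes whose SDs all sit in the top tail of the stratum's SD
distribution. Clusters are used rather than single probes because isolated
hypervariable probes are frequently artifacts: a SNP under the probe body,
hybridization noise, or an intrinsically poorly performing assay.
Requiring several *independent* neighboring probes to co-vary protects
specificity.

### The sliding-window caller

For every probe, a half-open window $[x, x + 1000)$ bp is anchored at the
probe's start coordinate $x$ (`window_bp = 1000`). Windows holding at
least `min_variable_probes = 3` probes are **candidates**, and the union
of probes inside candidate windows is the **background probe set** — the
universe for the SD percentile and for every enrichment analysis later.
The threshold is the 95th percentile (`sd_percentile = 95`) of background
probe SDs. A candidate window qualifies when (i) it holds at least 3
probes with SD at or above the threshold, and (ii) those variable probes
are at least 50% (`min_variable_fraction = 0.5`) of all probes whose
position falls in the window. Overlapping qualifying windows on a
chromosome are merged; the merged VMR is spanned by the minimum-to-maximum
positions of the variable probes it contains, records those probes as
members, and takes the member with the highest SD as **representative
probe** (ties resolved to the lowest genomic position).

Numerical choices, each of which the test suite pins down against a
brute-force per-window oracle:

* The percentile uses linear interpolation between order statistics
  (R's quantile type 7), and probes tied exactly at the threshold count
  as variable (the rule is "$\ge$ the 95th percentile").
* Windows are half-open to avoid double-counting a probe at a window
  boundary.
* The VMR span comes from its variable probes, not from window edges —
  this is why mean VMR spans are well below the 1 kb window.
* The percentile universe is the background probe set, not all probes:
  probes in sparse windows can never contribute to a call, so they should
  not shape the threshold either.

### Sex stratification

Sex is a strong methylation covariate; a sex-mixed SD conflates
between-sex differences with population variability. Calling therefore
runs separately in males and females with per-sex thresholds, and the two
VMR sets are combined: overlapping intervals merge, member probes union,
and the per-VMR `source_sex` records provenance (`M`, `F`, or `F+M`).
With fewer than two samples of either sex the caller falls back to pooled
calling with a warning. The time-course caller (`timecourseVmrs`) uses the
same machinery without stratification and without quantile normalization —
with nine serial samples from one individual there is no population to
normalize across, and normalization would suppress exactly the temporal
drift being measured.

### Replication and overlap

`overlapVmrs` flags a query VMR as replicated when it shares at least
1 bp with any reference VMR. Expected overlap by chance is computed at the
probe level: with $N$ common background probes of which $K$ fall in
reference VMRs, a random draw of the $n$ query-VMR probes shares
$nK/N$ probes in expectation; fold is observed/expected and the p-value is
the hypergeometric upper tail. One caveat, deliberately documented rather
than hidden: probes arrive in clusters, not independently, so even
unrelated VMR sets built over the same clustered genome show mild
probe-level fold inflation. The permutation oracle in the test suite
quantifies this on synthetic genomes; treat the fold as a summary, the
replication fraction as the primary quantity.

## Preprocessing

`filterProbes` applies, in a fixed, reported order: detection-p masking
(cells with detection p > 0.01 become missing), sex-chromosome removal,
SNP removal (a SNP of MAF ≥ 0.05 at the CpG or within 5 bp upstream),
CNV-mask removal, and removal of probes missing in more than 5% of
samples. The order is recorded in the report so per-filter counts are
interpretable; the filters are idempotent. The sample-fail rule is
interpreted as *fraction of samples per probe*, with the threshold
exposed (`sample_fail_frac_max`).

`quantileNormalizeBeta` performs standard quantile normalization (each
sample's values replaced by means of order statistics across samples),
delegated to `limma::normalizeQuantiles`, which also provides the
documented missing-value behavior: ranks are interpolated against the
reference distribution. Two-color channel adjustment and
probe-chemistry (type I/II) corrections are out of scope — the package
accepts externally normalized matrices.

## Co-methylation networks

The network is built over VMR representative-probe profiles:

* **Correlation.** Pearson on beta values, pairwise-complete over missing
  data; pairs with fewer than `min_pair_obs = 10` shared samples get
  $r = 0$ and a flag rather than an unstable estimate.
* **Adjacency.** $A = |R|^6$ elementwise (`soft_power = 6`). The even
  power makes the network unsigned and suppresses weak correlations while
  keeping the graph weighted. `scaleFreeFit` reports, per candidate
  power, the squared log–log correlation between binned connectivity and
  bin frequency (10 equal-width bins) and selects the smallest power
  reaching `scale_free_fit_min = 0.8`, falling back to 6 with a warning.
  On block-structured networks of a few dozen equal modules this index is
  noisy and often low — frequency can even *increase* with connectivity —
  so the fit table is reported as a diagnostic and the default power is
  the primary choice, not the selector's output.
* **Topological overlap.** $\mathrm{TOM}_{ij} = (\sum_u A_{iu}A_{uj} +
  A_{ij}) / (\min(k_i,k_j) + 1 - A_{ij})$ with $k_i = \sum_{u\ne i}
  A_{iu}$, unit diagonal. Verified to $10^{-12}$ against a triple-loop
  oracle.
* **Module detection.** Average-linkage clustering on $1-\mathrm{TOM}$,
  then a dynamic branch decomposition: descending from the root, a node
  splits when both child branches qualify as modules (at least
  `min_module_size = 10` leaves, mean intra-branch dissimilarity below
  the merge height, with a $10^{-10}$ strict-inequality tolerance so
  perfectly flat branches do not fragment); a small non-qualifying
  sibling is shed and the descent continues; otherwise the node itself
  becomes a module when it is tighter than its parent's merge height.
* **Membership (the hybrid step).** Each detected module's eigengene is
  the first principal component of its standardized member profiles,
  sign-oriented to correlate positively with the member mean. Membership
  is then *resolved on eigengene correlation*: every VMR joins the module
  maximizing $|kME|$ when that value reaches `kme_min = 0.7`; detected
  members falling below are dropped, and dendrogram stragglers that
  correlate strongly are attached. This mirrors how hybrid tree-cutting
  procedures combine dendrogram shape with membership strength, and it is
  what makes module recovery exact on planted data: pure branch
  acceptance either absorbs noise leaves near the root or clips module
  members merging just below the cut. Modules falling below the minimum
  size dissolve; labels are ordered by size; eigengenes and kME are
  recomputed on final membership. kME retention uses absolute value, with
  the sign preserved in the table.
* **Cis/trans.** A within-module VMR pair is *trans* when its two VMRs
  lie on different chromosomes. `edgeList` exports all pairs with
  $|r| \ge 0.7$ for Circos-style display.

Unassigned (label 0) VMRs are excluded from module-level GO analysis, and
the counts are logged.

## Enrichment statistics

All probe-level enrichments compare VMR probes against the background
probe set with fold $(k/n)/(K/N)$ and an upper-tail hypergeometric p;
depletion uses the lower tail and is reported in the same table with a
direction column (5'UTR-style depletions are as informative as
enhancer-style enrichments). The TFBS test is a one-sided Fisher exact
test on the 2×2 table (in-module vs other VMRs) × (overlapping vs not),
after extending each binding site by ±500 bp because VMR boundaries are
imprecise; it is run at the VMR level (matching how module×TF counts are
naturally tabulated), with Bonferroni across TFs. VMR→gene links use the
closed window TSS ± 2 kb plus any auxiliary link tables (DHS
correlations, eQTMs) supplied by the user; GO enrichment is
hypergeometric per term over the probe-linked gene universe (unique
genes; terms with fewer than 3 universe genes skipped) with
Benjamini–Hochberg FDR.

## Environmental statistics

* **Twin discordance**: per probe, the mean over pairs of
  $|\beta_{t1}-\beta_{t2}|$. Under the generator's model — independent
  environmental latents of SD $\sigma_e$ per twin plus measurement noise
  $\sigma_0$ — the discordance expectation is the folded-normal mean
  $\sqrt{2/\pi}\,\sigma_\Delta$ with $\sigma_\Delta^2 =
  2(\sigma_e^2+\sigma_0^2)$; the acceptance suite verifies the observed
  mean within 10%.
* **Exposure tests**: equal-variance Student's t per probe (Welch behind
  a flag), probes with fewer than 3 values per group flagged missing.
  $-\log_{10} p$ tracks feed `compareVmrVsBackground`, a Wilcoxon
  rank-sum comparison (two-sided and one-sided) of any per-probe scalar
  between VMR and non-VMR probes; fully tied inputs return p = 1.
* **Heritability overlay**: consumed as a user-supplied per-probe table —
  the package does not estimate heritability — and additionally
  stratified into shared-vs-cell-type-specific VMR probes when several
  VMR sets are provided.

## The synthetic-data generator

The generator encodes the study conditions under which every property is
verified. Genome-level truth — which probe clusters are variable loci,
which belong to trans modules, which respond to environment — is drawn
once per configuration seed and shared by *all* cohort simulators
(population, twins, exposure, time-course), because these are properties
of the genome, not of a cohort; this is what gives time-course VMRs their
structural overlap with population VMRs.

Defaults (the reference conditions): 100 samples; 20,000 probes on 5
chromosomes in clusters of Poisson(4)+1 probes spaced ≤ 200 bp, clusters
separated by > 10 kb; baseline means from a bimodal mixture (peaks 0.10
and 0.90, 10% intermediate mass); iid Gaussian noise of SD 0.02; 50
planted VMR clusters receiving per-sample latent shifts of SD 0.15 (≥ 3×
noise, so planted effects are unambiguous); 3 trans modules of 12 VMRs at
loading 0.9, members interleaved across chromosomes so every module
contains trans pairs; 30% of planted VMRs environmentally responsive;
5 sex-affected clusters with a 0.05 male–female offset. Twin cohorts use
100 pairs with environmental latent SD 0.10; exposure cohorts 64 samples
per group with a 0.05 mean shift; time courses 9 samples with a 0.3 total
drift and 0.01 noise (single-batch chips).

Two deliberate modeling choices:

* Beta values are clamped Gaussians on [0.001, 0.999] rather than Beta
  variates: the caller's statistic is the SD, which clamped Gaussians let
  us control exactly, and the clamp floor avoids degenerate zero-variance
  probes.
* Planted clusters receive intermediate baselines (0.35–0.65 with small
  per-probe jitter) instead of bimodal extremes: a latent shift of SD
  0.10–0.15 around a baseline of 0.1 or 0.9 would be truncated by the
  [0,1] range, and genuinely variable sites are intermediate-methylation
  by nature — a locus pinned at 0 or 1 in every sample is not variable.

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: probe-chemistry (Infinium
I/II) differences, batch and chip effects, cell-composition mixtures, age
trajectories, genotype-driven (mQTL) variability structure, and realistic
linkage between annotation classes and methylation level. Results on real
cohorts depend on upstream normalization quality in ways the synthetic
conditions cannot test.

## Problem sizes and verification design

The automated checks run at sizes chosen to finish comfortably on one
CPU while keeping Monte-Carlo error small relative to the tolerances:
caller-oracle equivalence on 100 random manifests of 300–2,000 probes
(exact set equality); planted-VMR recovery on ten seeds of the full
20,000-probe default (sensitivity and false-discovery proportion
averaged over seeds — single-seed false-discovery fluctuates roughly
0–0.12 around its mean because a 95th-percentile rule always admits a
tail of chance windows); TOM exactness at 50–100 nodes; module recovery
on twenty 3,200-probe genomes with 3×12 planted module VMRs; 1,000-run
null calibrations for the enrichment and rank-sum statistics. The
acceptance script (`scripts/acceptance.R`) recomputes all of these from
scratch from a single command-line seed.

## Known limitations

* The module decomposition is a compact reimplementation of dynamic
  hybrid tree cutting's *behavior* (branch shape + eigengene
  membership), not a line-for-line port; label-for-label parity with
  other implementations is not guaranteed, planted-structure recovery is.
* The scale-free fit index is reported but noisy at network sizes below a
  few hundred nodes; the default power of 6 is the operative choice.
* Probe-level enrichment p-values inherit the usual caveat that probes
  cluster physically; strong claims should be checked against the
  interval-level (VMR-level) tests also provided.
* The caller's false-discovery behavior is a property of the percentile
  rule itself: ~5% of background probes are always "variable", so a
  small number of chance VMRs is expected in any stratum, and rises with
  the number of strata unioned.
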