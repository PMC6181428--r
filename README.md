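# vmrscan

Detection and network analysis of **Variably Methylated Regions (VMRs)**
from methylation-array beta-value matrices.

Most CpGs in the human genome show tightly regulated, nearly invariant
methylation across individuals; a small set of loci instead carries high
inter-individual epigenetic variability. Single hypervariable probes are
unreliable (SNPs under the probe, hybridization artifacts), so the robust
signal is a *cluster* of neighboring CpGs that are all hypervariable.
`vmrscan` implements this analysis end to end for anyone studying
population epigenetic variation with 450k-style arrays:

1. **VMR calling.** For each probe, the sample standard deviation of its
   beta value β ∈ [0,1] is computed per stratum (cell type × sex). A 1 kb
   sliding window anchored at each probe's start coordinate is a VMR
   candidate when it contains ≥ 3 probes with SD at or above the 95th
   percentile of the background SD distribution **and** those variable
   probes are ≥ 50% of the window's probes. Overlapping qualifying windows
   merge; each VMR spans its variable probes and is summarized by the
   probe with the highest SD. Calling runs separately in males and
   females and the per-sex calls are combined, so sex effects cannot
   masquerade as population variability.
2. **Co-methylation networks.** Over the VMR representative probes, a
   weighted network is built from the Pearson correlation matrix R via
   soft-thresholded adjacency A = |R|⁶, transformed to the topological
   overlap matrix TOM_ij = (Σ_u A_iu A_uj + A_ij)/(min(k_i,k_j)+1−A_ij).
   Average-linkage clustering on 1−TOM with dynamic branch decomposition
   (minimum module size 10) yields modules; membership is resolved on the
   module eigengene (first principal component) with |kME| ≥ 0.7.
   Within-module VMR pairs on different chromosomes are *trans*
   associations — the signature of shared trans-acting regulation.
3. **Enrichment.** Probe-level annotation enrichment with fold
   (k/n)/(K/N) and hypergeometric p; per-module transcription-factor
   binding-site enrichment (sites extended ±500 bp, one-sided Fisher,
   Bonferroni); VMR→gene linking (TSS ± 2 kb plus auxiliary link tables);
   GO enrichment with Benjamini–Hochberg FDR.
4. **Environmental signatures.** Monozygotic-twin mean absolute
   methylation discordance, per-probe two-group Student's t (e.g. season
   of conception), Wilcoxon rank-sum comparisons of any per-probe track
   between VMR and background probes, heritability overlays, and VMR
   calling on isogenic time-course cultures (no sex stratification, no
   quantile normalization) with per-VMR Spearman trends.
5. **Synthetic cohorts.** A generator producing clustered manifests,
   bimodal baselines, planted high-variance clusters, latent trans
   factors, twin pairs, exposure groups and time courses — with full
   ground truth — so every stage is testable without controlled-access
   cohort data.

## Worked example

```r
library(vmrscan)

cfg <- pipelineConfig(seed = 1, out_dir = "vmrscan_demo")
res <- runPipeline(cfg)   # simulate -> preprocess -> call -> network ->
                          # enrich -> environment; ~15 s on one CPU
res$vmrs
#> VMRSet with 53 VMRs (stratum: combined )
#>   mean span: 470.1 bp; mean probes per VMR: 5.04
#>   background universe: 19381 probes
res$network$modules
#> ModuleAssignment: 3 modules, 36 of 53 VMRs assigned
res$recovery
#> $sensitivity  [1] 1
#> $false_discovery_proportion  [1] 0.05660377
round(res$twins$mean_env_discordance, 4)
#> [1] 0.1168
```

Reading the output: all 50 planted VMRs were recovered (3 extra calls are
the expected chance hits of a 95th-percentile rule); the three planted
trans modules are recovered exactly (36 module VMRs assigned, kME ≥ 0.7);
and mean twin discordance at environmentally responsive probes, 0.1168,
sits on the folded-normal prediction √(2/π)·√(2(0.1²+0.02²)) ≈ 0.115 for
an environmental latent of SD 0.10 over noise of SD 0.02. Per-stage
tables (VMR BED, module/kME tables, edge lists, enrichment results,
seasonal tests) are written under `out_dir` with provenance headers.

Individual stages are exported directly — `readManifest()`, `readBeta()`,
`filterProbes()`, `quantileNormalizeBeta()`, `callVmrsSexStratified()`,
`tomSimilarity()`, `detectModules()`, `moduleMembership()`,
`probeFeatureEnrichment()`, `goEnrichment()`, `twinDiscordance()`,
`seasonalTest()`, `timecourseVmrs()`, … — see the methods vignette
(`vignettes/vmrscan-methods.Rmd`) for the full model description. A thin
command-line wrapper lives at `inst/scripts/vmrscan.R`.

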