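#' Simulation configuration
#'
#' Encodes the statistical structure the synthetic cohorts emulate:
#' clustered CpG probe positions, bimodal baseline methylation, planted
#' high-variance probe clusters (true VMRs), latent trans co-regulation
#' factors shared by module-assigned VMRs, sex effects, and the fraction of
#' planted VMRs that respond to environment. Defaults are the package's
#' reference study conditions: 100 samples, 20,000 probes over 5
#' chromosomes, 50 planted VMRs with per-sample latent shift SD 0.15 over a
#' measurement noise SD of 0.02, and 3 trans modules of 12 VMRs at loading
#' 0.9.
#'
#' @param n_chrom number of chromosomes.
#' @param probes_per_chrom probes per chromosome.
#' @param cluster_size_mean mean probes per CpG cluster (size ~ Poisson+1).
#' @param intra_cluster_spacing_bp maximum spacing between neighboring
#'   probes within a cluster (bp).
#' @param n_samples number of individuals.
#' @param baseline_noise_sd iid Gaussian measurement noise SD on beta.
#' @param n_planted_vmrs number of probe clusters given a per-sample latent
#'   methylation shift (true VMRs).
#' @param vmr_effect_sd SD of the per-sample latent shift at planted VMRs.
#' @param n_trans_modules number of latent trans co-regulation factors.
#' @param vmrs_per_module planted VMRs sharing each factor.
#' @param module_loading loading of module VMRs on their factor, in (0,1].
#' @param frac_env_vmrs fraction of planted VMRs flagged environmentally
#'   responsive.
#' @param sex_effect_sd mean male/female beta offset at sex-affected
#'   clusters.
#' @param n_sex_clusters number of non-VMR clusters given a sex offset.
#' @param seed integer seed; every simulator derives its stream from it.
#' @return a validated list of class \code{SimConfig}.
#' @export
simConfig <- function(n_chrom = 5, probes_per_chrom = 4000,
                      cluster_size_mean = 4, intra_cluster_spacing_bp = 200,
                      n_samples = 100, baseline_noise_sd = 0.02,
                      n_planted_vmrs = 50, vmr_effect_sd = 0.15,
                      n_trans_modules = 3, vmrs_per_module = 12,
                      module_loading = 0.9, frac_env_vmrs = 0.3,
                      sex_effect_sd = 0.05, n_sex_clusters = 5, seed = 1) {
  cfg <- list(n_chrom = n_chrom, probes_per_chrom = probes_per_chrom,
              cluster_size_mean = cluster_size_mean,
              intra_cluster_spacing_bp = intra_cluster_spacing_bp,
              n_samples = n_samples, baseline_noise_sd = baseline_noise_sd,
              n_planted_vmrs = n_planted_vmrs, vmr_effect_sd = vmr_effect_sd,
              n_trans_modules = n_trans_modules,
              vmrs_per_module = vmrs_per_module,
              module_loading = module_loading, frac_env_vmrs = frac_env_vmrs,
              sex_effect_sd = sex_effect_sd, n_sex_clusters = n_sex_clusters,
              seed = as.integer(seed))
  counts <- c("n_chrom", "probes_per_chrom", "cluster_size_mean",
              "intra_cluster_spacing_bp", "n_samples", "n_planted_vmrs",
              "n_trans_modules", "vmrs_per_module")
  if (any(unlist(cfg[counts]) <= 0)) stop("all counts must be positive")
  fracs <- c("module_loading", "frac_env_vmrs")
  if (any(unlist(cfg[fracs]) <= 0 | unlist(cfg[fracs]) > 1))
    stop("fractions must lie in (0, 1]")
  class(cfg) <- c("SimConfig", "list")
  cfg
}

clampBeta <- function(x) pmin(pmax(x, 0.001), 0.999)

#' Simulate a clustered probe manifest
#'
#' Probes are placed in clusters (size ~ Poisson(cluster_size_mean)+1,
#' within-cluster spacing up to \code{intra_cluster_spacing_bp}) separated by
#' gaps > 10 kb, emulating the clumped CpG layout of methylation arrays so
#' that most clusters put >= 3 probes inside a 1 kb window.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{manifest} (sorted named GRanges), \code{clusters}
#'   (data.frame cluster_id, chrom, start, end, n_probes, span) and
#'   \code{probe_cluster} (named vector probe id -> cluster id).
#' @export
simulateManifest <- function(config) {
  set.seed(config$seed)
  rows <- list(); cl <- 0L
  for (ch in seq_len(config$n_chrom)) {
    chrom <- paste0("chr", ch)
    pos <- 10000L; placed <- 0L
    while (placed < config$probes_per_chrom) {
      cl <- cl + 1L
      size <- min(stats::rpois(1, config$cluster_size_mean) + 1L,
                  config$probes_per_chrom - placed)
      gaps <- if (size > 1)
        round(stats::runif(size - 1, 30, config$intra_cluster_spacing_bp))
        else integer(0)
      p <- pos + cumsum(c(0L, gaps))
      rows[[length(rows) + 1L]] <- data.frame(chrom = chrom, pos = p,
                                              cluster = cl)
      placed <- placed + size
      pos <- p[length(p)] + 10001L + round(stats::rexp(1, 1 / 15000))
    }
  }
  df <- do.call(rbind, rows)
  df$probe_id <- sprintf("cg%07d", seq_len(nrow(df)))
  man <- manifestFromDataFrame(df[, c("probe_id", "chrom", "pos")])
  pc <- stats::setNames(df$cluster, df$probe_id)[names(man)]
  agg <- do.call(rbind, lapply(split(df, df$cluster), function(d)
    data.frame(cluster_id = d$cluster[1], chrom = d$chrom[1],
               start = min(d$pos), end = max(d$pos), n_probes = nrow(d))))
  agg <- agg[order(agg$cluster_id), ]
  agg$span <- agg$end - agg$start
  rownames(agg) <- NULL
  list(manifest = man, clusters = agg, probe_cluster = pc)
}

baselineMeans <- function(n) {
  comp <- sample.int(3, n, replace = TRUE, prob = c(0.45, 0.45, 0.10))
  mu <- numeric(n)
  mu[comp == 1] <- stats::rnorm(sum(comp == 1), 0.10, 0.03)
  mu[comp == 2] <- stats::rnorm(sum(comp == 2), 0.90, 0.03)
  mu[comp == 3] <- stats::runif(sum(comp == 3), 0.25, 0.75)
  clampBeta(mu)
}

# Planted clusters get intermediate baselines: variable sites cannot sit at
# the 0/1 boundary or clamping would erase the planted variance.
plantedBaselines <- function(sim, plantedClusters) {
  base <- stats::setNames(stats::runif(length(plantedClusters), 0.35, 0.65),
                          as.character(plantedClusters))
  mu <- baselineMeans(length(sim$manifest))
  names(mu) <- names(sim$manifest)
  inPlanted <- sim$probe_cluster %in% plantedClusters
  mu[inPlanted] <- clampBeta(
    base[as.character(sim$probe_cluster[inPlanted])] +
      stats::rnorm(sum(inPlanted), 0, 0.02))
  mu
}

eligibleClusters <- function(sim, windowBp = 1000) {
  cls <- sim$clusters
  cls$cluster_id[cls$n_probes >= 3 & cls$span < windowBp - 100]
}

# Genome-level truth shared by every cohort simulator: which clusters are
# variable loci, which belong to trans modules, and which respond to
# environment are properties of the (synthetic) genome, not of a cohort.
genomeTruth <- function(sim, config) {
  set.seed(config$seed + 1L)
  elig <- eligibleClusters(sim)
  if (length(elig) < config$n_planted_vmrs)
    stop("config error: more planted VMRs requested than eligible clusters")
  planted <- sort(sample(elig, config$n_planted_vmrs))
  nMod <- config$n_trans_modules * config$vmrs_per_module
  if (nMod > length(planted))
    stop("config error: module VMRs exceed planted VMRs")
  iv <- truthIntervals(sim, planted)
  # interleave chrom-sorted planted clusters across modules -> trans spread
  ordc <- order(as.character(seqnames(iv)))
  vmr2mod <- stats::setNames(integer(length(iv)), names(iv))
  vmr2mod[ordc[seq_len(nMod)]] <- rep_len(seq_len(config$n_trans_modules),
                                          nMod)
  envVmrs <- sort(sample(names(iv),
                         max(1, round(config$frac_env_vmrs * length(iv)))))
  clusterOf <- function(v) mcols(iv)$cluster_id[match(v, names(iv))]
  probesIn <- function(cl) names(sim$probe_cluster)[sim$probe_cluster %in% cl]
  list(planted = planted, intervals = iv, vmr_to_module = vmr2mod,
       env_responsive_vmrs = envVmrs, cluster_of = clusterOf,
       env_probes = probesIn(clusterOf(envVmrs)),
       planted_probes = probesIn(planted))
}

truthIntervals <- function(sim, planted) {
  cls <- sim$clusters[match(planted, sim$clusters$cluster_id), ]
  gr <- GRanges(cls$chrom, IRanges(cls$start, cls$end))
  names(gr) <- sprintf("tv%03d", seq_along(gr))
  mcols(gr)$cluster_id <- cls$cluster_id
  gr
}

#' Simulate a population beta matrix with planted VMRs and trans modules
#'
#' Per-probe baseline means come from a bimodal mixture (peaks near 0.1 and
#' 0.9 with minor intermediate mass); iid Gaussian noise is added and values
#' clamped to [0.001, 0.999]. Each planted cluster v receives a per-sample
#' latent shift z_v ~ N(0, vmr_effect_sd) added to all member probes;
#' module-assigned VMRs share a factor f_m:
#' z_v = effect_sd (loading f_m + sqrt(1 - loading^2) eps_v), producing
#' co-methylation in trans. Module members are spread across chromosomes so
#' each module contains trans pairs. Sex-flagged clusters receive a mean
#' male/female offset.
#'
#' @param sim output of \code{\link{simulateManifest}}.
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{beta} (a \linkS4class{BetaSet}) and \code{truth}
#'   (planted intervals, vmr -> module map, env-responsive set, sex-affected
#'   clusters, latent factor and shift matrices, probe memberships).
#' @export
simulatePopulation <- function(sim, config) {
  gt <- genomeTruth(sim, config)
  planted <- gt$planted
  iv <- gt$intervals
  vmr2mod <- gt$vmr_to_module
  envVmrs <- gt$env_responsive_vmrs
  set.seed(config$seed + 101L)
  nonPlanted <- setdiff(eligibleClusters(sim), planted)
  sexClusters <- sort(sample(nonPlanted,
                             min(config$n_sex_clusters, length(nonPlanted))))
  mu <- plantedBaselines(sim, planted)
  n <- config$n_samples
  sex <- rep(c("M", "F"), length.out = n)
  f <- matrix(stats::rnorm(n * config$n_trans_modules), n,
              config$n_trans_modules)
  eps <- matrix(stats::rnorm(n * length(planted)), n, length(planted))
  z <- config$vmr_effect_sd * eps
  hasMod <- vmr2mod > 0
  if (any(hasMod)) {
    lam <- config$module_loading
    z[, hasMod] <- config$vmr_effect_sd *
      (lam * f[, vmr2mod[hasMod], drop = FALSE] +
         sqrt(1 - lam^2) * eps[, hasMod, drop = FALSE])
  }
  colnames(z) <- names(iv)
  p <- length(sim$manifest)
  beta <- matrix(mu, p, n) +
    matrix(stats::rnorm(p * n, 0, config$baseline_noise_sd), p, n)
  rownames(beta) <- names(sim$manifest)
  colnames(beta) <- sprintf("s%03d", seq_len(n))
  idx <- match(sim$probe_cluster, planted)   # NA for background probes
  inP <- !is.na(idx)
  beta[inP, ] <- beta[inP, ] + t(z)[idx[inP], , drop = FALSE]
  sexProbe <- sim$probe_cluster %in% sexClusters
  if (any(sexProbe))
    beta[sexProbe, sex == "M"] <- beta[sexProbe, sex == "M"] +
      config$sex_effect_sd
  beta <- clampBeta(beta)
  md <- DataFrame(sex = sex, cell_type = "synthetic",
                  row.names = colnames(beta))
  envProbes <- names(sim$probe_cluster)[
    sim$probe_cluster %in% mcols(iv)$cluster_id[names(iv) %in% envVmrs]]
  truth <- list(planted_vmr_intervals = iv, vmr_to_module = vmr2mod,
                env_responsive_vmrs = envVmrs, env_probes = envProbes,
                sex_clusters = sexClusters, factors = f, shifts = z,
                planted_clusters = planted,
                planted_probes = names(sim$probe_cluster)[inP])
  list(beta = BetaSet(beta, sim$manifest, md), truth = truth)
}

#' Simulate monozygotic twin pairs
#'
#' Planted VMRs are partitioned into a genetic set, whose latent shift is
#' shared exactly by both members of a pair (SD \code{vmr_effect_sd}), and
#' an environmental set whose latent is drawn independently per individual
#' (SD \code{env_sd}). Twin discordance at environmental VMRs therefore
#' follows the folded-normal law |N(0, 2(env_sd^2 + noise^2))|.
#'
#' @param sim output of \code{\link{simulateManifest}}.
#' @param config a \code{\link{simConfig}}.
#' @param n_pairs number of twin pairs (>= 2).
#' @param genetic_share fraction of planted VMRs in the genetic set; the
#'   default \code{NULL} takes the genome-level environmentally responsive
#'   flags (so the same loci respond across cohort simulators) and treats
#'   the remaining planted VMRs as genetic.
#' @param env_sd latent shift SD at environmental VMRs per individual.
#' @return list with \code{beta} (BetaSet; colData carries
#'   \code{twin_pair_id}) and \code{truth} (genetic/environmental VMR sets
#'   and probe sets, planted intervals).
#' @export
simulateTwins <- function(sim, config, n_pairs = 100, genetic_share = NULL,
                          env_sd = 0.1) {
  if (n_pairs < 2) stop("config error: n_pairs must be >= 2")
  gt <- genomeTruth(sim, config)
  planted <- gt$planted
  iv <- gt$intervals
  set.seed(config$seed + 102L)
  if (is.null(genetic_share)) {
    envVmrs <- gt$env_responsive_vmrs
  } else {
    envVmrs <- sort(sample(names(iv),
                           length(iv) - round(genetic_share * length(iv))))
  }
  genVmrs <- setdiff(names(iv), envVmrs)
  mu <- plantedBaselines(sim, planted)
  n <- 2L * n_pairs
  pairId <- rep(sprintf("pair%03d", seq_len(n_pairs)), each = 2)
  zPair <- matrix(stats::rnorm(n_pairs * length(iv), 0, config$vmr_effect_sd),
                  n_pairs, length(iv), dimnames = list(NULL, names(iv)))
  zInd <- matrix(stats::rnorm(n * length(iv), 0, env_sd), n, length(iv),
                 dimnames = list(NULL, names(iv)))
  z <- zPair[rep(seq_len(n_pairs), each = 2), , drop = FALSE]
  z[, envVmrs] <- zInd[, envVmrs]
  p <- length(sim$manifest)
  beta <- matrix(mu, p, n) +
    matrix(stats::rnorm(p * n, 0, config$baseline_noise_sd), p, n)
  rownames(beta) <- names(sim$manifest)
  colnames(beta) <- sprintf("tw%03d", seq_len(n))
  idx <- match(sim$probe_cluster, planted)
  inP <- !is.na(idx)
  beta[inP, ] <- beta[inP, ] + t(z)[idx[inP], , drop = FALSE]
  beta <- clampBeta(beta)
  md <- DataFrame(sex = rep("unknown", n), cell_type = "whole_blood",
                  twin_pair_id = pairId, row.names = colnames(beta))
  clOf <- function(v) mcols(iv)$cluster_id[match(v, names(iv))]
  truth <- list(planted_vmr_intervals = iv, genetic_vmrs = genVmrs,
                env_responsive_vmrs = envVmrs,
                genetic_probes = names(sim$probe_cluster)[
                  sim$probe_cluster %in% clOf(genVmrs)],
                env_probes = names(sim$probe_cluster)[
                  sim$probe_cluster %in% clOf(envVmrs)],
                planted_clusters = planted)
  list(beta = BetaSet(beta, sim$manifest, md), truth = truth)
}

#' Simulate a two-group exposure cohort
#'
#' A balanced rainy/dry design in which environmentally responsive probes
#' receive a mean beta shift of \code{delta} in the rainy group only; all
#' other probes carry baseline plus noise, so per-probe t-test p-values are
#' uniform under delta = 0.
#'
#' @param sim output of \code{\link{simulateManifest}}.
#' @param config a \code{\link{simConfig}}.
#' @param n_per_group samples per exposure group.
#' @param delta mean beta shift at responsive probes in the rainy group.
#' @return list with \code{beta} (BetaSet; colData carries \code{group}) and
#'   \code{truth} (responsive VMR intervals and probe set).
#' @export
simulateExposure <- function(sim, config, n_per_group = 64, delta = 0.05) {
  gt <- genomeTruth(sim, config)
  planted <- gt$planted
  iv <- gt$intervals
  envVmrs <- gt$env_responsive_vmrs
  set.seed(config$seed + 103L)
  mu <- plantedBaselines(sim, planted)
  n <- 2L * n_per_group
  group <- rep(c("rainy", "dry"), each = n_per_group)
  p <- length(sim$manifest)
  beta <- matrix(mu, p, n) +
    matrix(stats::rnorm(p * n, 0, config$baseline_noise_sd), p, n)
  rownames(beta) <- names(sim$manifest)
  colnames(beta) <- sprintf("ex%03d", seq_len(n))
  envProbes <- names(sim$probe_cluster)[
    sim$probe_cluster %in% mcols(iv)$cluster_id[names(iv) %in% envVmrs]]
  beta[envProbes, group == "rainy"] <- beta[envProbes, group == "rainy"] + delta
  beta <- clampBeta(beta)
  md <- DataFrame(sex = rep("unknown", n), cell_type = "whole_blood",
                  group = group, row.names = colnames(beta))
  truth <- list(planted_vmr_intervals = iv, env_responsive_vmrs = envVmrs,
                env_probes = envProbes, planted_clusters = planted)
  list(beta = BetaSet(beta, sim$manifest, md), truth = truth)
}

#' Simulate an isogenic time-course
#'
#' Emulates serially harvested isogenic cultures: responsive probes drift
#' linearly with the time index, beta(t) = beta0 + trend t/(T-1) + noise,
#' while all other probes carry noise only. With trend 0.3 over 9 time
#' points the ramp alone contributes an SD of about 0.1, far above the 95th
#' percentile of noise-only probe SDs.
#'
#' @param sim output of \code{\link{simulateManifest}}.
#' @param config a \code{\link{simConfig}}.
#' @param n_timepoints number of serial samples (>= 3).
#' @param trend_magnitude total beta drift across the course.
#' @param noise_sd measurement noise SD (time-course chips are processed in
#'   one batch, so the default is below the population noise).
#' @return list with \code{beta} (BetaSet; colData carries
#'   \code{time_point}) and \code{truth} (responsive intervals/probes).
#' @export
simulateTimecourse <- function(sim, config, n_timepoints = 9,
                               trend_magnitude = 0.3, noise_sd = 0.01) {
  if (n_timepoints < 3) stop("config error: n_timepoints must be >= 3")
  gt <- genomeTruth(sim, config)
  planted <- gt$planted
  iv <- gt$intervals
  envVmrs <- gt$env_responsive_vmrs
  set.seed(config$seed + 104L)
  mu <- plantedBaselines(sim, planted)
  tt <- seq_len(n_timepoints) - 1L
  p <- length(sim$manifest)
  beta <- matrix(mu, p, n_timepoints) +
    matrix(stats::rnorm(p * n_timepoints, 0, noise_sd), p, n_timepoints)
  rownames(beta) <- names(sim$manifest)
  colnames(beta) <- sprintf("tp%d", tt)
  envProbes <- names(sim$probe_cluster)[
    sim$probe_cluster %in% mcols(iv)$cluster_id[names(iv) %in% envVmrs]]
  ramp <- trend_magnitude * tt / (n_timepoints - 1)
  beta[envProbes, ] <- beta[envProbes, ] +
    matrix(ramp, length(envProbes), n_timepoints, byrow = TRUE)
  beta <- clampBeta(beta)
  md <- DataFrame(sex = rep("unknown", n_timepoints),
                  cell_type = "fibroblast_culture", time_point = tt,
                  row.names = colnames(beta))
  truth <- list(planted_vmr_intervals = iv, env_responsive_vmrs = envVmrs,
                env_probes = envProbes, planted_clusters = planted)
  list(beta = BetaSet(beta, sim$manifest, md), truth = truth)
}

#' Simulate annotation interval sets and a gene-to-GO table
#'
#' Emits gene models anchored near probe clusters (TSS, 5'UTR, CDS, intron,
#' 3'UTR), a CGI-class tiling (island/shore/shelf/sea) that covers every
#' probe exactly once, one transcription factor whose binding sites cover a
#' configurable fraction of module-1 VMR clusters against a lower background
#' rate, imprinted-like intervals over a subset of environmentally
#' responsive VMRs, and a gene-to-GO-term table with one term enriched among
#' module-1-linked genes.
#'
#' @param sim output of \code{\link{simulateManifest}}.
#' @param truth truth tables from \code{\link{simulatePopulation}}.
#' @param config a \code{\link{simConfig}}.
#' @param tf_module_frac fraction of module-1 VMR clusters covered by TF
#'   sites.
#' @param tf_background_frac fraction of other planted clusters covered.
#' @param imprinted_frac fraction of env-responsive VMRs covered by
#'   imprinted-like intervals.
#' @return list with \code{tss} (named GRanges), \code{gene_features} (list
#'   of GRanges: five_utr, cds, intron, three_utr), \code{cgi} (list of
#'   GRanges: island, shore, shelf, sea), \code{tfbs} (list with one GRanges
#'   per TF), \code{imprinted} (GRanges) and \code{gene2go} (data.frame
#'   gene, term).
#' @export
simulateAnnotations <- function(sim, truth, config, tf_module_frac = 0.8,
                                tf_background_frac = 0.1,
                                imprinted_frac = 0.5) {
  set.seed(config$seed + 105L)
  cls <- sim$clusters
  iv <- truth$planted_vmr_intervals
  plantedCl <- mcols(iv)$cluster_id
  # genes: one per planted cluster plus a background sample of other clusters
  bgGenes <- sample(setdiff(cls$cluster_id, plantedCl),
                    min(200, nrow(cls) - length(plantedCl)))
  geneCl <- c(plantedCl, bgGenes)
  gcls <- cls[match(geneCl, cls$cluster_id), ]
  gene <- sprintf("GENE%04d", seq_along(geneCl))
  tssPos <- gcls$start - round(stats::runif(nrow(gcls), 200, 1500))
  tss <- GRanges(gcls$chrom, IRanges(pmax(tssPos, 1), width = 1), gene = gene)
  names(tss) <- gene
  gene_features <- list(
    five_utr = GRanges(gcls$chrom, IRanges(pmax(tssPos, 1), pmax(tssPos, 1) + 200)),
    cds = GRanges(gcls$chrom, IRanges(pmax(tssPos, 1) + 201, pmax(tssPos, 1) + 1200)),
    intron = GRanges(gcls$chrom, IRanges(pmax(tssPos, 1) + 1201, pmax(tssPos, 1) + 3200)),
    three_utr = GRanges(gcls$chrom, IRanges(pmax(tssPos, 1) + 3201, pmax(tssPos, 1) + 3500)))
  # CGI tiling: each cluster box (span +- 1kb, gaps are >10kb so disjoint)
  # gets one class; chromosome complement is sea.  Every probe sits inside
  # exactly one cluster box, hence exactly one class.
  cgiClass <- sample(c("island", "shore", "shelf", "sea"), nrow(cls),
                     replace = TRUE, prob = c(0.4, 0.25, 0.15, 0.2))
  box <- GRanges(cls$chrom, IRanges(pmax(cls$start - 1000, 1), cls$end + 1000))
  chromEnd <- tapply(end(box), as.character(seqnames(box)), max) + 20000
  whole <- GRanges(names(chromEnd), IRanges(1, as.integer(chromEnd)))
  seaExtra <- GenomicRanges::setdiff(whole, box)
  cgi <- list(island = box[cgiClass == "island"],
              shore = box[cgiClass == "shore"],
              shelf = box[cgiClass == "shelf"],
              sea = c(box[cgiClass == "sea"], granges(seaExtra)))
  # TFBS: planted at module-1 VMR clusters vs background rate elsewhere
  mod1 <- names(truth$vmr_to_module)[truth$vmr_to_module == 1L]
  mod1Cl <- mcols(iv)$cluster_id[names(iv) %in% mod1]
  otherCl <- setdiff(plantedCl, mod1Cl)
  hit <- c(sample(mod1Cl, round(tf_module_frac * length(mod1Cl))),
           sample(otherCl, round(tf_background_frac * length(otherCl))))
  hcls <- cls[match(hit, cls$cluster_id), ]
  tf1 <- GRanges(hcls$chrom,
                 IRanges(pmax(hcls$start - 50, 1), hcls$end + 50))
  names(tf1) <- sprintf("TF1_site%03d", seq_along(tf1))
  # imprinted-like intervals over a subset of env-responsive VMRs only
  envIv <- iv[names(iv) %in% truth$env_responsive_vmrs]
  impIv <- envIv[sample(seq_along(envIv),
                        round(imprinted_frac * length(envIv)))]
  imprinted <- granges(impIv)
  names(imprinted) <- sprintf("imprinted%02d", seq_along(imprinted))
  # gene2go: GO:MOD1 enriched in module-1 genes; random background terms
  mod1Genes <- gene[match(mod1Cl, geneCl)]
  goRows <- data.frame(
    gene = c(sample(mod1Genes, round(0.8 * length(mod1Genes))),
             sample(setdiff(gene, mod1Genes),
                    max(1, round(0.05 * (length(gene) - length(mod1Genes)))))),
    term = "GO:MOD1")
  for (k in seq_len(20)) {
    g <- sample(gene, max(3, round(0.1 * length(gene))))
    goRows <- rbind(goRows, data.frame(gene = g,
                                       term = sprintf("GO:RND%02d", k)))
  }
  list(tss = tss, gene_features = gene_features, cgi = cgi,
       tfbs = list(TF1 = tf1), imprinted = imprinted,
       gene2go = unique(goRows))
}
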