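#' Pipeline configuration
#'
#' Assembles and validates the parameter blocks for a full synthetic run:
#' simulate -> preprocess -> call -> network -> enrich -> environment.
#' Unknown keys are rejected before any computation.
#'
#' @param seed integer master seed, recorded in all provenance.
#' @param out_dir output directory (created if absent); NULL disables file
#'   output.
#' @param sim list of \code{\link{simConfig}} overrides.
#' @param vmr list of \code{\link{vmrParams}} overrides.
#' @param network list of \code{\link{networkParams}} overrides.
#' @param twins list: n_pairs, genetic_share, env_sd.
#' @param exposure list: n_per_group, delta.
#' @param timecourse list: n_timepoints, trend_magnitude, noise_sd.
#' @param stages character vector of stages to run.
#' @return validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(seed = 1, out_dir = NULL, sim = list(),
                           vmr = list(), network = list(), twins = list(),
                           exposure = list(), timecourse = list(),
                           stages = c("simulate", "preprocess", "call",
                                      "network", "enrich", "environment")) {
  checkKeys <- function(given, allowed, block) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop("config schema error: unknown key(s) in ", block, ": ",
           paste(bad, collapse = ", "))
  }
  checkKeys(sim, names(formals(simConfig)), "sim")
  checkKeys(vmr, names(formals(vmrParams)), "vmr")
  checkKeys(network, names(formals(networkParams)), "network")
  checkKeys(twins, c("n_pairs", "genetic_share", "env_sd"), "twins")
  checkKeys(exposure, c("n_per_group", "delta"), "exposure")
  checkKeys(timecourse, c("n_timepoints", "trend_magnitude", "noise_sd"),
            "timecourse")
  known <- c("simulate", "preprocess", "call", "network", "enrich",
             "environment")
  if (!all(stages %in% known))
    stop("config schema error: unknown stage(s): ",
         paste(setdiff(stages, known), collapse = ", "))
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 sim = do.call(simConfig, sim),
                 vmr = do.call(vmrParams, vmr),
                 network = do.call(networkParams, network),
                 twins = utils::modifyList(
                   list(n_pairs = 100, env_sd = 0.1), twins),
                 exposure = utils::modifyList(
                   list(n_per_group = 64, delta = 0.05), exposure),
                 timecourse = utils::modifyList(
                   list(n_timepoints = 9, trend_magnitude = 0.3,
                        noise_sd = 0.01), timecourse),
                 stages = stages),
            class = c("PipelineConfig", "list"))
}

#' Read a pipeline configuration from JSON
#' @param path JSON file whose keys mirror \code{\link{pipelineConfig}}
#'   arguments.
#' @return a \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(pipelineConfig, cfg)
}

plantedRecovery <- function(called, truthIv) {
  gr <- vmrRanges(called)
  sens <- if (length(truthIv)) mean(countOverlaps(truthIv, gr) > 0) else NA
  fdp <- if (length(gr)) mean(countOverlaps(gr, truthIv) == 0) else 0
  list(sensitivity = sens, false_discovery_proportion = fdp,
       n_called = length(gr), n_planted = length(truthIv))
}

moduleLabelsVsTruth <- function(assignment, called, truth) {
  # per truth-module VMR: the module label of the overlapping called VMR
  iv <- truth$planted_vmr_intervals
  modVmrs <- names(truth$vmr_to_module)[truth$vmr_to_module > 0]
  gr <- vmrRanges(called)
  lab <- moduleLabels(assignment)
  calledLab <- vapply(modVmrs, function(v) {
    hit <- S4Vectors::subjectHits(findOverlaps(iv[v], gr))
    if (length(hit) == 0) return(0L)
    as.integer(lab[mcols(gr)$vmr_id[hit[1]]])
  }, 0L)
  data.frame(vmr = modVmrs, truth_module = truth$vmr_to_module[modVmrs],
             called_module = calledLab)
}

#' Run the full synthetic analysis pipeline
#'
#' Deterministic, single-process orchestration of all stages on synthetic
#' data generated from the config's seed. When \code{out_dir} is set, every
#' table is written with a provenance block, VMRs are exported as BED, and
#' a \code{provenance.json} records the full configuration; rerunning with
#' the same config yields identical outputs.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return (invisibly) a list of all stage results: simulation truth,
#'   filtered/normalized beta, called VMR sets, network objects, enrichment
#'   tables, environmental statistics, and planted-structure recovery
#'   metrics.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  res <- list(config = config)
  outDir <- config$out_dir
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  emit <- function(df, name, stage) {
    if (!is.null(outDir))
      writeResultTable(df, file.path(outDir, name), stage = stage,
                       params = list(), seed = config$seed)
  }
  stage <- function(s) s %in% config$stages

  logMsg("simulate", "generating manifest and cohorts (seed ",
         config$seed, ")")
  sim <- simulateManifest(config$sim)
  pop <- simulatePopulation(sim, config$sim)
  ann <- simulateAnnotations(sim, pop$truth, config$sim)
  res$sim <- sim; res$population <- pop; res$annotations <- ann
  if (!is.null(outDir)) {
    writeManifest(sim$manifest, file.path(outDir, "manifest.tsv"))
    writeBeta(pop$beta, file.path(outDir, "beta_population.tsv"),
              file.path(outDir, "samples_population.tsv"))
    writeBed(pop$truth$planted_vmr_intervals,
             file.path(outDir, "truth_planted_vmrs.bed"))
  }

  bs <- pop$beta
  if (stage("preprocess")) {
    logMsg("preprocess", "filtering and quantile-normalizing")
    flt <- filterProbes(bs)
    res$filter_report <- flt$report
    bs <- quantileNormalizeBeta(flt$beta)
    emit(flt$report, "filter_report.tsv", "preprocess")
  }

  if (stage("call")) {
    logMsg("call", "sex-stratified VMR calling")
    vmrs <- callVmrsSexStratified(bs, config$vmr)
    res$vmrs <- vmrs
    res$recovery <- plantedRecovery(vmrs, pop$truth$planted_vmr_intervals)
    gr <- vmrRanges(vmrs)
    vt <- data.frame(vmr_id = mcols(gr)$vmr_id,
                     chrom = as.character(seqnames(gr)),
                     start = start(gr), end = end(gr),
                     n_probes = mcols(gr)$n_probes,
                     span_bp = width(gr),
                     representative_probe = mcols(gr)$representative_probe,
                     max_sd = mcols(gr)$max_sd,
                     source_sex = mcols(gr)$source_sex)
    emit(vt, "vmr_table.tsv", "call")
    if (!is.null(outDir)) {
      writeBed(vmrs, file.path(outDir, "vmrs.bed"))
      writeLines(backgroundProbes(vmrs),
                 file.path(outDir, "background_probes.txt"))
    }
  } else vmrs <- NULL

  if (stage("network") && !is.null(vmrs) && nVmrs(vmrs) >= 3) {
    logMsg("network", "co-methylation network over ", nVmrs(vmrs), " VMRs")
    repM <- representativeMatrix(bs, vmrs)
    R <- vmrCorrelation(repM, config$network)
    sff <- scaleFreeFit(R, config$network)
    A <- adjacency(R, config$network$soft_power)
    tom <- tomSimilarity(A)
    mods0 <- detectModules(tom, config$network)
    mods <- moduleMembership(repM, mods0, config$network)
    ct <- classifyCisTrans(mods, vmrs)
    edges <- edgeList(R, vmrs, config$network$edge_abs_r_min)
    res$network <- list(rep_matrix = repM, R = R, scale_free = sff,
                        tom = tom, modules = mods, cis_trans = ct,
                        edges = edges)
    res$module_truth <- moduleLabelsVsTruth(mods, vmrs, pop$truth)
    emit(as.data.frame(mods@membership), "modules.tsv", "network")
    emit(sff$table, "scale_free_fit.tsv", "network")
    emit(edges, "edges.tsv", "network")
    emit(ct$summary, "cis_trans_summary.tsv", "network")
    if (!is.null(outDir))
      utils::write.table(res$network$modules@eigengenes,
                         file.path(outDir, "eigengenes.tsv"), sep = "\t",
                         quote = FALSE)
  }

  if (stage("enrich") && !is.null(vmrs) && nVmrs(vmrs) > 0) {
    logMsg("enrich", "annotation, TFBS and GO enrichment")
    bg <- backgroundProbes(vmrs)
    vp <- intersect(vmrProbes(vmrs), bg)
    man <- sim$manifest
    feat <- do.call(rbind, lapply(names(ann$cgi), function(cls)
      probeFeatureEnrichment(vp, bg, ann$cgi[[cls]], man, id = cls,
                             direction = "auto")))
    feat <- rbind(feat, do.call(rbind,
      lapply(names(ann$gene_features), function(f)
        probeFeatureEnrichment(vp, bg, ann$gene_features[[f]], man,
                               id = f, direction = "auto"))))
    feat$p_adjusted <- stats::p.adjust(feat$p_raw, "BH")
    res$feature_enrichment <- feat
    emit(feat, "feature_enrichment.tsv", "enrich")
    links <- linkVmrsToGenes(vmrs, ann$tss)
    res$gene_links <- links
    emit(links$links, "gene_links.tsv", "enrich")
    if (!is.null(res$network)) {
      mem <- res$network$modules@membership
      tfres <- lapply(sort(setdiff(unique(mem$module), 0L)), function(m) {
        tf <- tfbsModuleEnrichment(mem$vmr_id[mem$module == m], vmrs,
                                   ann$tfbs)
        tf$module <- m
        tf
      })
      res$tfbs_enrichment <- do.call(rbind, tfres)
      if (!is.null(res$tfbs_enrichment))
        emit(res$tfbs_enrichment, "tfbs_enrichment.tsv", "enrich")
      universe <- unique(links$links$gene)
      gores <- lapply(sort(setdiff(unique(mem$module), 0L)), function(m) {
        sg <- unique(links$links$gene[
          links$links$vmr_id %in% mem$vmr_id[mem$module == m]])
        if (length(sg) == 0) return(NULL)
        go <- goEnrichment(sg, universe, ann$gene2go)
        if (nrow(go)) go$module <- m
        go
      })
      gores <- gores[!vapply(gores, is.null, TRUE)]
      if (length(gores)) {
        res$go_enrichment <- do.call(rbind, gores)
        emit(res$go_enrichment, "go_enrichment.tsv", "enrich")
      }
    }
  }

  if (stage("environment")) {
    logMsg("environment", "twins, exposure and time-course analyses")
    tw <- simulateTwins(sim, config$sim, config$twins$n_pairs,
                        config$twins$genetic_share, config$twins$env_sd)
    disc <- twinDiscordance(tw$beta)
    twCmp <- compareVmrVsBackground(
      disc$discordance, tw$truth$env_probes,
      setdiff(names(disc$discordance), tw$truth$env_probes))
    res$twins <- list(data = tw, discordance = disc, comparison = twCmp,
                      mean_env_discordance =
                        mean(disc$discordance[tw$truth$env_probes]))
    ex <- simulateExposure(sim, config$sim, config$exposure$n_per_group,
                           config$exposure$delta)
    st <- seasonalTest(ex$beta)
    nl <- stats::setNames(st$neglog10_p, st$probe_id)
    exCmp <- compareVmrVsBackground(
      nl, ex$truth$env_probes, setdiff(st$probe_id, ex$truth$env_probes))
    res$exposure <- list(data = ex, test = st, comparison = exCmp)
    emit(st, "seasonal_test.tsv", "environment")
    tc <- simulateTimecourse(sim, config$sim,
                             config$timecourse$n_timepoints,
                             config$timecourse$trend_magnitude,
                             config$timecourse$noise_sd)
    tcv <- timecourseVmrs(tc$beta, config$vmr)
    res$timecourse <- list(data = tc, vmrs = tcv$vmrs, trends = tcv$trends)
    if (!is.null(vmrs) && nVmrs(tcv$vmrs) > 0 && nVmrs(vmrs) > 0)
      res$timecourse$overlap_with_population <- overlapVmrs(tcv$vmrs, vmrs)
    if (!is.null(outDir)) writeBed(tcv$vmrs,
                                   file.path(outDir, "timecourse_vmrs.bed"))
    env_summary <- data.frame(
      statistic = c("twin_discordance_wilcoxon_p",
                    "seasonal_wilcoxon_p", "n_timecourse_vmrs"),
      value = c(twCmp$p_greater, exCmp$p_greater, nVmrs(tcv$vmrs)))
    emit(env_summary, "environment_summary.tsv", "environment")
  }

  if (!is.null(outDir)) {
    prov <- list(package = "vmrscan",
                 version = as.character(utils::packageVersion("vmrscan")),
                 seed = config$seed, stages = config$stages,
                 sim = unclass(config$sim), vmr = unclass(config$vmr),
                 network = unclass(config$network))
    jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}
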