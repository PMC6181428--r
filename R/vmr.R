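#' VMR caller parameters
#'
#' The sliding-window rule: a 1 kb window anchored at each probe's start
#' coordinate qualifies when it contains at least \code{min_variable_probes}
#' probes at or above the \code{sd_percentile}-th percentile of per-probe
#' SD, and those variable probes make up at least
#' \code{min_variable_fraction} of the probes in the window.
#'
#' @param window_bp window length in bp.
#' @param min_variable_probes minimum variable probes per window (>= 2).
#' @param min_variable_fraction minimum variable fraction of window probes.
#' @param sd_percentile SD percentile defining "variable" (0-100).
#' @param min_samples_per_probe minimum non-missing samples for a probe's
#'   SD to enter the percentile computation.
#' @return list of class \code{VMRParams}.
#' @export
vmrParams <- function(window_bp = 1000, min_variable_probes = 3,
                      min_variable_fraction = 0.5, sd_percentile = 95,
                      min_samples_per_probe = 10) {
  stopifnot(window_bp > 0, min_variable_probes >= 2,
            min_variable_fraction > 0, min_variable_fraction <= 1,
            sd_percentile > 0, sd_percentile < 100)
  structure(list(window_bp = window_bp,
                 min_variable_probes = min_variable_probes,
                 min_variable_fraction = min_variable_fraction,
                 sd_percentile = sd_percentile,
                 min_samples_per_probe = min_samples_per_probe),
            class = c("VMRParams", "list"))
}

#' Per-probe standard deviation within a stratum
#'
#' Sample SD (denominator n-1) of beta values per probe over non-missing
#' values of the selected samples. Probes observed in fewer than
#' \code{minSamples} samples are flagged and excluded from downstream
#' percentile computation.
#'
#' @param bs a \linkS4class{BetaSet}.
#' @param samples sample names/indices defining the stratum (default: all).
#' @param stratum character label recorded on the track.
#' @param minSamples minimum non-missing values per probe.
#' @return a \linkS4class{VariabilityTrack}.
#' @export
probeSD <- function(bs, samples = NULL, stratum = "all", minSamples = 10) {
  beta <- betaValues(bs)
  if (!is.null(samples)) beta <- beta[, samples, drop = FALSE]
  if (ncol(beta) == 0) stop("empty stratum: no samples selected")
  n <- rowSums(!is.na(beta))
  mu <- rowMeans(beta, na.rm = TRUE)
  ss <- rowSums(beta * beta, na.rm = TRUE) - n * mu * mu
  sd <- sqrt(pmax(ss, 0) / pmax(n - 1, 1))
  sd[n < 2] <- NA
  new("VariabilityTrack", sd = stats::setNames(sd, rownames(beta)),
      nUsed = stats::setNames(as.integer(n), rownames(beta)),
      stratum = stratum, threshold = NA_real_,
      excluded = rownames(beta)[n < minSamples])
}

#' Enumerate probe-anchored candidate windows
#'
#' One half-open window [pos, pos + window_bp) per probe on its chromosome.
#' Windows with at least \code{min_variable_probes} member probes are
#' retained as candidates; the union of their member probes is the
#' background probe set used for the SD percentile and all enrichment
#' analyses.
#'
#' @param manifest named GRanges of probe positions (sorted).
#' @param params a \code{\link{vmrParams}}.
#' @return list with \code{windows} (GRanges of candidate windows, 1-based
#'   closed [pos, pos+window_bp-1], with \code{anchor} and \code{members}
#'   metadata) and \code{background} (character vector of probe ids).
#' @export
enumerateWindows <- function(manifest, params = vmrParams()) {
  if (length(manifest) == 0)
    return(list(windows = GRanges(), background = character(0)))
  win <- GRanges(seqnames(manifest),
                 IRanges(start(manifest),
                         start(manifest) + params$window_bp - 1L))
  hits <- findOverlaps(win, manifest)
  memb <- split(names(manifest)[S4Vectors::subjectHits(hits)],
                factor(S4Vectors::queryHits(hits),
                       levels = seq_along(win)))
  nMemb <- lengths(memb)
  cand <- which(nMemb >= params$min_variable_probes)
  w <- win[cand]
  mcols(w)$anchor <- names(manifest)[cand]
  mcols(w)$members <- CharacterList(memb[cand])
  list(windows = w,
       background = unique(unlist(memb[cand], use.names = FALSE)))
}

#' Call VMRs from a variability track
#'
#' The SD threshold is the \code{sd_percentile}-th percentile (linear
#' interpolation between order statistics) of per-probe SDs over the
#' background probe set; probes with SD at or above it are "variable"
#' (ties included). A candidate window qualifies when it holds at least
#' \code{min_variable_probes} variable probes and their fraction of all
#' window probes is at least \code{min_variable_fraction}. Overlapping
#' qualifying windows on a chromosome are merged; each merged VMR spans the
#' minimum to maximum position of the variable probes it contains, records
#' them as members, and takes the member with the highest SD (ties: lowest
#' genomic position) as representative.
#'
#' @param track a \linkS4class{VariabilityTrack}.
#' @param windows output of \code{\link{enumerateWindows}}.
#' @param params a \code{\link{vmrParams}}.
#' @param manifest named GRanges of probe positions.
#' @return a \linkS4class{VMRSet}.
#' @export
callVmrs <- function(track, windows, params, manifest) {
  bg <- setdiff(intersect(windows$background, names(track@sd)),
                track@excluded)
  bg <- bg[!is.na(track@sd[bg])]
  if (length(bg) == 0) stop("SD percentile undefined: no background probes")
  thr <- unname(stats::quantile(track@sd[bg], params$sd_percentile / 100,
                                type = 7))
  track@threshold <- thr
  isVar <- !is.na(track@sd) & track@sd >= thr
  varProbes <- names(track@sd)[isVar]
  w <- windows$windows
  memb <- mcols(w)$members
  ul <- unlist(memb, use.names = FALSE)
  grp <- rep(seq_along(memb), lengths(memb))
  nVar <- tabulate(grp[ul %in% varProbes], nbins = length(memb))
  qual <- nVar >= params$min_variable_probes &
    nVar / lengths(memb) >= params$min_variable_fraction
  merged <- reduce(w[qual])
  vgr <- manifest[names(manifest) %in% varProbes]
  rows <- lapply(seq_along(merged), function(i) {
    inReg <- vgr[S4Vectors::subjectHits(findOverlaps(merged[i], vgr))]
    sds <- track@sd[names(inReg)]
    o <- order(-sds, start(inReg))
    list(chrom = as.character(seqnames(merged[i])),
         start = min(start(inReg)), end = max(start(inReg)),
         probes = names(inReg), rep = names(inReg)[o[1]],
         max_sd = unname(sds[o[1]]))
  })
  if (length(rows)) {
    gr <- GRanges(vapply(rows, `[[`, "", "chrom"),
                  IRanges(vapply(rows, function(r) r$start, 0),
                          vapply(rows, function(r) r$end, 0)))
    mcols(gr)$vmr_id <- sprintf("%s_vmr%04d", track@stratum, seq_along(gr))
    mcols(gr)$n_probes <- vapply(rows, function(r) length(r$probes), 0L)
    mcols(gr)$probe_ids <- CharacterList(lapply(rows, `[[`, "probes"))
    mcols(gr)$representative_probe <- vapply(rows, `[[`, "", "rep")
    mcols(gr)$max_sd <- vapply(rows, function(r) r$max_sd, 0)
    mcols(gr)$source_sex <- track@stratum
  } else {
    gr <- GRanges()
    mcols(gr) <- DataFrame(vmr_id = character(0), n_probes = integer(0),
                           probe_ids = CharacterList(),
                           representative_probe = character(0),
                           max_sd = numeric(0), source_sex = character(0))
  }
  new("VMRSet", ranges = gr, stratum = track@stratum,
      params = c(unclass(params), list(threshold = thr)),
      background = bg)
}

combineVmrSets <- function(sets, sdTracks, stratum) {
  grs <- lapply(sets, function(s) s@ranges)
  allGr <- do.call(c, lapply(grs, granges))
  merged <- reduce(allGr)
  sdMat <- do.call(cbind, lapply(sdTracks, function(t) t@sd))
  maxSd <- apply(sdMat, 1, max, na.rm = TRUE)
  rows <- lapply(seq_along(merged), function(i) {
    src <- character(); probes <- character()
    for (k in seq_along(grs)) {
      ov <- S4Vectors::queryHits(findOverlaps(grs[[k]], merged[i]))
      if (length(ov)) {
        src <- c(src, unique(mcols(grs[[k]])$source_sex[ov]))
        probes <- c(probes,
                    unlist(mcols(grs[[k]])$probe_ids[ov], use.names = FALSE))
      }
    }
    probes <- unique(probes)
    sds <- maxSd[probes]
    o <- order(-sds)
    list(probes = probes, rep = probes[o[1]], max_sd = unname(sds[o[1]]),
         src = paste(sort(unique(src)), collapse = "+"))
  })
  mcols(merged)$vmr_id <- sprintf("%s_vmr%04d", stratum, seq_along(merged))
  mcols(merged)$n_probes <- vapply(rows, function(r) length(r$probes), 0L)
  mcols(merged)$probe_ids <- CharacterList(lapply(rows, `[[`, "probes"))
  mcols(merged)$representative_probe <- vapply(rows, `[[`, "", "rep")
  mcols(merged)$max_sd <- vapply(rows, function(r) r$max_sd, 0)
  mcols(merged)$source_sex <- vapply(rows, `[[`, "", "src")
  new("VMRSet", ranges = merged, stratum = stratum,
      params = sets[[1]]@params,
      background = unique(unlist(lapply(sets, backgroundProbes))))
}

#' Sex-stratified VMR calling
#'
#' Males and females are analyzed separately (per-sex SD tracks and
#' per-sex percentile thresholds) to avoid sex-effect false positives; VMRs
#' found in either sex are then combined, merging overlapping intervals and
#' taking the union of member probes. Falls back to a pooled call with a
#' warning when either sex has fewer than two samples.
#'
#' @param bs a \linkS4class{BetaSet} with a \code{sex} column in colData.
#' @param params a \code{\link{vmrParams}}.
#' @return a \linkS4class{VMRSet} (stratum \code{"combined"}, per-VMR
#'   \code{source_sex} in \{M, F, F+M\}; or \code{"pooled"} on fallback).
#' @export
callVmrsSexStratified <- function(bs, params = vmrParams()) {
  sex <- colData(bs)$sex
  manifest <- probeRanges(bs)
  wins <- enumerateWindows(manifest, params)
  nM <- sum(sex == "M"); nF <- sum(sex == "F")
  if (nM < 2 || nF < 2) {
    warning("sex stratification unavailable (M=", nM, ", F=", nF,
            "); falling back to pooled calling")
    tr <- probeSD(bs, stratum = "pooled",
                  minSamples = params$min_samples_per_probe)
    return(callVmrs(tr, wins, params, manifest))
  }
  trM <- probeSD(bs, samples = which(sex == "M"), stratum = "M",
                 minSamples = params$min_samples_per_probe)
  trF <- probeSD(bs, samples = which(sex == "F"), stratum = "F",
                 minSamples = params$min_samples_per_probe)
  setM <- callVmrs(trM, wins, params, manifest)
  setF <- callVmrs(trF, wins, params, manifest)
  if (nVmrs(setM) == 0 && nVmrs(setF) == 0) {
    out <- setM
    out@stratum <- "combined"
    return(out)
  }
  combineVmrSets(list(setM, setF)[c(nVmrs(setM) > 0, nVmrs(setF) > 0)],
                 list(trM, trF), "combined")
}

#' Overlap/replication of one VMR set against another
#'
#' A query VMR replicates when its interval shares at least \code{minBp}
#' base pairs with any reference VMR. Enrichment over chance is computed at
#' the probe level: with N background probes of which K lie in reference
#' VMRs, drawing the n query-VMR probes at random yields
#' nK/N expected shared probes; fold is observed/expected with an
#' upper-tail hypergeometric p-value.
#'
#' @param query,reference \linkS4class{VMRSet}s on one coordinate frame.
#' @param minBp minimum overlap in bp (default 1).
#' @param background optional character vector of background probe ids
#'   (default: intersection of the two sets' backgrounds).
#' @return list with \code{table} (per-query replication flags),
#'   \code{n_query}, \code{n_replicated}, \code{frac_replicated},
#'   \code{probe_overlap} (k, n, K, N, expected, fold, p).
#' @export
overlapVmrs <- function(query, reference, minBp = 1, background = NULL) {
  qGr <- vmrRanges(query); rGr <- vmrRanges(reference)
  if (length(qGr) && length(rGr) &&
      !any(as.character(seqnames(qGr)) %in% as.character(seqnames(rGr))))
    warning("query and reference share no chromosome names")
  rep <- countOverlaps(qGr, rGr, minoverlap = minBp) > 0
  if (is.null(background)) {
    background <- intersect(backgroundProbes(query),
                            backgroundProbes(reference))
    if (length(background) == 0)
      background <- union(backgroundProbes(query),
                          backgroundProbes(reference))
  }
  qP <- intersect(vmrProbes(query), background)
  rP <- intersect(vmrProbes(reference), background)
  k <- length(intersect(qP, rP)); n <- length(qP)
  K <- length(rP); N <- length(background)
  expected <- n * K / N
  list(table = data.frame(vmr_id = mcols(qGr)$vmr_id, replicated = rep),
       n_query = length(qGr), n_replicated = sum(rep),
       frac_replicated = if (length(qGr)) mean(rep) else NA_real_,
       probe_overlap = data.frame(
         k = k, n = n, K = K, N = N, expected = expected,
         fold = if (expected > 0) k / expected else NA_real_,
         p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)))
}

#' Cross-cell-type correlation at shared VMR probes
#'
#' For each shared-VMR probe, the Pearson correlation across paired
#' individuals between the beta values measured in two cell types; high
#' mean correlation indicates that population variability at shared VMRs is
#' established upstream of the two lineages or co-regulated.
#'
#' @param bsA,bsB \linkS4class{BetaSet}s for the two cell types.
#' @param sharedProbeIds probes inside VMRs found in both cell types.
#' @param pairedSampleIds data.frame with columns \code{a} and \code{b}
#'   naming the same individual's sample in each set, or a single character
#'   vector of ids present in both.
#' @return list with \code{per_probe} (named r vector) and \code{mean_r}.
#' @export
sharedVmrCorrelation <- function(bsA, bsB, sharedProbeIds, pairedSampleIds) {
  if (is.atomic(pairedSampleIds))
    pairedSampleIds <- data.frame(a = pairedSampleIds, b = pairedSampleIds)
  if (nrow(pairedSampleIds) < 3)
    stop("need >= 3 paired individuals")
  a <- betaValues(bsA)[sharedProbeIds, pairedSampleIds$a, drop = FALSE]
  b <- betaValues(bsB)[sharedProbeIds, pairedSampleIds$b, drop = FALSE]
  r <- vapply(seq_along(sharedProbeIds), function(i)
    suppressWarnings(stats::cor(a[i, ], b[i, ],
                                use = "pairwise.complete.obs")),
    0)
  names(r) <- sharedProbeIds
  list(per_probe = r, mean_r = mean(r, na.rm = TRUE))
}
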