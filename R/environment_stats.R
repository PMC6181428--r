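#' Monozygotic twin methylation discordance
#'
#' Per probe, the mean over twin pairs of the absolute beta difference
#' between the two members, using pairs where both values are present.
#' Twin discordance is a proxy for the non-genetic component of methylation
#' variability.
#'
#' @param bs a \linkS4class{BetaSet}; pairing is taken from the
#'   \code{twin_pair_id} column of colData unless \code{pairMap} is given.
#' @param pairMap optional named list/split mapping pair id -> 2 sample
#'   ids.
#' @return list with \code{discordance} (named per-probe means),
#'   \code{n_pairs} (per-probe pair counts).
#' @export
twinDiscordance <- function(bs, pairMap = NULL) {
  if (is.null(pairMap)) {
    pid <- colData(bs)$twin_pair_id
    if (is.null(pid)) stop("twin_pair_id missing from sample metadata")
    pairMap <- split(colnames(bs), pid)
  }
  bad <- names(pairMap)[lengths(pairMap) != 2]
  if (length(bad))
    stop("pair(s) without exactly 2 samples: ",
         paste(utils::head(bad, 5), collapse = ", "))
  beta <- betaValues(bs)
  s1 <- vapply(pairMap, `[`, "", 1)
  s2 <- vapply(pairMap, `[`, "", 2)
  d <- abs(beta[, s1, drop = FALSE] - beta[, s2, drop = FALSE])
  list(discordance = rowMeans(d, na.rm = TRUE),
       n_pairs = rowSums(!is.na(d)))
}

#' Compare a per-probe statistic between VMR and background probes
#'
#' Wilcoxon rank-sum test of the statistic's distribution in VMR probes
#' against non-VMR background probes (the sets must be disjoint); both the
#' two-sided and the one-sided (VMR greater) p-values are reported with
#' group medians.
#'
#' @param track named numeric vector of a per-probe scalar (discordance,
#'   -log10 seasonal p, heritability, ...).
#' @param vmrProbes,backgroundProbes disjoint probe id sets.
#' @return list with \code{p_two_sided}, \code{p_greater}, \code{medians},
#'   \code{n}.
#' @export
compareVmrVsBackground <- function(track, vmrProbes, backgroundProbes) {
  if (length(intersect(vmrProbes, backgroundProbes)))
    stop("vmrProbes and backgroundProbes must be disjoint")
  x <- track[vmrProbes]; y <- track[backgroundProbes]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("empty comparison group")
  # fully tied inputs make the rank-sum statistic degenerate: no evidence
  pSafe <- function(alt) {
    p <- suppressWarnings(stats::wilcox.test(x, y,
                                             alternative = alt)$p.value)
    if (is.nan(p)) 1 else p
  }
  list(p_two_sided = pSafe("two.sided"),
       p_greater = pSafe("greater"),
       medians = c(vmr = stats::median(x), background = stats::median(y)),
       n = c(vmr = length(x), background = length(y)))
}

#' Per-probe two-group Student's t-test (e.g. rainy vs dry season)
#'
#' Equal-variance two-sample t-test per probe between the two exposure
#' groups (Welch available via \code{pooled = FALSE}); probes with fewer
#' than 3 non-missing values in either group are flagged missing.
#'
#' @param bs a \linkS4class{BetaSet}; groups are taken from the
#'   \code{group} colData column unless \code{groups} is given.
#' @param groups optional character vector of group labels per sample
#'   (exactly two levels).
#' @param pooled use pooled-variance Student's t (default) or Welch.
#' @return data.frame (probe_id, mean_1, mean_2, t, p, neglog10_p), with
#'   the group level names in the \code{"groups"} attribute.
#' @export
seasonalTest <- function(bs, groups = NULL, pooled = TRUE) {
  if (is.null(groups)) groups <- colData(bs)$group
  if (is.null(groups)) stop("no group labels available")
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("exactly two groups required")
  beta <- betaValues(bs)
  x <- beta[, groups == lev[1], drop = FALSE]
  y <- beta[, groups == lev[2], drop = FALSE]
  n1 <- rowSums(!is.na(x)); n2 <- rowSums(!is.na(y))
  m1 <- rowMeans(x, na.rm = TRUE); m2 <- rowMeans(y, na.rm = TRUE)
  v1 <- (rowSums(x * x, na.rm = TRUE) - n1 * m1^2) / pmax(n1 - 1, 1)
  v2 <- (rowSums(y * y, na.rm = TRUE) - n2 * m2^2) / pmax(n2 - 1, 1)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  bad <- n1 < 3 | n2 < 3
  tstat[bad] <- NA; p[bad] <- NA
  out <- data.frame(probe_id = rownames(beta), mean_1 = m1, mean_2 = m2,
                    t = tstat, p = p, neglog10_p = -log10(p),
                    row.names = NULL)
  attr(out, "groups") <- lev
  out
}

#' Heritability overlay on VMRs
#'
#' Compares user-supplied per-probe heritability estimates between VMR and
#' background probes (Wilcoxon rank-sum, via
#' \code{\link{compareVmrVsBackground}}); when VMR sets from several cell
#' types are provided, VMR probes are additionally stratified into shared
#' (found in more than one cell type) versus cell-type-specific.
#'
#' @param h2 named numeric vector of per-probe heritability in [0, 1].
#' @param vmrs a \linkS4class{VMRSet} or a list of them (one per cell
#'   type).
#' @param backgroundProbes background probe ids (VMR probes are removed
#'   internally).
#' @return list with \code{comparison} (VMR vs background) and, when
#'   stratifiable, \code{shared_vs_specific} medians and rank-sum p.
#' @export
heritabilityOverlay <- function(h2, vmrs, backgroundProbes) {
  vlist <- if (is(vmrs, "VMRSet")) list(vmrs) else vmrs
  probeSets <- lapply(vlist, vmrProbes)
  vp <- unique(unlist(probeSets))
  bg <- setdiff(backgroundProbes, vp)
  if (mean(vp %in% names(h2)) < 0.5)
    warning("heritability missing for >50% of VMR probes")
  out <- list(comparison = compareVmrVsBackground(h2, vp, bg))
  if (length(probeSets) > 1) {
    counts <- table(unlist(probeSets))
    shared <- names(counts)[counts > 1]
    specific <- names(counts)[counts == 1]
    if (length(shared) && length(specific)) {
      xs <- h2[shared]; xp <- h2[specific]
      out$shared_vs_specific <- list(
        medians = c(shared = stats::median(xs, na.rm = TRUE),
                    specific = stats::median(xp, na.rm = TRUE)),
        p_greater = stats::wilcox.test(xs, xp,
                                       alternative = "greater")$p.value)
    }
  }
  out
}

#' Time-course VMR calling with trend statistics
#'
#' Runs the standard sliding-window VMR caller over the serial samples of
#' an isogenic time-course, treating the time points as the population:
#' no sex stratification, no quantile normalization, and no minimum-sample
#' exclusion (the caller's percentile uses every probe). Each called VMR is
#' annotated with the Spearman correlation of its representative probe's
#' beta against the time index.
#'
#' @param bs a \linkS4class{BetaSet} with a \code{time_point} colData
#'   column (>= 3 samples).
#' @param params a \code{\link{vmrParams}}.
#' @return list with \code{vmrs} (a \linkS4class{VMRSet}) and
#'   \code{trends} (data.frame vmr_id, spearman_rho, p).
#' @export
timecourseVmrs <- function(bs, params = vmrParams()) {
  if (ncol(bs) < 3) stop("time-course requires >= 3 samples")
  tp <- colData(bs)$time_point
  if (is.null(tp)) tp <- seq_len(ncol(bs)) - 1L
  manifest <- probeRanges(bs)
  wins <- enumerateWindows(manifest, params)
  track <- probeSD(bs, stratum = "timecourse", minSamples = 2)
  vmrs <- callVmrs(track, wins, params, manifest)
  gr <- vmrRanges(vmrs)
  beta <- betaValues(bs)
  trends <- do.call(rbind, lapply(seq_along(gr), function(i) {
    v <- beta[mcols(gr)$representative_probe[i], ]
    ct <- suppressWarnings(stats::cor.test(v, tp, method = "spearman"))
    data.frame(vmr_id = mcols(gr)$vmr_id[i],
               spearman_rho = unname(ct$estimate), p = ct$p.value)
  }))
  if (is.null(trends))
    trends <- data.frame(vmr_id = character(0), spearman_rho = numeric(0),
                         p = numeric(0))
  list(vmrs = vmrs, trends = trends)
}
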