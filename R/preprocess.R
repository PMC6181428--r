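#' Probe/sample filtering parameters
#'
#' Defaults follow standard 450k-style quality control: per-cell detection
#' p-value masking at 0.01, removal of probes failed in more than 5% of
#' samples, removal of probes with a common SNP (MAF >= 0.05) at the CpG or
#' within 5 bp upstream, removal of probes inside a CNV mask, and removal of
#' sex-chromosome probes.
#'
#' @param detection_p_max detection p-value above which a cell is masked.
#' @param sample_fail_frac_max maximum fraction of samples a probe may be
#'   missing/failed in before it is dropped.
#' @param snp_maf_min minimum minor allele frequency for a SNP to trigger
#'   probe removal.
#' @param snp_window_upstream_bp SNP search window upstream of the CpG (bp).
#' @param drop_sex_chroms drop probes on chrX/chrY.
#' @return list of class \code{FilterParams}.
#' @export
filterParams <- function(detection_p_max = 0.01, sample_fail_frac_max = 0.05,
                         snp_maf_min = 0.05, snp_window_upstream_bp = 5,
                         drop_sex_chroms = TRUE) {
  stopifnot(detection_p_max > 0, detection_p_max < 1,
            sample_fail_frac_max > 0, sample_fail_frac_max <= 1,
            snp_maf_min >= 0, snp_maf_min <= 0.5,
            snp_window_upstream_bp >= 0)
  structure(list(detection_p_max = detection_p_max,
                 sample_fail_frac_max = sample_fail_frac_max,
                 snp_maf_min = snp_maf_min,
                 snp_window_upstream_bp = snp_window_upstream_bp,
                 drop_sex_chroms = drop_sex_chroms),
            class = c("FilterParams", "list"))
}

#' Filter probes and mask failed measurements
#'
#' Applies, in a fixed and reported order: (1) per-cell masking of beta
#' values whose detection p exceeds the threshold; (2) removal of
#' sex-chromosome probes; (3) removal of probes whose CpG position or its
#' upstream window intersects a SNP with sufficient minor allele frequency;
#' (4) removal of probes inside the CNV mask; (5) removal of probes
#' missing or failed in more than \code{sample_fail_frac_max} of samples.
#'
#' @param bs a \linkS4class{BetaSet}.
#' @param detp optional detection p-value matrix aligned to
#'   \code{betaValues(bs)} (probes x samples).
#' @param snpSites optional GRanges of SNP positions; a numeric \code{maf}
#'   metadata column, when present, is thresholded at \code{snp_maf_min}.
#' @param cnvMask optional GRanges of copy-number-variant regions.
#' @param params a \code{\link{filterParams}}.
#' @return list with \code{beta} (filtered BetaSet) and \code{report}
#'   (data.frame of probes dropped per filter, in application order).
#' @export
filterProbes <- function(bs, detp = NULL, snpSites = NULL, cnvMask = NULL,
                         params = filterParams()) {
  beta <- betaValues(bs)
  steps <- character(); dropped <- integer()
  note <- function(step, n) {
    steps <<- c(steps, step); dropped <<- c(dropped, n)
  }
  if (!is.null(detp)) {
    if (!identical(dim(detp), dim(beta)))
      stop("schema error: detp dimensions must match beta")
    beta[detp > params$detection_p_max] <- NA
  }
  note("detection_p_masking", 0L)
  gr <- probeRanges(bs)
  keep <- rep(TRUE, nrow(beta))
  if (params$drop_sex_chroms) {
    sexChr <- as.character(seqnames(gr)) %in% c("chrX", "chrY", "X", "Y")
    keep <- keep & !sexChr
  }
  note("sex_chromosome_drop", sum(!keep))
  prev <- keep
  if (!is.null(snpSites) && length(snpSites)) {
    if (!is.null(mcols(snpSites)$maf))
      snpSites <- snpSites[mcols(snpSites)$maf >= params$snp_maf_min]
    win <- GRanges(seqnames(gr),
                   IRanges(pmax(start(gr) - params$snp_window_upstream_bp, 1),
                           start(gr)))
    hit <- countOverlaps(win, snpSites) > 0
    keep <- keep & !hit
  }
  note("snp_drop", sum(prev & !keep))
  prev <- keep
  if (!is.null(cnvMask) && length(cnvMask))
    keep <- keep & !(countOverlaps(gr, cnvMask) > 0)
  note("cnv_drop", sum(prev & !keep))
  prev <- keep
  failFrac <- rowMeans(is.na(beta))
  keep <- keep & failFrac <= params$sample_fail_frac_max
  note("sample_fail_fraction_drop", sum(prev & !keep))
  out <- bs[keep, ]
  SummarizedExperiment::assay(out, "beta") <- beta[keep, , drop = FALSE]
  report <- data.frame(filter = steps, probes_dropped = dropped)
  report <- rbind(report,
                  data.frame(filter = c("input_probes", "output_probes"),
                             probes_dropped = c(nrow(beta), sum(keep))))
  list(beta = out, report = report)
}

#' Quantile-normalize beta values across samples
#'
#' Replaces each sample's non-missing values by the mean of order statistics
#' across samples (standard quantile normalization, via
#' \code{limma::normalizeQuantiles}); missing values are handled by rank
#' interpolation against the reference distribution. With complete data the
#' per-sample sorted vectors are identical afterwards. A single-sample input
#' is returned unchanged with a warning.
#'
#' @param bs a \linkS4class{BetaSet}.
#' @return a \linkS4class{BetaSet} with the normalized beta assay.
#' @export
quantileNormalizeBeta <- function(bs) {
  beta <- betaValues(bs)
  if (ncol(beta) < 2) {
    warning("quantile normalization needs >= 2 samples; returning input")
    return(bs)
  }
  qn <- limma::normalizeQuantiles(beta)
  dimnames(qn) <- dimnames(beta)
  SummarizedExperiment::assay(bs, "beta") <- qn
  bs
}
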