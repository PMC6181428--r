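#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   countOverlaps reduce granges
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

#' BetaSet: methylation beta values with probe coordinates and sample metadata
#'
#' A \linkS4class{RangedSummarizedExperiment} subclass holding a single
#' \code{"beta"} assay of methylation fractions (probes as rows, samples as
#' columns), probe genomic positions as \code{rowRanges} (1-based CpG
#' coordinates, width 1) and per-sample metadata in \code{colData}
#' (\code{sex}, \code{cell_type}, and optionally \code{twin_pair_id},
#' \code{group}, \code{time_point}).
#'
#' Validity requires all non-missing beta values in [0, 1] and unique probe
#' and sample identifiers.
#'
#' @export
setClass("BetaSet", contains = "RangedSummarizedExperiment")

setValidity("BetaSet", function(object) {
  msg <- character()
  if (!("beta" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- assay(object, "beta")
    if (any(b < 0 | b > 1, na.rm = TRUE))
      msg <- c(msg, "beta values must lie in [0, 1] or be NA")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids (rownames) must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a BetaSet
#'
#' @param beta numeric matrix, probes x samples, values in [0,1] or NA.
#'   Rownames are probe ids, colnames sample ids.
#' @param manifest \code{GRanges} of probe positions named by probe id
#'   (see \code{\link{readManifest}}). Probes absent from the manifest are
#'   dropped with a warning.
#' @param sampleData \code{DataFrame} or data.frame of per-sample metadata;
#'   a \code{sex} column (\code{"M"}, \code{"F"} or \code{"unknown"}) is
#'   added as \code{"unknown"} when missing.
#' @return A \linkS4class{BetaSet}.
#' @export
BetaSet <- function(beta, manifest, sampleData = NULL) {
  if (is.null(rownames(beta)))
    stop("beta must have probe ids as rownames")
  if (is.null(colnames(beta)))
    colnames(beta) <- paste0("s", seq_len(ncol(beta)))
  keep <- rownames(beta) %in% names(manifest)
  if (!all(keep)) {
    warning(sum(!keep), " probe(s) absent from manifest dropped")
    beta <- beta[keep, , drop = FALSE]
  }
  rr <- manifest[rownames(beta)]
  if (is.null(sampleData))
    sampleData <- DataFrame(row.names = colnames(beta))
  sampleData <- as(sampleData, "DataFrame")
  if (is.null(sampleData$sex)) sampleData$sex <- "unknown"
  se <- SummarizedExperiment(assays = list(beta = beta), rowRanges = rr,
                             colData = sampleData)
  new("BetaSet", se)
}

#' @describeIn BetaSet beta-value matrix (probes x samples)
#' @param x,object a \code{BetaSet}
#' @export
betaValues <- function(x) assay(x, "beta")

#' @describeIn BetaSet probe coordinates as a named GRanges
#' @export
probeRanges <- function(x) {
  gr <- rowRanges(x)
  names(gr) <- rownames(x)
  gr
}

#' VMRSet: called variably methylated regions
#'
#' Holds VMRs as a \code{GRanges} (1-based, closed intervals spanning the
#' variable member probes) with per-VMR metadata columns \code{vmr_id},
#' \code{n_probes} (number of variable member probes), \code{probe_ids}
#' (\code{CharacterList} of variable member probes), \code{representative_probe}
#' (member with the highest standard deviation), \code{max_sd}, and
#' \code{source_sex} for sex-stratified calls. The \code{background} slot
#' records the probe universe (probes in candidate windows) used for the
#' percentile threshold and all enrichment analyses; \code{params} records
#' the caller parameters and per-stratum thresholds.
#'
#' @slot ranges GRanges of VMR intervals plus metadata columns.
#' @slot stratum character label of the stratum the calls come from.
#' @slot params list of caller parameters and thresholds.
#' @slot background character vector of background probe ids.
#' @export
setClass("VMRSet", representation(ranges = "GRanges", stratum = "character",
                                  params = "list", background = "character"))

setValidity("VMRSet", function(object) {
  m <- mcols(object@ranges)
  need <- c("vmr_id", "n_probes", "probe_ids", "representative_probe", "max_sd")
  if (!all(need %in% colnames(m)))
    return(paste("missing VMR metadata column(s):",
                 paste(setdiff(need, colnames(m)), collapse = ", ")))
  if (length(object@ranges) && anyDuplicated(m$vmr_id))
    return("vmr_id must be unique")
  TRUE
})

#' @describeIn VMRSet VMR intervals as GRanges with metadata
#' @param x a \code{VMRSet}
#' @export
vmrRanges <- function(x) x@ranges

#' @describeIn VMRSet number of VMRs
#' @export
nVmrs <- function(x) length(x@ranges)

#' @describeIn VMRSet representative probe id per VMR (named by vmr_id)
#' @export
representativeProbes <- function(x) {
  stats::setNames(mcols(x@ranges)$representative_probe, mcols(x@ranges)$vmr_id)
}

#' @describeIn VMRSet all variable member probe ids across VMRs
#' @export
vmrProbes <- function(x) unique(unlist(mcols(x@ranges)$probe_ids))

#' @describeIn VMRSet background probe universe used by the caller
#' @export
backgroundProbes <- function(x) x@background

setMethod("show", "VMRSet", function(object) {
  cat("VMRSet with", length(object@ranges), "VMRs (stratum:",
      object@stratum, ")\n")
  if (length(object@ranges)) {
    cat("  mean span:", round(mean(width(object@ranges)), 1), "bp;",
        "mean probes per VMR:",
        round(mean(mcols(object@ranges)$n_probes), 2), "\n")
  }
  cat("  background universe:", length(object@background), "probes\n")
})

#' Per-probe variability track within a stratum
#'
#' Sample standard deviations (denominator n-1) of beta values per probe,
#' computed over the non-missing values of one stratum, together with the
#' number of samples used and (once a caller has run) the percentile
#' threshold value.
#'
#' @slot sd named numeric vector of per-probe SDs.
#' @slot nUsed named integer vector of sample counts per probe.
#' @slot stratum character stratum label.
#' @slot threshold numeric; the SD percentile threshold (NA until computed).
#' @slot excluded character; probes with too few samples, excluded from the
#'   percentile computation.
#' @export
setClass("VariabilityTrack", representation(sd = "numeric", nUsed = "integer",
                                            stratum = "character",
                                            threshold = "numeric",
                                            excluded = "character"))

setMethod("show", "VariabilityTrack", function(object) {
  cat("VariabilityTrack:", length(object@sd), "probes, stratum",
      object@stratum, "\n  threshold:",
      ifelse(is.na(object@threshold), "not computed", object@threshold), "\n")
})

#' ModuleAssignment: co-methylation module labels and eigengenes
#'
#' @slot membership DataFrame with columns \code{vmr_id}, \code{module}
#'   (integer, 0 = unassigned) and \code{kME} (correlation with the own-module
#'   eigengene; NA for unassigned VMRs).
#' @slot eigengenes samples x modules matrix of module eigengene profiles.
#' @slot params list of network parameters.
#' @export
setClass("ModuleAssignment",
         representation(membership = "DataFrame", eigengenes = "matrix",
                        params = "list"))

setMethod("show", "ModuleAssignment", function(object) {
  tab <- table(object@membership$module)
  assigned <- sum(object@membership$module > 0)
  cat("ModuleAssignment:", length(setdiff(names(tab), "0")), "modules,",
      assigned, "of", nrow(object@membership), "VMRs assigned\n")
})

#' @describeIn ModuleAssignment membership table (vmr_id, module, kME)
#' @param x a \code{ModuleAssignment}
#' @export
moduleLabels <- function(x) {
  stats::setNames(x@membership$module, x@membership$vmr_id)
}

#' @describeIn ModuleAssignment eigengene matrix (samples x modules)
#' @export
moduleEigengenes <- function(x) x@eigengenes
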