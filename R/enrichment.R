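hyperUpper <- function(k, K, N, n) stats::phyper(k - 1, K, N - K, n,
                                                 lower.tail = FALSE)
hyperLower <- function(k, K, N, n) stats::phyper(k, K, N - K, n)

enrichRow <- function(id, k, n, K, N, method, direction = "enrichment") {
  fold <- if (K > 0 && n > 0) (k / n) / (K / N) else NA_real_
  p <- if (K == 0) 1 else if (direction == "depletion")
    hyperLower(k, K, N, n) else hyperUpper(k, K, N, n)
  data.frame(id = id, k = k, n = n, K = K, N = N, fold = fold,
             p_raw = p, p_adjusted = NA_real_, method = method,
             direction = direction, stringsAsFactors = FALSE)
}

#' Probe-level feature enrichment
#'
#' A probe hits a feature when its CpG position lies inside any feature
#' interval. Fold enrichment is (k/n) / (K/N): the fraction of VMR probes
#' hitting the feature over the fraction of background probes hitting it.
#' The p-value is the upper-tail hypergeometric probability P(X >= k) for
#' enrichment; depletion is reported via the lower tail with a direction
#' column.
#'
#' @param vmrProbes character vector of VMR probe ids (subset of
#'   background).
#' @param background character vector of background probe ids.
#' @param feature GRanges of feature intervals.
#' @param manifest named GRanges of probe positions.
#' @param id feature name for the output row.
#' @param direction \code{"enrichment"} (default), \code{"depletion"}, or
#'   \code{"auto"} (depletion tail when fold < 1).
#' @return one-row data.frame (id, k, n, K, N, fold, p_raw, p_adjusted,
#'   method, direction).
#' @export
probeFeatureEnrichment <- function(vmrProbes, background, feature, manifest,
                                   id = "feature",
                                   direction = "enrichment") {
  if (!all(vmrProbes %in% background))
    stop("vmrProbes must be a subset of background")
  bgGr <- manifest[names(manifest) %in% background]
  hits <- names(bgGr)[countOverlaps(bgGr, feature) > 0]
  k <- sum(vmrProbes %in% hits); n <- length(vmrProbes)
  K <- length(hits); N <- length(background)
  if (direction == "auto") {
    fold <- if (K > 0 && n > 0) (k / n) / (K / N) else NA_real_
    direction <- if (!is.na(fold) && fold < 1) "depletion" else "enrichment"
  }
  enrichRow(id, k, n, K, N, "hypergeometric", direction)
}

#' Per-module TFBS enrichment (Fisher's exact test)
#'
#' Each TFBS interval is extended by \code{extendBp} on both sides before
#' overlap (VMR boundaries are imprecise); a VMR overlaps when it shares at
#' least 1 bp with any extended site. The 2x2 table crosses in-module
#' versus other VMRs with TFBS overlap versus not, over all VMRs of the
#' cell type; the one-sided (enrichment) Fisher exact p is reported, with
#' Bonferroni correction across TFs.
#'
#' @param moduleVmrs \linkS4class{VMRSet} (or character vmr ids) of the
#'   module's VMRs.
#' @param allVmrs \linkS4class{VMRSet} of all VMRs in the cell type.
#' @param tfbs named list of GRanges, one per transcription factor.
#' @param extendBp extension in bp (default 500).
#' @return data.frame, one row per TF: counts (k = in-module VMRs
#'   overlapping, n = module size, K = all VMRs overlapping, N = all VMRs),
#'   fold, odds ratio, raw and Bonferroni p.
#' @export
tfbsModuleEnrichment <- function(moduleVmrs, allVmrs, tfbs, extendBp = 500) {
  allGr <- vmrRanges(allVmrs)
  modIds <- if (is(moduleVmrs, "VMRSet"))
    mcols(vmrRanges(moduleVmrs))$vmr_id else moduleVmrs
  inMod <- mcols(allGr)$vmr_id %in% modIds
  if (!any(inMod)) stop("empty module")
  rows <- lapply(names(tfbs), function(tf) {
    ext <- tfbs[[tf]] + extendBp
    ov <- countOverlaps(allGr, ext) > 0
    k <- sum(ov & inMod); n <- sum(inMod)
    K <- sum(ov); N <- length(allGr)
    tab <- matrix(c(k, n - k, K - k, N - n - (K - k)), 2, 2)
    ft <- stats::fisher.test(tab, alternative = "greater")
    fold <- if (K > 0) (k / n) / (K / N) else NA_real_
    data.frame(id = tf, k = k, n = n, K = K, N = N, fold = fold,
               odds_ratio = unname(ft$estimate), p_raw = ft$p.value,
               p_adjusted = NA_real_, method = "fisher",
               direction = "enrichment", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, "bonferroni")
  attr(out, "correction") <- "bonferroni"
  out
}

#' Link VMRs to genes
#'
#' A VMR is linked to a gene when its interval intersects the closed window
#' [TSS - 2000, TSS + 2000] (boundary inclusive); auxiliary link tables
#' (e.g. DHS-correlation or eQTM links, columns \code{vmr_id},
#' \code{gene}, \code{type}) are appended with their provenance.
#'
#' @param vmrs a \linkS4class{VMRSet}.
#' @param tss GRanges of transcription start sites with a \code{gene}
#'   metadata column (or names).
#' @param linkTables optional data.frame (or list of them) of extra links.
#' @param tssWindowBp half-width of the TSS window (default 2000).
#' @return list with \code{links} (vmr_id, gene, type) and
#'   \code{frac_linked}, the fraction of VMRs linked to at least one gene.
#' @export
linkVmrsToGenes <- function(vmrs, tss, linkTables = NULL, tssWindowBp = 2000) {
  gr <- vmrRanges(vmrs)
  genes <- if (!is.null(mcols(tss)$gene)) mcols(tss)$gene else names(tss)
  win <- GRanges(seqnames(tss),
                 IRanges(pmax(start(tss) - tssWindowBp, 1),
                         start(tss) + tssWindowBp))
  hits <- findOverlaps(gr, win)
  links <- data.frame(
    vmr_id = mcols(gr)$vmr_id[S4Vectors::queryHits(hits)],
    gene = genes[S4Vectors::subjectHits(hits)],
    type = "tss_2kb", stringsAsFactors = FALSE)
  if (!is.null(linkTables)) {
    if (is.data.frame(linkTables)) linkTables <- list(linkTables)
    for (lt in linkTables) {
      if (is.null(lt$type)) lt$type <- "aux_link"
      links <- rbind(links, lt[, c("vmr_id", "gene", "type")])
    }
  }
  links <- unique(links)
  list(links = links,
       frac_linked = if (length(gr))
         mean(mcols(gr)$vmr_id %in% links$vmr_id) else NA_real_)
}

#' Gene Ontology enrichment (hypergeometric with BH FDR)
#'
#' Per term: k study genes carrying the term out of K universe genes
#' carrying it, with upper-tail hypergeometric p, gene-level fold
#' (k/n)/(K/N), and Benjamini-Hochberg q-values across tested terms. Terms
#' annotating fewer than \code{minTermGenes} universe genes are skipped.
#' Genes linked by several VMRs count once.
#'
#' @param studyGenes character vector of study genes (subset of universe).
#' @param universeGenes character vector of background genes.
#' @param gene2go data.frame with columns \code{gene} and \code{term}.
#' @param minTermGenes minimum universe genes per tested term (default 3).
#' @return data.frame, one row per tested term.
#' @export
goEnrichment <- function(studyGenes, universeGenes, gene2go,
                         minTermGenes = 3) {
  if (length(universeGenes) == 0) stop("empty gene universe")
  studyGenes <- unique(studyGenes); universeGenes <- unique(universeGenes)
  if (!all(studyGenes %in% universeGenes))
    stop("study genes must be a subset of the universe")
  g2g <- gene2go[gene2go$gene %in% universeGenes, , drop = FALSE]
  termGenes <- split(g2g$gene, g2g$term)
  termGenes <- termGenes[lengths(lapply(termGenes, unique)) >= minTermGenes]
  n <- length(studyGenes); N <- length(universeGenes)
  rows <- lapply(names(termGenes), function(tm) {
    tg <- unique(termGenes[[tm]])
    enrichRow(tm, sum(studyGenes %in% tg), n, length(tg), N,
              "hypergeometric")
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(id = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), fold = numeric(0),
                      p_raw = numeric(0), p_adjusted = numeric(0),
                      method = character(0), direction = character(0)))
  out$p_adjusted <- stats::p.adjust(out$p_raw, "BH")
  attr(out, "correction") <- "BH"
  out[order(out$p_raw), ]
}
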