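#' Read a probe manifest
#'
#' Reads a delimited text file with header columns \code{probe_id},
#' \code{chrom} and \code{pos} (1-based CpG coordinate, the anchor used for
#' sliding windows) and returns probe positions sorted by (chrom, pos).
#'
#' @param path path to a tab- (default) or otherwise-delimited text file.
#' @param sep field separator.
#' @return A named \code{GRanges} of width-1 probe positions, sorted by
#'   chromosome then position, with a \code{probe_id} metadata column.
#' @export
readManifest <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% colnames(df)))
    stop("manifest schema error: missing column(s): ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  if (!is.numeric(df$pos) || any(df$pos != as.integer(df$pos)))
    stop("manifest parse error: pos must be integer")
  if (any(df$pos < 1)) stop("manifest parse error: pos must be >= 1")
  if (anyDuplicated(df$probe_id))
    stop("manifest schema error: duplicate probe_id")
  manifestFromDataFrame(df)
}

#' Build a manifest GRanges from a data frame
#'
#' @param df data.frame with columns probe_id, chrom, pos.
#' @return sorted named GRanges, as from \code{\link{readManifest}}.
#' @export
manifestFromDataFrame <- function(df) {
  o <- order(df$chrom, df$pos)
  df <- df[o, , drop = FALSE]
  gr <- GRanges(df$chrom, IRanges(df$pos, width = 1), probe_id = df$probe_id)
  names(gr) <- df$probe_id
  gr
}

#' Write a manifest to delimited text
#' @param manifest named GRanges of probe positions.
#' @param path output path.
#' @export
writeManifest <- function(manifest, path) {
  df <- data.frame(probe_id = names(manifest),
                   chrom = as.character(seqnames(manifest)),
                   pos = start(manifest))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a beta-value matrix
#'
#' Reads a delimited text matrix whose first column is \code{sample_id} and
#' whose remaining columns are probe ids, plus an optional sidecar metadata
#' file keyed by \code{sample_id}. Values outside [0,1] are rejected; the
#' token \code{NA} maps to missing. Probe columns are aligned to manifest
#' order; probes unknown to the manifest are dropped with a warning.
#'
#' @param path beta matrix file (samples as rows).
#' @param manifest named GRanges from \code{\link{readManifest}}.
#' @param metaPath optional sidecar sample metadata file with a
#'   \code{sample_id} column.
#' @param sep field separator.
#' @return A \linkS4class{BetaSet} (probes x samples internally).
#' @export
readBeta <- function(path, manifest, metaPath = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (colnames(df)[1] != "sample_id")
    stop("beta schema error: first column must be sample_id")
  samples <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  if (any(m < 0 | m > 1, na.rm = TRUE))
    stop("beta range error: values must lie in [0, 1]")
  rownames(m) <- samples
  beta <- t(m)  # probes x samples
  known <- rownames(beta) %in% names(manifest)
  if (!all(known)) {
    warning("dropping ", sum(!known), " probe column(s) not in manifest: ",
            paste(utils::head(rownames(beta)[!known], 5), collapse = ", "))
    beta <- beta[known, , drop = FALSE]
  }
  ord <- names(manifest)[names(manifest) %in% rownames(beta)]
  beta <- beta[ord, , drop = FALSE]
  sd <- NULL
  if (!is.null(metaPath)) {
    md <- utils::read.table(metaPath, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(md))
      stop("metadata schema error: sample_id column required")
    rownames(md) <- md$sample_id
    sd <- DataFrame(md[colnames(beta), setdiff(colnames(md), "sample_id"),
                       drop = FALSE])
  }
  BetaSet(beta, manifest, sd)
}

#' Write a BetaSet's beta matrix (and optionally metadata) to delimited text
#'
#' @param bs a \code{BetaSet}.
#' @param path output path for the samples-x-probes matrix.
#' @param metaPath optional output path for the sample metadata.
#' @export
writeBeta <- function(bs, path, metaPath = NULL) {
  m <- t(betaValues(bs))
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metaPath)) {
    md <- as.data.frame(colData(bs))
    md <- data.frame(sample_id = colnames(bs), md, check.names = FALSE)
    utils::write.table(md, metaPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Export intervals as BED
#'
#' Internal intervals are 1-based closed; BED output is 0-based half-open
#' (handled by rtracklayer). The BED name column carries the VMR or feature
#' id. Ordering is deterministic (chrom, start); overlapping intervals are
#' written unmerged. An empty set yields a file holding only a header
#' comment.
#'
#' @param x a \code{GRanges} or \code{VMRSet}.
#' @param path output path.
#' @export
writeBed <- function(x, path) {
  if (is(x, "VMRSet")) {
    gr <- granges(x@ranges)
    names(gr) <- mcols(x@ranges)$vmr_id
  } else {
    gr <- granges(x)
    if (is.null(names(gr)) && !is.null(mcols(x)$name)) names(gr) <- mcols(x)$name
  }
  if (length(gr) == 0) {
    writeLines("# empty interval set", path)
    return(invisible(path))
  }
  gr <- gr[order(as.character(seqnames(gr)), start(gr))]
  if (is.null(names(gr))) names(gr) <- paste0("iv_", seq_along(gr))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Import a BED file as 1-based closed GRanges
#'
#' @param path BED file path.
#' @return GRanges (1-based closed, rtracklayer conversion), names from the
#'   BED name column. An empty/comment-only file gives an empty GRanges.
#' @export
readBed <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln) & nzchar(ln)]
  if (length(ln) == 0) return(GRanges())
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(mcols(gr)$name)) names(gr) <- mcols(gr)$name
  gr
}

#' Write a result table with a provenance block
#'
#' Writes a tab-delimited table preceded by '#'-prefixed provenance lines
#' (stage, parameters, seed, timestamp) so every pipeline output records how
#' it was produced.
#'
#' @param df data.frame of results.
#' @param path output path.
#' @param stage character stage tag.
#' @param params named list of parameters (serialized as JSON).
#' @param seed integer seed used (NA when the stage is deterministic).
#' @export
writeResultTable <- function(df, path, stage, params = list(), seed = NA) {
  hdr <- c(paste0("# stage: ", stage),
           paste0("# params: ",
                  jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA)),
           paste0("# seed: ", seed),
           paste0("# timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by \code{writeResultTable}
#' @param path file path.
#' @return data.frame; provenance lines are attached as the
#'   \code{"provenance"} attribute.
#' @export
readResultTable <- function(path) {
  ln <- readLines(path)
  prov <- ln[grepl("^#", ln)]
  df <- utils::read.table(text = ln[!grepl("^#", ln)], header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  attr(df, "provenance") <- prov
  df
}

logMsg <- function(stage, ...) {
  message("[", stage, "] ", ...)
}
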