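#' Co-methylation network parameters
#'
#' @param soft_power soft-thresholding exponent for the adjacency (default
#'   6; even powers make the network unsigned).
#' @param candidate_powers powers scanned by \code{\link{scaleFreeFit}}.
#' @param scale_free_fit_min minimum scale-free topology fit index for a
#'   power to be chosen.
#' @param min_module_size minimum VMRs per module.
#' @param kme_min minimum |module membership| to retain a VMR in its module.
#' @param edge_abs_r_min |r| threshold for the exported edge list.
#' @param min_pair_obs minimum overlapping samples for a pairwise
#'   correlation; sparser pairs get r = 0 and a flag.
#' @return list of class \code{NetworkParams}.
#' @export
networkParams <- function(soft_power = 6, candidate_powers = 1:20,
                          scale_free_fit_min = 0.8, min_module_size = 10,
                          kme_min = 0.7, edge_abs_r_min = 0.7,
                          min_pair_obs = 10) {
  stopifnot(soft_power >= 1, scale_free_fit_min > 0, scale_free_fit_min <= 1,
            min_module_size >= 2, kme_min > 0, kme_min <= 1)
  structure(list(soft_power = soft_power, candidate_powers = candidate_powers,
                 scale_free_fit_min = scale_free_fit_min,
                 min_module_size = min_module_size, kme_min = kme_min,
                 edge_abs_r_min = edge_abs_r_min,
                 min_pair_obs = min_pair_obs),
            class = c("NetworkParams", "list"))
}

#' Representative-probe beta matrix for a VMR set
#'
#' One column per VMR: the beta profile of its representative probe (the
#' member with the highest population SD; ties broken by lowest genomic
#' position at call time).
#'
#' @param bs a \linkS4class{BetaSet}.
#' @param vmrs a \linkS4class{VMRSet}.
#' @return numeric matrix, samples x VMRs, columns named by vmr_id.
#' @export
representativeMatrix <- function(bs, vmrs) {
  rep <- representativeProbes(vmrs)
  miss <- !(rep %in% rownames(bs))
  if (any(miss))
    stop("representative probe missing from beta matrix for VMR(s): ",
         paste(names(rep)[miss], collapse = ", "))
  m <- t(betaValues(bs)[rep, , drop = FALSE])
  colnames(m) <- names(rep)
  m
}

#' Pairwise VMR correlation matrix
#'
#' Pearson correlation between representative-probe beta profiles, with
#' pairwise-complete handling of missing values; pairs with fewer than
#' \code{min_pair_obs} overlapping samples are set to 0 and flagged in the
#' \code{"sparse_pairs"} attribute.
#'
#' @param repMatrix samples x VMRs matrix from
#'   \code{\link{representativeMatrix}}.
#' @param params a \code{\link{networkParams}}.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
vmrCorrelation <- function(repMatrix, params = networkParams()) {
  R <- suppressWarnings(stats::cor(repMatrix,
                                   use = "pairwise.complete.obs"))
  obs <- crossprod(!is.na(repMatrix))
  sparse <- obs < params$min_pair_obs
  flagged <- sum(sparse[upper.tri(sparse)] |
                   is.na(R[upper.tri(R)]))
  R[sparse | is.na(R)] <- 0
  diag(R) <- 1
  attr(R, "sparse_pairs") <- flagged
  R
}

#' Scale-free topology fit across candidate soft powers
#'
#' For each power, connectivity k_i = sum_{j != i} |r_ij|^power. The k
#' values are split into 10 equal-width bins; the fit index is the squared
#' Pearson correlation between log10(mean k per bin) and log10(bin
#' frequency). The chosen power is the smallest whose fit reaches
#' \code{scale_free_fit_min}, falling back to \code{soft_power} (with a
#' warning) when none does or the fit is undefined.
#'
#' @param R correlation matrix (>= 30 nodes recommended).
#' @param params a \code{\link{networkParams}}.
#' @return list with \code{table} (power, fit, mean_k) and
#'   \code{chosen_power}.
#' @export
scaleFreeFit <- function(R, params = networkParams()) {
  powers <- params$candidate_powers
  fits <- meank <- rep(NA_real_, length(powers))
  for (i in seq_along(powers)) {
    A <- abs(R)^powers[i]
    diag(A) <- 0
    k <- rowSums(A)
    meank[i] <- mean(k)
    if (all(k == 0) || length(unique(k)) < 3) next
    br <- seq(min(k), max(k), length.out = 11)
    bin <- cut(k, br, include.lowest = TRUE)
    freq <- tabulate(bin, nbins = 10)
    mk <- tapply(k, bin, mean)
    ok <- freq > 0 & !is.na(mk) & mk > 0
    if (sum(ok) < 3) next
    fits[i] <- suppressWarnings(
      stats::cor(log10(mk[ok]), log10(freq[ok]))^2)
  }
  pass <- which(!is.na(fits) & fits >= params$scale_free_fit_min)
  if (length(pass)) {
    chosen <- powers[pass[1]]
  } else {
    warning("no candidate power reaches scale-free fit ",
            params$scale_free_fit_min, "; falling back to power ",
            params$soft_power)
    chosen <- params$soft_power
  }
  list(table = data.frame(power = powers, fit = fits, mean_k = meank),
       chosen_power = chosen)
}

#' Soft-thresholded adjacency
#'
#' Elementwise |R|^power; an even power maps correlations of either sign
#' into [0, 1] (unsigned network).
#'
#' @param R correlation matrix.
#' @param power soft-thresholding exponent.
#' @return adjacency matrix with unit diagonal.
#' @export
adjacency <- function(R, power = 6) {
  A <- abs(R)^power
  diag(A) <- 1
  A
}

#' Topological overlap matrix
#'
#' Unsigned TOM: with k_i = sum_{u != i} A_iu,
#' TOM_ij = (sum_u A_iu A_uj + A_ij) / (min(k_i, k_j) + 1 - A_ij) for
#' i != j (the sum excluding u in \{i, j\}) and TOM_ii = 1. Node pairs with
#' many strong shared neighbors score high even when their direct adjacency
#' is moderate.
#'
#' @param A symmetric adjacency matrix (diagonal ignored).
#' @return symmetric TOM with unit diagonal, entries in [0, 1].
#' @export
tomSimilarity <- function(A) {
  if (!isSymmetric(unname(A), tol = 1e-10))
    stop("adjacency must be symmetric")
  A0 <- A
  diag(A0) <- 0
  k <- rowSums(A0)
  num <- A0 %*% A0 + A0        # (A0 %*% A0)_ij = sum_u A_iu A_uj, u not in {i,j}
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - A0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

## --- dynamic branch decomposition over an average-linkage dendrogram ---

hclustLeaves <- function(merge, node) {
  # node: row of merge; returns leaf indices under that internal node
  stack <- node
  leaves <- integer(0)
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    for (child in merge[nd, ]) {
      if (child < 0) leaves <- c(leaves, -child)
      else stack <- c(stack, child)
    }
  }
  leaves
}

meanDiss <- function(D, leaves) {
  if (length(leaves) < 2) return(0)
  sub <- D[leaves, leaves]
  mean(sub[upper.tri(sub)])
}

#' Detect co-methylation modules by dynamic branch decomposition
#'
#' Average-linkage hierarchical clustering on 1 - TOM, followed by a
#' dynamic decomposition of the dendrogram: starting at the root, a node is
#' split into its two child branches when both children independently
#' qualify as modules (at least \code{min_module_size} leaves and mean
#' intra-branch dissimilarity below the node's merge height); otherwise the
#' node itself is accepted as a module when it qualifies against its
#' parent's merge height. Leaves in no accepted branch are labeled 0
#' (unassigned). Module labels are ordered by size, largest first.
#'
#' @param tom TOM matrix from \code{\link{tomSimilarity}}.
#' @param params a \code{\link{networkParams}}.
#' @return a \linkS4class{ModuleAssignment} (kME column NA until
#'   \code{\link{moduleMembership}} is run).
#' @export
detectModules <- function(tom, params = networkParams()) {
  n <- nrow(tom)
  ids <- colnames(tom)
  if (is.null(ids)) ids <- paste0("v", seq_len(n))
  labels <- integer(n)
  if (n < params$min_module_size) {
    warning("fewer nodes than min_module_size; all unassigned")
  } else {
    D <- 1 - tom
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    nodeLeaves <- lapply(seq_len(nrow(hc$merge)), function(i)
      hclustLeaves(hc$merge, i))
    nodeMd <- vapply(nodeLeaves, function(lv) meanDiss(D, lv), 0)
    childSize <- function(c) if (c < 0) 1L else length(nodeLeaves[[c]])
    # strict-inequality tolerance so that flat branches (all pairwise
    # dissimilarities tied at the merge height) are not split
    qualifies <- function(c, height) {
      c > 0 && length(nodeLeaves[[c]]) >= params$min_module_size &&
        nodeMd[c] < height - 1e-10
    }
    modules <- list()
    decompose <- function(node, parentHeight) {
      if (length(nodeLeaves[[node]]) < params$min_module_size) return()
      h <- hc$height[node]
      ch <- hc$merge[node, ]
      ok <- vapply(ch, qualifies, TRUE, height = h)
      if (all(ok)) {
        for (c in ch) decompose(c, h)
      } else if (any(ok) &&
                 childSize(ch[!ok]) < params$min_module_size) {
        # shed a small straggler branch, keep descending the main branch
        decompose(ch[ok], parentHeight)
      } else if (nodeMd[node] < parentHeight) {
        modules[[length(modules) + 1L]] <<- nodeLeaves[[node]]
      }
    }
    decompose(nrow(hc$merge), Inf)
    if (length(modules)) {
      o <- order(-lengths(modules))
      for (m in seq_along(o)) labels[modules[[o[m]]]] <- m
    }
  }
  new("ModuleAssignment",
      membership = DataFrame(vmr_id = ids, module = labels,
                             kME = NA_real_),
      eigengenes = matrix(numeric(0), 0, 0), params = unclass(params))
}

moduleEigengene <- function(X) {
  # X: samples x members, complete columns standardized; PC1 score vector
  Z <- scale(X)
  Z[is.na(Z)] <- 0
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  e <- pc$x[, 1]
  if (stats::cor(e, rowMeans(Z)) < 0) e <- -e
  e / stats::sd(e)
}

#' Module eigengenes and membership (kME) assignment
#'
#' The eigengene of a module is the first principal component of its
#' standardized member columns, sign-oriented to correlate positively with
#' the member mean. kME(v, m) is the Pearson correlation between VMR v's
#' profile and module m's eigengene. Membership is resolved on |kME| (the
#' hybrid step): every VMR joins the module maximizing |kME| when that
#' value reaches \code{kme_min} -- detected members falling below the
#' threshold are removed, dendrogram stragglers correlating strongly with
#' an eigengene are attached -- and modules falling below
#' \code{min_module_size} afterwards are dissolved to unassigned.
#' Eigengenes are recomputed on the final members.
#'
#' @param repMatrix samples x VMRs matrix.
#' @param assignment a \linkS4class{ModuleAssignment} from
#'   \code{\link{detectModules}}.
#' @param params a \code{\link{networkParams}}.
#' @return a filtered \linkS4class{ModuleAssignment} with kME values and
#'   final eigengene matrix.
#' @export
moduleMembership <- function(repMatrix, assignment, params = networkParams()) {
  mem <- assignment@membership
  mods <- sort(setdiff(unique(mem$module), 0L))
  kme <- rep(NA_real_, nrow(mem))
  newLab <- integer(nrow(mem))
  constant <- apply(repMatrix[, mem$vmr_id, drop = FALSE], 2,
                    function(col) !(stats::sd(col, na.rm = TRUE) > 0))
  if (any(constant))
    message("ignoring ", sum(constant), " constant VMR column(s)")
  if (length(mods)) {
    kmeMat <- matrix(NA_real_, nrow(mem), length(mods),
                     dimnames = list(mem$vmr_id, mods))
    for (j in seq_along(mods)) {
      idx <- which(mem$module == mods[j] & !constant)
      if (length(idx) < 2) next
      e <- moduleEigengene(repMatrix[, mem$vmr_id[idx], drop = FALSE])
      kmeMat[!constant, j] <- suppressWarnings(
        stats::cor(repMatrix[, mem$vmr_id[!constant], drop = FALSE], e,
                   use = "pairwise.complete.obs")[, 1])
    }
    best <- apply(abs(kmeMat), 1, function(r)
      if (all(is.na(r))) NA_integer_ else which.max(r))
    bestK <- kmeMat[cbind(seq_len(nrow(mem)), best)]
    take <- !is.na(bestK) & abs(bestK) >= params$kme_min
    newLab[take] <- mods[best[take]]
    kme[take] <- bestK[take]
  }
  # dissolve undersized modules, relabel by size desc, recompute eigengenes
  for (m in mods) {
    if (sum(newLab == m) < params$min_module_size)
      newLab[newLab == m] <- 0L
  }
  keep <- sort(setdiff(unique(newLab), 0L))
  sizes <- vapply(keep, function(m) sum(newLab == m), 0L)
  relab <- integer(max(c(keep, 0L)))
  relab[keep[order(-sizes)]] <- seq_along(keep)
  finalLab <- newLab
  finalLab[newLab > 0] <- relab[newLab[newLab > 0]]
  eg <- NULL
  for (m in sort(unique(finalLab[finalLab > 0]))) {
    sel <- finalLab == m
    X <- repMatrix[, mem$vmr_id[sel], drop = FALSE]
    e <- moduleEigengene(X)
    kme[sel] <- suppressWarnings(
      stats::cor(X, e, use = "pairwise.complete.obs")[, 1])
    eg <- cbind(eg, e)
  }
  if (is.null(eg)) eg <- matrix(numeric(0), nrow(repMatrix), 0)
  colnames(eg) <- if (ncol(eg)) paste0("ME", seq_len(ncol(eg))) else character(0)
  rownames(eg) <- rownames(repMatrix)
  kme[finalLab == 0] <- NA_real_
  new("ModuleAssignment",
      membership = DataFrame(vmr_id = mem$vmr_id, module = finalLab,
                             kME = kme),
      eigengenes = eg, params = assignment@params)
}

#' Classify within-module VMR pairs as cis or trans
#'
#' A pair of co-module VMRs is trans when the two lie on different
#' chromosomes, cis otherwise.
#'
#' @param assignment a \linkS4class{ModuleAssignment}.
#' @param vmrs the \linkS4class{VMRSet} the assignment refers to.
#' @return list with \code{pairs} (module, vmr_i, vmr_j, type) and
#'   \code{summary} (per-module cis/trans pair counts and chromosome list).
#' @export
classifyCisTrans <- function(assignment, vmrs) {
  gr <- vmrRanges(vmrs)
  chrom <- stats::setNames(as.character(seqnames(gr)), mcols(gr)$vmr_id)
  mem <- assignment@membership
  pairs <- list(); summ <- list()
  for (m in sort(setdiff(unique(mem$module), 0L))) {
    v <- mem$vmr_id[mem$module == m]
    if (length(v) < 2) {
      summ[[as.character(m)]] <- data.frame(module = m, n_vmrs = length(v),
                                            n_cis = 0L, n_trans = 0L,
                                            chroms = unname(chrom[v]))
      next
    }
    cmb <- utils::combn(v, 2)
    type <- ifelse(chrom[cmb[1, ]] != chrom[cmb[2, ]], "trans", "cis")
    pairs[[as.character(m)]] <- data.frame(module = m, vmr_i = cmb[1, ],
                                           vmr_j = cmb[2, ], type = type)
    summ[[as.character(m)]] <- data.frame(
      module = m, n_vmrs = length(v), n_cis = sum(type == "cis"),
      n_trans = sum(type == "trans"),
      chroms = paste(sort(unique(chrom[v])), collapse = ","))
  }
  list(pairs = if (length(pairs)) do.call(rbind, c(pairs,
                                                   make.row.names = FALSE))
       else data.frame(module = integer(0), vmr_i = character(0),
                       vmr_j = character(0), type = character(0)),
       summary = if (length(summ)) do.call(rbind, c(summ,
                                                    make.row.names = FALSE))
       else data.frame())
}

#' Export strong correlation edges
#'
#' Upper-triangle VMR pairs with |r| at or above the threshold, labeled
#' cis/trans, ready for Circos-style plotting or graph tools.
#'
#' @param R VMR correlation matrix (dimnames = vmr ids).
#' @param vmrs the corresponding \linkS4class{VMRSet}.
#' @param threshold minimum |r| (default from \code{\link{networkParams}}).
#' @return data.frame (vmr_i, vmr_j, r, type).
#' @export
edgeList <- function(R, vmrs, threshold = 0.7) {
  gr <- vmrRanges(vmrs)
  chrom <- stats::setNames(as.character(seqnames(gr)), mcols(gr)$vmr_id)
  idx <- which(upper.tri(R) & abs(R) >= threshold, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(vmr_i = character(0), vmr_j = character(0),
                      r = numeric(0), type = character(0)))
  vi <- rownames(R)[idx[, 1]]; vj <- colnames(R)[idx[, 2]]
  data.frame(vmr_i = vi, vmr_j = vj, r = R[idx],
             type = ifelse(chrom[vi] != chrom[vj], "trans", "cis"),
             row.names = NULL)
}
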