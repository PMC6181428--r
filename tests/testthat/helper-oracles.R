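# Independent oracle implementations used to verify the package's
# algorithms.  These deliberately share no code with R/: plain loops and
# closed forms only.

# Brute-force sliding-window VMR caller: evaluates every probe-anchored
# window independently, merges overlapping qualifying windows by sweeping,
# and spans each region by its variable probes.
bruteVmrOracle <- function(chrom, pos, sdv, windowBp = 1000, minProbes = 3,
                           minFrac = 0.5, percentile = 95) {
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]; sdv <- sdv[o]
  n <- length(pos)
  members <- vector("list", n)
  for (i in seq_len(n)) {
    members[[i]] <- which(chrom == chrom[i] & pos >= pos[i] &
                            pos < pos[i] + windowBp)
  }
  bg <- sort(unique(unlist(members[lengths(members) >= minProbes])))
  thr <- stats::quantile(sdv[bg], percentile / 100, type = 7)
  isVar <- sdv >= thr
  qual <- logical(n)
  for (i in seq_len(n)) {
    m <- members[[i]]
    if (length(m) < minProbes) next
    nv <- sum(isVar[m])
    qual[i] <- nv >= minProbes && nv / length(m) >= minFrac
  }
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(qual & chrom == ch)
    if (!length(idx)) next
    starts <- pos[idx]; ends <- pos[idx] + windowBp - 1
    ord <- order(starts)
    starts <- starts[ord]; ends <- ends[ord]
    curS <- starts[1]; curE <- ends[1]
    flush <- function(s, e) {
      vp <- which(chrom == ch & isVar & pos >= s & pos <= e)
      out[[length(out) + 1]] <<- list(chrom = ch, start = min(pos[vp]),
                                      end = max(pos[vp]),
                                      probes = sort(vp))
    }
    if (length(starts) > 1) {
      for (j in 2:length(starts)) {
        if (starts[j] <= curE) curE <- max(curE, ends[j])
        else { flush(curS, curE); curS <- starts[j]; curE <- ends[j] }
      }
    }
    flush(curS, curE)
  }
  out
}

# canonical string form of a VMR call for set comparison
vmrKey <- function(chrom, start, end) paste(chrom, start, end, sep = ":")

oracleKeys <- function(or) vapply(or, function(v)
  vmrKey(v$chrom, v$start, v$end), "")

vmrsetKeys <- function(vmrs) {
  gr <- vmrRanges(vmrs)
  vmrKey(as.character(GenomicRanges::seqnames(gr)),
         GenomicRanges::start(gr), GenomicRanges::end(gr))
}

# Brute-force TOM: triple loop over the formula
bruteTom <- function(A) {
  n <- nrow(A)
  diag(A) <- 0
  k <- rowSums(A)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + A[i, u] * A[u, j]
    tom[i, j] <- (s + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  tom
}

# Exact hypergeometric upper tail by combinatorial sum (log-scale terms)
hyperOracle <- function(k, K, N, n) {
  xs <- k:min(n, K)
  if (length(xs) == 0 || k > min(n, K)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# quick synthetic manifest for caller-oracle tests
randomManifestTrack <- function(nProbes, seed) {
  set.seed(seed)
  nChrom <- sample(1:3, 1)
  chrom <- sort(sample(paste0("chr", seq_len(nChrom)), nProbes,
                       replace = TRUE))
  pos <- unlist(lapply(split(seq_len(nProbes), chrom), function(i) {
    # mixture of tight clusters and scattered probes
    p <- cumsum(sample(c(50:400, 2000:8000), length(i), replace = TRUE,
                       prob = c(rep(4, 351), rep(1, 6001))))
    p + 100
  }))
  ids <- sprintf("p%05d", seq_len(nProbes))
  df <- data.frame(probe_id = ids, chrom = chrom, pos = as.integer(pos))
  sdv <- stats::runif(nProbes, 0, 0.2)
  names(sdv) <- ids
  list(df = df, sd = sdv)
}

smallSim <- function(seed = 1, ...) {
  cfg <- simConfig(n_chrom = 3, probes_per_chrom = 700, seed = seed,
                   n_planted_vmrs = 30, n_trans_modules = 2,
                   vmrs_per_module = 10, ...)
  list(cfg = cfg, sim = simulateManifest(cfg))
}
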