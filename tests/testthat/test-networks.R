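blockRepMatrix <- function(sizes, loading = 0.9, n = 100, noise = 0,
                           seed = 1) {
  set.seed(seed)
  f <- matrix(rnorm(n * length(sizes)), n)
  X <- do.call(cbind, lapply(seq_along(sizes), function(m)
    loading * f[, m] + sqrt(1 - loading^2) *
      matrix(rnorm(n * sizes[m]), n)))
  if (noise > 0) X <- cbind(X, matrix(rnorm(n * noise), n))
  colnames(X) <- sprintf("v%03d", seq_len(ncol(X)))
  X
}

mkVmrSetOnChroms <- function(ids, chroms) {
  gr <- GenomicRanges::GRanges(chroms,
                               IRanges::IRanges(seq_along(ids) * 1000,
                                                width = 500))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    vmr_id = ids, n_probes = 3L,
    probe_ids = IRanges::CharacterList(as.list(paste0(ids, "_p"))),
    representative_probe = paste0(ids, "_p"),
    max_sd = rep(0.2, length(ids)), source_sex = "all")
  new("VMRSet", ranges = gr, stratum = "all", params = list(),
      background = paste0(ids, "_p"))
}

test_that("representativeMatrix picks the highest-SD probe per VMR", {
  # one variable cluster (a, b, c; b most variable) against 30 quiet
  # background clusters that define the percentile universe
  bgPos <- as.vector(outer(c(0, 100, 200), seq(20000, by = 15000,
                                               length.out = 30), "+"))
  ids <- c("a", "b", "c", sprintf("bg%03d", seq_along(bgPos)))
  man <- manifestFromDataFrame(data.frame(
    probe_id = ids, chrom = "chr1", pos = c(100, 200, 300, sort(bgPos))))
  set.seed(2)
  n <- 40
  beta <- matrix(0.5 + rnorm(length(ids) * n, 0, 0.01), length(ids), n,
                 dimnames = list(ids, paste0("s", 1:n)))
  beta["a", ] <- 0.5 + rnorm(n, 0, 0.05)
  beta["b", ] <- 0.5 + rnorm(n, 0, 0.12)
  beta["c", ] <- 0.5 + rnorm(n, 0, 0.08)
  bs <- BetaSet(pmin(pmax(beta, 0.001), 0.999), man)
  tr <- probeSD(bs, minSamples = 2)
  wins <- enumerateWindows(probeRanges(bs), vmrParams())
  called <- callVmrs(tr, wins, vmrParams(), probeRanges(bs))
  expect_equal(nVmrs(called), 1)
  expect_equal(S4Vectors::mcols(vmrRanges(called))$representative_probe, "b")
  m <- representativeMatrix(bs, called)
  expect_equal(ncol(m), nVmrs(called))
  expect_equal(unname(m[, 1]), unname(betaValues(bs)["b", ]))
  bad <- bs[setdiff(ids, "b"), ]
  expect_error(representativeMatrix(bad, called), "missing")
})

test_that("SD ties break to the lowest genomic position", {
  man <- manifestFromDataFrame(data.frame(
    probe_id = c("a", "b", "c"), chrom = "chr1", pos = c(100, 200, 300)))
  sdv <- c(a = 0.3, b = 0.3, c = 0.3)
  tr <- new("VariabilityTrack", sd = sdv,
            nUsed = c(a = 50L, b = 50L, c = 50L), stratum = "all",
            threshold = NA_real_, excluded = character(0))
  wins <- enumerateWindows(man, vmrParams())
  called <- callVmrs(tr, wins, vmrParams(), man)
  expect_equal(S4Vectors::mcols(vmrRanges(called))$representative_probe, "a")
})

test_that("TOM matches its closed forms and the brute-force oracle", {
  A0 <- diag(4)
  expect_equal(tomSimilarity(A0), diag(4))

  A1 <- matrix(1, 3, 3)
  tom1 <- tomSimilarity(A1)
  expect_equal(unname(tom1), matrix(1, 3, 3))  # (1+1)/(2+1-1) = 1

  set.seed(8)
  for (n in c(50, 80)) {
    R <- cor(matrix(rnorm(40 * n), 40, n))
    A <- adjacency(R, 6)
    expect_equal(tomSimilarity(A), bruteTom(A), tolerance = 1e-12)
  }
  expect_error(tomSimilarity(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("soft-thresholded adjacency is bounded and monotone in |r|", {
  set.seed(9)
  R <- cor(matrix(rnorm(30 * 40), 30, 40))
  A <- adjacency(R, 6)
  expect_true(all(A >= 0 & A <= 1))
  o <- order(abs(R[1, -1]))
  expect_true(all(diff(A[1, -1][o]) >= 0))
})

test_that("scaleFreeFit reports per-power indices, falls back on
           degenerate input and is permutation invariant", {
  expect_warning(sf0 <- scaleFreeFit(diag(40)), "falling back")
  expect_equal(sf0$chosen_power, 6)
  expect_true(all(is.na(sf0$table$fit)))

  X <- blockRepMatrix(c(rep(3, 20), rep(8, 6), 20), noise = 10, seed = 3)
  R <- cor(X)
  sf <- suppressWarnings(scaleFreeFit(R))
  expect_equal(nrow(sf$table), 20)
  expect_true(all(diff(sf$table$mean_k) < 0))  # mean k falls with power
  perm <- sample(ncol(R))
  sfP <- suppressWarnings(scaleFreeFit(R[perm, perm]))
  expect_equal(sfP$table$fit, sf$table$fit, tolerance = 1e-12)
  # when some power passes, the smallest passing power is chosen
  pass <- which(!is.na(sf$table$fit) &
                  sf$table$fit >= networkParams()$scale_free_fit_min)
  if (length(pass)) expect_equal(sf$chosen_power, sf$table$power[pass[1]])
})

test_that("detectModules separates clean blocks and respects min size", {
  tomBlock <- function(sizes, intra = 0.8, inter = 0.05) {
    n <- sum(sizes)
    lab <- rep(seq_along(sizes), sizes)
    tom <- matrix(inter, n, n)
    for (m in seq_along(sizes)) tom[lab == m, lab == m] <- intra
    diag(tom) <- 1
    dimnames(tom) <- list(sprintf("v%03d", 1:n), sprintf("v%03d", 1:n))
    tom
  }
  tom <- tomBlock(c(15, 15))
  mods <- detectModules(tom)
  lab <- moduleLabels(mods)
  expect_equal(as.integer(sort(table(lab))), c(15, 15))
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:15])), 1)

  expect_warning(m9 <- detectModules(tomBlock(9)), "unassigned")
  expect_true(all(moduleLabels(m9) == 0))

  # permutation invariance up to relabeling
  set.seed(10)
  tom3 <- tomBlock(c(12, 12, 14), intra = 0.7)
  perm <- sample(nrow(tom3))
  l1 <- moduleLabels(detectModules(tom3))[perm]
  l2 <- moduleLabels(detectModules(tom3[perm, perm]))
  expect_equal(mclust::adjustedRandIndex(l1, l2), 1)
})

test_that("module eigengenes and kME behave as constructed", {
  # two identical member profiles -> kME 1
  set.seed(11)
  prof <- rnorm(50)
  X <- cbind(v1 = prof, v2 = prof, v3 = prof + rnorm(50, 0, 2),
             v4 = prof + rnorm(50, 0, 2), v5 = prof + rnorm(50, 0, 2),
             v6 = prof + rnorm(50, 0, 2), v7 = prof + rnorm(50, 0, 2),
             v8 = prof + rnorm(50, 0, 2), v9 = prof + rnorm(50, 0, 2),
             v10 = prof + rnorm(50, 0, 2))
  asn <- new("ModuleAssignment",
             membership = S4Vectors::DataFrame(
               vmr_id = colnames(X), module = rep(1L, 10), kME = NA_real_),
             eigengenes = matrix(numeric(0), 0, 0),
             params = unclass(networkParams()))
  got <- moduleMembership(X, asn, networkParams(kme_min = 0.1,
                                                min_module_size = 2))
  k <- got@membership$kME[got@membership$vmr_id %in% c("v1", "v2")]
  expect_true(all(k > 0.95))

  # anti-correlated member retained through |kME|
  Xa <- blockRepMatrix(c(12), loading = 0.9, seed = 12)
  Xa[, 1] <- -Xa[, 1]
  asn2 <- new("ModuleAssignment",
              membership = S4Vectors::DataFrame(
                vmr_id = colnames(Xa), module = rep(1L, 12),
                kME = NA_real_),
              eigengenes = matrix(numeric(0), 0, 0),
              params = unclass(networkParams()))
  got2 <- moduleMembership(Xa, asn2, networkParams())
  m1 <- got2@membership
  expect_equal(m1$module[1], 1L)          # retained
  expect_lt(m1$kME[1], -0.7)              # with its sign recorded

  # planted loading 0.9 -> mean kME about 0.9
  Xp <- blockRepMatrix(c(12, 12), loading = 0.9, n = 100, seed = 13)
  tom <- tomSimilarity(adjacency(cor(Xp), 6))
  got3 <- moduleMembership(Xp, detectModules(tom), networkParams())
  expect_equal(mean(abs(got3@membership$kME), na.rm = TRUE), 0.9,
               tolerance = 0.05)
})

test_that("cis/trans classification counts pairs by chromosome", {
  vmrs <- mkVmrSetOnChroms(c("a", "b", "c"), c("chr2", "chr7", "chr7"))
  asn <- new("ModuleAssignment",
             membership = S4Vectors::DataFrame(
               vmr_id = c("a", "b", "c"), module = c(1L, 1L, 1L),
               kME = 0.9),
             eigengenes = matrix(numeric(0), 0, 0), params = list())
  ct <- classifyCisTrans(asn, vmrs)
  expect_equal(nrow(ct$pairs), 3)                   # C(3,2)
  expect_equal(sum(ct$pairs$type == "trans"), 2)
  expect_equal(sum(ct$pairs$type == "cis"), 1)

  vmrs1 <- mkVmrSetOnChroms(c("a", "b"), c("chr2", "chr2"))
  asn1 <- new("ModuleAssignment",
              membership = S4Vectors::DataFrame(
                vmr_id = c("a", "b"), module = c(1L, 1L), kME = 0.9),
              eigengenes = matrix(numeric(0), 0, 0), params = list())
  expect_equal(classifyCisTrans(asn1, vmrs1)$summary$n_trans, 0)
})

test_that("edgeList thresholds the upper triangle", {
  vmrs <- mkVmrSetOnChroms(c("a", "b", "c"), c("chr1", "chr1", "chr2"))
  R <- diag(3)
  dimnames(R) <- list(c("a", "b", "c"), c("a", "b", "c"))
  R["a", "b"] <- R["b", "a"] <- 0.75
  R["a", "c"] <- R["c", "a"] <- -0.9
  expect_equal(nrow(edgeList(R, vmrs, threshold = 1.01)), 0)
  e <- edgeList(R, vmrs, threshold = 0.7)
  expect_equal(nrow(e), 2)
  expect_equal(sum(abs(R[upper.tri(R)]) >= 0.7), nrow(e))
  expect_equal(e$type[e$vmr_i == "a" & e$vmr_j == "c"], "trans")
})
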