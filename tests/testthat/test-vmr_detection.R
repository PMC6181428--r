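mkTrack <- function(sdv, stratum = "all") {
  new("VariabilityTrack", sd = sdv,
      nUsed = stats::setNames(rep(100L, length(sdv)), names(sdv)),
      stratum = stratum, threshold = NA_real_, excluded = character(0))
}

mkMan <- function(pos, chrom = "chr1", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("p%03d", seq_along(pos))
  manifestFromDataFrame(data.frame(
    probe_id = ids, chrom = rep(chrom, length.out = length(pos)),
    pos = pos))
}

test_that("probeSD computes n-1 sample SDs and flags sparse probes", {
  man <- mkMan(c(100, 200, 300))
  m <- rbind(p001 = c(0.2, 0.4, 0.3, 0.1),
             p002 = rep(0.5, 4),
             p003 = c(0.2, 0.4, NA, NA))
  bs <- BetaSet(m, man)
  tr <- probeSD(bs, minSamples = 3)
  expect_equal(unname(tr@sd["p001"]), sd(c(0.2, 0.4, 0.3, 0.1)))
  expect_equal(unname(tr@sd["p002"]), 0)
  expect_equal(unname(tr@sd["p003"]), sd(c(0.2, 0.4)))  # 0.1414214
  expect_equal(unname(tr@sd["p003"]), 0.1414214, tolerance = 1e-6)
  expect_equal(tr@excluded, "p003")
  expect_error(probeSD(bs, samples = integer(0)), "empty stratum")
})

test_that("the 95th-percentile threshold interpolates order statistics", {
  pos <- seq(100, by = 2000, length.out = 100)  # isolated probes
  # cluster 3 extra probes beside each so windows qualify as candidates
  sdv <- 0.001 * (1:100)
  names(sdv) <- sprintf("p%03d", 1:100)
  # direct quantile contract (type 7)
  expect_equal(unname(quantile(sdv, 0.95, type = 7)), 0.09505)
})

test_that("enumerateWindows applies the half-open probe-anchored rule", {
  man <- mkMan(c(100, 500, 900, 2500))
  w <- enumerateWindows(man, vmrParams())
  expect_equal(length(w$windows), 1)          # only window at 100 qualifies
  expect_equal(S4Vectors::mcols(w$windows)$anchor, "p001")
  expect_equal(sort(unlist(S4Vectors::mcols(w$windows)$members)),
               c("p001", "p002", "p003"), ignore_attr = TRUE)
  expect_equal(sort(w$background), c("p001", "p002", "p003"))

  man2 <- mkMan(c(100, 300, 600, 1100))
  w2 <- enumerateWindows(man2, vmrParams())
  m1 <- unlist(S4Vectors::mcols(
    w2$windows[S4Vectors::mcols(w2$windows)$anchor == "p001"])$members)
  expect_false("p004" %in% m1)  # 1100 excluded from [100, 1100)

  expect_equal(length(enumerateWindows(mkMan(integer(0)),
                                       vmrParams())$windows), 0)
})

test_that("window qualification needs both the count and fraction rules", {
  # window with 4 probes, 3 variable -> qualifies; 6 probes, 2 variable -> no
  pos <- c(100, 200, 300, 400,   5000, 5100, 5200, 5300, 5400, 5500)
  man <- mkMan(pos)
  sdv <- c(0.5, 0.5, 0.5, 0.01,  0.5, 0.5, 0.01, 0.01, 0.01, 0.01)
  # pad with background probes so the percentile is low
  bgPos <- seq(20000, by = 250, length.out = 90)
  man <- mkMan(c(pos, bgPos))
  sdv <- c(sdv, runif(90, 0.001, 0.05))
  names(sdv) <- names(man)
  tr <- mkTrack(sdv)
  w <- enumerateWindows(man, vmrParams())
  called <- callVmrs(tr, w, vmrParams(), man)
  gr <- vmrRanges(called)
  expect_equal(length(gr), 1)
  expect_equal(GenomicRanges::start(gr), 100)
  expect_equal(GenomicRanges::end(gr), 300)   # span of variable probes
  expect_equal(S4Vectors::mcols(gr)$n_probes, 3)
  expect_equal(S4Vectors::mcols(gr)$representative_probe, "p001")
})

test_that("callVmrs matches the brute-force oracle on random inputs", {
  for (seed in 1:15) {
    rt <- randomManifestTrack(nProbes = sample(200:600, 1), seed = seed)
    man <- manifestFromDataFrame(rt$df)
    tr <- mkTrack(rt$sd[names(man)])
    w <- enumerateWindows(man, vmrParams())
    called <- callVmrs(tr, w, vmrParams(), man)
    or <- bruteVmrOracle(rt$df$chrom, rt$df$pos,
                         rt$sd[rt$df$probe_id])
    expect_setequal(vmrsetKeys(called), oracleKeys(or))
  }
})

test_that("caller is monotone in its thresholds", {
  rt <- randomManifestTrack(400, seed = 99)
  man <- manifestFromDataFrame(rt$df)
  tr <- mkTrack(rt$sd[names(man)])
  counts <- sapply(c(80, 90, 95, 99), function(pct) {
    p <- vmrParams(sd_percentile = pct)
    nVmrs(callVmrs(tr, enumerateWindows(man, p), p, man))
  })
  expect_true(all(diff(counts) <= 0))

  n3 <- nVmrs(callVmrs(tr, enumerateWindows(man, vmrParams()),
                       vmrParams(), man))
  p2 <- vmrParams(min_variable_probes = 2)
  n2 <- nVmrs(callVmrs(tr, enumerateWindows(man, p2), p2, man))
  expect_gte(n2, n3)
})

test_that("sex-stratified calling unions per-sex calls", {
  set.seed(21)
  # probes: cluster A variable in males only, cluster B in females only,
  # cluster C in both; plus background clusters
  pos <- c(1000, 1200, 1400,  9000, 9200, 9400,  20000, 20200, 20400,
           seq(50000, by = 300, length.out = 200))
  man <- mkMan(pos)
  n <- 40; sex <- rep(c("M", "F"), each = n / 2)
  beta <- matrix(0.5 + rnorm(length(man) * n, 0, 0.01), length(man), n,
                 dimnames = list(names(man), paste0("s", 1:n)))
  zM <- rnorm(n / 2, 0, 0.2); zF <- rnorm(n / 2, 0, 0.2)
  zB <- rnorm(n, 0, 0.2)
  beta[1:3, sex == "M"] <- beta[1:3, sex == "M"] + rep(zM, each = 3)
  beta[4:6, sex == "F"] <- beta[4:6, sex == "F"] + rep(zF, each = 3)
  beta[7:9, ] <- beta[7:9, ] + rep(zB, each = 3)
  bs <- BetaSet(pmin(pmax(beta, 0.001), 0.999), man,
                S4Vectors::DataFrame(sex = sex))
  comb <- callVmrsSexStratified(bs, vmrParams())
  keys <- vmrsetKeys(comb)
  expect_true(vmrKey("chr1", 1000, 1400) %in% keys)   # male-only VMR kept
  expect_true(vmrKey("chr1", 9000, 9400) %in% keys)   # female-only VMR kept
  expect_true(vmrKey("chr1", 20000, 20400) %in% keys)

  # union contains each single-sex call set (as overlapping intervals)
  p <- vmrParams()
  wins <- enumerateWindows(man, p)
  for (sx in c("M", "F")) {
    one <- callVmrs(probeSD(bs, samples = which(sex == sx), stratum = sx),
                    wins, p, man)
    expect_true(all(GenomicRanges::countOverlaps(vmrRanges(one),
                                                 vmrRanges(comb)) > 0))
  }

  # pooled fallback when one sex is absent
  bsU <- BetaSet(betaValues(bs), man,
                 S4Vectors::DataFrame(sex = rep("unknown", n)))
  expect_warning(pooled <- callVmrsSexStratified(bsU, vmrParams()),
                 "pooled")
  expect_s4_class(pooled, "VMRSet")
})

test_that("merging overlapping male/female intervals spans their union", {
  grM <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1800))
  S4Vectors::mcols(grM) <- S4Vectors::DataFrame(
    vmr_id = "M_vmr0001", n_probes = 3L,
    probe_ids = IRanges::CharacterList(list(c("a", "b", "c"))),
    representative_probe = "a", max_sd = 0.2, source_sex = "M")
  grF <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1500, 2300))
  S4Vectors::mcols(grF) <- S4Vectors::DataFrame(
    vmr_id = "F_vmr0001", n_probes = 3L,
    probe_ids = IRanges::CharacterList(list(c("c", "d", "e"))),
    representative_probe = "c", max_sd = 0.3, source_sex = "F")
  sM <- new("VMRSet", ranges = grM, stratum = "M", params = list(),
            background = c("a", "b", "c"))
  sF <- new("VMRSet", ranges = grF, stratum = "F", params = list(),
            background = c("c", "d", "e"))
  trM <- mkTrack(c(a = 0.2, b = 0.1, c = 0.15, d = 0.1, e = 0.1), "M")
  trF <- mkTrack(c(a = 0.1, b = 0.1, c = 0.3, d = 0.2, e = 0.2), "F")
  comb <- vmrscan:::combineVmrSets(list(sM, sF), list(trM, trF), "combined")
  gr <- vmrRanges(comb)
  expect_equal(GenomicRanges::start(gr), 1000)
  expect_equal(GenomicRanges::end(gr), 2300)
  expect_setequal(unlist(S4Vectors::mcols(gr)$probe_ids),
                  c("a", "b", "c", "d", "e"))
  expect_equal(S4Vectors::mcols(gr)$representative_probe, "c")  # max sd 0.3
  expect_equal(S4Vectors::mcols(gr)$source_sex, "F+M")
})

test_that("VMR overlap uses the minimum-1-bp rule with probe-level fold", {
  mk <- function(start, end, probes, bg) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start, end))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      vmr_id = sprintf("v%02d", seq_along(gr)), n_probes = lengths(probes),
      probe_ids = IRanges::CharacterList(probes),
      representative_probe = vapply(probes, `[`, "", 1),
      max_sd = rep(0.2, length(gr)), source_sex = "all")
    new("VMRSet", ranges = gr, stratum = "all", params = list(),
        background = bg)
  }
  bg <- sprintf("b%03d", 1:100)
  q <- mk(100, 200, list(bg[1:3]), bg)
  r <- mk(200, 300, list(bg[2:4]), bg)
  ov <- overlapVmrs(q, r)
  expect_true(ov$table$replicated[1])  # shares exactly bp 200
  r2 <- mk(201, 300, list(bg[4:6]), bg)
  expect_false(overlapVmrs(q, r2)$table$replicated[1])

  ovSelf <- overlapVmrs(q, q)
  expect_equal(ovSelf$frac_replicated, 1)
  expect_gt(ovSelf$probe_overlap$fold, 1)

  # probe-level hypergeometric matches a permutation oracle
  set.seed(5)
  qp <- bg[1:20]; rp <- bg[c(1:10, 41:50)]
  qv <- mk(1000, 2000, list(qp), bg)
  rv <- mk(5000, 6000, list(rp), bg)
  obs <- overlapVmrs(qv, rv)$probe_overlap
  perm <- replicate(4000, length(intersect(sample(bg, 20), rp)))
  expect_equal(obs$expected, mean(perm), tolerance = 0.1)
  expect_equal(obs$p, mean(perm >= obs$k), tolerance = 0.05)
})

test_that("shared-VMR cross-cell-type correlations behave as constructed", {
  man <- mkMan(seq(100, by = 100, length.out = 20))
  set.seed(4)
  a <- matrix(runif(20 * 30, 0.2, 0.8), 20, 30,
              dimnames = list(names(man), paste0("i", 1:30)))
  bsA <- BetaSet(a, man)
  bsB <- BetaSet(a, man)
  r1 <- sharedVmrCorrelation(bsA, bsB, names(man)[1:5], paste0("i", 1:30))
  expect_equal(unname(r1$per_probe), rep(1, 5))
  expect_equal(r1$mean_r, 1)

  bsC <- BetaSet(1 - a, man)
  r2 <- sharedVmrCorrelation(bsA, bsC, names(man)[1:5], paste0("i", 1:30))
  expect_equal(r2$mean_r, -1)

  expect_error(sharedVmrCorrelation(bsA, bsB, names(man)[1:2],
                                    paste0("i", 1:2)), ">= 3")

  # attenuation: shared latent loading 0.9, small noise
  set.seed(6)
  nInd <- 60
  lat <- matrix(rnorm(20 * nInd), 20, nInd)
  noise <- function() matrix(rnorm(20 * nInd, 0, sqrt(1 - 0.81)), 20, nInd)
  mkM <- function() {
    x <- 0.9 * lat + noise()
    (x - min(x)) / diff(range(x))  # into [0,1], correlation-invariant
  }
  bsX <- BetaSet(matrix(mkM(), 20, nInd,
                        dimnames = list(names(man), paste0("i", 1:nInd))),
                 man)
  bsY <- BetaSet(matrix(mkM(), 20, nInd,
                        dimnames = list(names(man), paste0("i", 1:nInd))),
                 man)
  r3 <- sharedVmrCorrelation(bsX, bsY, names(man), paste0("i", 1:nInd))
  expect_equal(r3$mean_r, 0.81, tolerance = 0.05)
})
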