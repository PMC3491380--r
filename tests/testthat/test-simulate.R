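# synthetic-data generator: reference, TMRCA tracts, planted variants

test_that("simulated reference conserves lengths, QV fraction and gap rules", {
  cfg <- smallConfig(len = 10000, seed = 1)
  ref <- simulateReference(cfg)
  expect_equal(Biostrings::width(refSequence(ref))[[1]], 10000)
  expect_length(refQv(ref)$chr1, 10000)

  # QV-60 fraction close to its target on a 1 Mb chromosome
  cfg2 <- simulationConfig(chromLengths = c(chr1 = 1e6), qv60Fraction = 0.94,
                           seed = 2)
  ref2 <- simulateReference(cfg2)
  expect_equal(mean(refQv(ref2)$chr1 == 60L), 0.94, tolerance = 0.011)

  # no gaps requested -> no N bases, empty gap mask
  cfg3 <- smallConfig(len = 20000, seed = 3, gapDensity = 0)
  ref3 <- simulateReference(cfg3)
  expect_equal(length(refGaps(ref3)), 0L)
  expect_false(grepl("N", as.character(refSequence(ref3)[[1]]), fixed = TRUE))

  # N runs exactly match the gap mask
  cfg4 <- smallConfig(len = 50000, seed = 4, gapDensity = 0.01)
  ref4 <- simulateReference(cfg4)
  chars <- strsplit(as.character(refSequence(ref4)[[1]]), "")[[1]]
  gapIv <- as.data.frame(refGaps(ref4))
  inGap <- rep(FALSE, 50000)
  for (i in seq_len(nrow(gapIv)))
    inGap[gapIv$start[i]:gapIv$end[i]] <- TRUE
  expect_identical(chars == "N", inGap)

  expect_error(simulationConfig(chromLengths = c(chr1 = 0)), "positive")
})

test_that("TMRCA tracts tile chromosomes and follow the coalescent", {
  histConst <- DemographicHistory(0, 10000)

  # rho = 0: a single tract per chromosome
  cfg0 <- simulationConfig(chromLengths = c(chr1 = 1e5, chr2 = 2e5),
                           recombinationRate = 0, seed = 5)
  tr0 <- simulateTmrca(histConst, cfg0)
  expect_equal(nrow(tr0), 2L)
  expect_equal(tr0$end - tr0$start, c(1e5, 2e5))

  # tracts tile without gaps or overlap
  cfg <- simulationConfig(chromLengths = c(chr1 = 1e6), seed = 6)
  tr <- simulateTmrca(histConst, cfg)
  expect_equal(tr$start[1], 0)
  expect_equal(tr$end[nrow(tr)], 1e6)
  expect_equal(tr$start[-1], tr$end[-nrow(tr)])
  expect_true(all(tr$tmrca > 0))

  # site-weighted mean TMRCA ~ 2N within 3 Monte-Carlo SE (constant N).
  # Tracts are long-range correlated and length-weighted, which inflates
  # the variance of the mean well beyond 1/n: the empirical effective
  # sample size (estimated once from independent replicates) is about a
  # twelfth of the tract count.
  cfgBig <- simulationConfig(chromLengths = c(chr1 = 1e7), seed = 7)
  trBig <- simulateTmrca(histConst, cfgBig)
  w <- trBig$end - trBig$start
  m <- sum(trBig$tmrca * w) / sum(w)
  se <- 2 * 10000 / sqrt(nrow(trBig) / 12)
  expect_lt(abs(m - 2 * 10000), 3 * se)

  expect_error(simulateTmrca(DemographicHistory(numeric(0), numeric(0)), cfg))
})

test_that("TMRCA site-marginal matches the integrated coalescent CDF", {
  histories <- list(
    DemographicHistory(0, 10000),
    DemographicHistory(c(0, 20000, 60000), c(20000, 4000, 15000)),
    DemographicHistory(c(0, 5000), c(2000, 30000)))
  for (k in seq_along(histories)) {
    h <- histories[[k]]
    cfg <- simulationConfig(chromLengths = c(chr1 = 5e6), seed = 100 + k)
    tr <- simulateTmrca(h, cfg)
    # KS-style distance between the site-weighted empirical CDF and the
    # exact CDF, evaluated on a quantile grid; alpha = 0.01 critical value
    # with effective n = a third of the tract count (tracts are serially
    # correlated along the chromosome)
    q <- stats::quantile(tr$tmrca, probs = seq(0.02, 0.98, by = 0.02))
    d <- max(abs(siteWeightedEcdf(tr, q) - tmrcaCdf(q, h)))
    crit <- 1.63 / sqrt(nrow(tr) / 3)
    expect_lt(d, crit)
  }
})

test_that("planted variants follow the mutation, divergence and Ts/Tv laws", {
  hist <- DemographicHistory(0, 10000)

  # mu = 0 and divergence = 0 -> no SNVs
  cfg0 <- smallConfig(len = 50000, seed = 8, mutationRate = 0,
                      referenceDivergence = 0, smallIndelRate = 0)
  ref0 <- simulateReference(cfg0)
  tr0 <- simulateTmrca(hist, cfg0)
  truth0 <- imposeVariants(ref0, tr0, cfg0)
  expect_equal(nrow(truthSnvs(truth0)), 0L)

  # het fraction ~ 2 mu T under constant TMRCA
  cfg <- simulationConfig(chromLengths = c(chr1 = 1e7), seed = 9,
                          recombinationRate = 0, gapDensity = 0,
                          referenceDivergence = 0)
  ref <- simulateReference(cfg)
  trc <- data.frame(chrom = "chr1", start = 0, end = 1e7, tmrca = 20000)
  truth <- imposeVariants(ref, trc, cfg)
  snv <- truthSnvs(truth)
  p <- 2 * cfg$mutationRate * 20000
  nHet <- sum(snv$zygosity == "het")
  expect_lt(abs(nHet - 1e7 * p), 3 * sqrt(1e7 * p))

  # divergence realized as hom SNVs
  cfgD <- simulationConfig(chromLengths = c(chr1 = 1e6), seed = 10,
                           mutationRate = 0, gapDensity = 0)
  refD <- simulateReference(cfgD)
  trD <- simulateTmrca(hist, cfgD)
  truthD <- imposeVariants(refD, trD, cfgD)
  nHom <- sum(truthSnvs(truthD)$zygosity == "hom")
  expect_lt(abs(nHom - 1e6 * 0.004), 3 * sqrt(1e6 * 0.004))

  # emitted Ts/Tv ratio tracks the configured bias
  snvAll <- rbind(snv, truthSnvs(truthD))
  expect_equal(tsTvRatio(snvAll$ref, snvAll$alt), 2.39, tolerance = 0.1 / 2.39)

  # model breakdown guard (per-site mutation probability not small)
  trBad <- data.frame(chrom = "chr1", start = 0, end = 1e7, tmrca = 0.5 / cfg$mutationRate)
  expect_error(imposeVariants(ref, trBad, cfg), "breaks down")

  # hemizygous X: no heterozygous variants
  cfgX <- simulationConfig(chromLengths = c(chrX = 1e6), xChrom = "chrX",
                           seed = 11)
  refX <- simulateReference(cfgX)
  truthX <- imposeVariants(refX, simulateTmrca(hist, cfgX), cfgX)
  expect_equal(sum(truthSnvs(truthX)$zygosity == "het"), 0L)
})

test_that("generator is deterministic under a fixed seed", {
  cfg <- smallConfig(len = 30000, seed = 42)
  hist <- DemographicHistory(0, 8000)
  r1 <- simulateReference(cfg); r2 <- simulateReference(cfg)
  expect_identical(as.character(refSequence(r1)), as.character(refSequence(r2)))
  expect_identical(refQv(r1), refQv(r2))
  t1 <- simulateTmrca(hist, cfg); t2 <- simulateTmrca(hist, cfg)
  expect_identical(t1, t2)
  v1 <- imposeVariants(r1, t1, cfg); v2 <- imposeVariants(r2, t2, cfg)
  expect_identical(truthSnvs(v1), truthSnvs(v2))
  p1 <- emitPileup(r1, v1, cfg); p2 <- emitPileup(r2, v2, cfg)
  expect_identical(p1, p2)
  m1 <- emitMatePairs(r1, v1, config = cfg)
  m2 <- emitMatePairs(r2, v2, config = cfg)
  expect_identical(m1, m2)
})

test_that("pileup evidence matches the diploid genotype and error model", {
  hist <- DemographicHistory(0, 10000)

  # eps = 0, no variants -> every observed base equals the reference
  cfg0 <- smallConfig(len = 20000, seed = 12, baseErrorRate = 1e-12,
                      mutationRate = 0, referenceDivergence = 0)
  ref0 <- simulateReference(cfg0)
  truth0 <- imposeVariants(ref0, simulateTmrca(hist, cfg0), cfg0)
  pu0 <- emitPileup(ref0, truth0, cfg0)
  refCount <- pu0[[paste0("count", "A")]]  # assembled below
  cnt <- as.matrix(pu0[, c("countA", "countC", "countG", "countT")])
  own <- cnt[cbind(seq_len(nrow(pu0)), match(pu0$ref, c("A", "C", "G", "T")))]
  ok <- !is.na(match(pu0$ref, c("A", "C", "G", "T")))
  expect_equal(own[ok], pu0$depth[ok])

  # mean depth within 3 SE of its target over 1e6 sites
  cfgD <- simulationConfig(chromLengths = c(chr1 = 1e6), seed = 13,
                           gapDensity = 0, meanDepth = 41.5)
  refD <- simulateReference(cfgD)
  truthD <- imposeVariants(refD, simulateTmrca(hist, cfgD), cfgD)
  puD <- emitPileup(refD, truthD, cfgD)
  expect_lt(abs(mean(puD$depth) - 41.5), 3 * sqrt(41.5 / 1e6))

  # het sites: alt-base fraction ~ 1/2
  snv <- truthSnvs(truthD)
  het <- snv[snv$zygosity == "het", ]
  hp <- puD[match(het$pos, puD$pos), ]
  altN <- as.matrix(hp[, c("countA", "countC", "countG", "countT")])[
    cbind(seq_len(nrow(hp)), match(het$alt, c("A", "C", "G", "T")))]
  frac <- sum(altN) / sum(hp$depth)
  expect_lt(abs(frac - 0.5), 3 * 0.5 / sqrt(sum(hp$depth)))

  # truth/evidence agreement: het sites carry alt evidence
  expect_gt(min(altN), 0)
})

test_that("mate pairs reflect planted structural variants", {
  hist <- DemographicHistory(0, 10000)

  # no SVs: all congruent, spans inside the library insert range
  cfg0 <- simulationConfig(chromLengths = c(chr1 = 2e5), seed = 14)
  ref0 <- simulateReference(cfg0)
  truth0 <- imposeVariants(ref0, simulateTmrca(hist, cfg0), cfg0)
  mp0 <- emitMatePairs(ref0, truth0, config = cfg0)
  expect_true(all(mp0$congruent))
  for (lib in c("A", "B")) {
    s <- mp0$span[mp0$library == lib]
    rng <- cfg0$libraries[cfg0$libraries$id == lib, ]
    expect_true(all(s >= rng$insertMin & s <= rng$insertMax))
  }

  # planted 300-bp deletion: spanning pairs' median span ~ insert + 300
  li <- data.frame(chrom = "chr1", pos = 100000L, type = "del", length = 300L)
  cfgD <- simulationConfig(chromLengths = c(chr1 = 2e5), seed = 15,
                           largeIndels = li)
  truthD <- imposeVariants(ref0, simulateTmrca(hist, cfgD), cfgD)
  mpD <- emitMatePairs(ref0, truthD, config = cfgD)
  spanning <- mpD[mpD$pos1 < 100000 & mpD$pos2 > 100000 & mpD$library == "A", ]
  expect_gt(nrow(spanning), 5)
  expect_equal(stats::median(spanning$span), 700 + 300, tolerance = 100 / 1000)

  # planted inversion: exactly breakpoint-straddling pairs are incongruent
  inv <- data.frame(chrom = "chr1", start = 50000L, end = 80000L)
  cfgI <- simulationConfig(chromLengths = c(chr1 = 2e5), seed = 16,
                           inversions = inv)
  truthI <- imposeVariants(ref0, simulateTmrca(hist, cfgI), cfgI)
  mpI <- emitMatePairs(ref0, truthI, config = cfgI)
  straddle <- xor(mpI$pos1 >= 50000 & mpI$pos1 < 80000,
                  mpI$pos2 >= 50000 & mpI$pos2 < 80000)
  expect_identical(!mpI$congruent, straddle)

  # insert longer than the chromosome is rejected
  cfgBad <- simulationConfig(chromLengths = c(chr1 = 900), seed = 17)
  refBad <- simulateReference(cfgBad)
  truthBad <- imposeVariants(refBad, simulateTmrca(hist, cfgBad), cfgBad)
  expect_error(emitMatePairs(refBad, truthBad, config = cfgBad), "exceeds")
})

test_that("gene-model simulation yields valid, in-bounds models", {
  cfg <- smallConfig(len = 3e5, seed = 18)
  ref <- simulateReference(cfg)
  sim <- simulateAnnotation(cfg, ref, nGenes = 40, overlapFraction = 0.15)
  ann <- sim$annotation
  expect_gt(nrow(annTranscripts(ann)), 20)
  cdsLen <- tapply(annCds(ann)$end - annCds(ann)$start, annCds(ann)$tx_id, sum)
  expect_true(all(cdsLen %% 3 == 0))
  expect_true(all(annExons(ann)$end <= 3e5))
  expect_true(all(annExons(ann)$start >= 0))
  # all models validate cleanly against the patched reference
  v <- validateModels(ann, sim$reference)
  expect_equal(nrow(v$rejects), 0L)

  # requested gene count is honoured when there is room
  cfg2 <- simulationConfig(chromLengths = c(chr1 = 2e6), seed = 19)
  ref2 <- simulateReference(cfg2)
  sim2 <- simulateAnnotation(cfg2, ref2, nGenes = 100, overlapFraction = 0)
  expect_equal(length(unique(annTranscripts(sim2$annotation)$gene_id)), 100L)
})
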