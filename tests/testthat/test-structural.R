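# small indels, mate-pair large indels, inversion windows, SV context

test_that("small-indel caller applies length, support and ref-QV filters", {
  ev <- data.table::data.table(
    chrom = "chr1",
    pos = c(100L, 200L, 300L, 400L, 500L, 600L),
    type = c("del", "ins", "del", "del", "ins", "del"),
    length = c(11L, 4L, 2L, 12L, 3L, 3L),
    support = c(10L, 10L, 10L, 10L, 2L, 30L),
    depth = c(40L, 40L, 40L, 40L, 40L, 40L))
  qv <- c(60L, 60L, 44L, 60L, 60L, 60L)
  r <- callSmallIndels(ev, qv)
  # 11-bp deletion retained; 4-bp insertion out of range; QV 44 filtered;
  # 12-bp deletion out of range; support-2 insertion filtered
  expect_setequal(r$calls$pos, c(100L, 600L))
  expect_equal(r$rejected,
               c(out_of_range = 2L, support = 1L, ref_qv = 1L))
  # boundary: refQV 45 retained
  expect_equal(nrow(callSmallIndels(ev[3L], 45L)$calls), 1L)
  # zygosity from supporting fraction
  ev2 <- data.table::data.table(chrom = "chr1", pos = c(1L, 2L),
                                type = "del", length = 2L,
                                support = c(20L, 39L), depth = 40L)
  r2 <- callSmallIndels(ev2, c(60L, 60L))
  expect_equal(r2$calls$zygosity, c("het", "hom"))
})

test_that("small-indel discovery profile is flat for a uniform rate and
           detects a planted low-QV excess", {
  set.seed(61)
  n <- 200000L
  qvSites <- sample(c(40L, 50L, 60L), n, replace = TRUE, prob = c(.2, .2, .6))
  hist <- table(factor(qvSites, levels = c(40L, 50L, 60L)))
  qvHist <- stats::setNames(as.integer(hist), names(hist))
  # uniform rate 2e-3
  isIndel <- runif(n) < 2e-3
  ind <- data.table::data.table(type = sample(c("del", "ins"), sum(isIndel), TRUE),
                                qv = qvSites[isIndel])
  prof <- smallIndelProfile(ind, qvHist)
  tot <- prof$del_rate + prof$ins_rate
  cnt <- round(tot * prof$callable)
  ht <- suppressWarnings(stats::chisq.test(cnt, p = prof$callable / sum(prof$callable)))
  expect_gt(ht$p.value, 0.01)
  # planted 3x excess at QV 40
  excess <- runif(n) < ifelse(qvSites == 40L, 6e-3, 2e-3)
  ind2 <- data.table::data.table(type = "del", qv = qvSites[excess])
  prof2 <- smallIndelProfile(ind2, qvHist)
  ratio <- prof2$del_rate[prof2$qv == 40] / prof2$del_rate[prof2$qv == 60]
  expect_equal(ratio, 3, tolerance = 0.3)
  # no indels -> zero rates
  prof0 <- smallIndelProfile(ind2[0L], qvHist)
  expect_true(all(prof0$del_rate == 0))
})

test_that("mate-pair deviations call large indels with size estimates", {
  libs <- data.frame(id = c("A", "B"), insertMin = c(600, 800),
                     insertMax = c(800, 1000))
  mkPairs <- function(pos1, span, lib = "A", congruent = TRUE)
    data.table::data.table(chrom = "chr1", pos1 = pos1,
                           pos2 = pos1 + span, span = span,
                           congruent = congruent, library = lib)
  # 10 pairs at span ~1000 from library A (600-800): deletion of ~300
  p <- mkPairs(seq(1000, 1090, by = 10), span = 1000L)
  calls <- detectLargeIndels(p, libs)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$type, "del")
  expect_equal(calls$size, 300)
  expect_equal(calls$support, 10L)
  # spans inside the range: no call
  expect_equal(nrow(detectLargeIndels(mkPairs(1:10 * 10L, span = 650L), libs)),
               0L)
  # below min support: no call
  expect_equal(nrow(detectLargeIndels(p[1:2], libs)), 0L)
  # insertion signal: span below insertMin
  pIns <- mkPairs(seq(5000, 5045, by = 5), span = 450L)
  ci <- detectLargeIndels(pIns, libs)
  expect_equal(ci$type, "ins")
  expect_equal(ci$size, 250)
  # incongruent pairs never support an indel call
  pInc <- mkPairs(seq(1000, 1090, by = 10), span = 1000L, congruent = FALSE)
  expect_equal(nrow(detectLargeIndels(pInc, libs)), 0L)
})

test_that("calls merge across libraries by reciprocal overlap", {
  mkCall <- function(start, end, type = "del", size = 300, support = 5L,
                     lib = "A")
    data.table::data.table(chrom = "chr1", start = start, end = end,
                           type = type, size = size, support = support,
                           libraries = lib)
  # identical call in both libraries -> one merged call, both sources
  m <- mergeIndelCalls(mkCall(100L, 500L), mkCall(100L, 500L, lib = "B"))
  expect_equal(nrow(m), 1L)
  expect_equal(m$libraries, "A,B")
  expect_equal(m$support, 10L)
  # disjoint calls concatenate
  m2 <- mergeIndelCalls(mkCall(100L, 500L), mkCall(5000L, 5400L, lib = "B"))
  expect_equal(nrow(m2), 2L)
  # size is the support-weighted mean
  m3 <- mergeIndelCalls(mkCall(100L, 500L, size = 300, support = 10L),
                        mkCall(120L, 520L, size = 400, support = 30L, lib = "B"))
  expect_equal(m3$size, (300 * 10 + 400 * 30) / 40)
  # different types never merge
  m4 <- mergeIndelCalls(mkCall(100L, 500L, type = "del"),
                        mkCall(100L, 500L, type = "ins", lib = "B"))
  expect_equal(nrow(m4), 2L)

  # chained overlaps: transitive merge equals a connected-components oracle
  set.seed(62)
  for (rep in 1:10) {
    n <- 12L
    starts <- sort(sample(1:2000, n))
    ends <- starts + sample(150:400, n, replace = TRUE)
    callsA <- data.table::data.table(chrom = "chr1", start = starts,
                                     end = ends, type = "del", size = 100,
                                     support = 3L, libraries = "A")
    m <- mergeIndelCalls(callsA[seq(1, n, 2)], callsA[seq(2, n, 2)])
    # oracle: union-find over the 50%-reciprocal-overlap graph
    adj <- matrix(FALSE, n, n)
    for (i in 1:n) for (j in 1:n) {
      ov <- min(ends[i], ends[j]) - max(starts[i], starts[j])
      adj[i, j] <- ov >= 0.5 * (ends[i] - starts[i]) &&
        ov >= 0.5 * (ends[j] - starts[j])
    }
    # transitive closure
    reach <- adj
    for (k in 1:n) reach <- reach | (reach[, k] %o% reach[k, ] > 0)
    nComp <- length(unique(apply(reach, 1, function(r) min(which(r)))))
    expect_equal(nrow(m), nComp)
  }
})

test_that("inversion windows flag at the exact incongruent-pair threshold", {
  lens <- c(chr1 = 100000)
  mkInc <- function(n, at = 10100L)
    data.table::data.table(chrom = "chr1", pos1 = rep(at, n),
                           pos2 = rep(at + 700L, n), span = 700L,
                           congruent = FALSE, library = "A")
  # no incongruent pairs -> no flagged windows
  p0 <- data.table::data.table(chrom = "chr1", pos1 = 1:100, pos2 = 701:800,
                               span = 700L, congruent = TRUE, library = "A")
  s0 <- inversionScan(p0, lens)
  expect_equal(nrow(s0[s0$flagged]), 0L)
  # 49 pairs in a window: not flagged; 50: flagged
  s49 <- inversionScan(mkInc(49L), lens)
  expect_false(any(s49$flagged))
  s50 <- inversionScan(mkInc(50L), lens)
  expect_true(any(s50$flagged))
  expect_equal(max(s50$incongruent), 50L)
})

test_that("SV context flags repeat and gap overlap like interval intersection", {
  repeats <- grFromZeroBasedForTest("chr1", c(1000L, 5000L), c(2000L, 6000L))
  gaps <- grFromZeroBasedForTest("chr1", 3000L, 3500L)
  calls <- data.table::data.table(
    chrom = "chr1",
    start = c(1500L, 2500L, 3400L, 100L),
    end = c(1600L, 2600L, 3600L, 200L),
    type = c("del", "del", "ins", "del"))
  out <- svContext(calls, repeats, gaps)
  expect_equal(out$repeat_context, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$gap_context, c(FALSE, FALSE, TRUE, FALSE))
  # random agreement with brute-force interval intersection
  set.seed(63)
  rs <- sort(sample(1:50000, 20)); re <- rs + sample(50:500, 20, TRUE)
  mask <- grFromZeroBasedForTest("chr1", rs, re)
  cs <- sort(sample(1:50000, 50)); ce <- cs + sample(10:300, 50, TRUE)
  calls2 <- data.table::data.table(chrom = "chr1", start = cs, end = ce,
                                   type = "del")
  out2 <- svContext(calls2, mask, GenomicRanges::GRanges())
  brute <- vapply(seq_along(cs), function(i)
    any(cs[i] < re & ce[i] > rs), logical(1))
  expect_equal(out2$repeat_context, brute)
  expect_false(any(out2$gap_context))
})

test_that("clean simulations produce no false large-indel calls and planted
           SVs are recovered", {
  hist <- DemographicHistory(0, 10000)
  # clean 2-Mb genome at the default mate-pair coverage: no calls at all
  cfg0 <- simulationConfig(chromLengths = c(chr1 = 2e6), seed = 64)
  ref0 <- simulateReference(cfg0)
  truth0 <- imposeVariants(ref0, simulateTmrca(hist, cfg0), cfg0)
  mp0 <- emitMatePairs(ref0, truth0, config = cfg0)
  expect_equal(nrow(detectLargeIndels(mp0, cfg0$libraries)), 0L)

  # planted deletions and insertions recovered with bounded size error
  li <- data.frame(chrom = "chr1",
                   pos = c(2e5, 5e5, 8e5, 11e5, 14e5),
                   type = c("del", "del", "ins", "del", "ins"),
                   length = c(300L, 500L, 250L, 600L, 300L))
  cfg1 <- simulationConfig(chromLengths = c(chr1 = 2e6), seed = 65,
                           largeIndels = li)
  truth1 <- imposeVariants(ref0, simulateTmrca(hist, cfg1), cfg1)
  mp1 <- emitMatePairs(ref0, truth1, config = cfg1)
  callsA <- detectLargeIndels(mp1[mp1$library == "A", ], cfg1$libraries)
  callsB <- detectLargeIndels(mp1[mp1$library == "B", ], cfg1$libraries)
  merged <- mergeIndelCalls(callsA, callsB)
  # every planted SV recovered once, with the right type
  expect_equal(nrow(merged), 5L)
  o <- order(merged$start)
  expect_equal(merged$type[o], li$type)
  # size error bounded by half the insert-range width
  expect_true(all(abs(merged$size[o] - li$length) <= 100))
  # merged support equals the sum of member supports
  expect_equal(sum(merged$support), sum(callsA$support) + sum(callsB$support))
})
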