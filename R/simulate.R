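#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate
#' the study conditions of a male macaque diploid resequenced against a
#' draft reference: ~0.4\% divergence from the reference, mutation rate
#' 2.5e-8 per site per generation, transition/transversion bias 2.39,
#' ~41.5x mean pileup depth, and ~94\% of reference bases at assembly QV 60.
#'
#' @param chromLengths named integer vector of chromosome lengths (bp).
#' @param mutationRate mutation rate per site per generation.
#' @param recombinationRate recombination rate per site per generation.
#' @param tsTvBias expected ratio of transition to transversion SNVs.
#' @param referenceDivergence expected per-site fraction of fixed (homozygous)
#'   substitutions relative to the reference.
#' @param smallIndelRate per-site rate of small indels in the sample.
#' @param delMaxLen,insMaxLen maximum simulated small deletion / insertion
#'   lengths (bp).
#' @param largeIndels data.frame of planted large indels with columns
#'   \code{chrom}, \code{pos} (0-based ref position), \code{type}
#'   ("ins"/"del"), \code{length}.
#' @param inversions data.frame of planted inversions with columns
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open).
#' @param meanDepth mean pileup depth (reads per site).
#' @param baseErrorRate per-base sequencing error rate epsilon.
#' @param libraries data.frame of mate-pair libraries: \code{id},
#'   \code{insertMin}, \code{insertMax} (bp). Defaults to the two library
#'   designs of 600-800 bp and 800-1,000 bp inserts.
#' @param matePairCoverage total physical (span) coverage of mate pairs,
#'   split evenly across libraries.
#' @param qv60Fraction fraction of reference bases at assembly QV 60.
#' @param gapDensity fraction of the reference inside assembly gaps (N runs).
#' @param repeatDensity fraction of the reference inside the repeat mask.
#' @param indelNoiseRate per-site rate of spurious low-support gapped-read
#'   indel candidates.
#' @param xChrom name of the X chromosome (hemizygous in the male sample;
#'   no heterozygous variants are planted there), or NA for none.
#' @param seed root RNG seed; every generator stage derives its own stream
#'   from it.
#' @return a list of class \code{cynoseq_config}.
#' @examples
#' cfg <- simulationConfig(chromLengths = c(chr1 = 1e5), seed = 7)
#' @export
simulationConfig <- function(chromLengths = c(chr1 = 1e6),
                             mutationRate = 2.5e-8,
                             recombinationRate = 1e-8,
                             tsTvBias = 2.39,
                             referenceDivergence = 0.004,
                             smallIndelRate = 2e-4,
                             delMaxLen = 11L,
                             insMaxLen = 3L,
                             largeIndels = NULL,
                             inversions = NULL,
                             meanDepth = 41.5,
                             baseErrorRate = 0.01,
                             libraries = data.frame(
                               id = c("A", "B"),
                               insertMin = c(600, 800),
                               insertMax = c(800, 1000)),
                             matePairCoverage = 40,
                             qv60Fraction = 0.94,
                             gapDensity = 0.002,
                             repeatDensity = 0.25,
                             indelNoiseRate = 1e-5,
                             xChrom = NA_character_,
                             seed = 1L) {
  if (is.null(names(chromLengths)) || any(!nzchar(names(chromLengths))))
    stop("chromLengths must be named")
  if (any(chromLengths <= 0)) stop("chromosome lengths must be positive")
  rates <- c(mutationRate, recombinationRate, referenceDivergence,
             smallIndelRate, meanDepth, gapDensity, repeatDensity,
             indelNoiseRate)
  if (any(rates < 0)) stop("all rates must be non-negative")
  if (qv60Fraction < 0 || qv60Fraction > 1) stop("qv60Fraction must lie in [0,1]")
  if (baseErrorRate < 0 || baseErrorRate >= 0.75) stop("baseErrorRate out of range")
  if (any(libraries$insertMin >= libraries$insertMax))
    stop("library insert ranges must have min < max")
  if (is.null(largeIndels))
    largeIndels <- data.frame(chrom = character(), pos = integer(),
                              type = character(), length = integer())
  if (is.null(inversions))
    inversions <- data.frame(chrom = character(), start = integer(),
                             end = integer())
  structure(list(
    chromLengths = chromLengths, mutationRate = mutationRate,
    recombinationRate = recombinationRate, tsTvBias = tsTvBias,
    referenceDivergence = referenceDivergence,
    smallIndelRate = smallIndelRate, delMaxLen = as.integer(delMaxLen),
    insMaxLen = as.integer(insMaxLen), largeIndels = largeIndels,
    inversions = inversions, meanDepth = meanDepth,
    baseErrorRate = baseErrorRate, libraries = libraries,
    matePairCoverage = matePairCoverage, qv60Fraction = qv60Fraction,
    gapDensity = gapDensity, repeatDensity = repeatDensity,
    indelNoiseRate = indelNoiseRate, xChrom = xChrom,
    seed = as.integer(seed)),
    class = "cynoseq_config")
}

# place n non-overlapping intervals of the given lengths on [0, L); returns
# a two-column matrix (start, end), 0-based half-open, sorted
placeIntervals <- function(L, lens) {
  lens <- lens[lens > 0 & lens < L]
  if (length(lens) == 0L)
    return(cbind(start = integer(0), end = integer(0)))
  start <- sort(sample.int(L - max(lens), length(lens)) - 1L)
  end <- start + lens
  keep <- c(TRUE, start[-1L] >= cummax(end[-length(end)])[seq_len(length(end) - 1L)])
  cbind(start = start[keep], end = end[keep])
}

#' Simulate a draft reference assembly
#'
#' Generates random chromosome sequences with an assembly-QV track, assembly
#' gaps (N runs) and a repeat mask. QV is drawn in blocks (mean 200 bp) so
#' that the expected fraction of bases at QV 60 equals
#' \code{config$qv60Fraction}; the remainder is spread over QV 20-59.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a \code{\linkS4class{ReferenceAssembly}}.
#' @examples
#' ref <- simulateReference(simulationConfig(chromLengths = c(chr1 = 1e4)))
#' @export
simulateReference <- function(config) {
  stopifnot(inherits(config, "cynoseq_config"))
  withStageSeed(config$seed, "reference", {
    lens <- config$chromLengths
    seqs <- character(length(lens))
    qv <- vector("list", length(lens))
    gapL <- vector("list", length(lens))
    repL <- vector("list", length(lens))
    for (i in seq_along(lens)) {
      L <- as.integer(lens[i])
      base <- sample(BASES, L, replace = TRUE)
      # assembly gaps: runs of N, mean length 300 bp
      gapIv <- if (config$gapDensity > 0) {
        nGap <- max(1L, round(config$gapDensity * L / 300))
        placeIntervals(L, pmin(rpois(nGap, 300) + 1L, L %/% 4L))
      } else cbind(start = integer(0), end = integer(0))
      for (g in seq_len(nrow(gapIv)))
        base[(gapIv[g, 1L] + 1L):gapIv[g, 2L]] <- "N"
      # repeat mask, mean interval 400 bp
      repIv <- if (config$repeatDensity > 0) {
        nRep <- max(1L, round(config$repeatDensity * L / 400))
        placeIntervals(L, pmin(rpois(nRep, 400) + 1L, L %/% 4L))
      } else cbind(start = integer(0), end = integer(0))
      # QV in geometric blocks of mean 200 bp
      nBlock <- max(1L, ceiling(L / 200 * 1.5))
      blockLen <- rpois(nBlock, 200) + 1L
      while (sum(blockLen) < L) blockLen <- c(blockLen, rpois(nBlock, 200) + 1L)
      blockLen <- blockLen[cumsum(blockLen) - blockLen < L]
      blockQv <- ifelse(runif(length(blockLen)) < config$qv60Fraction, 60L,
                        sample(20:59, length(blockLen), replace = TRUE,
                               prob = seq(1, 4, length.out = 40)))
      v <- rep(blockQv, blockLen)[seq_len(L)]
      seqs[i] <- paste(base, collapse = "")
      qv[[i]] <- as.integer(v)
      gapL[[i]] <- gapIv
      repL[[i]] <- repIv
    }
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- names(lens)
    names(qv) <- names(lens)
    mkGr <- function(ivList) {
      ch <- rep(names(lens), vapply(ivList, nrow, integer(1)))
      m <- do.call(rbind, ivList)
      if (is.null(m) || nrow(m) == 0L)
        GenomicRanges::GRanges()
      else grFromZeroBased(ch, m[, 1L], m[, 2L])
    }
    new("ReferenceAssembly", sequence = dss, qv = qv,
        gaps = mkGr(gapL), repeats = mkGr(repL))
  })
}

# sample n TMRCAs (generations) from the stationary pairwise coalescent under
# a piecewise-constant history, by inversion of the cumulative hazard
sampleStationaryTmrca <- function(n, history) {
  st <- history@startTime
  N <- history@diploidSize
  k <- length(st)
  H <- c(0, cumsum(diff(st) / (2 * N[-k])))
  u <- rexp(n)
  idx <- findInterval(u, H)
  st[idx] + (u - H[idx]) * 2 * N[idx]
}

# coalescence times for lineage pairs floating from times u (generations):
# t solves H(t) = H(u) + Exp(1), with H the pairwise cumulative hazard
sampleCoalescentFrom <- function(u, history) {
  st <- history@startTime
  N <- history@diploidSize
  k <- length(st)
  H <- c(0, cumsum(diff(st) / (2 * N[-k])))
  iu <- findInterval(u, st)
  Hu <- H[iu] + (u - st[iu]) / (2 * N[iu])
  target <- Hu + rexp(length(u))
  idx <- findInterval(target, H)
  st[idx] + (target - H[idx]) * 2 * N[idx]
}

# numerically exact CDF of the stationary pairwise TMRCA (oracle-grade
# closed form; exported for tests and diagnostics)
#' Stationary pairwise-coalescent TMRCA distribution function
#'
#' Exact CDF of the time to coalescence of two lineages under a
#' piecewise-constant demographic history, from the cumulative hazard
#' \eqn{H(t) = \int_0^t dt/(2N(t))}: \eqn{F(t) = 1 - e^{-H(t)}}.
#'
#' @param t times in generations.
#' @param history a \code{\linkS4class{DemographicHistory}}.
#' @return \code{P(TMRCA <= t)}.
#' @export
tmrcaCdf <- function(t, history) {
  st <- history@startTime
  N <- history@diploidSize
  k <- length(st)
  H <- c(0, cumsum(diff(st) / (2 * N[-k])))
  idx <- findInterval(t, st)
  idx[idx < 1L] <- 1L
  1 - exp(-(H[idx] + (t - st[idx]) / (2 * N[idx])))
}

#' Simulate TMRCA tracts along chromosomes
#'
#' Walks each chromosome under the sequentially Markovian coalescent for a
#' sample of two haploid genomes: given the current pairwise TMRCA \eqn{T}
#' (generations), the distance to the next recombination breakpoint is
#' exponential with rate \eqn{2 \rho T} per bp (recombination anywhere on
#' the pairwise tree of total branch length \eqn{2T}); at a breakpoint the
#' recombination point is uniform on \eqn{[0, T]} and the detached lineage
#' fully re-coalesces from there under the piecewise-constant history (the
#' plain SMC: no re-coalescence into the removed branch). The first tract's
#' TMRCA is stationary, so the per-site TMRCA marginal is exactly the
#' stationary pairwise coalescent (see \code{\link{tmrcaCdf}}).
#'
#' @param history a \code{\linkS4class{DemographicHistory}}.
#' @param config a \code{\link{simulationConfig}}.
#' @return data.frame with columns chrom, start, end (0-based half-open),
#'   tmrca (generations). Tracts tile each chromosome without overlap.
#' @export
simulateTmrca <- function(history, config) {
  stopifnot(is(history, "DemographicHistory"), inherits(config, "cynoseq_config"))
  if (config$recombinationRate < 0) stop("recombination rate must be >= 0")
  rho <- config$recombinationRate
  withStageSeed(config$seed, "tmrca", {
    out <- vector("list", length(config$chromLengths))
    for (i in seq_along(config$chromLengths)) {
      L <- as.numeric(config$chromLengths[i])
      t <- sampleStationaryTmrca(1L, history)
      if (rho == 0) {
        out[[i]] <- data.frame(chrom = names(config$chromLengths)[i],
                               start = 0, end = L, tmrca = t)
        next
      }
      cap <- 64L
      starts <- numeric(cap); ends <- numeric(cap); tm <- numeric(cap)
      n <- 0L
      pos <- 0
      while (pos < L) {
        d <- ceiling(rexp(1L, rate = 2 * rho * t))
        n <- n + 1L
        if (n > cap) {
          cap <- cap * 2L
          length(starts) <- cap; length(ends) <- cap; length(tm) <- cap
        }
        starts[n] <- pos
        ends[n] <- min(pos + d, L)
        tm[n] <- t
        pos <- pos + d
        if (pos < L)
          t <- sampleCoalescentFrom(runif(1L, 0, t), history)
      }
      out[[i]] <- data.frame(chrom = names(config$chromLengths)[i],
                             start = starts[seq_len(n)],
                             end = ends[seq_len(n)], tmrca = tm[seq_len(n)])
    }
    do.call(rbind, out)
  })
}

# draw alt alleles given ref bases under the transition/transversion bias;
# P(transition) = bias/(bias+1), the two transversions equally likely
drawAltAlleles <- function(refBase, bias) {
  n <- length(refBase)
  isTs <- runif(n) < bias / (bias + 1)
  alt <- TRANSITION[refBase]
  tv <- !isTs
  if (any(tv)) {
    # the two transversion partners of each base
    tvPartners <- list(A = c("C", "T"), C = c("A", "G"),
                       G = c("C", "T"), T = c("A", "G"))
    pick <- 1L + (runif(sum(tv)) < 0.5)
    alt[tv] <- mapply(function(b, k) tvPartners[[b]][k], refBase[tv], pick)
  }
  unname(alt)
}

#' Plant variants on a reference under TMRCA tracts
#'
#' Heterozygous SNVs arise per site with probability \eqn{2 \mu T} for the
#' local tract TMRCA \eqn{T} (small-rate regime); homozygous SNVs (fixed
#' differences against the reference) arise at the configured reference
#' divergence; substitution types follow the Ts/Tv bias; small indels at
#' the configured rate. Planted large indels and inversions are copied from
#' the config. No variants are placed on assembly gaps. On the configured
#' X chromosome (male, hemizygous) no heterozygous variants are placed.
#'
#' @param ref a \code{\linkS4class{ReferenceAssembly}}.
#' @param tracts TMRCA tracts from \code{\link{simulateTmrca}}.
#' @param config a \code{\link{simulationConfig}}.
#' @return a \code{\linkS4class{SampleTruth}}.
#' @export
imposeVariants <- function(ref, tracts, config) {
  stopifnot(is(ref, "ReferenceAssembly"), inherits(config, "cynoseq_config"))
  mu <- config$mutationRate
  if (any(mu * tracts$tmrca >= 0.5))
    stop("mu * tmrca >= 0.5: per-site mutation model breaks down")
  withStageSeed(config$seed, "variants", {
    chroms <- names(config$chromLengths)
    snvL <- vector("list", length(chroms))
    indL <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      L <- as.integer(config$chromLengths[ci])
      baseChars <- strsplit(as.character(refSequence(ref)[[ch]]), "")[[1]]
      tr <- tracts[tracts$chrom == ch, , drop = FALSE]
      hetPos <- integer(0); hetT <- numeric(0)
      if (!identical(ch, config$xChrom) && nrow(tr) > 0L && mu > 0) {
        p <- pmin(2 * mu * tr$tmrca, 1)
        len <- as.integer(tr$end - tr$start)
        nHet <- rbinom(nrow(tr), len, p)
        has <- which(nHet > 0L)
        if (length(has)) {
          hetPos <- unlist(lapply(has, function(j)
            tr$start[j] + sample.int(len[j], nHet[j]) - 1L), use.names = FALSE)
          hetPos <- as.integer(hetPos)
        }
      }
      nHom <- rbinom(1L, L, min(config$referenceDivergence, 1))
      homPos <- if (nHom > 0L) sample.int(L, nHom) - 1L else integer(0)
      homPos <- setdiff(homPos, hetPos)
      pos <- c(hetPos, homPos)
      zyg <- c(rep("het", length(hetPos)), rep("hom", length(homPos)))
      ok <- baseChars[pos + 1L] %in% BASES
      pos <- pos[ok]; zyg <- zyg[ok]
      o <- order(pos)
      pos <- pos[o]; zyg <- zyg[o]
      refB <- baseChars[pos + 1L]
      altB <- if (length(pos)) drawAltAlleles(refB, config$tsTvBias) else character(0)
      snvL[[ci]] <- data.frame(chrom = rep(ch, length(pos)), pos = pos,
                               ref = refB, alt = altB, zygosity = zyg,
                               stringsAsFactors = FALSE)
      # small indels
      nInd <- rbinom(1L, L, min(config$smallIndelRate, 1))
      if (nInd > 0L) {
        ipos <- sort(sample.int(L - 16L, nInd)) - 1L
        iok <- baseChars[ipos + 1L] %in% BASES
        ipos <- ipos[iok]
        isDel <- runif(length(ipos)) < 0.62
        dl <- 1L + stats::rgeom(length(ipos), 0.45)
        ilen <- ifelse(isDel, pmin(dl, config$delMaxLen),
                       pmin(dl, config$insMaxLen))
        izyg <- ifelse(identical(ch, config$xChrom) |
                         runif(length(ipos)) < 0.5, "hom", "het")
        indL[[ci]] <- data.frame(chrom = rep(ch, length(ipos)), pos = ipos,
                                 type = ifelse(isDel, "del", "ins"),
                                 length = as.integer(ilen), zygosity = izyg,
                                 stringsAsFactors = FALSE)
      } else {
        indL[[ci]] <- data.frame(chrom = character(), pos = integer(),
                                 type = character(), length = integer(),
                                 zygosity = character())
      }
    }
    new("SampleTruth",
        snvs = do.call(rbind, snvL),
        smallIndels = do.call(rbind, indL),
        largeIndels = config$largeIndels,
        inversions = config$inversions)
  })
}
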