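#' @import data.table
NULL

# index matrix: row b (1..4, base index) lists the three other base indices
OTHER_IDX <- t(vapply(1:4, function(b) setdiff(1:4, b), integer(3)))

# add nReads reads from a single true allele to the count matrix, with
# per-base error eps spread evenly over the three other bases
addAlleleReads <- function(counts, alleleIdx, nReads, eps) {
  n <- length(nReads)
  correct <- rbinom(n, nReads, 1 - eps)
  err <- nReads - correct
  e1 <- rbinom(n, err, 1 / 3)
  e2 <- rbinom(n, err - e1, 1 / 2)
  e3 <- err - e1 - e2
  rows <- seq_len(n)
  counts[cbind(rows, alleleIdx)] <- counts[cbind(rows, alleleIdx)] + correct
  counts[cbind(rows, OTHER_IDX[alleleIdx, 1L])] <-
    counts[cbind(rows, OTHER_IDX[alleleIdx, 1L])] + e1
  counts[cbind(rows, OTHER_IDX[alleleIdx, 2L])] <-
    counts[cbind(rows, OTHER_IDX[alleleIdx, 2L])] + e2
  counts[cbind(rows, OTHER_IDX[alleleIdx, 3L])] <-
    counts[cbind(rows, OTHER_IDX[alleleIdx, 3L])] + e3
  counts
}

#' Emit per-site pileup evidence
#'
#' Simulates mapped-read pileups: depth is Poisson with the configured mean,
#' reads at heterozygous sites come from either allele with probability 1/2,
#' and each read is observed correctly with probability \eqn{1-\epsilon},
#' otherwise as one of the three other bases uniformly. Assembly-gap (N)
#' sites receive depth 0.
#'
#' @param ref a \code{\linkS4class{ReferenceAssembly}}.
#' @param truth a \code{\linkS4class{SampleTruth}} consistent with \code{ref}.
#' @param config a \code{\link{simulationConfig}}.
#' @param chroms chromosomes to emit (default: all). Emitting one chromosome
#'   at a time bounds memory on long genomes.
#' @return a \code{data.table} with columns chrom, pos (0-based), ref,
#'   refQV, depth, countA, countC, countG, countT.
#' @export
emitPileup <- function(ref, truth, config, chroms = NULL) {
  stopifnot(is(ref, "ReferenceAssembly"), is(truth, "SampleTruth"))
  if (is.null(chroms)) chroms <- names(refSequence(ref))
  snv <- truthSnvs(truth)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    out[[ci]] <- withStageSeed(config$seed, paste0("pileup_", ch), {
      sq <- refSequence(ref)[[ch]]
      L <- length(sq)
      baseChars <- strsplit(as.character(sq), "")[[1]]
      refIdx <- match(baseChars, BASES)          # NA at gap Ns
      depth <- rpois(L, config$meanDepth)
      depth[is.na(refIdx)] <- 0L
      # diploid genotype per site: allele indices a1, a2
      a1 <- refIdx
      a2 <- refIdx
      s <- snv[snv$chrom == ch, , drop = FALSE]
      if (nrow(s)) {
        ai <- match(s$alt, BASES)
        at <- s$pos + 1L
        a2[at] <- ai
        hom <- s$zygosity == "hom"
        a1[at[hom]] <- ai[hom]
      }
      counts <- matrix(0L, nrow = L, ncol = 4L)
      ok <- !is.na(refIdx) & depth > 0L
      het <- ok & (a1 != a2)
      n1 <- depth
      n1[het] <- rbinom(sum(het), depth[het], 0.5)
      idx <- which(ok)
      counts[idx, ] <- addAlleleReads(counts[idx, , drop = FALSE], a1[idx],
                                      n1[idx], config$baseErrorRate)
      hidx <- which(het)
      if (length(hidx))
        counts[hidx, ] <- addAlleleReads(counts[hidx, , drop = FALSE],
                                         a2[hidx], depth[hidx] - n1[hidx],
                                         config$baseErrorRate)
      data.table::data.table(
        chrom = ch, pos = 0:(L - 1L), ref = baseChars,
        refQV = refQv(ref)[[ch]], depth = as.integer(depth),
        countA = counts[, 1L], countC = counts[, 2L],
        countG = counts[, 3L], countT = counts[, 4L])
    })
  }
  data.table::rbindlist(out)
}

# piecewise map from sample-genome coordinates to reference coordinates for
# one chromosome, given planted (homozygous) large indels.
# Returns a function(posSample) -> ref pos (NA inside inserted material).
sampleToRefMap <- function(L, largeIndels) {
  if (nrow(largeIndels) == 0L) {
    return(list(length = L, map = function(p) p))
  }
  li <- largeIndels[order(largeIndels$pos), , drop = FALSE]
  segStartS <- numeric(0)  # segment starts in sample coords
  segOff <- numeric(0)     # ref = sample + offset; NA for inserted segments
  cursorR <- 0             # current ref coord
  cursorS <- 0             # current sample coord
  for (i in seq_len(nrow(li))) {
    p <- li$pos[i]; len <- li$length[i]
    segStartS <- c(segStartS, cursorS)
    segOff <- c(segOff, cursorR - cursorS)
    cursorS <- cursorS + (p - cursorR)
    cursorR <- p
    if (li$type[i] == "del") {
      cursorR <- cursorR + len
    } else {
      segStartS <- c(segStartS, cursorS)
      segOff <- c(segOff, NA_real_)
      cursorS <- cursorS + len
    }
  }
  segStartS <- c(segStartS, cursorS)
  segOff <- c(segOff, cursorR - cursorS)
  sampleLen <- L - sum(li$length[li$type == "del"]) +
    sum(li$length[li$type == "ins"])
  list(length = sampleLen, map = function(p) {
    k <- findInterval(p, segStartS)
    p + segOff[k]
  })
}

#' Emit mate-pair mapping records
#'
#' Samples mate pairs uniformly along the (SV-carrying) sample genome with
#' inserts uniform in each library's range, then maps tag positions back to
#' reference coordinates: planted deletions inflate and insertions deflate
#' the observed reference span; pairs with a tag inside inserted material
#' are dropped (unmappable); pairs straddling exactly one inversion
#' breakpoint are flagged orientation-incongruent.
#'
#' @param ref a \code{\linkS4class{ReferenceAssembly}}.
#' @param truth a \code{\linkS4class{SampleTruth}}.
#' @param libraries data.frame with columns id, insertMin, insertMax;
#'   defaults to \code{config$libraries}.
#' @param config a \code{\link{simulationConfig}}.
#' @return \code{data.table}: chrom, pos1, pos2 (0-based 5' tag positions,
#'   pos1 < pos2), span (pos2 - pos1 on the reference), congruent (logical),
#'   library.
#' @export
emitMatePairs <- function(ref, truth, libraries = NULL, config) {
  stopifnot(is(ref, "ReferenceAssembly"), is(truth, "SampleTruth"))
  if (is.null(libraries)) libraries <- config$libraries
  chroms <- names(refSequence(ref))
  li <- truthLargeIndels(truth)
  inv <- truthInversions(truth)
  out <- list()
  for (ch in chroms) {
    L <- as.numeric(config$chromLengths[ch])
    if (any(libraries$insertMax >= L))
      stop("insert size exceeds chromosome length")
    m <- sampleToRefMap(L, li[li$chrom == ch, , drop = FALSE])
    invCh <- inv[inv$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(libraries))) {
      lib <- libraries[k, ]
      meanIns <- (lib$insertMin + lib$insertMax) / 2
      nPairs <- round(L * config$matePairCoverage /
                        nrow(libraries) / meanIns)
      out[[paste(ch, lib$id)]] <- withStageSeed(
        config$seed, paste0("matepair_", ch, "_", lib$id), {
          insert <- round(runif(nPairs, lib$insertMin, lib$insertMax))
          s1 <- floor(runif(nPairs, 0, m$length - insert))
          s2 <- s1 + insert
          r1 <- m$map(s1)
          r2 <- m$map(s2)
          ok <- !is.na(r1) & !is.na(r2)
          r1 <- r1[ok]; r2 <- r2[ok]
          congruent <- rep(TRUE, length(r1))
          for (j in seq_len(nrow(invCh))) {
            in1 <- r1 >= invCh$start[j] & r1 < invCh$end[j]
            in2 <- r2 >= invCh$start[j] & r2 < invCh$end[j]
            congruent[xor(in1, in2)] <- FALSE
          }
          data.table::data.table(chrom = ch, pos1 = as.integer(r1),
                                 pos2 = as.integer(r2),
                                 span = as.integer(r2 - r1),
                                 congruent = congruent,
                                 library = lib$id)
        })
    }
  }
  data.table::rbindlist(out)
}

#' Emit gapped-alignment small-indel evidence
#'
#' For every true small indel, emits an evidence row with a Poisson site
#' depth and a supporting-read count that is binomial with success 1/2 for
#' heterozygous and \eqn{1-\epsilon} for homozygous indels. Spurious
#' low-support candidates are added at \code{config$indelNoiseRate} per
#' site (support 1-2, random type and length up to 14 bp) to exercise
#' support and length filters.
#'
#' @param ref a \code{\linkS4class{ReferenceAssembly}}.
#' @param truth a \code{\linkS4class{SampleTruth}}.
#' @param config a \code{\link{simulationConfig}}.
#' @return \code{data.table}: chrom, pos (0-based), type, length, support,
#'   depth.
#' @export
emitGapEvidence <- function(ref, truth, config) {
  stopifnot(is(ref, "ReferenceAssembly"), is(truth, "SampleTruth"))
  withStageSeed(config$seed, "gap_evidence", {
    ind <- truthSmallIndels(truth)
    depth <- pmax(rpois(nrow(ind), config$meanDepth), 1L)
    pSup <- ifelse(ind$zygosity == "het", 0.5, 1 - config$baseErrorRate)
    support <- pmax(rbinom(nrow(ind), depth, pSup), 1L)
    real <- data.table::data.table(chrom = ind$chrom, pos = ind$pos,
                                   type = ind$type, length = ind$length,
                                   support = support, depth = depth)
    noiseL <- list()
    for (ch in names(config$chromLengths)) {
      L <- as.integer(config$chromLengths[ch])
      nN <- rbinom(1L, L, min(config$indelNoiseRate, 1))
      if (nN > 0L) {
        nd <- pmax(rpois(nN, config$meanDepth), 2L)
        noiseL[[ch]] <- data.table::data.table(
          chrom = ch, pos = sample.int(L - 16L, nN) - 1L,
          type = sample(c("del", "ins"), nN, replace = TRUE),
          length = sample.int(14L, nN, replace = TRUE),
          support = sample(1:2, nN, replace = TRUE),
          depth = nd)
      }
    }
    ev <- data.table::rbindlist(c(list(real), noiseL))
    data.table::setorder(ev, chrom, pos)
    ev[]
  })
}
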