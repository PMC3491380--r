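#' @include utils.R
NULL

# the 10 unordered diploid genotypes over {A,C,G,T}
GENOTYPES <- local({
  m <- expand.grid(a = BASES, b = BASES, stringsAsFactors = FALSE)
  m <- m[m$a <= m$b, ]
  m <- m[order(m$a, m$b), ]
  unname(as.matrix(m))
})
GENOTYPE_NAMES <- paste0(GENOTYPES[, 1L], GENOTYPES[, 2L])

# per-read emission probabilities: row = genotype, col = observed base.
# A read is drawn from either allele with prob 1/2 and observed correctly
# with prob 1-eps, else uniformly one of the other three bases.
genotypeEmissionMatrix <- function(errorRate) {
  pBase <- function(obs, allele) ifelse(obs == allele, 1 - errorRate, errorRate / 3)
  m <- matrix(0, nrow = nrow(GENOTYPES), ncol = 4L,
              dimnames = list(GENOTYPE_NAMES, BASES))
  for (g in seq_len(nrow(GENOTYPES)))
    for (b in seq_len(4L))
      m[g, b] <- 0.5 * pBase(BASES[b], GENOTYPES[g, 1L]) +
        0.5 * pBase(BASES[b], GENOTYPES[g, 2L])
  m
}

# zygosity class of each genotype given the reference base:
# 1 = hom_ref, 2 = het, 3 = hom_alt
genotypeClassFor <- function(refBase) {
  isRef1 <- GENOTYPES[, 1L] == refBase
  isRef2 <- GENOTYPES[, 2L] == refBase
  hom <- GENOTYPES[, 1L] == GENOTYPES[, 2L]
  ifelse(hom & isRef1, 1L, ifelse(hom, 3L, 2L))
}

# prior over the 10 genotypes given the reference base. Heterozygous mass
# hetPrior is split over the three ref-containing hets; homAltPrior over the
# three hom-alts; non-ref hets (both alleles non-ref, a second-order event)
# get mass hetPrior*homAltPrior/3 each; hom_ref takes the remainder.
genotypePriorFor <- function(refBase, hetPrior, homAltPrior) {
  cls <- genotypeClassFor(refBase)
  refHet <- cls == 2L & (GENOTYPES[, 1L] == refBase | GENOTYPES[, 2L] == refBase)
  nonRefHet <- cls == 2L & !refHet
  p <- numeric(nrow(GENOTYPES))
  p[refHet] <- hetPrior / 3
  p[cls == 3L] <- homAltPrior / 3
  p[nonRefHet] <- hetPrior * homAltPrior / 3
  p[cls == 1L] <- 1 - sum(p)
  stats::setNames(p, GENOTYPE_NAMES)
}

#' Posterior over the ten diploid genotypes at one site
#'
#' Evaluates the binomial-mixture read model at a single pileup column:
#' each read is drawn from one of the two genotype alleles with probability
#' 1/2 and observed correctly with probability \eqn{1-\epsilon}, otherwise
#' uniformly as one of the other three bases.
#'
#' @param counts integer vector of observed base counts, named or ordered
#'   A, C, G, T.
#' @param refBase the reference base at the site.
#' @param errorRate per-read base error rate (0 < eps < 0.75).
#' @param hetPrior prior mass on ref-containing heterozygotes.
#' @param homAltPrior prior mass on homozygous-alternative genotypes.
#' @return named numeric vector of posterior probabilities over the 10
#'   unordered genotypes (sums to 1). If depth is 0 the prior is returned
#'   with attribute \code{noData = TRUE}.
#' @examples
#' genotypePosteriors(c(A = 30, C = 0, G = 0, T = 0), "A")
#' @export
genotypePosteriors <- function(counts, refBase, errorRate = 0.01,
                               hetPrior = 0.003, homAltPrior = 0.004) {
  stopifnot(errorRate > 0, errorRate < 0.75,
            hetPrior > 0, hetPrior < 1, refBase %in% BASES)
  counts <- as.numeric(counts)
  prior <- genotypePriorFor(refBase, hetPrior, homAltPrior)
  if (sum(counts) == 0) {
    return(structure(prior, noData = TRUE))
  }
  ll <- drop(log(genotypeEmissionMatrix(errorRate)) %*% counts)
  lp <- ll + log(prior)
  lp <- lp - max(lp)
  p <- exp(lp)
  stats::setNames(p / sum(p), GENOTYPE_NAMES)
}

#' Call zygosity at one site from genotype posteriors
#'
#' The maximum-a-posteriori genotype determines the zygosity class; the
#' call quality is \eqn{-10 \log_{10}(1 - p_{MAP})}, capped at 99. If the
#' best genotype of a different zygosity class has posterior within a
#' factor \code{ambiguityMargin} of the MAP genotype, the call is marked
#' ambiguous (such sites are excluded from SNV counts downstream). Exact
#' ties are broken toward the zygosity-conservative class
#' (hom_ref > het > hom_alt).
#'
#' @param posteriors named genotype posterior vector from
#'   \code{\link{genotypePosteriors}}.
#' @param refBase the reference base.
#' @param ambiguityMargin posterior-ratio threshold below which calls with
#'   competing zygosity classes are ambiguous.
#' @return list with zygosity ("hom_ref", "het", "hom_alt", "ambiguous" or
#'   "no_call"), alt (allele or NA), callQV.
#' @export
callSite <- function(posteriors, refBase, ambiguityMargin = 10) {
  if (abs(sum(posteriors) - 1) > 1e-6)
    stop("posteriors must be normalized")
  if (isTRUE(attr(posteriors, "noData")))
    return(list(zygosity = "no_call", alt = NA_character_, callQV = 0))
  cls <- genotypeClassFor(refBase)
  # conservative tie-break: order candidates by class rank within equal posterior
  o <- order(-posteriors, cls)
  top <- o[1L]
  pMap <- posteriors[top]
  other <- o[cls[o] != cls[top]][1L]
  zyg <- c("hom_ref", "het", "hom_alt")[cls[top]]
  if (!is.na(other) && pMap / posteriors[other] < ambiguityMargin)
    zyg <- "ambiguous"
  alleles <- GENOTYPES[top, ]
  alt <- setdiff(alleles, refBase)
  alt <- if (length(alt) == 0L) NA_character_ else alt[1L]
  callQV <- min(-10 * log10(max(1 - pMap, 1e-10)), 99)
  list(zygosity = zyg, alt = alt, callQV = as.numeric(callQV))
}

#' Vectorised diploid genotype calling over a pileup table
#'
#' Applies the model of \code{\link{genotypePosteriors}} and the call rule
#' of \code{\link{callSite}} to every pileup column, in chunks.
#'
#' @param pileup a pileup \code{data.table} as emitted by
#'   \code{\link{emitPileup}} (columns chrom, pos, ref, refQV, depth,
#'   countA..countT).
#' @param errorRate,hetPrior,homAltPrior,ambiguityMargin model parameters,
#'   see \code{\link{genotypePosteriors}} and \code{\link{callSite}}.
#' @param chunkSize rows per processing chunk.
#' @return \code{data.table}: chrom, pos, ref, refQV, depth, zygosity,
#'   alt, callQV. Zygosity is "no_call" at depth-0 sites and at sites with
#'   a non-ACGT reference base.
#' @export
callGenotypes <- function(pileup, errorRate = 0.01, hetPrior = 0.003,
                          homAltPrior = 0.004, ambiguityMargin = 10,
                          chunkSize = 1000000L) {
  stopifnot(errorRate > 0, errorRate < 0.75)
  logEm <- t(log(genotypeEmissionMatrix(errorRate)))  # 4 x 10
  logPrior <- t(vapply(BASES, function(r)
    log(genotypePriorFor(r, hetPrior, homAltPrior)), numeric(10L)))  # 4 x 10
  clsMat <- t(vapply(BASES, genotypeClassFor, integer(10L)))          # 4 x 10
  n <- nrow(pileup)
  zyg <- rep("no_call", n)
  alt <- rep(NA_character_, n)
  qv <- numeric(n)
  cm <- as.matrix(pileup[, c("countA", "countC", "countG", "countT")])
  refIdx <- match(pileup$ref, BASES)
  usable <- which(!is.na(refIdx) & pileup$depth > 0L)
  zygNames <- c("hom_ref", "het", "hom_alt")
  for (lo in seq(1L, length(usable), by = chunkSize)) {
    sel <- usable[lo:min(lo + chunkSize - 1L, length(usable))]
    C <- cm[sel, , drop = FALSE]
    ri <- refIdx[sel]
    lp <- C %*% logEm + logPrior[ri, , drop = FALSE]
    mx <- lp[cbind(seq_len(nrow(lp)), max.col(lp, ties.method = "first"))]
    post <- exp(lp - mx)
    post <- post / rowSums(post)
    cls <- clsMat[ri, , drop = FALSE]
    # per-row best posterior within each zygosity class
    best <- matrix(0, nrow = nrow(post), ncol = 3L)
    bestIdx <- matrix(1L, nrow = nrow(post), ncol = 3L)
    for (k in 1:3) {
      masked <- post
      masked[cls != k] <- -1
      j <- max.col(masked, ties.method = "first")
      bestIdx[, k] <- j
      best[, k] <- masked[cbind(seq_len(nrow(post)), j)]
    }
    # MAP class; ties broken toward the conservative class (lowest index)
    mapCls <- max.col(best, ties.method = "first")
    rows <- seq_len(nrow(post))
    pMap <- best[cbind(rows, mapCls)]
    # strongest competing class of different zygosity
    comp <- best
    comp[cbind(rows, mapCls)] <- -1
    pAltCls <- comp[cbind(rows, max.col(comp, ties.method = "first"))]
    amb <- pMap / pmax(pAltCls, 1e-300) < ambiguityMargin
    z <- zygNames[mapCls]
    z[amb] <- "ambiguous"
    gIdx <- bestIdx[cbind(rows, mapCls)]
    a1 <- GENOTYPES[gIdx, 1L]
    a2 <- GENOTYPES[gIdx, 2L]
    rB <- BASES[ri]
    altC <- ifelse(a1 == rB, a2, ifelse(a2 == rB, a1,
      # non-ref het: report the allele with more read support
      ifelse(C[cbind(rows, match(a1, BASES))] >=
               C[cbind(rows, match(a2, BASES))], a1, a2)))
    altC[mapCls == 1L] <- NA_character_
    zyg[sel] <- z
    alt[sel] <- altC
    qv[sel] <- pmin(-10 * log10(pmax(1 - pMap, 1e-10)), 99)
  }
  data.table::data.table(chrom = pileup$chrom, pos = pileup$pos,
                         ref = pileup$ref, refQV = pileup$refQV,
                         depth = pileup$depth, zygosity = zyg,
                         alt = alt, callQV = qv)
}

#' Variant filter thresholds
#'
#' The quality-stratified SNV filters: minimum site coverage 5, minimum
#' Phred call quality 40, and minimum reference-assembly QV 45.
#'
#' @param minDepth,minCallQv,minRefQv thresholds; all must be >= 0.
#' @return list of class \code{cynoseq_thresholds}.
#' @export
filterThresholds <- function(minDepth = 5L, minCallQv = 40, minRefQv = 45L) {
  stopifnot(minDepth >= 0, minCallQv >= 0, minRefQv >= 0)
  structure(list(minDepth = minDepth, minCallQv = minCallQv,
                 minRefQv = minRefQv), class = "cynoseq_thresholds")
}

#' Apply coverage / call-quality / reference-quality filters to SNV calls
#'
#' A variant call (het or hom_alt) is retained iff depth >= minDepth AND
#' call QV >= minCallQv AND reference QV >= minRefQv. Rejected calls are
#' tallied by the first failing rule, tested in the order depth, call QV,
#' reference QV. Non-variant rows (hom_ref, no_call, ambiguous) are not
#' part of either output.
#'
#' @param calls a call table from \code{\link{callGenotypes}} (must carry a
#'   refQV column).
#' @param thresholds a \code{\link{filterThresholds}} object.
#' @return list with \code{retained} (call \code{data.table}) and
#'   \code{rejected} (named counts: depth, call_qv, ref_qv).
#' @export
applyCallFilters <- function(calls, thresholds = filterThresholds()) {
  stopifnot(inherits(thresholds, "cynoseq_thresholds"),
            "refQV" %in% names(calls))
  v <- calls[calls$zygosity %in% c("het", "hom_alt"), ]
  failDepth <- v$depth < thresholds$minDepth
  failCall <- !failDepth & v$callQV < thresholds$minCallQv
  failRef <- !failDepth & !failCall & v$refQV < thresholds$minRefQv
  keep <- !(failDepth | failCall | failRef)
  list(retained = v[keep, ],
       rejected = c(depth = sum(failDepth), call_qv = sum(failCall),
                    ref_qv = sum(failRef)))
}

#' Hemizygous-X handling for a male sample
#'
#' On the X chromosome of a male only homozygous SNVs are countable;
#' heterozygous X calls are moved to an excluded tally. Autosomal calls are
#' unchanged.
#'
#' @param calls a call table.
#' @param xChrom name of the X chromosome.
#' @return list with \code{calls} (X het calls removed) and
#'   \code{excludedXHet} (count).
#' @export
maleXMode <- function(calls, xChrom) {
  drop <- calls$chrom == xChrom & calls$zygosity == "het"
  list(calls = calls[!drop, ], excludedXHet = sum(drop))
}

#' SNV discovery rate stratified by reference assembly quality
#'
#' For every reference-QV value, the rate of heterozygous and homozygous
#' SNV calls per callable site. Callability is depth >= minDepth; SNVs are
#' counted after the depth and call-QV filters but deliberately BEFORE the
#' reference-QV filter — the profile is that filter's diagnostic.
#'
#' @param calls call table over all sites (from \code{\link{callGenotypes}}).
#' @param thresholds a \code{\link{filterThresholds}} object.
#' @return \code{data.table}: qv, callable, het_rate, hom_rate. QV values
#'   with no callable sites are absent.
#' @export
discoveryProfile <- function(calls, thresholds = filterThresholds()) {
  refQV <- zygosity <- depth <- callQV <- NULL  # R CMD check NSE
  callable <- calls[depth >= thresholds$minDepth]
  prof <- callable[, list(
    callable = .N,
    het = sum(zygosity == "het" & callQV >= thresholds$minCallQv),
    hom = sum(zygosity == "hom_alt" & callQV >= thresholds$minCallQv)),
    by = refQV]
  data.table::setorder(prof, refQV)
  data.table::data.table(qv = prof$refQV, callable = prof$callable,
                         het_rate = prof$het / prof$callable,
                         hom_rate = prof$hom / prof$callable)
}
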