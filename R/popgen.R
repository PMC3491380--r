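#' Diversity and divergence from a single diploid resequenced genome
#'
#' Against a reference from a sister species, nucleotide diversity
#' \eqn{\pi} is estimated as the fraction of heterozygous SNVs per callable
#' site (the difference between the two sequenced chromosomes), and the
#' between-species divergence \eqn{d_{xy}} (Nei) as the fraction of
#' homozygous SNVs plus one half of the heterozygous fraction.
#'
#' @param hetCount,homCount retained heterozygous / homozygous SNV counts.
#' @param callableSites number of callable sites (must be > 0).
#' @return list: callable, het, hom, pi, dxy.
#' @examples
#' diversityEstimate(2000, 4000, 1e6)  # pi = 0.002, dxy = 0.005
#' @export
diversityEstimate <- function(hetCount, homCount, callableSites) {
  if (callableSites <= 0) stop("callable site count must be positive")
  list(callable = callableSites, het = hetCount, hom = homCount,
       pi = hetCount / callableSites,
       dxy = (homCount + 0.5 * hetCount) / callableSites)
}

#' @rdname diversityEstimate
#' @param calls a retained variant call table (zygosity "het"/"hom_alt").
#' @export
diversityFromCalls <- function(calls, callableSites) {
  diversityEstimate(sum(calls$zygosity == "het"),
                    sum(calls$zygosity %in% c("hom", "hom_alt")),
                    callableSites)
}

#' Nonsynonymous/synonymous SNV ratio
#'
#' Within-species scope counts heterozygous SNVs only; between-species
#' scope weights each SNV as hom + 0.5 het, consistent with the
#' \eqn{d_{xy}} estimator.
#'
#' @param effects annotated variant calls (columns zygosity, effect).
#' @param scope "within" or "between".
#' @return list: nonsynonymous, synonymous, ratio (NA with a warning when
#'   the synonymous count is 0).
#' @export
codingRatio <- function(effects, scope = c("within", "between")) {
  scope <- match.arg(scope)
  zyg <- effects$zygosity
  het <- zyg == "het"
  hom <- zyg %in% c("hom", "hom_alt")
  w <- if (scope == "within") as.numeric(het) else hom + 0.5 * het
  n <- sum(w[effects$effect == "nonsynonymous"])
  s <- sum(w[effects$effect == "synonymous"])
  ratio <- if (s == 0) { warning("no synonymous SNVs; ratio undefined"); NA_real_ }
           else n / s
  list(nonsynonymous = n, synonymous = s, ratio = ratio)
}

#' Pearson chi-square test on a 2x2 table
#'
#' The Pearson statistic without continuity correction, with the p-value
#' from the upper tail of the chi-square(1) distribution (the regularized
#' incomplete gamma function).
#'
#' @param n11,n12,n21,n22 non-negative cell counts; both margins of the
#'   table must be positive.
#' @return list: statistic, df (= 1), p.value.
#' @examples
#' chiSquare2x2(10, 20, 30, 40)
#' @export
chiSquare2x2 <- function(n11, n12, n21, n22) {
  cells <- as.numeric(c(n11, n12, n21, n22))
  if (any(cells < 0)) stop("counts must be non-negative")
  n11 <- cells[1L]; n12 <- cells[2L]; n21 <- cells[3L]; n22 <- cells[4L]
  n <- sum(cells)
  r1 <- n11 + n12; r2 <- n21 + n22
  c1 <- n11 + n21; c2 <- n12 + n22
  if (any(c(r1, r2, c1, c2) == 0)) stop("zero margin: test undefined")
  stat <- n * (n11 * n22 - n12 * n21)^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Transition/transversion ratio of a set of SNVs
#'
#' Transitions are A<->G and C<->T; everything else is a transversion.
#'
#' @param ref,alt reference and alternative alleles.
#' @return number of transitions / number of transversions; NA with a
#'   warning when there is no transversion.
#' @export
tsTvRatio <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  ts <- sum(isTransition(ref, alt))
  tv <- length(ref) - ts
  if (tv == 0L) { warning("no transversions; Ts/Tv undefined"); return(NA_real_) }
  ts / tv
}

#' Sliding-window SNV density
#'
#' Counts heterozygous and homozygous SNVs in sliding windows (default
#' 1 Mb windows, 100 kb steps) along each chromosome. Windows are 0-based
#' half-open; the last windows are truncated at the chromosome end.
#'
#' @param calls variant call table (chrom, pos, zygosity).
#' @param chromLengths named chromosome lengths.
#' @param window,step window and step size in bp; \code{window >= step > 0}.
#' @return \code{data.table}: chrom, start, end, het, hom.
#' @export
densityWindows <- function(calls, chromLengths, window = 1000000L,
                           step = 100000L) {
  if (!(window >= step && step > 0)) stop("need window >= step > 0")
  out <- list()
  for (ch in names(chromLengths)) {
    L <- as.numeric(chromLengths[ch])
    starts <- seq(0, max(L - step, 0), by = step)
    starts <- starts[starts < L]
    ends <- pmin(starts + window, L)
    v <- calls[calls$chrom == ch, ]
    hetPos <- sort(v$pos[v$zygosity == "het"])
    homPos <- sort(v$pos[v$zygosity %in% c("hom", "hom_alt")])
    cnt <- function(p) {
      if (length(p) == 0L) return(integer(length(starts)))
      findInterval(ends - 0.5, p) - findInterval(starts - 0.5, p)
    }
    out[[ch]] <- data.table::data.table(chrom = ch, start = starts,
                                        end = ends, het = cnt(hetPos),
                                        hom = cnt(homPos))
  }
  data.table::rbindlist(out)
}
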