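#' @importFrom stats rbinom rpois rexp runif rgeom optim setNames pchisq
#'   quantile median
#' @importFrom utils head tail
NULL

# Derive a reproducible per-stage seed from a root seed. Keeps results of one
# stage invariant to how many draws another stage consumed.
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647)
}

withStageSeed <- function(seed, stage, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(stageSeed(seed, stage))
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# 0-based half-open intervals <-> GRanges (1-based closed).
grFromZeroBased <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
}

zeroBasedFromGr <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# Membership of 0-based positions in a set of 0-based half-open intervals
# on the same chromosome. ivStart/ivEnd sorted, non-overlapping.
posInIntervals <- function(pos, ivStart, ivEnd) {
  if (length(ivStart) == 0L) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos, ivStart)
  idx > 0L & pos < ivEnd[pmax(idx, 1L)]
}

# round-half-up to `decimals` places (the convention used when percentages
# are printed in summary tables; R's round() is round-half-even).
roundHalfUp <- function(x, decimals = 0L) {
  p <- 10^decimals
  floor(x * p + 0.5) / p
}

#' Format a percentage with round-half-up
#'
#' @param part,whole numerator and denominator counts; \code{whole} must be
#'   positive.
#' @param decimals digits after the decimal point.
#' @return the numeric percentage, rounded half-up.
#' @examples
#' percentOf(1, 2, 1)   # 50
#' percentOf(434, 1139, 0)
#' @export
percentOf <- function(part, whole, decimals = 0L) {
  if (any(whole <= 0)) stop("percentOf: whole must be positive")
  roundHalfUp(100 * part / whole, decimals)
}

BASES <- c("A", "C", "G", "T")

# transition partner of each base
TRANSITION <- c(A = "G", C = "T", G = "A", T = "C")

isTransition <- function(ref, alt) TRANSITION[ref] == alt
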