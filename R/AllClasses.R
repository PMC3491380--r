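#' @import methods
#' @importFrom S4Vectors metadata metadata<-
NULL

#' Piecewise-constant demographic history
#'
#' Ordered epochs of constant diploid population size. Epoch \code{i} spans
#' \code{[startTime[i], startTime[i+1])} generations before present; the last
#' epoch extends to infinity. The first epoch must start at 0.
#'
#' @slot startTime numeric vector of epoch start times in generations before
#'   present, strictly increasing, first element 0.
#' @slot diploidSize numeric vector of diploid population sizes, one per epoch,
#'   all positive.
#'
#' @examples
#' DemographicHistory(startTime = c(0, 20000, 60000),
#'                    diploidSize = c(20000, 4000, 15000))
#' @export
setClass("DemographicHistory",
  representation(startTime = "numeric", diploidSize = "numeric"))

setValidity("DemographicHistory", function(object) {
  st <- object@startTime
  ds <- object@diploidSize
  if (length(st) == 0L) return("history needs at least one epoch")
  if (length(st) != length(ds)) return("startTime and diploidSize lengths differ")
  if (st[1L] != 0) return("first epoch must start at time 0")
  if (length(st) > 1L && any(diff(st) <= 0)) return("startTime must be strictly increasing")
  if (any(!is.finite(ds)) || any(ds <= 0)) return("all diploid sizes must be positive")
  TRUE
})

#' @rdname DemographicHistory-class
#' @param startTime,diploidSize see slots.
#' @export
DemographicHistory <- function(startTime, diploidSize) {
  new("DemographicHistory", startTime = as.numeric(startTime),
      diploidSize = as.numeric(diploidSize))
}

#' @export
setMethod("show", "DemographicHistory", function(object) {
  cat("DemographicHistory with", length(object@startTime), "epoch(s)\n")
  print(data.frame(start_gen = object@startTime, diploid_N = object@diploidSize))
})

#' Number of epochs in a demographic history
#' @param x a \code{DemographicHistory}.
#' @export
setMethod("length", "DemographicHistory", function(x) length(x@startTime))

#' Reference assembly with per-base quality
#'
#' A draft reference genome: sequence, per-base assembly quality values
#' (Phred-scaled, 0-60), and gap (N-run) and repeat masks. All interval
#' coordinates are 0-based half-open internally; conversion to 1-based
#' happens only at file-format boundaries.
#'
#' @slot sequence a \code{DNAStringSet}, one entry per chromosome.
#' @slot qv list of integer vectors, per-base assembly QV per chromosome.
#' @slot gaps a \code{GRanges} of N runs.
#' @slot repeats a \code{GRanges} of repeat intervals.
#'
#' @export
setClass("ReferenceAssembly",
  representation(sequence = "ANY", qv = "list", gaps = "ANY", repeats = "ANY"))

setValidity("ReferenceAssembly", function(object) {
  seqs <- object@sequence
  if (!methods::is(seqs, "DNAStringSet")) return("sequence must be a DNAStringSet")
  if (is.null(names(seqs))) return("chromosomes must be named")
  if (!identical(names(object@qv), names(seqs))) return("qv names must match chromosome names")
  len <- Biostrings::width(seqs)
  qlen <- vapply(object@qv, length, integer(1))
  if (!all(qlen == len)) return("QV track length must equal sequence length")
  for (v in object@qv) {
    if (any(v < 0L | v > 60L)) return("QV values must lie in [0, 60]")
  }
  TRUE
})

#' @export
setMethod("show", "ReferenceAssembly", function(object) {
  w <- Biostrings::width(object@sequence)
  cat("ReferenceAssembly:", length(w), "chromosome(s),",
      format(sum(w), big.mark = ","), "bp\n")
  cat("  gaps:", length(object@gaps), "interval(s); repeats:",
      length(object@repeats), "interval(s)\n")
})

#' @rdname ReferenceAssembly-class
#' @param x a \code{ReferenceAssembly}.
#' @export
refSequence <- function(x) x@sequence

#' @rdname ReferenceAssembly-class
#' @export
refQv <- function(x) x@qv

#' @rdname ReferenceAssembly-class
#' @export
refGaps <- function(x) x@gaps

#' @rdname ReferenceAssembly-class
#' @export
refRepeats <- function(x) x@repeats

#' @rdname ReferenceAssembly-class
#' @export
setMethod("length", "ReferenceAssembly", function(x) length(x@sequence))

#' Known truth for a simulated diploid sample
#'
#' Phased diploid variants planted by the simulator: SNVs, small indels,
#' large indels and inversions, each with zygosity. Positions are 0-based.
#'
#' @slot snvs data.frame: chrom, pos, ref, alt, zygosity ("het"/"hom").
#' @slot smallIndels data.frame: chrom, pos, type ("ins"/"del"), length, zygosity.
#' @slot largeIndels data.frame: chrom, pos, type, length.
#' @slot inversions data.frame: chrom, start, end (0-based half-open).
#' @export
setClass("SampleTruth",
  representation(snvs = "data.frame", smallIndels = "data.frame",
                 largeIndels = "data.frame", inversions = "data.frame"))

setValidity("SampleTruth", function(object) {
  sn <- object@snvs
  need <- c("chrom", "pos", "ref", "alt", "zygosity")
  if (nrow(sn) && !all(need %in% names(sn))) return("snvs missing columns")
  if (nrow(sn) && !all(sn$zygosity %in% c("het", "hom"))) return("bad zygosity")
  TRUE
})

#' @export
setMethod("show", "SampleTruth", function(object) {
  cat("SampleTruth:", nrow(object@snvs), "SNVs (",
      sum(object@snvs$zygosity == "het"), "het /",
      sum(object@snvs$zygosity == "hom"), "hom ),",
      nrow(object@smallIndels), "small indels,",
      nrow(object@largeIndels), "large indels,",
      nrow(object@inversions), "inversion(s)\n")
})

#' @rdname SampleTruth-class
#' @param x a \code{SampleTruth}.
#' @export
truthSnvs <- function(x) x@snvs

#' @rdname SampleTruth-class
#' @export
truthSmallIndels <- function(x) x@smallIndels

#' @rdname SampleTruth-class
#' @export
truthLargeIndels <- function(x) x@largeIndels

#' @rdname SampleTruth-class
#' @export
truthInversions <- function(x) x@inversions

#' Fitted piecewise-constant population-size trajectory
#'
#' Result of fitting the discretised-coalescent hidden Markov model to a
#' binned heterozygosity sequence by EM, optionally with block-bootstrap
#' confidence intervals.
#'
#' @slot theta fitted per-bin scaled mutation rate.
#' @slot rho per-bin scaled recombination rate (held fixed during EM).
#' @slot lambda fitted relative sizes, one per atomic time interval.
#' @slot groups integer vector mapping atomic intervals to free parameter groups.
#' @slot boundaries atomic time-interval boundaries (coalescent-scaled time).
#' @slot logLik per-iteration log-likelihood trace.
#' @slot trajectory data.frame of the scaled trajectory (filled by
#'   \code{\link{scaleFit}}).
#' @slot bootstrap list of bootstrap replicate lambda matrices and the CI table.
#' @export
setClass("PsmcFit",
  representation(theta = "numeric", rho = "numeric", lambda = "numeric",
                 groups = "integer", boundaries = "numeric",
                 logLik = "numeric", trajectory = "data.frame",
                 bootstrap = "list"))

setValidity("PsmcFit", function(object) {
  if (object@theta <= 0) return("theta must be positive")
  if (any(object@lambda <= 0)) return("all lambda must be positive")
  if (length(object@lambda) != length(object@boundaries) - 1L)
    return("lambda length must equal number of atomic intervals")
  ll <- object@logLik
  if (length(ll) > 1L && any(diff(ll) < -1e-6 * abs(ll[-length(ll)])))
    return("log-likelihood must be non-decreasing across EM iterations")
  TRUE
})

#' @export
setMethod("show", "PsmcFit", function(object) {
  cat("PsmcFit:", length(object@lambda), "atomic intervals,",
      max(object@groups), "free size groups\n")
  cat("  theta =", signif(object@theta, 4), " rho =", signif(object@rho, 4),
      " logLik =", format(utils::tail(object@logLik, 1L), nsmall = 2), "\n")
  if (nrow(object@trajectory))
    cat("  scaled trajectory available (", nrow(object@trajectory), "rows )\n")
})

#' @rdname PsmcFit-class
#' @param x a \code{PsmcFit}.
#' @export
fitTheta <- function(x) x@theta

#' @rdname PsmcFit-class
#' @export
fitLambda <- function(x) x@lambda

#' @rdname PsmcFit-class
#' @export
fitLogLik <- function(x) x@logLik

#' @rdname PsmcFit-class
#' @export
fitTrajectory <- function(x) x@trajectory
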