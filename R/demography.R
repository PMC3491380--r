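#' @useDynLib cynoseq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Bin a genome into heterozygosity symbols
#'
#' Divides each chromosome into fixed-size bins and assigns each bin a
#' symbol: \code{N} if less than half of the bin is callable, otherwise
#' \code{K} if it contains at least one retained heterozygous SNV, else
#' \code{T}.
#'
#' @param calls retained variant call table (chrom, pos, zygosity); only
#'   het rows are used.
#' @param chromLengths named chromosome lengths (bp).
#' @param binSize bin width in bp (> 0).
#' @param callable optional named list of per-chromosome logical vectors of
#'   per-site callability; NULL means fully callable.
#' @return object of class \code{cynoseq_bins}: integer symbols (0 = T,
#'   1 = K, 2 = N), segment starts, bin size, chromosome names.
#' @export
makeBins <- function(calls, chromLengths, binSize = 100L, callable = NULL) {
  if (binSize <= 0) stop("binSize must be positive")
  symbols <- list()
  segStart <- integer(0)
  off <- 0L
  for (ch in names(chromLengths)) {
    L <- as.integer(chromLengths[ch])
    nb <- ceiling(L / binSize)
    sym <- integer(nb)
    hetPos <- calls$pos[calls$chrom == ch & calls$zygosity == "het"]
    if (length(hetPos)) {
      kb <- unique(hetPos %/% binSize) + 1L
      sym[kb] <- 1L
    }
    if (!is.null(callable[[ch]])) {
      cv <- callable[[ch]]
      if (length(cv) != L) stop("callable vector length mismatch for ", ch)
      bin <- rep(seq_len(nb), each = binSize, length.out = L)
      frac <- tapply(cv, bin, mean)
      sym[frac < 0.5] <- 2L
    }
    symbols[[ch]] <- sym
    segStart <- c(segStart, off)
    off <- off + nb
  }
  structure(list(symbols = unlist(symbols, use.names = FALSE),
                 segStart = segStart, binSize = as.integer(binSize),
                 chroms = names(chromLengths)),
            class = "cynoseq_bins")
}

#' Parse a time-interval grouping pattern
#'
#' Grammar: terms joined by \code{+}; a term is either \code{s} (one group
#' spanning s atomic intervals) or \code{n*s} (n groups each spanning s).
#' \code{"6+29*2"} gives one group of 6 plus 29 groups of 2 (64 atomic
#' intervals).
#'
#' @param text the pattern string.
#' @return integer vector of group spans.
#' @examples
#' parsePattern("6+29*2")
#' @export
parsePattern <- function(text) {
  terms <- strsplit(gsub(" ", "", text), "+", fixed = TRUE)[[1]]
  if (length(terms) == 0L) stop("empty pattern")
  spans <- integer(0)
  for (tm in terms) {
    if (grepl("^[0-9]+\\*[0-9]+$", tm)) {
      ns <- as.integer(strsplit(tm, "*", fixed = TRUE)[[1]])
      spans <- c(spans, rep(ns[2L], ns[1L]))
    } else if (grepl("^[0-9]+$", tm)) {
      spans <- c(spans, as.integer(tm))
    } else {
      stop("malformed pattern term: '", tm, "'")
    }
  }
  if (any(spans <= 0L)) stop("group spans must be positive")
  spans
}

#' Exponentially spaced discretised time grid
#'
#' Boundaries \eqn{t_k = \alpha(\exp(k/n \cdot \ln(1 + t_{max}/\alpha)) - 1)}
#' for \eqn{k = 0..n}, in coalescent-scaled time (units of \eqn{2N_0}
#' generations): \eqn{t_0 = 0} and \eqn{t_n = t_{max}}.
#'
#' @param atomicCount number of atomic intervals n (>= 2).
#' @param tMax last finite boundary (scaled time).
#' @param alpha spacing parameter.
#' @return numeric vector of n + 1 strictly increasing boundaries.
#' @export
timeGrid <- function(atomicCount, tMax = 15, alpha = 0.1) {
  if (atomicCount < 2L) stop("need at least 2 atomic intervals")
  if (tMax <= 0) stop("tMax must be positive")
  k <- 0:atomicCount
  alpha * (exp(k / atomicCount * log(1 + tMax / alpha)) - 1)
}

# stationary state prior and conditional mean TMRCA per atomic interval,
# under relative sizes lambda (one per interval). The last interval is
# treated as extending to infinity for both mass and mean.
statePrior <- function(lambda, boundaries) {
  K <- length(lambda)
  a <- boundaries[seq_len(K)]
  b <- boundaries[-1L]
  d <- b - a
  # survival to each lower boundary
  hz <- d / lambda
  S <- exp(-c(0, cumsum(hz[-K])))
  piK <- S * -expm1(-hz)
  piK[K] <- S[K]  # tail mass beyond the penultimate boundary
  em <- exp(-hz)
  den <- -expm1(-hz)
  tbar <- a + lambda - d * em / den
  tbar[K] <- a[K] + lambda[K]
  list(pi = piK, tbar = tbar)
}

#' HMM quantities of a discretised-coalescent model
#'
#' Exposes the per-state stationary prior, representative (conditional
#' mean) TMRCA, stay probability and het-emission probability, plus the
#' full transition matrix, for inspection and independent verification.
#'
#' @param theta,rho per-bin scaled mutation and recombination rates.
#' @param lambda relative population size per atomic interval.
#' @param boundaries time-grid boundaries (length = intervals + 1).
#' @return list: pi, tbar, stay, jump (the jump-target distribution),
#'   emitK, transition (K x K matrix).
#' @details The transition either stays in the current state (probability
#'   \eqn{e^{-\rho \bar t_i}}) or jumps to a state drawn from
#'   \eqn{q_j \propto \pi_j (1 - e^{-\rho \bar t_j})}. This jump target
#'   makes the chain reversible with stationary distribution \eqn{\pi},
#'   so the coalescent marginal is preserved along the sequence (a plain
#'   jump to \eqn{\pi} would overweight short-TMRCA states, which stay
#'   longer).
#' @export
smcMatrices <- function(theta, rho, lambda, boundaries) {
  stopifnot(theta > 0, rho >= 0, all(lambda > 0),
            length(boundaries) == length(lambda) + 1L)
  sp <- statePrior(lambda, boundaries)
  stay <- exp(-rho * sp$tbar)
  emitK <- -expm1(-theta * sp$tbar)
  w <- sp$pi * (1 - stay)
  q <- if (sum(w) > 0) w / sum(w) else sp$pi
  A <- diag(stay) + (1 - stay) %o% q
  list(pi = sp$pi, tbar = sp$tbar, stay = stay, jump = q, emitK = emitK,
       transition = A)
}

#' Forward-backward pass of the binned-coalescent HMM
#'
#' Scaled forward-backward over a binned heterozygosity sequence under the
#' sequentially-Markovian-coalescent transition (stay with probability
#' \eqn{e^{-\rho \bar t}}, otherwise jump to a state drawn from the
#' stationary coalescent prior) and emission
#' \eqn{P(K \mid t) = 1 - e^{-\theta \bar t}}; missing (N) bins emit 1 for
#' every state. Chromosomes are independent segments starting from the
#' prior.
#'
#' @param bins a \code{\link{makeBins}} object.
#' @param theta,rho,lambda,boundaries model parameters, see
#'   \code{\link{smcMatrices}}.
#' @param returnPosteriors also return the per-bin state posterior matrix.
#' @return list: loglik, expected-count statistics, and optionally
#'   \code{posteriors} (bins x states; rows sum to 1).
#' @export
forwardBackward <- function(bins, theta, rho, lambda, boundaries,
                            returnPosteriors = FALSE) {
  m <- smcMatrices(theta, rho, lambda, boundaries)
  .smcForwardBackward(bins$symbols, bins$segStart, m$pi, m$jump, m$stay,
                      m$emitK, returnPosteriors)
}

# expected complete-data log-likelihood (up to constants) as a function of
# candidate parameters, given E-step sufficient statistics
emQ <- function(logPar, stats, boundaries, groups, rho) {
  theta <- exp(logPar[1L])
  lambda <- exp(logPar[-1L])[groups]
  sp <- statePrior(lambda, boundaries)
  stay <- exp(-rho * sp$tbar)
  jump <- 1 - stay
  emitK <- pmax(-expm1(-theta * sp$tbar), 1e-300)
  emitT <- pmax(exp(-theta * sp$tbar), 1e-300)
  piK <- pmax(sp$pi, 1e-300)
  w <- piK * jump
  q <- pmax(w / sum(w), 1e-300)
  diagA <- pmax(stay + jump * q, 1e-300)
  sum(stats$init * log(piK)) +
    sum(stats$nK * log(emitK)) + sum(stats$nT * log(emitT)) +
    sum(stats$sDiag * log(diagA)) +
    sum(stats$rowOff * log(pmax(jump, 1e-300))) +
    sum(stats$colOff * log(q))
}

#' Fit the binned-coalescent HMM by EM
#'
#' Baum-Welch estimation of the per-group relative sizes \eqn{\lambda_k}
#' and the per-bin scaled mutation rate \eqn{\theta}; the scaled
#' recombination rate \eqn{\rho} is held fixed (default
#' \code{rhoOverTheta} times the initial \eqn{\theta}). The M-step
#' maximises the expected complete-data log-likelihood numerically over
#' the grouped parameters (a generalised EM step: the update is accepted
#' only if it improves the objective, so the log-likelihood trace is
#' non-decreasing).
#'
#' @param bins a \code{\link{makeBins}} object with at least one K and one
#'   T bin.
#' @param pattern grouping pattern for the atomic intervals, see
#'   \code{\link{parsePattern}}.
#' @param tMax,alpha time-grid parameters, see \code{\link{timeGrid}}.
#' @param iterations EM iterations.
#' @param rhoOverTheta fixed ratio of scaled recombination to the initial
#'   mutation-rate estimate.
#' @param thetaInit optional initial theta (default: from the genome-wide
#'   K-bin fraction under a constant-size model).
#' @return a \code{\linkS4class{PsmcFit}}.
#' @export
emFit <- function(bins, pattern = "6+29*2", tMax = 15, alpha = 0.1,
                  iterations = 25L, rhoOverTheta = 0.2, thetaInit = NULL) {
  sym <- bins$symbols
  if (!any(sym == 1L) || !any(sym == 0L))
    stop("degenerate input: need at least one K and one T bin")
  spans <- parsePattern(pattern)
  K <- sum(spans)
  groups <- rep(seq_along(spans), spans)
  boundaries <- timeGrid(K, tMax = tMax, alpha = alpha)
  pK <- mean(sym[sym != 2L] == 1L)
  if (is.null(thetaInit)) thetaInit <- pK / max(1 - pK, 1e-12)
  rho <- rhoOverTheta * thetaInit
  par <- c(log(thetaInit), rep(0, length(spans)))
  llTrace <- numeric(0)
  for (it in seq_len(iterations)) {
    lambda <- exp(par[-1L])[groups]
    st <- forwardBackward(bins, exp(par[1L]), rho, lambda, boundaries)
    llTrace <- c(llTrace, st$loglik)
    opt <- stats::optim(par, function(p) -emQ(p, st, boundaries, groups, rho),
                        method = "BFGS",
                        control = list(maxit = 60, reltol = 1e-10))
    if (-opt$value > emQ(par, st, boundaries, groups, rho)) par <- opt$par
  }
  lambda <- exp(par[-1L])[groups]
  final <- forwardBackward(bins, exp(par[1L]), rho, lambda, boundaries)
  llTrace <- c(llTrace, final$loglik)
  new("PsmcFit", theta = exp(par[1L]), rho = rho, lambda = lambda,
      groups = groups, boundaries = boundaries, logLik = llTrace,
      trajectory = data.frame(), bootstrap = list())
}

#' Scale a fitted trajectory to years and diploid individuals
#'
#' \eqn{N_0 = \theta / (4 \mu b)} for bin size \eqn{b};
#' \eqn{N_k = N_0 \lambda_k}; boundary times in years are
#' \eqn{2 N_0 t_k g} for generation time \eqn{g}.
#'
#' @param fit a \code{\linkS4class{PsmcFit}}.
#' @param mu mutation rate per site per generation.
#' @param generationTime generation time in years.
#' @param binSize bin width used to build the bin sequence (bp).
#' @return the fit with its \code{trajectory} slot filled
#'   (t_years_low, t_years_high, N, and bootstrap bounds when available).
#' @export
scaleFit <- function(fit, mu = 2.5e-8, generationTime = 6, binSize = 100L) {
  stopifnot(is(fit, "PsmcFit"), mu > 0, generationTime > 0)
  N0 <- fit@theta / (4 * mu * binSize)
  K <- length(fit@lambda)
  tYears <- 2 * N0 * fit@boundaries * generationTime
  tr <- data.frame(t_years_low = tYears[seq_len(K)],
                   t_years_high = tYears[-1L],
                   N = N0 * fit@lambda)
  if (!is.null(fit@bootstrap$lambda)) {
    lam <- fit@bootstrap$lambda            # reps x K
    th <- fit@bootstrap$theta
    Nmat <- lam * (th / (4 * mu * binSize))
    lv <- (1 - fit@bootstrap$level) / 2
    tr$N_lo <- apply(Nmat, 2L, stats::quantile, probs = lv)
    tr$N_hi <- apply(Nmat, 2L, stats::quantile, probs = 1 - lv)
  }
  fit@trajectory <- tr
  fit
}

#' Block-bootstrap confidence intervals for the size trajectory
#'
#' Resamples contiguous genome blocks (default 5 Mb) with replacement to
#' the original bin count, refits the model on each replicate, and stores
#' percentile intervals per atomic time interval.
#'
#' @param bins a \code{\link{makeBins}} object.
#' @param fit the point-estimate \code{\linkS4class{PsmcFit}} (its pattern,
#'   grid and settings are reused).
#' @param blockBp block length in bp.
#' @param reps bootstrap replicates (0 = none).
#' @param level confidence level.
#' @param pattern,tMax,alpha,iterations,rhoOverTheta fit settings (must
#'   match the point fit).
#' @param seed RNG seed for block resampling.
#' @return the fit with its \code{bootstrap} slot filled.
#' @export
bootstrapCi <- function(bins, fit, blockBp = 5e6, reps = 20L, level = 0.95,
                        pattern = "6+29*2", tMax = 15, alpha = 0.1,
                        iterations = 25L, rhoOverTheta = 0.2, seed = 1L) {
  stopifnot(is(fit, "PsmcFit"))
  if (reps == 0L) return(fit)
  blockBins <- max(1L, as.integer(blockBp / bins$binSize))
  segEnd <- c(bins$segStart[-1L], length(bins$symbols))
  blocks <- list()
  for (s in seq_along(bins$segStart)) {
    from <- bins$segStart[s] + 1L
    while (from <= segEnd[s]) {
      to <- min(from + blockBins - 1L, segEnd[s])
      blocks[[length(blocks) + 1L]] <- c(from, to)
      from <- to + 1L
    }
  }
  if (length(blocks) < 2L) stop("need at least 2 blocks for the bootstrap")
  nBins <- length(bins$symbols)
  lamMat <- matrix(NA_real_, nrow = reps, ncol = length(fit@lambda))
  thetaV <- numeric(reps)
  withStageSeed(seed, "bootstrap", {
    for (r in seq_len(reps)) {
      total <- 0L
      symL <- list()
      starts <- integer(0)
      while (total < nBins) {
        b <- blocks[[sample.int(length(blocks), 1L)]]
        sym <- bins$symbols[b[1L]:b[2L]]
        starts <- c(starts, total)
        symL[[length(symL) + 1L]] <- sym
        total <- total + length(sym)
      }
      rb <- structure(list(symbols = unlist(symL, use.names = FALSE),
                           segStart = starts, binSize = bins$binSize,
                           chroms = "bootstrap"),
                      class = "cynoseq_bins")
      rf <- emFit(rb, pattern = pattern, tMax = tMax, alpha = alpha,
                  iterations = iterations, rhoOverTheta = rhoOverTheta)
      lamMat[r, ] <- rf@lambda
      thetaV[r] <- rf@theta
    }
  })
  fit@bootstrap <- list(lambda = lamMat, theta = thetaV, level = level,
                        reps = reps)
  fit
}
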