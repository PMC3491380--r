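# shared fixtures, built in code

grFromZeroBasedForTest <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
}

smallConfig <- function(len = 50000, seed = 1L, ...) {
  simulationConfig(chromLengths = c(chr1 = len), seed = seed, ...)
}

# brute-force genotype likelihood: enumerate all 2^depth read-to-allele
# assignments, each with probability (1/2)^depth, reads observed correctly
# with prob 1-eps else one of the other three bases with eps/3 each
bruteGenotypeLik <- function(obsBases, alleles, eps) {
  d <- length(obsBases)
  pRead <- function(x, a) if (x == a) 1 - eps else eps / 3
  total <- 0
  for (mask in 0:(2^d - 1)) {
    assign <- as.integer(intToBits(mask))[seq_len(d)] + 1L
    p <- prod(vapply(seq_len(d), function(i)
      pRead(obsBases[i], alleles[assign[i]]), numeric(1)))
    total <- total + p * 0.5^d
  }
  total
}

countsFromBases <- function(obsBases) {
  v <- table(factor(obsBases, levels = c("A", "C", "G", "T")))
  stats::setNames(as.integer(v), c("A", "C", "G", "T"))
}

# numeric site-weighted empirical CDF of tract TMRCAs evaluated at q
siteWeightedEcdf <- function(tracts, q) {
  w <- tracts$end - tracts$start
  vapply(q, function(x) sum(w[tracts$tmrca <= x]) / sum(w), numeric(1))
}

# brute-force log-likelihood of an HMM by summing over all state paths
brutePathLogLik <- function(symbols, pi, A, emitK) {
  K <- length(pi)
  emit <- function(sym, j) if (sym == 2) 1 else if (sym == 1) emitK[j] else 1 - emitK[j]
  n <- length(symbols)
  paths <- do.call(expand.grid, rep(list(seq_len(K)), n))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- as.integer(paths[r, ])
    p <- pi[s[1]] * emit(symbols[1], s[1])
    for (t in seq_len(n - 1)) {
      p <- p * A[s[t], s[t + 1]] * emit(symbols[t + 1], s[t + 1])
    }
    total <- total + p
  }
  log(total)
}

makeBinObject <- function(symbols, segStart = 0L, binSize = 100L) {
  structure(list(symbols = as.integer(symbols), segStart = as.integer(segStart),
                 binSize = as.integer(binSize),
                 chroms = paste0("chr", seq_along(segStart))),
            class = "cynoseq_bins")
}
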