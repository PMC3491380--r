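#' Call small indels from gapped-alignment evidence
#'
#' Retains candidates with enough supporting reads, length within the
#' caller's detectable range (deletions shorter than 12 bp, insertions
#' shorter than 4 bp), and reference assembly QV at the site of at least
#' \code{minRefQv}. Zygosity is heterozygous when the supporting-read
#' fraction is below \code{homFraction}, homozygous otherwise.
#'
#' @param evidence \code{data.table} of gapped-read candidates (chrom, pos,
#'   type, length, support, depth) as from \code{\link{emitGapEvidence}}.
#' @param refQvAt function(chrom, pos) returning the reference QV at sites,
#'   or an integer vector parallel to \code{evidence} rows.
#' @param minSupport minimum supporting reads.
#' @param minRefQv minimum reference assembly QV.
#' @param homFraction supporting fraction at or above which a call is
#'   homozygous.
#' @param delMaxLen,insMaxLen exclusive upper length limits of the caller.
#' @return list: \code{calls} (chrom, pos, type, length, support, depth,
#'   zygosity) and \code{rejected} (named tally: out_of_range, support,
#'   ref_qv).
#' @export
callSmallIndels <- function(evidence, refQvAt, minSupport = 3L,
                            minRefQv = 45L, homFraction = 0.75,
                            delMaxLen = 12L, insMaxLen = 4L) {
  stopifnot(all(c("chrom", "pos", "type", "length", "support", "depth")
                %in% names(evidence)))
  qv <- if (is.function(refQvAt)) refQvAt(evidence$chrom, evidence$pos)
        else refQvAt
  outOfRange <- (evidence$type == "del" & evidence$length >= delMaxLen) |
    (evidence$type == "ins" & evidence$length >= insMaxLen)
  lowSupport <- !outOfRange & evidence$support < minSupport
  lowQv <- !outOfRange & !lowSupport & qv < minRefQv
  keep <- !(outOfRange | lowSupport | lowQv)
  calls <- data.table::as.data.table(evidence)[keep, ]
  calls$zygosity <- ifelse(calls$support / calls$depth < homFraction,
                           "het", "hom")
  list(calls = calls,
       rejected = c(out_of_range = sum(outOfRange),
                    support = sum(lowSupport), ref_qv = sum(lowQv)))
}

#' Small-indel discovery rate by reference assembly quality
#'
#' Deletion and insertion rates per callable site for every reference QV
#' value, computed before the reference-QV filter (its diagnostic, the
#' analogue of the SNV discovery profile).
#'
#' @param indels small-indel candidates already support- and length-filtered
#'   but NOT reference-QV-filtered (chrom, pos, type), with a \code{qv}
#'   column or a parallel \code{qv} vector.
#' @param qvHistogram named integer vector: number of callable sites per
#'   reference QV value (names are QV values).
#' @param qv reference QV at each indel site (if not a column of
#'   \code{indels}).
#' @return \code{data.table}: qv, callable, del_rate, ins_rate.
#' @export
smallIndelProfile <- function(indels, qvHistogram, qv = indels$qv) {
  q <- as.integer(names(qvHistogram))
  tabFor <- function(type) {
    t0 <- table(factor(qv[indels$type == type], levels = q))
    as.integer(t0)
  }
  dels <- tabFor("del")
  inss <- tabFor("ins")
  callable <- as.numeric(qvHistogram)
  keep <- callable > 0
  data.table::data.table(qv = q[keep], callable = callable[keep],
                         del_rate = dels[keep] / callable[keep],
                         ins_rate = inss[keep] / callable[keep])
}

#' Detect large indels from mate-pair span deviations
#'
#' A pair is discordant when its observed reference span exceeds the
#' library's insert maximum (deletion signal) or falls below the minimum
#' (insertion signal). Discordant pairs of the same sign on the same
#' chromosome are clustered by overlap of their tag-bounded intervals; a
#' call is emitted when a cluster reaches \code{minSupport} pairs. The size
#' estimate is |median span - insert-range midpoint| and the call interval
#' is the intersection of the supporting pairs' inner intervals.
#'
#' @param pairs mate-pair table (chrom, pos1, pos2, span, congruent,
#'   library) as from \code{\link{emitMatePairs}}.
#' @param libraries data.frame: id, insertMin, insertMax.
#' @param minSupport minimum supporting pairs per call.
#' @return \code{data.table}: chrom, start, end, type, size, support,
#'   libraries.
#' @export
detectLargeIndels <- function(pairs, libraries, minSupport = 3L) {
  p <- data.table::as.data.table(pairs)
  lim <- libraries[match(p$library, libraries$id), ]
  sign <- ifelse(p$span > lim$insertMax, "del",
                 ifelse(p$span < lim$insertMin, "ins", NA))
  mid <- (lim$insertMin + lim$insertMax) / 2
  disc <- which(!is.na(sign) & p$congruent)
  if (length(disc) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), type = character(),
                                  size = numeric(), support = integer(),
                                  libraries = character()))
  d <- p[disc, ]
  d$type <- sign[disc]
  d$dev <- abs(d$span - mid[disc])
  out <- list()
  for (grp in split(d, list(d$chrom, d$type), drop = TRUE)) {
    o <- order(grp$pos1)
    grp <- grp[o, ]
    # single-linkage sweep over overlapping [pos1, pos2) intervals
    clusterEnd <- cummax(grp$pos2)
    newCluster <- c(TRUE, grp$pos1[-1L] >= clusterEnd[-nrow(grp)])
    cid <- cumsum(newCluster)
    for (k in unique(cid)) {
      g <- grp[cid == k, ]
      if (nrow(g) < minSupport) next
      out[[length(out) + 1L]] <- data.table::data.table(
        chrom = g$chrom[1L], start = max(g$pos1), end = min(g$pos2),
        type = g$type[1L], size = stats::median(g$dev),
        support = nrow(g),
        libraries = paste(sort(unique(g$library)), collapse = ","))
    }
  }
  if (length(out) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), type = character(),
                                  size = numeric(), support = integer(),
                                  libraries = character()))
  calls <- data.table::rbindlist(out)
  calls[calls$end <= calls$start, c("start", "end") :=
          list(start, start + 1L)]
  data.table::setorder(calls, chrom, start)
  calls[]
}

#' Merge large-indel calls across libraries
#'
#' Same-type calls with reciprocal overlap of at least \code{minOverlap}
#' are merged transitively (connected components); the merged size is the
#' support-weighted mean, the interval the union, the support the sum, and
#' the source libraries the union. An insertion occupies (almost) no
#' reference footprint, so for the overlap test an insertion call is
#' represented by an interval of its estimated inserted length centred on
#' its breakpoint.
#'
#' @param callsA,callsB call tables from \code{\link{detectLargeIndels}}.
#' @param minOverlap reciprocal-overlap fraction required for merging.
#' @return merged call table.
#' @export
mergeIndelCalls <- function(callsA, callsB, minOverlap = 0.5) {
  all <- data.table::rbindlist(list(callsA, callsB))
  if (nrow(all) == 0L) return(all)
  data.table::setorder(all, chrom, type, start)
  n <- nrow(all)
  # effective intervals for the overlap test
  effS <- as.numeric(all$start)
  effE <- as.numeric(all$end)
  ins <- all$type == "ins"
  if (any(ins)) {
    mid <- (effS[ins] + effE[ins]) / 2
    half <- pmax(all$size[ins], effE[ins] - effS[ins], 2) / 2
    effS[ins] <- mid - half
    effE[ins] <- mid + half
  }
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  maxPad <- max(c(0, all$size)) / 2
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (all$chrom[j] != all$chrom[i] || all$type[j] != all$type[i]) break
      # calls are sorted by original start; once past the padded end of i
      # no later call can overlap it
      if (all$start[j] - maxPad >= effE[i]) break
      ov <- min(effE[i], effE[j]) - max(effS[i], effS[j])
      if (ov >= minOverlap * (effE[i] - effS[i]) &&
          ov >= minOverlap * (effE[j] - effS[j])) {
        parent[findRoot(j)] <- findRoot(i)
      }
    }
  }
  root <- vapply(seq_len(n), findRoot, integer(1))
  out <- lapply(split(seq_len(n), root), function(ii) {
    g <- all[ii, ]
    data.table::data.table(
      chrom = g$chrom[1L], start = min(g$start), end = max(g$end),
      type = g$type[1L],
      size = sum(g$size * g$support) / sum(g$support),
      support = sum(g$support),
      libraries = paste(sort(unique(unlist(strsplit(g$libraries, ",")))),
                        collapse = ","))
  })
  merged <- data.table::rbindlist(out)
  data.table::setorder(merged, chrom, start)
  merged[]
}

#' Scan for inversion signatures in sliding windows
#'
#' Counts orientation-incongruent mate pairs whose leftmost tag lies in
#' each sliding window (default 500 bp windows, 250 bp steps) and flags
#' windows reaching \code{minCount} incongruent pairs.
#'
#' @param pairs mate-pair table (chrom, pos1, congruent).
#' @param chromLengths named chromosome lengths.
#' @param window,step window and step sizes (bp).
#' @param minCount incongruent-pair count at which a window is flagged.
#' @return \code{data.table}: chrom, start, end, incongruent, flagged.
#'   Only windows with at least one incongruent pair are returned.
#' @export
inversionScan <- function(pairs, chromLengths, window = 500L, step = 250L,
                          minCount = 50L) {
  inc <- pairs[!pairs$congruent, ]
  out <- list()
  for (ch in names(chromLengths)) {
    L <- as.numeric(chromLengths[ch])
    p <- sort(inc$pos1[inc$chrom == ch])
    if (length(p) == 0L) next
    starts <- seq(0, max(L - step, 0), by = step)
    ends <- pmin(starts + window, L)
    n <- findInterval(ends - 0.5, p) - findInterval(starts - 0.5, p)
    keep <- n > 0L
    out[[ch]] <- data.table::data.table(chrom = ch, start = starts[keep],
                                        end = ends[keep],
                                        incongruent = n[keep],
                                        flagged = n[keep] >= minCount)
  }
  if (length(out) == 0L)
    return(data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric(), incongruent = integer(),
                                  flagged = logical()))
  data.table::rbindlist(out)
}

#' Annotate structural-variant calls with repeat and gap context
#'
#' @param calls call table with chrom, start, end (0-based half-open).
#' @param repeatMask,gapMask \code{GRanges} masks.
#' @return calls with logical columns \code{repeat_context} and
#'   \code{gap_context}, plus a \code{tally} attribute of counts by type.
#' @export
svContext <- function(calls, repeatMask, gapMask) {
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) == 0L) {
    calls$repeat_context <- logical(0)
    calls$gap_context <- logical(0)
    return(calls)
  }
  q <- grFromZeroBased(calls$chrom, calls$start, calls$end)
  calls$repeat_context <- if (length(repeatMask))
    IRanges::overlapsAny(q, repeatMask) else FALSE
  calls$gap_context <- if (length(gapMask))
    IRanges::overlapsAny(q, gapMask) else FALSE
  tally <- calls[, list(repeat_context = sum(repeat_context),
                        gap_context = sum(gap_context)), by = "type"]
  data.table::setattr(calls, "tally", tally)
  calls[]
}
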