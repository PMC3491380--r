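#' Gene models: transcripts with exon and CDS intervals
#'
#' A light transcript-centric annotation container. All intervals are
#' 0-based half-open and sorted within each transcript.
#'
#' @slot transcripts data.frame: tx_id, gene_id, chrom, strand ("+"/"-").
#' @slot exons data.frame: tx_id, start, end.
#' @slot cds data.frame: tx_id, start, end.
#' @export
setClass("AnnotationSet",
  representation(transcripts = "data.frame", exons = "data.frame",
                 cds = "data.frame"))

setValidity("AnnotationSet", function(object) {
  tx <- object@transcripts
  if (nrow(tx) && !all(c("tx_id", "gene_id", "chrom", "strand") %in% names(tx)))
    return("transcripts missing columns")
  if (nrow(tx) && !all(tx$strand %in% c("+", "-"))) return("bad strand")
  for (tab in list(object@exons, object@cds)) {
    if (nrow(tab) && any(tab$end <= tab$start)) return("empty or inverted interval")
    if (nrow(tab) && !all(tab$tx_id %in% tx$tx_id)) return("orphan interval")
  }
  # CDS must lie within exons of the same transcript
  if (nrow(object@cds)) {
    ex <- split(object@exons, object@exons$tx_id)
    cd <- split(object@cds, object@cds$tx_id)
    for (id in names(cd)) {
      e <- ex[[id]]
      if (is.null(e)) return("CDS without exons")
      inside <- vapply(seq_len(nrow(cd[[id]])), function(i)
        any(cd[[id]]$start[i] >= e$start & cd[[id]]$end[i] <= e$end),
        logical(1))
      if (!all(inside)) return("CDS interval outside exons")
    }
  }
  TRUE
})

#' @export
setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet:", length(unique(object@transcripts$gene_id)), "gene(s),",
      nrow(object@transcripts), "transcript(s),",
      nrow(object@exons), "exon(s)\n")
})

#' @rdname AnnotationSet-class
#' @param x an \code{AnnotationSet}.
#' @export
annTranscripts <- function(x) x@transcripts

#' @rdname AnnotationSet-class
#' @export
annExons <- function(x) x@exons

#' @rdname AnnotationSet-class
#' @export
annCds <- function(x) x@cds

# genomic 0-based positions of CDS bases in coding (5'->3' of the mRNA)
# order for one transcript
cdsGenomicPositions <- function(cds, strand) {
  cds <- cds[order(cds$start), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(cds)), function(i)
    seq.int(cds$start[i], cds$end[i] - 1L)), use.names = FALSE)
  if (strand == "-") rev(pos) else pos
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# spliced CDS sequence (coding order) from a per-chromosome character vector
cdsSequence <- function(baseChars, cds, strand) {
  pos <- cdsGenomicPositions(cds, strand)
  b <- baseChars[pos + 1L]
  if (strand == "-") b <- unname(COMPLEMENT[b])
  paste(b, collapse = "")
}

translateCodons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Simulate gene models on a reference
#'
#' Places protein-coding gene models (1-4 exons, UTRs, CDS length divisible
#' by 3) on the reference, then patches the reference sequence so that every
#' CDS starts with ATG, ends with a stop codon, and contains no internal
#' stop. A configurable fraction of genes is placed overlapping a neighbour
#' to exercise the site-class priority rules, and a fraction can be emitted
#' at two loci to exercise multi-locus rejection.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param ref a \code{\linkS4class{ReferenceAssembly}}.
#' @param nGenes number of gene loci to place.
#' @param overlapFraction fraction of genes overlapping the previous gene.
#' @param multiLocusFraction fraction of genes duplicated at a second locus.
#' @return list with \code{annotation} (an \code{AnnotationSet}) and
#'   \code{reference} (the patched \code{ReferenceAssembly}).
#' @export
simulateAnnotation <- function(config, ref, nGenes = 100L,
                               overlapFraction = 0.1,
                               multiLocusFraction = 0) {
  stopifnot(is(ref, "ReferenceAssembly"))
  withStageSeed(config$seed, "annotation", {
    chroms <- names(config$chromLengths)
    lens <- as.numeric(config$chromLengths)
    baseChars <- lapply(chroms, function(ch)
      strsplit(as.character(refSequence(ref)[[ch]]), "")[[1]])
    names(baseChars) <- chroms
    txRows <- list(); exRows <- list(); cdsRows <- list()
    cursor <- stats::setNames(rep(1000, length(chroms)), chroms)
    lastSpan <- NULL
    geneIdx <- 0L
    placeOne <- function(geneId, txId, ch, start) {
      nEx <- sample(1:4, 1L)
      exLen <- sample(120:400, nEx, replace = TRUE)
      inLen <- if (nEx > 1L) sample(200:800, nEx - 1L, replace = TRUE) else integer(0)
      exStart <- start + c(0L, cumsum(exLen[-nEx] + inLen))
      exEnd <- exStart + exLen
      total <- sum(exLen)
      u5 <- sample(0:120, 1L)
      u3 <- sample(10:150, 1L)
      cdsLen <- total - u5 - u3
      cdsLen <- cdsLen - cdsLen %% 3L
      if (cdsLen < 30L) { u5 <- 0L; u3 <- total %% 3L; cdsLen <- total - u3 }
      strand <- sample(c("+", "-"), 1L)
      # CDS occupies exonic positions [u5, u5 + cdsLen) in genomic exon order
      # for "+", and the mirror-image window for "-" (so that the 5' UTR is
      # at the transcription start)
      off5 <- if (strand == "+") u5 else total - u5 - cdsLen
      cdsIv <- list()
      walked <- 0L
      for (i in seq_len(nEx)) {
        a <- max(off5 - walked, 0L)
        b <- min(off5 + cdsLen - walked, exLen[i])
        if (b > a)
          cdsIv[[length(cdsIv) + 1L]] <- c(exStart[i] + a, exStart[i] + b)
        walked <- walked + exLen[i]
      }
      cdsM <- do.call(rbind, cdsIv)
      list(tx = data.frame(tx_id = txId, gene_id = geneId, chrom = ch,
                           strand = strand, stringsAsFactors = FALSE),
           ex = data.frame(tx_id = txId, start = exStart, end = exEnd),
           cds = data.frame(tx_id = txId, start = cdsM[, 1L], end = cdsM[, 2L]),
           span = c(exStart[1L], exEnd[nEx]))
    }
    for (g in seq_len(nGenes)) {
      geneIdx <- geneIdx + 1L
      ci <- sample(seq_along(chroms), 1L, prob = lens)
      ch <- chroms[ci]
      overlap <- !is.null(lastSpan) && lastSpan$chrom == ch &&
        runif(1) < overlapFraction
      start <- if (overlap) lastSpan$span[1L] + sample(50:300, 1L)
               else cursor[ch] + sample(500:3000, 1L)
      gid <- sprintf("gene%04d", geneIdx)
      one <- placeOne(gid, sprintf("%s.t1", gid), ch, as.integer(start))
      if (one$span[2L] + 2000 > lens[ci]) next
      txRows[[length(txRows) + 1L]] <- one$tx
      exRows[[length(exRows) + 1L]] <- one$ex
      cdsRows[[length(cdsRows) + 1L]] <- one$cds
      if (!overlap) cursor[ch] <- max(cursor[ch], one$span[2L])
      lastSpan <- list(chrom = ch, span = one$span)
      if (runif(1) < multiLocusFraction) {
        start2 <- cursor[ch] + sample(5000:8000, 1L)
        two <- placeOne(gid, sprintf("%s.t2", gid), ch, as.integer(start2))
        if (two$span[2L] + 2000 <= lens[ci]) {
          txRows[[length(txRows) + 1L]] <- two$tx
          exRows[[length(exRows) + 1L]] <- two$ex
          cdsRows[[length(cdsRows) + 1L]] <- two$cds
          cursor[ch] <- max(cursor[ch], two$span[2L])
        }
      }
    }
    ann <- new("AnnotationSet",
               transcripts = do.call(rbind, txRows),
               exons = do.call(rbind, exRows),
               cds = do.call(rbind, cdsRows))
    # patch the reference: ATG start, stop at the end, no internal stops
    stops <- c("TAA", "TAG", "TGA")
    writeCodon <- function(ch, cds, strand, codonIdx, codon) {
      pos <- cdsGenomicPositions(cds, strand)
      at <- pos[(3L * (codonIdx - 1L) + 1L):(3L * codonIdx)]
      b <- strsplit(codon, "")[[1]]
      if (strand == "-") b <- unname(COMPLEMENT[b])  # pos already 5'->3'
      baseChars[[ch]][at + 1L] <<- b
    }
    # overlapping transcripts can invalidate each other when a codon is
    # recoded, so patch in rounds and finally drop any transcript that a
    # shared base still leaves inconsistent
    for (round in 1:3) {
      for (i in seq_len(nrow(annTranscripts(ann)))) {
        tx <- annTranscripts(ann)[i, ]
        cds <- annCds(ann)[annCds(ann)$tx_id == tx$tx_id, , drop = FALSE]
        sq <- cdsSequence(baseChars[[tx$chrom]], cds, tx$strand)
        nCodon <- nchar(sq) %/% 3L
        codons <- substring(sq, 3 * seq_len(nCodon) - 2, 3 * seq_len(nCodon))
        if (codons[1L] != "ATG") writeCodon(tx$chrom, cds, tx$strand, 1L, "ATG")
        internalStop <- which(codons[-c(1L, nCodon)] %in% stops) + 1L
        for (k in internalStop) {
          fixed <- sub("^T", "C", codons[k])  # every stop starts with T
          writeCodon(tx$chrom, cds, tx$strand, k, fixed)
        }
        if (!codons[nCodon] %in% stops)
          writeCodon(tx$chrom, cds, tx$strand, nCodon, "TAA")
      }
    }
    seqs <- Biostrings::DNAStringSet(vapply(baseChars, paste, character(1),
                                            collapse = ""))
    names(seqs) <- chroms
    refPatched <- new("ReferenceAssembly", sequence = seqs, qv = refQv(ref),
                      gaps = refGaps(ref), repeats = refRepeats(ref))
    v <- validateModels(ann, refPatched)
    stillBad <- v$rejects$tx_id[v$rejects$reason != "multi_locus"]
    if (length(stillBad)) {
      keep <- !(annTranscripts(ann)$tx_id %in% stillBad)
      ann <- new("AnnotationSet",
                 transcripts = annTranscripts(ann)[keep, , drop = FALSE],
                 exons = annExons(ann)[
                   !(annExons(ann)$tx_id %in% stillBad), , drop = FALSE],
                 cds = annCds(ann)[
                   !(annCds(ann)$tx_id %in% stillBad), , drop = FALSE])
    }
    list(annotation = ann, reference = refPatched)
  })
}

#' Validate transcript models against the reference
#'
#' Rejects transcripts whose CDS length is not divisible by 3, that contain
#' an internal stop codon, or that extend beyond chromosome bounds; rejects
#' entire genes mapped to multiple genomic loci (transcript spans on more
#' than one chromosome or in disjoint clusters).
#'
#' @param annotation an \code{AnnotationSet}.
#' @param ref a \code{\linkS4class{ReferenceAssembly}}.
#' @return list with \code{retained} (an \code{AnnotationSet}) and
#'   \code{rejects} (data.frame: tx_id, reason).
#' @export
validateModels <- function(annotation, ref) {
  stopifnot(is(annotation, "AnnotationSet"), is(ref, "ReferenceAssembly"))
  tx <- annTranscripts(annotation)
  lens <- stats::setNames(Biostrings::width(refSequence(ref)),
                          names(refSequence(ref)))
  baseCache <- new.env()
  getChars <- function(ch) {
    if (is.null(baseCache[[ch]]))
      baseCache[[ch]] <- strsplit(as.character(refSequence(ref)[[ch]]), "")[[1]]
    baseCache[[ch]]
  }
  rejects <- list()
  badTx <- character(0)
  # per-gene multi-locus check
  spanByTx <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    e <- annExons(annotation)[annExons(annotation)$tx_id == tx$tx_id[i], ]
    data.frame(tx_id = tx$tx_id[i], gene_id = tx$gene_id[i],
               chrom = tx$chrom[i], start = min(e$start), end = max(e$end))
  }))
  for (g in unique(spanByTx$gene_id)) {
    s <- spanByTx[spanByTx$gene_id == g, ]
    multi <- length(unique(s$chrom)) > 1L
    if (!multi && nrow(s) > 1L) {
      o <- order(s$start)
      multi <- any(s$start[o][-1L] > cummax(s$end[o])[-nrow(s)])
    }
    if (multi) {
      badTx <- c(badTx, s$tx_id)
      rejects[[length(rejects) + 1L]] <-
        data.frame(tx_id = s$tx_id, reason = "multi_locus")
    }
  }
  for (i in seq_len(nrow(tx))) {
    id <- tx$tx_id[i]
    if (id %in% badTx) next
    e <- annExons(annotation)[annExons(annotation)$tx_id == id, ]
    cds <- annCds(annotation)[annCds(annotation)$tx_id == id, , drop = FALSE]
    reason <- NULL
    if (max(e$end) > lens[tx$chrom[i]] || min(e$start) < 0L) {
      reason <- "out_of_bounds"
    } else if (sum(cds$end - cds$start) %% 3L != 0L) {
      reason <- "cds_not_multiple_of_3"
    } else {
      sq <- cdsSequence(getChars(tx$chrom[i]), cds, tx$strand[i])
      nCodon <- nchar(sq) %/% 3L
      codons <- substring(sq, 3 * seq_len(nCodon) - 2, 3 * seq_len(nCodon))
      if (any(codons[-nCodon] %in% c("TAA", "TAG", "TGA")))
        reason <- "internal_stop"
    }
    if (!is.null(reason)) {
      badTx <- c(badTx, id)
      rejects[[length(rejects) + 1L]] <- data.frame(tx_id = id, reason = reason)
    }
  }
  keep <- !(tx$tx_id %in% badTx)
  retained <- new("AnnotationSet",
                  transcripts = tx[keep, , drop = FALSE],
                  exons = annExons(annotation)[
                    annExons(annotation)$tx_id %in% tx$tx_id[keep], , drop = FALSE],
                  cds = annCds(annotation)[
                    annCds(annotation)$tx_id %in% tx$tx_id[keep], , drop = FALSE])
  rej <- if (length(rejects)) do.call(rbind, rejects)
         else data.frame(tx_id = character(), reason = character())
  list(retained = retained, rejects = rej)
}

# reduced 0-based interval table (chrom, start, end) for a class of intervals
reduceIntervals <- function(chrom, start, end) {
  if (length(start) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  gr <- GenomicRanges::reduce(grFromZeroBased(chrom, start, end))
  zeroBasedFromGr(gr)
}

#' Classify genomic sites by annotation priority
#'
#' Assigns every queried site its highest-priority class among all
#' overlapping transcripts: coding_exon > noncoding_exon (UTR) > intron >
#' intergenic.
#'
#' @param chrom,pos character / 0-based integer vectors of site coordinates.
#' @param annotation a validated \code{AnnotationSet}.
#' @return character vector of site classes.
#' @export
classifySites <- function(chrom, pos, annotation) {
  stopifnot(is(annotation, "AnnotationSet"), length(chrom) == length(pos))
  tx <- annTranscripts(annotation)
  ex <- annExons(annotation)
  cds <- annCds(annotation)
  chTx <- tx$chrom[match(ex$tx_id, tx$tx_id)]
  chCds <- tx$chrom[match(cds$tx_id, tx$tx_id)]
  spans <- do.call(rbind, lapply(split(ex, ex$tx_id), function(e)
    data.frame(tx_id = e$tx_id[1L], start = min(e$start), end = max(e$end))))
  chSpan <- tx$chrom[match(spans$tx_id, tx$tx_id)]
  cdsIv <- reduceIntervals(chCds, cds$start, cds$end)
  exIv <- reduceIntervals(chTx, ex$start, ex$end)
  spanIv <- reduceIntervals(chSpan, spans$start, spans$end)
  out <- rep("intergenic", length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    p <- pos[sel]
    inSet <- function(iv) {
      v <- iv[iv$chrom == ch, , drop = FALSE]
      posInIntervals(p, v$start, v$end)
    }
    cls <- rep("intergenic", length(p))
    cls[inSet(spanIv)] <- "intron"
    cls[inSet(exIv)] <- "noncoding_exon"
    cls[inSet(cdsIv)] <- "coding_exon"
    out[sel] <- cls
  }
  out
}

#' Coding effect of an SNV on one transcript
#'
#' Extracts the affected codon using the transcript frame and strand
#' (reverse-complementing on the minus strand), translates reference and
#' alternative codons with the standard nuclear code, and classifies the
#' change as synonymous, nonsynonymous, or nonsense (new stop codon).
#'
#' @param chrom,pos,alt the variant (0-based position; alt on the plus
#'   strand of the reference).
#' @param txId transcript identifier; \code{pos} must lie in its CDS.
#' @param annotation a validated \code{AnnotationSet}.
#' @param ref a \code{\linkS4class{ReferenceAssembly}}.
#' @param .chars optional pre-split character vector of the chromosome
#'   sequence (internal performance hook).
#' @return "synonymous", "nonsynonymous", "nonsense", or "unknown" when the
#'   reference codon contains N.
#' @export
snvEffect <- function(chrom, pos, alt, txId, annotation, ref, .chars = NULL) {
  tx <- annTranscripts(annotation)
  i <- match(txId, tx$tx_id)
  if (is.na(i)) stop("unknown transcript: ", txId)
  cds <- annCds(annotation)[annCds(annotation)$tx_id == txId, , drop = FALSE]
  strand <- tx$strand[i]
  baseChars <- if (is.null(.chars))
    strsplit(as.character(refSequence(ref)[[chrom]]), "")[[1]]
  else .chars
  cpos <- cdsGenomicPositions(cds, strand)
  j <- match(pos, cpos)
  if (is.na(j)) stop("position not in CDS of ", txId)
  codonIdx <- (j - 1L) %/% 3L + 1L
  at <- cpos[(3L * (codonIdx - 1L) + 1L):(3L * codonIdx)]
  refCodon <- baseChars[at + 1L]
  altB <- alt
  if (strand == "-") {
    refCodon <- unname(COMPLEMENT[refCodon])
    altB <- unname(COMPLEMENT[alt])
  }
  if (any(!refCodon %in% BASES)) return("unknown")
  altCodon <- refCodon
  altCodon[which(at == pos)] <- altB
  aaRef <- translateCodons(paste(refCodon, collapse = ""))
  aaAlt <- translateCodons(paste(altCodon, collapse = ""))
  if (aaAlt == aaRef) "synonymous"
  else if (aaAlt == "*") "nonsense"
  else "nonsynonymous"
}

#' Effect of an indel by site class
#'
#' In coding exons, indels with length divisible by 3 are in-frame and all
#' others frameshift; outside coding exons the effect is "none".
#'
#' @param siteClass site class of the indel's leftmost reference base
#'   (see \code{\link{classifySites}}).
#' @param length indel length in bp (> 0).
#' @return "frameshift", "in_frame" or "none".
#' @export
indelEffect <- function(siteClass, length) {
  stopifnot(all(length > 0))
  ifelse(siteClass != "coding_exon", "none",
         ifelse(length %% 3L == 0L, "in_frame", "frameshift"))
}

#' Flag variants overlapping a repeat mask
#'
#' @param chrom,start,end variant reference intervals, 0-based half-open
#'   (an SNV is \code{[pos, pos+1)}).
#' @param mask a \code{GRanges} repeat mask.
#' @return logical vector: TRUE iff the interval intersects the mask.
#' @export
repeatOverlap <- function(chrom, start, end, mask) {
  if (length(mask) == 0L) return(rep(FALSE, length(start)))
  q <- grFromZeroBased(chrom, start, end)
  IRanges::overlapsAny(q, mask)
}

#' Annotate SNV calls with site class and coding effect
#'
#' Site class follows the priority rule of \code{\link{classifySites}}; for
#' coding sites the effect is computed against every transcript whose CDS
#' covers the site and the highest-impact effect is kept
#' (nonsense > nonsynonymous > synonymous).
#'
#' @param calls a variant call table (chrom, pos, ref, alt, zygosity).
#' @param annotation a validated \code{AnnotationSet}.
#' @param ref a \code{\linkS4class{ReferenceAssembly}}.
#' @return the calls with added columns \code{site_class}, \code{effect}
#'   and \code{repeat_overlap}.
#' @export
annotateCalls <- function(calls, annotation, ref) {
  calls <- data.table::as.data.table(calls)
  calls$site_class <- classifySites(calls$chrom, calls$pos, annotation)
  calls$effect <- "none"
  calls$gene <- NA_character_
  tx <- annTranscripts(annotation)
  cds <- annCds(annotation)
  if (nrow(cds)) {
    cdsGr <- grFromZeroBased(tx$chrom[match(cds$tx_id, tx$tx_id)],
                             cds$start, cds$end)
    coding <- which(calls$site_class == "coding_exon")
    if (length(coding)) {
      charCache <- new.env()
      getChars <- function(ch) {
        if (is.null(charCache[[ch]]))
          charCache[[ch]] <- strsplit(as.character(refSequence(ref)[[ch]]), "")[[1]]
        charCache[[ch]]
      }
      q <- grFromZeroBased(calls$chrom[coding], calls$pos[coding],
                           calls$pos[coding] + 1L)
      hits <- GenomicRanges::findOverlaps(q, cdsGr)
      rank <- c(synonymous = 1L, nonsynonymous = 2L, nonsense = 3L, unknown = 0L)
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      geneOfTx <- stats::setNames(tx$gene_id, tx$tx_id)
      effBy <- tapply(seq_along(qh), qh, function(hh) {
        i <- coding[qh[hh[1L]]]
        txIds <- unique(cds$tx_id[sh[hh]])
        effs <- vapply(txIds, function(id)
          snvEffect(calls$chrom[i], calls$pos[i], calls$alt[i], id,
                    annotation, ref, .chars = getChars(calls$chrom[i])),
          character(1))
        k <- which.max(rank[effs])
        c(effs[k], geneOfTx[txIds[k]])
      })
      idx <- coding[as.integer(names(effBy))]
      calls$effect[idx] <- vapply(effBy, `[`, character(1), 1L)
      calls$gene[idx] <- vapply(effBy, `[`, character(1), 2L)
    }
  }
  calls$repeat_overlap <- repeatOverlap(calls$chrom, calls$pos,
                                        calls$pos + 1L, refRepeats(ref))
  calls[]
}
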