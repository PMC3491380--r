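# File-format boundaries. Internally all positions are 0-based half-open;
# on disk, pileup/mate-pair/VCF positions are 1-based, BED and bedGraph are
# 0-based half-open.

#' Read and write reference FASTA
#'
#' @param ref a \code{\linkS4class{ReferenceAssembly}}.
#' @param path file path.
#' @return \code{readReferenceFasta} returns a \code{DNAStringSet}.
#' @export
writeReferenceFasta <- function(ref, path) {
  Biostrings::writeXStringSet(refSequence(ref), filepath = path)
  invisible(path)
}

#' @rdname writeReferenceFasta
#' @export
readReferenceFasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write / read a per-base QV track as bedGraph
#'
#' Runs of equal QV are collapsed into 0-based half-open intervals.
#'
#' @param qv named list of per-chromosome integer QV vectors.
#' @param path file path.
#' @export
writeQvBedgraph <- function(qv, path) {
  rows <- lapply(names(qv), function(ch) {
    r <- rle(qv[[ch]])
    end <- cumsum(r$lengths)
    data.table::data.table(chrom = ch, start = c(0L, end[-length(end)]),
                           end = end, qv = r$values)
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t")
  invisible(path)
}

#' @rdname writeQvBedgraph
#' @export
readQvBedgraph <- function(path) {
  d <- data.table::fread(path, sep = "\t")
  out <- lapply(split(d, d$chrom), function(x) {
    x <- x[order(x$start), ]
    rep(as.integer(x$qv), x$end - x$start)
  })
  out[unique(d$chrom)]
}

#' Write / read simple BED intervals
#'
#' @param iv data.frame with chrom, start, end (0-based half-open) and
#'   optionally name.
#' @param path file path.
#' @export
writeBed <- function(iv, path) {
  data.table::fwrite(iv, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname writeBed
#' @export
readBed <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  if (ncol(d) >= 4L) names(d)[4L] <- "name"
  d
}

#' Write / read pileup evidence TSV
#'
#' On disk the position column is 1-based (\code{pos1}); in memory it is
#' 0-based (\code{pos}).
#'
#' @param pileup a pileup table from \code{\link{emitPileup}}.
#' @param path file path.
#' @export
writePileup <- function(pileup, path) {
  out <- data.table::copy(data.table::as.data.table(pileup))
  out[, "pos1" := out$pos + 1L]
  out[, "pos" := NULL]
  data.table::setcolorder(out, c("chrom", "pos1", "ref", "refQV", "depth",
                                 "countA", "countC", "countG", "countT"))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname writePileup
#' @export
readPileup <- function(path) {
  d <- data.table::fread(path, sep = "\t")
  need <- c("chrom", "pos1", "ref", "refQV", "depth",
            "countA", "countC", "countG", "countT")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("pileup file missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(d$countA + d$countC + d$countG + d$countT != d$depth)
  if (length(bad)) stop("pileup line ", bad[1L] + 1L,
                        ": base counts do not sum to depth")
  d[, "pos" := d$pos1 - 1L]
  d[, "pos1" := NULL]
  data.table::setcolorder(d, c("chrom", "pos", "ref", "refQV", "depth",
                               "countA", "countC", "countG", "countT"))
  d[]
}

#' Write / read mate-pair records TSV
#'
#' Disk columns: chrom, pos5_tag1, pos5_tag2 (1-based), span,
#' congruent_flag (0/1), library_id.
#'
#' @param pairs a mate-pair table from \code{\link{emitMatePairs}}.
#' @param path file path.
#' @export
writeMatePairs <- function(pairs, path) {
  out <- data.table::data.table(chrom = pairs$chrom,
                                pos5_tag1 = pairs$pos1 + 1L,
                                pos5_tag2 = pairs$pos2 + 1L,
                                span = pairs$span,
                                congruent_flag = as.integer(pairs$congruent),
                                library_id = pairs$library)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname writeMatePairs
#' @export
readMatePairs <- function(path) {
  d <- data.table::fread(path, sep = "\t")
  data.table::data.table(chrom = d$chrom, pos1 = d$pos5_tag1 - 1L,
                         pos2 = d$pos5_tag2 - 1L, span = d$span,
                         congruent = d$congruent_flag == 1L,
                         library = d$library_id)
}

#' Write variant calls as VCF 4.2
#'
#' Emits GT, DP and GQ fields. Heterozygous calls become 0/1, homozygous
#' alternative 1/1. Positions are converted to 1-based.
#'
#' @param calls variant call table (chrom, pos, ref, alt, zygosity, callQV,
#'   depth).
#' @param path file path.
#' @param sample sample name for the genotype column.
#' @export
writeVcf <- function(calls, path, sample = "SAMPLE") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=cynoseq",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample, sep = "\t")), con)
  if (nrow(calls)) {
    gt <- ifelse(calls$zygosity == "het", "0/1", "1/1")
    lines <- paste(calls$chrom, calls$pos + 1L, ".", calls$ref, calls$alt,
                   roundHalfUp(calls$callQV, 0L), "PASS", ".", "GT:DP:GQ",
                   paste0(gt, ":", calls$depth, ":",
                          roundHalfUp(calls$callQV, 0L)),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a VCF written by \code{\link{writeVcf}} back into a call table
#'
#' @param path file path.
#' @return variant call table with 0-based positions.
#' @export
readVcfCalls <- function(path) {
  hdr <- readLines(path, n = 200L)
  skip <- sum(startsWith(hdr, "##"))
  d <- data.table::fread(path, sep = "\t", skip = skip, header = TRUE)
  names(d)[1L] <- sub("^#", "", names(d)[1L])
  fmt <- strsplit(d[[10L]], ":", fixed = TRUE)
  gt <- vapply(fmt, `[`, character(1), 1L)
  data.table::data.table(chrom = as.character(d$CHROM), pos = d$POS - 1L,
                         ref = d$REF, alt = d$ALT,
                         zygosity = ifelse(gt == "0/1", "het", "hom_alt"),
                         depth = as.integer(vapply(fmt, `[`, character(1), 2L)),
                         callQV = as.numeric(vapply(fmt, `[`, character(1), 3L)))
}

#' Write gene models as GFF3
#'
#' @param annotation an \code{AnnotationSet}.
#' @param path file path.
#' @export
writeGff3 <- function(annotation, path) {
  tx <- annTranscripts(annotation)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(tx))) {
    id <- tx$tx_id[i]
    e <- annExons(annotation)[annExons(annotation)$tx_id == id, , drop = FALSE]
    cds <- annCds(annotation)[annCds(annotation)$tx_id == id, , drop = FALSE]
    strand <- tx$strand[i]
    mk <- function(type, start, end, phase, attr)
      paste(tx$chrom[i], "cynoseq", type, start + 1L, end, ".", strand,
            phase, attr, sep = "\t")
    lines <- mk("mRNA", min(e$start), max(e$end), ".",
                sprintf("ID=%s;Parent=%s", id, tx$gene_id[i]))
    lines <- c(lines, mk("exon", e$start, e$end, ".",
                         sprintf("Parent=%s", id)))
    # CDS phase per GFF3: bases to remove to reach the next codon start
    cds <- cds[order(cds$start), , drop = FALSE]
    lenIn <- cds$end - cds$start
    if (strand == "+") {
      before <- c(0L, cumsum(lenIn[-length(lenIn)]))
    } else {
      after <- rev(c(0L, cumsum(rev(lenIn))[-length(lenIn)]))
      before <- after
    }
    phase <- (3L - before %% 3L) %% 3L
    lines <- c(lines, mk("CDS", cds$start, cds$end, phase,
                         sprintf("Parent=%s", id)))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Accepts the subset written by \code{\link{writeGff3}} (mRNA, exon, CDS
#' records with ID/Parent attributes). Malformed or out-of-bounds records
#' raise an error naming the offending line.
#'
#' @param path file path.
#' @param chromLengths optional named lengths used for bounds checking.
#' @return an \code{AnnotationSet}.
#' @export
readGff3 <- function(path, chromLengths = NULL) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  badLen <- which(lengths(fields) != 9L)
  if (length(badLen))
    stop("GFF3 parse error at line ", body[badLen[1L]], ": expected 9 fields")
  getAttr <- function(attr, key) {
    m <- regmatches(attr, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attr))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
           character(1))
  }
  tab <- data.frame(
    line = body,
    chrom = vapply(fields, `[`, character(1), 1L),
    type = vapply(fields, `[`, character(1), 3L),
    start = as.integer(vapply(fields, `[`, character(1), 4L)) - 1L,
    end = as.integer(vapply(fields, `[`, character(1), 5L)),
    strand = vapply(fields, `[`, character(1), 7L),
    attr = vapply(fields, `[`, character(1), 9L),
    stringsAsFactors = FALSE)
  if (anyNA(tab$start) || anyNA(tab$end))
    stop("GFF3 parse error at line ",
         tab$line[which(is.na(tab$start) | is.na(tab$end))[1L]],
         ": non-numeric coordinates")
  if (!is.null(chromLengths)) {
    bad <- which(tab$end > chromLengths[tab$chrom] | tab$start < 0L)
    if (length(bad))
      stop("GFF3 parse error at line ", tab$line[bad[1L]],
           ": feature out of chromosome bounds")
  }
  mrna <- tab[tab$type == "mRNA", , drop = FALSE]
  tx <- data.frame(tx_id = getAttr(mrna$attr, "ID"),
                   gene_id = getAttr(mrna$attr, "Parent"),
                   chrom = mrna$chrom, strand = mrna$strand,
                   stringsAsFactors = FALSE)
  ex <- tab[tab$type == "exon", , drop = FALSE]
  cds <- tab[tab$type == "CDS", , drop = FALSE]
  new("AnnotationSet", transcripts = tx,
      exons = data.frame(tx_id = getAttr(ex$attr, "Parent"),
                         start = ex$start, end = ex$end),
      cds = data.frame(tx_id = getAttr(cds$attr, "Parent"),
                       start = cds$start, end = cds$end))
}

#' Write / read a bin sequence in a FASTA-like text format
#'
#' One header line per chromosome (\code{>name}), then one character per
#' bin: K (heterozygous), T (homozygous callable), N (missing), wrapped at
#' 60 columns.
#'
#' @param bins a \code{\link{makeBins}} object.
#' @param path file path.
#' @export
writeBins <- function(bins, path) {
  con <- file(path, "w")
  on.exit(close(con))
  segEnd <- c(bins$segStart[-1L], length(bins$symbols))
  for (s in seq_along(bins$chroms)) {
    writeLines(paste0(">", bins$chroms[s]), con)
    sym <- bins$symbols[(bins$segStart[s] + 1L):segEnd[s]]
    chars <- c("T", "K", "N")[sym + 1L]
    txt <- paste(chars, collapse = "")
    starts <- seq(1L, nchar(txt), by = 60L)
    writeLines(substring(txt, starts, pmin(starts + 59L, nchar(txt))), con)
  }
  invisible(path)
}

#' @rdname writeBins
#' @param binSize bin width recorded in the returned object.
#' @export
readBins <- function(path, binSize = 100L) {
  lines <- readLines(path)
  hd <- which(startsWith(lines, ">"))
  if (length(hd) == 0L) stop("no chromosome headers in bin file")
  chroms <- sub("^>", "", lines[hd])
  ends <- c(hd[-1L] - 1L, length(lines))
  symbols <- integer(0)
  segStart <- integer(0)
  for (s in seq_along(hd)) {
    txt <- paste(lines[(hd[s] + 1L):ends[s]], collapse = "")
    sym <- match(strsplit(txt, "")[[1]], c("T", "K", "N")) - 1L
    if (anyNA(sym)) stop("invalid bin symbol in ", chroms[s])
    segStart <- c(segStart, length(symbols))
    symbols <- c(symbols, sym)
  }
  structure(list(symbols = symbols, segStart = segStart,
                 binSize = as.integer(binSize), chroms = chroms),
            class = "cynoseq_bins")
}

#' Write a scaled trajectory with confidence bounds as TSV
#'
#' @param fit a scaled \code{\linkS4class{PsmcFit}}.
#' @param path file path.
#' @export
writeTrajectory <- function(fit, path) {
  if (nrow(fit@trajectory) == 0L) stop("scale the fit first (scaleFit)")
  data.table::fwrite(fit@trajectory, path, sep = "\t")
  invisible(path)
}
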