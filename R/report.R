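#' Aggregate a sequencing-library summary table
#'
#' Sums run, read, mapped-read and analyzed-read counts and the per-library
#' coverage depths into a totals row, and reports mapped and analyzed
#' percentages of total reads, rounded half-up to one decimal.
#'
#' @param rows data.frame with columns library, reads, mapped, analyzed,
#'   runs, coverage (as in \code{\link{librarySummaryTable}}).
#' @return list: \code{totals} (one-row data.frame) and the percentages
#'   \code{mapped_pct}, \code{analyzed_pct}.
#' @export
aggregateSequencingSummary <- function(rows) {
  stopifnot(nrow(rows) >= 1L)
  totals <- data.frame(
    library = "Total",
    runs = sum(rows$runs),
    reads = sum(as.numeric(rows$reads)),
    mapped = sum(as.numeric(rows$mapped)),
    analyzed = sum(as.numeric(rows$analyzed)),
    coverage = sum(rows$coverage))
  list(totals = totals,
       mapped_pct = percentOf(totals$mapped, totals$reads, 1L),
       analyzed_pct = percentOf(totals$analyzed, totals$reads, 1L))
}

#' Aggregate a per-chromosome-class variant summary table
#'
#' Column sums across chromosome classes (e.g. autosomes + X) for every
#' count column.
#'
#' @param rows data.frame with a \code{chromosome_class} column followed by
#'   count columns (as in \code{\link{variantCountTable}}).
#' @return one-row data.frame of totals.
#' @export
aggregateVariantSummary <- function(rows) {
  stopifnot(nrow(rows) >= 1L)
  countCols <- setdiff(names(rows), "chromosome_class")
  totals <- lapply(rows[countCols], function(x) sum(as.numeric(x), na.rm = TRUE))
  cbind(data.frame(chromosome_class = "Total"), as.data.frame(totals))
}

#' Bundled sequencing-library summary of the macaque resequencing run
#'
#' Per-library sequencing and mapping counts for the male Malaysian
#' cynomolgus macaque resequenced against the Indian rhesus reference: one
#' 50-bp fragment library and two 25x2 mate-pair libraries (600-800 bp and
#' 800-1,000 bp inserts). Shipped as plain TSV input for the summary
#' aggregators.
#'
#' @return data.frame: library, read_length, insert, runs, reads, mapped,
#'   analyzed, coverage.
#' @export
librarySummaryTable <- function() {
  p <- system.file("extdata", "library_summary.tsv", package = "cynoseq",
                   mustWork = TRUE)
  utils::read.delim(p, stringsAsFactors = FALSE)
}

#' Bundled per-chromosome-class SNV counts of the macaque resequencing run
#'
#' Counts of retained heterozygous and homozygous SNVs, nonsynonymous (A),
#' synonymous (S), UTR, intronic and intergenic SNVs for autosomes and the
#' X chromosome (male: only homozygous X SNVs counted). Shipped as plain
#' TSV input for the summary aggregators.
#'
#' @return data.frame with a chromosome_class column and count columns.
#' @export
variantCountTable <- function() {
  p <- system.file("extdata", "variant_counts.tsv", package = "cynoseq",
                   mustWork = TRUE)
  utils::read.delim(p, stringsAsFactors = FALSE)
}

#' Bundled small-indel effect counts of the macaque resequencing run
#'
#' Counts of frameshifting and non-frameshifting (3x-bp) small indels in
#' autosomal protein-coding regions, total small insertions and deletions,
#' and their repeat-region subsets.
#'
#' @return data.frame: quantity, count.
#' @export
indelCountTable <- function() {
  p <- system.file("extdata", "indel_counts.tsv", package = "cynoseq",
                   mustWork = TRUE)
  utils::read.delim(p, stringsAsFactors = FALSE)
}
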