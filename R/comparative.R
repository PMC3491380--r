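#' Build a multi-individual genotype panel
#'
#' Aligns per-individual variant calls on shared reference coordinates. At
#' every site in the union of variant sites, each individual's genotype is
#' its call if present, "missing" if the site is in that individual's
#' uncallable set, and "hom_ref" otherwise.
#'
#' @param variants named list (one element per individual) of variant call
#'   tables with columns chrom, pos, alt, zygosity ("het"/"hom_alt" or
#'   "hom").
#' @param groups named character vector mapping individual ids to species
#'   group labels.
#' @param missing optional named list of data.frames (chrom, pos) of
#'   uncallable sites per individual.
#' @return list of class \code{cynoseq_panel} with elements \code{sites}
#'   (a \code{data.table}: chrom, pos, then per individual \code{<id>.gt}
#'   and \code{<id>.alt}) and \code{groups}.
#' @export
genotypePanel <- function(variants, groups, missing = NULL) {
  ids <- names(variants)
  if (is.null(ids) || any(!nzchar(ids))) stop("individuals must be named")
  if (!all(ids %in% names(groups))) stop("every individual needs a group label")
  if (any(!nzchar(groups))) stop("group labels must be non-empty")
  normZyg <- function(z) ifelse(z == "hom", "hom_alt", z)
  siteL <- lapply(variants, function(v) data.table::data.table(
    chrom = v$chrom, pos = v$pos))
  sites <- unique(data.table::rbindlist(siteL))
  data.table::setkey(sites, chrom, pos)
  for (id in ids) {
    v <- data.table::as.data.table(variants[[id]])
    v <- data.table::data.table(chrom = v$chrom, pos = v$pos,
                                gt = normZyg(v$zygosity), alt = v$alt)
    data.table::setkey(v, chrom, pos)
    m <- v[sites]
    gt <- m$gt
    alt <- m$alt
    gt[is.na(gt)] <- "hom_ref"
    if (!is.null(missing[[id]]) && nrow(missing[[id]])) {
      mm <- data.table::data.table(chrom = missing[[id]]$chrom,
                                   pos = missing[[id]]$pos, miss = TRUE)
      data.table::setkey(mm, chrom, pos)
      isMiss <- !is.na(mm[sites]$miss)
      gt[isMiss] <- "missing"
      alt[isMiss] <- NA_character_
    }
    sites[, paste0(id, ".gt") := gt]
    sites[, paste0(id, ".alt") := alt]
  }
  structure(list(sites = sites, groups = groups[ids]),
            class = "cynoseq_panel")
}

panelCol <- function(panel, id, what) panel$sites[[paste0(id, ".", what)]]

nonRef <- function(gt) gt %in% c("het", "hom_alt")

#' SNV sites shared by two individuals
#'
#' Sites where both individuals carry the same alternative allele in any
#' non-reference genotype (homozygous or heterozygous).
#'
#' @param panel a \code{\link{genotypePanel}}.
#' @param a,b individual ids.
#' @return \code{data.table} (chrom, pos) of shared sites.
#' @export
sharedSnvs <- function(panel, a, b) {
  ga <- panelCol(panel, a, "gt"); gb <- panelCol(panel, b, "gt")
  sel <- nonRef(ga) & nonRef(gb) &
    panelCol(panel, a, "alt") == panelCol(panel, b, "alt")
  sel[is.na(sel)] <- FALSE
  panel$sites[sel, c("chrom", "pos")]
}

#' Union of two individuals' SNV sites
#'
#' All sites where either individual carries a non-reference genotype;
#' satisfies |union| = |a| + |b| - |shared-by-position|.
#'
#' @inheritParams sharedSnvs
#' @return \code{data.table} (chrom, pos).
#' @export
mergedUnion <- function(panel, a, b) {
  sel <- nonRef(panelCol(panel, a, "gt")) | nonRef(panelCol(panel, b, "gt"))
  panel$sites[sel, c("chrom", "pos")]
}

#' SNVs private to one individual
#'
#' Non-reference sites of \code{a} at which every other panel member is
#' homozygous reference. Sites where any other individual is missing are
#' excluded (no evidence either way).
#'
#' @inheritParams sharedSnvs
#' @return \code{data.table} (chrom, pos).
#' @export
privateSnvs <- function(panel, a) {
  ids <- names(panel$groups)
  stopifnot(a %in% ids)
  others <- setdiff(ids, a)
  sel <- nonRef(panelCol(panel, a, "gt"))
  for (o in others) {
    g <- panelCol(panel, o, "gt")
    sel <- sel & g == "hom_ref"
  }
  panel$sites[sel, c("chrom", "pos")]
}

#' Completely differentiated SNVs between two species groups
#'
#' Sites at which every member of group 1 is homozygous for one allele and
#' every member of group 2 homozygous for a different allele — no
#' heterozygotes and no missing calls anywhere in either group.
#'
#' @param panel a \code{\link{genotypePanel}}.
#' @param group1,group2 group labels (disjoint, each non-empty).
#' @return \code{data.table} (chrom, pos).
#' @export
completelyDifferentiated <- function(panel, group1, group2) {
  ids1 <- names(panel$groups)[panel$groups == group1]
  ids2 <- names(panel$groups)[panel$groups == group2]
  if (length(ids1) == 0L || length(ids2) == 0L) stop("empty group")
  if (length(intersect(ids1, ids2))) stop("groups must be disjoint")
  # homozygous allele carried by each individual: ref base placeholder "."
  # for hom_ref, the alt allele for hom_alt, NA for het/missing
  homAllele <- function(id) {
    g <- panelCol(panel, id, "gt")
    ifelse(g == "hom_ref", ".", ifelse(g == "hom_alt",
                                       panelCol(panel, id, "alt"), NA))
  }
  groupAllele <- function(ids) {
    al <- homAllele(ids[1L])
    for (id in ids[-1L]) {
      x <- homAllele(id)
      al[is.na(x) | is.na(al) | x != al] <- NA
    }
    al
  }
  a1 <- groupAllele(ids1)
  a2 <- groupAllele(ids2)
  sel <- !is.na(a1) & !is.na(a2) & a1 != a2
  panel$sites[sel, c("chrom", "pos")]
}

#' Fraction of one individual's heterozygous SNVs that are heterozygous in
#' another
#'
#' @inheritParams sharedSnvs
#' @return |sites het in both with the same alt| / |sites het in a|;
#'   \code{NaN} with a warning if \code{a} has no heterozygous site.
#' @export
sharedHetFraction <- function(panel, a, b) {
  ga <- panelCol(panel, a, "gt"); gb <- panelCol(panel, b, "gt")
  hetA <- ga == "het"
  if (!any(hetA)) {
    warning("individual ", a, " has no heterozygous sites")
    return(NaN)
  }
  both <- hetA & gb == "het" &
    panelCol(panel, a, "alt") == panelCol(panel, b, "alt")
  both[is.na(both)] <- FALSE
  sum(both) / sum(hetA)
}

#' Category-restricted candidate-gene screen
#'
#' Lists, per user-supplied category, the genes carrying at least one
#' homozygous nonsynonymous SNV among the completely differentiated sites.
#' Category labels (e.g. GO ids) are opaque strings; no ontology traversal.
#'
#' @param effects annotated variant calls of the focal individual
#'   (columns chrom, pos, zygosity, effect, gene as produced by
#'   \code{\link{annotateCalls}}).
#' @param differentiatedSites \code{data.table} (chrom, pos) from
#'   \code{\link{completelyDifferentiated}}.
#' @param categoryMap data.frame with columns \code{gene}, \code{category}.
#' @param knownGenes optional character vector of valid gene ids; map rows
#'   naming other genes are dropped with a warning.
#' @return \code{data.table}: category, gene, n_snvs.
#' @export
geneScreen <- function(effects, differentiatedSites, categoryMap,
                       knownGenes = NULL) {
  stopifnot(all(c("gene", "category") %in% names(categoryMap)))
  if (!is.null(knownGenes)) {
    unknown <- setdiff(categoryMap$gene, knownGenes)
    if (length(unknown)) {
      warning("unknown genes in category map ignored: ",
              paste(unknown, collapse = ", "))
      categoryMap <- categoryMap[!categoryMap$gene %in% unknown, , drop = FALSE]
    }
  }
  ef <- data.table::as.data.table(effects)
  ds <- data.table::as.data.table(differentiatedSites)
  ds$differentiated <- TRUE
  data.table::setkeyv(ds, c("chrom", "pos"))
  qual <- ef[ef$effect == "nonsynonymous" &
               ef$zygosity %in% c("hom", "hom_alt"), ]
  if (nrow(qual)) {
    m <- ds[qual, on = c("chrom", "pos")]
    qual <- qual[!is.na(m$differentiated), ]
  }
  gene <- category <- NULL  # NSE
  cm <- data.table::as.data.table(categoryMap)
  hits <- merge(qual, cm, by = "gene", allow.cartesian = TRUE)
  if (nrow(hits) == 0L)
    return(data.table::data.table(category = character(), gene = character(),
                                  n_snvs = integer()))
  out <- hits[, list(n_snvs = .N), by = c("category", "gene")]
  data.table::setorder(out, category, gene)
  out[]
}
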