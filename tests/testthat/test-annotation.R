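# site classification and coding-effect annotation

# a tiny hand-built reference + two-gene annotation used across tests:
# gene on "+" strand with 2 exons, and a "-" strand single-exon gene
tinyScene <- function() {
  # plus gene: exon1 [10,25), intron, exon2 [35,55)
  #   5' UTR [10,16), CDS [16,25)+[35,50) (24 bp = 8 codons), 3' UTR [50,55)
  # layout the CDS as ATG + 6 arbitrary non-stop codons + TAA
  cds1 <- "ATGGAAGAATACCTGCATGCA"   # 7 codons: M E E Y L H A
  cds2 <- "TAA"
  codingSeq <- paste0(cds1, cds2)   # 24 bp
  base <- rep("G", 200)
  base[11:16] <- strsplit("TTTTTT", "")[[1]]               # 5' UTR
  coding <- strsplit(codingSeq, "")[[1]]
  base[17:25] <- coding[1:9]                               # CDS in exon 1
  base[36:50] <- coding[10:24]                             # CDS in exon 2
  base[51:55] <- strsplit("AAAAA", "")[[1]]                # 3' UTR
  # minus-strand gene at [120,150): CDS whole exon, 30 bp
  # coding strand sequence (reverse complement of genome):
  minusCds <- "ATGCATGAAGAATACCTGCATGCAGAATAA"  # 10 codons, ends with stop
  mc <- strsplit(minusCds, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  base[121:150] <- rev(unname(comp[mc]))
  seqs <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(seqs) <- "chr1"
  ref <- new("ReferenceAssembly", sequence = seqs,
             qv = list(chr1 = rep(60L, 200)),
             gaps = GenomicRanges::GRanges(),
             repeats = GenomicRanges::GRanges("chr1", IRanges::IRanges(61, 80)))
  ann <- new("AnnotationSet",
             transcripts = data.frame(
               tx_id = c("tx1", "tx2"), gene_id = c("g1", "g2"),
               chrom = "chr1", strand = c("+", "-"),
               stringsAsFactors = FALSE),
             exons = data.frame(tx_id = c("tx1", "tx1", "tx2"),
                                start = c(10L, 35L, 120L),
                                end = c(25L, 55L, 150L)),
             cds = data.frame(tx_id = c("tx1", "tx1", "tx2"),
                              start = c(16L, 35L, 120L),
                              end = c(25L, 50L, 150L)))
  list(ref = ref, ann = ann)
}

test_that("model validation rejects bad transcripts and multi-locus genes", {
  sc <- tinyScene()
  v <- validateModels(sc$ann, sc$ref)
  expect_equal(nrow(v$rejects), 0L)
  expect_equal(nrow(annTranscripts(v$retained)), 2L)

  # CDS length not divisible by 3
  bad <- sc$ann
  bad@cds$end[2L] <- 49L
  v2 <- validateModels(bad, sc$ref)
  expect_true("tx1" %in% v2$rejects$tx_id)
  expect_equal(v2$rejects$reason[v2$rejects$tx_id == "tx1"],
               "cds_not_multiple_of_3")

  # internal stop: break the genome under the first CDS codon after ATG
  chars <- strsplit(as.character(refSequence(sc$ref)[[1]]), "")[[1]]
  chars[20:22] <- c("T", "A", "A")
  seqs <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(seqs) <- "chr1"
  refBad <- new("ReferenceAssembly", sequence = seqs, qv = refQv(sc$ref),
                gaps = refGaps(sc$ref), repeats = refRepeats(sc$ref))
  v3 <- validateModels(sc$ann, refBad)
  expect_equal(v3$rejects$reason[v3$rejects$tx_id == "tx1"], "internal_stop")

  # gene present at two loci is rejected entirely
  multi <- sc$ann
  multi@transcripts <- rbind(multi@transcripts,
    data.frame(tx_id = "tx3", gene_id = "g1", chrom = "chr1", strand = "+",
               stringsAsFactors = FALSE))
  multi@exons <- rbind(multi@exons,
                       data.frame(tx_id = "tx3", start = 170L, end = 185L))
  multi@cds <- rbind(multi@cds,
                     data.frame(tx_id = "tx3", start = 170L, end = 185L))
  v4 <- validateModels(multi, sc$ref)
  expect_setequal(v4$rejects$tx_id[v4$rejects$reason == "multi_locus"],
                  c("tx1", "tx3"))

  # out-of-bounds transcript
  oob <- sc$ann
  oob@exons$end[3L] <- 500L
  v5 <- validateModels(oob, sc$ref)
  expect_equal(v5$rejects$reason[v5$rejects$tx_id == "tx2"], "out_of_bounds")
})

test_that("site classification follows the priority order", {
  sc <- tinyScene()
  cls <- classifySites(rep("chr1", 6), c(17L, 12L, 28L, 100L, 125L, 52L),
                       sc$ann)
  expect_equal(cls, c("coding_exon", "noncoding_exon", "intron", "intergenic",
                      "coding_exon", "noncoding_exon"))

  # a site in the CDS of one transcript and the intron of another is coding
  overl <- sc$ann
  overl@transcripts <- rbind(overl@transcripts,
    data.frame(tx_id = "tx3", gene_id = "g3", chrom = "chr1", strand = "+",
               stringsAsFactors = FALSE))
  # tx3 exons flank position 40 so that 40 is intronic for tx3
  overl@exons <- rbind(overl@exons,
                       data.frame(tx_id = c("tx3", "tx3"),
                                  start = c(2L, 58L), end = c(8L, 64L)))
  expect_equal(classifySites("chr1", 40L, overl), "coding_exon")
  # priority is total: every site gets exactly one class
  all <- classifySites(rep("chr1", 200), 0:199, sc$ann)
  expect_true(all(all %in% c("coding_exon", "noncoding_exon", "intron",
                             "intergenic")))
})

test_that("SNV effects: synonymous, nonsense, strand symmetry", {
  sc <- tinyScene()
  # tx1 codon 2 is GAA (Glu) at genome [19,22); GAA->GAG at codon pos 3 is
  # synonymous (pos 21 A->G)
  expect_equal(snvEffect("chr1", 21L, "G", "tx1", sc$ann, sc$ref),
               "synonymous")
  # codon 4 TAC (Tyr) occupies genome positions 35-37: TAC->TAA at codon
  # position 3 (genome pos 37, C->A) is nonsense
  expect_equal(snvEffect("chr1", 37L, "A", "tx1", sc$ann, sc$ref),
               "nonsense")
  # nonsynonymous: codon 2 GAA->GCA (Glu->Ala), genome pos 20 A->C
  expect_equal(snvEffect("chr1", 20L, "C", "tx1", sc$ann, sc$ref),
               "nonsynonymous")
})

test_that("effects agree with a whole-CDS translate-before/after oracle", {
  cfg <- smallConfig(len = 2e5, seed = 30)
  ref0 <- simulateReference(cfg)
  sim <- simulateAnnotation(cfg, ref0, nGenes = 30, overlapFraction = 0)
  ann <- sim$annotation
  ref <- sim$reference
  tx <- annTranscripts(ann)
  chars <- strsplit(as.character(refSequence(ref)[[1]]), "")[[1]]
  gc <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(31)
  nChecked <- 0
  for (rep in seq_len(1000)) {
    i <- sample(nrow(tx), 1)
    cds <- annCds(ann)[annCds(ann)$tx_id == tx$tx_id[i], , drop = FALSE]
    cpos <- unlist(lapply(seq_len(nrow(cds)), function(k)
      seq.int(cds$start[k], cds$end[k] - 1L)))
    pos <- sample(cpos, 1)
    refBase <- chars[pos + 1L]
    alt <- sample(setdiff(c("A", "C", "G", "T"), refBase), 1)
    # oracle: translate the whole CDS before and after the substitution
    translateCds <- function(v) {
      b <- v[sort(cpos) + 1L]
      if (tx$strand[i] == "-") b <- rev(unname(comp[b]))
      codons <- apply(matrix(b, nrow = 3), 2, paste, collapse = "")
      unname(gc[codons])
    }
    before <- translateCds(chars)
    after <- chars
    after[pos + 1L] <- alt
    after <- translateCds(after)
    j <- which(before != after)
    oracle <- if (length(j) == 0) "synonymous"
              else if (any(after[j] == "*")) "nonsense"
              else "nonsynonymous"
    got <- snvEffect("chr1", pos, alt, tx$tx_id[i], ann, ref)
    expect_equal(got, oracle,
                 label = paste("tx", tx$tx_id[i], "pos", pos, "alt", alt))
    nChecked <- nChecked + 1
  }
  expect_equal(nChecked, 1000)
})

test_that("indel effects and repeat overlap follow interval rules", {
  expect_equal(indelEffect("coding_exon", 3L), "in_frame")
  expect_equal(indelEffect("coding_exon", 4L), "frameshift")
  expect_equal(indelEffect("intergenic", 5L), "none")
  expect_equal(indelEffect(c("coding_exon", "intron"), c(6L, 6L)),
               c("in_frame", "none"))

  sc <- tinyScene()
  mask <- refRepeats(sc$ref)  # [60,80) 0-based
  expect_true(repeatOverlap("chr1", 65L, 66L, mask))
  expect_false(repeatOverlap("chr1", 90L, 91L, mask))
  # deletion straddling the mask edge intersects it
  expect_true(repeatOverlap("chr1", 55L, 62L, mask))
  expect_true(repeatOverlap("chr1", 79L, 85L, mask))
  expect_false(repeatOverlap("chr1", 80L, 85L, mask))
})

test_that("annotated call tallies are conserved and gene ids recorded", {
  cfg <- smallConfig(len = 2e5, seed = 32)
  ref0 <- simulateReference(cfg)
  sim <- simulateAnnotation(cfg, ref0, nGenes = 25, overlapFraction = 0)
  hist <- DemographicHistory(0, 20000)
  truth <- imposeVariants(sim$reference, simulateTmrca(hist, cfg), cfg)
  snv <- truthSnvs(truth)
  eff <- annotateCalls(snv, sim$annotation, sim$reference)
  expect_equal(nrow(eff), nrow(snv))
  expect_true(all(table(eff$site_class) >= 0))
  expect_equal(sum(table(eff$site_class)), nrow(snv))
  # coding effect only in coding exons
  expect_true(all(eff$site_class[eff$effect != "none"] == "coding_exon"))
  expect_true(all(!is.na(eff$gene[eff$effect != "none"])))
})
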