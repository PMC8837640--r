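# A compact hand-built locus: one plus- and one minus-strand gene with
# known codons, assembled base by base so every expected effect can be
# derived on paper.
makeMiniLocus <- function() {
  ## plus gene: ATG GCT TGG TAA at 101..112, utr5 91..100, utr3 113..122
  ## minus gene: same codons, written reverse-complemented at 201..212
  chrom <- rep("C", 400)
  chrom[101:112] <- strsplit("ATGGCTTGGTAA", "")[[1]]
  minus_cds <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("ATGGCTTGGTAA")))
  chrom[201:212] <- strsplit(minus_cds, "")[[1]]
  genome <- Biostrings::DNAStringSet(c(C = paste(chrom, collapse = "")))
  plus <- GeneModel("plus", "C", "+", cds = rbind(c(101, 112)),
                    utr5 = rbind(c(91, 100)), utr3 = rbind(c(113, 122)))
  minus <- GeneModel("minus", "C", "-", cds = rbind(c(201, 212)),
                     utr5 = rbind(c(213, 222)), utr3 = rbind(c(191, 200)))
  list(genome = genome, plus = plus, minus = minus, chrom = chrom)
}

test_that("SNP coding effects follow the standard genetic code", {
  ml <- makeMiniLocus()
  eff <- function(pos, ref, alt, gene) {
    codingEffect(pos, ref, alt, gene, ml$genome)$term
  }
  ## plus strand: codon 2 GCT; third base 106 T->C keeps Ala
  expect_identical(eff(106L, "T", "C", ml$plus), "synonymous_variant")
  ## second base 105 C->T gives GTT (Val)
  expect_identical(eff(105L, "C", "T", ml$plus), "missense_variant")
  ## codon 3 TGG -> TGA at 109
  expect_identical(eff(109L, "G", "A", ml$plus), "stop_gained")
  ## stop codon TAA -> CAA at 110
  expect_identical(eff(110L, "T", "C", ml$plus), "stop_lost")
  ## start codon ATG -> ATA at 103
  expect_identical(eff(103L, "G", "A", ml$plus), "initiator_codon_variant")
  ## mirrored positions on the minus gene (complemented alleles)
  expect_identical(eff(207L, "A", "G", ml$minus), "synonymous_variant")
  expect_identical(eff(204L, "C", "T", ml$minus), "stop_gained")
  expect_identical(eff(210L, "C", "T", ml$minus), "initiator_codon_variant")
})

test_that("InDel effects classify frame and codon alignment", {
  ## 10-codon gene so inframe edits stay interior
  cds <- "ATGGCTGCAGATGAAGGCTTACATCCATAA"
  chrom <- rep("A", 200)
  chrom[51:80] <- strsplit(cds, "")[[1]]
  genome <- Biostrings::DNAStringSet(c(Z = paste(chrom, collapse = "")))
  gene <- GeneModel("g", "Z", "+", cds = rbind(c(51, 80)))
  seg <- function(a, b) paste(chrom[a:b], collapse = "")
  ## 1 bp deletion in codon 5 (cds 13..15 -> delete base 63)
  del1 <- codingEffect(62L, seg(62, 63), seg(62, 62), gene, genome)
  expect_identical(del1$term, "frameshift_variant")
  ## whole-codon deletion aligned on the boundary (codon 5, bases 63..65)
  del3 <- codingEffect(62L, seg(62, 65), seg(62, 62), gene, genome)
  expect_identical(del3$term, "conservative_inframe_deletion")
  ## 3 bp deletion straddling codons 5 and 6 (bases 64..66)
  del3b <- codingEffect(63L, seg(63, 66), seg(63, 63), gene, genome)
  expect_identical(del3b$term, "disruptive_inframe_deletion")
  ## codon insertion at the 4/5 boundary (after cds base 12 = genome 62)
  ins3 <- codingEffect(62L, seg(62, 62), paste0(seg(62, 62), "AAG"),
                       gene, genome)
  expect_identical(ins3$term, "conservative_inframe_insertion")
  ins3b <- codingEffect(63L, seg(63, 63), paste0(seg(63, 63), "AAG"),
                        gene, genome)
  expect_identical(ins3b$term, "disruptive_inframe_insertion")
  ## 1 bp insertion: frameshift
  ins1 <- codingEffect(62L, seg(62, 62), paste0(seg(62, 62), "A"),
                       gene, genome)
  expect_identical(ins1$term, "frameshift_variant")
})

test_that("frameshift secondary terms track the recomputed ORF", {
  ## ATG AAA TGA: deleting one base of codon 2 shifts ...ATGA into frame,
  ## the original stop is read through later depending on tail bases.
  chrom <- strsplit(paste0(strrep("C", 50), "ATGAAATAAGGG", strrep("C", 50)),
                    "")[[1]]
  genome <- Biostrings::DNAStringSet(c(Z = paste(chrom, collapse = "")))
  gene <- GeneModel("g", "Z", "+", cds = rbind(c(51, 59)))
  ## delete cds base 4 (genome 54): mutated CDS ATGAAT AA. -> reads
  ## ATG AAT AA -> no in-frame stop in the remaining 8 bases: stop_lost
  fs <- codingEffect(53L, paste(chrom[53:54], collapse = ""),
                     chrom[53], gene, genome)
  expect_identical(fs$term, "frameshift_variant")
  expect_identical(fs$secondary, "stop_lost")
  ## deleting the G of ATG start: start_lost
  fs2 <- codingEffect(52L, paste(chrom[52:53], collapse = ""),
                      chrom[52], gene, genome)
  expect_identical(fs2$secondary, "start_lost")
})

test_that("region classification follows anchor points and precedence", {
  ml <- makeMiniLocus()
  genes <- list(ml$plus, ml$minus)
  rc <- function(pos) classifyRegion("C", pos, genes, flank = 50L)
  expect_identical(rc(105L)$region, "exonic")
  expect_identical(rc(95L)$region, "utr5")
  expect_identical(rc(115L)$region, "utr3")
  ## 30 bp 5' of the plus start codon (past the 10 bp UTR): upstream
  expect_identical(rc(71L)$region, "upstream")
  ## 30 bp 3' of the plus stop codon: downstream of plus...
  expect_identical(rc(142L)$region, "downstream")
  ## ...but 201 - 142 < 50 would also be downstream of minus; gene is plus
  expect_identical(rc(142L)$gene, "plus")
  ## beyond both flanks: intergenic
  expect_identical(rc(10L)$region, "intergenic")
  ## minus-strand anchors: upstream lies at higher coordinates
  expect_identical(rc(240L)$region, "upstream")
  expect_identical(rc(240L)$gene, "minus")
  ## exonic beats a neighbouring gene's flank
  expect_identical(rc(205L)$region, "exonic")
})

test_that("strand-mirrored genes yield identical region and effect labels", {
  toy <- makeToyGenome(seed = 31)
  ann <- annotateVariants(toy$gm, toy$genes, toy$genome)
  tt <- merge(toy$truth, ann, by = "pos")
  plus <- tt[tt$gene.x %in% "toyG01" & !is.na(tt$so_term.x), ]
  minus <- tt[tt$gene.x %in% "toyG02" & !is.na(tt$so_term.x), ]
  expect_identical(sort(plus$so_term.y), sort(minus$so_term.y))
  expect_identical(unique(plus$region.y), unique(minus$region.y))
})

test_that("transition/transversion classification and ratio", {
  ## all six unordered substitution classes: 3 ts-capable? no - A<->G and
  ## C<->T are the transitions, the other four are transversions
  ref <- c("A", "C", "G", "A", "A", "C")
  alt <- c("G", "T", "A", "C", "T", "G")
  expect_identical(isTransition(ref, alt),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  gm <- gmFromStrings(matrix("0/1", 6, 2), ref = ref, alt = as.list(alt))
  r <- tstvRatio(gm)
  expect_identical(r$n_ts + r$n_tv, 6L)
  expect_equal(r$ratio, 1.0)
  gm_tv <- gmFromStrings(matrix("0/1", 2, 2), ref = c("A", "C"),
                         alt = list("C", "G"), pos = c(10L, 20L))
  expect_equal(tstvRatio(gm_tv)$ratio, 0)
  gm_ts <- gmFromStrings(matrix("0/1", 1, 2), ref = "A", alt = list("G"))
  expect_warning(r_ts <- tstvRatio(gm_ts), "undefined")
  expect_true(is.na(r_ts$ratio))
})

test_that("gene fusion is reported for deletions bridging two genes", {
  toy <- makeToyGenome(seed = 5)
  fus_truth <- toy$truth[toy$truth$so_term %in% "bidirectional_gene_fusion", ]
  expect_identical(nrow(fus_truth), 1L)
  fus <- detectGeneFusion("ToyChr1", fus_truth$pos, fus_truth$ref,
                          fus_truth$alt, toy$genes)
  expect_identical(fus$term, "bidirectional_gene_fusion")
  expect_setequal(fus$genes, c("toyG05", "toyG06"))
  ## a deletion inside one gene is not a fusion
  cons <- toy$truth[toy$truth$so_term %in% "conservative_inframe_deletion", ][1, ]
  expect_null(detectGeneFusion("ToyChr1", cons$pos, cons$ref, cons$alt,
                               toy$genes))
  ## nor is a wholly intergenic deletion
  expect_null(detectGeneFusion("ToyChr1", 2000L, "AAAA", "A", toy$genes))
})

test_that("syn/nonsyn ratio and region summary aggregate correctly", {
  terms <- c(rep("synonymous_variant", 8), rep("missense_variant", 3),
             "stop_gained", "stop_lost")
  r <- synNonsynRatio(terms)
  expect_equal(r$ratio, 8 / 5)
  expect_warning(r0 <- synNonsynRatio(rep("synonymous_variant", 2)),
                 "undefined")
  expect_true(is.na(r0$ratio))
  rs <- regionSummary(c(rep("intergenic", 6), rep("exonic", 2)))
  expect_equal(sum(rs$pct), 100)
  expect_equal(rs$pct[rs$region == "exonic"], 25)
  expect_equal(regionSummary(rep("intergenic", 4))$pct, 100)
})
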