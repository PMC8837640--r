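#' @include GeneModel-class.R simulate.R io-annotation.R
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

.randBases <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.nonStopCodons <- function() {
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1, paste,
                      collapse = "")
  setdiff(all_codons, STOP_CODONS)
}

## random CDS: ATG, n-2 non-stop codons, TAA
.randCodons <- function(n) {
  c("ATG", sample(.nonStopCodons(), n - 2L, replace = TRUE), "TAA")
}

## Writes one gene into the chromosome character buffer and returns the
## GeneModel plus the updated buffer.  The gene is designed on the coding
## strand ([utr5][exon1]([intron][exon2])[utr3]) and reverse-complemented
## as a whole for minus-strand genes, mirroring the segment coordinates.
.placeGene <- function(chrom_chars, chrom_name, at, id, strand, codons,
                       utr_len = 60L, intron_after = NULL,
                       intron_len = 300L) {
  cds <- paste(codons, collapse = "")
  u5 <- .randBases(utr_len)
  u3 <- .randBases(utr_len)
  segs <- list()
  if (is.null(intron_after)) {
    frag <- paste0(u5, cds, u3)
    segs$cds <- rbind(c(utr_len + 1L, utr_len + nchar(cds)))
  } else {
    ex1 <- substr(cds, 1L, intron_after * 3L)
    ex2 <- substr(cds, intron_after * 3L + 1L, nchar(cds))
    intron <- .randBases(intron_len)
    frag <- paste0(u5, ex1, intron, ex2, u3)
    s1 <- utr_len + 1L
    segs$cds <- rbind(c(s1, s1 + nchar(ex1) - 1L),
                      c(s1 + nchar(ex1) + intron_len,
                        s1 + nchar(ex1) + intron_len + nchar(ex2) - 1L))
  }
  Lf <- nchar(frag)
  segs$utr5 <- if (utr_len > 0L) rbind(c(1L, utr_len)) else NULL
  segs$utr3 <- if (utr_len > 0L) rbind(c(Lf - utr_len + 1L, Lf)) else NULL
  if (strand == "-") {
    frag <- .revComp(frag)
    mirror <- function(m) {
      if (is.null(m)) return(NULL)
      out <- cbind(Lf - m[, 2] + 1L, Lf - m[, 1] + 1L)
      out[order(out[, 1]), , drop = FALSE]
    }
    segs <- lapply(segs, mirror)
  }
  to_ir <- function(m, off) {
    if (is.null(m)) IRanges() else IRanges(m[, 1] + off, m[, 2] + off)
  }
  off <- at - 1L
  gene <- GeneModel(id, chrom_name, strand,
                    cds = to_ir(segs$cds, off),
                    utr5 = to_ir(segs$utr5, off),
                    utr3 = to_ir(segs$utr3, off))
  chrom_chars[at:(at + Lf - 1L)] <- strsplit(frag, "")[[1]]
  list(gene = gene, chrom = chrom_chars, len = Lf)
}

.revComp <- function(x) as.character(reverseComplement(DNAString(x)))

#' Write gene models to a GFF3 file
#'
#' Emits gene / mRNA / CDS / UTR features (one transcript per gene) via
#' [rtracklayer::export()], in the form [readGeneModels()] reads back.
#'
#' @param genes list of [GeneModel] objects.
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(genes, path) {
  rows <- list()
  for (gene in genes) {
    gid <- geneId(gene)
    tid <- paste0(gid, ".t1")
    span <- geneSpan(gene)
    add <- function(type, s, e, id = NA_character_, parent = NA_character_,
                    phase = NA_integer_) {
      data.frame(chrom = gene@chrom, start = s, end = e, type = type,
                 strand = gene@strand, ID = id, Parent = parent,
                 phase = phase, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- add("gene", span[1], span[2], id = gid)
    rows[[length(rows) + 1L]] <- add("mRNA", span[1], span[2], id = tid,
                                     parent = gid)
    seg_rows <- function(ir, type, phases = rep(NA_integer_, length(ir))) {
      if (length(ir) == 0L) return(NULL)
      do.call(rbind, lapply(seq_along(ir), function(i) {
        add(type, start(ir)[i], end(ir)[i],
            id = paste0(tid, ".", type, i), parent = tid,
            phase = phases[i])
      }))
    }
    ## phase: bases to skip before the first complete codon, per segment
    tx_cds <- cdsSegments(gene)
    tx_phase <- (3L - cumsum(c(0L, head(width(tx_cds), -1L))) %% 3L) %% 3L
    genomic_order <- order(start(tx_cds))
    rows[[length(rows) + 1L]] <- seg_rows(gene@cds, "CDS",
                                          tx_phase[genomic_order])
    rows[[length(rows) + 1L]] <- seg_rows(gene@utr5, "five_prime_UTR")
    rows[[length(rows) + 1L]] <- seg_rows(gene@utr3, "three_prime_UTR")
  }
  df <- do.call(rbind, rows)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  mcols(gr)$type <- df$type
  mcols(gr)$ID <- df$ID
  mcols(gr)$Parent <- CharacterList(
    lapply(df$Parent, function(p) if (is.na(p)) character() else p))
  mcols(gr)$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Generate an annotated toy genome with implanted variants
#'
#' Builds a single-chromosome genome carrying seven designed genes —
#' mirrored plus/minus-strand gene pairs for SNP effects and for InDel
#' effects, an adjacent opposite-strand gene pair bridged by a short
#' deletion (the fusion case), and a two-exon gene — and implants at
#' least one variant of each coding effect class (synonymous, missense,
#' stop_gained, stop_lost, initiator_codon_variant, frameshift with a
#' designed stop_gained secondary, conservative inframe insertion and
#' deletion, bidirectional gene fusion) on both strands where the class
#' permits, plus one marker site per non-coding region class (UTRs,
#' intron, upstream, downstream, intergenic).  Every emitted variant is
#' recorded exactly once in the truth ledger with its expected labels.
#'
#' All reference CDSs translate without internal stop codons; every
#' implant is carried homozygous-alternate by every sample.
#'
#' @param seed integer seed; the output is fully deterministic given it.
#' @param n_samples number of (identical) diploid carrier samples.
#' @param out_dir optional directory; when given, `genome.fasta`,
#'   `genes.gff3`, `variants.vcf` and `truth.json` are written there.
#' @return list with `genome` ([Biostrings::DNAStringSet]), `genes`
#'   (named list of [GeneModel]), `gm` ([GenotypeMatrix]), `truth`
#'   (data.frame: chrom, pos, ref, alt, variant_class, gene, so_term,
#'   secondary, region) and, with `out_dir`, the file `paths`.
#' @export
makeToyGenome <- function(seed = 1L, n_samples = 3L, out_dir = NULL) {
  set.seed(seed)
  chrom_name <- "ToyChr1"
  gap <- 12000L
  chrom <- sample(c("A", "C", "G", "T"), 120000L, replace = TRUE)

  ## designed codon layouts -------------------------------------------------
  snp_codons <- function() {
    cod <- .randCodons(40L)
    cod[5] <- "GCT"   # synonymous target (GCT -> GCC, Ala)
    cod[10] <- "GCT"  # missense target (GCT -> GTT, Ala -> Val)
    cod[15] <- "TGG"  # stop_gained target (TGG -> TGA)
    cod
  }
  indel_codons <- function() {
    cod <- .randCodons(40L)
    cod[8] <- "ATA"   # frameshift target: deleting its first base ...
    cod[9] <- "AGC"   # ... makes codon 8 read TAA (designed stop_gained)
    cod[15] <- "GAT"  # conservative inframe deletion target
    cod
  }

  genes <- list()
  cursor <- 8000L
  place <- function(id, strand, codons, utr_len = 60L,
                    intron_after = NULL, advance = gap) {
    res <- .placeGene(chrom, chrom_name, cursor, id, strand, codons,
                      utr_len = utr_len, intron_after = intron_after)
    chrom <<- res$chrom
    genes[[id]] <<- res$gene
    cursor <<- cursor + res$len + advance
    res$gene
  }
  place("toyG01", "+", snp_codons())
  place("toyG02", "-", snp_codons())
  place("toyG03", "+", indel_codons())
  place("toyG04", "-", indel_codons())
  place("toyG05", "+", .randCodons(30L), utr_len = 0L, advance = 15L)
  place("toyG06", "-", .randCodons(30L), utr_len = 0L)
  place("toyG07", "+", .randCodons(40L), intron_after = 20L)

  ## implant helpers --------------------------------------------------------
  truth <- list()
  note <- function(pos, ref, alt, vclass, gene, term, secondary, region) {
    truth[[length(truth) + 1L]] <<- data.frame(
      chrom = chrom_name, pos = pos, ref = ref, alt = alt,
      variant_class = vclass, gene = gene, so_term = term,
      secondary = secondary, region = region, stringsAsFactors = FALSE)
  }
  at <- function(p) chrom[p]
  span <- function(a, b) paste(chrom[a:b], collapse = "")
  snp_implant <- function(gene, codon_idx, codon_off, tx_alt, term) {
    cpos <- (codon_idx - 1L) * 3L + codon_off
    g <- genomeCoord(gene, cpos)
    alt <- if (gene@strand == "-") .complementBase(tx_alt) else tx_alt
    stopifnot(at(g) != alt)
    note(g, at(g), alt, "SNP", geneId(gene), term, NA_character_, "exonic")
  }
  del_implant <- function(gene, cds_from, cds_to, term, secondary) {
    gpos <- sort(vapply(cds_from:cds_to, function(p) genomeCoord(gene, p),
                        integer(1)))
    stopifnot(all(diff(gpos) == 1L))
    anchor <- gpos[1] - 1L
    note(anchor, span(anchor, gpos[length(gpos)]), at(anchor), "InDel",
         geneId(gene), term, secondary, "exonic")
  }
  ins_implant <- function(gene, cds_after, tx_seq, term) {
    if (gene@strand == "+") {
      anchor <- genomeCoord(gene, cds_after)
      ins <- tx_seq
    } else {
      anchor <- genomeCoord(gene, cds_after + 1L)
      ins <- .revComp(tx_seq)
    }
    note(anchor, at(anchor), paste0(at(anchor), ins), "InDel",
         geneId(gene), term, NA_character_, "exonic")
  }

  for (id in c("toyG01", "toyG02")) {
    g <- genes[[id]]
    snp_implant(g, 5L, 3L, "C", "synonymous_variant")     # GCT -> GCC
    snp_implant(g, 10L, 2L, "T", "missense_variant")      # GCT -> GTT
    snp_implant(g, 15L, 3L, "A", "stop_gained")           # TGG -> TGA
    snp_implant(g, 40L, 1L, "C", "stop_lost")             # TAA -> CAA
    snp_implant(g, 1L, 3L, "A", "initiator_codon_variant")# ATG -> ATA
  }
  for (id in c("toyG03", "toyG04")) {
    g <- genes[[id]]
    del_implant(g, 22L, 22L, "frameshift_variant", "stop_gained")
    del_implant(g, 43L, 45L, "conservative_inframe_deletion", NA_character_)
    ins_implant(g, 75L, "GCA", "conservative_inframe_insertion")
  }

  ## fusion deletion: bridges toyG05 (+) and toyG06 (-) coding spans
  g5 <- genes[["toyG05"]]; g6 <- genes[["toyG06"]]
  d1 <- max(end(g5@cds)) - 4L
  d2 <- min(start(g6@cds)) + 4L
  stopifnot(d2 - d1 + 1L < MAX_INDEL_LEN)
  anchor <- d1 - 1L
  note(anchor, span(anchor, d2), at(anchor), "InDel",
       paste0(geneId(g5), "&", geneId(g6)), "bidirectional_gene_fusion",
       NA_character_, "exonic")

  ## non-coding region markers ---------------------------------------------
  region_snp <- function(pos, gene, region) {
    ref <- at(pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    note(pos, ref, alt, "SNP", gene, NA_character_, NA_character_, region)
  }
  g1 <- genes[["toyG01"]]; g7 <- genes[["toyG07"]]
  region_snp(start(g1@utr5) + 20L, "toyG01", "utr5")
  region_snp(start(g1@utr3) + 20L, "toyG01", "utr3")
  region_snp(startCodonPos(g1) - 3000L, "toyG01", "upstream")
  region_snp(stopCodonPos(g1) + 3000L, "toyG01", "downstream")
  region_snp(end(g7@cds)[1] + 150L, "toyG07", "intronic")
  region_snp(max(end(g7@cds)) + 7000L, NA_character_, "intergenic")

  truth <- do.call(rbind, truth)
  if (anyDuplicated(truth$pos)) stop("implant spec conflict: overlapping implants")
  occupied <- IRanges(truth$pos, truth$pos + nchar(truth$ref) - 1L)
  if (sum(IRanges::width(IRanges::reduce(occupied))) !=
      sum(IRanges::width(occupied))) {
    stop("implant spec conflict: overlapping implants")
  }

  genome <- DNAStringSet(setNames(paste(chrom, collapse = ""), chrom_name))
  n_var <- nrow(truth)
  gm <- GenotypeMatrix(
    chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
    alt = as.list(truth$alt),
    allele1 = matrix(1L, n_var, n_samples),
    allele2 = matrix(1L, n_var, n_samples),
    samples = paste0("toy", seq_len(n_samples)))
  truth <- truth[order(truth$pos), ]
  rownames(truth) <- NULL
  metadata(gm)$truth <- truth

  out <- list(genome = genome, genes = genes, gm = gm, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      fasta = file.path(out_dir, "genome.fasta"),
      gff3 = file.path(out_dir, "genes.gff3"),
      vcf = file.path(out_dir, "variants.vcf"),
      truth = file.path(out_dir, "truth.json"))
    writeXStringSet(genome, paths$fasta)
    writeGeneModels(genes, paths$gff3)
    writeVcfGenotypes(gm, paths$vcf)
    write_json(truth, paths$truth, na = "null")
    out$paths <- paths
  }
  out
}
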