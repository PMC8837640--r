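#' @include AllGenerics.R
NULL

#' GeneModel: a strand-aware protein-coding gene model
#'
#' One transcript per gene: ordered CDS segments plus optional 5' and 3'
#' UTR segments, all as 1-based closed genomic intervals on one
#' chromosome.  Segments are stored genomically ascending; accessors that
#' need transcription order ([cdsSegments()]) reverse them for
#' minus-strand genes.  The CDS is taken to include the stop codon.
#'
#' @slot geneId gene identifier.
#' @slot chrom chromosome id.
#' @slot strand `"+"` or `"-"`.
#' @slot cds [IRanges::IRanges] of CDS segments, genomically ascending.
#' @slot utr5,utr3 [IRanges::IRanges] of UTR segments (may be empty).
#'
#' @seealso [readGeneModels()], [codingEffect()], [classifyRegion()]
#' @export
setClass("GeneModel",
         representation(geneId = "character",
                        chrom = "character",
                        strand = "character",
                        cds = "IRanges",
                        utr5 = "IRanges",
                        utr3 = "IRanges"))

setValidity("GeneModel", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be '+' or '-'")
  if (length(object@cds) == 0L) msg <- c(msg, "gene model needs >= 1 CDS segment")
  s <- start(object@cds)
  if (is.unsorted(s)) msg <- c(msg, "CDS segments must be genomically ascending")
  ir <- IRanges::reduce(c(object@cds, object@utr5, object@utr3))
  if (sum(IRanges::width(ir)) !=
      sum(IRanges::width(c(object@cds, object@utr5, object@utr3)))) {
    msg <- c(msg, "gene segments must not overlap")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a GeneModel
#'
#' @param geneId gene identifier.
#' @param chrom chromosome id.
#' @param strand `"+"` or `"-"`.
#' @param cds [IRanges::IRanges] (or 2-column matrix of start/end) of CDS
#'   segments including the stop codon.
#' @param utr5,utr3 optional UTR segments, same form.
#' @return a [GeneModel].
#' @export
GeneModel <- function(geneId, chrom, strand, cds,
                      utr5 = IRanges(), utr3 = IRanges()) {
  as_ir <- function(x) {
    if (is.matrix(x)) x <- IRanges(x[, 1], x[, 2])
    sort(x)
  }
  new("GeneModel", geneId = geneId, chrom = chrom, strand = strand,
      cds = as_ir(cds), utr5 = as_ir(utr5), utr3 = as_ir(utr3))
}

#' @describeIn GeneModel gene identifier.
#' @param x a `GeneModel`.
#' @export
setMethod("geneId", "GeneModel", function(x) x@geneId)

#' @describeIn GeneModel CDS segments in transcription order (5' to 3' of
#'   the mRNA): genomically ascending on `+`, descending on `-`.
#' @export
setMethod("cdsSegments", "GeneModel", function(x) {
  if (x@strand == "+") x@cds else rev(x@cds)
})

#' @describeIn GeneModel genomic position of the first base of the start
#'   codon (the 5'-most CDS base in transcription order).
#' @export
setMethod("startCodonPos", "GeneModel", function(x) {
  if (x@strand == "+") min(start(x@cds)) else max(end(x@cds))
})

#' @describeIn GeneModel genomic position of the last base of the stop
#'   codon (the 3'-most CDS base in transcription order).
#' @export
setMethod("stopCodonPos", "GeneModel", function(x) {
  if (x@strand == "+") max(end(x@cds)) else min(start(x@cds))
})

#' @describeIn GeneModel `TRUE` when the spliced CDS length is a multiple
#'   of 3 (translatable model).
#' @export
setMethod("isWellFormed", "GeneModel", function(x) {
  sum(IRanges::width(x@cds)) %% 3L == 0L
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s [%s%s] %d CDS segment(s), CDS %d bp%s\n",
              object@geneId, object@chrom, object@strand,
              length(object@cds), sum(IRanges::width(object@cds)),
              if (isWellFormed(object)) "" else " (not a multiple of 3)"))
})

#' Genomic span of a gene's transcribed region
#'
#' The interval from the first to the last transcribed base (UTRs and CDS).
#' @param gene a [GeneModel].
#' @return length-2 integer vector `c(start, end)`.
#' @export
geneSpan <- function(gene) {
  segs <- c(gene@cds, gene@utr5, gene@utr3)
  c(min(start(segs)), max(end(segs)))
}

#' Spliced CDS sequence of a gene
#'
#' Concatenates the CDS segments and reverse-complements for minus-strand
#' genes, yielding the coding sequence 5' to 3' (ATG ... stop).
#'
#' @param gene a [GeneModel].
#' @param genome a named [Biostrings::DNAStringSet] of chromosome
#'   sequences.
#' @return a [Biostrings::DNAString].
#' @export
cdsSequence <- function(gene, genome) {
  chromSeq <- genome[[gene@chrom]]
  parts <- lapply(seq_along(gene@cds), function(i) {
    subseq(chromSeq, start(gene@cds)[i], end(gene@cds)[i])
  })
  s <- do.call(Biostrings::xscat, parts)
  if (gene@strand == "-") s <- reverseComplement(s)
  s
}

#' Map between genomic and spliced-CDS coordinates
#'
#' `cdsCoord` converts a genomic position inside a CDS segment to its
#' 1-based offset along the spliced CDS (transcription orientation);
#' `genomeCoord` is the inverse.  Positions outside the CDS map to `NA`.
#'
#' @param gene a [GeneModel].
#' @param pos genomic position (`cdsCoord`) or spliced-CDS offset
#'   (`genomeCoord`).
#' @return integer position, or `NA` if outside the CDS.
#' @export
cdsCoord <- function(gene, pos) {
  segs <- cdsSegments(gene)
  off <- 0L
  for (i in seq_along(segs)) {
    s <- start(segs)[i]; e <- end(segs)[i]
    if (pos >= s && pos <= e) {
      within <- if (gene@strand == "+") pos - s else e - pos
      return(off + within + 1L)
    }
    off <- off + (e - s + 1L)
  }
  NA_integer_
}

#' @rdname cdsCoord
#' @export
genomeCoord <- function(gene, pos) {
  segs <- cdsSegments(gene)
  off <- 0L
  for (i in seq_along(segs)) {
    w <- IRanges::width(segs)[i]
    if (pos <= off + w) {
      within <- pos - off - 1L
      return(if (gene@strand == "+") start(segs)[i] + within
             else end(segs)[i] - within)
    }
    off <- off + w
  }
  NA_integer_
}
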