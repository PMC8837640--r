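#' @include AllGenerics.R
NULL

#' GenotypeMatrix: diploid calls at biallelic and multi-allelic sites
#'
#' A `GenotypeMatrix` holds unphased diploid genotype calls for a panel of
#' samples at a set of variant sites, as a
#' [SummarizedExperiment::RangedSummarizedExperiment] with two integer
#' assays, `allele1` and `allele2`.  Allele index 0 is the reference
#' allele, indices 1.. refer to the alternate alleles of the site.  A
#' missing call has `NA` in both assays; calls are stored with
#' `allele1 <= allele2` so the pair is unordered.  Sites are kept sorted
#' by (chromosome, position) and carry their REF/ALT allele strings and a
#' variant class (`"SNP"` or `"InDel"`, insertions/deletions being < 50 bp)
#' as row metadata.
#'
#' Phase in the source VCF (`|` vs `/`) is read but not retained: all
#' statistics in the package (allele-count diversity, genotype-dosage
#' r-squared) are phase-free.
#'
#' @slot .. see [SummarizedExperiment::RangedSummarizedExperiment].
#'
#' @seealso [readVcfGenotypes()], [simulateGenotypes()], [siteStats()]
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

MAX_INDEL_LEN <- 50L

.classifyAlleles <- function(ref, alts) {
  lens <- nchar(c(ref, alts))
  if (all(lens == 1L)) return("SNP")
  if (max(lens) - min(lens) >= 1L) return("InDel")
  "SNP"  # e.g. MNP-free inputs; same-length alleles > 1 bp do not occur here
}

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  rr <- rowRanges(object)
  need <- c("ref", "alt", "variantClass")
  if (!all(need %in% names(mcols(rr)))) {
    return(paste("rowRanges must carry mcols:", paste(need, collapse = ", ")))
  }
  if (nrow(object) == 0L) return(TRUE)
  refs <- mcols(rr)$ref
  alts <- mcols(rr)$alt
  allele_ok <- function(a) grepl("^[ACGT]+$", a)
  if (!all(allele_ok(refs)) || !all(allele_ok(unlist(alts)))) {
    msg <- c(msg, "REF/ALT alleles must be non-empty strings over {A,C,G,T}")
  }
  if (any(start(rr) < 1L)) msg <- c(msg, "positions must be >= 1")
  key <- paste(as.character(seqnames(rr)), start(rr),
               refs, vapply(alts, paste, "", collapse = ","))
  if (anyDuplicated(key)) msg <- c(msg, "duplicate (chrom, pos, ref, alt) site")
  o <- order(as.character(seqnames(rr)), start(rr))
  if (!identical(o, seq_along(rr))) msg <- c(msg, "sites must be sorted by (chrom, pos)")
  a1 <- assay(object, "allele1")
  a2 <- assay(object, "allele2")
  if (!identical(is.na(a1), is.na(a2))) {
    msg <- c(msg, "allele1/allele2 must be NA together (missing call)")
  }
  if (any(a1 > a2, na.rm = TRUE)) {
    msg <- c(msg, "calls must be stored with allele1 <= allele2")
  }
  n_alt <- lengths(alts)
  bad_idx <- a2 > rep(n_alt, ncol(object)) | a1 < 0L
  if (any(bad_idx, na.rm = TRUE)) {
    msg <- c(msg, "allele indices must lie in 0..n_alt for their site")
  }
  lendiff <- vapply(seq_along(refs), function(i) {
    lens <- nchar(c(refs[i], alts[[i]]))
    max(lens) - min(lens)
  }, integer(1))
  if (any(lendiff >= MAX_INDEL_LEN)) {
    msg <- c(msg, sprintf("allele length difference must be < %d bp", MAX_INDEL_LEN))
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a GenotypeMatrix
#'
#' Assembles a [GenotypeMatrix] from parallel site vectors and two
#' sites-by-samples integer allele matrices.  Sites are sorted by
#' (chromosome, position); calls are canonicalised to
#' `allele1 <= allele2`; the variant class (SNP vs InDel) is derived from
#' the allele lengths.
#'
#' @param chrom character vector of chromosome ids, one per site.
#' @param pos integer vector of 1-based reference positions.
#' @param ref character vector of reference alleles.
#' @param alt list (or [IRanges::CharacterList]) of alternate-allele
#'   character vectors, one element per site.
#' @param allele1,allele2 integer matrices (sites x samples) of allele
#'   indices; `NA` in both marks a missing call.
#' @param samples character vector of sample ids (column names).
#'
#' @return a [GenotypeMatrix].
#' @examples
#' gm <- GenotypeMatrix(
#'   chrom = c("Chr01", "Chr01"), pos = c(100L, 250L),
#'   ref = c("A", "T"), alt = list("G", "C"),
#'   allele1 = matrix(0L, 2, 3), allele2 = matrix(c(0L, 1L), 2, 3),
#'   samples = c("s1", "s2", "s3"))
#' nSites(gm)
#' @export
GenotypeMatrix <- function(chrom, pos, ref, alt, allele1, allele2, samples) {
  stopifnot(length(chrom) == length(pos), length(ref) == length(pos),
            length(alt) == length(pos),
            nrow(allele1) == length(pos), nrow(allele2) == length(pos),
            ncol(allele1) == length(samples))
  alt <- as.list(alt)
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]; ref <- ref[o]; alt <- alt[o]
  allele1 <- allele1[o, , drop = FALSE]
  allele2 <- allele2[o, , drop = FALSE]
  swap <- !is.na(allele1) & !is.na(allele2) & allele1 > allele2
  if (any(swap)) {
    tmp <- allele1[swap]
    allele1[swap] <- allele2[swap]
    allele2[swap] <- tmp
  }
  vclass <- vapply(seq_along(ref),
                   function(i) .classifyAlleles(ref[i], alt[[i]]),
                   character(1))
  rr <- GRanges(chrom, IRanges(as.integer(pos), width = nchar(ref)))
  mcols(rr)$ref <- as.character(ref)
  mcols(rr)$alt <- CharacterList(alt)
  mcols(rr)$variantClass <- vclass
  storage.mode(allele1) <- "integer"
  storage.mode(allele2) <- "integer"
  dimnames(allele1) <- list(NULL, samples)
  dimnames(allele2) <- list(NULL, samples)
  se <- SummarizedExperiment(
    assays = SimpleList(allele1 = allele1, allele2 = allele2),
    rowRanges = rr,
    colData = DataFrame(row.names = samples))
  new("GenotypeMatrix", se)
}

#' @describeIn GenotypeMatrix number of variant sites (rows).
#' @param x a `GenotypeMatrix`.
#' @export
setMethod("nSites", "GenotypeMatrix", function(x) nrow(x))

#' @describeIn GenotypeMatrix sample ids (columns).
#' @export
setMethod("sampleNames", "GenotypeMatrix", function(x) colnames(x))

#' @describeIn GenotypeMatrix reference allele strings.
#' @export
setMethod("refAllele", "GenotypeMatrix",
          function(x) mcols(rowRanges(x))$ref)

#' @describeIn GenotypeMatrix alternate alleles as a CharacterList.
#' @export
setMethod("altAlleles", "GenotypeMatrix",
          function(x) mcols(rowRanges(x))$alt)

#' @describeIn GenotypeMatrix `"SNP"` or `"InDel"` per site.
#' @export
setMethod("variantClass", "GenotypeMatrix",
          function(x) mcols(rowRanges(x))$variantClass)

#' Chromosome and position of each site
#'
#' @param x a [GenotypeMatrix].
#' @return `siteChrom`: character vector; `sitePos`: integer vector of
#'   1-based positions.
#' @export
siteChrom <- function(x) as.character(seqnames(rowRanges(x)))

#' @rdname siteChrom
#' @export
sitePos <- function(x) start(rowRanges(x))

#' @describeIn GenotypeMatrix alternate-allele dosage matrix: the number
#'   of non-reference alleles (0, 1 or 2) in each call, `NA` when missing.
#'   For multi-allelic sites every alternate allele counts.
#' @export
setMethod("altDosage", "GenotypeMatrix", function(x) {
  a1 <- assay(x, "allele1")
  a2 <- assay(x, "allele2")
  d <- (a1 > 0L) + (a2 > 0L)
  storage.mode(d) <- "integer"
  dimnames(d) <- list(NULL, colnames(x))
  d
})

setMethod("show", "GenotypeMatrix", function(object) {
  cls <- table(variantClass(object))
  cat("GenotypeMatrix:", nrow(object), "sites x", ncol(object), "samples\n")
  cat("  chromosomes:", paste(unique(siteChrom(object)), collapse = ", "), "\n")
  cat("  classes:",
      paste(sprintf("%s=%d", names(cls), as.integer(cls)), collapse = ", "),
      "\n")
  n_missing <- sum(is.na(assay(object, "allele1")))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", n_missing,
              if (length(object)) 100 * n_missing / prod(dim(object)) else 0))
})

#' Subset a GenotypeMatrix to sites of one variant class
#'
#' @param x a [GenotypeMatrix].
#' @param class `"SNP"` or `"InDel"`.
#' @return the sites of the requested class, samples unchanged.
#' @export
variantClassSubset <- function(x, class = c("SNP", "InDel")) {
  class <- match.arg(class)
  x[variantClass(x) == class, ]
}
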