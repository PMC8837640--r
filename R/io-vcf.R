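#' @include GenotypeMatrix-class.R
NULL

## GT string -> pair of allele indices; anything with a "." is missing.
.parseGT <- function(gt) {
  parts <- strsplit(gt, "[/|]")
  a1 <- vapply(parts, function(p) {
    if (length(p) != 2L || any(p == ".")) NA_integer_ else as.integer(p[1])
  }, integer(1))
  a2 <- vapply(parts, function(p) {
    if (length(p) != 2L || any(p == ".")) NA_integer_ else as.integer(p[2])
  }, integer(1))
  list(a1 = a1, a2 = a2)
}

#' Read a VCF file into a GenotypeMatrix
#'
#' Loads all records of a VCF v4.2 file (parsed with
#' [VariantAnnotation::readVcf()]) into a [GenotypeMatrix].  Multi-allelic
#' records are retained as-is; `./.` and partial calls (e.g. `./1`) map to
#' missing; phase separators are accepted but the phase itself is
#' discarded.  Sites come out sorted by (chromosome, position).
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @return a [GenotypeMatrix].
#' @seealso [writeVcfGenotypes()] for the inverse; the two round-trip
#'   losslessly.
#' @export
readVcfGenotypes <- function(path) {
  vcf <- readVcf(path, genome = "unknown")
  if (!"GT" %in% names(geno(vcf))) {
    stop("VCF at ", path, " has no GT FORMAT field")
  }
  gt <- geno(vcf)$GT
  n_sites <- nrow(gt)
  samples <- colnames(gt)
  parsed <- .parseGT(as.vector(gt))
  a1 <- matrix(parsed$a1, nrow = n_sites)
  a2 <- matrix(parsed$a2, nrow = n_sites)
  rr <- rowRanges(vcf)
  GenotypeMatrix(
    chrom = as.character(seqnames(rr)),
    pos = start(rr),
    ref = as.character(ref(vcf)),
    alt = lapply(alt(vcf), as.character),
    allele1 = a1, allele2 = a2,
    samples = samples)
}

#' Write a GenotypeMatrix as a VCF v4.2 file
#'
#' Serialises sites, alleles and genotype calls with
#' [VariantAnnotation::writeVcf()].  Calls are written unphased
#' (`a/b` with `a <= b`; missing as `./.`), so
#' `readVcfGenotypes(writeVcfGenotypes(x))` reproduces `x` exactly.
#'
#' @param x a [GenotypeMatrix].
#' @param path output path (should end in `.vcf` for plain text).
#' @return `path`, invisibly.
#' @export
writeVcfGenotypes <- function(x, path) {
  samples <- sampleNames(x)
  a1 <- assay(x, "allele1")
  a2 <- assay(x, "allele2")
  gt <- matrix("./.", nrow = nrow(x), ncol = ncol(x),
               dimnames = list(NULL, samples))
  called <- !is.na(a1)
  gt[called] <- paste0(a1[called], "/", a2[called])
  rr <- granges(rowRanges(x))
  names(rr) <- NULL
  fx <- DataFrame(
    REF = DNAStringSet(refAllele(x)),
    ALT = DNAStringSetList(as.list(altAlleles(x))),
    QUAL = rep(NA_real_, nrow(x)),
    FILTER = rep(NA_character_, nrow(x)))
  vcf <- VCF(rowRanges = rr,
             colData = DataFrame(row.names = samples),
             fixed = fx,
             geno = SimpleList(GT = gt))
  hdr <- VCFHeader(samples = samples)
  geno(hdr) <- DataFrame(Number = "1", Type = "String",
                         Description = "Genotype", row.names = "GT")
  meta(hdr) <- IRanges::DataFrameList(
    fileformat = DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
  metadata(vcf)$header <- hdr
  writeVcf(vcf, path)
  invisible(path)
}
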