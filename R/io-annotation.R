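#' @include GeneModel-class.R
NULL

#' Read chromosome sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that truncates
#' sequence names at the first whitespace, matching VCF/GFF3 chromosome
#' ids.
#'
#' @param path FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
readGenome <- function(path) {
  genome <- readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`, `mRNA`, `CDS`, `five_prime_UTR` and `three_prime_UTR`
#' features (via [rtracklayer::import()]) and assembles one [GeneModel]
#' per gene, taking the first mRNA when several are present.  CDS
#' segments are stored genomically; [cdsSegments()] yields them in
#' transcription order.
#'
#' @param path GFF3 file.
#' @param genome optional named [Biostrings::DNAStringSet]; when given,
#'   gene models referencing chromosomes absent from it raise an error.
#' @return a named list of [GeneModel] objects.
#' @export
readGeneModels <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  get_id <- function(g) as.character(g$ID)
  get_parent <- function(g) {
    vapply(g$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
           character(1))
  }
  genes <- gr[typ == "gene"]
  mrnas <- gr[typ == "mRNA"]
  mrna_gene <- setNames(get_parent(mrnas), get_id(mrnas))
  out <- list()
  for (i in seq_along(genes)) {
    gid <- get_id(genes)[i]
    tx <- names(mrna_gene)[mrna_gene == gid][1]
    if (is.na(tx)) next
    pick <- function(type) {
      seg <- gr[typ == type & get_parent(gr) == tx]
      IRanges(start(seg), end(seg))
    }
    chrom <- as.character(seqnames(genes))[i]
    if (!is.null(genome) && !chrom %in% names(genome)) {
      stop("gene ", gid, " references unknown chromosome ", chrom)
    }
    gene <- GeneModel(
      geneId = gid, chrom = chrom,
      strand = as.character(BiocGenerics::strand(genes))[i],
      cds = pick("CDS"),
      utr5 = pick("five_prime_UTR"),
      utr3 = pick("three_prime_UTR"))
    if (!isWellFormed(gene)) {
      warning("gene ", gid, ": CDS length not a multiple of 3")
    }
    out[[gid]] <- gene
  }
  out
}

#' Default year-of-release bins for sub-populations
#'
#' The five breeding-period bins used for sub-population reporting:
#' SA 1963-1980, SB 1983-1988, SC 1991-2000, SD 2001-2010, SE 2011-2017.
#'
#' @return data.frame with columns `subpop`, `from`, `to`.
#' @export
defaultYearBins <- function() {
  data.frame(subpop = c("SA", "SB", "SC", "SD", "SE"),
             from = c(1963L, 1983L, 1991L, 2001L, 2011L),
             to = c(1980L, 1988L, 2000L, 2010L, 2017L))
}

#' Assign release years to sub-population bins
#'
#' @param years integer vector of release years.
#' @param bins data.frame as from [defaultYearBins()].
#' @return character vector of sub-population labels; years outside every
#'   bin give `NA` with a warning.
#' @export
assignSubpop <- function(years, bins = defaultYearBins()) {
  out <- rep(NA_character_, length(years))
  for (i in seq_len(nrow(bins))) {
    hit <- !is.na(years) & years >= bins$from[i] & years <= bins$to[i]
    out[hit] <- bins$subpop[i]
  }
  unassigned <- !is.na(years) & is.na(out)
  if (any(unassigned)) {
    warning(sum(unassigned), " sample(s) with release year outside all bins",
            " left unassigned")
  }
  out
}

#' Read a sample metadata table
#'
#' Expects a TSV with columns `sample` and `year` (header required) and
#' bins the years into sub-populations.
#'
#' @param path TSV file.
#' @param bins year bins, see [defaultYearBins()].
#' @return data.frame with columns `sample`, `year`, `subpop`.
#' @export
readSampleMeta <- function(path, bins = defaultYearBins()) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "year") %in% names(df))) {
    stop("sample metadata must have columns 'sample' and 'year'")
  }
  df$subpop <- assignSubpop(df$year, bins)
  df[c("sample", "year", "subpop")]
}

#' Write a sample metadata table
#'
#' @param meta data.frame with at least `sample` and `year`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeSampleMeta <- function(meta, path) {
  write.table(meta[c("sample", "year")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
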