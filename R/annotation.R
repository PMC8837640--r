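#' @include GeneModel-class.R GenotypeMatrix-class.R
NULL

REGION_LEVELS <- c("exonic", "utr5", "utr3", "intronic",
                   "upstream", "downstream", "intergenic")

HIGH_IMPACT <- c("stop_gained", "stop_lost", "initiator_codon_variant",
                 "start_lost", "frameshift_variant",
                 "bidirectional_gene_fusion", "gene_fusion")
MODERATE_IMPACT <- c("missense_variant",
                     "conservative_inframe_insertion",
                     "conservative_inframe_deletion",
                     "disruptive_inframe_insertion",
                     "disruptive_inframe_deletion")

.impactOf <- function(term) {
  if (is.na(term)) return(NA_character_)
  if (term %in% HIGH_IMPACT) "HIGH"
  else if (term %in% MODERATE_IMPACT) "MODERATE"
  else "LOW"
}

.complementBase <- function(x) chartr("ACGT", "TGCA", x)

.revComp <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}

.translateCodon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  ifelse(is.na(aa), "X", aa)
}

## trim shared suffix then shared prefix of a ref/alt pair; returns the
## minimal representation and the genomic position of its first ref base
## (for a pure insertion, the position of the base after the insertion
## point).
.trimAlleles <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Classify a variant site by genomic region
#'
#' Labels a position as exonic, UTR, intronic, upstream, downstream or
#' intergenic relative to a set of gene models.  Upstream and downstream
#' are anchored at the start and stop *codon* positions: a site within
#' `flank` bp 5' of the start codon is upstream, within `flank` bp 3' of
#' the stop codon is downstream (strand decides the direction).  When a
#' site touches features of several genes, the precedence
#' exonic > UTR > intronic > upstream/downstream > intergenic decides the
#' label, and the reported gene is the one providing it.
#'
#' @param chrom chromosome id of the site.
#' @param pos 1-based position.
#' @param genes list of [GeneModel] objects.
#' @param flank flank size in bp (default 5000).
#' @return list with `region` and `gene` (gene id or `NA`).
#' @export
classifyRegion <- function(chrom, pos, genes, flank = 5000L) {
  best <- "intergenic"
  best_gene <- NA_character_
  rank <- function(r) match(r, c("exonic", "utr5", "utr3", "intronic",
                                 "upstream", "downstream", "intergenic"))
  for (gene in genes) {
    if (gene@chrom != chrom) next
    label <- NULL
    if (any(pos >= start(gene@cds) & pos <= end(gene@cds))) {
      label <- "exonic"
    } else if (length(gene@utr5) &&
               any(pos >= start(gene@utr5) & pos <= end(gene@utr5))) {
      label <- "utr5"
    } else if (length(gene@utr3) &&
               any(pos >= start(gene@utr3) & pos <= end(gene@utr3))) {
      label <- "utr3"
    } else {
      span <- geneSpan(gene)
      if (pos >= span[1] && pos <= span[2]) {
        label <- "intronic"
      } else {
        sc <- startCodonPos(gene)
        st <- stopCodonPos(gene)
        up <- if (gene@strand == "+") {
          pos >= sc - flank && pos < sc
        } else {
          pos > sc && pos <= sc + flank
        }
        down <- if (gene@strand == "+") {
          pos > st && pos <= st + flank
        } else {
          pos >= st - flank && pos < st
        }
        if (up) label <- "upstream" else if (down) label <- "downstream"
      }
    }
    if (!is.null(label) && rank(label) < rank(best)) {
      best <- label
      best_gene <- geneId(gene)
    }
  }
  list(region = best, gene = best_gene)
}

#' Transition / transversion classification and ratio
#'
#' A substitution is a transition when it exchanges the two purines
#' (A, G) or the two pyrimidines (C, T); all other substitutions are
#' transversions.
#'
#' `isTransition` is vectorised over ref/alt pairs; `tstvRatio` counts
#' transitions and transversions over the biallelic SNPs of a matrix and
#' returns their ratio (`NA` with a warning when no transversion is
#' observed).
#'
#' @param ref,alt single-base allele strings.
#' @return `isTransition`: logical vector. `tstvRatio`: list with
#'   `n_ts`, `n_tv`, `ratio`.
#' @export
isTransition <- function(ref, alt) {
  pair <- paste0(pmin(ref, alt), pmax(ref, alt))
  pair %in% c("AG", "CT")
}

#' @rdname isTransition
#' @param x a [GenotypeMatrix].
#' @export
tstvRatio <- function(x) {
  snp <- variantClass(x) == "SNP" & lengths(altAlleles(x)) == 1L
  ref <- refAllele(x)[snp]
  alt <- unlist(altAlleles(x)[snp])
  ts <- isTransition(ref, alt)
  n_ts <- sum(ts)
  n_tv <- sum(!ts)
  ratio <- if (n_tv == 0L) {
    warning("no transversions observed; ts/tv ratio undefined")
    NA_real_
  } else n_ts / n_tv
  list(n_ts = n_ts, n_tv = n_tv, ratio = ratio)
}

## mutated spliced CDS after applying an edit given in transcription
## coordinates; edit is list(type = "del"/"ins", at, len or seq)
.mutateCds <- function(cds_seq, edit) {
  s <- as.character(cds_seq)
  if (edit$type == "del") {
    paste0(substr(s, 1L, edit$from - 1L),
           substr(s, edit$to + 1L, nchar(s)))
  } else {
    paste0(substr(s, 1L, edit$after), edit$seq,
           substr(s, edit$after + 1L, nchar(s)))
  }
}

## secondary consequence of a frameshifted CDS: start_lost when the first
## codon is no longer ATG; stop_lost when no in-frame stop remains;
## stop_gained when a stop appears before the final codon.
.frameshiftSecondary <- function(mut_cds) {
  if (substr(mut_cds, 1L, 3L) != "ATG") return("start_lost")
  n_codon <- nchar(mut_cds) %/% 3L
  codons <- substring(mut_cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- .translateCodon(codons)
  stop_at <- which(aa == "*")
  if (length(stop_at) == 0L) return("stop_lost")
  if (stop_at[1] < n_codon) return("stop_gained")
  NA_character_
}

#' Coding effect of a variant on a gene
#'
#' Classifies a variant overlapping the CDS of a gene by its
#' sequence-ontology term, using the standard nuclear genetic code and
#' treating the CDS as including the stop codon.
#'
#' SNPs are classified by comparing the reference and alternate codon
#' translations: `synonymous_variant`, `missense_variant`,
#' `stop_gained`, `stop_lost`, or `initiator_codon_variant` when the
#' change destroys the ATG of codon 1.  InDels whose length change is not
#' a multiple of 3 are `frameshift_variant`, with a secondary term
#' (`start_lost`, `stop_lost`, `stop_gained`) when the recomputed open
#' reading frame loses its start or stop or truncates early.  In-frame
#' InDels aligned on codon boundaries are
#' `conservative_inframe_insertion`/`_deletion`; those straddling a codon
#' boundary are the `disruptive_` counterparts.
#'
#' Alleles are normalised (shared suffix/prefix trimmed) before
#' classification, so equivalent VCF representations give the same call.
#'
#' @param pos 1-based genomic position of the variant (VCF convention:
#'   for InDels, the anchor base).
#' @param ref,alt reference and alternate allele strings.
#' @param gene a [GeneModel]; must be well-formed (CDS a multiple of 3).
#' @param genome named [Biostrings::DNAStringSet].
#' @return list with `term`, `secondary` (`NA` or a term), `gene`,
#'   `impact` (`HIGH`/`MODERATE`/`LOW`); `term` is `NA` when the variant
#'   does not touch the CDS.
#' @export
codingEffect <- function(pos, ref, alt, gene, genome) {
  if (!isWellFormed(gene)) {
    warning("gene ", geneId(gene), ": CDS not a multiple of 3; ",
            "annotation skipped")
    return(list(term = NA_character_, secondary = NA_character_,
                gene = geneId(gene), impact = NA_character_))
  }
  tr <- .trimAlleles(pos, ref, alt)
  cds_seq <- cdsSequence(gene, genome)
  minus <- gene@strand == "-"
  res <- function(term, secondary = NA_character_) {
    list(term = term, secondary = secondary, gene = geneId(gene),
         impact = .impactOf(term))
  }
  if (nchar(tr$ref) == 1L && nchar(tr$alt) == 1L) {
    cpos <- cdsCoord(gene, tr$pos)
    if (is.na(cpos)) return(res(NA_character_))
    ci <- (cpos - 1L) %/% 3L
    offset <- (cpos - 1L) %% 3L
    codon <- substr(as.character(cds_seq), ci * 3L + 1L, ci * 3L + 3L)
    alt_b <- if (minus) .complementBase(tr$alt) else tr$alt
    new_codon <- codon
    substr(new_codon, offset + 1L, offset + 1L) <- alt_b
    ref_aa <- .translateCodon(codon)
    alt_aa <- .translateCodon(new_codon)
    if (ci == 0L && codon == "ATG" && new_codon != "ATG") {
      return(res("initiator_codon_variant"))
    }
    if (ref_aa != "*" && alt_aa == "*") return(res("stop_gained"))
    if (ref_aa == "*" && alt_aa != "*") return(res("stop_lost"))
    if (ref_aa == alt_aa) return(res("synonymous_variant"))
    return(res("missense_variant"))
  }
  ## InDel path: pure insertion or pure deletion after normalisation
  diff <- nchar(tr$alt) - nchar(tr$ref)
  if (diff == 0L) return(res(NA_character_))  # balanced substitution: out of scope
  if (diff < 0L) {
    ## deletion of ref bases tr$pos .. tr$pos + nchar(tr$ref) - nchar(tr$alt) - 1
    ## after trimming alt is empty or 1 anchor base; normalise to empty alt
    del_start <- tr$pos + nchar(tr$alt)
    del_end <- tr$pos + nchar(tr$ref) - 1L
    cc <- vapply(del_start:del_end, function(p) cdsCoord(gene, p), integer(1))
    if (all(is.na(cc))) return(res(NA_character_))
    if (any(is.na(cc))) {
      ## deletion extends past the CDS: treat as frameshift-like truncation
      cc <- cc[!is.na(cc)]
    }
    cfrom <- min(cc); cto <- max(cc)
    n_del <- cto - cfrom + 1L
    if (n_del %% 3L != 0L) {
      mut <- .mutateCds(cds_seq, list(type = "del", from = cfrom, to = cto))
      return(res("frameshift_variant", .frameshiftSecondary(mut)))
    }
    term <- if ((cfrom - 1L) %% 3L == 0L) {
      "conservative_inframe_deletion"
    } else "disruptive_inframe_deletion"
    return(res(term))
  }
  ## insertion between tr$pos - 1 and tr$pos (alt carries the anchor base
  ## when nchar(tr$ref) == 1; after full trimming ref may be length 0)
  ins_seq <- substr(tr$alt, nchar(tr$ref) + 1L, nchar(tr$alt))
  gL <- tr$pos + nchar(tr$ref) - 1L   # last shared base, insertion after it
  gR <- gL + 1L
  c_after <- if (minus) cdsCoord(gene, gR) else cdsCoord(gene, gL)
  if (is.na(c_after)) return(res(NA_character_))
  ins_tx <- if (minus) .revComp(ins_seq) else ins_seq
  n_ins <- nchar(ins_tx)
  if (n_ins %% 3L != 0L) {
    mut <- .mutateCds(cds_seq, list(type = "ins", after = c_after,
                                    seq = ins_tx))
    return(res("frameshift_variant", .frameshiftSecondary(mut)))
  }
  term <- if (c_after %% 3L == 0L) {
    "conservative_inframe_insertion"
  } else "disruptive_inframe_insertion"
  res(term)
}

#' Detect a deletion that fuses two genes
#'
#' Reports a fusion when a deletion bridges the coding spans of two
#' different genes: it removes part of each gene's CDS extent together
#' with the gap between them.  The call is `bidirectional_gene_fusion`
#' when the two genes lie on opposite strands, `gene_fusion` otherwise.
#'
#' @param chrom chromosome of the deletion.
#' @param pos,ref,alt the VCF record of the deletion allele.
#' @param genes list of [GeneModel] objects.
#' @return list with `term`, `genes` (the two gene ids) and `impact`, or
#'   `NULL` when the deletion does not bridge two genes.
#' @export
detectGeneFusion <- function(chrom, pos, ref, alt, genes) {
  tr <- .trimAlleles(pos, ref, alt)
  if (nchar(tr$alt) >= nchar(tr$ref)) return(NULL)
  del_start <- tr$pos + nchar(tr$alt)
  del_end <- tr$pos + nchar(tr$ref) - 1L
  hit <- list()
  for (gene in genes) {
    if (gene@chrom != chrom) next
    cds_span <- c(min(start(gene@cds)), max(end(gene@cds)))
    if (del_start <= cds_span[2] && del_end >= cds_span[1]) {
      hit[[length(hit) + 1L]] <- gene
    }
  }
  if (length(hit) < 2L) return(NULL)
  strands <- vapply(hit, function(g) g@strand, character(1))
  term <- if (length(unique(strands)) > 1L) {
    "bidirectional_gene_fusion"
  } else "gene_fusion"
  list(term = term,
       genes = vapply(hit, geneId, character(1)),
       impact = "HIGH")
}

#' Annotate all variants of a genotype matrix
#'
#' Driver that combines [classifyRegion()], [codingEffect()] and
#' [detectGeneFusion()] over every site.  Coding effects are called for
#' the first alternate allele of exonic variants; a deletion bridging two
#' genes is reported as a fusion instead of a per-gene effect.
#'
#' @param x a [GenotypeMatrix].
#' @param genes list of [GeneModel] objects.
#' @param genome named [Biostrings::DNAStringSet].
#' @param flank upstream/downstream flank in bp (default 5000).
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `variant_class`, `region`, `gene`, `so_term`, `secondary`, `impact`.
#' @export
annotateVariants <- function(x, genes, genome, flank = 5000L) {
  n <- nSites(x)
  chrom <- siteChrom(x)
  pos <- sitePos(x)
  ref <- refAllele(x)
  alt1 <- vapply(as.list(altAlleles(x)), `[`, character(1), 1L)
  vclass <- variantClass(x)
  region <- character(n); gene_id <- character(n)
  term <- rep(NA_character_, n); secondary <- rep(NA_character_, n)
  impact <- rep(NA_character_, n)
  gene_by_id <- setNames(genes, vapply(genes, geneId, character(1)))
  for (i in seq_len(n)) {
    rc <- classifyRegion(chrom[i], pos[i], genes, flank)
    region[i] <- rc$region
    gene_id[i] <- rc$gene
    if (vclass[i] == "InDel") {
      fus <- detectGeneFusion(chrom[i], pos[i], ref[i], alt1[i], genes)
      if (!is.null(fus)) {
        term[i] <- fus$term
        gene_id[i] <- paste(fus$genes, collapse = "&")
        impact[i] <- fus$impact
        next
      }
    }
    if (rc$region == "exonic" && !is.na(rc$gene)) {
      eff <- codingEffect(pos[i], ref[i], alt1[i],
                          gene_by_id[[rc$gene]], genome)
      term[i] <- eff$term
      secondary[i] <- eff$secondary
      impact[i] <- eff$impact
    }
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt1,
             variant_class = vclass, region = region, gene = gene_id,
             so_term = term, secondary = secondary, impact = impact,
             stringsAsFactors = FALSE)
}

#' Region percentage summary
#'
#' @param regions character vector of region labels (e.g. the `region`
#'   column of [annotateVariants()]).
#' @return data.frame with columns `region`, `n`, `pct`; percentages sum
#'   to 100 up to rounding.
#' @export
regionSummary <- function(regions) {
  tab <- table(factor(regions, levels = REGION_LEVELS))
  tab <- tab[tab > 0L]
  data.frame(region = names(tab), n = as.integer(tab),
             pct = 100 * as.integer(tab) / length(regions),
             row.names = NULL)
}

#' Synonymous / non-synonymous ratio
#'
#' Ratio of synonymous SNP effect calls to non-synonymous ones
#' (missense, stop_gained, stop_lost, initiator_codon_variant /
#' start_lost).
#'
#' @param terms character vector of sequence-ontology terms.
#' @return list with `n_syn`, `n_nonsyn`, `ratio` (`NA` with a warning
#'   when no non-synonymous call is present).
#' @export
synNonsynRatio <- function(terms) {
  nonsyn_terms <- c("missense_variant", "stop_gained", "stop_lost",
                    "initiator_codon_variant", "start_lost")
  n_syn <- sum(terms == "synonymous_variant", na.rm = TRUE)
  n_nonsyn <- sum(terms %in% nonsyn_terms, na.rm = TRUE)
  ratio <- if (n_nonsyn == 0L) {
    warning("no non-synonymous calls; syn/nonsyn ratio undefined")
    NA_real_
  } else n_syn / n_nonsyn
  list(n_syn = n_syn, n_nonsyn = n_nonsyn, ratio = ratio)
}
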