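#' @include popdiv-package.R
NULL

#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))

#' @export
setGeneric("altAlleles", function(x) standardGeneric("altAlleles"))

#' @export
setGeneric("variantClass", function(x) standardGeneric("variantClass"))

#' @export
setGeneric("altDosage", function(x) standardGeneric("altDosage"))

#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @export
setGeneric("cdsSegments", function(x) standardGeneric("cdsSegments"))

#' @export
setGeneric("startCodonPos", function(x) standardGeneric("startCodonPos"))

#' @export
setGeneric("stopCodonPos", function(x) standardGeneric("stopCodonPos"))

#' @export
setGeneric("isWellFormed", function(x) standardGeneric("isWellFormed"))

#' @export
setGeneric("halfDecayDistance", function(x, ...) {
  standardGeneric("halfDecayDistance")
})
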