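## Accessor generics for the package's S4 classes.

#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @export
setGeneric("nPhenotypes", function(x) standardGeneric("nPhenotypes"))
#' @export
setGeneric("effectSize", function(x) standardGeneric("effectSize"))
#' @export
setGeneric("traitCorrelation", function(x) standardGeneric("traitCorrelation"))
#' @export
setGeneric("distFamily", function(x) standardGeneric("distFamily"))
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))
#' @export
setGeneric("randomSeed", function(x) standardGeneric("randomSeed"))

#' @export
setGeneric("assocMethod", function(x) standardGeneric("assocMethod"))
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @export
setGeneric("perTraitP", function(x) standardGeneric("perTraitP"))
#' @export
setGeneric("nUsed", function(x) standardGeneric("nUsed"))

#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))
#' @export
setGeneric("powerValue", function(x) standardGeneric("powerValue"))
#' @export
setGeneric("mcSE", function(x) standardGeneric("mcSE"))

#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @export
setGeneric("rankings", function(x) standardGeneric("rankings"))
#' @export
setGeneric("topSNPs", function(x, ...) standardGeneric("topSNPs"))
#' @export
setGeneric("meanTraitCorrelation",
           function(x) standardGeneric("meanTraitCorrelation"))
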