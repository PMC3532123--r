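#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats cor dhyper median quantile rbeta rbinom rnbinom rnorm
#'   runif setNames var
#' @importFrom utils read.delim write.table
NULL

#' @rdname sbScore
#' @export
setGeneric("sbScore", function(x, ...) standardGeneric("sbScore"))

#' @rdname gatkSbScore
#' @export
setGeneric("gatkSbScore", function(x, ...) standardGeneric("gatkSbScore"))

#' @rdname fisherScore
#' @export
setGeneric("fisherScore", function(x, ...) standardGeneric("fisherScore"))

#' @rdname strandBiasScores
#' @export
setGeneric("strandBiasScores", function(x, ...)
  standardGeneric("strandBiasScores"))

#' @rdname strandGenotypes
#' @export
setGeneric("strandGenotypes", function(x, ...)
  standardGeneric("strandGenotypes"))

#' @rdname hasGenotypeConflict
#' @export
setGeneric("hasGenotypeConflict", function(x, ...)
  standardGeneric("hasGenotypeConflict"))

#' @rdname titvRatio
#' @export
setGeneric("titvRatio", function(x, ...) standardGeneric("titvRatio"))

#' @rdname StrandCounts
#' @export
setGeneric("strandCounts", function(x, ...) standardGeneric("strandCounts"))
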