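#' Accessor generics
#'
#' Generics for the core data classes: FPKM assay, design factors and the
#' native-environment label of a [PopExpressionSet]; gene identifiers,
#' transcript lengths and SNP counts of a [SNPSet]; and per-gene phasing
#' results of a [DiplotypeSet].
#'
#' @param x An object of the appropriate class.
#' @param ... Passed to methods.
#' @return See the method documentation for each class.
#' @name popExpVar-generics
NULL

#' @rdname popExpVar-generics
#' @export
setGeneric("fpkm", function(x, ...) standardGeneric("fpkm"))

#' @rdname popExpVar-generics
#' @export
setGeneric("popFactor", function(x, ...) standardGeneric("popFactor"))

#' @rdname popExpVar-generics
#' @export
setGeneric("envFactor", function(x, ...) standardGeneric("envFactor"))

#' @rdname popExpVar-generics
#' @export
setGeneric("individualId", function(x, ...) standardGeneric("individualId"))

#' @rdname popExpVar-generics
#' @export
setGeneric("nativeEnv", function(x, ...) standardGeneric("nativeEnv"))

#' @rdname popExpVar-generics
#' @export
setGeneric("newEnv", function(x, ...) standardGeneric("newEnv"))

#' @rdname popExpVar-generics
#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))

#' @rdname popExpVar-generics
#' @export
setGeneric("geneLengths", function(x, ...) standardGeneric("geneLengths"))

#' @rdname popExpVar-generics
#' @export
setGeneric("nSnps", function(x, ...) standardGeneric("nSnps"))

#' @rdname popExpVar-generics
#' @export
setGeneric("snpGenotypes", function(x, gene, ...) standardGeneric("snpGenotypes"))

#' @rdname popExpVar-generics
#' @export
setGeneric("snpPositions", function(x, gene, ...) standardGeneric("snpPositions"))

#' @rdname popExpVar-generics
#' @export
setGeneric("snpQuality", function(x, gene, ...) standardGeneric("snpQuality"))

#' @rdname popExpVar-generics
#' @export
setGeneric("assignments", function(x, ...) standardGeneric("assignments"))

#' @rdname popExpVar-generics
#' @export
setGeneric("hapFreqs", function(x, ...) standardGeneric("hapFreqs"))
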