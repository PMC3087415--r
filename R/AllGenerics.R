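#' @name accessors
#' @title Accessors for GenomeRecord and GenomePartition
#' @description Slot accessors: `recordId()`, `organismName()`,
#'   `genomeSeq()`, `features()`, `isCircularGenome()` for
#'   [GenomeRecord-class]; `orthologPairs()`, `uniqueLoci()` for
#'   [GenomePartition-class]; `truthOrthologs()`, `truthEvents()` for
#'   [TruthTable-class].
#' @param x object.
#' @param genome `"A"` or `"B"` (for `uniqueLoci`).
#' @return the slot content.
NULL

#' @rdname accessors
#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))
#' @rdname accessors
#' @export
setMethod("recordId", "GenomeRecord", function(x) x@recordId)

#' @rdname accessors
#' @export
setGeneric("organismName", function(x) standardGeneric("organismName"))
#' @rdname accessors
#' @export
setMethod("organismName", "GenomeRecord", function(x) x@organism)

#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setMethod("genomeSeq", "GenomeRecord", function(x) x@seq)

#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname accessors
#' @export
setMethod("features", "GenomeRecord", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("isCircularGenome", function(x) standardGeneric("isCircularGenome"))
#' @rdname accessors
#' @export
setMethod("isCircularGenome", "GenomeRecord", function(x) x@circular)

#' @rdname accessors
#' @export
setGeneric("orthologPairs", function(x) standardGeneric("orthologPairs"))
#' @rdname accessors
#' @export
setMethod("orthologPairs", "GenomePartition", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("uniqueLoci", function(x, genome = c("A", "B"))
  standardGeneric("uniqueLoci"))
#' @rdname accessors
#' @export
setMethod("uniqueLoci", "GenomePartition", function(x, genome = c("A", "B")) {
  if (match.arg(genome) == "A") x@uniqueA else x@uniqueB
})

#' @rdname accessors
#' @export
setGeneric("truthOrthologs", function(x) standardGeneric("truthOrthologs"))
#' @rdname accessors
#' @export
setMethod("truthOrthologs", "TruthTable", function(x) x@orthologMap)

#' @rdname accessors
#' @export
setGeneric("truthEvents", function(x) standardGeneric("truthEvents"))
#' @rdname accessors
#' @export
setMethod("truthEvents", "TruthTable", function(x) x@events)
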