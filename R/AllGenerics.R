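#' Accessors for GenomeAnnotation
#'
#' `genes()`, `operons()`, `promoterBoxes()`, `repliconTable()` and
#' `genomeSequences()` extract the corresponding slots; `promoterBoxes<-`
#' replaces the box annotation (re-validating the object).
#'
#' @param x A [GenomeAnnotation-class].
#' @param value Replacement promoter-box `GRanges`.
#' @return The slot content; `GRanges` for `genes`/`promoterBoxes`,
#'   `data.frame` for `operons`/`repliconTable`, `DNAStringSet` for
#'   `genomeSequences`.
#' @name annotation-accessors
NULL

#' @rdname annotation-accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname annotation-accessors
#' @export
setGeneric("operons", function(x) standardGeneric("operons"))

#' @rdname annotation-accessors
#' @export
setGeneric("promoterBoxes", function(x) standardGeneric("promoterBoxes"))

#' @rdname annotation-accessors
#' @export
setGeneric("promoterBoxes<-", function(x, value) standardGeneric("promoterBoxes<-"))

#' @rdname annotation-accessors
#' @export
setGeneric("repliconTable", function(x) standardGeneric("repliconTable"))

#' @rdname annotation-accessors
#' @export
setGeneric("genomeSequences", function(x) standardGeneric("genomeSequences"))

#' @rdname annotation-accessors
setMethod("genes", "GenomeAnnotation", function(x) x@genes)

#' @rdname annotation-accessors
setMethod("operons", "GenomeAnnotation", function(x) x@operons)

#' @rdname annotation-accessors
setMethod("promoterBoxes", "GenomeAnnotation", function(x) x@boxes)

#' @rdname annotation-accessors
setMethod("promoterBoxes<-", "GenomeAnnotation", function(x, value) {
  sl <- stats::setNames(x@replicons$length, x@replicons$id)
  GenomeInfoDb::seqlevels(value) <- x@replicons$id
  GenomeInfoDb::seqlengths(value) <- sl
  x@boxes <- value
  methods::validObject(x)
  x
})

#' @rdname annotation-accessors
setMethod("repliconTable", "GenomeAnnotation", function(x) x@replicons)

#' @rdname annotation-accessors
setMethod("genomeSequences", "GenomeAnnotation", function(x) x@sequences)
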