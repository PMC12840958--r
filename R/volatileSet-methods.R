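#' @include AllClasses.R
NULL

#' Accessors for VolatileSet
#'
#' \code{contents} returns the numeric content matrix (ug/kg; n.d. cells 0),
#' \code{detectionMask} the logical detected/censored mask,
#' \code{cultivars} the per-sample cultivar labels, \code{replicateIndex}
#' the per-sample replicate numbers and \code{compoundIDs} the compound
#' identifiers.
#'
#' @param x a [VolatileSet-class].
#' @return A matrix, character vector or integer vector as described.
#' @name VolatileSet-accessors
#' @aliases contents detectionMask cultivars replicateIndex compoundIDs
NULL

#' @rdname VolatileSet-accessors
#' @export
setGeneric("contents", function(x) standardGeneric("contents"))

#' @rdname VolatileSet-accessors
#' @export
setMethod("contents", "VolatileSet", function(x)
  SummarizedExperiment::assay(x, "content"))

#' @rdname VolatileSet-accessors
#' @export
setGeneric("detectionMask", function(x) standardGeneric("detectionMask"))

#' @rdname VolatileSet-accessors
#' @export
setMethod("detectionMask", "VolatileSet", function(x)
  SummarizedExperiment::assay(x, "detected"))

#' @rdname VolatileSet-accessors
#' @export
setGeneric("cultivars", function(x) standardGeneric("cultivars"))

#' @rdname VolatileSet-accessors
#' @export
setMethod("cultivars", "VolatileSet", function(x)
  as.character(SummarizedExperiment::colData(x)$cultivar))

#' @rdname VolatileSet-accessors
#' @export
setGeneric("replicateIndex", function(x) standardGeneric("replicateIndex"))

#' @rdname VolatileSet-accessors
#' @export
setMethod("replicateIndex", "VolatileSet", function(x)
  as.integer(SummarizedExperiment::colData(x)$replicate))

#' @rdname VolatileSet-accessors
#' @export
setGeneric("compoundIDs", function(x) standardGeneric("compoundIDs"))

#' @rdname VolatileSet-accessors
#' @export
setMethod("compoundIDs", "VolatileSet", function(x) rownames(x))

setMethod("show", "VolatileSet", function(object) {
  cv <- unique(cultivars(object))
  cat(sprintf(
    "VolatileSet: %d compounds x %d samples (%d cultivar%s)\n",
    nrow(object), ncol(object), length(cv), if (length(cv) == 1) "" else "s"))
  nd <- sum(!detectionMask(object))
  cat(sprintf("  n.d. (censored) cells: %d of %d\n",
              nd, length(detectionMask(object))))
  cat("  cultivars:", paste(cv, collapse = ", "), "\n")
  invisible(NULL)
})
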