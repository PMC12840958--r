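#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

#' Recognised volatile chemical classes
#'
#' The eight chemical classes a compound metadata table may use.
#'
#' @export
CHEM_CLASSES <- c("aldehyde", "ketone", "alcohol", "ester",
                  "hydrocarbon", "ether", "heterocyclic", "other")

#' VolatileSet: replicate-level volatile content matrix
#'
#' An S4 container for a compound x sample matrix of GC-MS volatile contents
#' (ug/kg), extending [SummarizedExperiment::SummarizedExperiment].  Two
#' assays are carried: \code{content}, the numeric contents with
#' not-detected (n.d.) cells valued 0, and \code{detected}, a logical mask
#' that is \code{FALSE} exactly where a cell was censored below the
#' detection capability.  n.d. is thereby kept distinguishable from a small
#' measured value: contents enter downstream arithmetic as 0 (the convention
#' of the shipped reference table, where n.d. compounds contribute nothing)
#' while the censoring mask is preserved.
#'
#' Column metadata must contain \code{cultivar} and \code{replicate};
#' each (cultivar, replicate) pair identifies one sample and must be unique.
#' Row names are compound identifiers.
#'
#' @seealso [readContentMatrix()], [cultivarMeans()]
#' @export
setClass("VolatileSet", contains = "SummarizedExperiment")

setValidity("VolatileSet", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("content", "detected") %in% an))
    return("assays must include 'content' and 'detected'")
  ct <- SummarizedExperiment::assay(object, "content")
  dt <- SummarizedExperiment::assay(object, "detected")
  if (!is.numeric(ct) || anyNA(ct))
    msg <- c(msg, "'content' must be numeric without NA")
  else if (any(ct < 0))
    msg <- c(msg, "contents must be non-negative")
  if (!is.logical(dt) || anyNA(dt))
    msg <- c(msg, "'detected' must be logical without NA")
  else if (is.numeric(ct) && !anyNA(ct) && any(ct[!dt] != 0))
    msg <- c(msg, "censored (n.d.) cells must carry content 0")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("cultivar", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'cultivar' and 'replicate'")
  else if (anyDuplicated(paste(cd$cultivar, cd$replicate, sep = "\r")))
    msg <- c(msg, "(cultivar, replicate) pairs must be unique")
  if (is.null(rownames(object)))
    msg <- c(msg, "compound identifiers (rownames) are required")
  else if (anyDuplicated(rownames(object)))
    msg <- c(msg, "compound identifiers must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a VolatileSet
#'
#' @param content numeric compound x sample matrix (ug/kg); censored cells 0.
#' @param detected logical matrix of the same shape, \code{FALSE} where a
#'   cell is n.d.  Defaults to \code{content > 0}.
#' @param cultivar character/factor of cultivar labels, one per column.
#' @param replicate integer replicate index within cultivar, one per column.
#' @param compoundData optional \code{DataFrame}/data.frame of compound
#'   metadata (rows matched to \code{rownames(content)}).
#'
#' @return A [VolatileSet-class] object.
#' @export
VolatileSet <- function(content, detected = content > 0,
                        cultivar, replicate,
                        compoundData = NULL) {
  content <- as.matrix(content)
  storage.mode(content) <- "double"
  detected <- as.matrix(detected)
  cd <- S4Vectors::DataFrame(cultivar = as.character(cultivar),
                             replicate = as.integer(replicate))
  rownames(cd) <- paste(cd$cultivar, cd$replicate, sep = "_")
  colnames(content) <- rownames(cd)
  dimnames(detected) <- dimnames(content)
  rd <- if (is.null(compoundData)) {
    S4Vectors::DataFrame(row.names = rownames(content))
  } else {
    S4Vectors::DataFrame(compoundData[rownames(content), , drop = FALSE])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(content = content, detected = detected),
    colData = cd, rowData = rd)
  new("VolatileSet", se)
}

#' OPLSFit: a fitted two-class OPLS-DA model
#'
#' Holds the single predictive component (scores \code{t}, weights \code{w},
#' loadings \code{p}, y-loading), zero or more orthogonal components
#' (\code{Tortho}, \code{Wortho}, \code{Portho}), the variance summaries
#' R2X/R2Y, the VIP vector, and (after [permutationTest()]) a permutation
#' p-value.  Predictive scores are orthogonal to every orthogonal score
#' column, and VIP satisfies mean(VIP^2) = 1.
#'
#' @seealso [oplsDA()], [vipScores()], [permutationTest()]
#' @export
setClass("OPLSFit", representation(
  scores = "numeric",        # predictive score t, one per sample
  weights = "numeric",       # predictive weight w (unit norm), per variable
  loadings = "numeric",      # predictive X-loading p, per variable
  yloading = "numeric",      # regression of y on t
  orthoScores = "matrix",    # samples x nOrtho
  orthoWeights = "matrix",   # variables x nOrtho
  orthoLoadings = "matrix",  # variables x nOrtho
  R2X = "numeric",
  R2Y = "numeric",
  vip = "numeric",
  nOrtho = "integer",
  y = "numeric",             # centred +/-1 class code used in the fit
  classes = "character",     # the two class labels, in code order (-1, +1)
  permutationP = "numeric"   # NA until permutationTest() is run
))

setValidity("OPLSFit", function(object) {
  msg <- character()
  p <- length(object@weights)
  if (length(object@loadings) != p || length(object@vip) != p)
    msg <- c(msg, "weights, loadings and vip must have one entry per variable")
  if (object@nOrtho > 0 && ncol(object@orthoScores) != object@nOrtho)
    msg <- c(msg, "orthoScores must have nOrtho columns")
  if (length(object@R2Y) == 1 &&
      (object@R2Y < -1e-8 || object@R2Y > 1 + 1e-8))
    msg <- c(msg, "R2Y must lie in [0, 1]")
  if (p > 0 && abs(mean(object@vip^2) - 1) > 1e-6)
    msg <- c(msg, "VIP must satisfy mean(VIP^2) = 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OPLSFit", function(object) {
  cat("OPLSFit: two-class OPLS-DA model\n")
  cat(sprintf("  samples: %d  variables: %d  orthogonal components: %d\n",
              length(object@scores), length(object@weights), object@nOrtho))
  cat(sprintf("  classes: %s (-1) vs %s (+1)\n",
              object@classes[1], object@classes[2]))
  cat(sprintf("  R2X = %.3f  R2Y = %.3f\n", object@R2X, object@R2Y))
  if (!is.na(object@permutationP))
    cat(sprintf("  permutation p = %.4g\n", object@permutationP))
  invisible(NULL)
})
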