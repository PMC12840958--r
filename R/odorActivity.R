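#' Odor activity value of a single content/threshold pair
#'
#' OAV is the ratio of a compound's content to its odor threshold in the
#' same medium (here: water), \eqn{OAV_i = C_i / OT_i}.  A compound with
#' OAV > 1 is conventionally taken to contribute perceptibly to aroma.
#'
#' @param content content(s) in ug/kg, >= 0; vectorised.
#' @param threshold odor threshold(s) in ug/kg; \code{NA} (no documented
#'   threshold) yields an \emph{undefined} OAV, returned as \code{NA} --
#'   never coerced to 0.
#' @return Dimensionless OAV(s); \code{NA} where the threshold is absent.
#' @examples
#' computeOAV(5.12, 0.07)   # 73.14...
#' computeOAV(200, 1)       # 200
#' @export
computeOAV <- function(content, threshold) {
  if (any(content < 0, na.rm = TRUE)) stop("content must be >= 0")
  if (any(threshold <= 0, na.rm = TRUE)) stop("threshold must be > 0")
  content / threshold
}

#' Compound x cultivar OAV matrix
#'
#' Divides per-cultivar mean contents by each compound's odor threshold.
#' Rows for compounds without a documented threshold are \code{NA}
#' (undefined), and are excluded from every OAV-derived screen and share.
#'
#' @param means compound x cultivar mean content matrix (ug/kg), e.g. from
#'   [cultivarMeans()]; n.d. compounds enter as 0.
#' @param records compound metadata from [readCompoundTable()]; joined on
#'   compound id (the matrix rownames).
#' @return Numeric compound x cultivar matrix with attribute
#'   \code{"defined"}: a logical vector, \code{TRUE} for thresholded
#'   compounds.
#' @examples
#' tab <- readCompoundTable(table1Path("compounds"))
#' vs  <- readContentMatrix(table1Path("contents"))
#' oav <- oavMatrix(cultivarMeans(vs), tab)
#' sum(attr(oav, "defined"))   # compounds carrying a documented threshold
#' @export
oavMatrix <- function(means, records) {
  ids <- rownames(means)
  miss <- setdiff(ids, records$compound_id)
  if (length(miss))
    stop(sprintf("compounds absent from the metadata table: %s",
                 paste(miss, collapse = ", ")))
  ot <- records[ids, "odor_threshold"]
  oav <- sweep(means, 1, ot, "/")
  dimnames(oav) <- dimnames(means)
  attr(oav, "defined") <- stats::setNames(!is.na(ot), ids)
  oav
}

.definedIDs <- function(oav) {
  d <- attr(oav, "defined")
  if (is.null(d)) d <- !apply(is.na(oav), 1, any)
  rownames(oav)[d]
}

#' Key odor-active compounds
#'
#' The compounds that were perceived at the GC-O sniffing port
#' (\code{gco_detected}) \emph{and} whose OAV exceeds 1.0 (strictly) in at
#' least one cultivar.
#'
#' @param oav OAV matrix from [oavMatrix()].
#' @param records compound metadata.
#' @return Character vector of compound ids, in matrix row order.
#' @export
keyOdorants <- function(oav, records) {
  ids <- .definedIDs(oav)
  gco <- records[ids, "gco_detected"]
  mx <- apply(oav[ids, , drop = FALSE], 1, max)
  ids[gco & mx > 1.0]
}

#' Key odorants shared by every cultivar
#'
#' The subset of [keyOdorants()] whose OAV strictly exceeds 1.0 in
#' \emph{every} cultivar.
#'
#' @inheritParams keyOdorants
#' @return Character vector of compound ids.
#' @export
sharedKeyOdorants <- function(oav, records) {
  if (ncol(oav) < 1) stop("need at least one cultivar")
  key <- keyOdorants(oav, records)
  mn <- apply(oav[key, , drop = FALSE], 1, min)
  key[mn > 1.0]
}

#' Share of total OAV contributed by a compound subset
#'
#' For one cultivar, the sum of OAVs over \code{subset} divided by the sum
#' over \emph{all} threshold-documented compounds.  Undefined (no
#' threshold) compounds are excluded from numerator and denominator alike;
#' n.d. compounds contribute 0.
#'
#' @param oav OAV matrix from [oavMatrix()].
#' @param subset character vector of compound ids (must all be defined).
#' @param cultivar cultivar label (a column of \code{oav}).
#' @return Fraction in [0, 1].
#' @export
oavShare <- function(oav, subset, cultivar) {
  def <- .definedIDs(oav)
  bad <- setdiff(subset, def)
  if (length(bad))
    stop(sprintf("subset contains non-thresholded compound(s): %s",
                 paste(bad, collapse = ", ")))
  if (!cultivar %in% colnames(oav))
    stop(sprintf("unknown cultivar '%s'", cultivar))
  tot <- sum(oav[def, cultivar])
  if (tot <= 0) stop(sprintf("total OAV of cultivar '%s' is zero", cultivar))
  sum(oav[subset, cultivar]) / tot
}

#' Range of a subset's OAV share across cultivars
#'
#' @inheritParams oavShare
#' @return Named numeric vector \code{c(min = ..., max = ...)} of the
#'   [oavShare()] values across cultivars.
#' @examples
#' tab <- readCompoundTable(table1Path("compounds"))
#' oav <- oavMatrix(cultivarMeans(readContentMatrix(table1Path("contents"))), tab)
#' # nonanal carries 29.9% to 47.2% of the total OAV depending on cultivar
#' round(100 * shareRange(oav, "F2"), 1)
#' @export
shareRange <- function(oav, subset) {
  sh <- vapply(colnames(oav), function(cv) oavShare(oav, subset, cv),
               numeric(1))
  c(min = min(sh), max = max(sh))
}

#' Write an OAV matrix as CSV
#'
#' Long form \code{compound_id,cultivar,oav,defined_flag}; undefined OAVs
#' are written as empty cells with \code{defined_flag = FALSE}.
#'
#' @param oav OAV matrix from [oavMatrix()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeOAV <- function(oav, path) {
  def <- attr(oav, "defined")
  df <- data.frame(
    compound_id = rep(rownames(oav), times = ncol(oav)),
    cultivar = rep(colnames(oav), each = nrow(oav)),
    oav = as.vector(oav),
    defined_flag = rep(unname(def), times = ncol(oav)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
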