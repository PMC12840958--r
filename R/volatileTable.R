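#' @include AllClasses.R
NULL

# shortest decimal string that reads back to exactly the same double
.fmtNum <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("-")
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

.requireCols <- function(df, cols, path) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss))
    stop(sprintf("'%s': missing required column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
}

.numOrNA <- function(x, what, path, allow_nd = FALSE) {
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  absent <- x == "-" | x == ""
  nd <- tolower(x) %in% c("n.d.", "nd", "n.d")
  if (any(nd) && !allow_nd)
    stop(sprintf("'%s': 'n.d.' is not allowed in column '%s'", path, what),
         call. = FALSE)
  rest <- !absent & !nd
  suppressWarnings(vals <- as.numeric(x[rest]))
  if (anyNA(vals))
    stop(sprintf("'%s': non-numeric value in column '%s': %s", path, what,
                 x[rest][which(is.na(vals))[1]]), call. = FALSE)
  out[rest] <- vals
  out
}

#' Read a compound metadata table
#'
#' Reads a comma-separated compound metadata file (columns
#' \code{compound_id,name,chem_class,odor_threshold,odor_desc_lit,
#' odor_desc_exp,gco_detected,ri_exp,ri_lit,id_methods}; identification
#' methods semicolon-joined; \code{-} marks an absent optional value).
#' Odor thresholds are ug/kg in water; retention indices are dimensionless
#' Kovats units.
#'
#' @param path path to the CSV file.
#' @return A data.frame with one row per compound: \code{compound_id},
#'   \code{name}, \code{chem_class} (factor over [CHEM_CLASSES]),
#'   \code{odor_threshold}, \code{odor_desc_lit}, \code{odor_desc_exp},
#'   \code{gco_detected}, \code{ri_exp}, \code{ri_lit} and the list column
#'   \code{id_methods}.  Row names are compound ids.
#' @examples
#' tab <- readCompoundTable(table1Path("compounds"))
#' nrow(tab)          # 45 volatiles
#' classCounts(tab)
#' @export
readCompoundTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  .requireCols(df, c("compound_id", "name", "chem_class", "odor_threshold",
                     "odor_desc_lit", "odor_desc_exp", "gco_detected",
                     "ri_exp", "ri_lit", "id_methods"), path)
  if (nrow(df) == 0) {
    out <- data.frame(compound_id = character(), name = character(),
                      chem_class = factor(character(), levels = CHEM_CLASSES),
                      odor_threshold = numeric(),
                      odor_desc_lit = character(),
                      odor_desc_exp = character(),
                      gco_detected = logical(),
                      ri_exp = numeric(), ri_lit = numeric(),
                      stringsAsFactors = FALSE)
    out$id_methods <- list()
    return(out)
  }
  dup <- duplicated(df$compound_id)
  if (any(dup))
    stop(sprintf("'%s': duplicate compound_id: %s", path,
                 paste(unique(df$compound_id[dup]), collapse = ", ")))
  bad <- !(df$chem_class %in% CHEM_CLASSES)
  if (any(bad))
    stop(sprintf("'%s': unknown chem_class '%s' in row %d (compound '%s')",
                 path, df$chem_class[which(bad)[1]], which(bad)[1],
                 df$compound_id[which(bad)[1]]))
  ot <- .numOrNA(df$odor_threshold, "odor_threshold", path)
  if (any(!is.na(ot) & ot <= 0))
    stop(sprintf("'%s': odor_threshold must be > 0 where present", path))
  gco <- toupper(trimws(df$gco_detected)) %in% c("TRUE", "T", "1", "YES")
  idm <- strsplit(df$id_methods, ";", fixed = TRUE)
  idm <- lapply(idm, trimws)
  badm <- !vapply(idm, function(m) all(m %in% c("MS", "RI", "STD", "O")),
                  logical(1))
  if (any(badm))
    stop(sprintf("'%s': unknown identification method in row %d",
                 path, which(badm)[1]))
  hasO <- vapply(idm, function(m) "O" %in% m, logical(1))
  if (any(gco != hasO))
    stop(sprintf(
      "'%s': gco_detected flag inconsistent with 'O' id method (row %d)",
      path, which(gco != hasO)[1]))
  out <- data.frame(
    compound_id = df$compound_id,
    name = df$name,
    chem_class = factor(df$chem_class, levels = CHEM_CLASSES),
    odor_threshold = ot,
    odor_desc_lit = ifelse(trimws(df$odor_desc_lit) == "-", NA_character_,
                           df$odor_desc_lit),
    odor_desc_exp = ifelse(trimws(df$odor_desc_exp) == "-", NA_character_,
                           df$odor_desc_exp),
    gco_detected = gco,
    ri_exp = .numOrNA(df$ri_exp, "ri_exp", path),
    ri_lit = .numOrNA(df$ri_lit, "ri_lit", path),
    stringsAsFactors = FALSE)
  out$id_methods <- idm
  rownames(out) <- out$compound_id
  out
}

#' Write a compound metadata table
#'
#' Inverse of [readCompoundTable()]; read-write-read is lossless.
#'
#' @param records data.frame as returned by [readCompoundTable()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeCompoundTable <- function(records, path) {
  df <- data.frame(
    compound_id = records$compound_id,
    name = records$name,
    chem_class = as.character(records$chem_class),
    odor_threshold = .fmtNum(records$odor_threshold),
    odor_desc_lit = ifelse(is.na(records$odor_desc_lit), "-",
                           records$odor_desc_lit),
    odor_desc_exp = ifelse(is.na(records$odor_desc_exp), "-",
                           records$odor_desc_exp),
    gco_detected = ifelse(records$gco_detected, "TRUE", "FALSE"),
    ri_exp = .fmtNum(records$ri_exp),
    ri_lit = .fmtNum(records$ri_lit),
    id_methods = vapply(records$id_methods, paste, character(1),
                        collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "-")
  invisible(path)
}

#' Read a replicate-level content matrix
#'
#' Reads volatile contents (ug/kg) in long form
#' (\code{compound_id,cultivar,replicate,content}) or wide form (first
#' column \code{compound_id}, remaining columns one per sample, named
#' either \code{<cultivar>} or \code{<cultivar>_<replicate>}).  The token
#' \code{n.d.} marks a not-detected (censored) cell; it is recorded with
#' content 0 and \code{detected = FALSE}, not treated as missing at random.
#'
#' @param path path to the CSV file.
#' @return A [VolatileSet-class].
#' @examples
#' vs <- readContentMatrix(table1Path("contents"))
#' dim(vs)   # 45 compounds x 4 single-replicate cultivar columns
#' @export
readContentMatrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  long <- all(c("compound_id", "cultivar", "replicate", "content") %in%
                colnames(df))
  if (long) {
    comp <- unique(df$compound_id)
    cult <- df$cultivar
    rep_ <- suppressWarnings(as.integer(df$replicate))
    if (anyNA(rep_)) stop(sprintf("'%s': non-integer replicate index", path))
    samp <- paste(cult, rep_, sep = "_")
    usamp <- unique(samp)
    val <- .parseContent(df$content, path)
    ct <- matrix(0, length(comp), length(usamp),
                 dimnames = list(comp, usamp))
    dt <- matrix(FALSE, length(comp), length(usamp),
                 dimnames = list(comp, usamp))
    idx <- cbind(match(df$compound_id, comp), match(samp, usamp))
    if (anyDuplicated(idx))
      stop(sprintf("'%s': duplicate (compound, cultivar, replicate) entry",
                   path))
    ct[idx] <- ifelse(val$nd, 0, val$value)
    dt[idx] <- !val$nd
    scult <- cult[match(usamp, samp)]
    srep <- rep_[match(usamp, samp)]
  } else {
    if (colnames(df)[1] != "compound_id")
      stop(sprintf(
        "'%s': expected long form columns or wide form starting 'compound_id'",
        path))
    comp <- df$compound_id
    if (anyDuplicated(comp))
      stop(sprintf("'%s': duplicate compound_id in wide form", path))
    scols <- colnames(df)[-1]
    has <- grepl("_[0-9]+$", scols)
    srep <- rep(1L, length(scols))
    srep[has] <- as.integer(sub(".*_([0-9]+)$", "\\1", scols[has]))
    scult <- scols
    scult[has] <- sub("_[0-9]+$", "", scols[has])
    ct <- matrix(0, length(comp), length(scols),
                 dimnames = list(comp, scols))
    dt <- matrix(FALSE, length(comp), length(scols),
                 dimnames = list(comp, scols))
    for (j in seq_along(scols)) {
      val <- .parseContent(df[[scols[j]]], path)
      ct[, j] <- ifelse(val$nd, 0, val$value)
      dt[, j] <- !val$nd
    }
  }
  VolatileSet(content = ct, detected = dt,
              cultivar = scult, replicate = srep)
}

.parseContent <- function(x, path) {
  x <- trimws(x)
  nd <- tolower(x) %in% c("n.d.", "nd", "n.d")
  suppressWarnings(v <- as.numeric(x))
  bad <- !nd & is.na(v)
  if (any(bad))
    stop(sprintf("'%s': non-numeric content '%s' (only 'n.d.' is allowed)",
                 path, x[which(bad)[1]]))
  if (any(v[!nd] < 0))
    stop(sprintf("'%s': negative content %s", path, v[!nd][v[!nd] < 0][1]))
  list(value = ifelse(nd, 0, v), nd = nd)
}

#' Write a content matrix in long form
#'
#' Writes \code{compound_id,cultivar,replicate,content} rows with
#' \code{n.d.} for censored cells and full-precision numbers, so that
#' write-read round trips are bit-identical.
#'
#' @param x a [VolatileSet-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeContentMatrix <- function(x, path) {
  ct <- contents(x)
  dt <- detectionMask(x)
  df <- data.frame(
    compound_id = rep(rownames(ct), times = ncol(ct)),
    cultivar = rep(cultivars(x), each = nrow(ct)),
    replicate = rep(replicateIndex(x), each = nrow(ct)),
    content = ifelse(as.vector(dt), .fmtNum(as.vector(ct)), "n.d."),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Count compounds per chemical class
#'
#' @param records compound metadata (from [readCompoundTable()]).
#' @return Named integer vector of counts over the classes present, in
#'   [CHEM_CLASSES] order; counts sum to \code{nrow(records)}.
#' @export
classCounts <- function(records) {
  tab <- table(records$chem_class)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[out > 0]
}

#' Per-cultivar mean contents
#'
#' Arithmetic mean of replicate contents per compound and cultivar, with
#' n.d. cells contributing 0.  A compound that is n.d. in every replicate
#' of a cultivar has mean 0 and is flagged absent (attribute
#' \code{"absent"}, a logical matrix), so present/absent contrasts stay
#' distinguishable from small measured values.
#'
#' @param x a [VolatileSet-class].
#' @return Numeric compound x cultivar matrix with attribute
#'   \code{"absent"}.
#' @export
cultivarMeans <- function(x) {
  cv <- cultivars(x)
  ucv <- unique(cv)
  ct <- contents(x)
  dt <- detectionMask(x)
  m <- matrix(0, nrow(ct), length(ucv), dimnames = list(rownames(ct), ucv))
  ab <- matrix(FALSE, nrow(ct), length(ucv),
               dimnames = dimnames(m))
  for (j in seq_along(ucv)) {
    cols <- which(cv == ucv[j])
    if (length(cols) == 0) stop("cultivar with zero replicates")
    m[, j] <- rowMeans(ct[, cols, drop = FALSE])
    ab[, j] <- rowSums(dt[, cols, drop = FALSE]) == 0
  }
  attr(m, "absent") <- ab
  m
}

#' Path to the packaged reference table of 45 rice volatiles
#'
#' The package ships, as plain CSV, the published reference table of 45
#' volatile compounds quantified in cooked medium-milled fragrant Simiao
#' rice from four cultivars (CV1-CV4): compound metadata (odor thresholds
#' in water, GC-O detection flags, retention indices) and the per-cultivar
#' relative contents in ug/kg.
#'
#' @param which \code{"compounds"} or \code{"contents"}.
#' @return File path to the requested fixture CSV.
#' @examples
#' tab <- readCompoundTable(table1Path("compounds"))
#' vs  <- readContentMatrix(table1Path("contents"))
#' @export
table1Path <- function(which = c("compounds", "contents")) {
  which <- match.arg(which)
  system.file("extdata", paste0("table1_", which, ".csv"),
              package = "volatilomics", mustWork = TRUE)
}
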