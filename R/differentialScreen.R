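#' Screen thresholds for discriminating volatiles
#'
#' The threshold bundle of the pairwise screen: a compound is
#' discriminating when VIP > \code{vip_min}, FC > \code{fc_hi} or
#' FC < \code{fc_lo}, and BH-adjusted q < \code{q_max} (all strict);
#' \code{oav_min} is the OAV cut used for key odor-active compounds.
#'
#' @param vip_min VIP threshold (default 1.0).
#' @param fc_hi upper fold-change threshold (default 1.2).
#' @param fc_lo lower fold-change threshold (default 0.8).
#' @param q_max FDR-adjusted q-value threshold (default 0.05).
#' @param oav_min OAV threshold (default 1.0).
#' @return List of class \code{"ScreenConfig"}.
#' @export
screenConfig <- function(vip_min = 1.0, fc_hi = 1.2, fc_lo = 0.8,
                         q_max = 0.05, oav_min = 1.0) {
  if (!(fc_lo < 1 && 1 < fc_hi)) stop("need fc_lo < 1 < fc_hi")
  if (!(q_max > 0 && q_max < 1)) stop("need 0 < q_max < 1")
  structure(list(vip_min = vip_min, fc_hi = fc_hi, fc_lo = fc_lo,
                 q_max = q_max, oav_min = oav_min),
            class = "ScreenConfig")
}

#' Welch's two-sample t-test with degenerate-input handling
#'
#' Unequal-variance t with Satterthwaite degrees of freedom, two-sided.
#' Degenerate groups are resolved explicitly rather than erroring deep in
#' the pipeline: two constant, equal groups give \code{t = 0, p = 1}; two
#' constant, different groups have undefined degrees of freedom and are
#' flagged untestable (\code{NA}s).
#'
#' @param x,y numeric replicate vectors, each of length >= 2.
#' @param varEqual pool the variances (Student's t).  Default \code{FALSE}
#'   (Welch).
#' @return List \code{(t, p, df, untestable)}.
#' @export
welchT <- function(x, y, varEqual = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                untestable = TRUE))
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, p = 1, df = NA_real_, untestable = FALSE))
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                untestable = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = varEqual)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), untestable = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values,
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)}, mapped back to
#' the input order.
#'
#' @param p p-values in [0, 1] (hard error otherwise; \code{NA} entries
#'   are passed through).
#' @return q-values, elementwise >= p.
#' @export
bhFDR <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fold change between group means
#'
#' \code{fc = mean_int / mean_ref} (cultivar of interest over reference).
#' A compound absent from the reference but present in the target is a
#' present/absent contrast: \code{+Inf}.  Absent from both: untestable,
#' \code{NaN}.
#'
#' @param mean_ref,mean_int group mean contents, >= 0; vectorised.
#' @return Fold change(s).
#' @export
foldChange <- function(mean_ref, mean_int) {
  if (any(mean_ref < 0 | mean_int < 0, na.rm = TRUE))
    stop("means must be >= 0")
  ifelse(mean_ref == 0 & mean_int == 0, NaN, mean_int / mean_ref)
}

#' Classify a compound on the volcano criteria
#'
#' \code{"up"} if q < q_max, fc > fc_hi and vip > vip_min;
#' \code{"down"} if q < q_max, fc < fc_lo and vip > vip_min;
#' otherwise \code{"not_significant"}.  All inequalities strict; an
#' \code{NA}/\code{NaN} in any input gives \code{"untestable"}.
#' \code{fc = +Inf} (present/absent) satisfies \code{fc > fc_hi}.
#'
#' @param q,fc,vip vectors of q-values, fold changes and VIP scores.
#' @param config a [screenConfig()].
#' @return Character vector of statuses.
#' @export
volcanoClassify <- function(q, fc, vip, config = screenConfig()) {
  n <- max(length(q), length(fc), length(vip))
  q <- rep_len(q, n); fc <- rep_len(fc, n); vip <- rep_len(vip, n)
  out <- rep("not_significant", n)
  out[is.na(q) | is.nan(fc) | is.na(fc) | is.na(vip)] <- "untestable"
  test <- out != "untestable"
  out[test & q < config$q_max & fc > config$fc_hi &
        vip > config$vip_min] <- "up"
  out[test & q < config$q_max & fc < config$fc_lo &
        vip > config$vip_min] <- "down"
  out
}

#' Pairwise discriminating-volatile screen
#'
#' For each compound, compares the replicates of \code{target} against
#' those of \code{ref}: two-sample t-test, BH-FDR across the testable
#' compounds of this comparison, fold change on the group means (target
#' over reference), and VIP from a two-class OPLS-DA fitted to the
#' z-scored replicate contents of the two cultivars.  Statuses follow
#' [volcanoClassify()].  A compound n.d. in every replicate of both
#' cultivars is untestable.
#'
#' The default t-test pools the variances (Student): under multiplicative
#' replicate noise the group sds scale with the group means, and with
#' triplicates the Welch-Satterthwaite degrees of freedom then collapse
#' towards 2, leaving the screen underpowered for even 2-fold effects
#' once the FDR correction is applied.  With equal group sizes the two
#' statistics coincide, only the reference distribution differs.
#' \code{varEqual = FALSE} switches to Welch for sensitivity checks.
#'
#' @param x a [VolatileSet-class] with replicate-level contents.
#' @param ref reference cultivar label.
#' @param target cultivar-of-interest label (the FC numerator).
#' @param config a [screenConfig()].
#' @param nOrtho orthogonal components for the VIP model (default 1).
#' @param varEqual pool variances in the t-test (default \code{TRUE}).
#' @return A data.frame of class \code{"DiffTable"}: per compound
#'   \code{mean_ref}, \code{mean_int}, \code{fc}, \code{log2fc},
#'   \code{t_stat}, \code{p_value}, \code{q_value}, \code{vip},
#'   \code{status}.  \code{log2fc} for present/absent compounds uses a
#'   pseudo-count of half the smallest nonzero mean in the comparison
#'   (display only; classification uses the raw fc).
#' @export
discriminatingScreen <- function(x, ref, target, config = screenConfig(),
                                 nOrtho = 1, varEqual = TRUE) {
  cv <- cultivars(x)
  for (lab in c(ref, target))
    if (!lab %in% cv) stop(sprintf("cultivar '%s' not present", lab))
  keep <- cv %in% c(ref, target)
  ct <- contents(x)[, keep, drop = FALSE]
  grp <- cv[keep]
  mref <- rowMeans(ct[, grp == ref, drop = FALSE])
  mint <- rowMeans(ct[, grp == target, drop = FALSE])
  fc <- foldChange(mref, mint)
  pseudo <- {
    nz <- c(mref, mint); nz <- nz[nz > 0]
    if (length(nz)) min(nz) / 2 else NA_real_
  }
  log2fc <- log2((mint + ifelse(mint == 0 | mref == 0, pseudo, 0)) /
                 (mref + ifelse(mint == 0 | mref == 0, pseudo, 0)))
  tt <- lapply(seq_len(nrow(ct)), function(i)
    welchT(ct[i, grp == ref], ct[i, grp == target], varEqual = varEqual))
  p <- vapply(tt, `[[`, numeric(1), "p")
  tstat <- vapply(tt, `[[`, numeric(1), "t")
  untest <- vapply(tt, `[[`, logical(1), "untestable") | is.nan(fc)
  p[untest] <- NA_real_
  tstat[untest] <- NA_real_
  q <- bhFDR(p)
  # VIP from the two-class OPLS-DA of this comparison
  fit <- oplsDA(zscoreMatrix(t(ct)), grp, nOrtho = nOrtho)
  vip <- unname(fit@vip)
  status <- volcanoClassify(q, fc, vip, config)
  status[untest] <- "untestable"
  out <- data.frame(
    compound_id = rownames(ct),
    mean_ref = mref, mean_int = mint,
    fc = fc, log2fc = log2fc,
    t_stat = tstat, p_value = p, q_value = q, vip = vip,
    status = status,
    row.names = rownames(ct), stringsAsFactors = FALSE)
  attr(out, "comparison") <- c(ref = ref, target = target)
  class(out) <- c("DiffTable", "data.frame")
  out
}

#' Discriminating compounds of a DiffTable
#'
#' @param table a \code{DiffTable} from [discriminatingScreen()].
#' @return Compound ids with status \code{"up"} or \code{"down"}.
#' @export
discriminating <- function(table) {
  table$compound_id[table$status %in% c("up", "down")]
}

#' Venn membership of discriminating compounds across comparisons
#'
#' @param tables named list of \code{DiffTable}s over the same compound
#'   universe.
#' @return List with \code{membership} (per compound, the character
#'   vector of comparisons in which it is discriminating; compounds
#'   discriminating nowhere are dropped) and \code{counts} (named region
#'   counts, names like \code{"A&B"}); region counts sum to the union
#'   size.
#' @export
vennIntersections <- function(tables) {
  if (is.null(names(tables)))
    names(tables) <- paste0("comparison", seq_along(tables))
  sets <- lapply(tables, discriminating)
  univ <- unique(unlist(sets))
  membership <- lapply(stats::setNames(univ, univ), function(id)
    names(sets)[vapply(sets, function(s) id %in% s, logical(1))])
  key <- vapply(membership, paste, character(1), collapse = "&")
  counts <- table(key)
  list(membership = membership,
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Discriminating key odor-active compounds
#'
#' The intersection of the compounds discriminating in \emph{any}
#' comparison with the key odor-active set from [keyOdorants()].
#'
#' @param tables list of \code{DiffTable}s (or a [vennIntersections()]
#'   result).
#' @param keySet character vector of key odor-active compound ids.
#' @return Character vector of compound ids, in \code{keySet} order.
#' @export
discriminatingKeyOdorants <- function(tables, keySet) {
  disc <- if (is.list(tables) && !is.null(tables$membership))
    names(tables$membership)
  else unique(unlist(lapply(tables, discriminating)))
  keySet[keySet %in% disc]
}

#' ROC curve and AUC of a single marker
#'
#' Threshold sweep over the unique marker values, higher score predicting
#' the positive class; tied scores contribute diagonal half-steps.  The
#' trapezoidal AUC equals the Mann-Whitney U statistic divided by
#' \eqn{n_1 n_2}, i.e. the probability that a random positive sample
#' scores above a random negative one (ties counting one half).
#'
#' @param scores numeric marker values, one per sample.
#' @param labels logical (or two-level) vector; \code{TRUE}/second level
#'   is the positive class.
#' @return List of class \code{"ROCCurve"}: \code{fpr}, \code{tpr}
#'   (monotone from (0,0) to (1,1)) and \code{auc}.
#' @export
rocCurve <- function(scores, labels) {
  if (is.logical(labels)) pos <- labels
  else {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2) stop("labels must contain exactly two classes")
    pos <- as.character(labels) == lv[2]
  }
  if (all(pos) || !any(pos)) stop("both label groups must be non-empty")
  n1 <- sum(pos); n2 <- sum(!pos)
  ths <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(ths, function(th) sum(scores[pos] >= th), numeric(1)) / n1)
  fpr <- c(0, vapply(ths, function(th) sum(scores[!pos] >= th), numeric(1)) / n2)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "ROCCurve")
}
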