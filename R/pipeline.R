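#' Run the full odor-activity screening analysis
#'
#' Orchestrates the whole pipeline: load (or accept) the compound
#' metadata and replicate-level contents, aggregate to cultivar means,
#' compute the OAV matrix and the key odor-active compound screens, and
#' -- when replicate-level data are available -- the pairwise
#' discriminating-volatile screens against every other cultivar, their
#' Venn intersection, the discriminating key odor-active set and
#' one-vs-rest ROC validation of the candidate markers.  With
#' single-replicate input (e.g. the packaged reference table of cultivar
#' means) the statistical stages are skipped explicitly, with a message,
#' never silently.
#'
#' @param compounds compound metadata: a path for [readCompoundTable()]
#'   or its data.frame.
#' @param contents replicate contents: a path for [readContentMatrix()],
#'   a [VolatileSet-class], or a [synthSpec()] (generated on the fly).
#' @param target the cultivar of interest (FC numerator; default
#'   \code{"CV4"}).
#' @param config a [screenConfig()].
#' @param nOrtho orthogonal OPLS-DA components per comparison.
#' @param seed integer seed for every stochastic stage.
#' @param outdir if non-NULL, writes \code{oav.csv},
#'   \code{diff_<ref>_vs_<target>.csv} and \code{summary.json} there.
#' @return The summary list (invisibly identical to what
#'   \code{summary.json} contains): compound/threshold counts, key and
#'   shared odorant sets, per-cultivar OAV totals, the dominant
#'   compound's shares, per-comparison up/down counts, the triple
#'   intersection, discriminating key odorants, and per-marker AUCs.
#' @examples
#' res <- runFullAnalysis(table1Path("compounds"), table1Path("contents"))
#' res$n_compounds      # 45
#' res$key_odorants$size  # 17
#' @export
runFullAnalysis <- function(compounds, contents, target = "CV4",
                            config = screenConfig(), nOrtho = 1,
                            seed = 1, outdir = NULL) {
  records <- if (is.character(compounds)) readCompoundTable(compounds)
             else compounds
  vs <- if (is.character(contents)) readContentMatrix(contents)
        else if (inherits(contents, "SynthSpec")) generateReplicates(contents)
        else contents
  if (!target %in% cultivars(vs))
    stop(sprintf("target cultivar '%s' not present in the data", target))
  extra <- setdiff(compoundIDs(vs), records$compound_id)
  if (length(extra))
    stop(sprintf("contents contain compounds missing from metadata: %s",
                 paste(extra, collapse = ", ")))

  means <- cultivarMeans(vs)
  oav <- oavMatrix(means, records)
  def <- .definedIDs(oav)
  key <- keyOdorants(oav, records)
  shared <- sharedKeyOdorants(oav, records)
  totals <- colSums(oav[def, , drop = FALSE])
  dominant <- def[which.max(rowSums(oav[def, , drop = FALSE]))]
  domShares <- vapply(colnames(oav), function(cvn)
    oavShare(oav, dominant, cvn), numeric(1))

  summary <- list(
    n_compounds = nrow(vs),
    n_thresholded = length(def),
    class_counts = as.list(classCounts(records)),
    key_odorants = list(size = length(key), compounds = key),
    shared_key_odorants = list(size = length(shared), compounds = shared),
    oav_totals = as.list(totals),
    dominant_compound = list(
      compound_id = dominant,
      name = records[dominant, "name"],
      shares = as.list(domShares)),
    seed = seed)

  nrepmax <- max(table(cultivars(vs)))
  if (nrepmax < 2) {
    message("single-replicate input: t-test/OPLS-DA screening stages ",
            "skipped (need >= 2 replicates per cultivar)")
    summary$screen <- NULL
  } else {
    refs <- setdiff(unique(cultivars(vs)), target)
    tables <- lapply(stats::setNames(refs, refs), function(r)
      discriminatingScreen(vs, ref = r, target = target, config = config,
                           nOrtho = nOrtho))
    names(tables) <- paste0(refs, "_vs_", target)
    venn <- vennIntersections(tables)
    inAll <- names(venn$membership)[vapply(venn$membership, length,
                                           integer(1)) == length(tables)]
    dko <- discriminatingKeyOdorants(tables, key)
    # candidate markers: discriminating key odorants elevated in the
    # target cultivar (fc > fc_hi) in every comparison
    upAll <- Reduce(intersect, lapply(tables, function(tb)
      tb$compound_id[tb$status == "up"]))
    markers <- intersect(dko, upAll)
    pos <- cultivars(vs) == target
    aucs <- vapply(markers, function(m)
      rocCurve(contents(vs)[m, ], pos)$auc, numeric(1))
    summary$screen <- list(
      target = target,
      up_down_counts = lapply(tables, function(tb)
        list(up = sum(tb$status == "up"),
             down = sum(tb$status == "down"))),
      n_discriminating_union = length(venn$membership),
      triple_intersection = list(size = length(inAll), compounds = inAll),
      discriminating_key_odorants = list(size = length(dko),
                                         compounds = dko),
      marker_auc = as.list(aucs))
    summary$.tables <- tables
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeOAV(oav, file.path(outdir, "oav.csv"))
    if (!is.null(summary$screen))
      for (nm in names(summary$.tables))
        utils::write.csv(summary$.tables[[nm]],
                         file.path(outdir, paste0("diff_", nm, ".csv")),
                         row.names = FALSE)
    out <- summary
    out$.tables <- NULL
    jsonlite::write_json(out, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(summary)
}

.sig3 <- function(x) formatC(signif(x, 3), format = "fg", big.mark = "")
.pct1 <- function(x) sprintf("%.1f%%", 100 * x)

#' Render a human-readable report from a pipeline summary
#'
#' Formats every quantity of a [runFullAnalysis()] summary following the
#' reporting conventions of the shipped reference study: contents and
#' totals to 3 significant figures, OAV shares as percentages with one
#' decimal.  No number is computed here that the summary does not
#' already contain.
#'
#' @param summary a [runFullAnalysis()] return value.
#' @return Character vector of report lines.
#' @export
renderReport <- function(summary) {
  lines <- c(
    "Odor-activity screening report",
    "==============================",
    sprintf("Volatile compounds detected: %d (%d with documented odor threshold)",
            summary$n_compounds, summary$n_thresholded),
    sprintf("Classes: %s",
            paste(sprintf("%s %d", names(summary$class_counts),
                          unlist(summary$class_counts)), collapse = ", ")),
    "",
    sprintf("Key odor-active compounds (OAV > 1.0 and GC-O detected): %d",
            summary$key_odorants$size),
    sprintf("  %s", .noneOr(summary$key_odorants$compounds)),
    sprintf("Shared by all cultivars (OAV > 1.0 everywhere): %d",
            summary$shared_key_odorants$size),
    sprintf("  %s", .noneOr(summary$shared_key_odorants$compounds)),
    "",
    "Total OAV per cultivar:",
    sprintf("  %s: %s", names(summary$oav_totals),
            vapply(summary$oav_totals, .sig3, character(1))),
    sprintf("Dominant contributor: %s (%s)",
            summary$dominant_compound$name,
            summary$dominant_compound$compound_id),
    sprintf("  share of total OAV across cultivars: %s-%s",
            .pct1(min(unlist(summary$dominant_compound$shares))),
            .pct1(max(unlist(summary$dominant_compound$shares)))))
  if (!is.null(summary$screen)) {
    sc <- summary$screen
    lines <- c(lines, "",
      sprintf("Discriminating-volatile screen (target %s):", sc$target),
      sprintf("  %s: %d up, %d down", names(sc$up_down_counts),
              vapply(sc$up_down_counts, function(x) x$up, numeric(1)),
              vapply(sc$up_down_counts, function(x) x$down, numeric(1))),
      sprintf("  discriminating in all comparisons: %s",
              .noneOr(sc$triple_intersection$compounds)),
      sprintf("  discriminating key odor-active compounds: %s",
              .noneOr(sc$discriminating_key_odorants$compounds)))
    lines <- c(lines,
      if (length(sc$marker_auc))
        sprintf("  marker AUC (%s vs rest): %s = %.3f", sc$target,
                names(sc$marker_auc), unlist(sc$marker_auc))
      else sprintf("  marker AUC (%s vs rest): none", sc$target))
  }
  lines
}

.noneOr <- function(x) if (length(x)) paste(x, collapse = ", ") else "none"
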