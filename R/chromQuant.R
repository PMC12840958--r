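#' Build an n-alkane retention ladder
#'
#' @param carbon integer carbon numbers (C5-C30), strictly increasing.
#' @param rt retention times in minutes, strictly increasing.
#' @return data.frame of class \code{"AlkaneLadder"}.
#' @export
alkaneLadder <- function(carbon, rt) {
  carbon <- as.integer(carbon)
  if (length(carbon) != length(rt))
    stop("carbon and rt must have equal length")
  if (any(carbon < 5L) || any(carbon > 30L))
    stop("carbon numbers must lie in [5, 30]")
  if (is.unsorted(carbon, strictly = TRUE))
    stop("carbon numbers must be strictly increasing")
  if (is.unsorted(rt, strictly = TRUE))
    stop("retention times must be strictly increasing")
  structure(data.frame(carbon = carbon, rt = as.numeric(rt)),
            class = c("AlkaneLadder", "data.frame"))
}

#' Read an n-alkane ladder from CSV
#'
#' Expects columns \code{carbon_number,retention_time_min}.
#'
#' @param path CSV path.
#' @return An [alkaneLadder()] data.frame.
#' @export
readAlkaneLadder <- function(path) {
  df <- utils::read.csv(path)
  .requireCols(df, c("carbon_number", "retention_time_min"), path)
  alkaneLadder(df$carbon_number, df$retention_time_min)
}

#' Kovats retention index under temperature-programmed GC
#'
#' Linear (van den Dool-Kratz) retention index for temperature-programmed
#' chromatography: for a peak at retention time \eqn{t} bracketed by the
#' alkanes \eqn{C_n} and \eqn{C_{n+1}},
#' \deqn{RI = 100 n + 100 (t - t_n) / (t_{n+1} - t_n).}
#' A retention time coinciding with an alkane's returns exactly
#' \eqn{100 n}.  No extrapolation is performed: times outside the ladder
#' are an error, not a guess.
#'
#' @param rt retention time(s) in minutes; vectorised.
#' @param ladder an [alkaneLadder()].
#' @return Numeric retention indices (dimensionless).
#' @examples
#' lad <- alkaneLadder(c(7, 8), c(7, 9))
#' kovatsRI(8, lad)    # 750
#' kovatsRI(7.5, lad)  # 725
#' @export
kovatsRI <- function(rt, ladder) {
  if (nrow(ladder) < 2) stop("ladder needs at least 2 alkanes")
  if (any(rt < ladder$rt[1] | rt > ladder$rt[nrow(ladder)]))
    stop("retention time outside the alkane ladder range (no extrapolation)")
  i <- findInterval(rt, ladder$rt, rightmost.closed = TRUE)
  n <- ladder$carbon[i]
  t0 <- ladder$rt[i]
  t1 <- ladder$rt[i + 1]
  dn <- ladder$carbon[i + 1] - n
  100 * n + 100 * dn * (rt - t0) / (t1 - t0)
}

#' Does an experimental retention index match a literature value?
#'
#' @param ri_exp experimental Kovats index.
#' @param ri_lit literature Kovats index.
#' @param tol tolerance in RI units (default 10, wide enough to cover the
#'   largest experimental-vs-literature gap in the shipped reference table).
#' @return Logical: \code{abs(ri_exp - ri_lit) <= tol}.
#' @export
riMatch <- function(ri_exp, ri_lit, tol = 10) {
  if (any(tol < 0)) stop("tol must be >= 0")
  abs(ri_exp - ri_lit) <= tol
}

#' Internal-standard spike parameters
#'
#' @param is_volume_ul spiked internal-standard volume, uL.
#' @param is_conc_ug_ml internal-standard concentration, ug/mL.
#' @param sample_mass_g analysed sample mass, g.
#' @return List of class \code{"SpikeConfig"}.  The defaults are a 10 uL
#'   spike of 8.16 ug/mL 2-methyl-3-heptanone into a 4 g sample, i.e.
#'   0.0816 ug of standard per 0.004 kg: 20.4 ug/kg per unit area ratio.
#' @export
spikeConfig <- function(is_volume_ul = 10, is_conc_ug_ml = 8.16,
                        sample_mass_g = 4) {
  if (is_volume_ul <= 0 || is_conc_ug_ml <= 0 || sample_mass_g <= 0)
    stop("all spike parameters must be > 0")
  structure(list(is_volume_ul = is_volume_ul,
                 is_conc_ug_ml = is_conc_ug_ml,
                 sample_mass_g = sample_mass_g),
            class = "SpikeConfig")
}

#' Internal-standard semi-quantification
#'
#' Converts a peak area to a relative content by the area ratio to the
#' internal-standard peak:
#' \deqn{content = (A / A_{IS}) \cdot m_{IS} / m_{sample}}
#' with the spiked standard mass \eqn{m_{IS}} computed volumetrically
#' (volume x concentration, no purity correction) and the sample mass in
#' kg, giving ug/kg.
#'
#' @param area peak area(s), arbitrary detector units, >= 0; vectorised.
#' @param is_area internal-standard peak area, same units, > 0.
#' @param spike a [spikeConfig()].
#' @return Content(s) in ug/kg.
#' @examples
#' semiQuantify(1, 1, spikeConfig())    # 20.4 ug/kg per unit area ratio
#' @export
semiQuantify <- function(area, is_area, spike = spikeConfig()) {
  if (length(is_area) != 1 || is_area <= 0)
    stop("is_area must be a single value > 0")
  if (any(area < 0)) stop("peak areas must be >= 0")
  is_mass_ug <- spike$is_volume_ul / 1000 * spike$is_conc_ug_ml
  (area / is_area) * is_mass_ug / (spike$sample_mass_g / 1000)
}
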