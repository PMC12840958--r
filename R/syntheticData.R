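#' Specification for synthetic replicate generation
#'
#' Describes the study conditions the generator emulates: cultivar-level
#' mean contents, triplicate measurement with log-normal replicate noise
#' at a given coefficient of variation, a detection limit below which a
#' draw is recorded as n.d., and optional planted fold-change effects.
#'
#' Defaults mirror the shipped reference study: triplicates (n = 3),
#' 5\% CV (small enough that fold changes beyond 1.2 are nearly always
#' significant at n = 3), and a 1.0 ug/kg detection limit, near the
#' smallest entries of the reference table.
#'
#' @param base_means compound x cultivar mean content matrix (ug/kg),
#'   e.g. [cultivarMeans()] of the packaged reference table.
#' @param cv coefficient of variation of replicate noise (fraction).
#' @param n_replicates replicates per cultivar (>= 1).
#' @param detection_limit content below which a draw is censored (ug/kg).
#' @param effects data.frame \code{(compound_id, cultivar, multiplier)}
#'   of planted effects; multipliers > 0, or exactly 0 for a knock-out.
#' @param seed master integer seed.
#' @return List of class \code{"SynthSpec"}.
#' @seealso [generateReplicates()], [plantEffect()]
#' @export
synthSpec <- function(base_means, cv = 0.05, n_replicates = 3,
                      detection_limit = 1.0,
                      effects = NULL, seed = 1) {
  if (cv < 0) stop("cv must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (is.null(effects))
    effects <- data.frame(compound_id = character(), cultivar = character(),
                          multiplier = numeric(), stringsAsFactors = FALSE)
  if (any(effects$multiplier < 0))
    stop("effect multipliers must be > 0, or exactly 0 for a knock-out")
  structure(list(base_means = as.matrix(base_means), cv = cv,
                 n_replicates = as.integer(n_replicates),
                 detection_limit = detection_limit,
                 effects = effects, seed = as.integer(seed)),
            class = "SynthSpec")
}

#' Plant a fold-change effect into a synthetic spec
#'
#' @param spec a [synthSpec()].
#' @param compound_id compound present in \code{base_means}.
#' @param cultivar cultivar present in \code{base_means}.
#' @param multiplier factor applied to the base mean (> 0, or 0 to knock
#'   the compound out of that cultivar).
#' @return The updated spec.
#' @export
plantEffect <- function(spec, compound_id, cultivar, multiplier) {
  if (!compound_id %in% rownames(spec$base_means))
    stop(sprintf("unknown compound '%s'", compound_id))
  if (!cultivar %in% colnames(spec$base_means))
    stop(sprintf("unknown cultivar '%s'", cultivar))
  if (multiplier < 0) stop("multiplier must be > 0, or exactly 0")
  spec$effects <- rbind(spec$effects,
                        data.frame(compound_id = compound_id,
                                   cultivar = cultivar,
                                   multiplier = multiplier,
                                   stringsAsFactors = FALSE))
  spec
}

# stable 31-adic string hash into [0, 2^31 - 2]; independent of R's RNG
.stableHash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483629
  h
}

#' Generate a replicate-level content matrix
#'
#' Draws \code{n_replicates} values per compound and cultivar from a
#' log-normal distribution whose \emph{arithmetic} mean equals the
#' (effect-multiplied) base mean \eqn{\mu} and whose coefficient of
#' variation is \code{cv}: \eqn{\sigma^2_{log} = \ln(1 + cv^2)},
#' \eqn{\mu_{log} = \ln\mu - \sigma^2_{log}/2}.  Draws below the
#' detection limit are recorded as n.d.; \eqn{\mu = 0} yields n.d.
#' replicates.  With \code{cv = 0} every replicate is exactly \eqn{\mu}.
#'
#' Each (compound, cultivar) cell uses its own RNG substream derived from
#' the master seed by a stable string hash, so identical seeds give
#' bit-identical output and adding a compound does not shift the draws of
#' the others.
#'
#' @param spec a [synthSpec()].
#' @param family \code{"lognormal"} (default) or \code{"gaussian"}
#'   (mean \eqn{\mu}, sd \eqn{cv\,\mu}, truncated at 0; intended for
#'   t-test calibration studies).
#' @return A [VolatileSet-class].
#' @export
generateReplicates <- function(spec, family = c("lognormal", "gaussian")) {
  family <- match.arg(family)
  bm <- spec$base_means
  for (e in seq_len(nrow(spec$effects))) {
    ef <- spec$effects[e, ]
    bm[ef$compound_id, ef$cultivar] <-
      bm[ef$compound_id, ef$cultivar] * ef$multiplier
  }
  nrep <- spec$n_replicates
  cults <- colnames(bm)
  comps <- rownames(bm)
  ct <- matrix(0, length(comps), length(cults) * nrep,
               dimnames = list(comps, NULL))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (j in seq_along(cults)) for (i in seq_along(comps)) {
    mu <- bm[i, j]
    cols <- (j - 1) * nrep + seq_len(nrep)
    if (mu <= 0) { ct[i, cols] <- 0; next }
    if (spec$cv == 0) { ct[i, cols] <- mu; next }
    set.seed((spec$seed + .stableHash(paste(comps[i], cults[j],
                                            sep = "\r"))) %% 2147483629)
    ct[i, cols] <- if (family == "lognormal") {
      sdlog <- sqrt(log(1 + spec$cv^2))
      stats::rlnorm(nrep, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
    } else {
      pmax(stats::rnorm(nrep, mean = mu, sd = spec$cv * mu), 0)
    }
  }
  dt <- ct >= spec$detection_limit & ct > 0
  ct[!dt] <- 0
  VolatileSet(content = ct, detected = dt,
              cultivar = rep(cults, each = nrep),
              replicate = rep(seq_len(nrep), times = length(cults)))
}
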