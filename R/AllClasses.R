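#' @include constants.R
NULL

#' Raw time-depth record
#'
#' A time-depth-recorder (TDR) record as deployed: sample times in seconds
#' since record start, depths in metres, plus animal metadata.  Times must be
#' strictly increasing and depths non-negative and finite.
#'
#' @slot times numeric, seconds since record start (strictly increasing).
#' @slot depths numeric, metres (>= 0, finite).
#' @slot samplingInterval numeric, nominal sampling interval in seconds
#'   (native tags record at 4 or 10 s).
#' @slot species character, one of \code{"loggerhead"}, \code{"leatherback"},
#'   \code{"green"}.
#' @slot bodyMass numeric, kg (> 0).
#' @slot id character identifier.
#' @seealso \code{\link{readTDR}}, \code{\link{regularize}}
#' @export
setClass("RawRecord",
  representation(
    times = "numeric",
    depths = "numeric",
    samplingInterval = "numeric",
    species = "character",
    bodyMass = "numeric",
    id = "character"
  )
)

setValidity("RawRecord", function(object) {
  msg <- character()
  if (length(object@times) != length(object@depths))
    msg <- c(msg, "times and depths must have equal length")
  if (length(object@times) >= 2 && any(diff(object@times) <= 0)) {
    bad <- which(diff(object@times) <= 0)[1] + 1
    msg <- c(msg, sprintf("non-monotone times at row %d", bad))
  }
  if (any(!is.finite(object@depths)))
    msg <- c(msg, "non-finite depth values")
  if (any(object@depths < 0)) {
    bad <- which(object@depths < 0)[1]
    msg <- c(msg, sprintf("negative depth at row %d", bad))
  }
  if (!(object@species %in% .SPECIES))
    msg <- c(msg, sprintf("unknown species '%s' (valid: %s)",
                          object@species, paste(.SPECIES, collapse = ", ")))
  if (!is.finite(object@bodyMass) || object@bodyMass <= 0)
    msg <- c(msg, "bodyMass must be > 0")
  if (length(msg)) msg else TRUE
})

#' Regularized 1 Hz depth series
#'
#' Depths at exactly 1 s spacing after linear interpolation of a raw record
#' and subtraction of the surface offset (2 m by default, clamped at 0 so
#' that depth 0 denotes the surface, where breathing occurs).
#'
#' @slot depths numeric, metres at 1 Hz (>= 0).
#' @slot offsetApplied numeric, metres subtracted before clamping.
#' @slot t0 numeric, time of the first sample (s).
#' @slot species,bodyMass,id animal metadata carried from the record.
#' @seealso \code{\link{regularize}}, \code{\link{segmentDives}},
#'   \code{\link{simulateGas}}
#' @export
setClass("DepthSeries",
  representation(
    depths = "numeric",
    offsetApplied = "numeric",
    t0 = "numeric",
    species = "character",
    bodyMass = "numeric",
    id = "character"
  )
)

setValidity("DepthSeries", function(object) {
  msg <- character()
  if (any(!is.finite(object@depths)) || any(object@depths < 0))
    msg <- c(msg, "depths must be finite and >= 0")
  if (!(object@species %in% .SPECIES))
    msg <- c(msg, "unknown species")
  if (!is.finite(object@bodyMass) || object@bodyMass <= 0)
    msg <- c(msg, "bodyMass must be > 0")
  if (length(msg)) msg else TRUE
})

#' Resolved model configuration for one animal
#'
#' All species physiology, body composition, circulation, metabolic and lung
#' parameters resolved to concrete numbers for one animal, plus the variant
#' label.  Built by \code{\link{turtleConfig}}; derive the six experiment
#' variants with \code{\link{makeVariant}}.
#'
#' @slot species character.
#' @slot bodyMass numeric, kg.
#' @slot variant character label (\code{"control"}, \code{"obese"},
#'   \code{"emaciated"}, \code{"surface_high"}, \code{"surface_low"},
#'   \code{"dive_high"}, \code{"dive_low"}).
#' @slot speciesParams list, per-species physiology (mass-specific TLC,
#'   O2 stores, Hb, PCV, Mb, P50, Hill coefficient).
#' @slot bodyComposition named numeric, compartment mass fractions
#'   (blood, brain, fat_bone, central, muscle; sums to 1).
#' @slot circulation list: surface mass-specific cardiac output
#'   (ml min-1 kg-1), diving fraction, surface and diving flow splits.
#' @slot metabolic list: surface metabolic rate (ml O2 min-1 kg-1) and the
#'   diving fraction.
#' @slot gas list of gas constants, see \code{\link{gasConstants}}.
#' @slot lung list lung geometry/mechanics, see \code{\link{lungGeometry}}.
#' @slot options list: Mb half-saturation tension, respiratory quotient,
#'   arterial/venous blood split.
#' @export
setClass("TurtleConfig",
  representation(
    species = "character",
    bodyMass = "numeric",
    variant = "character",
    speciesParams = "list",
    bodyComposition = "numeric",
    circulation = "list",
    metabolic = "list",
    gas = "list",
    lung = "list",
    options = "list"
  )
)

setValidity("TurtleConfig", function(object) {
  msg <- character()
  if (abs(sum(object@bodyComposition) - 1) > 1e-6)
    msg <- c(msg, "body composition fractions must sum to 1")
  for (nm in c("surfaceSplit", "diveSplit")) {
    s <- object@circulation[[nm]]
    if (abs(sum(s) - 1) > 1e-6)
      msg <- c(msg, sprintf("%s must sum to 1", nm))
    if (!identical(names(s), .COMPARTMENTS))
      msg <- c(msg, sprintf("%s must be named %s", nm,
                            paste(.COMPARTMENTS, collapse = ", ")))
  }
  df <- object@circulation$diveFraction
  if (!is.numeric(df) || df <= 0 || df > 1)
    msg <- c(msg, "diveFraction must be in (0, 1]")
  if (object@lung$dlvFraction <= 0 || object@lung$dlvFraction > 1)
    msg <- c(msg, "dlvFraction must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Simulated gas-dynamics trajectory
#'
#' Result of \code{\link{simulateGas}}: the full 1 Hz state trajectory
#' (ambient pressure, lung volumes and faveolar partial pressures, shunt,
#' arterial and mixed venous tensions, the four compartment tensions and the
#' lung + tissue gas inventories) plus flagged events and the configuration
#' and series it was produced from.
#'
#' @slot trajectory numeric matrix, one row per 1 Hz sample; see
#'   \code{\link{trajectory}} for column names.
#' @slot events list: sample indices where a tissue O2 tension or the lung
#'   gas store was floored at zero.
#' @slot config the \code{\linkS4class{TurtleConfig}} used.
#' @slot series the \code{\linkS4class{DepthSeries}} simulated.
#' @export
setClass("SimulationResult",
  representation(
    trajectory = "matrix",
    events = "list",
    config = "TurtleConfig",
    series = "DepthSeries"
  )
)

setValidity("SimulationResult", function(object) {
  if (nrow(object@trajectory) != length(object@series@depths))
    return("trajectory length must equal series length")
  TRUE
})

#' Specification of a synthetic dive bout
#'
#' Per-depth-bin dive proportions, duration and maximum-depth distributions
#' (mean and SD of truncated normals), surface-interval distribution, number
#' of dives, RNG seed and animal metadata.  Consumed by
#' \code{\link{generateBout}}; specs mirroring the published per-individual
#' dive summaries ship with the package (\code{\link{referenceBoutSpecs}}).
#'
#' @slot id character.
#' @slot species character; \code{bodyMass} numeric, kg.
#' @slot bodyMass numeric, kg.
#' @slot nDives integer, number of dives to generate.
#' @slot proportions numeric length 3 (shallow, medium, deep), percent,
#'   summing to 100 +/- 0.1.
#' @slot durationMean,durationSD numeric length 3, seconds.
#' @slot depthMean,depthSD numeric length 3, metres (maximum dive depth).
#' @slot surfaceMean,surfaceSD numeric, post-dive surface interval, seconds.
#' @slot seed integer RNG seed; fixes the output exactly.
#' @slot shape list: bottom-time fraction, ascent-pause depth (m) and
#'   duration (s).
#' @export
setClass("BoutSpec",
  representation(
    id = "character",
    species = "character",
    bodyMass = "numeric",
    nDives = "integer",
    proportions = "numeric",
    durationMean = "numeric",
    durationSD = "numeric",
    depthMean = "numeric",
    depthSD = "numeric",
    surfaceMean = "numeric",
    surfaceSD = "numeric",
    seed = "integer",
    shape = "list"
  )
)

setValidity("BoutSpec", function(object) {
  msg <- character()
  if (length(object@proportions) != 3)
    msg <- c(msg, "proportions must have length 3 (shallow, medium, deep)")
  if (abs(sum(object@proportions) - 100) > 0.1 + 1e-9)
    msg <- c(msg, "bin proportions must sum to 100 (+/- 0.1)")
  if (any(object@proportions < 0))
    msg <- c(msg, "proportions must be >= 0")
  pos <- object@proportions > 0
  if (any(object@durationMean[pos] <= 0) || any(object@depthMean[pos] <= 0))
    msg <- c(msg, "duration and depth means must be positive for occupied bins")
  if (object@nDives < 1) msg <- c(msg, "nDives must be >= 1")
  if (!(object@species %in% .SPECIES)) msg <- c(msg, "unknown species")
  if (length(msg)) msg else TRUE
})
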