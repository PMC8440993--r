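#' @include constants.R AllClasses.R
NULL

# Species physiology. TLC is mass-specific (ml per kg); the loggerhead value
# follows the allometric relation (113.6 * M^0.923) / M.  Hb is stored in
# g per ml blood (the conventional g/dl figures divided by 100); P50 in mmHg.
.speciesTable <- list(
  loggerhead = list(tlcPerKg = function(M) 113.6 * M^0.923 / M,
                    o2StoreLung = 16.4, o2StoreBlood = 7.84,
                    o2StoreMuscle = 3.93, hb = 0.088, pcv = 30,
                    mb = 2.9, p50mmHg = 25),
  leatherback = list(tlcPerKg = function(M) 64,
                     o2StoreLung = 9.25, o2StoreBlood = 13.8,
                     o2StoreMuscle = 4.50, hb = 0.156, pcv = 39,
                     mb = 4.9, p50mmHg = 40),
  green = list(tlcPerKg = function(M) 115,
               o2StoreLung = 16.6, o2StoreBlood = 8.72,
               o2StoreMuscle = 3.93, hb = 0.098, pcv = 29,
               mb = 2.9, p50mmHg = 47)
)

#' Species physiological parameters
#'
#' Resolves the per-species physiology for a given body mass: mass-specific
#' total lung capacity (allometric for the loggerhead, constant for
#' leatherback and green turtles), reference O2 stores of lung, blood and
#' muscle, hemoglobin and myoglobin concentrations, packed cell volume, P50
#' of the O2-hemoglobin dissociation curve and the Hill coefficient (2.7 for
#' all species).
#'
#' @param species one of \code{"loggerhead"}, \code{"leatherback"},
#'   \code{"green"}.
#' @param bodyMass body mass, kg (> 0).
#' @return Named list: \code{tlcPerKg} (ml kg-1), \code{o2StoreLung},
#'   \code{o2StoreBlood}, \code{o2StoreMuscle} (ml O2 kg-1), \code{hb}
#'   (g per ml blood), \code{pcv} (percent), \code{mb} (g per kg muscle),
#'   \code{p50mmHg}, \code{p50ATA}, \code{hillH}, \code{vdFraction}.
#' @examples
#' speciesParams("leatherback", 350)$tlcPerKg  # 64
#' speciesParams("loggerhead", 1)$tlcPerKg     # 113.6
#' @export
speciesParams <- function(species, bodyMass) {
  if (!(species %in% .SPECIES))
    stop("unknown species '", species, "' (valid: ",
         paste(.SPECIES, collapse = ", "), ")", call. = FALSE)
  stopifnot(is.numeric(bodyMass), bodyMass > 0)
  tab <- .speciesTable[[species]]
  list(
    species = species,
    tlcPerKg = tab$tlcPerKg(bodyMass),
    o2StoreLung = tab$o2StoreLung,
    o2StoreBlood = tab$o2StoreBlood,
    o2StoreMuscle = tab$o2StoreMuscle,
    hb = tab$hb,
    pcv = tab$pcv,
    mb = tab$mb,
    p50mmHg = tab$p50mmHg,
    p50ATA = tab$p50mmHg / 760,
    hillH = 2.7,
    vdFraction = 0.07
  )
}

# Compartment mass fractions (% body mass): blood, brain, fat/bone, central
# circulation; muscle is the residual so each row sums to exactly 100%.
.compositionTable <- list(
  control = c(blood = 7.0, brain = 0.06, fat_bone = 30, central = 9.0),
  obese = c(blood = 6, brain = 0.054, fat_bone = 40, central = 8),
  emaciated = c(blood = 8, brain = 0.066, fat_bone = 20, central = 10)
)

#' Body compartment composition
#'
#' Compartment sizes as fractions of body mass for the generic sea turtle in
#' control, obese and emaciated nutritional condition.  Muscle (which lumps
#' muscle, skin, connective tissue and all remaining organs) is computed as
#' the remainder so that the five fractions sum to exactly 1.
#'
#' @param condition \code{"control"}, \code{"obese"} or \code{"emaciated"}.
#' @return Named numeric (fractions of body mass): \code{blood},
#'   \code{brain}, \code{fat_bone}, \code{central}, \code{muscle}.
#' @examples
#' bodyComposition("control") * 100  # 7, 0.06, 30, 9, 53.94
#' @export
bodyComposition <- function(condition = c("control", "obese", "emaciated")) {
  condition <- match.arg(condition)
  pct <- .compositionTable[[condition]]
  pct <- c(pct, muscle = 100 - sum(pct))
  pct / 100
}

#' Mass-specific cardiac output at the surface
#'
#' Allometric scaling of total cardiac output from a reference measurement
#' (8.4 ml min-1 in a 1.2 kg green turtle):
#' sQtot = (Qref / Mref) * (M / Mref)^-0.25, in ml min-1 kg-1.
#'
#' @param bodyMass body mass, kg.
#' @param referenceQ reference cardiac output, ml min-1 (default 8.4).
#' @param referenceMass reference body mass, kg (default 1.2).
#' @return Mass-specific cardiac output, ml min-1 kg-1 (7.0 at the reference
#'   mass).
#' @examples
#' surfaceSqtot(1.2)             # 7
#' surfaceSqtot(19.2)            # 7 / 16^0.25 = 3.5
#' @export
surfaceSqtot <- function(bodyMass, referenceQ = 8.4, referenceMass = 1.2) {
  stopifnot(all(bodyMass > 0))
  (referenceQ / referenceMass) * (bodyMass / referenceMass)^(-0.25)
}

#' Build a resolved model configuration
#'
#' Assembles species physiology, body composition, circulation and metabolic
#' schedules and lung mechanics into a validated
#' \code{\linkS4class{TurtleConfig}}.  Defaults are the control model:
#' allometric surface cardiac output, diving cardiac output 5\% of surface,
#' surface flow split 60/34/4/2\% and diving split 92.8/5.0/2.0/0.2\%
#' (central circulation / muscle / brain / fat-bone), surface metabolic rate
#' 4.23 ml O2 min-1 kg-1 with diving metabolism 5\% of surface, diving lung
#' volume equal to total lung capacity.
#'
#' @param species one of \code{"loggerhead"}, \code{"leatherback"},
#'   \code{"green"}.
#' @param bodyMass body mass, kg.
#' @param condition body condition, \code{"control"}, \code{"obese"} or
#'   \code{"emaciated"}.
#' @param surfaceSqtotOverride if non-\code{NULL}, replaces the allometric
#'   surface sQtot (ml min-1 kg-1).
#' @param diveFraction diving cardiac output as a fraction of surface
#'   (default 0.05).
#' @param dlvFraction diving lung volume as a fraction of TLC at dive start
#'   (default 1).
#' @param surfaceMR surface mass-specific metabolic rate, ml O2 min-1 kg-1
#'   (default 4.23; set 0 to disable metabolism, e.g. for pure inert-gas
#'   kinetics runs).
#' @param diveMRFraction diving metabolic rate as a fraction of surface
#'   (default 0.05).
#' @param gas gas constants, see \code{\link{gasConstants}}.
#' @param shuntExponent,shuntBaseline,rigidAirwayFraction lung-mechanics
#'   shape parameters, see \code{\link{lungGeometry}} and
#'   \code{\link{shuntFraction}}.
#' @param mbP50mmHg myoglobin half-saturation tension, mmHg (default 3; the
#'   steep hyperbolic Mb curve releases its O2 only at low tissue PO2).
#' @param rq respiratory quotient, ml CO2 produced per ml O2 consumed
#'   (default 1).
#' @param variant variant label stored on the object (use
#'   \code{\link{makeVariant}} rather than setting this directly).
#' @return A \code{\linkS4class{TurtleConfig}}.
#' @examples
#' cfg <- turtleConfig("green", 70)
#' cfg
#' @export
turtleConfig <- function(species, bodyMass,
                         condition = "control",
                         surfaceSqtotOverride = NULL,
                         diveFraction = 0.05,
                         dlvFraction = 1,
                         surfaceMR = 4.23,
                         diveMRFraction = 0.05,
                         gas = gasConstants(),
                         shuntExponent = 12,
                         shuntBaseline = 0,
                         rigidAirwayFraction = 0.25,
                         mbP50mmHg = 3,
                         rq = 1,
                         variant = "control") {
  sp <- speciesParams(species, bodyMass)
  comp <- bodyComposition(condition)
  sq <- if (is.null(surfaceSqtotOverride)) surfaceSqtot(bodyMass)
        else as.numeric(surfaceSqtotOverride)
  circulation <- list(
    surfaceSqtot = sq,
    diveFraction = diveFraction,
    surfaceSplit = c(brain = 0.04, fat_bone = 0.02, central = 0.60,
                     muscle = 0.34),
    diveSplit = c(brain = 0.020, fat_bone = 0.002, central = 0.928,
                  muscle = 0.050)
  )
  metabolic <- list(surfaceMR = surfaceMR, diveMRFraction = diveMRFraction)
  lung <- lungGeometry(species, bodyMass, dlvFraction = dlvFraction,
                       rigidAirwayFraction = rigidAirwayFraction)
  lung$shuntExponent <- shuntExponent
  lung$shuntBaseline <- shuntBaseline
  new("TurtleConfig",
      species = species, bodyMass = as.numeric(bodyMass), variant = variant,
      speciesParams = sp, bodyComposition = comp, circulation = circulation,
      metabolic = metabolic, gas = gas, lung = lung,
      options = list(mbP50ATA = mbP50mmHg / 760, rq = rq,
                     arterialFraction = 0.33, venousFraction = 0.67,
                     condition = condition))
}

.VARIANTS <- c("control", "obese", "emaciated", "surface_high", "surface_low",
               "dive_high", "dive_low")

#' Derive an experiment variant from a control configuration
#'
#' Changes exactly one knob of the control model: body condition (obese or
#' emaciated), surface cardiac output (10 or 2.5 ml min-1 kg-1), or diving
#' cardiac output fraction (3.3\% for \code{dive_high}, 10\% for
#' \code{dive_low}).  The dive-variant labels follow the convention that
#' "high"/"low" name the direction of nitrogen risk, not of blood flow:
#' \code{dive_high} (greater supersaturation risk contrast) sets the smaller
#' fraction 0.033 and \code{dive_low} sets 0.10; the numeric fraction is
#' always stored alongside the label.
#'
#' @param base a control \code{\linkS4class{TurtleConfig}}.
#' @param variant one of \code{"control"}, \code{"obese"},
#'   \code{"emaciated"}, \code{"surface_high"}, \code{"surface_low"},
#'   \code{"dive_high"}, \code{"dive_low"}.
#' @return A \code{\linkS4class{TurtleConfig}} with the single knob changed
#'   and the variant label set.
#' @examples
#' ctl <- turtleConfig("green", 70)
#' makeVariant(ctl, "dive_high")@circulation$diveFraction  # 0.033
#' @export
makeVariant <- function(base, variant) {
  stopifnot(is(base, "TurtleConfig"))
  variant <- match.arg(variant, .VARIANTS)
  if (base@variant != "control")
    stop("variants must be derived from a control configuration ",
         "(compound variants are not supported)", call. = FALSE)
  if (variant == "control") return(base)
  cfg <- base
  cfg@variant <- variant
  if (variant %in% c("obese", "emaciated")) {
    cfg@bodyComposition <- bodyComposition(variant)
    cfg@options$condition <- variant
  } else if (variant == "surface_high") {
    cfg@circulation$surfaceSqtot <- 10
  } else if (variant == "surface_low") {
    cfg@circulation$surfaceSqtot <- 2.5
  } else if (variant == "dive_high") {
    cfg@circulation$diveFraction <- 0.033
  } else if (variant == "dive_low") {
    cfg@circulation$diveFraction <- 0.10
  }
  validObject(cfg)
  cfg
}
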