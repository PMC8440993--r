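#' @include AllClasses.R
NULL

#' Depths of a series or record
#'
#' @param x a \code{DepthSeries} or \code{RawRecord}.
#' @return Numeric vector of depths (m).
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))

#' @rdname depths
#' @export
setMethod("depths", "DepthSeries", function(x) x@depths)

#' @rdname depths
#' @export
setMethod("depths", "RawRecord", function(x) x@depths)

#' Species of an object
#' @param x an object with animal metadata.
#' @return Character scalar.
#' @export
setGeneric("species", function(x) standardGeneric("species"))

#' @rdname species
#' @export
setMethod("species", "DepthSeries", function(x) x@species)
#' @rdname species
#' @export
setMethod("species", "RawRecord", function(x) x@species)
#' @rdname species
#' @export
setMethod("species", "TurtleConfig", function(x) x@species)

#' Body mass of an object
#' @param x an object with animal metadata.
#' @return Numeric scalar, kg.
#' @export
setGeneric("bodyMass", function(x) standardGeneric("bodyMass"))

#' @rdname bodyMass
#' @export
setMethod("bodyMass", "DepthSeries", function(x) x@bodyMass)
#' @rdname bodyMass
#' @export
setMethod("bodyMass", "RawRecord", function(x) x@bodyMass)
#' @rdname bodyMass
#' @export
setMethod("bodyMass", "TurtleConfig", function(x) x@bodyMass)

#' State trajectory of a simulation
#'
#' One row per 1 Hz sample.  Columns: \code{time_s}, \code{depth_m},
#' \code{p_amb} (ATA), \code{diving} (0/1), \code{shunt}, \code{vfa_ml},
#' faveolar partial pressures \code{fav_pn2/po2/pco2}, arterial
#' \code{art_pn2/po2/pco2}, mixed venous \code{mv_pn2/po2/pco2}, the four
#' compartment tensions (\code{brain_}, \code{fat_}, \code{central_},
#' \code{muscle_} each \code{pn2/po2/pco2}, ATA) and the lung + tissue gas
#' inventories \code{inv_n2/o2/co2} (ml STPD).
#'
#' @param x a \code{SimulationResult}.
#' @return Numeric matrix.
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' @rdname trajectory
#' @export
setMethod("trajectory", "SimulationResult", function(x) x@trajectory)

#' Mixed venous nitrogen tension trace
#' @param x a \code{SimulationResult}.
#' @return Numeric vector, ATA, one value per 1 Hz sample.
#' @export
setGeneric("mixedVenousPN2", function(x) standardGeneric("mixedVenousPN2"))

#' @rdname mixedVenousPN2
#' @export
setMethod("mixedVenousPN2", "SimulationResult",
          function(x) x@trajectory[, "mv_pn2"])

#' Whole-body gas inventories
#'
#' Lung gas store plus dissolved (and, for muscle O2, myoglobin-bound)
#' tissue stores, per gas, over time.  Blood is a transit medium in this
#' model and carries no standing store.
#'
#' @param x a \code{SimulationResult}.
#' @return Matrix with columns \code{inv_n2}, \code{inv_o2}, \code{inv_co2}
#'   (ml STPD).
#' @export
setGeneric("gasInventory", function(x) standardGeneric("gasInventory"))

#' @rdname gasInventory
#' @export
setMethod("gasInventory", "SimulationResult",
          function(x) x@trajectory[, c("inv_n2", "inv_o2", "inv_co2")])

setMethod("show", "RawRecord", function(object) {
  cat(sprintf("RawRecord '%s': %d samples @ %gs, %s, %.1f kg\n",
              object@id, length(object@depths), object@samplingInterval,
              object@species, object@bodyMass))
})

setMethod("show", "DepthSeries", function(object) {
  n <- length(object@depths)
  cat(sprintf("DepthSeries '%s': %d samples @ 1 Hz (%.1f h), %s, %.1f kg\n",
              object@id, n, n / 3600, object@species, object@bodyMass))
  cat(sprintf("  offset applied: %g m; max depth %.1f m; %.1f%% submerged\n",
              object@offsetApplied, max(object@depths),
              100 * mean(object@depths > 0)))
})

setMethod("show", "TurtleConfig", function(object) {
  cat(sprintf("TurtleConfig: %s, %.1f kg, variant '%s'\n",
              object@species, object@bodyMass, object@variant))
  cat(sprintf("  sQtot surface %.2f ml/min/kg, diving fraction %.3f\n",
              object@circulation$surfaceSqtot,
              object@circulation$diveFraction))
  cat(sprintf("  TLC %.0f ml, dead space %.0f ml, DLV %.0f%% TLC\n",
              object@lung$tlcTotal, object@lung$vd0,
              100 * object@lung$dlvFraction))
  cat("  composition (% mass):",
      paste(sprintf("%s %.2f", names(object@bodyComposition),
                    100 * object@bodyComposition), collapse = ", "), "\n")
})

setMethod("show", "SimulationResult", function(object) {
  n <- nrow(object@trajectory)
  mv <- object@trajectory[, "mv_pn2"]
  cat(sprintf("SimulationResult: %d samples (%.1f h), %s '%s', variant '%s'\n",
              n, n / 3600, object@config@species, object@series@id,
              object@config@variant))
  cat(sprintf("  mixed venous PN2: %.3f-%.3f ATA; events: %d O2-floor, %d lung-floor\n",
              min(mv), max(mv), length(object@events$tissueO2Floor),
              length(object@events$lungFloor)))
})

setMethod("show", "BoutSpec", function(object) {
  cat(sprintf("BoutSpec '%s': %s, %.0f kg, %d dives, seed %d\n",
              object@id, object@species, object@bodyMass, object@nDives,
              object@seed))
  cat(sprintf("  bins (shallow/medium/deep): %.1f/%.1f/%.1f %%\n",
              object@proportions[1], object@proportions[2],
              object@proportions[3]))
})
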