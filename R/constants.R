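# Internal constants: compartment order is fixed everywhere in the package
# (and in the C++ core) as brain, fat/bone, central circulation, muscle.

.COMPARTMENTS <- c("brain", "fat_bone", "central", "muscle")
.SPECIES <- c("loggerhead", "leatherback", "green")

# Surface (breathing) blood-gas boundary conditions, ATA.  The four partial
# pressures (N2, O2, CO2, water vapor) sum to 1 ATA.
.SURFACE_TENSIONS <- c(n2 = 0.741, o2 = 0.164, co2 = 0.033)
.PH2O <- 0.062

#' Default physical gas constants
#'
#' Surface blood-gas tensions (ATA) and Ostwald solubility coefficients
#' (ml gas per ml tissue or blood per ATA) used throughout the model.  The
#' surface tensions are the breathing boundary conditions; the solubilities
#' are literature-standard values for lean tissue, fat and blood.  CO2 is
#' carried with a single effective solubility rather than a full dissociation
#' curve.  All values can be overridden through \code{\link{turtleConfig}}.
#'
#' @return Named list with elements \code{surfaceTensions} (N2/O2/CO2, ATA),
#'   \code{ph2o} (ATA), \code{betaN2Lean}, \code{betaN2Fat}, \code{betaO2},
#'   \code{betaCO2} (ml ml-1 ATA-1) and \code{hbO2Capacity} (ml O2 per g Hb).
#' @examples
#' gc <- gasConstants()
#' sum(gc$surfaceTensions) + gc$ph2o  # 1 ATA
#' @export
gasConstants <- function() {
  list(
    surfaceTensions = .SURFACE_TENSIONS,
    ph2o = .PH2O,
    betaN2Lean = 0.0144,
    betaN2Fat = 0.067,
    betaO2 = 0.0236,
    betaCO2 = 0.47,
    hbO2Capacity = 1.34
  )
}
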