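#' @include constants.R parameters.R
NULL

#' Ambient pressure at depth
#'
#' Hydrostatic convention: 1 ATA at the surface plus 1 ATA per 10 m of
#' seawater.
#'
#' @param depth depth, m (>= 0).  Vectorized.
#' @return Ambient pressure, ATA.
#' @examples
#' ambientPressure(c(0, 90, 184))  # 1, 10, 19.4
#' @export
ambientPressure <- function(depth) {
  stopifnot(all(depth >= 0))
  1 + depth / 10
}

#' Lung geometry for one animal
#'
#' Total lung capacity (TLC) is split into the maximum faveolar (gas
#' exchanging) volume and the airway dead space, taken as 7\% of TLC for all
#' three species.  Compression of the lung at depth follows Boyle's law for
#' the total gas volume; the conducting airways are compliant with shape
#' parameters \code{Kp} (ATA) and \code{n}, softened by a rigid
#' (cartilage-supported) fraction that guarantees a finite faveolar collapse
#' depth.  The faveolar pressure-volume constants \code{a}, \code{b},
#' \code{c} of the human-alveolus parameterization are carried for
#' provenance and reporting.
#'
#' @param species,bodyMass animal identity (kg).
#' @param dlvFraction diving lung volume at dive start, fraction of TLC
#'   (default 1; forced-dive validation uses 0.5).
#' @param rigidAirwayFraction fraction of the dead space that does not
#'   compress (default 0.25, calibrated so that a green turtle diving on
#'   half a lung retains well under 5\% of its maximum faveolar volume at
#'   90 m and collapses just beyond it (~97 m), while the majority of its
#'   lung gas still sits in the faveoli at 30 m).
#' @return Named list: \code{tlcTotal}, \code{vd0}, \code{vfaMax} (ml),
#'   \code{dlvFraction}, \code{kp}, \code{nAirway},
#'   \code{rigidAirwayFraction}, and the carried constants \code{a},
#'   \code{b}, \code{c}.
#' @examples
#' g <- lungGeometry("green", 70, dlvFraction = 0.5)
#' g$vfaMax + g$vd0 == g$tlcTotal
#' @export
lungGeometry <- function(species, bodyMass, dlvFraction = 1,
                         rigidAirwayFraction = 0.25) {
  sp <- speciesParams(species, bodyMass)
  tlc <- sp$tlcPerKg * bodyMass
  vd0 <- sp$vdFraction * tlc
  list(
    tlcTotal = tlc,
    vd0 = vd0,
    vfaMax = tlc - vd0,
    dlvFraction = dlvFraction,
    a = 1.04, b = 0.20, c = 1.21,
    kp = -6.44, nAirway = 0.74,
    rigidAirwayFraction = rigidAirwayFraction
  )
}

# Compliant dead-space volume at ambient pressure P (ATA): the compliant
# share decays as an inverse power of the excess pressure on the |Kp| scale
# (slower than Boyle, finite slope everywhere); the rigid share is
# cartilage-supported and does not compress.
.deadSpaceVolume <- function(geometry, pAmb) {
  compliant <- (1 + (pAmb - 1) / abs(geometry$kp))^(-geometry$nAirway)
  r <- geometry$rigidAirwayFraction
  geometry$vd0 * (r + (1 - r) * compliant)
}

#' Lung compression at depth
#'
#' Total lung gas volume obeys Boyle's law (with the water-vapor partial
#' pressure held at 0.062 ATA); the compliant dead space shrinks according
#' to its (Kp, n) parameterization but never below its rigid fraction and
#' never faster than the total volume; the faveolar volume is the remainder,
#' clipped to [0, VfAmax].  The faveoli are collapsed (gas exchange stops)
#' once the remainder reaches zero.
#'
#' @param geometry lung geometry from \code{\link{lungGeometry}}.
#' @param pAmb ambient pressure, ATA (>= 1).  Vectorized.
#' @param gasStore optional total lung gas store, ml STPD dry; defaults to
#'   the nominal store at dive start,
#'   \code{dlvFraction * tlcTotal * (1 - 0.062)}.
#' @return \code{data.frame} with columns \code{pAmb}, \code{vTot},
#'   \code{vd}, \code{vfa} (ml) and \code{collapsed}.
#' @examples
#' g <- lungGeometry("green", 70)
#' compressLung(g, c(1, 4, 10, 30))
#' @export
compressLung <- function(geometry, pAmb, gasStore = NULL) {
  if (any(pAmb < 1))
    stop("ambient pressure must be >= 1 ATA", call. = FALSE)
  if (is.null(gasStore))
    gasStore <- geometry$dlvFraction * geometry$tlcTotal * (1 - .PH2O)
  vTot <- gasStore / (pAmb - .PH2O)
  vd <- pmin(.deadSpaceVolume(geometry, pAmb), vTot)
  vfa <- pmin(geometry$vfaMax, pmax(0, vTot - vd))
  data.frame(pAmb = pAmb, vTot = vTot, vd = vd, vfa = vfa,
             collapsed = vfa <= 0)
}

#' Pulmonary shunt from faveolar volume
#'
#' Fraction of cardiac output bypassing gas exchange, as a smooth monotone
#' non-increasing function of faveolar volume:
#' \code{s0 + (1 - s0) * (1 - vfa/vfaMax)^gamma}.  It equals the baseline
#' \code{s0} at full faveolar volume and 1 at collapse.  The exponent is a
#' calibration constant (default 12), fixed once against the forced-dive
#' validation scenario so that the shunt is small at 30 m on a full lung and
#' dominant near the 19.4 ATA apex.
#'
#' @param vfa faveolar volume, ml (0 <= vfa <= vfaMax).  Vectorized.
#' @param vfaMax maximum faveolar volume, ml.
#' @param s0 baseline shunt at full volume (default 0).
#' @param gamma shape exponent (default 12).
#' @return Shunt fraction in [0, 1].
#' @examples
#' shuntFraction(c(0, 500, 1000), vfaMax = 1000)
#' @export
shuntFraction <- function(vfa, vfaMax, s0 = 0, gamma = 12) {
  if (any(vfa < 0) || any(vfa > vfaMax + 1e-9))
    stop("vfa must lie in [0, vfaMax]", call. = FALSE)
  s0 + (1 - s0) * (1 - pmin(vfa, vfaMax) / vfaMax)^gamma
}

#' Lung compression diagnostic curve
#'
#' Tabulates the compression model over a depth grid for plotting or
#' export: ambient pressure, faveolar volume (absolute and as a fraction of
#' maximum) and pulmonary shunt.
#'
#' @param geometry lung geometry from \code{\link{lungGeometry}}.
#' @param depth depth grid, m (default 0-200 m at 1 m).
#' @param s0,gamma shunt shape, see \code{\link{shuntFraction}}.
#' @return \code{data.frame}: \code{depth_m}, \code{p_amb}, \code{vfa_ml},
#'   \code{vfa_fraction}, \code{shunt}.
#' @examples
#' head(compressionCurve(lungGeometry("green", 70)))
#' @export
compressionCurve <- function(geometry, depth = 0:200, s0 = 0, gamma = 12) {
  cmp <- compressLung(geometry, ambientPressure(depth))
  data.frame(depth_m = depth, p_amb = cmp$pAmb, vfa_ml = cmp$vfa,
             vfa_fraction = cmp$vfa / geometry$vfaMax,
             shunt = shuntFraction(cmp$vfa, geometry$vfaMax, s0, gamma))
}

#' Faveolar collapse pressure
#'
#' Smallest ambient pressure at which the faveolar volume reaches zero, by
#' root finding on the compression model.  Finite because the rigid airway
#' fraction keeps the dead space from vanishing while the total gas volume
#' keeps falling as 1/P; increases with the diving lung volume.
#'
#' @param geometry lung geometry from \code{\link{lungGeometry}}.
#' @return Collapse pressure, ATA (depth = 10 * (P - 1) m).
#' @export
collapsePressure <- function(geometry) {
  store <- geometry$dlvFraction * geometry$tlcTotal * (1 - .PH2O)
  # unclamped faveolar margin: strictly decreasing, crosses zero once
  f <- function(p) store / (p - .PH2O) - .deadSpaceVolume(geometry, p)
  if (f(1) <= 0) return(1)
  upper <- 2
  while (f(upper) > 0 && upper < 1e6) upper <- upper * 2
  uniroot(f, c(1, upper), tol = 1e-8)$root
}
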