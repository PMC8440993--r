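#' @include AllClasses.R parameters.R lung-mechanics.R
NULL

#' Hill saturation of hemoglobin
#'
#' Fractional O2 saturation \code{S = PO2^h / (P50^h + PO2^h)}.  A Hill
#' coefficient of 2.7 is used for all three species.
#'
#' @param po2 O2 tension (same unit as \code{p50}).  Vectorized.
#' @param p50 half-saturation tension.
#' @param h Hill coefficient (default 2.7).
#' @return Saturation fraction in [0, 1).
#' @examples
#' hillSaturation(40, 40)       # 0.5 by definition of P50
#' hillSaturation(80, 40)       # 2^2.7 / (1 + 2^2.7) = 0.8666
#' @export
hillSaturation <- function(po2, p50, h = 2.7) {
  stopifnot(all(po2 >= 0))
  ph <- po2^h
  ph / (p50^h + ph)
}

#' Blood O2 content
#'
#' Hemoglobin-bound plus physically dissolved O2 per ml of blood:
#' \code{1.34 * [Hb] * S(PO2) + betaO2 * PO2}, with the Hill saturation
#' curve of the species.
#'
#' @param po2 O2 tension, ATA.  Vectorized.
#' @param params species parameters from \code{\link{speciesParams}} (uses
#'   \code{hb}, \code{p50ATA}, \code{hillH}).
#' @param gas gas constants (uses \code{hbO2Capacity}, \code{betaO2}).
#' @return ml O2 (STPD) per ml blood.
#' @examples
#' sp <- speciesParams("leatherback", 350)
#' bloodO2Content(sp$p50ATA, sp)  # ~0.1058
#' @export
bloodO2Content <- function(po2, params, gas = gasConstants()) {
  gas$hbO2Capacity * params$hb *
    hillSaturation(po2, params$p50ATA, params$hillH) + gas$betaO2 * po2
}

#' One perfusion-limited exchange step
#'
#' Exact exponential update of a single compartment tension over one time
#' step with piecewise-constant coefficients: the tension relaxes toward the
#' arterial tension with rate \code{k = Q * betaBlood / (V * betaTissue)}
#' plus a constant source/sink \code{u} (ATA per minute; negative for O2
#' consumption), and is floored at 0.
#'
#' @param tension current compartment tension, ATA.
#' @param arterial arterial tension, ATA.
#' @param Q compartment blood flow, ml min-1.
#' @param V compartment volume, ml.
#' @param betaBlood,betaTissue effective solubilities, ml ml-1 ATA-1.
#' @param dt step, seconds (default 1).
#' @param u source term, ATA min-1 (default 0).
#' @return Updated tension, ATA.
#' @examples
#' # tau = V * betaTissue / (Q * betaBlood)
#' perfusionStep(0.741, 4, Q = 10, V = 600, betaBlood = 0.0144,
#'               betaTissue = 0.0144)
#' @export
perfusionStep <- function(tension, arterial, Q, V, betaBlood, betaTissue,
                          dt = 1, u = 0) {
  k <- Q * betaBlood / (V * betaTissue)
  .perfusion_step(tension, arterial, k, u, dt / 60)
}

# Flatten a TurtleConfig into the plain numeric list the C++ core consumes.
.simPar <- function(config) {
  comp <- config@bodyComposition[.COMPARTMENTS]
  M <- config@bodyMass
  vol <- comp * M * 1000                     # g ~ ml at unit density
  gas <- config@gas
  sp <- config@speciesParams
  circ <- config@circulation
  lung <- config@lung
  betaN2 <- c(brain = gas$betaN2Lean, fat_bone = gas$betaN2Fat,
              central = gas$betaN2Lean, muscle = gas$betaN2Lean)
  diveMRspec <- config@metabolic$surfaceMR * config@metabolic$diveMRFraction
  list(
    compVolume = unname(vol),
    betaN2 = unname(betaN2),
    surfaceSplit = unname(circ$surfaceSplit[.COMPARTMENTS]),
    diveSplit = unname(circ$diveSplit[.COMPARTMENTS]),
    diveMR = unname(diveMRspec * comp * M),  # ml O2/min per compartment
    betaN2Blood = gas$betaN2Lean,
    betaO2 = gas$betaO2,
    betaCO2 = gas$betaCO2,
    hb = sp$hb,
    p50 = sp$p50ATA,
    hillH = sp$hillH,
    o2cap = gas$hbO2Capacity,
    mbCap = sp$mb * comp[["muscle"]] * M * gas$hbO2Capacity,
    mbP50 = config@options$mbP50ATA,
    rq = config@options$rq,
    qSurface = circ$surfaceSqtot * M,
    qDive = circ$surfaceSqtot * circ$diveFraction * M,
    tlc = lung$tlcTotal,
    vd0 = lung$vd0,
    vfaMax = lung$vfaMax,
    dlv = lung$dlvFraction,
    kp = lung$kp,
    nAirway = lung$nAirway,
    rigidFraction = lung$rigidAirwayFraction,
    shuntExponent = lung$shuntExponent,
    shuntBaseline = lung$shuntBaseline,
    ph2o = gas$ph2o,
    surfaceTensions = unname(.SURFACE_TENSIONS)
  )
}

.TRAJ_COLS <- c("time_s", "depth_m", "p_amb", "diving", "shunt", "vfa_ml",
                "fav_pn2", "fav_po2", "fav_pco2",
                "art_pn2", "art_po2", "art_pco2",
                "mv_pn2", "mv_po2", "mv_pco2",
                "brain_pn2", "brain_po2", "brain_pco2",
                "fat_pn2", "fat_po2", "fat_pco2",
                "central_pn2", "central_po2", "central_pco2",
                "muscle_pn2", "muscle_po2", "muscle_pco2",
                "inv_n2", "inv_o2", "inv_co2")

#' Simulate gas dynamics over a depth profile
#'
#' Advances the full body gas state over a regularized 1 Hz depth series.
#' The initial state is surface equilibrium (all tensions at the breathing
#' constants 0.741 / 0.164 / 0.033 ATA).  At every surfacing, breathing is
#' instantaneous: arterial and faveolar tensions snap to the surface
#' constants and the lung refills to the diving lung volume; at each descent
#' the lung store starts from that refilled composition.  During submergence
#' the lung compresses (Boyle total volume, compliant dead space), the
#' pulmonary shunt rises with faveolar compression, arterial tensions are
#' the shunt-weighted mix of faveolar and mixed venous tensions, and each
#' compartment exchanges with the blood perfusion-limited (analytic
#' exponential update per step), consuming O2 and producing CO2 at the
#' diving metabolic rate.  The lung store is debited by the exact tissue
#' store changes, so the lung + tissue inventory of a sealed (non-breathing,
#' non-collapsed) phase is conserved to numerical precision.
#'
#' @param series a \code{\linkS4class{DepthSeries}}.
#' @param config a \code{\linkS4class{TurtleConfig}}.
#' @param nsub integer sub-steps per 1 s sample (default 1; increase to
#'   check step-size convergence).
#' @return A \code{\linkS4class{SimulationResult}}.
#' @examples
#' s <- new("DepthSeries", depths = c(0, rep(50, 300), 0, 0),
#'          offsetApplied = 2, t0 = 0, species = "green", bodyMass = 70,
#'          id = "square")
#' res <- simulateGas(s, turtleConfig("green", 70))
#' res
#' @export
simulateGas <- function(series, config, nsub = 1L) {
  stopifnot(is(series, "DepthSeries"), is(config, "TurtleConfig"))
  raw <- .sim_core(series@depths, .simPar(config), as.integer(nsub))
  traj <- raw$trajectory
  colnames(traj) <- .TRAJ_COLS
  res <- new("SimulationResult", trajectory = traj,
             events = list(tissueO2Floor = unique(raw$tissueO2Floor),
                           lungFloor = unique(raw$lungFloor)),
             config = config, series = series)
  if (length(res@events$tissueO2Floor))
    warning(sprintf("tissue O2 store exhausted at %d sample(s); tension floored at 0",
                    length(res@events$tissueO2Floor)), call. = FALSE)
  res
}
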