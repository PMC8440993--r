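#' @include AllClasses.R dive-records.R
NULL

# Truncated-normal sampling by inversion (deterministic under a seed and
# free of rejection loops).  An SD of 0 degenerates to the clamped mean.
.rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  if (phi - plo < 0.01)
    stop(sprintf(paste0("infeasible spec: truncation to [%g, %g] retains ",
                        "<1%% of N(%g, %g^2)"), lo, hi, mean, sd),
         call. = FALSE)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Construct a dive-bout specification
#'
#' Statistical description of a dive bout: per-bin (shallow/medium/deep)
#' dive proportions and truncated-normal duration and maximum-depth
#' distributions, a surface-interval distribution, the number of dives and
#' the RNG seed.  Durations are truncated at 10 s and depths at 1 m and at
#' the bin boundaries, so each drawn dive realizes its drawn bin exactly.
#'
#' @param species,bodyMass animal identity (kg).
#' @param nDives number of dives.
#' @param proportions length-3 percentages (shallow, medium, deep), summing
#'   to 100 +/- 0.1.
#' @param durationMean,durationSD length-3, seconds.
#' @param depthMean,depthSD length-3, metres.
#' @param surfaceMean,surfaceSD post-dive surface interval, seconds
#'   (defaults 120 +/- 60; not constrained by field summaries).
#' @param seed integer RNG seed.
#' @param bottomFraction fraction of each dive spent at maximum depth
#'   (default 0.4).
#' @param pauseDepth,pauseSeconds brief ascent pause (default 15 s at 15 m,
#'   applied to dives deeper than twice the pause depth), mirroring the
#'   10-20 m ascent pause seen in all three species.
#' @param id identifier.
#' @return A \code{\linkS4class{BoutSpec}}.
#' @seealso \code{\link{generateBout}}, \code{\link{referenceBoutSpecs}}
#' @export
boutSpec <- function(species, bodyMass, nDives, proportions,
                     durationMean, durationSD, depthMean, depthSD,
                     surfaceMean = 120, surfaceSD = 60, seed = 1L,
                     bottomFraction = 0.4, pauseDepth = 15,
                     pauseSeconds = 15, id = "synthetic") {
  new("BoutSpec", id = as.character(id), species = species,
      bodyMass = as.numeric(bodyMass), nDives = as.integer(nDives),
      proportions = as.numeric(proportions),
      durationMean = as.numeric(durationMean),
      durationSD = as.numeric(durationSD),
      depthMean = as.numeric(depthMean), depthSD = as.numeric(depthSD),
      surfaceMean = as.numeric(surfaceMean),
      surfaceSD = as.numeric(surfaceSD), seed = as.integer(seed),
      shape = list(bottomFraction = bottomFraction, pauseDepth = pauseDepth,
                   pauseSeconds = pauseSeconds))
}

# Depth bin sampling ranges: a drawn maximum depth always realizes its bin.
.BIN_LO <- c(1, 30, 90.001)
.BIN_HI <- c(29.999, 90, Inf)

# One trapezoidal dive profile of exactly n 1 Hz samples reaching maxDepth,
# with an optional ascent pause.  All samples are > 0.
.diveProfile <- function(n, maxDepth, shape) {
  if (n == 1) return(maxDepth)
  td <- 0.3 * (n + 1)
  tb <- shape$bottomFraction * (n + 1)
  ta <- (n + 1) - td - tb
  knotT <- c(0, td, td + tb)
  knotD <- c(0, maxDepth, maxDepth)
  pause <- shape$pauseSeconds
  pd <- shape$pauseDepth
  if (pause > 0 && maxDepth > 2 * pd && ta > pause + 2) {
    ta1 <- (ta - pause) * (maxDepth - pd) / maxDepth
    knotT <- c(knotT, td + tb + ta1, td + tb + ta1 + pause, n + 1)
    knotD <- c(knotD, pd, pd, 0)
  } else {
    knotT <- c(knotT, n + 1)
    knotD <- c(knotD, 0)
  }
  prof <- approx(knotT, knotD, xout = seq_len(n))$y
  prof <- pmax(prof, 0.1)
  prof[which.max(prof)] <- maxDepth   # guarantee the drawn maximum is hit
  prof
}

#' Generate a synthetic dive bout
#'
#' Draws each dive's depth bin from the spec's proportions, its duration
#' and maximum depth from per-bin truncated normals, shapes it as a
#' descent-bottom-ascent trapezoid (with a brief ascent pause on deeper
#' dives), and separates dives by truncated-normal surface intervals.  The
#' output is a surface-referenced 1 Hz \code{\linkS4class{DepthSeries}}
#' that starts and ends at the surface, so segmentation recovers exactly
#' \code{nDives} complete dives.  The spec's seed fixes the output exactly;
#' the caller's RNG state is left untouched.
#'
#' @param spec a \code{\linkS4class{BoutSpec}}.
#' @return A \code{\linkS4class{DepthSeries}}.
#' @examples
#' sp <- boutSpec("green", 70, nDives = 5, proportions = c(100, 0, 0),
#'                durationMean = c(300, 0, 0), durationSD = c(60, 0, 0),
#'                depthMean = c(10, 0, 0), depthSD = c(3, 0, 0), seed = 7)
#' series <- generateBout(sp)
#' nrow(segmentDives(series))  # 5
#' @export
generateBout <- function(spec) {
  stopifnot(is(spec, "BoutSpec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec@seed)

  n <- spec@nDives
  bins <- sample.int(3, n, replace = TRUE, prob = spec@proportions / 100)
  pieces <- vector("list", 2 * n + 1)
  pieces[[1]] <- numeric(10)  # lead-in surface
  for (i in seq_len(n)) {
    b <- bins[i]
    dur <- max(10L, as.integer(round(
      .rtruncnorm(1, spec@durationMean[b], spec@durationSD[b], lo = 10))))
    dep <- .rtruncnorm(1, spec@depthMean[b], spec@depthSD[b],
                       lo = .BIN_LO[b], hi = .BIN_HI[b])
    surf <- max(2L, as.integer(round(
      .rtruncnorm(1, spec@surfaceMean, spec@surfaceSD, lo = 10))))
    pieces[[2 * i]] <- .diveProfile(dur, dep, spec@shape)
    pieces[[2 * i + 1]] <- numeric(surf)
  }
  new("DepthSeries", depths = unlist(pieces), offsetApplied = 0, t0 = 0,
      species = spec@species, bodyMass = spec@bodyMass, id = spec@id)
}

#' Reference bout specifications
#'
#' Bout specs mirroring the published per-individual dive summaries of six
#' leatherback (Dc1-Dc6), three loggerhead (Cc1-Cc3) and four green
#' (Cm1-Cm4) turtles, shipped as a YAML data file.
#'
#' @param id individual identifier (e.g. \code{"Dc1"}); \code{NULL} returns
#'   all thirteen.
#' @param nDives,seed number of dives and RNG seed attached to each spec.
#' @return A \code{\linkS4class{BoutSpec}}, or a named list of them.
#' @examples
#' referenceBoutSpecs("Dc1", nDives = 100)
#' @export
referenceBoutSpecs <- function(id = NULL, nDives = 500L, seed = 1L) {
  path <- system.file("extdata", "bout_specs.yaml", package = "gasdive")
  raw <- yaml::read_yaml(path)
  build <- function(nm) {
    x <- raw[[nm]]
    g <- function(f) vapply(c("shallow", "medium", "deep"),
                            function(b) as.numeric(x[[b]][[f]]), numeric(1))
    boutSpec(species = x$species, bodyMass = x$body_mass, nDives = nDives,
             proportions = g("proportion"),
             durationMean = g("duration_mean"), durationSD = g("duration_sd"),
             depthMean = g("depth_mean"), depthSD = g("depth_sd"),
             seed = seed, id = nm)
  }
  if (!is.null(id)) {
    if (!(id %in% names(raw)))
      stop("unknown individual '", id, "' (valid: ",
           paste(names(raw), collapse = ", "), ")", call. = FALSE)
    return(build(id))
  }
  setNames(lapply(names(raw), build), names(raw))
}

#' Step-wise forced-dive profile
#'
#' A staircase compression to a target ambient pressure and back: equal
#' pressure increments, each held for a fixed time, with surface samples at
#' both ends.  Used for the forced-submergence validation scenario.
#'
#' @param targetPressure apex pressure, ATA (> 1; default 19.4, i.e. 184 m).
#' @param nSteps number of equal pressure steps each way (default 8).
#' @param stepHold hold per step, s (default 600).
#' @param species,bodyMass,id metadata for the emitted series.
#' @return A \code{\linkS4class{DepthSeries}}.
#' @examples
#' max(depths(forcedDiveProfile(19.4)))  # 184 m
#' @export
forcedDiveProfile <- function(targetPressure = 19.4, nSteps = 8L,
                              stepHold = 600, species = "green",
                              bodyMass = 21, id = "forced-dive") {
  stopifnot(targetPressure > 1, nSteps >= 1, stepHold >= 1)
  stepDepths <- 10 * (targetPressure - 1) * seq_len(nSteps) / nSteps
  up <- rep(stepDepths, each = stepHold)
  down <- rep(rev(stepDepths[-nSteps]), each = stepHold)
  new("DepthSeries",
      depths = c(numeric(60), up, down, numeric(60)),
      offsetApplied = 0, t0 = 0, species = species,
      bodyMass = as.numeric(bodyMass), id = id)
}

#' Packaged forced-dive validation scenario
#'
#' The forced-submergence scenario used to check the model against measured
#' arterial PN2 in a green turtle compressed step-wise to 19.4 ATA: surface
#' cardiac output 3.42 ml min-1 kg-1, diving cardiac output
#' 0.17 ml min-1 kg-1, diving lung volume 50\% of total lung capacity.
#' (At the allometric reference, 3.42 ml min-1 kg-1 corresponds to a 21 kg
#' green turtle.)
#'
#' @param nSteps,stepHold staircase shape, see \code{\link{forcedDiveProfile}}.
#' @return List with elements \code{series} and \code{config}, ready for
#'   \code{\link{simulateGas}}.
#' @export
forcedDiveScenario <- function(nSteps = 8L, stepHold = 600) {
  series <- forcedDiveProfile(19.4, nSteps = nSteps, stepHold = stepHold)
  config <- turtleConfig("green", bodyMass = 21,
                         surfaceSqtotOverride = 3.42,
                         diveFraction = 0.17 / 3.42,
                         dlvFraction = 0.5)
  list(series = series, config = config)
}
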