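#' @include gas-dynamics.R dive-records.R
NULL

#' End-dive mixed venous PN2 per dive
#'
#' The nitrogen supersaturation index of each dive: the arithmetic mean of
#' mixed venous PN2 over the final 5 s of the dive (dives shorter than 5 s
#' use all their samples and are flagged).  Boundary-truncated dives are
#' excluded.
#'
#' @param result a \code{\linkS4class{SimulationResult}}.
#' @param dives dive table from \code{\link{segmentDives}} run on the same
#'   series (computed from the result's series if omitted).
#' @param window window length, s (default 5).
#' @param compartment which trace to summarize: \code{"mixed_venous"}
#'   (default) or one of \code{"brain"}, \code{"fat_bone"},
#'   \code{"central"}, \code{"muscle"}.
#' @return \code{data.frame}, one row per completed dive: \code{dive} (row
#'   in \code{dives}), \code{bin}, \code{endPN2} (ATA),
#'   \code{shortWindow}.
#' @seealso \code{\link{aggregateEndDive}}, \code{\link{percentChange}}
#' @export
endDivePN2 <- function(result, dives = NULL, window = 5,
                       compartment = c("mixed_venous", "brain", "fat_bone",
                                       "central", "muscle")) {
  stopifnot(is(result, "SimulationResult"))
  compartment <- match.arg(compartment)
  col <- switch(compartment, mixed_venous = "mv_pn2", brain = "brain_pn2",
                fat_bone = "fat_pn2", central = "central_pn2",
                muscle = "muscle_pn2")
  if (is.null(dives)) dives <- segmentDives(result@series)
  if (nrow(result@trajectory) != length(result@series@depths))
    stop("result and series are inconsistent", call. = FALSE)
  pn2 <- result@trajectory[, col]
  keep <- which(!dives$truncated)
  if (length(keep) == 0)
    stop("no completed (non-truncated) dives", call. = FALSE)
  rows <- lapply(keep, function(i) {
    last <- dives$end[i]                # 0-based exclusive == 1-based last
    m <- min(window, dives$duration[i])
    data.frame(dive = i, bin = dives$bin[i],
               endPN2 = mean(pn2[(last - m + 1):last]),
               shortWindow = m < window, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate end-dive PN2 per depth bin
#'
#' @param perDive output of \code{\link{endDivePN2}}.
#' @return \code{data.frame}: \code{bin}, \code{n}, \code{meanPN2},
#'   \code{maxPN2} (ATA), ordered shallow, medium, deep (occupied bins
#'   only), plus a final \code{"all"} row across bins.
#' @export
aggregateEndDive <- function(perDive) {
  bins <- factor(perDive$bin, levels = c("shallow", "medium", "deep"))
  out <- do.call(rbind, lapply(levels(bins), function(b) {
    sel <- perDive[bins == b, , drop = FALSE]
    if (nrow(sel) == 0) return(NULL)
    data.frame(bin = b, n = nrow(sel), meanPN2 = mean(sel$endPN2),
               maxPN2 = max(sel$endPN2), stringsAsFactors = FALSE)
  }))
  out <- rbind(out, data.frame(bin = "all", n = nrow(perDive),
                               meanPN2 = mean(perDive$endPN2),
                               maxPN2 = max(perDive$endPN2),
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Percent change of end-dive PN2 versus control
#'
#' \code{100 * (variant - control) / control}, applied per depth bin to the
#' mean and the maximum end-dive PN2.
#'
#' @param control,variant aggregates from \code{\link{aggregateEndDive}} for
#'   the same record and dive set.
#' @return \code{data.frame}: \code{bin}, \code{meanChangePct},
#'   \code{maxChangePct}.
#' @examples
#' a <- data.frame(bin = "all", n = 2, meanPN2 = 4, maxPN2 = 2)
#' b <- data.frame(bin = "all", n = 2, meanPN2 = 5, maxPN2 = 1.5)
#' percentChange(a, b)  # +25, -25
#' @export
percentChange <- function(control, variant) {
  m <- merge(control, variant, by = "bin", suffixes = c("_c", "_v"),
             sort = FALSE)
  if (any(m$meanPN2_c == 0) || any(m$maxPN2_c == 0))
    stop("control end-dive PN2 is zero; percent change undefined",
         call. = FALSE)
  data.frame(bin = m$bin,
             meanChangePct = 100 * (m$meanPN2_v - m$meanPN2_c) / m$meanPN2_c,
             maxChangePct = 100 * (m$maxPN2_v - m$maxPN2_c) / m$maxPN2_c,
             stringsAsFactors = FALSE)
}

#' Supersaturation (M-)ratio
#'
#' Expresses a mixed venous PN2 relative to a reference pressure.  The
#' default \code{"surface_n2_referenced"} mode divides by the surface
#' equilibrium N2 tension (0.741 ATA), the reading consistent with the
#' conventional M-ratio; \code{"ambient_referenced"} computes the relative
#' supersaturation \code{(PN2 - Pamb) / Pamb} against the ambient pressure.
#'
#' @param pn2 mixed venous PN2, ATA (>= 0).  Vectorized.
#' @param mode \code{"surface_n2_referenced"} (default) or
#'   \code{"ambient_referenced"}.
#' @param pAmb ambient pressure for the ambient-referenced mode, ATA
#'   (default 1).
#' @return Ratio (dimensionless).
#' @examples
#' supersaturationRatio(9.40)   # 12.7
#' supersaturationRatio(0.741)  # 1 at surface equilibrium
#' @export
supersaturationRatio <- function(pn2,
                                 mode = c("surface_n2_referenced",
                                          "ambient_referenced"),
                                 pAmb = 1) {
  stopifnot(all(pn2 >= 0))
  mode <- match.arg(mode)
  if (mode == "surface_n2_referenced") pn2 / .SURFACE_TENSIONS[["n2"]]
  else (pn2 - pAmb) / pAmb
}

#' Per-sample supersaturation field
#'
#' Both supersaturation readings along a simulated trajectory: the
#' ambient-referenced field \code{(mv PN2 - Pamb) / Pamb} and the
#' surface-referenced ratio \code{mv PN2 / 0.741}.
#'
#' @param result a \code{\linkS4class{SimulationResult}}.
#' @return \code{data.frame}: \code{time_s}, \code{depth_m},
#'   \code{ambientReferenced}, \code{surfaceReferenced}.
#' @export
supersaturationField <- function(result) {
  tr <- trajectory(result)
  data.frame(time_s = tr[, "time_s"], depth_m = tr[, "depth_m"],
             ambientReferenced = (tr[, "mv_pn2"] - tr[, "p_amb"]) / tr[, "p_amb"],
             surfaceReferenced = tr[, "mv_pn2"] / .SURFACE_TENSIONS[["n2"]])
}

#' Run the control model and all experiment variants
#'
#' Simulates the control configuration plus the six single-knob variants
#' (obese, emaciated, surface-high/low cardiac output, dive-high/low diving
#' cardiac output) on one depth series, and collects the dive table,
#' per-variant end-dive PN2 metrics, percent-change comparisons against
#' control, the control supersaturation field and a reproducibility
#' manifest.  Deterministic given its inputs.
#'
#' @param series a \code{\linkS4class{DepthSeries}}.
#' @param config the control \code{\linkS4class{TurtleConfig}}.
#' @param variants variant labels to run (default: control plus all six).
#' @param keepTrajectories keep each variant's full trajectory matrix
#'   (default \code{FALSE}: only metrics are retained, plus the control
#'   supersaturation field).
#' @return List of class \code{"gasdiveSuite"}: \code{dives},
#'   \code{perDive} and \code{aggregates} (named by variant),
#'   \code{comparisons} (percent change vs control per variant),
#'   \code{supersaturation} (control), \code{manifest}, and optionally
#'   \code{trajectories}.
#' @export
runSuite <- function(series, config, variants = .VARIANTS,
                     keepTrajectories = FALSE) {
  stopifnot(is(series, "DepthSeries"), is(config, "TurtleConfig"))
  if (config@variant != "control")
    stop("runSuite expects the control configuration", call. = FALSE)
  variants <- match.arg(variants, .VARIANTS, several.ok = TRUE)
  if (!("control" %in% variants)) variants <- c("control", variants)
  dives <- segmentDives(series)
  perDive <- list(); aggregates <- list(); trajectories <- list()
  supersat <- NULL
  for (v in variants) {
    cfg <- makeVariant(config, v)
    res <- simulateGas(series, cfg)
    perDive[[v]] <- endDivePN2(res, dives)
    aggregates[[v]] <- aggregateEndDive(perDive[[v]])
    if (v == "control") supersat <- supersaturationField(res)
    if (keepTrajectories) trajectories[[v]] <- trajectory(res)
  }
  comparisons <- lapply(aggregates[setdiff(variants, "control")],
                        function(a) percentChange(aggregates$control, a))
  out <- list(dives = dives, perDive = perDive, aggregates = aggregates,
              comparisons = comparisons, supersaturation = supersat,
              manifest = runManifest(config, series = series,
                                     variants = variants))
  if (keepTrajectories) out$trajectories <- trajectories
  class(out) <- "gasdiveSuite"
  out
}

#' @export
print.gasdiveSuite <- function(x, ...) {
  cat(sprintf("gasdive suite: %d dives, %d variant(s)\n",
              nrow(x$dives), length(x$aggregates)))
  ctl <- x$aggregates$control
  all <- ctl[ctl$bin == "all", ]
  cat(sprintf("  control end-dive mixed venous PN2: mean %.3f, max %.3f ATA\n",
              all$meanPN2, all$maxPN2))
  for (v in names(x$comparisons)) {
    cc <- x$comparisons[[v]]
    aa <- cc[cc$bin == "all", ]
    cat(sprintf("  %-13s mean %+6.1f%%  max %+6.1f%%\n", v,
                aa$meanChangePct, aa$maxChangePct))
  }
  invisible(x)
}
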