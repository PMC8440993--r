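#' @include AllClasses.R
NULL

#' Read a time-depth-recorder CSV
#'
#' Reads a two-column CSV (\code{time_s}, \code{depth_m}; header required)
#' into a validated \code{\linkS4class{RawRecord}}.  Times must be strictly
#' increasing and depths non-negative; violations are hard errors naming the
#' offending row.
#'
#' @param path path to the CSV file.
#' @param species one of \code{"loggerhead"}, \code{"leatherback"},
#'   \code{"green"}.
#' @param bodyMass body mass, kg.
#' @param id record identifier (defaults to the file name).
#' @param samplingInterval nominal sampling interval, s.  If \code{NULL} it
#'   is taken as the median time step.
#' @return A \code{\linkS4class{RawRecord}}.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(time_s = c(0, 10, 20), depth_m = c(0, 12, 0)),
#'           f, row.names = FALSE)
#' readTDR(f, species = "green", bodyMass = 70)
#' @export
readTDR <- function(path, species, bodyMass, id = basename(path),
                    samplingInterval = NULL) {
  dat <- read.csv(path)
  need <- c("time_s", "depth_m")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  times <- as.numeric(dat$time_s)
  dep <- as.numeric(dat$depth_m)
  if (any(!is.finite(times)) || any(!is.finite(dep)))
    stop("non-numeric or missing time/depth values in ", path, call. = FALSE)
  if (is.null(samplingInterval))
    samplingInterval <- if (length(times) >= 2) median(diff(times)) else NA_real_
  new("RawRecord", times = times, depths = dep,
      samplingInterval = as.numeric(samplingInterval),
      species = species, bodyMass = as.numeric(bodyMass), id = as.character(id))
}

#' Regularize a raw record to 1 Hz
#'
#' Linearly interpolates depth to exactly 1 s intervals, then subtracts the
#' surface offset (2 m by default) and clamps at 0 m.  The offset absorbs
#' measurement error and tag tethering so that every breathing event sits at
#' depth 0; it slightly reduces the maximum depth of each dive.
#'
#' @param record a \code{\linkS4class{RawRecord}} with at least 2 samples, or
#'   an already-regular \code{DepthSeries} (in which case only the offset is
#'   applied).
#' @param offset metres subtracted from all depths before clamping at 0
#'   (default 2).
#' @return A \code{\linkS4class{DepthSeries}}.
#' @examples
#' r <- new("RawRecord", times = c(0, 10), depths = c(0, 12),
#'          samplingInterval = 10, species = "green", bodyMass = 70, id = "x")
#' depths(regularize(r))  # 0 0 0.4 1.6 ... 10
#' @export
setGeneric("regularize", function(record, offset = 2) {
  standardGeneric("regularize")
})

#' @rdname regularize
#' @export
setMethod("regularize", "RawRecord", function(record, offset = 2) {
  if (length(record@times) < 2)
    stop("record must contain at least 2 samples", call. = FALSE)
  grid <- seq(record@times[1], record@times[length(record@times)], by = 1)
  dep <- approx(record@times, record@depths, xout = grid)$y
  dep <- pmax(0, dep - offset)
  new("DepthSeries", depths = dep, offsetApplied = as.numeric(offset),
      t0 = record@times[1], species = record@species,
      bodyMass = record@bodyMass, id = record@id)
})

#' @rdname regularize
#' @export
setMethod("regularize", "DepthSeries", function(record, offset = 2) {
  new("DepthSeries", depths = pmax(0, record@depths - offset),
      offsetApplied = record@offsetApplied + offset, t0 = record@t0,
      species = record@species, bodyMass = record@bodyMass, id = record@id)
})

#' Classify a dive by its maximum depth
#'
#' Depth bins follow the operational boundaries used for dive summaries:
#' shallow below 30 m, medium from 30 to 90 m inclusive, deep beyond 90 m.
#' Vectorized.
#'
#' @param maxDepth maximum dive depth(s), m (>= 0).
#' @return Character vector of \code{"shallow"}, \code{"medium"},
#'   \code{"deep"}.
#' @examples
#' binDive(c(25, 30, 90, 96.9))
#' @export
binDive <- function(maxDepth) {
  stopifnot(all(maxDepth >= 0))
  ifelse(maxDepth < 30, "shallow", ifelse(maxDepth <= 90, "medium", "deep"))
}

#' Segment a depth series into dives
#'
#' A dive is each maximal run of consecutive 1 Hz samples with depth > 0
#' (breathing begins the instant the animal reaches 0 m, so no depth
#' threshold is used beyond the surface offset already applied by
#' \code{\link{regularize}}).  Runs touching the series boundaries are
#' flagged truncated.
#'
#' @param series a \code{\linkS4class{DepthSeries}}.
#' @return \code{data.frame} with one row per dive: \code{start} and
#'   \code{end} (0-based half-open 1 Hz sample interval), \code{duration}
#'   (s), \code{maxDepth}, \code{meanDepth} (m), \code{bin} and
#'   \code{truncated}.  Zero rows if the animal never submerges.
#' @examples
#' s <- new("DepthSeries", depths = c(0, 3, 8, 3, 0, 0, 5, 0),
#'          offsetApplied = 2, t0 = 0, species = "green", bodyMass = 70,
#'          id = "toy")
#' segmentDives(s)
#' @export
segmentDives <- function(series) {
  stopifnot(is(series, "DepthSeries"))
  d <- series@depths
  n <- length(d)
  r <- rle(d > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) {
    return(data.frame(start = integer(), end = integer(),
                      duration = integer(), maxDepth = numeric(),
                      meanDepth = numeric(), bin = character(),
                      truncated = logical(), stringsAsFactors = FALSE))
  }
  s1 <- starts[keep]  # 1-based first in-dive sample
  e1 <- ends[keep]    # 1-based last in-dive sample
  maxd <- vapply(seq_along(s1), function(i) max(d[s1[i]:e1[i]]), numeric(1))
  meand <- vapply(seq_along(s1), function(i) mean(d[s1[i]:e1[i]]), numeric(1))
  data.frame(
    start = s1 - 1L,             # 0-based inclusive
    end = e1,                    # 0-based exclusive
    duration = e1 - s1 + 1L,
    maxDepth = maxd,
    meanDepth = meand,
    bin = binDive(maxd),
    truncated = (s1 == 1L) | (e1 == n),
    stringsAsFactors = FALSE
  )
}

#' Per-bin dive summaries
#'
#' Mean and sample SD of dive duration and maximum depth, and the
#' percentage of dives, per depth bin.
#'
#' @param dives dive table from \code{\link{segmentDives}} (>= 1 row).
#' @param excludeTruncated drop boundary-truncated dives first
#'   (default \code{FALSE}).
#' @return \code{data.frame} with one row per occupied bin (ordered shallow,
#'   medium, deep): \code{bin}, \code{n}, \code{proportionPct},
#'   \code{durationMean}, \code{durationSD}, \code{maxDepthMean},
#'   \code{maxDepthSD}.  Proportions sum to 100.
#' @export
summarizeDives <- function(dives, excludeTruncated = FALSE) {
  if (excludeTruncated) dives <- dives[!dives$truncated, , drop = FALSE]
  if (nrow(dives) == 0)
    stop("no dives to summarize", call. = FALSE)
  bins <- factor(dives$bin, levels = c("shallow", "medium", "deep"))
  out <- do.call(rbind, lapply(levels(bins), function(b) {
    sel <- dives[bins == b, , drop = FALSE]
    if (nrow(sel) == 0) return(NULL)
    data.frame(bin = b, n = nrow(sel),
               proportionPct = 100 * nrow(sel) / nrow(dives),
               durationMean = mean(sel$duration),
               durationSD = if (nrow(sel) > 1) sd(sel$duration) else NA_real_,
               maxDepthMean = mean(sel$maxDepth),
               maxDepthSD = if (nrow(sel) > 1) sd(sel$maxDepth) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
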