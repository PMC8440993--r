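#' @include parameters.R
NULL

# md5 of an arbitrary R object via a temporary serialized file.
.objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Reproducibility manifest for a model run
#'
#' Captures everything needed to re-run a simulation bit-identically: the
#' package version, the RNG seed (if any), every resolved parameter value
#' including the unit-interpretation choices (Hb in g per ml, P50 converted
#' from mmHg to ATA, Ostwald solubilities), input digests, and a hash over
#' the resolved configuration.
#'
#' @param config a \code{\linkS4class{TurtleConfig}}.
#' @param seed RNG seed used, or \code{NA} for deterministic runs.
#' @param series optional \code{\linkS4class{DepthSeries}} whose depths are
#'   digested.
#' @param variants optional character vector of variant labels run.
#' @return Named list with \code{package}, \code{version},
#'   \code{timestamp}, \code{seed}, \code{configHash}, \code{seriesDigest},
#'   \code{variants} and \code{resolved} (the flattened parameter values).
#' @export
runManifest <- function(config, seed = NA_integer_, series = NULL,
                        variants = NULL) {
  stopifnot(is(config, "TurtleConfig"))
  resolved <- list(
    species = config@species,
    bodyMass = config@bodyMass,
    variant = config@variant,
    condition = config@options$condition,
    bodyComposition = config@bodyComposition,
    circulation = config@circulation,
    metabolic = config@metabolic,
    speciesParams = config@speciesParams[setdiff(names(config@speciesParams),
                                                 "species")],
    lung = config@lung,
    gas = config@gas,
    mbP50ATA = config@options$mbP50ATA,
    rq = config@options$rq
  )
  list(
    package = "gasdive",
    version = as.character(packageVersion("gasdive")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    configHash = .objectHash(resolved[setdiff(names(resolved), "timestamp")]),
    seriesDigest = if (is.null(series)) NA_character_
                   else .objectHash(series@depths),
    variants = variants,
    resolved = resolved
  )
}
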