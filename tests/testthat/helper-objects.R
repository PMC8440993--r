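# Shared fixtures, built in code.

mkSeries <- function(depths, species = "green", bodyMass = 70, id = "test") {
  new("DepthSeries", depths = as.numeric(depths), offsetApplied = 0, t0 = 0,
      species = species, bodyMass = bodyMass, id = id)
}

mkRecord <- function(times, depths, species = "green", bodyMass = 70,
                     id = "test") {
  new("RawRecord", times = as.numeric(times), depths = as.numeric(depths),
      samplingInterval = if (length(times) > 1) median(diff(times)) else 1,
      species = species, bodyMass = bodyMass, id = id)
}

# Brute-force dive segmentation oracle: scans every sample.
segmentOracle <- function(depths) {
  n <- length(depths)
  out <- NULL
  i <- 1
  while (i <= n) {
    if (depths[i] > 0) {
      j <- i
      while (j < n && depths[j + 1] > 0) j <- j + 1
      out <- rbind(out, data.frame(
        start = i - 1L, end = j, duration = j - i + 1L,
        maxDepth = max(depths[i:j]), meanDepth = mean(depths[i:j]),
        truncated = (i == 1L) || (j == n)))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(),
                      duration = integer(), maxDepth = numeric(),
                      meanDepth = numeric(), truncated = logical())
  out
}

# A SimulationResult whose mixed venous PN2 trace is set by hand, for
# exercising the end-dive metric arithmetic in isolation.
mkResultWithMV <- function(depths, mv) {
  stopifnot(length(depths) == length(mv))
  cols <- c("time_s", "depth_m", "p_amb", "diving", "shunt", "vfa_ml",
            "fav_pn2", "fav_po2", "fav_pco2", "art_pn2", "art_po2",
            "art_pco2", "mv_pn2", "mv_po2", "mv_pco2",
            "brain_pn2", "brain_po2", "brain_pco2",
            "fat_pn2", "fat_po2", "fat_pco2",
            "central_pn2", "central_po2", "central_pco2",
            "muscle_pn2", "muscle_po2", "muscle_pco2",
            "inv_n2", "inv_o2", "inv_co2")
  traj <- matrix(0, nrow = length(depths), ncol = length(cols),
                 dimnames = list(NULL, cols))
  traj[, "depth_m"] <- depths
  traj[, "p_amb"] <- 1 + depths / 10
  traj[, "mv_pn2"] <- mv
  new("SimulationResult", trajectory = traj,
      events = list(tissueO2Floor = integer(), lungFloor = integer()),
      config = turtleConfig("green", 70), series = mkSeries(depths))
}
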