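test_that("Hill saturation matches its defining values", {
  expect_equal(hillSaturation(40, 40), 0.5)
  expect_equal(hillSaturation(80, 40), 2^2.7 / (1 + 2^2.7))  # 0.8666
  expect_equal(hillSaturation(0, 40), 0)
  p <- seq(0, 200, by = 5)
  expect_true(all(diff(hillSaturation(p, 40)) > 0))
})

test_that("blood O2 content combines Hb carriage and dissolved gas", {
  sp <- speciesParams("leatherback", 350)
  expect_equal(bloodO2Content(0, sp), 0)
  # at P50: half-saturated Hb plus the dissolved term
  expect_equal(bloodO2Content(sp$p50ATA, sp),
               0.5 * 1.34 * 0.156 + 0.0236 * 40 / 760,
               tolerance = 1e-10)
  p <- seq(0, 0.5, by = 0.01)
  expect_true(all(diff(bloodO2Content(p, sp)) > 0))
})

test_that("the perfusion kernel reproduces the closed-form exponential", {
  # dP/dt = (Part - P)/tau with tau = V*betaT/(Q*betaB)
  Q <- 10; V <- 600; bB <- 0.0144; bT <- 0.0144
  tau <- V * bT / (Q * bB)  # minutes
  p0 <- 0.741; part <- 4
  p <- p0
  for (i in 1:600) p <- perfusionStep(p, part, Q, V, bB, bT, dt = 1)
  expect_equal(p, part + (p0 - part) * exp(-10 / tau), tolerance = 1e-12)
  # fixed point
  expect_equal(perfusionStep(part, part, Q, V, bB, bT), part)
})

test_that("an all-surface series is a flat fixed point at the breathing constants", {
  r <- simulateGas(mkSeries(numeric(600)), turtleConfig("green", 70))
  tr <- trajectory(r)
  expect_equal(max(abs(tr[, c("brain_pn2", "fat_pn2", "central_pn2",
                              "muscle_pn2", "mv_pn2", "art_pn2")] - 0.741)), 0)
  expect_equal(max(abs(tr[, c("brain_po2", "mv_po2")] - 0.164)), 0)
  expect_equal(max(abs(tr[, c("brain_pco2", "mv_pco2")] - 0.033)), 0)
})

test_that("the full simulator matches per-compartment closed forms under a constant arterial tension", {
  # A practically infinite lung pins the faveolar (hence arterial, shunt 0)
  # tensions, reducing each compartment to an independent one-compartment
  # exchange with a constant drive -- the analytic oracle.
  cfg <- turtleConfig("green", 70, surfaceMR = 0)
  cfg@lung$tlcTotal <- 1e9   # huge store: faveolar fractions stay fixed
  cfg@lung$vd0 <- 0
  cfg@lung$vfaMax <- 1e6     # always saturated by the Boyle volume: shunt 0
  depth <- 50
  nsec <- 3600
  r <- simulateGas(mkSeries(c(0, rep(depth, nsec))), cfg)
  tr <- trajectory(r)
  expect_lt(max(abs(tr[-1, "shunt"])), 1e-9)
  # dry-gas N2 fraction 0.741/0.938 at ambient-minus-vapor pressure
  part <- 0.741 / 0.938 * (ambientPressure(depth) - 0.062)
  expect_equal(unname(tr[2, "art_pn2"]), part, tolerance = 1e-6)

  gc <- gasConstants()
  comp <- bodyComposition("control")
  M <- 70
  qd <- surfaceSqtot(M) * 0.05 * M
  split <- c(brain = 0.020, fat_bone = 0.002, central = 0.928, muscle = 0.050)
  beta <- c(brain = gc$betaN2Lean, fat_bone = gc$betaN2Fat,
            central = gc$betaN2Lean, muscle = gc$betaN2Lean)
  for (cc in names(split)) {
    V <- comp[[cc]] * M * 1000
    k <- qd * split[[cc]] * gc$betaN2Lean / (V * beta[[cc]])  # per minute
    for (tmin in c(10, 30, 60)) {
      want <- part + (0.741 - part) * exp(-k * tmin)
      col <- paste0(sub("fat_bone", "fat", cc), "_pn2")
      got <- unname(tr[1 + tmin * 60, col])
      expect_equal(got, want, tolerance = 1e-3)  # within 0.1%
    }
  }
})

test_that("halving the step changes the end-dive mixed venous PN2 by well under 0.5%", {
  sp <- boutSpec("green", 70, nDives = 10, proportions = c(60, 40, 0),
                 durationMean = c(200, 400, 0), durationSD = c(50, 80, 0),
                 depthMean = c(10, 50, 0), depthSD = c(4, 10, 0), seed = 9)
  s <- generateBout(sp)
  cfg <- turtleConfig("green", 70)
  r1 <- suppressWarnings(simulateGas(s, cfg, nsub = 1L))
  r2 <- suppressWarnings(simulateGas(s, cfg, nsub = 2L))
  n <- length(depths(s))
  end1 <- mixedVenousPN2(r1)[n]
  end2 <- mixedVenousPN2(r2)[n]
  expect_lt(abs(end1 - end2) / end2, 0.005)
})

test_that("a sealed submerged phase conserves every gas inventory", {
  cfg <- turtleConfig("green", 70, surfaceMR = 0)
  # varying (but always submerged) profile, no collapse at these depths
  d <- c(0, rep(c(rep(20, 300), rep(45, 300)), 3))
  inv <- gasInventory(simulateGas(mkSeries(d), cfg))
  sealed <- inv[-1, , drop = FALSE]  # after the initial breath
  for (g in 1:3)
    expect_lt(diff(range(sealed[, g])) / sealed[1, g], 1e-10)
})

test_that("after faveolar collapse the arterial blood equals mixed venous and the lung freezes", {
  cfg <- turtleConfig("green", 70, dlvFraction = 0.5)
  pstar <- collapsePressure(cfg@lung)
  depth <- 10 * (pstar - 1) + 40  # comfortably beyond collapse
  r <- suppressWarnings(simulateGas(mkSeries(c(0, rep(depth, 900))), cfg))
  tr <- trajectory(r)
  deeprows <- which(tr[, "shunt"] == 1)
  expect_gt(length(deeprows), 800)
  expect_equal(max(abs(tr[deeprows, "art_pn2"] - tr[deeprows, "mv_pn2"])), 0,
               tolerance = 1e-5)
  expect_true(all(tr[deeprows, "vfa_ml"] == 0))
})

test_that("initial O2 stores sit within 50% of the reference species values", {
  for (spn in c("loggerhead", "leatherback", "green")) {
    M <- switch(spn, loggerhead = 60, leatherback = 334, green = 70)
    cfg <- turtleConfig(spn, M)
    sp <- cfg@speciesParams
    gc <- cfg@gas
    lung <- cfg@lung$dlvFraction * cfg@lung$tlcTotal * 0.164
    expect_lt(abs(lung - sp$o2StoreLung * M) / (sp$o2StoreLung * M), 0.5)
    bloodVol <- cfg@bodyComposition[["blood"]] * M * 1000
    blood <- bloodO2Content(0.164, sp, gc) * bloodVol
    expect_lt(abs(blood - sp$o2StoreBlood * M) / (sp$o2StoreBlood * M), 0.5)
    muscleKg <- cfg@bodyComposition[["muscle"]] * M
    mbCap <- sp$mb * muscleKg * gc$hbO2Capacity
    muscle <- mbCap * 0.164 / (0.164 + cfg@options$mbP50ATA) +
      gc$betaO2 * muscleKg * 1000 * 0.164
    expect_lt(abs(muscle - sp$o2StoreMuscle * M) / (sp$o2StoreMuscle * M), 0.5)
  }
})

test_that("nitrogen loads the central circulation faster than fat on a square dive", {
  cfg <- turtleConfig("green", 70)
  r <- simulateGas(mkSeries(c(0, rep(50, 600), numeric(60))), cfg)
  tr <- trajectory(r)
  rise <- tr[601, c("central_pn2", "fat_pn2")] - 0.741
  expect_gt(rise[["central_pn2"]], rise[["fat_pn2"]])
  expect_gt(rise[["central_pn2"]], 0)
})

test_that("the forced-dive scenario completes with a rising then plateauing arterial PN2", {
  sc <- forcedDiveScenario(nSteps = 8L, stepHold = 300)
  r <- suppressWarnings(simulateGas(sc$series, sc$config))
  tr <- trajectory(r)
  art <- tr[, "art_pn2"]
  # rises well above surface equilibrium during compression ...
  expect_gt(max(art), 0.741 * 2)
  # ... then plateaus: once collapsed the sealed lung drops out and arterial
  # tracks the slowly-moving mixed venous tension
  collapsed <- which(tr[, "shunt"] == 1)
  expect_gt(length(collapsed), 100)
  expect_lt(diff(range(art[collapsed])), 0.2 * (max(art) - 0.741))
  expect_equal(max(abs(art[collapsed] - tr[collapsed, "mv_pn2"])), 0,
               tolerance = 1e-5)
  # and the trajectory is finite and bounded by ambient pressure
  expect_true(all(is.finite(art)))
  expect_true(all(art <= max(tr[, "p_amb"])))
})

test_that("O2 exhaustion during an extreme dive is flagged but the run continues", {
  cfg <- turtleConfig("green", 70)
  expect_warning(r <- simulateGas(mkSeries(c(0, rep(60, 4 * 3600))), cfg),
                 "O2 store exhausted")
  expect_gt(length(r@events$tissueO2Floor), 0)
  expect_true(all(trajectory(r)[, "muscle_po2"] >= 0))
})
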