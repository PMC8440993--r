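test_that("a fixed seed makes bout generation exactly reproducible", {
  sp <- boutSpec("green", 70, nDives = 20, proportions = c(80, 20, 0),
                 durationMean = c(200, 500, 0), durationSD = c(60, 90, 0),
                 depthMean = c(8, 45, 0), depthSD = c(3, 10, 0), seed = 77)
  s1 <- generateBout(sp)
  s2 <- generateBout(sp)
  expect_identical(depths(s1), depths(s2))
})

test_that("bout generation leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generateBout(boutSpec("green", 70, nDives = 3,
                                  proportions = c(100, 0, 0),
                                  durationMean = c(100, 0, 0),
                                  durationSD = c(10, 0, 0),
                                  depthMean = c(10, 0, 0),
                                  depthSD = c(2, 0, 0), seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("an all-shallow spec never exceeds 30 m and realizes every dive", {
  sp <- boutSpec("green", 70, nDives = 40, proportions = c(100, 0, 0),
                 durationMean = c(120, 0, 0), durationSD = c(200, 0, 0),
                 depthMean = c(20, 0, 0), depthSD = c(15, 0, 0), seed = 3)
  s <- generateBout(sp)
  expect_lt(max(depths(s)), 30)
  d <- segmentDives(s)
  expect_equal(nrow(d), 40)
  expect_false(any(d$truncated))
  expect_true(all(d$bin == "shallow"))
})

test_that("generated series round-trip through segmentation to the spec", {
  sp <- boutSpec("leatherback", 334, nDives = 300,
                 proportions = c(60, 30, 10),
                 durationMean = c(300, 700, 900), durationSD = c(60, 90, 80),
                 depthMean = c(15, 50, 110), depthSD = c(5, 10, 10),
                 seed = 42)
  s <- generateBout(sp)
  sm <- summarizeDives(segmentDives(s))
  expect_equal(sm$proportionPct, c(60, 30, 10), tolerance = 0.12)
  # mild truncation here, so realized moments track the nominal ones
  expect_equal(sm$durationMean, c(300, 700, 900), tolerance = 0.05)
  expect_equal(sm$maxDepthMean, c(15, 50, 110), tolerance = 0.05)
  expect_equal(sum(sm$proportionPct), 100, tolerance = 1e-6)
})

test_that("realized durations converge to the analytic truncated-normal mean", {
  mu <- 209; sig <- 251; lo <- 10
  sp <- boutSpec("leatherback", 334, nDives = 2000,
                 proportions = c(100, 0, 0),
                 durationMean = c(mu, 0, 0), durationSD = c(sig, 0, 0),
                 depthMean = c(6.3, 0, 0), depthSD = c(7, 0, 0), seed = 8)
  d <- segmentDives(generateBout(sp))
  # one-sided truncated normal moments (independent closed form)
  a <- (lo - mu) / sig
  Z <- 1 - pnorm(a)
  lam <- dnorm(a) / Z
  m <- mu + sig * lam
  v <- sig^2 * (1 + a * lam - lam^2)
  se <- sqrt(v / nrow(d))
  expect_lt(abs(mean(d$duration) - m), 3 * se + 0.5)  # +0.5 s for rounding
})

test_that("infeasible truncation is rejected with a clear error", {
  sp <- boutSpec("green", 70, nDives = 5, proportions = c(100, 0, 0),
                 durationMean = c(100, 0, 0), durationSD = c(5, 0, 0),
                 depthMean = c(200, 0, 0), depthSD = c(5, 0, 0), seed = 1)
  # shallow-bin depths are truncated to [1, 30); N(200, 5) has no mass there
  expect_error(generateBout(sp), "infeasible spec")
})

test_that("the forced-dive staircase reaches the target pressure monotonically", {
  s <- forcedDiveProfile(19.4, nSteps = 8, stepHold = 30)
  d <- depths(s)
  expect_equal(max(d), 184)
  apex <- which.max(d)[1]
  expect_true(all(diff(d[1:apex]) >= 0))
  # single-step profile is one square dive
  s1 <- forcedDiveProfile(6, nSteps = 1, stepHold = 30)
  dv <- segmentDives(s1)
  expect_equal(nrow(dv), 1)
  expect_equal(dv$maxDepth, 50)
})

test_that("reference bout specs load all thirteen individuals with their fields", {
  specs <- referenceBoutSpecs(nDives = 50)
  expect_length(specs, 13)
  dc1 <- specs$Dc1
  expect_equal(dc1@proportions, c(87.2, 11.6, 1.2))
  expect_equal(dc1@durationMean[2], 827)
  expect_equal(dc1@depthMean[3], 108.7)
  expect_equal(dc1@bodyMass, 334)
  expect_identical(dc1@species, "leatherback")
  expect_error(referenceBoutSpecs("Xy9"), "unknown individual")
})
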