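test_that("readTDR reads a valid CSV and rejects malformed records", {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write.csv(data.frame(time_s = c(0, 10, 20), depth_m = c(0, 12, 0)), f,
            row.names = FALSE)
  rec <- readTDR(f, species = "green", bodyMass = 70, id = "toy")
  expect_s4_class(rec, "RawRecord")
  expect_length(depths(rec), 3)
  expect_identical(rec@times, c(0, 10, 20))

  write.csv(data.frame(time_s = c(0, 10, 5), depth_m = c(0, 1, 2)), f,
            row.names = FALSE)
  expect_error(readTDR(f, "green", 70), "non-monotone times at row 3")

  write.csv(data.frame(time_s = c(0, 10), depth_m = c(0, -1)), f,
            row.names = FALSE)
  expect_error(readTDR(f, "green", 70), "negative depth at row 2")

  write.csv(data.frame(t = 0:2, depth_m = c(0, 1, 0)), f, row.names = FALSE)
  expect_error(readTDR(f, "green", 70), "missing column")

  write.csv(data.frame(time_s = 0:1, depth_m = c(0, 1)), f,
            row.names = FALSE)
  expect_error(readTDR(f, "flatback", 70), "unknown species")
})

test_that("regularize interpolates to 1 Hz then subtracts and clamps the offset", {
  rec <- mkRecord(c(0, 10), c(0, 12))
  s <- regularize(rec)  # default 2 m offset
  expect_equal(depths(s),
               c(0, 0, 0.4, 1.6, 2.8, 4.0, 5.2, 6.4, 7.6, 8.8, 10.0))
  expect_identical(s@offsetApplied, 2)

  # a constant 2 m trace is all surface after the offset (breathing at 0 m)
  flat <- regularize(mkRecord(seq(0, 40, 10), rep(2, 5)))
  expect_true(all(depths(flat) == 0))

  # offset 0 on a constant trace is the identity
  same <- regularize(mkRecord(seq(0, 40, 10), rep(5, 5)), offset = 0)
  expect_true(all(depths(same) == 5))

  expect_error(regularize(mkRecord(0, 3)), "at least 2 samples")
})

test_that("regularize with offset 0 is idempotent on a 1 Hz series", {
  s <- mkSeries(c(0, 1, 3, 2, 0, 4, 0))
  expect_equal(depths(regularize(s, offset = 0)), depths(s))
})

test_that("segmentDives finds maximal submerged runs and flags truncation", {
  d <- segmentDives(mkSeries(c(0, 3, 8, 3, 0, 0, 5, 0)))
  expect_equal(nrow(d), 2)
  expect_equal(d$duration, c(3L, 1L))
  expect_equal(d$maxDepth, c(8, 5))
  expect_equal(d$start, c(1L, 6L))
  expect_equal(d$end, c(4L, 7L))
  expect_false(any(d$truncated))

  expect_equal(nrow(segmentDives(mkSeries(numeric(10)))), 0)

  tr <- segmentDives(mkSeries(c(1, 1, 0)))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$duration, 2L)
  expect_true(tr$truncated)
})

test_that("segmentDives agrees with a brute-force scan on random series", {
  set.seed(401)
  for (rep in 1:20) {
    n <- sample(c(10, 100, 1000, 10000), 1)
    d <- pmax(0, round(rnorm(n, 1, 4), 1))
    got <- segmentDives(mkSeries(d))
    want <- segmentOracle(d)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$duration, want$duration)
    expect_equal(got$maxDepth, want$maxDepth)
    expect_equal(got$meanDepth, want$meanDepth)
    expect_equal(got$truncated, want$truncated)
  }
})

test_that("depth bins use the operational boundaries", {
  expect_identical(binDive(25), "shallow")
  expect_identical(binDive(30), "medium")
  expect_identical(binDive(90), "medium")
  expect_identical(binDive(96.9), "deep")
  expect_identical(binDive(29.999), "shallow")
  expect_error(binDive(-1))
})

test_that("summarizeDives computes per-bin statistics and proportions", {
  two <- data.frame(start = c(0, 200), end = c(100, 400),
                    duration = c(100, 200), maxDepth = c(10, 20),
                    meanDepth = c(5, 10), bin = c("shallow", "shallow"),
                    truncated = c(FALSE, FALSE))
  s <- summarizeDives(two)
  expect_equal(s$durationMean, 150)
  expect_equal(s$durationSD, sd(c(100, 200)))  # sample SD, 70.71
  expect_equal(s$proportionPct, 100)

  three <- data.frame(start = 1:3, end = 2:4, duration = c(10, 20, 30),
                      maxDepth = c(10, 50, 100), meanDepth = c(5, 25, 50),
                      bin = c("shallow", "medium", "deep"),
                      truncated = FALSE)
  s3 <- summarizeDives(three)
  expect_equal(s3$proportionPct, rep(100 / 3, 3))
  expect_equal(sum(s3$proportionPct), 100, tolerance = 1e-3)
  expect_equal(sum(s3$n), 3)

  expect_error(summarizeDives(two[0, ]), "no dives")
})
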