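test_that("near-surface episodes merge short gaps and match a run-length oracle", {
  cfg <- classifierConfig()
  times <- seq(0, 10, by = 0.05)
  # all far -> none
  none <- nearSurfaceEpisodes(rep(10, length(times)), times, cfg)
  expect_identical(nrow(none), 0L)
  # one block
  d <- rep(10, length(times)); d[10:20] <- 3
  one <- nearSurfaceEpisodes(d, times, cfg)
  expect_identical(nrow(one), 1L)
  expect_equal(one$start_ns, times[10])
  expect_equal(one$end_ns, times[20])
  # 0.1 ns excursion with 0.2 ns gap tolerance -> merged into one episode
  d2 <- rep(10, length(times))
  d2[21:40] <- 3; d2[44:60] <- 3  # gap frames 41:43 = 0.15 ns spacing
  merged <- nearSurfaceEpisodes(d2, times, cfg)
  expect_identical(nrow(merged), 1L)
  expect_equal(merged$startFrame, 21L)
  expect_equal(merged$endFrame, 60L)
  # a 0.5 ns excursion is not merged
  d3 <- rep(10, length(times))
  d3[21:40] <- 3; d3[52:60] <- 3
  expect_identical(nrow(nearSurfaceEpisodes(d3, times, cfg)), 2L)
  expect_error(nearSurfaceEpisodes(numeric(0), numeric(0), cfg), "empty")
})

test_that("episode labelling implements the A / T / RA decision rules", {
  cfg <- classifierConfig()
  times <- seq(0, 20, by = 0.05)
  n <- length(times)
  dist <- rep(3, n)
  mkEp <- function(i1, i2) data.frame(startFrame = i1, endFrame = i2,
                                      start_ns = times[i1],
                                      end_ns = times[i2])
  # 10 ns episode, parallel 95% of frames -> A
  ep <- mkEp(1L, 201L)
  ang <- rep(10, n); ang[seq(1, 201, by = 20)] <- 80  # ~5% tilted
  segA <- labelEpisode(ep, ang, NULL, dist, times, cfg)
  expect_identical(segA$label, "A")
  # 1 ns episode, never parallel -> T
  epT <- mkEp(1L, 21L)
  segT <- labelEpisode(epT, rep(80, n), NULL, dist, times, cfg)
  expect_identical(segT$label, "T")
  expect_false(segT$flagged)
  # long never-parallel episode stays T but is flagged
  segTlong <- labelEpisode(mkEp(1L, 201L), rep(80, n), NULL, dist, times, cfg)
  expect_identical(segTlong$label, "T")
  expect_true(segTlong$flagged)
  # 4 ns episode, parallel 50% -> RA (high fraction but short is also RA)
  ang50 <- rep(c(10, 80), length.out = n)
  expect_identical(labelEpisode(mkEp(1L, 81L), ang50, NULL, dist, times,
                                cfg)$label, "RA")
  expect_identical(labelEpisode(mkEp(1L, 81L), rep(10, n), NULL, dist, times,
                                cfg)$label, "RA")
  # rule table: exhaustive over duration x fraction classes
  for (durFrames in c(21L, 81L, 201L)) {
    for (frac in c(0, 0.5, 1)) {
      angF <- rep(80, n)
      ep <- mkEp(1L, durFrames)
      nPar <- round(frac * durFrames)
      if (nPar > 0) angF[seq_len(nPar)] <- 5
      lab <- labelEpisode(ep, angF, NULL, dist, times, cfg)$label
      dur <- times[durFrames] - times[1]
      expected <- if (dur >= 5 && frac >= 0.8) "A"
        else if (frac < 0.2) "T" else "RA"
      expect_identical(lab, expected)
    }
  }
})

test_that("adsorbed percentage is the union measure over dyes", {
  segs <- data.frame(dye = "R6G_1", np = "SNP1", label = "A",
                     start_ns = 0, end_ns = 31)
  expect_equal(adsorbedPercentage(segs, 100), 31)
  expect_equal(adsorbedPercentage(segs[0, ], 100), 0)
  # overlapping segments from two dyes: union, checked frame-wise
  segs2 <- data.frame(dye = c("R6G_1", "R6G_2", "R6G_1"),
                      np = "SNP1", label = c("A", "RA", "A"),
                      start_ns = c(10, 25, 60), end_ns = c(40, 55, 70))
  times <- seq(0, 100, by = 0.01)
  covered <- rep(FALSE, length(times))
  for (i in 1:3) covered <- covered |
    (times >= segs2$start_ns[i] & times < segs2$end_ns[i])
  expect_equal(adsorbedPercentage(segs2, 100), 100 * mean(covered),
               tolerance = 1e-3)
  # T segments are not counted by default
  segs3 <- rbind(segs2, data.frame(dye = "R6G_3", np = "SNP1", label = "T",
                                   start_ns = 80, end_ns = 90))
  expect_equal(adsorbedPercentage(segs3, 100), adsorbedPercentage(segs2, 100))
  expect_error(adsorbedPercentage(segs, 0), "positive")
})

test_that("repetition averaging rounds half away from zero like the printed tables", {
  expect_identical(averageOverRepetitions(c(3, 21, 12, 0)), 9)
  expect_identical(averageOverRepetitions(c(0, 0, 0, 0)), 0)
  expect_identical(averageOverRepetitions(c(53, 29, 51, 24)), 39)
  expect_identical(averageOverRepetitions(c(31, 20, 21, 18)), 23) # mean 22.5
  expect_identical(averageOverRepetitions(c(30, 24, 28, 48)), 33) # mean 32.5
  expect_equal(averageOverRepetitions(c(1, 2), rounding = FALSE), 1.5)
  expect_error(averageOverRepetitions(numeric(0)), "no repetition")
})

test_that("raising the adsorption threshold never decreases episode time", {
  set.seed(6)
  times <- seq(0, 50, by = 0.05)
  for (rep_ in 1:5) {
    d <- 6 + cumsum(rnorm(length(times), sd = 0.3))
    d <- pmax(abs(d), 0.5)
    prev <- -1
    for (thr in c(3, 5, 8, 12)) {
      cfg <- classifierConfig(adsorptionThreshold = thr)
      eps <- nearSurfaceEpisodes(d, times, cfg)
      tot <- if (nrow(eps)) sum(eps$end_ns - eps$start_ns) else 0
      expect_gte(tot, prev)
      prev <- tot
    }
  }
})

test_that("classifier recovers a scripted ground truth exactly when noise-free", {
  script <- data.frame(
    dye = c("R6G_1", "R6G_2", "R6G_2", "R6G_3"),
    np = "SNP1",
    label = c("A", "T", "RA", "A"),
    start_ns = c(12, 3, 10, 0),
    end_ns = c(30, 4, 14, 8))
  sim <- scriptedSim(stateIntervals = script, nDye = 3, duration = 30,
                     timestep = 0.02, seed = 9)
  np <- staticNp(nFrames(sim$trajectory))
  metrics <- trajectoryMetrics(sim$trajectory, paste0("R6G_", 1:3),
                               list(SNP1 = np))
  segs <- classifyStates(metrics)
  dt <- 0.02
  expect_identical(nrow(segs), nrow(script))
  for (i in seq_len(nrow(script))) {
    hit <- segs[segs$dye == script$dye[i] &
                  abs(segs$start_ns - script$start_ns[i]) <= dt, ]
    expect_identical(nrow(hit), 1L)
    expect_identical(hit$label, script$label[i])
    expect_lte(abs(hit$end_ns - script$end_ns[i]), dt * 1.001)
  }
  # frame-level agreement is exact
  times <- frameTimes(sim$trajectory)
  for (d in paste0("R6G_", 1:3)) {
    expect_identical(frameLabels(segs, times, d),
                     truthFrameLabels(sim$groundTruth@stateIntervals,
                                      times, d))
  }
})

test_that("classifier agreement stays above 95% under 0.5 A positional noise", {
  script <- data.frame(
    dye = c("R6G_1", "R6G_2"), np = "SNP1", label = c("A", "RA"),
    start_ns = c(10, 4), end_ns = c(28, 9))
  sim <- scriptedSim(stateIntervals = script, nDye = 2, duration = 30,
                     timestep = 0.02, noiseSd = 0.5, seed = 13)
  np <- staticNp(nFrames(sim$trajectory))
  metrics <- trajectoryMetrics(sim$trajectory, paste0("R6G_", 1:2),
                               list(SNP1 = np))
  segs <- classifyStates(metrics)
  times <- frameTimes(sim$trajectory)
  agree <- vapply(paste0("R6G_", 1:2), function(d) {
    mean(frameLabels(segs, times, d) ==
           truthFrameLabels(sim$groundTruth@stateIntervals, times, d))
  }, numeric(1))
  expect_gte(min(agree), 0.95)
})
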