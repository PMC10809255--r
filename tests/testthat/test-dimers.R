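# brute-force exclusive assignment oracle for one frame: enumerate all
# matchings of contacting pairs, keep the one minimizing total core distance
bruteAssign <- function(contact, dist) {
  nd <- nrow(contact)
  pairs <- which(upper.tri(contact) & contact, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(matrix(integer(0), 0, 2))
  best <- NULL; bestCost <- Inf
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), nrow(pairs)))
  for (s in seq_len(nrow(subsets))) {
    sel <- which(unlist(subsets[s, ]))
    used <- as.vector(pairs[sel, , drop = FALSE])
    if (anyDuplicated(used)) next
    cost <- -length(sel) * 1e6 +
      sum(dist[pairs[sel, , drop = FALSE]])
    if (cost < bestCost) { bestCost <- cost; best <- pairs[sel, , drop = FALSE] }
  }
  best
}

test_that("dimer detection finds scripted events and nothing else", {
  # dyes never within cutoff -> no events
  simFar <- scriptedSim(nDye = 3, duration = 5, timestep = 0.05, seed = 21)
  fdFar <- dimerFrameData(simFar$trajectory, paste0("R6G_", 1:3))
  expect_identical(nrow(detectDimers(fdFar)), 0L)

  # scripted dimer from 36 to 80 ns -> one ~44 ns event
  ev <- data.frame(dye_a = "R6G_1", dye_b = "R6G_2", start_ns = 36,
                   end_ns = 80, location = "solute")
  sim <- scriptedSim(dimerEvents = ev, nDye = 3, duration = 100,
                     timestep = 0.05, seed = 22)
  fd <- dimerFrameData(sim$trajectory, paste0("R6G_", 1:3),
                       np = staticNp(nFrames(sim$trajectory)))
  got <- detectDimers(fd)
  expect_identical(nrow(got), 1L)
  expect_identical(got$dye_a, "R6G_1")
  expect_equal(got$start_ns, 36, tolerance = 0.06)
  expect_equal(got$end_ns - got$start_ns, 44, tolerance = 0.11)

  # exclusivity: events from per-frame greedy matching agree with the
  # brute-force exhaustive assignment on every frame of a stacked triple
  cfg <- dimerConfig(minDimerDuration = 0.5)
  nf <- 40
  times <- (seq_len(nf) - 1) * 0.05
  coreCom <- array(0, c(nf, 3, 3))
  normals <- array(0, c(nf, 3, 3))
  for (f in seq_len(nf)) {
    # three cores in a row, spacing 3.4 and 3.8: pairwise stacked, one
    # shared middle dye
    coreCom[f, , ] <- rbind(c(0, 0, 0), c(3.4, 0, 0), c(7.2, 0, 0))
    normals[f, , ] <- rbind(c(1, 0, 0), c(-1, 0, 0), c(1, 0, 0))
  }
  fd3 <- list(times = times, coreCom = coreCom, normals = normals,
              dyes = paste0("R6G_", 1:3), np = NULL, surfDist = NULL)
  got3 <- detectDimers(fd3, cfg)
  expect_identical(nrow(got3), 1L)   # only the closest pair dimerizes
  expect_identical(c(got3$dye_a, got3$dye_b), c("R6G_1", "R6G_2"))
  contact <- matrix(FALSE, 3, 3); dist <- matrix(Inf, 3, 3)
  contact[1, 2] <- contact[2, 1] <- TRUE; dist[1, 2] <- dist[2, 1] <- 3.4
  contact[2, 3] <- contact[3, 2] <- TRUE; dist[2, 3] <- dist[3, 2] <- 3.8
  expect_identical(unname(bruteAssign(contact, dist)),
                   matrix(c(1L, 2L), 1, 2))
})

test_that("no dye belongs to two simultaneous dimer events", {
  sim <- scriptedSim(
    dimerEvents = data.frame(dye_a = c("R6G_1", "R6G_3"),
                             dye_b = c("R6G_2", "R6G_4"),
                             start_ns = c(5, 10), end_ns = c(15, 20),
                             location = "solute"),
    nDye = 4, duration = 25, timestep = 0.05, seed = 23)
  fd <- dimerFrameData(sim$trajectory, paste0("R6G_", 1:4))
  got <- detectDimers(fd)
  expect_identical(nrow(got), 2L)
  for (f in seq_along(fd$times)) {
    active <- got[got$startFrame <= f & got$endFrame >= f, ]
    members <- c(active$dye_a, active$dye_b)
    expect_identical(anyDuplicated(members), 0L)
  }
  # total dimer time per run <= trajectory length * floor(n_dyes / 2)
  expect_lte(sum(got$end_ns - got$start_ns),
             (max(fd$times) - min(fd$times)) * 2)
})

test_that("transient trimers are detected around dimer events", {
  # no third contact -> empty
  ev <- data.frame(dye_a = "R6G_1", dye_b = "R6G_2", start_ns = 2,
                   end_ns = 8, location = "solute")
  sim <- scriptedSim(dimerEvents = ev, nDye = 3, duration = 10,
                     timestep = 0.05, seed = 24)
  fd <- dimerFrameData(sim$trajectory, paste0("R6G_", 1:3))
  events <- detectDimers(fd)
  expect_identical(nrow(detectTrimers(events, fd)), 0L)

  # scripted 5 ns triple contact: place a third core stacked on dye 2
  # for 5 ns inside the event window
  ia <- match("R6G_3", fd$dyes)
  ib <- match("R6G_2", fd$dyes)
  sel <- which(fd$times >= 3 & fd$times < 8)
  fd2 <- fd
  for (f in sel) {
    # stacked on dye 2 but slightly farther than the 1-2 pair distance, so
    # exclusivity keeps the original dimer intact
    fd2$coreCom[f, ia, ] <- fd$coreCom[f, ib, ] + c(0, 0, 3.6)
    fd2$normals[f, ia, ] <- c(0, 0, 1)
    fd2$normals[f, ib, ] <- c(0, 0, -1)
  }
  # keep the original pair stacked: normals of 1 and 2 must still match
  fd2$normals[sel, match("R6G_1", fd$dyes), ] <-
    matrix(c(0, 0, 1), length(sel), 3, byrow = TRUE)
  events2 <- detectDimers(fd2)
  tri <- detectTrimers(events2, fd2)
  expect_gte(nrow(tri), 1L)
  expect_true(all(tri$transient))
  expect_equal(max(tri$end_ns) - min(tri$start_ns), 5, tolerance = 0.11)
})

test_that("event classification assigns location and end reason", {
  # censored: event reaching the final frame
  evC <- data.frame(dye_a = "R6G_1", dye_b = "R6G_2", start_ns = 10,
                    end_ns = 20, location = "solute")
  simC <- scriptedSim(dimerEvents = evC, nDye = 2, duration = 20,
                      timestep = 0.05, seed = 25)
  fdC <- dimerFrameData(simC$trajectory, paste0("R6G_", 1:2),
                        np = staticNp(nFrames(simC$trajectory)))
  gotC <- classifyEvents(detectDimers(fdC), fdC)
  expect_identical(gotC$end_reason, "censored")
  expect_identical(gotC$location, "solute")

  # matrix dimer that breaks near the surface, partner adsorbs within 1 ns
  evD <- data.frame(dye_a = "R6G_1", dye_b = "R6G_2", start_ns = 5,
                    end_ns = 12, location = "matrix")
  st <- data.frame(dye = "R6G_1", np = "SNP1", label = "A", start_ns = 12.2,
                   end_ns = 20)
  simD <- scriptedSim(stateIntervals = st, dimerEvents = evD, nDye = 2,
                      duration = 20, timestep = 0.05, seed = 26)
  npD <- staticNp(nFrames(simD$trajectory))
  fdD <- dimerFrameData(simD$trajectory, paste0("R6G_", 1:2), np = npD)
  metricsD <- trajectoryMetrics(simD$trajectory, paste0("R6G_", 1:2),
                                list(SNP1 = npD))
  segsD <- classifyStates(metricsD)
  gotD <- classifyEvents(detectDimers(fdD), fdD, segsD)
  expect_identical(gotD$location, "matrix")
  expect_identical(gotD$end_reason, "dissociation")
  expect_true(gotD$adsorption_followed)

  # intact pair leaving the surface -> desorption
  evE <- data.frame(dye_a = "R6G_1", dye_b = "R6G_2", start_ns = 5,
                    end_ns = 15, location = "matrix",
                    script_desorb = TRUE)
  simE <- scriptedSim(dimerEvents = evE, nDye = 2, duration = 20,
                      timestep = 0.05, seed = 27)
  fdE <- dimerFrameData(simE$trajectory, paste0("R6G_", 1:2),
                        np = staticNp(nFrames(simE$trajectory)))
  gotE <- classifyEvents(detectDimers(fdE), fdE)
  expect_identical(gotE$end_reason, "desorption")
  expect_identical(gotE$location, "matrix")
})

test_that("dimer statistics implement the count / total / pooled-lifetime means", {
  none <- data.frame(run = integer(0), start_ns = numeric(0),
                     end_ns = numeric(0))
  expect_equal(unlist(dimerStatistics(none, runs = 1:2)), c(
    mean_dimer_count = 0, total_time_ns = 0, mean_lifetime_ns = 0))
  one <- data.frame(run = c(1, 1), start_ns = c(0, 50), end_ns = c(10, 70))
  got <- dimerStatistics(one, runs = 1)
  expect_equal(got$mean_dimer_count, 2)
  expect_equal(got$total_time_ns, 30)
  expect_equal(got$mean_lifetime_ns, 15)
  # single run: lifetime x count equals total time exactly
  expect_equal(got$mean_lifetime_ns * got$mean_dimer_count, got$total_time_ns)
  # four runs scripted to mean count 4.75
  four <- data.frame(run = rep(1:4, c(5, 4, 5, 5)))
  four$start_ns <- 0; four$end_ns <- 10
  expect_equal(dimerStatistics(four, runs = 1:4)$mean_dimer_count, 4.75)
})
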