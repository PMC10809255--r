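test_that("topology round-trips through PDB + sidecar and rejects bad input", {
  top <- toyTopology()
  pdb <- file.path(withr::local_tempdir(), "toy.pdb")
  writeTopology(top, toyFrame(), pdb)
  got <- readTopology(pdb)
  expect_identical(nParticles(got), 9L)
  expect_setequal(groupNames(got), groupNames(top))
  expect_equal(masses(got), masses(top))
  expect_equal(charges(got), charges(top), tolerance = 1e-6)
  expect_identical(groupMembers(got, "R6G_1_core"),
                   groupMembers(top, "R6G_1_core"))

  expect_error(readTopology(file.path(tempdir(), "nope.pdb")), "not found")

  # duplicate ids in the sidecar
  sc <- utils::read.delim(paste0(pdb, ".tsv"))
  sc$particle_id[2] <- sc$particle_id[1]
  bad <- file.path(withr::local_tempdir(), "bad.tsv")
  utils::write.table(sc, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readTopology(pdb, sidecar = bad), "duplicate")

  # core group referencing a particle outside its parent dye
  expect_error(
    topology(0:8, rep(1, 9), rep(0, 9),
             groups = list(R6G_1 = 4:8, R6G_1_core = c(3L, 4L))),
    "not a subset")
})

test_that("synthetic fixture topology has one group per body plus cores", {
  sim <- scriptedSim(nDye = 6, duration = 1, timestep = 0.5,
                     dyeSiteCount = 64)
  # 6 dyes + 6 cores + 1 nanoparticle
  expect_length(groupNames(sim$topology), 13L)
  expect_length(groupMembers(sim$topology, "R6G_1"), 64L)
  expect_length(groupMembers(sim$topology, "R6G_1_core"), 30L)
})

test_that("trajectory table round-trips bit-identically at stored precision", {
  sim <- scriptedSim(nDye = 2, duration = 10, timestep = 0.05,
                     dyeSiteCount = 8, seed = 3)
  traj <- sim$trajectory
  traj@coords <- round(traj@coords, 4)  # stored precision
  td <- withr::local_tempdir()
  p1 <- file.path(td, "traj.tsv")
  writeTrajectory(traj, p1)
  back <- readTrajectory(p1, sim$topology)
  expect_identical(back@coords, traj@coords)
  expect_lt(max(abs(frameTimes(back) - frameTimes(traj))), 5e-7)
  p2 <- file.path(td, "traj2.tsv")
  writeTrajectory(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("trajectory reader rejects malformed input instead of repairing it", {
  top <- toyTopology()
  td <- withr::local_tempdir()
  oneFrame <- data.frame(frame = 0L, time_ns = "0.000000",
                         particle_id = 0:8,
                         x = sprintf("%.4f", toyFrame()[, 1]),
                         y = sprintf("%.4f", toyFrame()[, 2]),
                         z = sprintf("%.4f", toyFrame()[, 3]))
  p <- file.path(td, "one.tsv")
  utils::write.table(oneFrame, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  got <- readTrajectory(p, top)
  expect_identical(nFrames(got), 1L)

  # non-monotone times (0, 1, 1 ns)
  three <- do.call(rbind, lapply(0:2, function(f) {
    d <- oneFrame; d$frame <- f
    d$time_ns <- sprintf("%.6f", c(0, 1, 1)[f + 1])
    d
  }))
  pBad <- file.path(td, "bad_times.tsv")
  utils::write.table(three, pBad, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(readTrajectory(pBad, top), "strictly increasing")

  # particle-count mismatch vs topology
  pShort <- file.path(td, "short.tsv")
  utils::write.table(oneFrame[1:5, ], pShort, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(readTrajectory(pShort, top), "does not match")
})

test_that("result tables have deterministic schemas and an average row", {
  td <- withr::local_tempdir()
  # empty segment list -> header-only file
  p <- file.path(td, "empty.tsv")
  writeResultTable(classifyStates(data.frame(
    time_ns = 0, dye = "R6G_1", np = "SNP1", surface_dist_A = 10,
    parallel_angle_deg = 0, theta_deg = 90))[0, ], p, "segments")
  lines <- readLines(p)
  expect_length(lines, 1L)
  expect_match(lines, "^dye\tnp\tlabel\tstart_ns")

  # one segment -> one data row
  seg <- data.frame(dye = "R6G_1", np = "SNP1", label = "A", start_ns = 63,
                    end_ns = 100, mean_surface_distance_A = 2.5,
                    parallel_fraction = 0.97, mean_theta_deg = 129,
                    flagged = FALSE)
  p1 <- file.path(td, "one.tsv")
  writeResultTable(seg, p1, "segments")
  expect_length(readLines(p1), 2L)

  # repetition-by-system matrix gains an appended integer average row
  p2 <- file.path(td, "reps.tsv")
  writeResultTable(printedAdsorbedRepetitions(), p2, "adsorption_summary")
  back <- utils::read.delim(p2, check.names = FALSE)
  expect_identical(nrow(back), 5L)
  expect_identical(back$repetition[5], "average")
  expect_identical(as.integer(back[5, -1]),
                   c(23L, 9L, 33L, 4L, 39L, 9L, 33L, 6L))

  expect_error(writeResultTable(seg, file.path(td, "x.tsv"), "nope"),
               "unregistered schema")
})
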