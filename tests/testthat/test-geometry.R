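test_that("center of mass matches the brute-force weighted mean", {
  top <- topology(0:2, mass = c(1, 2, 3), charge = rep(0, 3),
                  groups = list(g = 0:2, one = 0L, pair = 0:1))
  fr <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(centerOfMass(top, fr, "one"), c(1, 0, 0))
  # equal masses, symmetric pair
  topEq <- topology(0:1, c(1, 1), c(0, 0), groups = list(p = 0:1))
  expect_equal(centerOfMass(topEq, rbind(c(-1, 0, 0), c(1, 0, 0)), "p"),
               c(0, 0, 0))
  # oracle: explicit sum
  expect_equal(centerOfMass(top, fr, "g"),
               (1 * fr[1, ] + 2 * fr[2, ] + 3 * fr[3, ]) / 6)
  expect_error(centerOfMass(top, fr, "unknown"), "unknown group")
})

test_that("surface distance is the radial norm minus the radius", {
  np <- staticNp(1, radius = 20)
  expect_equal(surfaceDistance(c(25, 0, 0), np), 5)
  expect_equal(surfaceDistance(c(0, 0, 0), np), -20)
  set.seed(1)
  for (i in 1:20) {
    p <- rnorm(3, sd = 30)
    expect_equal(surfaceDistance(p, np), sqrt(sum(p^2)) - 20)
  }
})

test_that("core-plane normal is rotation-equivariant and rejects degenerate cores", {
  sq <- rbind(c(1, 1, 0), c(-1, 1, 0), c(-1, -1, 0), c(1, -1, 0))
  top <- topology(0:3, rep(1, 4), rep(0, 4), groups = list(core = 0:3))
  n0 <- corePlaneNormal(top, sq, "core")
  expect_equal(abs(n0), c(0, 0, 1))
  set.seed(2)
  for (i in 1:10) {
    R <- randomRotation()
    n <- corePlaneNormal(top, sq %*% t(R), "core")
    expected <- as.numeric(R %*% c(0, 0, 1))
    expect_equal(abs(sum(n * expected)), 1, tolerance = 1e-9)
  }
  # sign convention follows the supplied radial direction
  nUp <- corePlaneNormal(top, sq, "core", radial = c(0.1, 0, 1))
  expect_gt(nUp[3], 0)
  nDown <- corePlaneNormal(top, sq, "core", radial = c(0, 0, -1))
  expect_lt(nDown[3], 0)
  # collinear points
  line <- cbind(1:4, 0, 0)
  expect_error(corePlaneNormal(top, line, "core"), "collinear")
  top2 <- topology(0:1, c(1, 1), c(0, 0), groups = list(core = 0:1))
  expect_error(corePlaneNormal(top2, sq[1:2, ], "core"), "at least 3")
})

test_that("parallelism angle folds to [0, 90] and matches the arccos oracle", {
  expect_equal(parallelismAngle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(parallelismAngle(c(1, 0, 0), c(0, 0, 1)), 90)
  expect_equal(parallelismAngle(c(0, 0, -1), c(0, 0, 1)), 0)  # folded
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    raw <- acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
    expect_equal(parallelismAngle(a, b), min(raw, 180 - raw))
  }
  expect_error(parallelismAngle(c(0, 0, 0), c(0, 0, 1)), "zero vector")
})

test_that("dipole moment follows the charge sum and the Debye conversion", {
  top <- topology(0:1, c(1, 1), c(1, -1), groups = list(d = 0:1))
  fr <- rbind(c(1, 0, 0), c(-1, 0, 0))
  dip <- dipoleMoment(top, fr, "d", reference = c(0, 0, 0))
  expect_equal(dip@components, c(2, 0, 0))
  expect_equal(dip@magnitudeDebye, 9.6064)
  expect_equal(dip@netCharge, 0)
  # all charges zero -> zero vector
  top0 <- topology(0:1, c(1, 1), c(0, 0), groups = list(d = 0:1))
  expect_equal(dipoleMoment(top0, fr, "d")@components, c(0, 0, 0))
})

test_that("reference-shift identity: neutral dipoles invariant, charged shift by -q t", {
  set.seed(4)
  for (i in 1:10) {
    n <- 6
    q <- rnorm(n)
    if (i %% 2 == 0) q <- q - mean(q)  # net neutral
    top <- topology(0:(n - 1), rep(1, n), q, groups = list(g = 0:(n - 1)))
    fr <- matrix(rnorm(3 * n, sd = 5), n, 3)
    t <- rnorm(3)
    d1 <- dipoleMoment(top, fr, "g", reference = c(0, 0, 0))
    d2 <- dipoleMoment(top, fr, "g", reference = t)
    # exact algebraic law: shifting the reference by t changes the dipole
    # by -q_net * t
    expect_equal(d2@components - d1@components, -sum(q) * t,
                 tolerance = 1e-10)
    if (abs(sum(q)) < 1e-12)
      expect_equal(d2@components, d1@components, tolerance = 1e-10)
  }
})

test_that("dipole angle theta reproduces ideal geometries", {
  mk <- function(v) new("DipoleVector", components = v,
                        magnitudeDebye = 4.8032 * sqrt(sum(v^2)),
                        referencePoint = c(0, 0, 0), netCharge = 0)
  expect_equal(dipoleAngleTheta(mk(c(0, 0, 1)), mk(c(0, 0, -2))), 180)
  expect_equal(dipoleAngleTheta(mk(c(1, 0, 0)), mk(c(0, 1, 0))), 90)
  expect_error(dipoleAngleTheta(mk(c(0, 0, 0)), mk(c(1, 0, 0))), "zero dipole")
})

test_that("COM, distances and angles are translation-invariant and rotation-equivariant", {
  top <- toyTopology()
  fr <- toyFrame()
  set.seed(5)
  for (i in 1:5) {
    shift <- rnorm(3, sd = 10)
    R <- randomRotation()
    frT <- sweep(fr, 2, -shift)  # translated
    frR <- fr %*% t(R)           # rotated
    com <- centerOfMass(top, fr, "R6G_1")
    expect_equal(centerOfMass(top, frT, "R6G_1"), com + shift)
    expect_equal(centerOfMass(top, frR, "R6G_1"), as.numeric(R %*% com))
    # parallelism angle invariant under rigid motion of the whole frame
    radial <- com - c(0, 0, 0)
    n1 <- corePlaneNormal(top, fr, "R6G_1_core", radial = radial)
    n2 <- corePlaneNormal(top, frR, "R6G_1_core",
                          radial = as.numeric(R %*% radial))
    expect_equal(parallelismAngle(n1, radial),
                 parallelismAngle(n2, as.numeric(R %*% radial)),
                 tolerance = 1e-9)
    # neutral-group dipole rotates with the frame
    qn <- charges(top); qn <- qn - mean(qn)
    topN <- topology(0:8, masses(top), qn, groups = top@groups)
    d <- dipoleMoment(topN, fr, "R6G_1")@components
    dR <- dipoleMoment(topN, frR, "R6G_1")@components
    expect_equal(dR, as.numeric(R %*% d), tolerance = 1e-9)
    dT <- dipoleMoment(topN, frT, "R6G_1")@components
    expect_equal(dT, d, tolerance = 1e-9)
  }
})
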