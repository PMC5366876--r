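test_that("default geometry reproduces the setup arithmetic", {
  g <- nucleusGeometry()
  expect_equal(fluence(g), 0.0625)
  expect_equal(g@scoringDiameter, 14.22)
  # the scoring sphere encloses the rotated source disc
  rdisc <- sqrt(g@sourceArea / pi)
  expect_lt(sqrt(rdisc^2 + (g@nucleusDiameter / 2)^2),
            g@scoringDiameter / 2)
  expect_error(nucleusGeometry(scoringDiameter = 9), "exceed")
})

test_that("run frames have parallel primaries and proper rotations", {
  g <- nucleusGeometry()
  set.seed(21)
  for (i in 1:10) {
    f <- makeRun(g)
    R <- f$rotation
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    expect_equal(sum(f$direction^2), 1, tolerance = 1e-12)
    # all starts lie on the rotated tangent plane, inside the disc
    p0 <- f$starts %*% f$rotation               # back to beam frame
    expect_equal(unname(p0[, 3]), rep(-5, 5), tolerance = 1e-9)
    expect_true(all(p0[, 1]^2 + p0[, 2]^2 <= g@sourceArea / pi + 1e-9))
  }
})

test_that("disc start positions are uniform over the source area", {
  g <- nucleusGeometry()
  set.seed(22)
  pts <- do.call(rbind, replicate(800, {
    f <- makeRun(g); (f$starts %*% f$rotation)[, 1:2]
  }, simplify = FALSE))
  # radius^2 of a uniform disc is uniform: chi-square over deciles
  r2 <- (pts[, 1]^2 + pts[, 2]^2) / (g@sourceArea / pi)
  ct <- table(cut(r2, seq(0, 1, 0.1)))
  p <- stats::chisq.test(ct)$p.value
  expect_gt(p, 0.001)
})

test_that("dose conversion matches the hand-derived unit oracle", {
  d <- data.frame(x = 0, y = 0, z = 0, energy = 1000)
  expect_equal(doseFromDeposits(d, 1), oracleDose(1000, 1), tolerance = 1e-12)
  expect_equal(doseFromDeposits(d, 1), 0.1602, tolerance = 1e-3)
  # linearity and empty region
  d2 <- d; d2$energy <- 2000
  expect_equal(doseFromDeposits(d2, 1), 2 * doseFromDeposits(d, 1))
  expect_equal(doseFromDeposits(d[0, ], 1), 0)
  far <- data.frame(x = 10, y = 0, z = 0, energy = 500)
  expect_equal(doseFromDeposits(far, 1, radius = 5), 0)
})

test_that("the dose-fluence LET relation round-trips", {
  expect_equal(letFromDoseFluence(1.0015, 0.0625), 100, tolerance = 2e-4)
  expect_equal(letFromDoseFluence(0, 0.0625), 0)
  for (let in c(0.2, 10, 870))
    expect_equal(letFromDoseFluence(doseFromLetFluence(let, 0.0625), 0.0625),
                 let, tolerance = 1e-12)
  expect_error(letFromDoseFluence(1, 0), "positive")
})

test_that("spherical-cap volume matches the closed form", {
  g <- nucleusGeometry()
  r <- 5
  expect_equal(capVolume(g, r), 2 / 3 * pi * r^3)          # half sphere
  expect_equal(capVolume(g, 10), 4 / 3 * pi * r^3)          # full sphere
  expect_equal(capVolume(g, 12), 4 / 3 * pi * r^3)
  h <- 3.8
  expect_equal(capVolume(g, h), pi * h^2 * (3 * r - h) / 3) # cap formula
})

test_that("slab profile closes energy and is flat for uniform deposits", {
  g <- nucleusGeometry()
  dep <- generateFixture("uniform_deposits", seed = 23, n = 40000)
  sp <- slabProfile(dep, g)
  inNuc <- dep$x^2 + dep$y^2 + dep$z^2 <= 25
  expect_equal(sum(sp$energy_eV), sum(dep$energy[inNuc]), tolerance = 1e-9)
  # uniform density -> LET profile flat across central slabs
  mid <- sp$let[10:40]
  expect_lt(max(abs(mid / mean(mid) - 1)), 0.15)
  expect_equal(sum(sp$volume), 4 / 3 * pi * 125, tolerance = 1e-6)
})

test_that("slab LET of a slow carbon beam shows the Bragg shape", {
  g <- nucleusGeometry()
  dep <- generateFixture("bragg_deposits", seed = 24, n = 100000)
  sp <- slabProfile(dep, g)              # run fluence: 5 primaries / 80 um^2
  pk <- which.max(sp$let[3:48]) + 2L     # edge slabs carry little volume
  expect_gt(pk, 5)                       # rises towards the Bragg maximum
  expect_gt(sp$let[pk], 1.1 * sp$let[3])
  expect_lt(sp$let[48], sp$let[pk] / 5)  # falls off beyond stopping depth
  smax <- max(scaledStopping("C", exp(seq(log(0.01), log(0.5), length.out = 300))))
  expect_equal(sp$let[pk], smax, tolerance = 0.15)
})

test_that("damage statistics are invariant under a fixed extra source rotation", {
  # rotating the whole frame leaves radial dose scoring unchanged
  g <- nucleusGeometry()
  set.seed(25)
  f <- makeRun(g)
  bt <- defaultBaseline()
  set.seed(26)
  tr <- simulateTrack("He", 0.5, f$starts[1, ], f$direction, bt)
  d1 <- doseFromDeposits(tr@deposits, capVolume(g, computeRange("He", 0.5, bt)),
                         radius = 5)
  R <- f$rotation
  dep2 <- tr@deposits
  rot <- as.matrix(dep2[, c("x", "y", "z")]) %*% R   # extra rigid rotation
  dep2$x <- rot[, 1]; dep2$y <- rot[, 2]; dep2$z <- rot[, 3]
  d2 <- doseFromDeposits(dep2, capVolume(g, computeRange("He", 0.5, bt)),
                         radius = 5)
  expect_equal(d1, d2, tolerance = 1e-12)
})
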