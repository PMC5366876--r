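test_that("model occupancy matches the volumetric arithmetic", {
  m <- testModel()
  nVox <- length(m@voxelKey)
  expect_equal(nVox * m@bpPerVoxel, m@genomeLength, tolerance = 1e-4)
  # every occupied grid cell points back to exactly one walk voxel
  occ <- m@occupancy[m@occupancy > 0L]
  expect_equal(sort(occ), seq_len(nVox))
  expect_equal(sum(m@chromLengths), m@genomeLength)
  # at full scale the defaults give an occupied fraction of ~0.28:
  # (6.4e9 / 5500) voxels over the ~4.19e6 voxels of the 10 um sphere
  sphereVox <- 4 / 3 * pi * 5^3 / 0.05^3
  expect_equal((6.4e9 / 5500) / sphereVox, 0.278, tolerance = 0.01)
})

test_that("every position in an occupied voxel maps to exactly one group", {
  m <- testModel()
  key <- m@voxelKey[c(10L, 500L, 2000L)]
  G <- m@gridDim; v <- m@voxelSize; rn <- G * v / 2
  cx <- ((key - 1) %% G + 0.5) * v - rn
  cy <- (((key - 1) %/% G) %% G + 0.5) * v - rn
  cz <- ((key - 1) %/% (G * G) + 0.5) * v - rn
  w <- IonTrackDamage:::.positionToVoxel(m, cx, cy, cz)
  expect_identical(w, c(10L, 500L, 2000L))
  loc1 <- IonTrackDamage:::.voxelBp(m, w, cx, cy, cz)
  loc2 <- IonTrackDamage:::.voxelBp(m, w, cx, cy, cz)
  expect_identical(loc1, loc2)                     # deterministic mapping
  expect_true(all(loc1$pos >= 1 &
                    loc1$pos <= m@chromLengths[loc1$chromosome]))
})

test_that("two seeds give different walks with identical genome coverage", {
  g <- nucleusGeometry()
  set.seed(1); m1 <- buildNucleusModel(g, genomeLength = 5e7)
  set.seed(2); m2 <- buildNucleusModel(g, genomeLength = 5e7)
  expect_false(identical(m1@voxelKey, m2@voxelKey))
  expect_identical(length(m1@voxelKey), length(m2@voxelKey))
  expect_identical(m1@chromLengths, m2@chromLengths)
  expect_identical(m1@bpStart, m2@bpStart)
})

test_that("the direct strand-break ramp has the stated endpoints", {
  expect_equal(directSbProbability(0), 0)
  expect_equal(directSbProbability(5), 0)
  expect_equal(directSbProbability(21.25), 0.5)
  expect_equal(directSbProbability(37.5), 1)
  expect_equal(directSbProbability(100), 1)
  e <- seq(5, 37.5, length.out = 20)
  expect_equal(directSbProbability(e), (e - 5) / 32.5)
})

test_that("a saturating deposit on a group breaks it exactly once", {
  m <- testModel()
  key <- m@voxelKey[123L]
  G <- m@gridDim; v <- m@voxelSize; rn <- G * v / 2
  cx <- ((key - 1) %% G + 0.5) * v - rn
  cy <- (((key - 1) %/% G) %% G + 0.5) * v - rn
  cz <- ((key - 1) %/% (G * G) + 0.5) * v - rn
  dep <- data.frame(x = cx, y = cy, z = cz, energy = 40, track_id = 1L)
  set.seed(31)
  b <- depositsToDirectBreaks(dep, m, damageParams(f_dna = 1))
  expect_identical(nrow(b), 1L)
  expect_identical(b$origin, "direct")
  # no deposits in occupied voxels -> no breaks
  none <- depositsToDirectBreaks(
    data.frame(x = 20, y = 20, z = 20, energy = 40, track_id = 1L),
    m, damageParams(f_dna = 1))
  expect_identical(nrow(none), 0L)
})

test_that("sub-threshold deposits accumulate on the group before breaking", {
  m <- testModel()
  key <- m@voxelKey[321L]
  G <- m@gridDim; v <- m@voxelSize; rn <- G * v / 2
  cx <- ((key - 1) %% G + 0.5) * v - rn
  cy <- (((key - 1) %/% G) %% G + 0.5) * v - rn
  cz <- ((key - 1) %/% (G * G) + 0.5) * v - rn
  # many independent groups, each receiving two 15 eV deposits at the
  # same point: the accumulated 30 eV breaks with p = (30 - 5)/32.5
  n <- 20000
  keys <- m@voxelKey[seq_len(n)]
  cx <- ((keys - 1) %% G + 0.5) * v - rn
  cy <- (((keys - 1) %/% G) %% G + 0.5) * v - rn
  cz <- ((keys - 1) %/% (G * G) + 0.5) * v - rn
  dep2 <- data.frame(x = rep(cx, 2), y = rep(cy, 2), z = rep(cz, 2),
                     energy = 15, track_id = 1L)
  set.seed(32)
  hits <- nrow(depositsToDirectBreaks(dep2, m, damageParams(f_dna = 1)))
  p <- 25 / 32.5
  expect_lt(abs(hits / n - p), 4 * sqrt(p * (1 - p) / n))
  # a single 15 eV deposit per group alone: p = 10/32.5
  dep1 <- dep2[seq_len(n), ]
  set.seed(33)
  h1 <- nrow(depositsToDirectBreaks(dep1, m, damageParams(f_dna = 1)))
  p1 <- 10 / 32.5
  expect_lt(abs(h1 / n - p1), 4 * sqrt(p1 * (1 - p1) / n))
})

test_that("SB to DSB conversion is a binomial thinning with opposite partners", {
  br <- data.frame(chromosome = 1L, pos = seq(1, by = 100, length.out = 1e5),
                   strand = "+", origin = "direct", track_id = 1L)
  set.seed(34)
  out <- convertSbToDsb(br, 0.01)
  conv <- out[out$origin == "converted", ]
  expect_equal(nrow(out) - nrow(br), nrow(conv))
  expect_lt(abs(nrow(conv) - 1000), 3 * sqrt(1000))
  expect_true(all(conv$strand == "-"))
  expect_true(all(conv$pos %in% br$pos))
  expect_identical(convertSbToDsb(br, 0), br)
})

test_that("the hydroxyl surrogate honours its stated probabilities", {
  m <- testModel()
  # radicals seeded around chromatin voxels; inflated p_deoxy for statistics
  set.seed(35)
  n <- 6000
  G <- m@gridDim; v <- m@voxelSize; rn <- G * v / 2
  keys <- sample(m@voxelKey, n, replace = TRUE)
  dep <- data.frame(
    x = ((keys - 1) %% G + 0.5) * v - rn + stats::runif(n, -0.1, 0.1),
    y = (((keys - 1) %/% G) %% G + 0.5) * v - rn + stats::runif(n, -0.1, 0.1),
    z = ((keys - 1) %/% (G * G) + 0.5) * v - rn + stats::runif(n, -0.1, 0.1),
    energy = 30, track_id = rep(1:50, length.out = n))
  pars <- damageParams(p_oh = 1, p_deoxy = 0.3, k_max = 1000L)
  b <- indirectBreaks(dep, m, pars)
  enc <- attr(b, "encounters")
  expect_gt(enc, 200)
  expect_lt(abs(nrow(b) / enc - 0.65), 4 * sqrt(0.65 * 0.35 / enc))
  # p_oh = 0 -> no indirect breaks
  b0 <- indirectBreaks(dep, m, damageParams(p_oh = 0))
  expect_identical(nrow(b0), 0L)
})

test_that("concentrated deposits yield fewer indirect breaks than dispersed", {
  m <- testModel()
  # same number and energy of deposits: spread out vs piled into one spot
  key <- m@voxelKey[50L]
  G <- m@gridDim; v <- m@voxelSize; rn <- G * v / 2
  cx <- ((key - 1) %% G + 0.5) * v - rn
  cy <- (((key - 1) %/% G) %% G + 0.5) * v - rn
  cz <- ((key - 1) %/% (G * G) + 0.5) * v - rn
  n <- 3000
  set.seed(36)
  r <- 4.5 * stats::runif(n)^(1 / 3)
  u <- matrix(stats::rnorm(3 * n), n, 3); u <- u / sqrt(rowSums(u^2))
  disp <- data.frame(x = r * u[, 1], y = r * u[, 2], z = r * u[, 3],
                     energy = 30, track_id = 1L)
  conc <- data.frame(x = cx + stats::runif(n, 0, 0.02),
                     y = cy + stats::runif(n, 0, 0.02),
                     z = cz + stats::runif(n, 0, 0.02),
                     energy = 30, track_id = 1L)
  pars <- damageParams(p_oh = 1, p_deoxy = 0.1, k_max = 10L)
  set.seed(37); nd <- nrow(indirectBreaks(disp, m, pars))
  set.seed(37); nc <- nrow(indirectBreaks(conc, m, pars))
  expect_lt(nc, nd / 2)
})

test_that("DNA mass per slab closes and peaks centrally", {
  m <- testModel()
  g <- nucleusGeometry()
  set.seed(38)
  dm <- dnaMassPerSlab(m, g, nRotations = 400L)
  expect_equal(sum(dm), m@genomeLength, tolerance = 5e-3)
  expect_gt(mean(dm[20:31]), mean(c(dm[1:5], dm[46:50])))
  # analytic rotation average: a voxel at radius rho is uniformly likely
  # to land at any depth in [r - rho, r + rho]
  G <- m@gridDim; v <- m@voxelSize; rn <- G * v / 2
  key <- m@voxelKey
  cx <- ((key - 1) %% G + 0.5) * v - rn
  cy <- (((key - 1) %/% G) %% G + 0.5) * v - rn
  cz <- ((key - 1) %/% (G * G) + 0.5) * v - rn
  rho <- sqrt(cx^2 + cy^2 + cz^2)
  edges <- seq(0, 10, by = g@slabThickness)
  want <- vapply(seq_len(50), function(i) {
    ov <- pmin(edges[i + 1], rn + rho) - pmax(edges[i], rn - rho)
    sum(m@bpPerVoxel * pmax(ov, 0) / (2 * rho))
  }, numeric(1))
  mid <- 4:47
  expect_lt(max(abs(dm[mid] / want[mid] - 1)), 0.03)
})

test_that("breaks are uniform over the genome for uniform deposits", {
  m <- testModel()
  set.seed(39)
  n <- 60000
  r <- 5 * stats::runif(n)^(1 / 3)
  u <- matrix(stats::rnorm(3 * n), n, 3); u <- u / sqrt(rowSums(u^2))
  dep <- data.frame(x = r * u[, 1], y = r * u[, 2], z = r * u[, 3],
                    energy = 40, track_id = 1L)
  b <- depositsToDirectBreaks(dep, m, damageParams(f_dna = 0.5))
  # genomic coordinate of a break, scaled to [0, 1] within its chromosome
  frac <- b$pos / m@chromLengths[b$chromosome]
  ct <- table(cut(frac, seq(0, 1, 0.2)))
  expect_gt(stats::chisq.test(ct)$p.value, 0.001)
})
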