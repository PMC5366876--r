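test_that("adjacent breaks merge per the run-length rule", {
  b <- data.frame(chromosome = 1L, pos = c(100, 101), strand = "+",
                  origin = "direct", track_id = 1L)
  m <- mergeAdjacent(b)
  expect_identical(nrow(m), 1L)
  expect_equal(m$pos, 100)
  # one intact group between breaks: both kept
  b2 <- data.frame(chromosome = 1L, pos = c(100, 102), strand = "+",
                   origin = "direct", track_id = 1L)
  expect_identical(nrow(mergeAdjacent(b2)), 2L)
  # breaks on different strands never merge
  b3 <- data.frame(chromosome = 1L, pos = c(100, 101), strand = c("+", "-"),
                   origin = "direct", track_id = 1L)
  expect_identical(nrow(mergeAdjacent(b3)), 2L)
  # idempotence
  expect_identical(mergeAdjacent(m), m)
})

test_that("merging agrees with the brute-force oracle on random instances", {
  set.seed(41)
  for (i in 1:300) {
    b <- randomBreakSet(sample(5:60, 1), span = 120, chromosomes = 2L)
    got <- mergeAdjacent(b)
    want <- oracleMergeAdjacent(b)
    expect_identical(nrow(got), nrow(want))
    expect_equal(got$pos, want$pos)
    expect_identical(got$strand, want$strand)
    expect_identical(mergeAdjacent(got), got)   # idempotent
  }
})

test_that("DSB calling follows the 10 bp opposite-strand rule", {
  mk <- function(pos, strand) data.frame(chromosome = 1L, pos = pos,
                                         strand = strand, origin = "direct",
                                         track_id = 1L)
  r <- callDsb(mk(c(100, 105), c("+", "-")))
  expect_identical(nrow(r$dsb), 1L)
  expect_identical(nrow(r$ssb), 0L)
  expect_equal(r$dsb$pos, floor((100 + 105) / 2))
  # 11 bp apart: no DSB, two SSB
  r2 <- callDsb(mk(c(100, 111), c("+", "-")))
  expect_identical(nrow(r2$dsb), 0L)
  expect_identical(nrow(r2$ssb), 2L)
  # same strand: never a DSB
  r3 <- callDsb(mk(c(100, 105), c("+", "+")))
  expect_identical(nrow(r3$dsb), 0L)
  # third break near an existing pair stays an SSB (greedy exclusivity)
  r4 <- callDsb(mk(c(100, 102, 104), c("+", "-", "-")))
  expect_identical(nrow(r4$dsb), 1L)
  expect_identical(nrow(r4$ssb), 1L)
})

test_that("greedy pairing tracks the maximum matching on random instances", {
  set.seed(42)
  agree <- 0L
  nInst <- 60L
  for (i in seq_len(nInst)) {
    b <- mergeAdjacent(randomBreakSet(30, span = 150))
    got <- nrow(callDsb(b)$dsb)
    opt <- oracleMaxMatching(b)
    expect_lte(got, opt)
    # greedy cannot miss more than half of the optimum
    expect_gte(2L * got, opt)
    if (got == opt) agree <- agree + 1L
  }
  expect_gte(agree / nInst, 0.95)
})

test_that("cluster chaining reproduces the worked scenarios", {
  mkdsb <- function(pos) data.frame(chromosome = 1L, pos = pos,
                                    pos1 = pos, pos2 = pos + 2,
                                    origin = "direct/direct", track_id = 1L)
  cl <- clusterDsb(mkdsb(c(1000, 1020)))
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$multiplicity, 2L)
  cl3 <- clusterDsb(mkdsb(c(1000, 1020, 1040)))   # transitive chaining
  expect_identical(nrow(cl3), 1L)
  expect_identical(cl3$multiplicity, 3L)
  cl2 <- clusterDsb(mkdsb(c(1000, 1030)))          # 30 bp: two isolated
  expect_identical(nrow(cl2), 2L)
  expect_true(all(!cl2$isCluster))
})

test_that("clustering agrees with the single-linkage oracle", {
  set.seed(43)
  for (i in 1:200) {
    pos <- sort(sample.int(2000, sample(3:40, 1)))
    d <- data.frame(chromosome = 1L, pos = pos, pos1 = pos, pos2 = pos,
                    origin = "x", track_id = 1L)
    got <- sort(clusterDsb(d)$multiplicity)
    want <- sort(oracleChains(pos, 25))
    expect_equal(got, as.integer(want))
  }
})

test_that("clustering agrees with interval reduction from IRanges", {
  set.seed(44)
  for (i in 1:40) {
    pos <- sort(sample.int(3000, 30))
    d <- data.frame(chromosome = 1L, pos = pos, pos1 = pos, pos2 = pos,
                    origin = "x", track_id = 1L)
    got <- clusterDsb(d)
    red <- IRanges::reduce(IRanges::IRanges(pos, pos), min.gapwidth = 25)
    expect_identical(nrow(got), length(red))
  }
})

test_that("the three 7-DSB scenarios score the printed sites and multiplicities", {
  s1 <- classifyBreaks(generateFixture("worked_example_isolated7"))
  expect_equal(unname(s1@counts[c("dsb", "dsbSites", "dsbClusters")]),
               c(7, 7, 0))
  s2 <- classifyBreaks(generateFixture("worked_example_2clusters"))
  expect_equal(unname(s2@counts[c("dsb", "dsbSites", "dsbClusters",
                                  "dsbIsolated", "multiplicity")]),
               c(7, 5, 2, 3, 2))
  s3 <- classifyBreaks(generateFixture("worked_example_chain7"))
  expect_equal(unname(s3@counts[c("dsb", "dsbSites", "dsbClusters",
                                  "multiplicity")]),
               c(7, 1, 1, 7))
})

test_that("fragment scoring bins gaps between same-track sites", {
  sites <- data.frame(chromosome = 1L, pos = c(10000, 60000),
                      multiplicity = 1L, isCluster = FALSE, track_id = 1L,
                      microFragments = 0L)
  fs <- fragmentSpectrum(sites)
  expect_equal(fs$count[fs$name == "10-100 kbp"], 1)
  expect_equal(sum(fs$count[fs$name != "10-100 kbp"]), 1) # PFGE bin overlaps
  # a single site yields no fragment
  expect_equal(sum(fragmentSpectrum(sites[1, ])$count), 0)
  # different tracks do not combine
  sites2 <- sites; sites2$track_id <- c(1L, 2L)
  expect_equal(sum(fragmentSpectrum(sites2)$count), 0)
})

test_that("fragment binning matches the consecutive-difference oracle", {
  set.seed(45)
  bins <- fragmentBins()
  for (i in 1:100) {
    n <- sample(3:25, 1)
    sites <- data.frame(chromosome = sample(1:2, n, TRUE),
                        pos = sample.int(5e6, n),
                        multiplicity = 1L, isCluster = FALSE,
                        track_id = sample(1:2, n, TRUE),
                        microFragments = 0L)
    lens <- oracleFragments(sites)
    want <- vapply(seq_len(nrow(bins)), function(k)
      sum(lens >= bins$lower[k] & lens <= bins$upper[k]), numeric(1))
    expect_equal(fragmentSpectrum(sites, bins)$count, want)
    # total fragments per chromosome and track = sites - 1
    expect_equal(length(attr(fragmentSpectrum(sites, bins), "lengths")),
                 sum(pmax(table(sites$track_id, sites$chromosome) - 1, 0)))
  }
})

test_that("summary identities hold on random classified instances", {
  set.seed(46)
  for (i in 1:25) {
    b <- convertSbToDsb(randomBreakSet(80, span = 3000), 0.05)
    s <- classifyBreaks(b, dose = 1.5, genomeLength = 1e9)
    cn <- s@counts
    expect_equal(cn[["dsbSites"]], cn[["dsbIsolated"]] + cn[["dsbClusters"]])
    expect_equal(cn[["sb"]], cn[["ssb"]] + 2 * cn[["dsb"]])
    sites <- attr(s, "sites")
    expect_equal(cn[["dsb"]],
                 cn[["dsbIsolated"]] + sum(sites$multiplicity[sites$isCluster]))
    expect_equal(unname(s@perGyPerGbp["dsb"]), cn[["dsb"]] / 1.5)
  }
})

test_that("classification is invariant under translation and relabeling", {
  set.seed(47)
  b <- randomBreakSet(60, span = 2000, chromosomes = 2L)
  s <- classifyBreaks(b)
  b2 <- b; b2$pos <- b2$pos + 7e6
  expect_equal(classifyBreaks(b2)@counts, s@counts)
  b3 <- b; b3$chromosome <- 3L - b3$chromosome   # swap labels
  expect_equal(classifyBreaks(b3)@counts, s@counts)
})

test_that("re-classifying reconstructed breaks is idempotent", {
  set.seed(48)
  b <- mergeAdjacent(randomBreakSet(70, span = 2500))
  s <- classifyBreaks(b)
  d <- attr(s, "dsb"); ssb <- attr(s, "ssb")
  rebuilt <- rbind(
    data.frame(chromosome = d$chromosome, pos = d$pos1, strand = d$strand1,
               origin = "direct", track_id = d$track_id),
    data.frame(chromosome = d$chromosome, pos = d$pos2, strand = d$strand2,
               origin = "direct", track_id = d$track_id),
    ssb[, c("chromosome", "pos", "strand", "origin", "track_id")])
  s2 <- classifyBreaks(rebuilt)
  expect_equal(s2@counts, s@counts)
})

test_that("break lists round-trip through TSV", {
  b <- generateFixture("random_breaks", seed = 49, n = 50)
  f <- tempfile(fileext = ".tsv")
  writeBreaks(b, f)
  b2 <- readBreaks(f)
  expect_equal(b2, b)
  bad <- b; names(bad)[2] <- "position"
  f2 <- tempfile(); utils::write.table(bad, f2, sep = "\t", row.names = FALSE)
  expect_error(readBreaks(f2), "columns")
})

test_that("zero dose with a per-Gy request raises an error", {
  b <- generateFixture("worked_example_chain7")
  expect_error(classifyBreaks(b, dose = 0), "positive dose")
  s <- classifyBreaks(b)          # dose NA: counts only
  expect_true(is.na(s@dose))
})
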