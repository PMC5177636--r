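test_that("window fragmentation follows the start/step/drop-partial rule", {
  s <- randomDNA(500)
  w <- fragmentSequence(s, windowSpec(300, 100))
  expect_equal(start(w), c(1, 101, 201))
  expect_equal(end(w), c(300, 400, 500))
  expect_equal(length(fragmentSequence(randomDNA(300), windowSpec())), 1L)
  expect_error(fragmentSequence(randomDNA(299), windowSpec()), "shorter")
  # whole-sequence extension doubles the tiled length
  w2 <- fragmentSequence(randomDNA(300), windowSpec(300, 100,
                                                    "whole_sequence_rc"))
  expect_equal(start(w2), c(1, 101, 201, 301))
})

test_that("k-mer counting is overlapping, strand-aware and N-skipping", {
  expect_equal(unname(countKmers("AAAA", 4)["AAAA"]), 1)
  expect_equal(unname(countKmers("AAAAA", 4)["AAAA"]), 2)
  both <- countKmers("AAAA", 4, "per_window_rc")
  expect_equal(unname(both[c("AAAA", "TTTT")]), c(1, 1))
  expect_equal(sum(both), 2)
  # k-mers containing N are skipped and totals adjust
  withN <- countKmers("AANACGT", 2)
  expect_equal(sum(withN), 4)  # AA, AC, CG, GT; the two N-containing skipped
  expect_error(countKmers("ACGT", 5), "k must be")
  # agreement with the naive substring-scanning oracle
  set.seed(11)
  for (i in 1:10) {
    s <- randomDNA(80)
    for (k in 2:4)
      expect_equal(countKmers(s, k, "per_window_rc"),
                   naiveKmerCounts(s, k, rc = TRUE))
  }
})

test_that("expected counts and z-scores reproduce the hand-derived values", {
  n4 <- countKmers("AAAAAAAAAA", 4)
  n3 <- countKmers("AAAAAAAAAA", 3)
  n2 <- countKmers("AAAAAAAAAA", 2)
  e <- expectedCounts(n3, n2)
  expect_equal(unname(e["AAAA"]), 8 * 8 / 9, tolerance = 1e-12)
  z <- tetraZScores(n4, n3, n2)
  # var = E * (9-8)(9-8) / 81; Z = (7 - 64/9)/sqrt(var)
  expect_equal(unname(z["AAAA"]), (7 - 64 / 9) / sqrt((64 / 9) / 81),
               tolerance = 1e-12)
  expect_equal(round(unname(z["AAAA"]), 4), -0.375)
  # zero-count core dinucleotide forces E = 0 for all 16 sharing tetramers
  expect_true(all(e[substr(names(e), 2, 3) == "CG"] == 0))
  expect_true(all(z[substr(names(z), 2, 3) == "CG"] == 0))
})

test_that("expected counts approach L/256 for uniform i.i.d. text", {
  set.seed(5)
  s <- randomDNA(1e6)
  n3 <- countKmers(s, 3)
  n2 <- countKmers(s, 2)
  e <- expectedCounts(n3, n2)
  L <- 1e6 - 3
  p <- 1 / 256
  sigma <- sqrt(L * p * (1 - p))
  expect_true(all(abs(e - L * p) < 6 * sigma))
  expect_lt(mean(abs(e - L * p) > 3 * sigma), 0.05)
})

test_that("signature matches the brute-force 256-loop oracle to 1e-12", {
  set.seed(21)
  for (i in 1:10) {
    s <- randomDNA(300, gc = runif(1, 0.3, 0.7))
    o <- naiveSignature(s, rc = TRUE)
    n4 <- countKmers(s, 4, "per_window_rc")
    n3 <- countKmers(s, 3, "per_window_rc")
    n2 <- countKmers(s, 2, "per_window_rc")
    expect_equal(n4, o$n4)
    expect_equal(unname(expectedCounts(n3, n2)), unname(o$expected),
                 tolerance = 1e-12)
    expect_equal(unname(tetraZScores(n4, n3, n2)), unname(o$z),
                 tolerance = 1e-12)
  }
})

test_that("pearsonR matches a two-pass oracle and handles degeneracy", {
  expect_equal(pearsonR(1:256, 1:256), 1)
  expect_equal(pearsonR(1:256, -(1:256)), -1)
  z1 <- as.numeric(1:256)
  z2 <- c(1:255, 0)
  expect_equal(pearsonR(z1, z2), twoPassPearson(z1, z2), tolerance = 1e-12)
  expect_warning(r0 <- pearsonR(rep(1, 256), z1), "zero-variance")
  expect_equal(r0, 0)
})

test_that("correlation matrix is symmetric, unit-diagonal and bounded", {
  set.seed(31)
  for (i in 1:10) {
    tc <- tetraCorrelation(randomDNA(sample(600:1500, 1)), windowSpec(),
                           id = sprintf("f%d", i))
    r <- corMatrix(tc)
    expect_equal(r, t(r))
    expect_true(all(abs(diag(r) - 1) < 1e-9))
    expect_true(all(r >= -1 - 1e-9 & r <= 1 + 1e-9))
  }
  # identical windows correlate perfectly
  s <- paste(rep(randomDNA(300), 4), collapse = "")
  tc <- tetraCorrelation(s, windowSpec(300, 300))
  expect_true(all(abs(corMatrix(tc) - 1) < 1e-9))
  expect_error(tetraCorrelation(randomDNA(350), windowSpec(300, 100)),
               "at least 2")
})

test_that("tetranucleotide count totals are conserved per window", {
  set.seed(41)
  s <- randomDNA(1000)
  tc <- tetraCorrelation(s, windowSpec())
  zm <- tetrascan:::.windowZMatrix(Biostrings::DNAString(s),
                                   scanWindows(tc), "per_window_rc")
  expect_true(all(zm$n4total == 2 * (300 - 3)))
})

test_that("a window and its reverse complement have identical signatures", {
  set.seed(51)
  tb <- tetrascan:::.kmerTables()
  for (i in 1:10) {
    w <- randomDNA(300)
    z <- tetraZScores(countKmers(w, 4, "per_window_rc"),
                      countKmers(w, 3, "per_window_rc"),
                      countKmers(w, 2, "per_window_rc"))
    zr <- tetraZScores(countKmers(revComp(w), 4, "per_window_rc"),
                       countKmers(revComp(w), 3, "per_window_rc"),
                       countKmers(revComp(w), 2, "per_window_rc"))
    # component-permutation by reverse complement maps one onto the other
    expect_equal(unname(z), unname(zr[tb$i_rc4]), tolerance = 1e-12)
    expect_equal(pearsonR(z, zr), 1, tolerance = 1e-9)
  }
})

test_that("region calling honours threshold, runs, masks and trivial cases", {
  host <- makeMarkovModel(48, 0.6, seed = 301)
  impl <- makeMarkovModel(60, 0.1, seed = 302)
  # implant spanning a known window block; manual threshold at the midpoint
  # of the two score modes recovers the block within one window
  f <- simulateFragment(3000, host,
                        implant = list(model = impl, start = 1201,
                                       length = 1000), seed = 303)
  tc <- tetraCorrelation(f$record)
  sc <- windowScores(tc)
  iw <- which(start(scanWindows(tc)) >= 1201 & end(scanWindows(tc)) <= 2200)
  thr <- (mean(sc[iw]) + mean(sc[-iw])) / 2
  reg <- callLowCorrelationRegions(tc, threshold = thr, minRun = 2)
  expect_equal(length(reg), 1L)
  expect_lte(abs(reg$windowFirst - min(iw)), 1)
  expect_lte(abs(reg$windowLast - max(iw)), 1)
  expect_lt(reg$meanRInside, thr)

  # a perfectly coherent matrix yields no calls
  s <- paste(rep(randomDNA(300), 6), collapse = "")
  tcU <- tetraCorrelation(s, windowSpec(300, 300))
  expect_equal(length(callLowCorrelationRegions(tcU, threshold = 0.5)), 0L)

  # masking the implant suppresses the call entirely
  maskGr <- GRanges(tc@seqId, IRanges(1201, 2200))
  regM <- callLowCorrelationRegions(tc, threshold = thr, mask = maskGr)
  expect_equal(length(regM), 0L)
  expect_error(windowScores(tc, GRanges(tc@seqId, IRanges(1, 3000))),
               "all windows are masked")
  expect_error(callLowCorrelationRegions(tc, threshold = 1.5), "threshold")
})

test_that("single-source fragments cohere more than chimeric ones", {
  host <- makeMarkovModel(48, 0.6, seed = 311)
  impl <- makeMarkovModel(60, 0.1, seed = 312)
  rs <- vapply(1:5, function(s) {
    f <- simulateFragment(12000, host, seed = 320 + s)
    meanR(tetraCorrelation(f$record))
  }, numeric(1))
  rs2 <- vapply(1:5, function(s) {
    f <- simulateFragment(12000, host,
                          implant = list(model = impl, start = 4001,
                                         length = 4000), seed = 330 + s)
    meanR(tetraCorrelation(f$record))
  }, numeric(1))
  expect_gt(mean(rs), mean(rs2))
  # implant-vs-host block correlations sit below host-vs-host ones
  f <- simulateFragment(12000, host,
                        implant = list(model = impl, start = 4001,
                                       length = 4000), seed = 340)
  tc <- tetraCorrelation(f$record)
  w <- scanWindows(tc)
  iw <- which(start(w) >= 4001 & end(w) <= 8000)
  hw <- setdiff(seq_along(w), iw)
  r <- corMatrix(tc)
  expect_gt(mean(r[hw, hw][upper.tri(r[hw, hw])]), mean(r[hw, iw]))
})

test_that("output writers produce well-formed TSV and BED", {
  set.seed(61)
  tc <- tetraCorrelation(randomDNA(800), windowSpec(), id = "cloneA")
  d <- tempfile()
  dir.create(d)
  writeCorrelationTSV(tc, file.path(d, "m.tsv"))
  m <- read.delim(file.path(d, "m.tsv"), check.names = FALSE)
  expect_equal(nrow(m), length(scanWindows(tc)))
  expect_equal(ncol(m), length(scanWindows(tc)) + 1)
  writeWindowSummaryTSV(tc, file.path(d, "w.tsv"))
  w <- read.delim(file.path(d, "w.tsv"))
  expect_identical(names(w), c("index", "start", "end", "mean_r"))
  reg <- GRanges("cloneA", IRanges(101, 400), windowFirst = 2L,
                 windowLast = 4L, meanRInside = 0.1, meanROutside = 0.5)
  writeRegionsBED(reg, file.path(d, "r.bed"))
  bed <- read.delim(file.path(d, "r.bed"), header = FALSE)
  expect_equal(bed$V2, 100)  # 0-based half-open conversion
  expect_equal(bed$V3, 400)
})
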