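test_that("Markov models are valid, calibrated and deterministic", {
  # sharpness 0 gives the i.i.d. model with exact base probabilities
  m0 <- makeMarkovModel(50, 0, seed = 1)
  expect_true(all(abs(m0@transitions - 0.25) < 1e-12))
  m30 <- makeMarkovModel(30, 0, seed = 1)
  expect_equal(unname(m30@transitions[1, ]), c(0.35, 0.15, 0.15, 0.35),
               tolerance = 1e-12)
  # rows sum to one under perturbation and the stationary GC hits the target
  m <- makeMarkovModel(30, 0.6, seed = 2)
  expect_true(all(abs(rowSums(m@transitions) - 1) < 1e-12))
  expect_equal(stationaryGC(m), 30, tolerance = 1e-6)
  gcSim <- unname(gcContent(simulateMarkov(100000, m, seed = 3)))
  expect_gte(gcSim, 28)
  expect_lte(gcSim, 32)
  # determinism
  expect_identical(makeMarkovModel(48, 0.6, seed = 7),
                   makeMarkovModel(48, 0.6, seed = 7))
  expect_error(makeMarkovModel(0, 0.1, seed = 1), "strictly between")
  expect_error(makeMarkovModel(100, 0.1, seed = 1), "strictly between")
})

test_that("simulated 4-mer composition matches the stationary distribution", {
  m <- makeMarkovModel(45, 0.4, seed = 11)
  s <- simulateMarkov(1e6, m, seed = 12)
  n4 <- countKmers(s, 4)
  # stationary tetranucleotide probabilities: pi3(n1n2n3) * P(n4 | n1n2n3)
  pi3 <- tetrascan:::.stationaryTrinuc(m@transitions)
  p4 <- as.vector(outer(seq_len(64), 1:4, function(i, b)
    pi3[i] * m@transitions[cbind(i, b)]))
  # map outer()'s (context, base) order onto the canonical 4-mer order
  k3 <- mkAllStrings(c("A", "C", "G", "T"), 3)
  nm <- as.vector(outer(seq_len(64), 1:4, function(i, b)
    paste0(k3[i], c("A", "C", "G", "T")[b])))
  p4 <- p4[match(names(n4), nm)]
  L <- 1e6 - 3
  sigma <- sqrt(L * p4 * (1 - p4))
  dev <- abs(n4 - L * p4) / sigma
  # overlapping counts are autocorrelated, so allow modest inflation over the
  # i.i.d. multinomial scale while requiring the bulk within 3 sigma
  expect_gt(mean(dev <= 3), 0.95)
  expect_true(all(dev < 8))
})

test_that("fragment simulation is deterministic with faithful truth", {
  host <- makeMarkovModel(48, 0.6, seed = 21)
  impl <- makeMarkovModel(60, 0.1, seed = 22)
  a <- simulateFragment(8000, host,
                       implant = list(model = impl, start = 3, length = 9790 %/% 4),
                       seed = 23)
  b <- simulateFragment(8000, host,
                       implant = list(model = impl, start = 3, length = 9790 %/% 4),
                       seed = 23)
  expect_identical(as.character(a$record), as.character(b$record))
  expect_equal(a$truth@implantEnd - a$truth@implantStart + 1L, 9790 %/% 4)
  # the truth layout mirrors the requested geometry exactly
  big <- simulateFragment(30000, host,
                          implant = list(model = impl, start = 3,
                                         length = 9790), seed = 24)
  expect_equal(big$truth@implantStart, 3L)
  expect_equal(big$truth@implantEnd, 9792L)
  expect_error(simulateFragment(5000, host,
                                implant = list(model = impl, start = 4000,
                                               length = 2000), seed = 1),
               "outside")
})

test_that("the rRNA block is copied verbatim and may not overlap implants", {
  host <- makeMarkovModel(48, 0.6, seed = 31)
  ref <- as.character(pseudo16S()[[1]])
  f <- simulateFragment(6000, host, rrna = list(start = 2001), seed = 32)
  expect_equal(substr(as.character(f$record[[1]]), 2001,
                      2000 + nchar(ref)), ref)
  expect_equal(f$truth@rrnaStart, 2001L)
  impl <- makeMarkovModel(60, 0.1, seed = 33)
  expect_error(simulateFragment(6000, host,
                                implant = list(model = impl, start = 2500,
                                               length = 1000),
                                rrna = list(start = 2001), seed = 34),
               "overlap")
})

test_that("CDS annotation hits the requested coverage and is reproducible", {
  host <- makeMarkovModel(48, 0.6, seed = 41)
  f <- simulateFragment(40000, host, seed = 42)
  anno <- makeCdsAnnotation(f$truth, hostCodingFrac = 0.75, seed = 43)
  cov <- codingPercent(anno, 40000)
  expect_gte(cov, 73)
  expect_lte(cov, 77)
  expect_true(all(width(anno) >= 300 & width(anno) <= 2000))
  # non-overlapping by construction
  expect_equal(sum(width(reduce(anno))), sum(width(anno)))
  expect_identical(makeCdsAnnotation(f$truth, 0.75, seed = 43),
                   makeCdsAnnotation(f$truth, 0.75, seed = 43))
  expect_equal(length(makeCdsAnnotation(f$truth, 0, 0, seed = 44)), 0L)
  # implant receives its own, sparser annotation
  impl <- makeMarkovModel(60, 0.1, seed = 45)
  fi <- simulateFragment(30000, host,
                         implant = list(model = impl, start = 10001,
                                        length = 10000), seed = 46)
  ai <- makeCdsAnnotation(fi$truth, 0.75, 0.30, seed = 47)
  inImpl <- ai[start(ai) >= 10001 & end(ai) <= 20000]
  covI <- 100 * sum(width(reduce(inImpl))) / 10000
  expect_gte(covI, 28)
  expect_lte(covI, 32)
  # infeasible fraction on a tiny region fails loudly
  tiny <- simulateFragment(400, host, seed = 48)
  expect_error(makeCdsAnnotation(tiny$truth, hostCodingFrac = 0.2,
                                 seed = 49), "infeasible")
})

test_that("generators restore the caller's RNG stream", {
  set.seed(555)
  before <- .Random.seed
  invisible(makeMarkovModel(48, 0.6, seed = 51))
  invisible(simulateFragment(3000, makeMarkovModel(48, 0.3, seed = 52),
                             seed = 53))
  expect_identical(.Random.seed, before)
})
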