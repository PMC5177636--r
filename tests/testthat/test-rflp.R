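test_that("digest places cuts after the offset base, honouring overlaps", {
  expect_equal(fragmentLengths(digestSequence("AAGCGCAA", id = "t")),
               c(5L, 3L))
  expect_equal(fragmentLengths(digestSequence("GCGCGC", id = "t")),
               c(3L, 2L, 1L))
  s <- randomDNA(500)
  noSite <- gsub("GCGC", "GCAC", s, fixed = TRUE)
  expect_equal(fragmentLengths(digestSequence(noSite, id = "t")),
               nchar(noSite))
  expect_error(digestSequence("", id = "t"))
  expect_error(digestSequence("ACGT", site = "GCNC", id = "t"),
               "non-degenerate")
})

test_that("digest conserves total length on random sequence/site pairs", {
  set.seed(71)
  for (i in 1:200) {
    s <- randomDNA(sample(50:400, 1), gc = runif(1, 0.25, 0.75))
    site <- randomDNA(sample(3:5, 1))
    off <- sample(0:nchar(site), 1)
    p <- digestSequence(s, site = site, cutOffset = off, id = "t")
    expect_equal(sum(fragmentLengths(p)), nchar(s))
    expect_true(all(fragmentLengths(p) >= 1))
  }
})

test_that("palindromic-site digest is strand-invariant", {
  set.seed(72)
  for (i in 1:25) {
    s <- randomDNA(300, gc = 0.6)
    # a centre cut (GC^GC) is exactly mirror-symmetric
    a <- fragmentLengths(digestSequence(s, cutOffset = 2, id = "t"))
    b <- fragmentLengths(digestSequence(revComp(s), cutOffset = 2,
                                        id = "t"))
    expect_equal(sort(a), sort(b))
    # the staggered GCG^C cut shifts each boundary by two bases between
    # strands; the profiles are identical at gel resolution
    pa <- digestSequence(s, id = "t")
    pb <- digestSequence(revComp(s), id = "t")
    expect_true(compareProfiles(pa, pb, toleranceFrac = 0.05)$matched ||
                  all(abs(fragmentLengths(pa) - fragmentLengths(pb)) <= 2))
  }
})

test_that("profile comparison applies fractional tolerance and symmetry", {
  mk <- function(lens, id = "p")
    new("DigestProfile", ampliconId = id,
        fragmentLengths = as.integer(sort(lens, decreasing = TRUE)),
        totalLength = as.integer(sum(lens)))
  expect_true(compareProfiles(mk(c(900, 600)), mk(c(900, 600)))$matched)
  expect_true(compareProfiles(mk(c(900, 600)), mk(c(910, 600)))$matched)
  cmp <- compareProfiles(mk(c(900, 600)), mk(c(700, 500, 300)))
  expect_false(cmp$matched)
  expect_equal(nrow(cmp$unmatchedFragments), 5)
  # verdict symmetry on random profiles
  set.seed(73)
  for (i in 1:50) {
    q <- mk(sample(50:1000, sample(2:5, 1)), "q")
    ct <- mk(sample(50:1000, sample(2:5, 1)), "c")
    expect_equal(compareProfiles(q, ct)$matched,
                 compareProfiles(ct, q)$matched)
  }
  expect_error(compareProfiles(mk(100), mk(100), toleranceFrac = 1),
               "toleranceFrac")
})

test_that("amplicon finding needs both primers, respects strand and bounds", {
  p <- primerPair()
  gene <- as.character(pseudo16S()[[1]])
  clone <- embedGene(gene)
  amp <- findAmplicons(clone, p, id = "cl")
  expect_equal(length(amp), 1L)
  expect_equal(width(amp), nchar(gene))
  expect_equal(amp$sequence, gene)
  expect_equal(as.character(strand(amp)), "+")
  # reverse-complemented template: same amplicon after orientation
  ampRC <- findAmplicons(revComp(clone), p, id = "clrc")
  expect_equal(length(ampRC), 1L)
  expect_equal(as.character(strand(ampRC)), "-")
  expect_equal(ampRC$sequence, gene)
  # forward primer alone is not enough
  half <- paste0(p@forward, randomDNA(1500))
  expect_equal(length(findAmplicons(half, p, id = "h")), 0L)
  # products outside the length window are rejected
  short <- paste0(p@forward, strrep("A", 500), revComp(p@reverse))
  expect_equal(length(findAmplicons(short, p, id = "s")), 0L)
  # constructed template of known product size
  tmpl <- paste0(p@forward, strrep("A", 1460), revComp(p@reverse))
  ampT <- findAmplicons(tmpl, p, id = "t")
  expect_equal(width(ampT), nchar(p@forward) + 1460 + nchar(p@reverse))
})

test_that("mismatch tolerance respects the 3-base 3' clamp", {
  p <- primerPair(maxMismatch = 2)
  fwd <- p@forward
  mid <- strrep("A", 1460)
  # two mismatches in the 5' half of the forward primer: still found
  fwd2 <- fwd
  substr(fwd2, 2, 2) <- "C"
  substr(fwd2, 5, 5) <- "A"
  tmpl <- paste0(fwd2, mid, revComp(p@reverse))
  expect_equal(length(findAmplicons(tmpl, p, id = "t")), 1L)
  # one mismatch inside the 3' clamp: rejected
  fwd3 <- fwd
  substr(fwd3, nchar(fwd3), nchar(fwd3)) <- "T"
  tmpl3 <- paste0(fwd3, mid, revComp(p@reverse))
  expect_equal(length(findAmplicons(tmpl3, p, id = "t")), 0L)
})

test_that("clone screening separates host, divergent and primer-free", {
  p <- primerPair()
  host16S <- as.character(pseudo16S()[[1]])
  control <- digestSequence(host16S, id = "host")
  # clone carrying the host 16S verbatim -> negative
  cloneNeg <- embedGene(host16S, seed = 81)
  expect_equal(screenClone(cloneNeg, p, control, id = "neg")$verdict,
               "negative")
  # divergent 16S: destroy one GCGC site and create another elsewhere
  div <- host16S
  sitePos <- gregexpr("GCGC", div)[[1]][1]
  substr(div, sitePos, sitePos) <- "A"
  substr(div, 401, 404) <- "GCGC"
  cloneDiv <- embedGene(div, seed = 82)
  expect_equal(screenClone(cloneDiv, p, control, id = "pos")$verdict,
               "positive")
  # no primer sites at all -> no_amplicon
  bare <- simulateMarkov(3000, makeMarkovModel(50, 0.3, seed = 83),
                         seed = 83)
  expect_equal(screenClone(bare, p, control, id = "none")$verdict,
               "no_amplicon")
})
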