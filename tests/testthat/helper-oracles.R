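# Independent oracles and small fixture builders shared across test files.
# The oracles deliberately avoid the code paths they check: k-mers are
# enumerated by substring scanning, correlation by the two-pass textbook
# formula.

randomDNA <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# naive k-mer counts by substring scanning (skips k-mers containing non-ACGT)
naiveKmerCounts <- function(s, k, rc = FALSE) {
  kmers <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[
    , k:1, drop = FALSE], 1, paste, collapse = ""))
  counts <- setNames(integer(4^k), kmers)
  texts <- s
  if (rc) texts <- c(texts, revComp(s))
  for (txt in texts) {
    n <- nchar(txt)
    for (i in seq_len(n - k + 1)) {
      w <- substr(txt, i, i + k - 1)
      if (w %in% kmers) counts[w] <- counts[w] + 1L
    }
  }
  counts
}

# brute-force 256-loop signature: expected counts, variances and z-scores
# computed cell by cell from the count tables
naiveSignature <- function(s, rc = TRUE) {
  n4 <- naiveKmerCounts(s, 4, rc)
  n3 <- naiveKmerCounts(s, 3, rc)
  n2 <- naiveKmerCounts(s, 2, rc)
  e <- v <- z <- setNames(numeric(256), names(n4))
  for (w in names(n4)) {
    a <- n3[substr(w, 1, 3)]
    b <- n3[substr(w, 2, 4)]
    core <- n2[substr(w, 2, 3)]
    if (core == 0) { e[w] <- 0; v[w] <- 0; z[w] <- 0; next }
    e[w] <- a * b / core
    v[w] <- e[w] * (core - a) * (core - b) / core^2
    z[w] <- if (v[w] <= 0 || e[w] == 0) 0 else (n4[w] - e[w]) / sqrt(v[w])
  }
  list(n4 = n4, n3 = n3, n2 = n2, expected = e, variance = v, z = z)
}

# two-pass textbook Pearson correlation
twoPassPearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# write a throwaway FASTA and return its path
tmpFasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# a clone carrying an embedded 16S-like gene at a known offset, on a
# simulated host backbone
embedGene <- function(gene, hostLen = 4000, offset = 1500, seed = 99) {
  host <- simulateMarkov(hostLen, makeMarkovModel(48, 0.3, seed = seed),
                         seed = seed)
  paste0(substr(host, 1, offset - 1), gene,
         substr(host, offset, hostLen - nchar(gene)))
}
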