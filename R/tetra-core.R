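# Windowed tetranucleotide signature analysis.
#
# The signature of a window is the 256-vector of z-scores of observed
# tetranucleotide counts against the maximal-order Markov expectation
#   E[N(n1n2n3n4)] = N(n1n2n3) * N(n2n3n4) / N(n2n3)
# with approximate variance
#   var = E * (N(n2n3) - N(n1n2n3)) * (N(n2n3) - N(n2n3n4)) / N(n2n3)^2.
# Internal coherence of a fragment is the pairwise Pearson correlation of
# window z-score vectors.

.asDNAString <- function(seq) {
  if (is(seq, "DNAString")) return(seq)
  if (is(seq, "DNAStringSet")) {
    if (length(seq) != 1L)
      stop("expected a single sequence, got ", length(seq), call. = FALSE)
    return(seq[[1]])
  }
  DNAString(seq)
}

.seqId <- function(seq, default = "seq") {
  if (is(seq, "DNAStringSet") && !is.null(names(seq))) names(seq)[1]
  else default
}

#' Cut a sequence into overlapping windows
#'
#' Windows start at positions 1, 1+step, 1+2*step, ...; a trailing stretch
#' shorter than the window length is dropped. In `whole_sequence_rc` mode the
#' windows tile the concatenation of the sequence and its reverse complement
#' (coordinates then refer to that extended sequence); in `per_window_rc` mode
#' they tile the original sequence only.
#'
#' @param record a [Biostrings::DNAStringSet] of length one, a
#'   [Biostrings::DNAString], or a nucleotide string.
#' @param spec a [WindowSpec-class] (default `windowSpec()`).
#' @param id sequence identifier used when `record` carries no name.
#' @return A [GenomicRanges::GRanges] of window coordinates with mcols
#'   `index` (1-based window ordinal).
#' @examples
#' fragmentSequence(paste(rep("ACGT", 125), collapse = ""), windowSpec())
#' @export
fragmentSequence <- function(record, spec = windowSpec(), id = NULL) {
  sid <- if (!is.null(id)) id else .seqId(record)
  d <- .asDNAString(record)
  L <- length(d)
  if (spec@extensionMode == "whole_sequence_rc") L <- 2L * L
  if (L < spec@windowLength)
    stop(sprintf(
      "sequence '%s' is shorter (%d bp analysed) than one window (%d bp)",
      sid, L, spec@windowLength), call. = FALSE)
  starts <- seq.int(1L, L - spec@windowLength + 1L, by = spec@step)
  gr <- GRanges(sid, IRanges(starts, width = spec@windowLength))
  mcols(gr) <- DataFrame(index = seq_along(starts))
  gr
}

#' Count overlapping k-mers
#'
#' Overlapping k-mers are counted with stride 1 in the canonical alphabetical
#' order of the 4^k k-mers. k-mers containing any ambiguity code (including N)
#' are skipped. With `extensionMode = "per_window_rc"` the sequence and its
#' reverse complement are counted as two separate strands (no k-mer spans the
#' junction) and the counts summed.
#'
#' @param seq nucleotide string, `DNAString` or single-sequence
#'   `DNAStringSet`.
#' @param k k-mer size: 2, 3 or 4.
#' @param extensionMode `"none"` (single strand) or `"per_window_rc"`.
#' @return Named integer vector of length `4^k`.
#' @examples
#' countKmers("AAAAA", 4)["AAAA"]                     # 2 (overlap counting)
#' countKmers("AAAA", 4, "per_window_rc")[c("AAAA", "TTTT")]
#' @export
countKmers <- function(seq, k, extensionMode = c("none", "per_window_rc")) {
  extensionMode <- match.arg(extensionMode)
  if (!k %in% c(2L, 3L, 4L)) stop("k must be 2, 3 or 4", call. = FALSE)
  d <- .asDNAString(seq)
  if (length(d) < k)
    stop("sequence shorter than k", call. = FALSE)
  n <- oligonucleotideFrequency(d, width = k)
  if (extensionMode == "per_window_rc")
    n <- n + oligonucleotideFrequency(reverseComplement(d), width = k)
  n
}

#' Maximal-order Markov expected tetranucleotide counts
#'
#' For each tetranucleotide n1n2n3n4,
#' `E = N(n1n2n3) * N(n2n3n4) / N(n2n3)`; when the core dinucleotide count is
#' zero, `E = 0`.
#'
#' @param n3 named counts of the 64 trinucleotides (canonical order).
#' @param n2 named counts of the 16 dinucleotides (canonical order).
#' @return Named numeric vector of 256 expected counts.
#' @examples
#' n3 <- countKmers("AAAAAAAAAA", 3); n2 <- countKmers("AAAAAAAAAA", 2)
#' expectedCounts(n3, n2)["AAAA"]  # 8*8/9
#' @export
expectedCounts <- function(n3, n2) {
  tb <- .kmerTables()
  if (length(n3) != 64L || length(n2) != 16L)
    stop("n3 must have 64 entries and n2 16 entries", call. = FALSE)
  if (abs(sum(n3) - sum(n2)) > 2)
    warning("trinucleotide and dinucleotide totals differ by more than the ",
            "number of counted strands; counts may come from different texts")
  core <- as.numeric(n2[tb$i_core])
  e <- as.numeric(n3[tb$i_left]) * as.numeric(n3[tb$i_right])
  e <- ifelse(core == 0, 0, e / ifelse(core == 0, 1, core))
  names(e) <- tb$k4
  e
}

#' Tetranucleotide z-scores against the maximal-order Markov null
#'
#' `Z = (N - E) / sqrt(var)` with
#' `var = E * (N(n2n3) - N(n1n2n3)) * (N(n2n3) - N(n2n3n4)) / N(n2n3)^2`;
#' cells with `var == 0` or `E == 0` get `Z = 0` so every window yields a
#' finite, comparable 256-vector.
#'
#' @param n4 named counts of the 256 tetranucleotides.
#' @param n3,n2 trinucleotide and dinucleotide counts from the same text.
#' @return Named numeric vector of 256 z-scores.
#' @export
tetraZScores <- function(n4, n3, n2) {
  tb <- .kmerTables()
  if (length(n4) != 256L)
    stop("n4 must have 256 entries", call. = FALSE)
  e <- expectedCounts(n3, n2)
  core <- as.numeric(n2[tb$i_core])
  v <- ifelse(core == 0, 0,
              e * (core - as.numeric(n3[tb$i_left])) *
                  (core - as.numeric(n3[tb$i_right])) /
                  ifelse(core == 0, 1, core)^2)
  z <- ifelse(v <= 0 | e == 0, 0, (as.numeric(n4) - e) / sqrt(pmax(v, 0)))
  names(z) <- tb$k4
  z
}

# z-score matrix (windows x 256) for all windows of a sequence, vectorised
# over windows via Views. Returns list(z, n4rows) where n4rows is the row sum
# of observed tetranucleotide counts (conservation bookkeeping).
.windowZMatrix <- function(d, windows, mode) {
  tb <- .kmerTables()
  v <- Views(d, start = start(windows), width = width(windows))
  N4 <- oligonucleotideFrequency(v, 4L)
  N3 <- oligonucleotideFrequency(v, 3L)
  N2 <- oligonucleotideFrequency(v, 2L)
  if (mode == "per_window_rc") {
    dr <- reverseComplement(d)
    L <- length(d)
    vr <- Views(dr, start = L - end(windows) + 1L, width = width(windows))
    N4 <- N4 + oligonucleotideFrequency(vr, 4L)
    N3 <- N3 + oligonucleotideFrequency(vr, 3L)
    N2 <- N2 + oligonucleotideFrequency(vr, 2L)
  }
  core <- N2[, tb$i_core, drop = FALSE]
  E <- N3[, tb$i_left, drop = FALSE] * N3[, tb$i_right, drop = FALSE]
  E <- ifelse(core == 0, 0, E / ifelse(core == 0, 1, core))
  V <- ifelse(core == 0, 0,
              E * (core - N3[, tb$i_left, drop = FALSE]) *
                  (core - N3[, tb$i_right, drop = FALSE]) /
                  ifelse(core == 0, 1, core)^2)
  Z <- ifelse(V <= 0 | E == 0, 0, (N4 - E) / sqrt(pmax(V, 1e-300)))
  colnames(Z) <- tb$k4
  list(z = Z, n4total = rowSums(N4))
}

#' Pearson correlation between two z-score vectors
#'
#' Standard product-moment correlation over the 256 components. A vector with
#' zero variance (degenerate window) correlates as 0, with a warning, rather
#' than propagating NaN.
#'
#' @param z1,z2 numeric vectors of equal length.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearsonR <- function(z1, z2) {
  if (length(z1) != length(z2))
    stop("vectors must have equal length", call. = FALSE)
  if (sd(z1) == 0 || sd(z2) == 0) {
    warning("zero-variance vector in correlation; returning 0")
    return(0)
  }
  as.numeric(cor(z1, z2))
}

#' Internal tetranucleotide correlation matrix of a fragment
#'
#' Cuts the fragment into windows, computes each window's tetranucleotide
#' z-score vector, and correlates all window pairs. Degenerate windows
#' (constant z-vector) correlate as 0 with a warning.
#'
#' @param record a single sequence ([Biostrings::DNAStringSet] of length one,
#'   `DNAString`, or string).
#' @param spec a [WindowSpec-class].
#' @param id identifier used when `record` carries no name.
#' @return A [TetraCorrelation-class].
#' @examples
#' set.seed(1)
#' s <- paste(sample(c("A", "C", "G", "T"), 1200, replace = TRUE),
#'            collapse = "")
#' tc <- tetraCorrelation(s, windowSpec())
#' meanR(tc)
#' @export
tetraCorrelation <- function(record, spec = windowSpec(), id = NULL) {
  sid <- if (!is.null(id)) id else .seqId(record)
  d <- .asDNAString(record)
  if (spec@extensionMode == "whole_sequence_rc")
    d <- xscat(d, reverseComplement(d))
  windows <- fragmentSequence(d, windowSpec(spec@windowLength, spec@step),
                              id = sid)
  if (length(windows) < 2L)
    stop(sprintf("sequence '%s' admits only %d window(s); need at least 2",
                 sid, length(windows)), call. = FALSE)
  zm <- .windowZMatrix(d, windows, spec@extensionMode)
  Z <- zm$z
  degen <- apply(Z, 1L, sd) == 0
  r <- matrix(0, nrow(Z), nrow(Z))
  ok <- !degen
  if (sum(ok) >= 2L)
    r[ok, ok] <- cor(t(Z[ok, , drop = FALSE]))
  if (any(degen))
    warning(sum(degen), " degenerate window(s) with constant z-vector; ",
            "their correlations are set to 0")
  diag(r) <- 1
  r <- (r + t(r)) / 2  # enforce exact symmetry against float noise
  new("TetraCorrelation", seqId = sid, windows = windows, r = r, z = Z,
      spec = spec)
}

#' Per-window mean correlation against the rest of the fragment
#'
#' For each window, the mean Pearson coefficient against all other (non-
#' masked) windows. Masked windows get `NA`.
#'
#' @param tc a [TetraCorrelation-class].
#' @param mask optional [GenomicRanges::GRanges] (e.g. rRNA annotation);
#'   windows overlapping any mask interval are excluded from both sides of
#'   the averaging.
#' @return Numeric vector, one score per window (`NA` for masked windows).
#' @export
windowScores <- function(tc, mask = NULL) {
  r <- tc@r
  nw <- nrow(r)
  masked <- rep(FALSE, nw)
  if (!is.null(mask) && length(mask) > 0L) {
    # compare by id to tolerate differing seqlevels between mask and windows
    rel <- as.character(seqnames(mask)) == tc@seqId
    if (any(rel))
      masked <- IRanges::overlapsAny(IRanges::ranges(tc@windows),
                                     IRanges::ranges(mask[rel]))
  }
  if (all(masked))
    stop("all windows are masked", call. = FALSE)
  keep <- which(!masked)
  sc <- rep(NA_real_, nw)
  if (length(keep) >= 2L) {
    sub <- r[keep, keep, drop = FALSE]
    sc[keep] <- (rowSums(sub) - 1) / (length(keep) - 1L)
  } else {
    sc[keep] <- NA_real_
  }
  sc
}

# centred running mean with shrinking edges
.runningMean <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  h <- w %/% 2L
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}

# least-squares single changepoint of sc[lo..hi]; returns the last index of
# the first segment, or NA when no split in the requested direction exists
.lsChangepoint <- function(sc, lo, hi, rising) {
  x <- sc[lo:hi]
  n <- length(x)
  if (n < 3L) return(NA_integer_)
  best <- Inf; bt <- NA_integer_
  for (t in seq_len(n - 1L)) {
    m1 <- mean(x[1:t]); m2 <- mean(x[(t + 1L):n])
    ok <- if (rising) m2 > m1 else m1 > m2
    if (!ok) next
    sse <- sum((x[1:t] - m1)^2) + sum((x[(t + 1L):n] - m2)^2)
    if (sse < best) { best <- sse; bt <- t }
  }
  if (is.na(bt)) NA_integer_ else lo + bt - 1L
}

#' Call low-correlation (candidate exogenous) regions
#'
#' Scores each window by its mean correlation against all other non-masked
#' windows and reports runs of at least `minRun` consecutive low-scoring
#' windows as regions.
#'
#' Two modes:
#' \describe{
#'   \item{automatic (`threshold = NULL`)}{scores are smoothed with a centred
#'     running mean of `smoothWidth` windows; a two-means split of the
#'     smoothed scores must separate by more than `gapFactor` times the pooled
#'     within-cluster SD (bimodality gate), otherwise no region is called.
#'     Windows below the midpoint of the two means are flagged, gaps of up to
#'     `bridge` windows inside a run are bridged, and each region edge is then
#'     refined by a least-squares changepoint fit on the raw scores within
#'     `refineWindows` windows of the coarse edge.}
#'   \item{manual (`threshold` given)}{raw scores below `threshold` are
#'     flagged directly (no gate, no smoothing, no refinement).}
#' }
#' In both modes reported region boundaries are corrected for window
#' overhang: a window is flagged when roughly a third or more of it is
#' foreign, so the union of flagged windows systematically overhangs the true
#' junction; each region edge is pulled in by `(windowLength - step) / 2`
#' bases (the expected overhang of the window midpoints).
#'
#' @param tc a [TetraCorrelation-class].
#' @param threshold optional absolute score threshold in (-1, 1); `NULL`
#'   (default) selects the automatic mode.
#' @param minRun minimum run length in windows (default 2).
#' @param mask optional `GRanges`; masked windows (e.g. rRNA) are excluded
#'   from scoring and can never be flagged.
#' @param smoothWidth running-mean width in windows for the automatic mode
#'   (default 5).
#' @param gapFactor bimodality gate: required ratio of cluster-mean gap to
#'   pooled within-cluster SD (default 3.5).
#' @param bridge maximal run interruption bridged, in windows (default 2).
#' @param refineWindows search radius of the changepoint edge refinement, in
#'   windows (default 20).
#' @return A [GenomicRanges::GRanges] of regions (possibly empty) with mcols
#'   `windowFirst`, `windowLast` (indices of the first/last flagged window),
#'   `meanRInside` (mean per-window score of the region's windows, i.e. their
#'   mean correlation against the rest of the fragment) and `meanROutside`
#'   (the same mean over the non-masked windows outside the region).
#' @export
callLowCorrelationRegions <- function(tc, threshold = NULL, minRun = 2,
                                      mask = NULL, smoothWidth = 5,
                                      gapFactor = 3.5, bridge = 2,
                                      refineWindows = 20) {
  if (!is.null(threshold) && (threshold <= -1 || threshold >= 1))
    stop("threshold must lie in (-1, 1)", call. = FALSE)
  sc <- windowScores(tc, mask)
  masked <- is.na(sc)
  keep <- which(!masked)
  empty <- GRanges()
  mcols(empty) <- DataFrame(windowFirst = integer(), windowLast = integer(),
                            meanRInside = numeric(), meanROutside = numeric())
  x <- sc[keep]
  if (length(x) < max(2L, minRun)) return(empty)
  if (is.null(threshold)) {
    s2 <- .runningMean(x, as.integer(smoothWidth))
    if (sd(s2) == 0) return(empty)
    km <- suppressWarnings(kmeans(s2, centers = sort(c(min(s2), max(s2)))))
    sw <- sqrt(mean(unlist(lapply(1:2, function(k)
      (s2[km$cluster == k] - km$centers[k])^2))))
    if (sw == 0 || abs(diff(km$centers)) <= gapFactor * sw) return(empty)
    flag <- s2 < mean(km$centers)
  } else {
    flag <- x < threshold
  }
  # bridge short interruptions inside runs
  if (bridge > 0L) {
    r <- rle(flag)
    inner <- which(!r$values & r$lengths <= bridge)
    inner <- inner[inner > 1L & inner < length(r$values)]
    if (length(inner)) {
      r$values[inner] <- TRUE
      flag <- inverse.rle(r)
    }
  }
  r <- rle(flag)
  endi <- cumsum(r$lengths)
  starti <- endi - r$lengths + 1L
  runs <- which(r$values & r$lengths >= minRun)
  if (!length(runs)) return(empty)
  spans <- lapply(runs, function(k) {
    i1 <- starti[k]; i2 <- endi[k]
    if (is.null(threshold)) {
      cp <- .lsChangepoint(x, max(1L, i1 - refineWindows),
                           min(i2, i1 + refineWindows), rising = FALSE)
      if (!is.na(cp) && cp + 1L <= i2) i1 <- cp + 1L
      cp <- .lsChangepoint(x, max(i1, i2 - refineWindows),
                           min(length(x), i2 + refineWindows), rising = TRUE)
      if (!is.na(cp) && cp >= i1) i2 <- cp
    }
    c(i1, i2)
  })
  spans <- unique(spans)
  w <- tc@windows
  trim <- (tc@spec@windowLength - tc@spec@step) %/% 2L
  out <- lapply(spans, function(sp) {
    wi <- keep[sp[1]]; wj <- keep[sp[2]]
    inside <- sp[1]:sp[2]
    outside <- setdiff(seq_along(x), inside)
    # mean per-window score (mean r against the rest of the fragment) of the
    # windows inside and outside the region -- the quantity thresholded on
    rIn <- mean(x[inside])
    rOut <- if (length(outside)) mean(x[outside]) else NA_real_
    st <- min(start(w)[wi] + trim, end(w)[wj] - trim)
    en <- max(end(w)[wj] - trim, st)
    gr <- GRanges(tc@seqId, IRanges(st, en))
    mcols(gr) <- DataFrame(windowFirst = wi, windowLast = wj,
                           meanRInside = rIn, meanROutside = rOut)
    gr
  })
  do.call(c, out)
}

#' Write a correlation matrix as square TSV
#'
#' Row and column names carry the window coordinates as `start-end`.
#'
#' @param tc a [TetraCorrelation-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCorrelationTSV <- function(tc, path) {
  lab <- sprintf("%d-%d", start(tc@windows), end(tc@windows))
  m <- tc@r
  dimnames(m) <- list(lab, lab)
  df <- data.frame(window = lab, m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-window summary as TSV
#'
#' Columns: window index, start, end, mean r against all other (non-masked)
#' windows.
#'
#' @inheritParams windowScores
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeWindowSummaryTSV <- function(tc, path, mask = NULL) {
  sc <- windowScores(tc, mask)
  df <- data.frame(index = mcols(tc@windows)$index,
                   start = start(tc@windows), end = end(tc@windows),
                   mean_r = round(sc, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called regions as BED
#'
#' BED is 0-based half-open; the 1-based inclusive region coordinates are
#' converted at this boundary.
#'
#' @param regions `GRanges` from [callLowCorrelationRegions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRegionsBED <- function(regions, path) {
  if (length(regions) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\tlow_correlation_region_%d\t%s\t.",
                   as.character(seqnames(regions)), start(regions) - 1L,
                   end(regions), seq_along(regions),
                   ifelse(is.na(regions$meanRInside), "0",
                          sprintf("%.4f", regions$meanRInside)))
  writeLines(lines, path)
  invisible(path)
}
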