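#' Window specification for signature scanning
#'
#' Holds the window length, step and reverse-complement extension mode used to
#' cut a fragment into windows. The defaults (300 bp windows, 100 bp step)
#' are the standard desk-scale settings for internal signature comparison of
#' 20-60 kb inserts.
#'
#' Extension modes:
#' \describe{
#'   \item{`per_window_rc`}{windows tile the original sequence; each window is
#'     counted together with its own reverse complement (two separate strands,
#'     counts summed). This is the strand-symmetric default.}
#'   \item{`whole_sequence_rc`}{the fragment is first concatenated with its
#'     reverse complement and windows tile the extended sequence, each counted
#'     single-stranded. Provided for compatibility with the literal
#'     extend-then-cut procedure; window coordinates then refer to the
#'     extended sequence.}
#' }
#'
#' @slot windowLength integer, window length in bases (>= 7).
#' @slot step integer, distance between consecutive window starts (>= 1,
#'   <= windowLength).
#' @slot extensionMode `"per_window_rc"` or `"whole_sequence_rc"`.
#' @exportClass WindowSpec
setClass("WindowSpec",
  representation(windowLength = "integer", step = "integer",
                 extensionMode = "character"),
  prototype(windowLength = 300L, step = 100L, extensionMode = "per_window_rc"))

setValidity("WindowSpec", function(object) {
  msg <- character()
  if (length(object@windowLength) != 1L || is.na(object@windowLength) ||
      object@windowLength < 7L)
    msg <- c(msg, "windowLength must be a single integer >= 7")
  if (length(object@step) != 1L || is.na(object@step) || object@step < 1L)
    msg <- c(msg, "step must be a single integer >= 1")
  if (length(msg) == 0L && object@step > object@windowLength)
    msg <- c(msg, "step must not exceed windowLength")
  if (!object@extensionMode %in% c("per_window_rc", "whole_sequence_rc"))
    msg <- c(msg, "extensionMode must be 'per_window_rc' or 'whole_sequence_rc'")
  if (length(msg)) msg else TRUE
})

#' Construct a WindowSpec
#'
#' @param windowLength window length in bases (default 300).
#' @param step step between window starts in bases (default 100).
#' @param extensionMode `"per_window_rc"` (default) or `"whole_sequence_rc"`;
#'   see [WindowSpec-class].
#' @return A [WindowSpec-class] object.
#' @examples
#' windowSpec()
#' windowSpec(500, 250)
#' @export
windowSpec <- function(windowLength = 300, step = 100,
                       extensionMode = c("per_window_rc", "whole_sequence_rc")) {
  extensionMode <- match.arg(extensionMode)
  new("WindowSpec", windowLength = as.integer(windowLength),
      step = as.integer(step), extensionMode = extensionMode)
}

setMethod("show", "WindowSpec", function(object) {
  cat(sprintf("WindowSpec: %d bp windows, step %d, mode %s\n",
              object@windowLength, object@step, object@extensionMode))
})

#' @describeIn WindowSpec-class window length accessor
#' @param x a `WindowSpec`
#' @export
windowLength <- function(x) x@windowLength

#' @describeIn WindowSpec-class step accessor
#' @export
windowStep <- function(x) x@step

#' @describeIn WindowSpec-class extension-mode accessor
#' @export
extensionMode <- function(x) x@extensionMode


#' Pairwise window correlation matrix of tetranucleotide z-scores
#'
#' Result container of [tetraCorrelation()]: the symmetric matrix of Pearson
#' coefficients between the 256-component z-score vectors of all window pairs
#' of one fragment, together with the window coordinates, the z-score matrix
#' itself and the window specification.
#'
#' @slot seqId identifier of the scanned sequence.
#' @slot windows [GenomicRanges::GRanges] of window coordinates (1-based
#'   inclusive, in the coordinates of the analysed sequence).
#' @slot r symmetric numeric matrix of Pearson coefficients, unit diagonal.
#' @slot z numeric matrix (windows x 256) of tetranucleotide z-scores.
#' @slot spec the [WindowSpec-class] used.
#' @exportClass TetraCorrelation
setClass("TetraCorrelation",
  representation(seqId = "character", windows = "GRanges", r = "matrix",
                 z = "matrix", spec = "WindowSpec"))

setValidity("TetraCorrelation", function(object) {
  r <- object@r
  msg <- character()
  if (nrow(r) != ncol(r)) msg <- c(msg, "r must be square")
  if (nrow(r) != length(object@windows))
    msg <- c(msg, "r dimension must match number of windows")
  if (nrow(r) > 0L) {
    if (max(abs(r - t(r))) > 1e-9) msg <- c(msg, "r must be symmetric")
    if (max(abs(diag(r) - 1)) > 1e-9) msg <- c(msg, "diagonal of r must be 1")
    if (min(r) < -1 - 1e-9 || max(r) > 1 + 1e-9)
      msg <- c(msg, "entries of r must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TetraCorrelation-class the correlation matrix
#' @param x a `TetraCorrelation`
#' @export
corMatrix <- function(x) x@r

#' @describeIn TetraCorrelation-class window coordinates as `GRanges`
#' @export
scanWindows <- function(x) x@windows

#' @describeIn TetraCorrelation-class z-score matrix (windows x 256)
#' @export
zScores <- function(x) x@z

#' @describeIn TetraCorrelation-class mean of the strict upper triangle
#'   (diagonal excluded)
#' @export
meanR <- function(x) {
  ut <- upper.tri(x@r)
  mean(x@r[ut])
}

#' @describeIn TetraCorrelation-class sample standard deviation (n-1
#'   denominator) of the strict upper triangle
#' @export
sdR <- function(x) {
  ut <- upper.tri(x@r)
  sd(x@r[ut])
}

setMethod("show", "TetraCorrelation", function(object) {
  cat(sprintf(
    "TetraCorrelation of '%s': %d windows (%d bp, step %d, %s)\n",
    object@seqId, length(object@windows), object@spec@windowLength,
    object@spec@step, object@spec@extensionMode))
  if (length(object@windows) >= 2L)
    cat(sprintf("  mean r = %.3f, sd = %.3f (off-diagonal upper triangle)\n",
                meanR(object), sdR(object)))
})


#' A PCR primer pair
#'
#' @slot forward forward primer, 5'->3', IUPAC codes allowed.
#' @slot reverse reverse primer, 5'->3' on the opposite strand, IUPAC codes
#'   allowed.
#' @slot name free-text label.
#' @slot maxMismatch maximum number of mismatches tolerated per primer site
#'   (none allowed in the three 3'-terminal bases).
#' @exportClass PrimerPair
setClass("PrimerPair",
  representation(forward = "character", reverse = "character",
                 name = "character", maxMismatch = "integer"))

setValidity("PrimerPair", function(object) {
  msg <- character()
  if (nchar(object@forward) < 10L || nchar(object@reverse) < 10L)
    msg <- c(msg, "both primers must be at least 10 bases long")
  if (object@maxMismatch < 0L) msg <- c(msg, "maxMismatch must be >= 0")
  ok <- rownames(Biostrings::IUPAC_CODE_MAP)
  bad <- function(p) any(!strsplit(p, "")[[1]] %in%
                           names(Biostrings::IUPAC_CODE_MAP))
  if (bad(object@forward) || bad(object@reverse))
    msg <- c(msg, "primers must contain IUPAC nucleotide codes only")
  if (length(msg)) msg else TRUE
})

#' Construct a primer pair
#'
#' The default is the universal bacterial 16S rDNA pair 27F/1492R, which
#' amplifies roughly 1.5 kb of the gene.
#'
#' @param forward,reverse primer sequences 5'->3' (IUPAC codes allowed).
#' @param name label for reports.
#' @param maxMismatch mismatches tolerated per site (default 2); the three
#'   3'-terminal bases must always match exactly (3' clamp).
#' @return A [PrimerPair-class].
#' @examples
#' primerPair()  # 27F / 1492R
#' @export
primerPair <- function(forward = "AGAGTTTGATCCTGGCTCAG",
                       reverse = "GGTTACCTTGTTACGACTT",
                       name = "27F/1492R", maxMismatch = 2) {
  new("PrimerPair", forward = toupper(forward), reverse = toupper(reverse),
      name = name, maxMismatch = as.integer(maxMismatch))
}

setMethod("show", "PrimerPair", function(object) {
  cat(sprintf("PrimerPair %s: F=%s R=%s (max %d mismatches, 3-base 3' clamp)\n",
              object@name, object@forward, object@reverse, object@maxMismatch))
})


#' Restriction digest fragment profile
#'
#' Ordered (descending) restriction fragment lengths of one digested molecule;
#' the lengths always sum to the molecule length.
#'
#' @slot ampliconId identifier of the digested sequence.
#' @slot fragmentLengths integer vector, sorted descending, each >= 1.
#' @slot totalLength length of the digested molecule.
#' @exportClass DigestProfile
setClass("DigestProfile",
  representation(ampliconId = "character", fragmentLengths = "integer",
                 totalLength = "integer"))

setValidity("DigestProfile", function(object) {
  msg <- character()
  if (length(object@fragmentLengths) == 0L)
    msg <- c(msg, "profile must contain at least one fragment")
  else {
    if (any(object@fragmentLengths < 1L))
      msg <- c(msg, "all fragment lengths must be >= 1")
    if (is.unsorted(rev(object@fragmentLengths)))
      msg <- c(msg, "fragment lengths must be sorted descending")
    if (sum(object@fragmentLengths) != object@totalLength)
      msg <- c(msg, "fragment lengths must sum to the molecule length")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn DigestProfile-class fragment lengths (descending)
#' @param x a `DigestProfile`
#' @export
fragmentLengths <- function(x) x@fragmentLengths

setMethod("show", "DigestProfile", function(object) {
  cat(sprintf("DigestProfile '%s': %d fragments [%s] (total %d bp)\n",
              object@ampliconId, length(object@fragmentLengths),
              paste(object@fragmentLengths, collapse = ", "),
              object@totalLength))
})


#' Third-order Markov sequence model
#'
#' Transition probabilities P(next base | preceding trinucleotide) over all 64
#' contexts. This is the compositional null the window z-scores test: a
#' sequence sampled from one such model carries a reproducible tetranucleotide
#' signature only through the strand asymmetry of its contexts (see the
#' methods vignette).
#'
#' @slot transitions 64 x 4 numeric matrix; rownames are the trinucleotide
#'   contexts in alphabetical order, colnames A, C, G, T; each row sums to 1.
#' @slot label free-text model label.
#' @exportClass MarkovModel3
setClass("MarkovModel3",
  representation(transitions = "matrix", label = "character"))

setValidity("MarkovModel3", function(object) {
  tr <- object@transitions
  msg <- character()
  if (!all(dim(tr) == c(64L, 4L)))
    msg <- c(msg, "transitions must be a 64 x 4 matrix")
  else {
    if (any(tr < 0)) msg <- c(msg, "transition probabilities must be >= 0")
    if (max(abs(rowSums(tr) - 1)) > 1e-12)
      msg <- c(msg, "each context's probabilities must sum to 1 (tol 1e-12)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MarkovModel3", function(object) {
  cat(sprintf("MarkovModel3 '%s': stationary GC %.1f%%\n",
              object@label, stationaryGC(object)))
})


#' Truth record for a simulated fragment
#'
#' Captures everything needed to regenerate a simulated fragment bit-exactly
#' and to evaluate detection calls against the known implant.
#'
#' @slot seqId fragment identifier.
#' @slot length fragment length in bp.
#' @slot hostModel,implantModel model labels ("" when absent).
#' @slot implantStart,implantEnd 1-based implant interval (NA when no implant).
#' @slot rrnaStart,rrnaEnd 1-based rRNA block interval (NA when absent).
#' @slot cdsIntervals [GenomicRanges::GRanges] of simulated CDS intervals.
#' @slot seed integer seed that regenerates the fragment.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(seqId = "character", length = "integer",
                 hostModel = "character", implantModel = "character",
                 implantStart = "integer", implantEnd = "integer",
                 rrnaStart = "integer", rrnaEnd = "integer",
                 cdsIntervals = "GRanges", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (object@length < 1L) msg <- c(msg, "length must be positive")
  if (!is.na(object@implantStart)) {
    if (is.na(object@implantEnd) || object@implantStart < 1L ||
        object@implantEnd > object@length ||
        object@implantStart > object@implantEnd)
      msg <- c(msg, "implant interval must lie within [1, length]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth '%s': %d bp, host model '%s', seed %d\n",
              object@seqId, object@length, object@hostModel, object@seed))
  if (!is.na(object@implantStart))
    cat(sprintf("  implant [%d, %d] from model '%s'\n", object@implantStart,
                object@implantEnd, object@implantModel))
  if (!is.na(object@rrnaStart))
    cat(sprintf("  rRNA block [%d, %d]\n", object@rrnaStart, object@rrnaEnd))
  if (length(object@cdsIntervals))
    cat(sprintf("  %d CDS intervals\n", length(object@cdsIntervals)))
})


#' Cross-clone correlation report
#'
#' Pearson correlation between two per-clone summary variables with the
#' two-sided p-value from the t-transform of the coefficient
#' (t = r sqrt(n-2)/sqrt(1-r^2), df = n-2).
#'
#' @slot n number of clones.
#' @slot r Pearson coefficient.
#' @slot p two-sided p-value.
#' @slot variableX,variableY names of the correlated variables.
#' @exportClass CorrelationReport
setClass("CorrelationReport",
  representation(n = "integer", r = "numeric", p = "numeric",
                 variableX = "character", variableY = "character"))

setValidity("CorrelationReport", function(object) {
  msg <- character()
  if (object@n < 3L) msg <- c(msg, "n must be >= 3")
  if (abs(object@r) > 1) msg <- c(msg, "r must lie in [-1, 1]")
  if (object@p <= 0 || object@p > 1) msg <- c(msg, "p must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CorrelationReport", function(object) {
  cat(sprintf("CorrelationReport: r(%s, %s) = %.3f, p = %.4f (n = %d)\n",
              object@variableX, object@variableY, object@r, object@p,
              object@n))
})
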