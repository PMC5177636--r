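# Synthetic fragment generator: 3rd-order Markov backbone, optional implanted
# segment from a second model, optional rRNA-like block copied from a packaged
# synthetic 16S reference, fake CDS annotation, full truth bookkeeping.
#
# Every stochastic operation is a pure function of its arguments including the
# seed; the global RNG state is saved and restored.

.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.BASES <- c("A", "C", "G", "T")

# stationary distribution over the 64 trinucleotide states by power iteration
.stationaryTrinuc <- function(tr) {
  # state i = (b1 b2 b3) -> state j = (b2 b3 b4) with probability tr[i, b4]
  M <- matrix(0, 64, 64)
  for (i0 in 0:63) for (b in 0:3) {
    j <- (i0 %% 16L) * 4L + b + 1L
    M[i0 + 1L, j] <- M[i0 + 1L, j] + tr[i0 + 1L, b + 1L]
  }
  pi0 <- rep(1 / 64, 64)
  for (iter in 1:500) {
    pi1 <- as.vector(pi0 %*% M)
    if (max(abs(pi1 - pi0)) < 1e-14) { pi0 <- pi1; break }
    pi0 <- pi1
  }
  pi0 / sum(pi0)
}

#' Stationary G+C percentage of a Markov model
#'
#' Computed exactly from the stationary distribution of the trinucleotide
#' state chain (power iteration), not by simulation.
#'
#' @param model a [MarkovModel3-class].
#' @return Stationary G+C content in percent.
#' @export
stationaryGC <- function(model) {
  pi3 <- .stationaryTrinuc(model@transitions)
  lastBase <- rep(1:4, 16)  # state index -> its third base
  freq <- vapply(1:4, function(b) sum(pi3[lastBase == b]), numeric(1))
  100 * (freq[2] + freq[3])
}

#' Build a 3rd-order Markov model with a target stationary G+C
#'
#' Each context row starts from the i.i.d. base distribution implied by
#' `gcTarget`, is perturbed multiplicatively by `exp(sharpness * N(0,1))`
#' (so `sharpness = 0` gives an i.i.d. model and larger values give stronger,
#' generically strand-asymmetric context dependence), and the G and C columns
#' are then rescaled by a common factor solved so that the exact stationary
#' G+C equals `gcTarget`.
#'
#' @param gcTarget stationary G+C percentage, strictly between 0 and 100.
#' @param sharpness context-dependence strength (>= 0). The packaged defaults
#'   used by [simulateFragment()] are 0.6 for host-like models and 0.1 for
#'   implant-like models.
#' @param seed integer seed; the model is a pure function of its arguments.
#' @param label model label.
#' @return A [MarkovModel3-class].
#' @examples
#' m <- makeMarkovModel(48, sharpness = 0.6, seed = 1)
#' stationaryGC(m)
#' @export
makeMarkovModel <- function(gcTarget, sharpness, seed, label = NULL) {
  if (gcTarget <= 0 || gcTarget >= 100)
    stop("gcTarget must lie strictly between 0 and 100", call. = FALSE)
  if (sharpness < 0) stop("sharpness must be >= 0", call. = FALSE)
  if (is.null(label))
    label <- sprintf("gc%g_sharp%g_seed%d", gcTarget, sharpness,
                     as.integer(seed))
  p <- c((100 - gcTarget) / 200, gcTarget / 200, gcTarget / 200,
         (100 - gcTarget) / 200)
  W <- .withSeed(seed, {
    eps <- matrix(rnorm(256), 64, 4)
    matrix(rep(p, each = 64), 64, 4) * exp(sharpness * eps)
  })
  W <- W / rowSums(W)
  rownames(W) <- mkAllStrings(.BASES, 3)
  colnames(W) <- .BASES
  gcOf <- function(delta) {
    W2 <- W
    W2[, c(2, 3)] <- W2[, c(2, 3)] * exp(delta)
    W2 <- W2 / rowSums(W2)
    m <- new("MarkovModel3", transitions = W2, label = label)
    stationaryGC(m)
  }
  f0 <- gcOf(0) - gcTarget
  delta <- if (abs(f0) < 1e-9) 0 else
    stats::uniroot(function(d) gcOf(d) - gcTarget, c(-6, 6),
                   tol = 1e-10)$root
  W[, c(2, 3)] <- W[, c(2, 3)] * exp(delta)
  W <- W / rowSums(W)
  # exact row normalisation against float drift
  W <- W / rowSums(W)
  new("MarkovModel3", transitions = W, label = label)
}

#' Sample a sequence from a Markov model
#'
#' The initial trinucleotide is drawn from the model's stationary
#' distribution; subsequent bases follow the context transitions.
#'
#' @param length sequence length in bp (>= 3).
#' @param model a [MarkovModel3-class].
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (for callers that manage their own seed).
#' @return A nucleotide string.
#' @export
simulateMarkov <- function(length, model, seed = NULL) {
  run <- function() {
    tr <- model@transitions
    cp <- t(apply(tr, 1, cumsum))
    pi3 <- .stationaryTrinuc(tr)
    s <- integer(length)
    st <- sample.int(64L, 1L, prob = pi3) - 1L
    s[1:3] <- c(st %/% 16L, (st %/% 4L) %% 4L, st %% 4L) + 1L
    if (length > 3L) {
      u <- runif(length)
      for (i in 4:length) {
        ctx <- (s[i - 3L] - 1L) * 16L + (s[i - 2L] - 1L) * 4L + s[i - 1L]
        s[i] <- findInterval(u[i], cp[ctx, ]) + 1L
      }
    }
    paste(.BASES[s[seq_len(length)]], collapse = "")
  }
  if (length < 3L) stop("length must be >= 3", call. = FALSE)
  if (is.null(seed)) run() else .withSeed(seed, run())
}

#' The packaged synthetic 16S-like reference
#'
#' A fixed, synthetic ~1.5 kb pseudo-16S sequence (not a real accession)
#' shipped with the package. It begins with the 27F primer site, ends with
#' the reverse complement of 1492R, and contains HhaI (GCGC) sites at fixed
#' positions, so it exercises the screening code without any download. Its
#' distinct composition reproduces the familiar observation that rRNA windows
#' stand out from their host backbone.
#'
#' @return A named [Biostrings::DNAStringSet] of length one.
#' @export
pseudo16S <- function() {
  path <- system.file("extdata", "pseudo16S_synthetic.fasta",
                      package = "tetrascan", mustWork = TRUE)
  readFasta(path)
}

#' Simulate a genome fragment with known implant
#'
#' The backbone is sampled from the host model; the implant interval is
#' resampled from the implant model with its context re-seeded at the
#' junction (drawn from the implant model's stationary distribution); the
#' optional rRNA block is copied verbatim from the packaged synthetic 16S
#' reference. The output is a pure function of the arguments including the
#' seed.
#'
#' @param length fragment length in bp.
#' @param host host [MarkovModel3-class].
#' @param implant optional `list(model = <MarkovModel3>, start = <int>,
#'   length = <int>)`.
#' @param rrna optional `c(start = <int>)` or `list(start = <int>,
#'   length = <int>)`; length defaults to the full packaged reference.
#' @param seed integer seed.
#' @param id fragment identifier (default derived from the seed).
#' @return A list with `record` (named `DNAStringSet` of length one) and
#'   `truth` (a [SyntheticTruth-class]).
#' @examples
#' host <- makeMarkovModel(48, 0.6, seed = 1)
#' frag <- simulateFragment(5000, host, seed = 7)
#' frag$truth
#' @export
simulateFragment <- function(length, host, implant = NULL, rrna = NULL,
                             seed = 0, id = NULL) {
  length <- as.integer(length)
  if (is.null(id)) id <- sprintf("synthetic_fragment_seed%d",
                                 as.integer(seed))
  iStart <- iEnd <- NA_integer_
  implantLabel <- ""
  if (!is.null(implant)) {
    stopifnot(is.list(implant), is(implant$model, "MarkovModel3"))
    iStart <- as.integer(implant$start)
    iEnd <- iStart + as.integer(implant$length) - 1L
    if (iStart < 1L || iEnd > length || iStart > iEnd)
      stop("implant interval outside [1, length]", call. = FALSE)
    implantLabel <- implant$model@label
  }
  rStart <- rEnd <- NA_integer_
  if (!is.null(rrna)) {
    ref <- pseudo16S()[[1]]
    rStart <- as.integer(rrna[["start"]])
    rLen <- if (!is.null(rrna[["length"]])) as.integer(rrna[["length"]])
            else length(ref)
    if (rLen > length(ref))
      stop("requested rRNA block longer than the packaged reference (",
           length(ref), " bp)", call. = FALSE)
    rEnd <- rStart + rLen - 1L
    if (rStart < 1L || rEnd > length)
      stop("rRNA interval outside [1, length]", call. = FALSE)
    if (!is.na(iStart) && rStart <= iEnd && rEnd >= iStart)
      stop("implant and rRNA blocks overlap", call. = FALSE)
  }
  seqChr <- .withSeed(seed, {
    backbone <- simulateMarkov(length, host)
    s <- backbone
    if (!is.na(iStart)) {
      piece <- simulateMarkov(iEnd - iStart + 1L, implant$model)
      s <- paste0(substr(s, 1L, iStart - 1L), piece,
                  substr(s, iEnd + 1L, length))
    }
    s
  })
  if (!is.na(rStart)) {
    ref <- as.character(pseudo16S()[[1]])
    piece <- substr(ref, 1L, rEnd - rStart + 1L)
    seqChr <- paste0(substr(seqChr, 1L, rStart - 1L), piece,
                     substr(seqChr, rEnd + 1L, length))
  }
  rec <- DNAStringSet(seqChr)
  names(rec) <- id
  mcols(rec) <- DataFrame(description = "simulated fragment",
                          source = "synthetic")
  truth <- new("SyntheticTruth", seqId = id, length = length,
               hostModel = host@label, implantModel = implantLabel,
               implantStart = iStart, implantEnd = iEnd,
               rrnaStart = rStart, rrnaEnd = rEnd,
               cdsIntervals = GRanges(), seed = as.integer(seed))
  list(record = rec, truth = truth)
}

# draw non-overlapping ORF intervals covering ~frac of [a, b]
.placeOrfs <- function(a, b, frac, minLen = 300L, maxLen = 2000L) {
  regionLen <- b - a + 1L
  target <- round(frac * regionLen)
  if (target == 0L) return(NULL)
  if (target < minLen) {
    # a sub-minimum target is representable only by a single minimum-length
    # ORF; accept it when that stays within the 2-point coverage tolerance
    if (regionLen >= minLen && (minLen - target) <= 0.02 * regionLen)
      target <- minLen
    else
      stop(sprintf(
        "coding fraction %.2f infeasible on a %d bp region (minimum ORF %d bp)",
        frac, regionLen, minLen), call. = FALSE)
  }
  lens <- integer()
  while (sum(lens) < target)
    lens <- c(lens, sample(minLen:maxLen, 1L))
  over <- sum(lens) - target
  k <- length(lens)
  if (lens[k] - over >= minLen) {
    lens[k] <- lens[k] - over
  } else {
    lens <- lens[-k]
    deficit <- target - sum(lens)
    i <- 1L
    while (deficit > 0L && i <= length(lens)) {
      room <- maxLen - lens[i]
      add <- min(room, deficit)
      lens[i] <- lens[i] + add
      deficit <- deficit - add
      i <- i + 1L
    }
    if (deficit > 0L) lens <- c(lens, max(minLen, deficit))
  }
  nOrf <- length(lens)
  gapTotal <- regionLen - sum(lens)
  if (gapTotal < 0L) {  # over-coverage beyond the region: trim the last ORF
    lens[nOrf] <- lens[nOrf] + gapTotal
    gapTotal <- 0L
  }
  cuts <- sort(runif(nOrf))
  gaps <- floor(gapTotal * diff(c(0, cuts, 1)))
  gaps[nOrf + 1L] <- gaps[nOrf + 1L] + (gapTotal - sum(gaps))
  starts <- a + cumsum(c(0L, lens[-nOrf])) + cumsum(gaps[seq_len(nOrf)])
  IRanges(as.integer(starts), width = lens)
}

#' Simulate a CDS annotation matching the truth layout
#'
#' Places non-overlapping CDS intervals covering approximately the requested
#' fraction of the host backbone and of the implant (each within about 2
#' percentage points), with ORF lengths drawn uniformly from 300-2000 bp.
#' The rRNA block, when present, receives no CDS.
#'
#' @param truth a [SyntheticTruth-class].
#' @param hostCodingFrac fraction of the host backbone covered by CDS
#'   (default 0.75).
#' @param implantCodingFrac fraction of the implant covered (default 0.30;
#'   exogenous regions are typically gene-poor after transfer).
#' @param seed integer seed.
#' @return A [GenomicRanges::GRanges] with mcols `kind = "CDS"` and `label`.
#' @export
makeCdsAnnotation <- function(truth, hostCodingFrac = 0.75,
                              implantCodingFrac = 0.30, seed = 0) {
  if (hostCodingFrac < 0 || hostCodingFrac > 1 ||
      implantCodingFrac < 0 || implantCodingFrac > 1)
    stop("coding fractions must lie in [0, 1]", call. = FALSE)
  blocked <- IRanges()
  if (!is.na(truth@implantStart))
    blocked <- c(blocked, IRanges(truth@implantStart, truth@implantEnd))
  if (!is.na(truth@rrnaStart))
    blocked <- c(blocked, IRanges(truth@rrnaStart, truth@rrnaEnd))
  hostSegs <- IRanges::setdiff(IRanges(1L, truth@length), blocked)
  # backbone slivers shorter than one ORF (e.g. beside an implant at the
  # fragment edge) cannot carry coding sequence; skip them silently
  hostSegs <- hostSegs[width(hostSegs) >= 300L]
  ir <- .withSeed(seed, {
    pieces <- list()
    for (i in seq_along(hostSegs)) {
      p <- .placeOrfs(start(hostSegs)[i], end(hostSegs)[i], hostCodingFrac)
      if (!is.null(p)) pieces[[length(pieces) + 1L]] <- p
    }
    if (!is.na(truth@implantStart) && implantCodingFrac > 0) {
      p <- .placeOrfs(truth@implantStart, truth@implantEnd,
                      implantCodingFrac)
      if (!is.null(p)) pieces[[length(pieces) + 1L]] <- p
    }
    if (length(pieces)) do.call(c, pieces) else IRanges()
  })
  if (length(ir) == 0L) {
    out <- GRanges()
    mcols(out) <- DataFrame(kind = character(), label = character())
    return(out)
  }
  ir <- ir[order(start(ir))]
  out <- GRanges(truth@seqId, ir)
  mcols(out) <- DataFrame(kind = rep("CDS", length(ir)),
                          label = sprintf("orf_%03d", seq_along(ir)))
  out
}

#' Simulate a small clone library
#'
#' Generates `length(implantLengths)` fragments sharing one host model
#' family; fragment i carries an implant of `implantLengths[i]` bp (0 = no
#' implant) centred in the fragment, plus a CDS annotation in which the
#' implant is gene-poor. Larger implants therefore depress both the coding
#' percentage and the internal signature coherence, coupling the two
#' clone-level summaries.
#'
#' @param implantLengths integer vector of implant sizes in bp (0 for none).
#' @param length fragment length (default 30000).
#' @param hostGC,implantGC stationary G+C targets (defaults 48 and 60).
#' @param hostSharpness,implantSharpness context-dependence strengths
#'   (defaults 0.6 and 0.1).
#' @param hostCodingFrac,implantCodingFrac CDS coverage of backbone and
#'   implant (defaults 0.75 and 0.30).
#' @param seed integer seed.
#' @return A list with `records` (a named `DNAStringSet`), `truths` (list of
#'   [SyntheticTruth-class]) and `annotations` (list of `GRanges`).
#' @export
simulateCloneSet <- function(implantLengths = c(0, 0, 3000, 6000, 10000),
                             length = 30000, hostGC = 48, implantGC = 60,
                             hostSharpness = 0.6, implantSharpness = 0.1,
                             hostCodingFrac = 0.75, implantCodingFrac = 0.30,
                             seed = 1) {
  n <- base::length(implantLengths)
  recs <- vector("list", n)
  truths <- vector("list", n)
  annos <- vector("list", n)
  for (i in seq_len(n)) {
    subSeed <- (as.integer(seed) * 131L + i) %% .Machine$integer.max
    host <- makeMarkovModel(hostGC, hostSharpness, seed = subSeed * 2L + 1L)
    impl <- NULL
    if (implantLengths[i] > 0) {
      implModel <- makeMarkovModel(implantGC, implantSharpness,
                                   seed = subSeed * 2L + 2L)
      st <- as.integer((length - implantLengths[i]) / 2) + 1L
      impl <- list(model = implModel, start = st,
                   length = as.integer(implantLengths[i]))
    }
    frag <- simulateFragment(length, host, implant = impl, seed = subSeed,
                             id = sprintf("clone_%02d", i))
    anno <- makeCdsAnnotation(frag$truth, hostCodingFrac, implantCodingFrac,
                              seed = subSeed + 7L)
    frag$truth@cdsIntervals <- anno
    recs[[i]] <- frag$record
    truths[[i]] <- frag$truth
    annos[[i]] <- anno
  }
  records <- do.call(c, recs)
  list(records = records, truths = truths, annotations = annos)
}
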