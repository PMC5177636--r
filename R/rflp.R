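# Computational half of 16S rDNA RFLP library screening: in-silico PCR with
# degenerate primers, restriction digestion, and fragment-profile comparison
# against the host control. PCR is modelled as bounded-mismatch site-pair
# finding with a 3-base 3' clamp; no thermodynamics.

# primer match positions on one strand: IUPAC-degeneracy-aware, at most
# maxMismatch mismatches, none of them in the `clamp` 3'-terminal bases of
# the primer as laid on this strand (clampEnd = "right" when the primer 3'
# end is the rightmost base of the site, "left" when it is the leftmost).
.primerSites <- function(subject, primer, maxMismatch, clamp = 3L,
                         clampEnd = c("right", "left")) {
  clampEnd <- match.arg(clampEnd)
  p <- DNAString(primer)
  hits <- matchPattern(p, subject, max.mismatch = maxMismatch, fixed = FALSE)
  # drop hits protruding beyond the template ends
  hits <- hits[start(hits) >= 1L & end(hits) <= length(subject)]
  if (length(hits) == 0L) return(IRanges())
  ok <- vapply(seq_along(hits), function(i) {
    idx <- if (clampEnd == "right")
      (length(p) - clamp + 1L):length(p) else 1:clamp
    neditAt(p[idx], subject,
            at = start(hits)[i] + idx[1] - 1L, fixed = FALSE) == 0L
  }, logical(1))
  IRanges::ranges(hits)[ok]
}

#' Find primer-pair amplicons in a sequence (in-silico PCR)
#'
#' The forward primer is matched on both strands with IUPAC-degeneracy-aware
#' comparison allowing up to `maxMismatch(primers)` mismatches, none within
#' the three 3'-terminal bases; the reverse primer is matched as its reverse
#' complement downstream on the same template strand. Every site pair whose
#' product length falls within `[minLen, maxLen]` is reported. The amplicon
#' spans primer to primer, inclusive of both primer sites.
#'
#' @param record a single sequence (`DNAStringSet` of length one, `DNAString`
#'   or string).
#' @param primers a [PrimerPair-class] (default 27F/1492R).
#' @param minLen,maxLen product length bounds in bp (defaults 1200 and 1700,
#'   bracketing the ~1.5 kb 16S product).
#' @param id identifier used when `record` carries no name.
#' @return A [GenomicRanges::GRanges] on the input sequence (possibly empty)
#'   with strand set to the template strand of the forward primer and mcols
#'   `sequence` (amplicon 5'->3' from the forward primer) and `ampliconId`.
#' @export
findAmplicons <- function(record, primers = primerPair(), minLen = 1200,
                          maxLen = 1700, id = NULL) {
  sid <- if (!is.null(id)) id else .seqId(record)
  d <- .asDNAString(record)
  L <- length(d)
  rcRev <- reverseComplement(DNAString(primers@reverse))
  out <- list()
  for (str in c("+", "-")) {
    tmpl <- if (str == "+") d else reverseComplement(d)
    f <- .primerSites(tmpl, primers@forward, primers@maxMismatch,
                      clampEnd = "right")
    if (length(f) == 0L) next
    # reverse primer lies on the opposite strand; on this template it appears
    # as its reverse complement, whose leftmost base is the primer's 3' end
    r <- .primerSites(tmpl, as.character(rcRev), primers@maxMismatch,
                      clampEnd = "left")
    if (length(r) == 0L) next
    for (i in seq_along(f)) for (j in seq_along(r)) {
      if (end(r)[j] <= end(f)[i]) next
      len <- end(r)[j] - start(f)[i] + 1L
      if (len < minLen || len > maxLen) next
      ampl <- as.character(subseq(tmpl, start(f)[i], end(r)[j]))
      # map back to original coordinates
      if (str == "+") {
        st <- start(f)[i]; en <- end(r)[j]
      } else {
        st <- L - end(r)[j] + 1L; en <- L - start(f)[i] + 1L
      }
      gr <- GRanges(sid, IRanges(st, en), strand = str)
      mcols(gr) <- DataFrame(
        sequence = ampl,
        ampliconId = sprintf("%s_amplicon_%d_%d%s", sid, st, en, str))
      out[[length(out) + 1L]] <- gr
    }
  }
  if (!length(out)) {
    empty <- GRanges()
    mcols(empty) <- DataFrame(sequence = character(),
                              ampliconId = character())
    return(empty)
  }
  do.call(c, out)
}

#' In-silico restriction digest
#'
#' Cuts after `cutOffset` bases of every occurrence of the recognition site
#' (overlapping occurrences each produce a cut) and returns the fragment
#' lengths between successive cuts and the molecule ends, sorted descending.
#' The default is HhaI: site GCGC, cut GCG^C.
#'
#' @param seq the molecule (string, `DNAString`, or single-sequence
#'   `DNAStringSet`).
#' @param site non-degenerate recognition sequence (default `"GCGC"`).
#' @param cutOffset cut placed after this many bases of the site (default 3).
#' @param id identifier for the profile.
#' @return A [DigestProfile-class].
#' @examples
#' fragmentLengths(digestSequence("AAGCGCAA"))  # 5 3
#' fragmentLengths(digestSequence("GCGCGC"))    # 3 2 1
#' @export
digestSequence <- function(seq, site = "GCGC", cutOffset = 3, id = NULL) {
  sid <- if (!is.null(id)) id else .seqId(seq, default = "amplicon")
  d <- .asDNAString(seq)
  if (length(d) == 0L) stop("empty sequence", call. = FALSE)
  if (cutOffset < 0 || cutOffset > nchar(site))
    stop("cutOffset must lie in [0, nchar(site)]", call. = FALSE)
  if (any(!strsplit(toupper(site), "")[[1]] %in% c("A", "C", "G", "T")))
    stop("recognition site must be non-degenerate (A/C/G/T only)",
         call. = FALSE)
  hits <- matchPattern(DNAString(toupper(site)), d)
  cuts <- sort(unique(start(hits) + as.integer(cutOffset) - 1L))
  cuts <- cuts[cuts >= 1L & cuts < length(d)]  # cut after this position
  bounds <- c(0L, cuts, length(d))
  lens <- diff(bounds)
  new("DigestProfile", ampliconId = sid,
      fragmentLengths = as.integer(sort(lens, decreasing = TRUE)),
      totalLength = length(d))
}

#' Compare two restriction fragment profiles
#'
#' Greedy length matching: working from the longest query fragment down, each
#' query fragment pairs with the closest unused control fragment within
#' `toleranceFrac * max(query length, control length)`. The profiles match
#' iff every fragment of both profiles pairs. The fractional tolerance is a
#' proxy for gel resolution.
#'
#' @param query,control [DigestProfile-class] objects.
#' @param toleranceFrac fractional length tolerance in `[0, 1)` (default
#'   0.05).
#' @return A list with elements `queryId`, `controlId`, `matched` (logical)
#'   and `unmatchedFragments` (data.frame with columns `length`, `profile`).
#' @export
compareProfiles <- function(query, control, toleranceFrac = 0.05) {
  stopifnot(is(query, "DigestProfile"), is(control, "DigestProfile"))
  if (toleranceFrac < 0 || toleranceFrac >= 1)
    stop("toleranceFrac must lie in [0, 1)", call. = FALSE)
  q <- query@fragmentLengths
  ct <- control@fragmentLengths
  usedC <- rep(FALSE, length(ct))
  matchedQ <- rep(FALSE, length(q))
  for (i in seq_along(q)) {
    cand <- which(!usedC &
                    abs(ct - q[i]) <= toleranceFrac * pmax(ct, q[i]))
    if (length(cand)) {
      pick <- cand[which.min(abs(ct[cand] - q[i]))]
      usedC[pick] <- TRUE
      matchedQ[i] <- TRUE
    }
  }
  unmatched <- rbind(
    if (any(!matchedQ)) data.frame(length = q[!matchedQ], profile = "query")
    else NULL,
    if (any(!usedC)) data.frame(length = ct[!usedC], profile = "control")
    else NULL)
  if (is.null(unmatched))
    unmatched <- data.frame(length = integer(), profile = character())
  list(queryId = query@ampliconId, controlId = control@ampliconId,
       matched = nrow(unmatched) == 0L, unmatchedFragments = unmatched)
}

#' Screen one clone for a non-host 16S rDNA insert
#'
#' Runs the in-silico PCR, digests every amplicon, and compares profiles
#' against the host control. The selection rule mirrors library screening
#' practice: a profile *different* from the host control marks a candidate
#' insert-borne 16S gene.
#'
#' @param record the clone sequence.
#' @param primers a [PrimerPair-class].
#' @param control the host-16S [DigestProfile-class] (built from a user-
#'   supplied reference via [digestSequence()]).
#' @param site,cutOffset restriction enzyme (defaults: HhaI, GCGC, cut after
#'   base 3).
#' @param toleranceFrac gel-resolution proxy for [compareProfiles()].
#' @param minLen,maxLen amplicon length bounds, as in [findAmplicons()].
#' @param id identifier used when `record` carries no name.
#' @return A list with `verdict` (`"positive"`, `"negative"` or
#'   `"no_amplicon"`), `amplicons` (the `GRanges` from [findAmplicons()]) and
#'   `profiles` (list of [DigestProfile-class], one per amplicon).
#' @export
screenClone <- function(record, primers = primerPair(), control,
                        site = "GCGC", cutOffset = 3, toleranceFrac = 0.05,
                        minLen = 1200, maxLen = 1700, id = NULL) {
  amp <- findAmplicons(record, primers, minLen = minLen, maxLen = maxLen,
                       id = id)
  if (length(amp) == 0L)
    return(list(verdict = "no_amplicon", amplicons = amp, profiles = list()))
  profiles <- lapply(seq_along(amp), function(i)
    digestSequence(amp$sequence[i], site = site, cutOffset = cutOffset,
                   id = amp$ampliconId[i]))
  differs <- vapply(profiles, function(p)
    !compareProfiles(p, control, toleranceFrac)$matched, logical(1))
  verdict <- if (any(differs)) "positive" else "negative"
  list(verdict = verdict, amplicons = amp, profiles = profiles)
}
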