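# Coding-density statistics and cross-clone correlation of coding percentage
# with internal signature coherence.

#' Coding-region percentage of a fragment
#'
#' Overlapping CDS intervals are merged before summing, so every base is
#' counted once; rRNA and other non-CDS intervals are ignored.
#'
#' @param intervals a [GenomicRanges::GRanges]; only rows with
#'   `kind == "CDS"` contribute (if no `kind` mcol is present, all intervals
#'   are treated as CDS).
#' @param length fragment length in bp (> 0).
#' @return Percentage of the fragment covered by coding intervals.
#' @examples
#' gr <- GenomicRanges::GRanges("f", IRanges::IRanges(c(1, 51), c(100, 150)),
#'                              kind = "CDS")
#' codingPercent(gr, 200)  # 75
#' @export
codingPercent <- function(intervals, length) {
  if (length <= 0) stop("fragment length must be positive", call. = FALSE)
  if (is.null(intervals) || length(intervals) == 0L) return(0)
  if (!is.null(mcols(intervals)$kind))
    intervals <- intervals[mcols(intervals)$kind == "CDS"]
  if (length(intervals) == 0L) return(0)
  if (min(start(intervals)) < 1L || max(end(intervals)) > length)
    stop("CDS interval outside [1, length]", call. = FALSE)
  merged <- reduce(intervals, ignore.strand = TRUE)
  100 * sum(width(merged)) / length
}

#' Two-sided p-value of a Pearson coefficient
#'
#' Uses the t-transform `t = r sqrt(n-2) / sqrt(1-r^2)` against the
#' t-distribution with `n - 2` degrees of freedom.
#'
#' @param r Pearson coefficient.
#' @param n number of observations (>= 3).
#' @return Two-sided p-value.
#' @examples
#' pearsonPValue(0.895, 5)  # ~0.040
#' @export
pearsonPValue <- function(r, n) {
  if (n < 3) stop("n must be >= 3", call. = FALSE)
  if (abs(r) >= 1) return(.Machine$double.xmin)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(-abs(t), df = n - 2)
}

#' Correlate two per-clone summary variables
#'
#' Pearson correlation across clones with the two-sided t-transform p-value.
#'
#' @param summaries a data.frame of per-clone summaries (e.g. from
#'   [buildCloneSummary()] rows bound together).
#' @param x,y column names of the two numeric variables.
#' @return A [CorrelationReport-class].
#' @examples
#' df <- data.frame(coding_percent = c(54.4, 75.6, 44.4, 58, 65),
#'                  mean_r = c(.45, .59, .20, .52, .48))
#' correlateClones(df, "coding_percent", "mean_r")
#' @export
correlateClones <- function(summaries, x, y) {
  for (v in c(x, y)) {
    if (!v %in% names(summaries))
      stop("no column '", v, "' in summaries", call. = FALSE)
    if (!is.numeric(summaries[[v]]))
      stop("column '", v, "' is not numeric", call. = FALSE)
  }
  n <- nrow(summaries)
  if (n < 3) stop("need at least 3 clones", call. = FALSE)
  xv <- summaries[[x]]; yv <- summaries[[y]]
  if (sd(xv) == 0) stop("variable '", x, "' is constant", call. = FALSE)
  if (sd(yv) == 0) stop("variable '", y, "' is constant", call. = FALSE)
  r <- as.numeric(cor(xv, yv))
  new("CorrelationReport", n = as.integer(n), r = r,
      p = pearsonPValue(r, n), variableX = x, variableY = y)
}

#' Build the per-clone summary row
#'
#' Joins the sequence-derived quantities (length, G+C), the annotation-derived
#' quantities (ORF count, coding percentage) and the signature statistics
#' (mean and SD of the off-diagonal window correlations).
#'
#' @param record the clone sequence (named `DNAStringSet` of length one).
#' @param intervals annotation `GRanges` for this clone (may be empty/NULL).
#' @param tc the clone's [TetraCorrelation-class].
#' @return A one-row data.frame with columns `seq_id`, `length`,
#'   `gc_percent`, `n_orfs`, `coding_percent`, `mean_r`, `sd_r`.
#' @export
buildCloneSummary <- function(record, intervals, tc) {
  sid <- .seqId(record)
  if (!identical(sid, tc@seqId))
    stop(sprintf("sequence id '%s' does not match correlation matrix id '%s'",
                 sid, tc@seqId), call. = FALSE)
  d <- .asDNAString(record)
  if (!is.null(intervals) && length(intervals) > 0L) {
    rel <- as.character(seqnames(intervals)) == sid
    if (!all(rel))
      stop(sprintf("intervals for '%s' contain foreign seq_id(s): %s", sid,
                   paste(unique(as.character(seqnames(intervals))[!rel]),
                         collapse = ", ")), call. = FALSE)
    cds <- if (!is.null(mcols(intervals)$kind))
      intervals[mcols(intervals)$kind == "CDS"] else intervals
  } else {
    cds <- GRanges()
  }
  data.frame(
    seq_id = sid,
    length = length(d),
    gc_percent = round(as.numeric(gcContent(d)), 1),
    n_orfs = length(cds),
    coding_percent = round(codingPercent(cds, length(d)), 1),
    mean_r = meanR(tc),
    sd_r = sdR(tc),
    stringsAsFactors = FALSE)
}
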