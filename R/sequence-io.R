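# Sequence and interval input/output.
#
# Sequences live in named DNAStringSet objects with mcols 'description' and
# 'source'; intervals live in GRanges with mcols 'kind' (CDS/rRNA/other) and
# 'label'. All user-facing coordinates are 1-based inclusive (GFF3 convention).

.IUPAC <- names(Biostrings::IUPAC_CODE_MAP)  # A C G T M R W S Y K V H D B N

# uppercase, U->T, then fail with residue and position on anything non-IUPAC
.normalizeSeq <- function(s, id) {
  s <- chartr("u", "T", toupper(s))
  s <- gsub("U", "T", s, fixed = TRUE)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% .IUPAC)
  if (length(bad))
    stop(sprintf("record '%s': invalid residue '%s' at position %d",
                 id, ch[bad[1]], bad[1]), call. = FALSE)
  if (!nchar(s))
    stop(sprintf("record '%s': empty sequence", id), call. = FALSE)
  s
}

#' Read a (multi-)FASTA file of nucleotide sequences
#'
#' Sequences are uppercased, U is mapped to T, and any residue outside the
#' IUPAC nucleotide alphabet is a hard error naming the record and position.
#' Record ids (the first whitespace-delimited token of each header) must be
#' unique.
#'
#' @param path path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] with `mcols()` columns
#'   `description` (remainder of the header) and `source` (the file path).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x some clone", "acgt"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(raw) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(raw)
  if (is.null(headers) || any(!nzchar(headers)))
    stop("malformed FASTA '", path, "': record with empty header",
         call. = FALSE)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- vapply(seq_along(raw), function(i)
    .normalizeSeq(as.character(raw[[i]]), ids[i]), character(1))
  out <- DNAStringSet(seqs)
  names(out) <- ids
  mcols(out) <- DataFrame(description = desc, source = path)
  out
}

#' Write sequences to FASTA
#'
#' @param x a named [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- DNAStringSet(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("all records must be named", call. = FALSE)
  writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Extract the sequence from a GenBank flat file
#'
#' Reads only the ORIGIN block (sequence extraction; features are ignored).
#' Useful for deposited accessions saved as GenBank records.
#'
#' @param path path to a GenBank flat file (single record).
#' @return A named [Biostrings::DNAStringSet] of length one; the name is the
#'   LOCUS/ACCESSION identifier.
#' @export
readGenBankSeq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  acc <- grep("^(ACCESSION|LOCUS)\\s+", lines, value = TRUE)
  id <- if (length(acc)) strsplit(sub("^\\S+\\s+", "", acc[1]), "\\s+")[[1]][1]
        else tools::file_path_sans_ext(basename(path))
  o <- grep("^ORIGIN", lines)
  e <- grep("^//", lines)
  if (!length(o) || !length(e) || e[length(e)] <= o[1])
    stop("no ORIGIN...// sequence block in '", path, "'", call. = FALSE)
  body <- lines[(o[1] + 1L):(e[e > o[1]][1] - 1L)]
  s <- gsub("[0-9[:space:]]", "", paste(body, collapse = ""))
  s <- .normalizeSeq(s, id)
  out <- DNAStringSet(s)
  names(out) <- id
  mcols(out) <- DataFrame(description = "", source = path)
  out
}

#' Reverse complement of a nucleotide sequence
#'
#' Thin character-level wrapper around
#' [Biostrings::reverseComplement()]; N complements to N, IUPAC ambiguity
#' codes to their complements. Applying it twice returns the input.
#'
#' @param seq a nucleotide string, [Biostrings::DNAString] or
#'   [Biostrings::DNAStringSet].
#' @return Object of the same type as the input.
#' @examples
#' revComp("AAAC")  # "GTTT"
#' @export
revComp <- function(seq) {
  if (is.character(seq)) {
    as.character(reverseComplement(DNAStringSet(seq)))
  } else {
    reverseComplement(seq)
  }
}

#' G+C content in percent
#'
#' 100 * (#G + #C) / (#A + #C + #G + #T). Ambiguity codes (including N) are
#' excluded from both numerator and denominator. A sequence with no
#' unambiguous base is an error.
#'
#' @param seq nucleotide string, [Biostrings::DNAString] or
#'   [Biostrings::DNAStringSet].
#' @return Numeric percentage (vector for a `DNAStringSet`).
#' @examples
#' gcContent("ATGC")  # 50
#' @export
gcContent <- function(seq) {
  if (is.character(seq)) seq <- DNAStringSet(seq)
  if (is(seq, "DNAString")) seq <- DNAStringSet(seq)
  counts <- letterFrequency(seq, c("A", "C", "G", "T"), OR = 0)
  denom <- rowSums(counts)
  if (any(denom == 0))
    stop("G+C content undefined: sequence contains no unambiguous base",
         call. = FALSE)
  out <- 100 * (counts[, "C"] + counts[, "G"]) / denom
  if (!is.null(names(seq))) names(out) <- names(seq)
  out
}

.KINDS <- c("CDS", "rRNA", "other")

.asKind <- function(type) {
  kind <- rep("other", length(type))
  kind[toupper(type) == "CDS"] <- "CDS"
  kind[toupper(type) == "RRNA"] <- "rRNA"
  kind
}

#' Read annotation intervals (GFF3 or 4/5-column TSV)
#'
#' The TSV dialect has columns `seq_id`, `start`, `end`, `kind` and an
#' optional `label`, with or without a header row. Coordinates are 1-based
#' inclusive in both dialects. Feature types other than CDS and rRNA are kept
#' with kind `"other"`.
#'
#' @param path input file.
#' @param format `"gff3"` or `"tsv"`.
#' @param seqlengths optional named vector of sequence lengths used to
#'   validate coordinates.
#' @return A [GenomicRanges::GRanges] with mcols `kind` and `label`.
#' @export
readIntervals <- function(path, format = c("gff3", "tsv"), seqlengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "gff3") {
    gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                   error = function(e) stop("malformed GFF3 '", path, "': ",
                                            conditionMessage(e),
                                            call. = FALSE))
    if (length(gr) == 0L) {
      warning("no intervals in '", path, "'")
      out <- GRanges()
      mcols(out) <- DataFrame(kind = character(), label = character())
      return(out)
    }
    kind <- .asKind(as.character(gr$type))
    label <- if (!is.null(gr$ID)) as.character(gr$ID) else rep("", length(gr))
    label[is.na(label)] <- ""
    out <- granges(gr)
    mcols(out) <- DataFrame(kind = kind, label = label)
  } else {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (!length(first) || !nzchar(first)) {
      warning("no intervals in '", path, "'")
      out <- GRanges()
      mcols(out) <- DataFrame(kind = character(), label = character())
      return(out)
    }
    hasHeader <- grepl("seq_id", first, fixed = TRUE)
    df <- read.delim(path, header = hasHeader, stringsAsFactors = FALSE)
    if (ncol(df) < 4L)
      stop("TSV intervals need >= 4 columns (seq_id, start, end, kind): ",
           path, call. = FALSE)
    names(df)[1:4] <- c("seq_id", "start", "end", "kind")
    if (ncol(df) >= 5L) names(df)[5] <- "label" else df$label <- ""
    st <- suppressWarnings(as.integer(df$start))
    en <- suppressWarnings(as.integer(df$end))
    bad <- which(is.na(st) | is.na(en) | st < 1L | en < st)
    if (length(bad))
      stop(sprintf("invalid interval at line %d of '%s' (start=%s end=%s)",
                   bad[1] + hasHeader, path, df$start[bad[1]],
                   df$end[bad[1]]), call. = FALSE)
    out <- GRanges(df$seq_id, IRanges(st, en))
    mcols(out) <- DataFrame(kind = .asKind(df$kind), label = df$label)
  }
  if (!is.null(seqlengths)) {
    sid <- as.character(seqnames(out))
    known <- sid %in% names(seqlengths)
    over <- known & end(out) > seqlengths[sid]
    if (any(over))
      stop(sprintf(
        "interval %d on '%s' (end %d) exceeds sequence length %d",
        which(over)[1], sid[which(over)[1]], end(out)[which(over)[1]],
        seqlengths[sid[which(over)[1]]]), call. = FALSE)
  }
  out
}

#' Write annotation intervals as GFF3
#'
#' @param gr a `GRanges` with mcols `kind` (and optionally `label`).
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
writeIntervalsGFF3 <- function(gr, path, source = "tetrascan") {
  lines <- "##gff-version 3"
  if (length(gr)) {
    label <- if (!is.null(gr$label)) gr$label else sprintf("f%d", seq_along(gr))
    type <- ifelse(gr$kind == "rRNA", "rRNA",
                   ifelse(gr$kind == "CDS", "CDS", "region"))
    lines <- c(lines, sprintf("%s\t%s\t%s\t%d\t%d\t.\t+\t.\tID=%s",
                              as.character(seqnames(gr)), source, type,
                              start(gr), end(gr), label))
  }
  writeLines(lines, path)
  invisible(path)
}
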