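# SAM text I/O for ungapped alignment records. Coordinates are 1-based in
# the file and 0-based half-open internally, converted only at this boundary.

.cigar_ref_span <- function(cigar) {
  # reference bases consumed: M, D, N, =, X
  if (cigar == "*") return(NA_integer_)
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  if (ops[1] == -1 || sum(attr(ops, "match.length")) != nchar(cigar)) {
    stop("malformed CIGAR: ", cigar)
  }
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  sum(len[op %in% c("M", "D", "N", "=", "X")])
}

#' Read alignments from a SAM file
#'
#' Parses SAM text (with `@SQ` headers) into an alignment table. File
#' coordinates are 1-based; the returned `ref_start` is 0-based so that the
#' covered reference interval is `[ref_start, ref_start + aligned_length)`.
#' Edit distance is taken from the `NM` tag when present, otherwise `NA`.
#'
#' @param path path to a SAM text file.
#' @return data.frame with columns `read_id`, `ref_id`, `ref_start`,
#'   `strand`, `aligned_length`, `edit_distance`, `is_mapped`, plus an
#'   attribute `ref_lengths` (named integer vector from the `@SQ` headers).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- startsWith(lines, "@")
  sq <- lines[startsWith(lines, "@SQ")]
  ref_lengths <- integer(0)
  if (length(sq)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    ref_lengths <- setNames(ln, sn)
  }
  body <- lines[!hdr & nzchar(lines)]
  if (!length(body)) {
    out <- data.frame(read_id = character(0), ref_id = character(0),
                      ref_start = integer(0), strand = character(0),
                      aligned_length = integer(0), edit_distance = integer(0),
                      is_mapped = logical(0), stringsAsFactors = FALSE)
    attr(out, "ref_lengths") <- ref_lengths
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) stop("malformed SAM record (fewer than 11 fields) at line ",
                          which(!hdr & nzchar(lines))[which(nf < 11L)[1]])
  qname <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  cigar <- vapply(f, `[[`, "", 6L)
  is_mapped <- bitwAnd(flag, 4L) == 0L
  unknown <- is_mapped & !(rname %in% names(ref_lengths))
  if (any(unknown)) {
    stop("reference '", rname[which(unknown)[1]], "' absent from @SQ headers")
  }
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[[1]])) else NA_integer_
  }, 1L)
  span <- vapply(cigar, .cigar_ref_span, 1L, USE.NAMES = FALSE)
  out <- data.frame(
    read_id = qname,
    ref_id = ifelse(is_mapped, rname, NA_character_),
    ref_start = ifelse(is_mapped, pos - 1L, NA_integer_),
    strand = ifelse(is_mapped, ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                    NA_character_),
    aligned_length = ifelse(is_mapped, span, NA_integer_),
    edit_distance = ifelse(is_mapped, nm, NA_integer_),
    is_mapped = is_mapped,
    stringsAsFactors = FALSE
  )
  attr(out, "ref_lengths") <- ref_lengths
  out
}

#' Write alignments to a SAM file
#'
#' Inverse of [read_alignments()] for ungapped records: `ref_start` (0-based)
#' becomes the 1-based `POS` and `aligned_length` becomes a single-`M` CIGAR.
#'
#' @param aln alignment data.frame as returned by [read_alignments()] or
#'   [map_reads()].
#' @param ref_lengths named integer vector of reference lengths for the
#'   `@SQ` headers.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, ref_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(ref_lengths), "\tLN:", ref_lengths))
  if (nrow(aln)) {
    flag <- ifelse(!aln$is_mapped, 4L, ifelse(aln$strand == "-", 16L, 0L))
    rec <- paste(aln$read_id, flag,
                 ifelse(aln$is_mapped, aln$ref_id, "*"),
                 ifelse(aln$is_mapped, aln$ref_start + 1L, 0L),
                 ifelse(aln$is_mapped, 60L, 0L),
                 ifelse(aln$is_mapped, paste0(aln$aligned_length, "M"), "*"),
                 "*", 0L, 0L, "*", "*",
                 sep = "\t")
    has_nm <- aln$is_mapped & !is.na(aln$edit_distance)
    rec[has_nm] <- paste0(rec[has_nm], "\tNM:i:", aln$edit_distance[has_nm])
    writeLines(c(hdr, rec), path)
  } else {
    writeLines(hdr, path)
  }
  invisible(path)
}
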