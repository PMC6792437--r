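# Sequence collections are plain data.frames:
#   seq_set:  id, desc, seq        (FASTA; nucleotide or protein)
#   read_set: id, seq, qual        (FASTQ, Sanger qualities)
# Validation is strict at parse time so downstream stages can assume clean
# alphabets and unique ids.

IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N", "-")
AA_CHARS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "B", "J", "Z", "X", "*", "-")

#' Construct a validated sequence collection
#'
#' The in-memory form used throughout the package: a data.frame with
#' columns `id`, `desc`, `seq`. Ids must be unique and non-empty, residues
#' non-empty; residues are upper-cased.
#'
#' @param id character vector of unique identifiers.
#' @param seq character vector of residues, same length as `id`.
#' @param desc descriptions (recycled).
#' @return data.frame with columns `id`, `desc`, `seq`.
#' @export
seq_set <- function(id, seq, desc = "") {
  stopifnot(length(id) == length(seq))
  desc <- rep_len(desc, length(id))
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(id))) stop("empty sequence id")
  if (any(!nzchar(seq))) stop("empty residues for id(s): ",
                              paste(id[!nzchar(seq)], collapse = ", "))
  data.frame(id = as.character(id), desc = as.character(desc),
             seq = toupper(as.character(seq)), stringsAsFactors = FALSE)
}

.check_alphabet <- function(seqs, ids, alphabet, lines = NULL) {
  allowed <- if (identical(alphabet, "nt")) IUPAC_NT else AA_CHARS
  for (i in seq_along(seqs)) {
    ch <- unique(strsplit(toupper(seqs[[i]]), "")[[1]])
    bad <- setdiff(ch, allowed)
    if (length(bad)) {
      where <- if (is.null(lines)) paste0("record '", ids[[i]], "'")
               else paste0("record '", ids[[i]], "' (line ", lines[[i]], ")")
      stop("alphabet violation in ", where, ": ", paste(bad, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Read a FASTA file
#'
#' Parses a (possibly line-wrapped) FASTA file into a data.frame with columns
#' `id`, `desc` and `seq`. Residues are upper-cased; the declared alphabet is
#' enforced at parse time and violations are reported with the offending line.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"nt"` (IUPAC nucleotide codes incl. ambiguity) or `"aa"`.
#' @return data.frame with columns `id`, `desc`, `seq`, one row per record,
#'   in file order.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a first", "ACGT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty FASTA file: ", path)
  if (!startsWith(lines[[1]], ">")) stop("not a FASTA file (no leading '>'): ", path)
  hdr <- startsWith(lines, ">")
  allowed <- if (identical(alphabet, "nt")) IUPAC_NT else AA_CHARS
  body_chars <- strsplit(toupper(lines[!hdr]), "")
  body_bad <- vapply(body_chars, function(ch) length(setdiff(ch, allowed)) > 0,
                     TRUE)
  if (any(body_bad)) {
    ln <- which(!hdr)[which(body_bad)[1]]
    bad <- setdiff(body_chars[[which(body_bad)[1]]], allowed)
    stop("alphabet violation at line ", ln, ": ", paste(bad, collapse = ", "))
  }
  rec <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  body <- split(lines[!hdr], rec[!hdr])
  seqs <- character(length(headers))
  present <- as.integer(names(body))
  seqs[present] <- vapply(body, paste0, "", collapse = "")
  first_line <- which(hdr)
  if (any(!nzchar(seqs))) {
    stop("record without residues at line ",
         first_line[which(!nzchar(seqs))[1]])
  }
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  seq_set(id, seqs, desc)
}

#' Write a FASTA file
#'
#' @param x data.frame with columns `id`, `seq` and optionally `desc`.
#' @param path output path.
#' @param width line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  hdr <- ifelse(nzchar(x$desc %||% ""), paste0(">", x$id, " ", x$desc),
                paste0(">", x$id))
  chunks <- lapply(seq_len(nrow(x)), function(i) {
    s <- x$seq[[i]]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    c(hdr[[i]], substring(s, starts, pmin(starts + width - 1L, n)))
  })
  writeLines(unlist(chunks), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a FASTQ file
#'
#' Strict 4-line-per-record FASTQ parser (Sanger qualities). Errors on
#' truncated records and on reads whose quality string length differs from
#' the read length.
#'
#' @param path path to a FASTQ file.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty FASTQ file: ", path)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record near line ", 4L * (length(lines) %/% 4L) + 1L)
  }
  i <- seq(1L, length(lines), by = 4L)
  if (any(!startsWith(lines[i], "@"))) {
    stop("malformed FASTQ header at line ", i[which(!startsWith(lines[i], "@"))[1]])
  }
  id <- sub("\\s.*$", "", sub("^@", "", lines[i]))
  seqs <- toupper(lines[i + 1L])
  qual <- lines[i + 3L]
  bad <- nchar(qual) != nchar(seqs)
  if (any(bad)) {
    stop("quality/sequence length mismatch for read '", id[which(bad)[1]],
         "' at line ", i[which(bad)[1]])
  }
  .check_alphabet(seqs, id, "nt", lines = i + 1L)
  data.frame(id = id, seq = seqs, qual = qual, stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#' @param x data.frame with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  stopifnot(all(nchar(x$qual) == nchar(x$seq)))
  writeLines(as.vector(rbind(paste0("@", x$id), x$seq, "+", x$qual)), path)
  invisible(path)
}

#' Reverse-complement nucleotide sequences
#' @param x character vector of IUPAC nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
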