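# Degenerate-primer expansion and in-silico matching: every window of primer
# length on both strands of each gene is scored by IUPAC-aware mismatch
# counting, and the best window decides primer compatibility.

IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)

.iupac_mask <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  m <- IUPAC_BITS[ch]
  if (anyNA(m)) stop("invalid IUPAC character(s): ",
                     paste(unique(ch[is.na(m)]), collapse = ", "))
  unname(m)
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

#' Expand a degenerate primer into all concrete sequences
#'
#' Cartesian product of the per-position IUPAC base sets; the expansion size
#' is the product of the code degeneracies.
#'
#' @param primer IUPAC nucleotide string.
#' @return character vector of concrete ACGT sequences.
#' @export
iupac_expand <- function(primer) {
  ch <- strsplit(toupper(primer), "")[[1]]
  bad <- setdiff(ch, names(IUPAC_SETS))
  if (length(bad)) stop("invalid IUPAC character(s): ",
                        paste(unique(bad), collapse = ", "))
  sets <- IUPAC_SETS[ch]
  out <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(out[, rev(seq_along(sets)), drop = FALSE], 1, paste, collapse = "")
}

.window_mismatches <- function(primer_mask, gene_mask) {
  m <- length(primer_mask); L <- length(gene_mask)
  nw <- L - m + 1L
  if (nw < 1L) return(integer(0))
  mm <- integer(nw)
  for (j in seq_len(m)) {
    mm <- mm + as.integer(bitwAnd(primer_mask[j], gene_mask[j:(j + nw - 1L)]) == 0L)
  }
  mm
}

#' Best match of one degenerate primer on one gene
#'
#' Scans every window of primer length on the + strand and on the reverse
#' complement; a position mismatches when the intersection of the primer
#' code's base set and the gene base's set is empty (so gene ambiguity codes
#' count as a match only when compatible). Returns the window with the
#' minimum mismatch count; ties go to the smallest position, + strand first.
#' The reported position is the window's 0-based start in + strand
#' coordinates.
#'
#' @param primer list or one-row data.frame with `name` and `seq` (IUPAC).
#' @param gene one-row nucleotide sequence data.frame.
#' @param max_mismatch compatibility threshold.
#' @return one-row data.frame: `primer`, `gene_id`, `strand`, `position`,
#'   `mismatches`, `compatible`. When the primer is longer than the gene,
#'   `strand`/`position`/`mismatches` are `NA` and `compatible` is `FALSE`.
#' @export
scan_primer <- function(primer, gene, max_mismatch = 0L) {
  pm <- .iupac_mask(primer$seq)
  gm <- .iupac_mask(gene$seq)
  if (length(pm) > length(gm)) {
    return(data.frame(primer = primer$name, gene_id = gene$id,
                      strand = NA_character_, position = NA_integer_,
                      mismatches = NA_integer_, compatible = FALSE,
                      stringsAsFactors = FALSE))
  }
  fwd <- .window_mismatches(pm, gm)
  rm_ <- .iupac_mask(revcomp(primer$seq))
  rev <- .window_mismatches(rm_, gm)
  best_f <- min(fwd); best_r <- min(rev)
  if (best_f <= best_r) {
    pos <- which(fwd == best_f)[1] - 1L
    res <- c(strand = "+", mismatches = best_f, position = pos)
  } else {
    pos <- which(rev == best_r)[1] - 1L
    res <- c(strand = "-", mismatches = best_r, position = pos)
  }
  mm <- as.integer(res[["mismatches"]])
  data.frame(primer = primer$name, gene_id = gene$id,
             strand = res[["strand"]], position = as.integer(res[["position"]]),
             mismatches = mm, compatible = mm <= max_mismatch,
             stringsAsFactors = FALSE)
}

#' Primer x gene compatibility report
#'
#' One row per primer x gene with the best match and the compatibility flag
#' at the configured mismatch threshold (default 0: any mismatch
#' disqualifies).
#'
#' @param primers data.frame with columns `name`, `seq` (IUPAC strings).
#' @param genes nucleotide sequence data.frame.
#' @param max_mismatch compatibility threshold.
#' @return data.frame of [scan_primer()] rows, `nrow(primers) * nrow(genes)`
#'   rows.
#' @export
compatibility_report <- function(primers, genes, max_mismatch = 0L) {
  stopifnot(nrow(primers) >= 1, nrow(genes) >= 1)
  do.call(rbind, lapply(seq_len(nrow(primers)), function(i) {
    do.call(rbind, lapply(seq_len(nrow(genes)), function(j) {
      scan_primer(primers[i, , drop = FALSE], genes[j, , drop = FALSE],
                  max_mismatch)
    }))
  }))
}

#' Read a primer table
#'
#' TSV with columns `name` and `seq` (IUPAC nucleotide strings); validated
#' on read.
#'
#' @param path TSV path.
#' @return data.frame `name`, `seq`.
#' @export
read_primers <- function(path) {
  p <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "seq") %in% names(p))) {
    stop("primer table must have columns 'name' and 'seq'")
  }
  lapply(p$seq, .iupac_mask)  # validation
  p$seq <- toupper(p$seq)
  p
}
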