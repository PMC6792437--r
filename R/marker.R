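# nifH marker screening: six-frame translation, local protein alignment
# against a reference set, Karlin-Altschul E-value filter, top-hit label
# check and PROSITE motif validation, plus recruited-read identity
# statistics. A candidate is called a nifH gene only when all three checks
# pass: E-value below threshold, best reference annotated with the label
# keyword, and the [4Fe-4S]-site motif present in the translation.

#' Six-frame translation
#'
#' Frames +1, +2, +3 of the sequence and +1, +2, +3 of its reverse
#' complement (reported as -1, -2, -3), bacterial/standard codon
#' assignments, stops rendered `*`, trailing partial codons dropped,
#' ambiguous codons rendered `X`.
#'
#' @param seq nucleotide string of length `>= 3`.
#' @return named character vector of 6 protein strings
#'   (`"+1"`, `"+2"`, `"+3"`, `"-1"`, `"-2"`, `"-3"`). Frames shorter than
#'   one codon are empty strings.
#' @export
six_frame_translate <- function(seq) {
  if (nchar(seq) < 3) stop("sequence shorter than one codon")
  fwd <- toupper(seq)
  rev <- revcomp(fwd)
  one <- function(s, off) {
    s <- substring(s, off + 1L)
    n <- nchar(s) %/% 3L
    if (n == 0) return("")
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, 1, 3L * n)),
      no.init.codon = TRUE, if.fuzzy.codon = "X"))
  }
  c("+1" = one(fwd, 0L), "+2" = one(fwd, 1L), "+3" = one(fwd, 2L),
    "-1" = one(rev, 0L), "-2" = one(rev, 1L), "-3" = one(rev, 2L))
}

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' Local (Smith-Waterman) protein alignment score
#'
#' Optimal local alignment under BLOSUM62 with affine gaps (a gap of length
#' L costs `gap_open + L * gap_extend`). The score is never negative: when
#' no positive-scoring local alignment exists the result is score 0 with an
#' empty alignment. Coordinates are 0-based half-open on both sequences.
#'
#' @param a,b amino-acid strings (residues must be in the BLOSUM62 alphabet,
#'   which includes `*` and `X`).
#' @param gap_open,gap_extend affine gap parameters.
#' @return list with `score`, `a_range` and `b_range` (integer `c(start,
#'   end)`, 0-based half-open; `c(0, 0)` for an empty alignment), `n_match`,
#'   `n_columns`.
#' @export
smith_waterman <- function(a, b, gap_open = 11, gap_extend = 1) {
  mat <- .blosum62()
  chars <- unique(strsplit(paste0(toupper(a), toupper(b)), "")[[1]])
  bad <- setdiff(chars, rownames(mat))
  if (length(bad)) stop("residue(s) outside the BLOSUM62 alphabet: ",
                        paste(bad, collapse = ", "))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend,
    type = "local")
  sc <- Biostrings::score(pa)
  if (sc <= 0 || Biostrings::nchar(pa) == 0) {
    return(list(score = 0, a_range = c(0L, 0L), b_range = c(0L, 0L),
                n_match = 0L, n_columns = 0L))
  }
  pr <- as.integer(c(
    Biostrings::start(Biostrings::pattern(pa)) - 1L,
    Biostrings::end(Biostrings::pattern(pa))))
  sr <- as.integer(c(
    Biostrings::start(Biostrings::subject(pa)) - 1L,
    Biostrings::end(Biostrings::subject(pa))))
  list(score = sc, a_range = pr, b_range = sr,
       n_match = Biostrings::nmatch(pa),
       n_columns = Biostrings::nchar(pa))
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * score)` for a local alignment score against
#' a search space of query length m and database length n.
#'
#' @param score alignment raw score (`>= 0`).
#' @param m query length; @param n database length (summed reference lengths).
#' @param lambda,K Karlin-Altschul parameters (ungapped-approximation
#'   defaults for BLOSUM62).
#' @return the E-value.
#' @export
karlin_altschul_evalue <- function(score, m, n, lambda = 0.3176, K = 0.134) {
  stopifnot(score >= 0, m >= 1, n >= 1, lambda > 0, K > 0)
  K * m * n * exp(-lambda * score)
}

#' Screen one gene for nifH
#'
#' Exhaustive translated search: all six reading frames are locally aligned
#' against every reference protein; the best (frame, reference) pair by raw
#' score is evaluated against the three-part rule — E-value below
#' `evalue_max` (search space: translated frame length x summed reference
#' lengths), best reference's description contains `label_keyword`
#' (case-insensitive), and the motif occurs in the best frame's full
#' translation.
#'
#' @param gene one-row nucleotide sequence data.frame.
#' @param refdb amino-acid sequence data.frame with annotation labels in
#'   `desc`.
#' @param motif PROSITE pattern (text or parsed) for the required site.
#' @param evalue_max E-value acceptance threshold.
#' @param label_keyword case-insensitive substring required in the best
#'   reference's description.
#' @param lambda,K,gap_open,gap_extend alignment/statistics parameters.
#' @return one-row data.frame: `gene_id`, `best_ref_id`, `frame`, `score`,
#'   `evalue`, `top_hit_label_ok`, `motif_ok`, `verdict`.
#' @export
screen_gene <- function(gene, refdb, motif, evalue_max = 1e-50,
                        label_keyword = "nitrogenase",
                        lambda = 0.3176, K = 0.134,
                        gap_open = 11, gap_extend = 1) {
  if (nchar(gene$seq) < 3) stop("gene shorter than 3 nt")
  if (!nrow(refdb)) stop("empty reference database")
  frames <- six_frame_translate(gene$seq)
  frames <- frames[nzchar(frames)]
  db_len <- sum(nchar(refdb$seq))
  subjects <- Biostrings::AAStringSet(refdb$seq)
  best <- list(score = -Inf, frame = NA_character_, ref = NA_integer_, m = 0L)
  for (f in names(frames)) {
    prot <- frames[[f]]
    scores <- Biostrings::pairwiseAlignment(
      subjects, Biostrings::AAString(prot), substitutionMatrix = .blosum62(),
      gapOpening = gap_open, gapExtension = gap_extend, type = "local",
      scoreOnly = TRUE)
    scores <- pmax(scores, 0)
    j <- which.max(scores)
    if (scores[j] > best$score) {
      best <- list(score = scores[j], frame = f, ref = j, m = nchar(prot))
    }
  }
  ev <- karlin_altschul_evalue(max(best$score, 0), max(best$m, 1), db_len,
                               lambda, K)
  label_ok <- grepl(label_keyword, refdb$desc[best$ref], ignore.case = TRUE)
  motif_ok <- nrow(prosite_scan(frames[[best$frame]], motif)) >= 1
  data.frame(gene_id = gene$id, best_ref_id = refdb$id[best$ref],
             frame = best$frame, score = best$score, evalue = ev,
             top_hit_label_ok = label_ok, motif_ok = motif_ok,
             verdict = ev < evalue_max && label_ok && motif_ok,
             stringsAsFactors = FALSE)
}

#' Screen a set of genes for nifH
#'
#' @param genes nucleotide sequence data.frame.
#' @inheritParams screen_gene
#' @return data.frame with one row per gene (see [screen_gene()]).
#' @export
screen_genes <- function(genes, refdb, motif, evalue_max = 1e-50,
                         label_keyword = "nitrogenase",
                         lambda = 0.3176, K = 0.134,
                         gap_open = 11, gap_extend = 1) {
  if (is.character(motif)) motif <- prosite_parse(motif)
  do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    screen_gene(genes[i, , drop = FALSE], refdb, motif, evalue_max,
                label_keyword, lambda, K, gap_open, gap_extend)
  }))
}

#' Identity statistics of reads recruited by a gene
#'
#' Aligns each recruited read to the gene with a local nucleotide alignment
#' (match +1, mismatch -1, gap -2); identity is 100 x matches / alignment
#' columns. Alignments shorter than `min_align_len` are excluded before
#' summarizing, mirroring the minimum-alignment-length rule used when
#' searching gene databases.
#'
#' @param gene one-row nucleotide sequence data.frame.
#' @param reads read data.frame of reads recruited to the gene.
#' @param min_align_len minimum alignment length in nt.
#' @return one-row data.frame: `gene_id`, `n_reads` (retained), `mean_identity`,
#'   `min_identity`, `max_identity` (percent; `NA` when no read is retained).
#' @export
recruited_read_identity <- function(gene, reads, min_align_len = 100L) {
  if (!nrow(reads)) {
    return(data.frame(gene_id = gene$id, n_reads = 0L,
                      mean_identity = NA_real_, min_identity = NA_real_,
                      max_identity = NA_real_, stringsAsFactors = FALSE))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  g <- Biostrings::DNAString(gene$seq)
  ident <- vapply(reads$seq, function(s) {
    best <- NA_real_
    for (q in c(s, revcomp(s))) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(q), g, substitutionMatrix = mat,
        gapOpening = 0, gapExtension = 2, type = "local")
      len <- Biostrings::nchar(pa)
      if (len < min_align_len) next
      id <- 100 * Biostrings::nmatch(pa) / len
      if (is.na(best) || id > best) best <- id
    }
    best
  }, 0, USE.NAMES = FALSE)
  ident <- ident[!is.na(ident)]
  if (!length(ident)) {
    return(data.frame(gene_id = gene$id, n_reads = 0L,
                      mean_identity = NA_real_, min_identity = NA_real_,
                      max_identity = NA_real_, stringsAsFactors = FALSE))
  }
  data.frame(gene_id = gene$id, n_reads = length(ident),
             mean_identity = mean(ident), min_identity = min(ident),
             max_identity = max(ident), stringsAsFactors = FALSE)
}
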