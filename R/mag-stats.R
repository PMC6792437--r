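# Per-MAG assembly and quality statistics: length, N50, GC, single-copy-gene
# completion/redundancy, the MAG definition rule and the representative score.

#' Contig N50
#'
#' Smallest contig length L such that contigs of length >= L sum to at least
#' half the total assembly length (descending-sort cumulative sum).
#'
#' @param lengths contig lengths in bp (all `>= 1`).
#' @return N50 in bp.
#' @export
contig_n50 <- function(lengths) {
  if (!length(lengths)) stop("empty contig length list")
  stopifnot(all(lengths >= 1))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Pooled GC content of a contig set
#'
#' `100 * (G + C) / (A + C + G + T)` over all contigs; ambiguous IUPAC bases
#' are excluded from both numerator and denominator.
#'
#' @param records sequence data.frame of contigs.
#' @return GC percentage.
#' @export
gc_content <- function(records) {
  if (!nrow(records)) stop("empty contig set")
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(records$seq))[, c("A", "C", "G", "T"), drop = FALSE])
  denom <- sum(counts)
  if (denom == 0) stop("no unambiguous bases in contig set")
  100 * (counts[["G"]] + counts[["C"]]) / denom
}

#' Completion and redundancy from single-copy core genes
#'
#' Completion is the percentage of the domain-specific single-copy gene
#' families present at least once; redundancy counts extra copies,
#' `100 * sum(max(0, count - 1)) / D`. Redundancy above 100 is possible (and
#' flagged by the caller, never clamped) when family counts exceed twice the
#' collection size.
#'
#' @param counts per-family occurrence counts (non-negative integers; absent
#'   families may be omitted or zero).
#' @param collection_size number of families D in the collection.
#' @return named numeric vector `c(completion =, redundancy =)` in percent.
#' @export
completion_redundancy <- function(counts, collection_size) {
  stopifnot(collection_size >= 1, all(counts >= 0))
  c(completion = 100 * sum(counts >= 1) / collection_size,
    redundancy = 100 * sum(pmax(0, counts - 1)) / collection_size)
}

#' The MAG definition rule
#'
#' A bin qualifies as a MAG when completion exceeds 70 percent or total
#' length exceeds 2 Mbp (both comparisons strict). Length alone can qualify
#' a bin whose completion is underestimated.
#'
#' @param completion completion percentage.
#' @param total_length total bin length in bp.
#' @param completeness_min,length_min rule thresholds.
#' @return logical.
#' @export
is_mag <- function(completion, total_length,
                   completeness_min = 70, length_min = 2e6) {
  completion > completeness_min | total_length > length_min
}

#' Representative score: completion minus redundancy
#'
#' The member of a redundant group with the largest score represents the
#' group in the non-redundant collection (archaea/bacteria).
#'
#' @param completion,redundancy percentages.
#' @return `completion - redundancy`.
#' @export
representative_score <- function(completion, redundancy) {
  completion - redundancy
}

#' Summary statistics for a set of MAGs
#'
#' Builds the per-MAG table (length, N50, number of contigs, GC, completion,
#' redundancy, MAG flag) from contigs plus a single-copy-gene annotation
#' table.
#'
#' @param contigs sequence data.frame of all contigs.
#' @param contig_map data.frame `contig_id`, `mag_id` assigning contigs to MAGs.
#' @param scg data.frame `mag_id`, `family_id`, `count` of single-copy-gene
#'   annotations (families absent from a MAG may be omitted).
#' @param collection_size number of families in the SCG collection.
#' @param completeness_min,length_min thresholds of the MAG rule.
#' @return data.frame with one row per MAG.
#' @export
mag_table <- function(contigs, contig_map, scg, collection_size,
                      completeness_min = 70, length_min = 2e6) {
  stopifnot(all(contig_map$contig_id %in% contigs$id))
  mags <- sort(unique(contig_map$mag_id))
  rows <- lapply(mags, function(m) {
    ids <- contig_map$contig_id[contig_map$mag_id == m]
    cs <- contigs[match(ids, contigs$id), , drop = FALSE]
    lens <- nchar(cs$seq)
    sc <- scg[scg$mag_id == m, , drop = FALSE]
    cr <- completion_redundancy(sc$count, collection_size)
    data.frame(mag_id = m, total_length = sum(lens), n_contigs = length(lens),
               n50 = contig_n50(lens), gc = gc_content(cs),
               completion = cr[["completion"]], redundancy = cr[["redundancy"]],
               redundancy_flag = cr[["redundancy"]] > 100,
               is_mag = is_mag(cr[["completion"]], sum(lens),
                               completeness_min, length_min),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
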