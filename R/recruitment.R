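# Competitive read recruitment and its summary statistics. Reads are
# recruited against all references at once (one FASTA of every scaffold);
# each read counts toward at most one reference, so recruited-read fractions
# are directly comparable across populations.

#' Competitively map reads against a reference collection
#'
#' Deterministic recruitment surrogate: exact k-mer seeding plus ungapped
#' extension of the full read on both strands; each read is assigned to the
#' single reference maximizing full-read identity. Reads failing
#' `min_identity` or `min_aligned_fraction` stay unmapped; ties between
#' references are broken uniformly at random under the seeded generator, the
#' usual behaviour of competitive mappers. Externally produced SAM
#' alignments ([read_alignments()]) can be used instead throughout.
#'
#' @param reads read data.frame (`id`, `seq`, ...) as from [read_fastq()].
#' @param references sequence data.frame of reference scaffolds.
#' @param k exact-seed length (`<=` read length, `<=` 31).
#' @param min_identity minimum identity over the aligned span.
#' @param min_aligned_fraction minimum fraction of the read aligned.
#' @param seed integer seed for tie-breaking.
#' @return alignment data.frame (`read_id`, `ref_id`, `ref_start`, `strand`,
#'   `aligned_length`, `edit_distance`, `is_mapped`) with attribute
#'   `ref_lengths`.
#' @export
map_reads <- function(reads, references, k = 21L, min_identity = 0.95,
                      min_aligned_fraction = 0.9, seed = 1L) {
  if (nrow(references) == 0) stop("empty reference set")
  if (k > min(nchar(reads$seq))) stop("seed length k exceeds read length")
  res <- .with_seed(seed, {
    .map_reads_cpp(reads$seq, references$seq, as.integer(k),
                   min_identity, min_aligned_fraction)
  })
  out <- data.frame(
    read_id = reads$id,
    ref_id = references$id[res$ref_idx],
    ref_start = res$ref_start,
    strand = res$strand,
    aligned_length = res$aligned_length,
    edit_distance = res$edit_distance,
    is_mapped = res$is_mapped,
    stringsAsFactors = FALSE
  )
  attr(out, "ref_lengths") <- setNames(nchar(references$seq), references$id)
  out
}

#' Per-position coverage from alignments
#'
#' `values[i]` counts the mapped alignments whose reference interval
#' `[ref_start, ref_start + aligned_length)` contains position `i` (0-based).
#'
#' @param alignments alignment data.frame; only rows on `ref_id` are used.
#' @param ref_id reference identifier.
#' @param ref_length reference length (bp).
#' @return integer vector of length `ref_length`.
#' @export
coverage_from_alignments <- function(alignments, ref_id, ref_length) {
  a <- alignments[alignments$is_mapped & alignments$ref_id == ref_id, ,
                  drop = FALSE]
  if (nrow(a) && any(a$ref_start + a$aligned_length > ref_length)) {
    stop("alignment extends past the end of reference '", ref_id, "'")
  }
  delta <- integer(ref_length + 1L)
  if (nrow(a)) {
    st <- tabulate(a$ref_start + 1L, nbins = ref_length + 1L)
    en <- tabulate(a$ref_start + a$aligned_length + 1L, nbins = ref_length + 1L)
    delta <- st - en
  }
  cumsum(delta)[seq_len(ref_length)]
}

#' Quartile-trimmed (Q2Q3) mean coverage
#'
#' Mean per-position coverage after excluding positions whose coverage falls
#' strictly below the first quartile or strictly above the third quartile of
#' the per-position distribution, suppressing the effect of non-specific
#' read recruitment. Quartiles use the linear-interpolation convention
#' (`stats::quantile` type 7). For a constant vector this equals the plain
#' mean.
#'
#' @param values non-negative per-position coverage vector.
#' @return trimmed mean coverage.
#' @export
q2q3_mean_coverage <- function(values) {
  if (!length(values)) stop("empty coverage vector")
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  keep <- values >= q[1] & values <= q[2]
  if (!any(keep)) return(mean(values))
  mean(values[keep])
}

#' Detection: fraction of positions covered
#'
#' @param values per-position coverage vector.
#' @param min_cov a position counts as detected when covered at least this
#'   many times.
#' @return fraction in `[0, 1]`.
#' @export
detection <- function(values, min_cov = 1L) {
  if (!length(values)) stop("empty coverage vector")
  mean(values >= min_cov)
}

#' Relative abundance as recruited-read fraction
#'
#' @param reads_recruited reads competitively recruited by the population.
#' @param total_sample_reads total reads in the sample.
#' @return fraction `reads_recruited / total_sample_reads`.
#' @export
relative_abundance <- function(reads_recruited, total_sample_reads) {
  if (any(total_sample_reads < 1)) stop("total_sample_reads must be >= 1")
  if (any(reads_recruited > total_sample_reads)) {
    stop("recruited reads exceed sample total")
  }
  reads_recruited / total_sample_reads
}

#' Translate relative abundance into cells per litre
#'
#' Assumes each litre of surface seawater contains `cell_density` archaeal
#' and bacterial cells (default 0.5 billion), so a population at relative
#' abundance a corresponds to `a * cell_density` cells per litre.
#'
#' @param rel_abundance relative abundance fraction(s) in `[0, 1]`.
#' @param cell_density cells per litre of surface seawater.
#' @return estimated cells per litre.
#' @export
cells_per_litre <- function(rel_abundance, cell_density = 5e8) {
  if (any(rel_abundance < 0 | rel_abundance > 1)) {
    stop("rel_abundance must be in [0, 1]")
  }
  rel_abundance * cell_density
}

#' Square-root normalization for display tables
#' @param x non-negative value(s).
#' @return `sqrt(x)`, element-wise.
#' @export
sqrt_normalize <- function(x) {
  if (any(x < 0)) stop("negative input")
  sqrt(x)
}

#' Per-reference recruitment summary for one sample
#'
#' Computes, for every reference, the mean coverage, Q2Q3-trimmed mean
#' coverage, detection and recruited-read count/relative abundance from a
#' competitive alignment set.
#'
#' @param alignments alignment data.frame with attribute `ref_lengths`
#'   (as from [map_reads()] or [read_alignments()]).
#' @param total_sample_reads total reads in the sample (defaults to
#'   `nrow(alignments)`, i.e. every read was presented to the mapper).
#' @param sample_id label copied into the output.
#' @param min_cov detection threshold.
#' @return data.frame with one row per reference: `ref_id`, `sample_id`,
#'   `mean_coverage`, `q2q3_mean_coverage`, `detection`, `reads_recruited`,
#'   `relative_abundance`.
#' @export
profile_sample <- function(alignments, total_sample_reads = nrow(alignments),
                           sample_id = "sample", min_cov = 1L) {
  ref_lengths <- attr(alignments, "ref_lengths")
  if (is.null(ref_lengths)) stop("alignments lack the ref_lengths attribute")
  rows <- lapply(names(ref_lengths), function(rid) {
    cov <- coverage_from_alignments(alignments, rid, ref_lengths[[rid]])
    n <- sum(alignments$is_mapped & alignments$ref_id == rid)
    data.frame(ref_id = rid, sample_id = sample_id,
               mean_coverage = mean(cov),
               q2q3_mean_coverage = q2q3_mean_coverage(cov),
               detection = detection(cov, min_cov),
               reads_recruited = n,
               relative_abundance = relative_abundance(n, max(total_sample_reads, 1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Population x sample relative-abundance matrix from per-sample profiles
#'
#' @param profiles list of [profile_sample()] outputs (one per sample).
#' @return matrix of relative-abundance fractions, populations x samples.
#' @export
abundance_matrix <- function(profiles) {
  refs <- unique(unlist(lapply(profiles, `[[`, "ref_id")))
  m <- vapply(profiles, function(p) {
    setNames(p$relative_abundance, p$ref_id)[refs]
  }, numeric(length(refs)))
  m <- matrix(m, nrow = length(refs),
              dimnames = list(refs, vapply(profiles, function(p) p$sample_id[1], "")))
  m[is.na(m)] <- 0
  m
}
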