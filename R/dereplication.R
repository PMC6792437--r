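# Non-redundant MAG collection: pairwise fragment-ANI, abundance-profile
# correlation, redundancy graph and representative selection. Two MAGs are
# redundant when ANI >= 99 percent over > 75 percent of the smaller genome
# AND their relative distributions across samples correlate at Pearson
# r > 0.9; redundancy groups are the connected components of that relation.

#' Fragment-based average nucleotide identity of two genomes
#'
#' The smaller genome is cut into consecutive fragments of `fragment_len`;
#' each fragment is anchored in the larger genome by exact k-mer seeding and
#' aligned with a banded edit-distance extension (both strands). Fragments
#' reaching `min_frag_identity` over at least `min_frag_coverage` of their
#' length are retained; ANI is the mean identity of retained fragments and
#' the aligned fraction is retained fragment bases over the smaller genome
#' length. Equal-length tie: the genome with the lexicographically smaller
#' id is fragmented.
#'
#' @param genome_a,genome_b one-row sequence data.frames.
#' @param fragment_len fragment size in bp.
#' @param min_frag_identity,min_frag_coverage fragment retention thresholds.
#' @param k exact-seed length for anchoring.
#' @param band band half-width of the edit-distance extension.
#' @return data.frame row: `mag_a`, `mag_b`, `ani` (percent; `NA` when no
#'   fragment aligns), `aligned_fraction`, `n_fragments_aligned`.
#' @export
fragment_ani <- function(genome_a, genome_b, fragment_len = 1000L,
                         min_frag_identity = 0.8, min_frag_coverage = 0.8,
                         k = 15L, band = 16L) {
  la <- nchar(genome_a$seq); lb <- nchar(genome_b$seq)
  if (la < 1 || lb < 1) stop("empty genome")
  smaller_first <- la < lb || (la == lb && genome_a$id <= genome_b$id)
  qry <- if (smaller_first) genome_a else genome_b
  sbj <- if (smaller_first) genome_b else genome_a
  L <- nchar(qry$seq)
  starts <- seq(1L, L, by = fragment_len)
  frags <- substring(qry$seq, starts, pmin(starts + fragment_len - 1L, L))
  res <- .fragment_ani_cpp(frags, sbj$seq, as.integer(k), as.integer(band))
  keep <- res$aligned == 1L & !is.na(res$identity) &
    res$identity >= min_frag_identity & res$coverage >= min_frag_coverage
  n_kept <- sum(keep)
  if (n_kept == 0) {
    ani <- NA_real_; frac <- 0
  } else {
    ani <- 100 * mean(res$identity[keep])
    frac <- sum(nchar(frags)[keep]) / L
  }
  data.frame(mag_a = genome_a$id, mag_b = genome_b$id, ani = ani,
             aligned_fraction = frac, n_fragments_aligned = n_kept,
             stringsAsFactors = FALSE)
}

#' Pearson correlation of two per-sample profiles
#'
#' Product-moment correlation, with an explicit undefined-correlation signal
#' (`NA`) when either vector is constant; an undefined correlation fails the
#' `> 0.9` redundancy criterion.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "pearson")
}

#' Redundancy graph: partition MAGs into redundancy groups
#'
#' Places an edge between two MAGs when `ani >= ani_min`,
#' `aligned_fraction > align_frac_min` and the Pearson correlation of their
#' relative distributions across samples is `> r_min`; groups are the
#' connected components (singletons are their own group). An optional
#' grouping key (e.g. phylum) restricts which pairs are compared, as a
#' performance aid only.
#'
#' @param mag_ids character vector of MAG identifiers.
#' @param ani_results data.frame `mag_a`, `mag_b`, `ani`, `aligned_fraction`
#'   (as from [fragment_ani()]; pairs may appear in either orientation).
#' @param abundance populations x samples matrix with one row per MAG.
#' @param ani_min,align_frac_min,r_min redundancy thresholds (`ani_min`
#'   inclusive, the other two strict).
#' @param taxon optional named character vector: pairs in different taxa are
#'   never compared.
#' @return list with `membership` (named integer vector of group ids) and
#'   `edges` (data.frame of passing pairs with their evidence triple).
#' @export
redundancy_graph <- function(mag_ids, ani_results, abundance,
                             ani_min = 99.0, align_frac_min = 0.75,
                             r_min = 0.9, taxon = NULL) {
  missing_ab <- setdiff(mag_ids, rownames(abundance))
  if (length(missing_ab)) {
    stop("missing abundance row(s) for MAG(s): ",
         paste(missing_ab, collapse = ", "))
  }
  pass <- logical(nrow(ani_results))
  rvals <- rep(NA_real_, nrow(ani_results))
  for (i in seq_len(nrow(ani_results))) {
    a <- ani_results$mag_a[i]; b <- ani_results$mag_b[i]
    if (!(a %in% mag_ids) || !(b %in% mag_ids)) next
    if (!is.null(taxon) && !identical(taxon[[a]], taxon[[b]])) next
    if (is.na(ani_results$ani[i])) next
    if (ani_results$ani[i] < ani_min) next
    if (ani_results$aligned_fraction[i] <= align_frac_min) next
    r <- pearson_r(abundance[a, ], abundance[b, ])
    rvals[i] <- r
    if (!is.na(r) && r > r_min) pass[i] <- TRUE
  }
  edges <- ani_results[pass, c("mag_a", "mag_b", "ani", "aligned_fraction"),
                       drop = FALSE]
  edges$pearson_r <- rvals[pass]
  g <- igraph::graph_from_data_frame(
    edges[, c("mag_a", "mag_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = mag_ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  list(membership = setNames(as.integer(comp$membership), mag_ids),
       edges = edges)
}

#' Select the representative MAG of a redundancy group
#'
#' Archaea and bacteria: the member with the largest completion minus
#' redundancy; eukarya: the longest member. Ties go to the larger genome,
#' then to the lexicographically smaller id.
#'
#' @param members MAG ids in the group.
#' @param stats data.frame with `mag_id`, `completion`, `redundancy`,
#'   `total_length`.
#' @param domain `"bacteria"`, `"archaea"` or `"eukarya"`.
#' @return the representative `mag_id`.
#' @export
select_representative <- function(members, stats,
                                  domain = c("bacteria", "archaea", "eukarya")) {
  domain <- match.arg(domain)
  if (!length(members)) stop("empty redundancy group")
  s <- stats[match(members, stats$mag_id), , drop = FALSE]
  if (anyNA(s$mag_id)) stop("missing stats for MAG(s): ",
                            paste(members[is.na(s$mag_id)], collapse = ", "))
  key <- if (domain == "eukarya") s$total_length
         else representative_score(s$completion, s$redundancy)
  ord <- order(-key, -s$total_length, s$mag_id)
  s$mag_id[ord[1]]
}

#' Dereplicate a MAG collection
#'
#' Runs all pairwise fragment-ANI comparisons (optionally restricted by a
#' taxon key), builds the redundancy graph against the abundance matrix and
#' selects one representative per group.
#'
#' @param genomes sequence data.frame, one row per MAG (concatenated contigs
#'   or complete genome sequence).
#' @param abundance populations x samples matrix, rownames matching genome ids.
#' @param stats per-MAG stats data.frame (see [select_representative()]).
#' @param cfg configuration list ([default_config()]).
#' @param domain domain passed to [select_representative()].
#' @param taxon optional named taxon key for pair restriction.
#' @return list with `groups` (data.frame `mag_id`, `group`, `representative`,
#'   `status`), `ani` (all pair results) and `edges` (passing pairs).
#' @export
dereplicate <- function(genomes, abundance, stats, cfg = default_config(),
                        domain = "bacteria", taxon = NULL) {
  ids <- genomes$id
  pairs <- if (length(ids) >= 2) utils::combn(length(ids), 2) else
    matrix(integer(0), nrow = 2)
  ani <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    if (!is.null(taxon) && !identical(taxon[[ids[i1]]], taxon[[ids[i2]]])) {
      return(NULL)
    }
    fragment_ani(genomes[i1, ], genomes[i2, ],
                 fragment_len = cfg$fragment_len,
                 min_frag_identity = cfg$min_frag_identity,
                 min_frag_coverage = cfg$min_frag_coverage,
                 k = cfg$ani_k, band = cfg$ani_band)
  }))
  if (is.null(ani)) {
    ani <- data.frame(mag_a = character(0), mag_b = character(0),
                      ani = numeric(0), aligned_fraction = numeric(0),
                      n_fragments_aligned = integer(0))
  }
  rg <- redundancy_graph(ids, ani, abundance, ani_min = cfg$ani_min,
                         align_frac_min = cfg$align_frac_min,
                         r_min = cfg$r_min, taxon = taxon)
  groups <- split(names(rg$membership), rg$membership)
  rep_of <- vapply(groups, select_representative, "", stats = stats,
                   domain = domain)
  out <- data.frame(mag_id = unlist(groups, use.names = FALSE),
                    group = rep(as.integer(names(groups)), lengths(groups)),
                    stringsAsFactors = FALSE)
  out$representative <- rep_of[as.character(out$group)]
  out$status <- ifelse(out$mag_id == out$representative, "Reference", "Redundant")
  out <- out[order(out$group, out$status, out$mag_id), ]
  rownames(out) <- NULL
  list(groups = out, ani = ani, edges = rg$edges)
}
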