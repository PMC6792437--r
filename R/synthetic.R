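# Synthetic communities with known truth: genomes of controlled GC, planted
# marker genes, near-identical genome variants, correlated abundance profiles
# and error-bearing reads with exact truth alignments. Everything downstream
# (recruitment, dereplication, screening) is validated against these truths.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a random genome of controlled length and GC content
#'
#' Bases are i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) = (1-gc)/2.
#'
#' @param length genome length in bp.
#' @param gc target GC fraction in `[0, 1]`.
#' @param seed integer seed; output is reproducible bit-for-bit.
#' @param id sequence identifier.
#' @return one-row data.frame (`id`, `desc`, `seq`).
#' @export
generate_genome <- function(length, gc = 0.5, seed = 1L, id = "genome") {
  stopifnot(length >= 1)
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  .with_seed(seed, {
    bases <- sample(c("G", "C", "A", "T"), length, replace = TRUE,
                    prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
    seq_set(id, paste(bases, collapse = ""),
            desc = sprintf("synthetic length=%d gc=%.3f", as.integer(length), gc))
  })
}

#' Create a near-identical genome variant by random substitution
#'
#' Each position is independently substituted to one of the three other
#' bases with probability `sub_rate` (no indels), emulating redundant MAGs
#' of one population recovered from independent co-assemblies. The realized
#' divergence (Hamming distance / length) is returned as truth.
#'
#' @param genome one-row sequence data.frame (see [generate_genome()]).
#' @param sub_rate per-position substitution probability in `[0, 1)`.
#' @param seed integer seed.
#' @param id identifier for the variant.
#' @return list with `record` (one-row data.frame) and `divergence`
#'   (realized fraction of substituted positions).
#' @export
mutate_genome <- function(genome, sub_rate, seed = 1L,
                          id = paste0(genome$id, "_v")) {
  stopifnot(sub_rate >= 0, sub_rate < 1)
  .with_seed(seed, {
    chars <- strsplit(genome$seq, "")[[1]]
    hit <- which(runif(length(chars)) < sub_rate)
    if (length(hit)) {
      bases <- c("A", "C", "G", "T")
      cur <- match(chars[hit], bases)
      shift <- sample.int(3L, length(hit), replace = TRUE)
      chars[hit] <- bases[(cur - 1L + shift) %% 4L + 1L]
    }
    list(record = seq_set(id, paste(chars, collapse = ""),
                          desc = sprintf("variant of %s sub_rate=%g", genome$id, sub_rate)),
         divergence = length(hit) / length(chars))
  })
}

#' Fragment a genome into contigs at a target completeness
#'
#' The genome is cut into consecutive contigs with lengths drawn uniformly
#' from `contig_len_range`; contigs are then retained in random order until
#' the retained length reaches `target_completeness` of the genome, so the
#' realized completeness is within one contig length of the target.
#'
#' @param genome one-row sequence data.frame.
#' @param target_completeness fraction of the genome to retain, `(0, 1]`.
#' @param contig_len_range integer vector `c(min, max)` of contig lengths (bp).
#' @param seed integer seed.
#' @return list with `contigs` (sequence data.frame; attribute `offset`
#'   gives each contig's 0-based genome offset) and `completeness`
#'   (realized retained fraction).
#' @export
fragment_genome <- function(genome, target_completeness, contig_len_range, seed = 1L) {
  stopifnot(target_completeness > 0, target_completeness <= 1)
  L <- nchar(genome$seq)
  if (max(contig_len_range) > L) stop("contig length range exceeds genome length")
  .with_seed(seed, {
    starts <- integer(0); lens <- integer(0); pos <- 0L
    while (pos < L) {
      len <- sample(seq.int(contig_len_range[1], contig_len_range[2]), 1L)
      len <- min(len, L - pos)
      starts <- c(starts, pos); lens <- c(lens, len)
      pos <- pos + len
    }
    ord <- sample.int(length(lens))
    keep_n <- which(cumsum(lens[ord]) >= target_completeness * L)[1]
    keep <- sort(ord[seq_len(keep_n)])
    ids <- sprintf("%s_c%03d", genome$id, seq_along(keep))
    contigs <- seq_set(ids, substring(genome$seq, starts[keep] + 1L,
                                      starts[keep] + lens[keep]),
                       desc = sprintf("offset=%d", starts[keep]))
    attr(contigs, "offset") <- starts[keep]
    list(contigs = contigs, completeness = sum(lens[keep]) / L)
  })
}

#' Simulate per-sample relative-abundance profiles
#'
#' Base abundances are log-normal per genome per sample and renormalized per
#' sample. Genomes declared a redundant pair share one base profile with
#' multiplicative log-normal noise of the stated sd, giving the
#' distribution-correlated profiles the dereplication rule assumes; unpaired
#' genomes are independent.
#'
#' @param n_genomes,n_samples community dimensions.
#' @param redundant_pairs list of length-2 integer vectors (genome indices);
#'   the second member of each pair tracks the first.
#' @param correlated_noise_sd sd (log scale) of the pair noise.
#' @param seed integer seed.
#' @param sdlog spread (log scale) of the base abundance distribution.
#' @return matrix (genomes x samples) with columns summing to 1; rownames
#'   `g1..gN`, colnames `s1..sM`.
#' @export
simulate_abundances <- function(n_genomes, n_samples, redundant_pairs = list(),
                                correlated_noise_sd = 0.05, seed = 1L, sdlog = 1) {
  stopifnot(n_genomes >= 1, n_samples >= 1)
  .with_seed(seed, {
    base <- matrix(rlnorm(n_genomes * n_samples, meanlog = 0, sdlog = sdlog),
                   nrow = n_genomes)
    for (p in redundant_pairs) {
      stopifnot(length(p) == 2, all(p >= 1), all(p <= n_genomes))
      base[p[2], ] <- base[p[1], ] *
        exp(rnorm(n_samples, 0, correlated_noise_sd))
    }
    ab <- sweep(base, 2, colSums(base), "/")
    dimnames(ab) <- list(paste0("g", seq_len(n_genomes)),
                         paste0("s", seq_len(n_samples)))
    ab
  })
}

#' Assemble a community specification
#'
#' @param genomes sequence data.frame of genomes.
#' @param abundance genomes x samples matrix of relative abundances
#'   (columns sum to 1, rows in genome order).
#' @param total_reads reads per sample (recycled across samples).
#' @param read_length read length in bp.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed for read simulation.
#' @return list of class `community_spec`.
#' @export
community_spec <- function(genomes, abundance, total_reads, read_length = 100L,
                           error_rate = 0.005, seed = 1L) {
  stopifnot(nrow(genomes) == nrow(abundance), all(abundance >= 0),
            all(abs(colSums(abundance) - 1) < 1e-8), all(total_reads >= 1))
  if (read_length > min(nchar(genomes$seq))) {
    stop("read_length exceeds the shortest genome")
  }
  total_reads <- rep_len(as.integer(total_reads), ncol(abundance))
  structure(list(genomes = genomes, abundance = abundance,
                 total_reads = total_reads, read_length = as.integer(read_length),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "community_spec")
}

.inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(list(seqs = seqs, n_err = integer(length(seqs))))
  rl <- nchar(seqs)
  n_err <- rbinom(length(seqs), rl, error_rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_err > 0)) {
    pos <- sample.int(rl[i], n_err[i])
    ch <- strsplit(seqs[i], "")[[1]]
    cur <- match(ch[pos], bases)
    ch[pos] <- bases[(cur - 1L + sample.int(3L, n_err[i], replace = TRUE)) %% 4L + 1L]
    seqs[i] <- paste(ch, collapse = "")
  }
  list(seqs = seqs, n_err = n_err)
}

#' Simulate shotgun reads from a community, with truth alignments
#'
#' Per sample, read origins are drawn multinomially with probability
#' proportional to abundance x genome length; start positions and strands are
#' uniform; substitution errors occur at `error_rate`. The truth table
#' records each read's exact origin, and `true_read_fraction` records the
#' multinomial origin probabilities — the truth definition of relative
#' abundance that recruitment is expected to recover.
#'
#' @param community a [community_spec()].
#' @return list with `reads` (named list of read data.frames per sample),
#'   `truth` (named list of alignment data.frames per sample, SAM-shaped)
#'   and `true_read_fraction` (genomes x samples matrix).
#' @export
simulate_reads <- function(community) {
  stopifnot(inherits(community, "community_spec"))
  g <- community$genomes
  glen <- nchar(g$seq)
  rl <- community$read_length
  .with_seed(community$seed, {
    probs <- sweep(community$abundance * glen, 2,
                   colSums(community$abundance * glen), "/")
    reads <- list(); truth <- list()
    for (s in seq_len(ncol(probs))) {
      sid <- colnames(probs)[s] %||% paste0("s", s)
      counts <- as.integer(rmultinom(1, community$total_reads[s], probs[, s]))
      gi <- rep.int(seq_len(nrow(g)), counts)
      start <- unlist(lapply(seq_len(nrow(g)), function(i) {
        if (counts[i] == 0) return(integer(0))
        sample.int(glen[i] - rl + 1L, counts[i], replace = TRUE) - 1L
      }))
      n <- length(gi)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      raw <- substring(g$seq[gi], start + 1L, start + rl)
      raw[strand == "-"] <- revcomp(raw[strand == "-"])
      err <- .inject_errors(raw, community$error_rate)
      ids <- sprintf("%s_r%06d", sid, seq_len(n))
      reads[[sid]] <- data.frame(id = ids, seq = err$seqs,
                                 qual = strrep("I", rl),
                                 stringsAsFactors = FALSE)
      truth[[sid]] <- data.frame(read_id = ids, ref_id = g$id[gi],
                                 ref_start = start, strand = strand,
                                 aligned_length = rl,
                                 edit_distance = err$n_err,
                                 is_mapped = TRUE, stringsAsFactors = FALSE)
    }
    rownames(probs) <- g$id
    list(reads = reads, truth = truth, true_read_fraction = probs)
  })
}

#' Plant a gene into a genome at a given offset
#'
#' Overwrites the genome residues at `[offset, offset + nchar(gene))` (0-based)
#' with the gene sequence, so the planted copy has a known exact location.
#'
#' @param genome one-row sequence data.frame.
#' @param gene_seq nucleotide string to plant.
#' @param offset 0-based insertion offset.
#' @return the modified genome (one-row data.frame).
#' @export
plant_gene <- function(genome, gene_seq, offset) {
  L <- nchar(genome$seq)
  n <- nchar(gene_seq)
  if (offset < 0 || offset + n > L) stop("planted gene does not fit in genome")
  genome$seq <- paste0(substr(genome$seq, 1, offset), gene_seq,
                       substr(genome$seq, offset + n + 1, L))
  genome
}

# codon table for reverse translation (standard/bacterial code; the two share
# all codon -> amino-acid assignments, differing only in initiators)
.codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Reverse-translate a protein with uniform codon choice
#'
#' @param protein amino-acid string (may end in `*`).
#' @param seed integer seed.
#' @return nucleotide string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein, seed = 1L) {
  tab <- .codons_by_aa()
  aa <- strsplit(protein, "")[[1]]
  bad <- setdiff(aa, names(tab))
  if (length(bad)) stop("cannot reverse-translate residue(s): ",
                        paste(unique(bad), collapse = ", "))
  .with_seed(seed, {
    paste(vapply(aa, function(a) {
      cs <- tab[[a]]
      cs[[sample.int(length(cs), 1L)]]
    }, ""), collapse = "")
  })
}

#' Bundled synthetic [4Fe-4S]-style motif pattern
#'
#' The cysteine-spacing PROSITE pattern planted in the synthetic nifH
#' reference set (also shipped as
#' `inst/extdata/synthetic_nifh_motif.prosite`). This is a synthetic
#' stand-in: real screens must supply the curated PROSITE signature for the
#' nitrogenase-reductase [4Fe-4S]-binding site as a config/pattern input.
#' @export
SYNTH_NIFH_MOTIF <- "C-x(2)-C-x(2)-C-x(3)-C"

#' Synthetic nifH-like reference protein set
#'
#' Generates a labelled reference database of synthetic nitrogenase-reductase
#' stand-in proteins. Each protein carries the bundled cysteine-spacing motif
#' (`C-x(2)-C-x(2)-C-x(3)-C`) at a random internal position and a
#' description containing the keyword "nitrogenase", so the full three-part
#' screening rule (E-value, top-hit label, motif) is exercisable with known
#' positives. These sequences are synthetic; they are not curated nifH
#' proteins.
#'
#' @param n number of reference proteins (default 9, the size of a
#'   nine-population HBD nifH database).
#' @param length protein length (residues).
#' @param seed integer seed.
#' @return sequence data.frame (`id`, `desc`, `seq`) of amino-acid records.
#' @export
synthetic_nifh_refdb <- function(n = 9L, length = 280L, seed = 1L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  .with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      p <- sample(aa, length, replace = TRUE)
      # plant the motif C xx C xx C xxx C (11 residues) away from the ends
      at <- sample.int(length - 30L, 1L) + 10L
      motif <- c("C", sample(aa, 2, TRUE), "C", sample(aa, 2, TRUE),
                 "C", sample(aa, 3, TRUE), "C")
      p[at:(at + 10L)] <- motif
      paste(p, collapse = "")
    }, "")
    seq_set(sprintf("nifH_ref_%02d", seq_len(n)), seqs,
            desc = "nitrogenase reductase (synthetic reference)")
  })
}

#' Mutate a protein at a given amino-acid divergence
#'
#' Used to create diverged true positives for screening sensitivity checks.
#' Positions inside `protect` (0-based half-open interval) are never touched,
#' so a planted motif can be preserved.
#'
#' @param protein amino-acid string.
#' @param divergence fraction of positions to substitute.
#' @param seed integer seed.
#' @param protect optional `c(start, end)` 0-based half-open interval to keep.
#' @return mutated amino-acid string.
#' @export
mutate_protein <- function(protein, divergence, seed = 1L, protect = NULL) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ch <- strsplit(protein, "")[[1]]
  idx <- seq_along(ch)
  if (!is.null(protect)) idx <- idx[idx <= protect[1] | idx > protect[2]]
  .with_seed(seed, {
    k <- round(divergence * length(ch))
    k <- min(k, length(idx))
    if (k > 0) {
      pos <- sample(idx, k)
      ch[pos] <- vapply(ch[pos], function(c0) sample(setdiff(aa, c0), 1L), "")
    }
    paste(ch, collapse = "")
  })
}
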