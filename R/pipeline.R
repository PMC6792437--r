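# End-to-end orchestration: synth -> recruit -> profile -> mag-stats ->
# derep -> screen-nifh -> primer-check -> enrich -> report, one config and
# one global seed. Stage seeds are derived by stable hashing of stage names,
# so each stage is individually reproducible. All outputs are TSV; the
# report stage writes a manifest with an md5 checksum per output and echoes
# the resolved parameter set.

#' Demo synthetic-community specification
#'
#' The bundled demonstration community: 8 bacterial genomes of which 3 are
#' near-identical variant pairs (substitution rate 0.002, the redundant-MAG
#' scenario) and 2 are singletons; nifH stand-in genes planted in two
#' populations; 4 samples of 50,000 reads (100 bp, 0.5 percent substitution
#' error); redundant pairs share correlated abundance profiles (noise sd
#' 0.05).
#'
#' @param genome_length genome size in bp.
#' @param n_samples,total_reads sampling design.
#' @param read_length,error_rate read simulation parameters.
#' @param sub_rate substitution rate of the planted variant pairs.
#' @param noise_sd multiplicative abundance noise (log scale) within pairs.
#' @return list consumed by [run_pipeline()].
#' @export
demo_synth_spec <- function(genome_length = 30000L, n_samples = 4L,
                            total_reads = 50000L, read_length = 100L,
                            error_rate = 0.005, sub_rate = 0.002,
                            noise_sd = 0.05) {
  list(genome_length = as.integer(genome_length),
       n_samples = as.integer(n_samples),
       total_reads = as.integer(total_reads),
       read_length = as.integer(read_length),
       error_rate = error_rate, sub_rate = sub_rate, noise_sd = noise_sd,
       n_pairs = 3L, n_singletons = 2L, scg_families = 100L)
}

.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# build the demo community with complete truth records
.synth_stage <- function(spec, seed) {
  gl <- spec$genome_length
  n_pop <- spec$n_pairs + spec$n_singletons        # true populations
  base_seeds <- vapply(seq_len(n_pop), function(i)
    derive_seed(seed, paste0("genome", i)), 0L)
  base <- do.call(rbind, lapply(seq_len(n_pop), function(i) {
    generate_genome(gl, gc = 0.45 + 0.02 * i, seed = base_seeds[i],
                    id = sprintf("MAG%02d", i))
  }))
  # plant nifH stand-in genes in populations 1 and n_pop (known truth)
  refdb <- synthetic_nifh_refdb(seed = derive_seed(seed, "refdb"))
  nif1 <- reverse_translate(refdb$seq[1], seed = derive_seed(seed, "nif1"))
  nif2 <- reverse_translate(refdb$seq[2], seed = derive_seed(seed, "nif2"))
  off1 <- 5000L; off2 <- 12000L
  base[1, ] <- plant_gene(base[1, , drop = FALSE], nif1, off1)
  base[n_pop, ] <- plant_gene(base[n_pop, , drop = FALSE], nif2, off2)
  planted <- seq_set(c("nifH_planted_1", "nifH_planted_2"), c(nif1, nif2),
                     desc = c(sprintf("planted in MAG01 at %d", off1),
                              sprintf("planted in MAG%02d at %d", n_pop, off2)))
  # variant copies of the first n_pairs populations (redundant MAGs)
  variants <- lapply(seq_len(spec$n_pairs), function(i) {
    mutate_genome(base[i, , drop = FALSE], spec$sub_rate,
                  seed = derive_seed(seed, paste0("variant", i)),
                  id = sprintf("MAG%02d_v", i))
  })
  genomes <- rbind(base, do.call(rbind, lapply(variants, `[[`, "record")))
  pair_idx <- lapply(seq_len(spec$n_pairs), function(i) c(i, n_pop + i))
  ab <- simulate_abundances(nrow(genomes), spec$n_samples,
                            redundant_pairs = pair_idx,
                            correlated_noise_sd = spec$noise_sd,
                            seed = derive_seed(seed, "abundance"))
  rownames(ab) <- genomes$id
  comm <- community_spec(genomes, ab, spec$total_reads, spec$read_length,
                         spec$error_rate, seed = derive_seed(seed, "reads"))
  sim <- simulate_reads(comm)
  # synthetic SCG truth: base genomes near-complete, variants less complete,
  # so the representative rule has signal
  D <- spec$scg_families
  scg <- .with_seed(derive_seed(seed, "scg"), {
    do.call(rbind, lapply(seq_len(nrow(genomes)), function(i) {
      compl <- if (i <= n_pop) runif(1, 0.92, 1.0) else runif(1, 0.75, 0.9)
      fams <- sort(sample.int(D, round(compl * D)))
      dup <- sample(fams, rbinom(1, 3, 0.5))
      counts <- setNames(rep(1L, length(fams)), fams)
      counts[as.character(dup)] <- 2L
      data.frame(mag_id = genomes$id[i],
                 family_id = paste0("scg", names(counts)),
                 count = as.integer(counts), stringsAsFactors = FALSE)
    }))
  })
  truth_pairs <- data.frame(
    mag_a = vapply(pair_idx, function(p) genomes$id[p[1]], ""),
    mag_b = vapply(pair_idx, function(p) genomes$id[p[2]], ""),
    divergence = vapply(variants, `[[`, 0, "divergence"),
    stringsAsFactors = FALSE)
  list(genomes = genomes, reads = sim$reads, truth_aln = sim$truth,
       true_read_fraction = sim$true_read_fraction, abundance_truth = ab,
       scg = scg, scg_families = D, refdb = refdb, planted = planted,
       truth_pairs = truth_pairs)
}

#' Run the full analysis pipeline on a synthetic demo community
#'
#' Executes synth, recruit, profile, mag-stats, derep, screen-nifh,
#' primer-check, enrich and report in order, writing every table under
#' `outdir`. Identical config + seed give byte-identical outputs. Disabling
#' `derep` makes downstream tables use the redundant MAG set; the manifest
#' records this.
#'
#' @param outdir output directory (created if missing).
#' @param seed global integer seed.
#' @param cfg configuration list from [default_config()] / [load_config()].
#' @param synth community specification from [demo_synth_spec()].
#' @param stages character vector of stages to run (subset of the default).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest data.frame.
#' @export
run_pipeline <- function(outdir, seed = 1L, cfg = default_config(),
                         synth = demo_synth_spec(),
                         stages = c("synth", "recruit", "profile", "mag_stats",
                                    "derep", "screen_nifh", "primer_check",
                                    "enrich", "report")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list(); outputs <- character(0)
  emit <- function(x, name) {
    p <- file.path(outdir, name)
    .write_tsv(x, p)
    outputs <<- c(outputs, p)
    p
  }

  stopifnot("synth" %in% stages)  # inputs come from the generator
  log_msg("stage synth")
  sy <- .synth_stage(synth, seed)
  res$synth <- sy
  write_fasta(sy$genomes, file.path(outdir, "genomes.fa"))
  write_fasta(sy$planted, file.path(outdir, "nifh_planted.fa"))
  outputs <- c(outputs, file.path(outdir, c("genomes.fa", "nifh_planted.fa")))
  for (s in names(sy$reads)) {
    write_fastq(sy$reads[[s]], file.path(outdir, paste0("reads_", s, ".fastq")))
    write_alignments(sy$truth_aln[[s]],
                     setNames(nchar(sy$genomes$seq), sy$genomes$id),
                     file.path(outdir, paste0("truth_", s, ".sam")))
    outputs <- c(outputs, file.path(outdir, paste0("reads_", s, ".fastq")),
                 file.path(outdir, paste0("truth_", s, ".sam")))
  }
  emit(sy$scg, "scg_annotations.tsv")
  emit(sy$truth_pairs, "truth_pairs.tsv")
  emit(data.frame(mag_id = rownames(sy$true_read_fraction),
                  sy$true_read_fraction, check.names = FALSE),
       "truth_read_fraction.tsv")

  aln <- NULL; profiles <- NULL; ab <- NULL; stats <- NULL; derep <- NULL
  if ("recruit" %in% stages) {
    log_msg("stage recruit")
    aln <- lapply(names(sy$reads), function(s) {
      map_reads(sy$reads[[s]], sy$genomes, k = cfg$map_k,
                min_identity = cfg$min_identity,
                min_aligned_fraction = cfg$min_aligned_fraction,
                seed = derive_seed(seed, paste0("map_", s)))
    })
    names(aln) <- names(sy$reads)
    res$recruit <- aln
  }
  if ("profile" %in% stages) {
    stopifnot(!is.null(aln))
    log_msg("stage profile")
    profiles <- lapply(names(aln), function(s) {
      profile_sample(aln[[s]], total_sample_reads = nrow(sy$reads[[s]]),
                     sample_id = s, min_cov = cfg$min_cov_detection)
    })
    ab <- abundance_matrix(profiles)
    res$profiles <- profiles; res$abundance <- ab
    emit(do.call(rbind, profiles), "profiles.tsv")
    emit(data.frame(mag_id = rownames(ab), ab, check.names = FALSE),
         "abundance.tsv")
    emit(data.frame(mag_id = rownames(ab),
                    cells_per_litre = cells_per_litre(rowMeans(ab),
                                                      cfg$cell_density)),
         "cells_per_litre.tsv")
  }
  if ("mag_stats" %in% stages) {
    log_msg("stage mag_stats")
    contig_map <- data.frame(contig_id = sy$genomes$id, mag_id = sy$genomes$id,
                             stringsAsFactors = FALSE)
    stats <- mag_table(sy$genomes, contig_map, sy$scg, sy$scg_families,
                       completeness_min = cfg$completeness_min,
                       length_min = cfg$length_min)
    res$mag_stats <- stats
    emit(stats, "mag_stats.tsv")
  }
  if ("derep" %in% stages) {
    stopifnot(!is.null(ab), !is.null(stats))
    log_msg("stage derep")
    derep <- dereplicate(sy$genomes, ab, stats, cfg)
    res$derep <- derep
    emit(derep$groups, "derep_groups.tsv")
    emit(derep$ani, "derep_ani.tsv")
  }
  mag_set <- if (!is.null(derep)) {
    unique(derep$groups$representative)
  } else {
    sy$genomes$id
  }
  res$nonredundant <- mag_set
  if ("screen_nifh" %in% stages) {
    log_msg("stage screen_nifh")
    decoys <- do.call(rbind, lapply(1:3, function(i) {
      generate_genome(nchar(sy$planted$seq[1]), gc = 0.5,
                      seed = derive_seed(seed, paste0("decoy", i)),
                      id = paste0("decoy_", i))
    }))
    genes <- rbind(sy$planted, decoys)
    verdicts <- screen_genes(genes, sy$refdb, SYNTH_NIFH_MOTIF,
                             evalue_max = cfg$evalue_max,
                             label_keyword = cfg$label_keyword,
                             lambda = cfg$ka_lambda, K = cfg$ka_K,
                             gap_open = cfg$sw_gap_open,
                             gap_extend = cfg$sw_gap_extend)
    res$screen <- verdicts
    emit(verdicts, "nifh_screen.tsv")
  }
  if ("primer_check" %in% stages) {
    log_msg("stage primer_check")
    # primers derived from the first planted gene: an exact site, its
    # reverse complement, and a single-mutation near-miss (truth known)
    site <- substr(sy$planted$seq[1], 101, 120)
    mut <- site
    substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                   substr(site, 10, 10))[1]
    primers <- data.frame(name = c("exact_fwd", "exact_rev", "one_mismatch"),
                          seq = c(site, revcomp(site), mut),
                          stringsAsFactors = FALSE)
    pc <- compatibility_report(primers, sy$planted,
                               max_mismatch = cfg$max_mismatch)
    res$primers <- pc
    emit(pc, "primer_compatibility.tsv")
  }
  if ("enrich" %in% stages) {
    stopifnot(!is.null(ab))
    log_msg("stage enrich")
    half <- ceiling(ncol(ab) / 2)
    groups <- setNames(rep(c("Pacific", "Other"),
                           c(half, ncol(ab) - half)), colnames(ab))
    enr <- enrichment_table(ab, groups, group_a = "Pacific", adjust = "BH")
    res$enrichment <- enr
    emit(enr, "enrichment.tsv")
  }
  if ("report" %in% stages) {
    log_msg("stage report")
    cfg_path <- file.path(outdir, "config_used.yaml")
    yaml::write_yaml(cfg, cfg_path)
    outputs <- c(outputs, cfg_path)
    manifest <- data.frame(
      file = basename(outputs),
      md5 = unname(tools::md5sum(outputs)),
      stringsAsFactors = FALSE)
    manifest <- rbind(manifest, data.frame(
      file = "__mag_set__",
      md5 = if (!is.null(derep)) "non-redundant (derep enabled)"
            else "redundant (derep disabled)",
      stringsAsFactors = FALSE))
    .write_tsv(manifest, file.path(outdir, "manifest.tsv"))
    res$manifest <- manifest
  }
  invisible(res)
}
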