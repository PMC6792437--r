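# Run configuration: every analysis threshold is named here with its default,
# so a run can echo the exact parameter set it used.

#' Default run configuration
#'
#' Returns the full list of tunable parameters with their defaults. The
#' dereplication (ANI >= 99, aligned fraction > 0.75, Pearson r > 0.9), MAG
#' definition (> 70% completion or > 2 Mbp), marker screening (E-value <
#' 1e-50, 100 nt minimum read alignment), primer compatibility (0 mismatches)
#' and cell-density (5e8 cells per litre of surface seawater) defaults are
#' the study thresholds this package is built around.
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    # dereplication
    ani_min = 99.0,            # percent; redundant when ANI reaches this
    align_frac_min = 0.75,     # fraction of the smaller genome, strict >
    r_min = 0.9,               # Pearson r on relative distributions, strict >
    fragment_len = 1000L,      # bp, ANI fragment size
    min_frag_identity = 0.8,   # fragment retained at >= this identity
    min_frag_coverage = 0.8,   # ... over >= this fraction of its length
    ani_k = 15L,               # exact-seed length for fragment anchoring
    ani_band = 16L,            # band half-width for fragment edit distance
    # MAG definition and quality
    completeness_min = 70,     # percent, strict >
    length_min = 2e6,          # bp, strict >
    # recruitment
    map_k = 21L,               # exact-seed length for read mapping
    min_identity = 0.95,       # full-read identity to accept a placement
    min_aligned_fraction = 0.9,
    min_cov_detection = 1L,    # a position counts as detected at >= this
    cell_density = 5e8,        # cells per litre of surface seawater
    # marker screening
    evalue_max = 1e-50,
    label_keyword = "nitrogenase",
    sw_gap_open = 11,
    sw_gap_extend = 1,
    ka_lambda = 0.3176,        # Karlin-Altschul ungapped-approximation defaults
    ka_K = 0.134,
    min_align_len = 100L,      # nt, recruited-read identity filter
    # primers
    max_mismatch = 0L,
    # synthesis
    indel_rate = 0,            # substitution-only by default
    seed = 1L
  )
}

#' Load a run configuration
#'
#' Reads a YAML file of named parameters and merges it over the defaults;
#' unknown keys are an error so typos cannot silently disable a threshold.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return named list of parameters.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}

#' Derive a stage seed from the global seed
#'
#' Fans one global seed out to per-stage seeds by stable hashing of the stage
#' name, so stages are individually reproducible without coupling their
#' random streams.
#'
#' @param seed global integer seed.
#' @param label stage name.
#' @return integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * (seq_len(nchar(label)) %% 31L + 1L))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

log_msg <- function(...) {
  message("[diazoscan ", format(Sys.time(), "%H:%M:%S"), "] ", ...)
}
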