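# Independent oracles used across the suite. Each is a deliberately naive
# implementation (brute force / closed form / direct translation), kept free
# of the code paths it checks.

# quartile-trimmed mean by explicit order-statistic interpolation and a
# position-by-position membership loop
q2q3_oracle <- function(v) {
  s <- sort(v)
  n <- length(s)
  interp <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    if (lo == n) return(s[n])
    s[lo] + (h - lo) * (s[lo + 1] - s[lo])
  }
  q1 <- interp(0.25); q3 <- interp(0.75)
  kept <- 0; total <- 0
  for (x in v) {
    if (x >= q1 && x <= q3) { kept <- kept + 1; total <- total + x }
  }
  if (kept == 0) mean(v) else total / kept
}

# affine-gap local alignment DP, no optimizations; a gap of length L costs
# open + L * ext
sw_oracle <- function(a, b, open = 11, ext = 1, mat = NULL) {
  if (is.null(mat)) {
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    mat <- e$BLOSUM62
  }
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq(2, m + 1)) {
    for (j in seq(2, n + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# PROSITE -> PCRE translation; overlapping starts found with a lookahead
prosite_regex_starts <- function(protein, pattern) {
  txt <- sub("\\.$", "", trimws(pattern))
  anchor_start <- startsWith(txt, "<")
  if (anchor_start) txt <- substring(txt, 2)
  anchor_end <- endsWith(txt, ">")
  if (anchor_end) txt <- substring(txt, 1, nchar(txt) - 1)
  toks <- strsplit(txt, "-", fixed = TRUE)[[1]]
  rx <- vapply(toks, function(tok) {
    rep_rx <- ""
    if (grepl("\\(", tok)) {
      cnt <- sub("^[^(]+\\(([^)]+)\\)$", "\\1", tok)
      rep_rx <- paste0("{", cnt, "}")
      tok <- sub("\\(.*$", "", tok)
    }
    core <- if (tok == "x") "." else if (startsWith(tok, "{"))
      paste0("[^", substr(tok, 2, nchar(tok) - 1), "]") else tok
    paste0(core, rep_rx)
  }, "")
  rx <- paste(rx, collapse = "")
  if (anchor_end) rx <- paste0(rx, "$")
  rx <- paste0("(?=", rx, ")")
  if (anchor_start) rx <- paste0("^", rx)
  m <- gregexpr(rx, protein, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# boolean transitive closure of a symmetric predicate matrix
closure_oracle <- function(pred) {
  n <- nrow(pred)
  reach <- pred | diag(TRUE, n)
  repeat {
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  # component labels: smallest reachable index
  apply(reach, 1, function(r) min(which(r)))
}

# N50: largest contig length L with sum(lengths >= L) >= half the assembly
n50_oracle <- function(lens) {
  half <- sum(lens) / 2
  ok <- vapply(sort(unique(lens)), function(L) sum(lens[lens >= L]) >= half,
               TRUE)
  max(sort(unique(lens))[ok])
}

# min-over-expansion Hamming distance of a degenerate primer at one window
primer_window_oracle <- function(primer, window) {
  exps <- iupac_expand(primer)
  wexp <- iupac_expand(window)  # gene ambiguity codes expand too
  best <- Inf
  for (e in exps) {
    ec <- strsplit(e, "")[[1]]
    for (w in wexp) {
      wc <- strsplit(w, "")[[1]]
      best <- min(best, sum(ec != wc))
    }
  }
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
random_protein <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                    "")[[1]], n, TRUE),
                                    collapse = "")
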