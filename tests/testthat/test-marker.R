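test_that("six-frame translation covers both strands with literal codons", {
  expect_equal(unname(six_frame_translate("ATG")[["+1"]]), "M")
  fr <- six_frame_translate("ATGAAACCCGGG")
  expect_length(fr, 6L)
  # reverse-complement symmetry: frame -1 of s is frame +1 of revcomp(s)
  s <- "ATGAAACCCGGGTTTACGT"
  expect_equal(unname(six_frame_translate(s)[["-1"]]),
               unname(six_frame_translate(revcomp(s))[["+1"]]))
  # stops are literal, trailing partial codons dropped
  expect_equal(unname(six_frame_translate("ATGTAAAA")[["+1"]]), "M*")
  expect_error(six_frame_translate("AT"), "codon")
})

test_that("local alignment scores match self-alignment and the DP oracle", {
  b62 <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  p <- "MKVWDERTA"
  self <- smith_waterman(p, p)
  expect_equal(self$score,
               sum(diag(b62[strsplit(p, "")[[1]], strsplit(p, "")[[1]]])))
  expect_equal(self$a_range, c(0L, nchar(p)))
  none <- smith_waterman("WWW", "PPP")
  expect_equal(none$score, 0)
  expect_equal(none$n_columns, 0L)
  expect_error(smith_waterman("MKV", "MK8"), "alphabet")
  set.seed(1)
  for (i in 1:200) {
    a <- random_protein(30); b <- random_protein(30)
    if (i %% 3 == 0) b <- paste0(substr(a, 1, 14), "AW", substr(a, 15, 30))
    expect_equal(smith_waterman(a, b)$score, sw_oracle(a, b))
  }
  # extending either sequence can only help a local alignment
  a <- random_protein(40)
  b <- random_protein(40)
  expect_gte(smith_waterman(paste0(a, "M"), b)$score,
             smith_waterman(a, b)$score)
})

test_that("Karlin-Altschul E-values follow the formula", {
  expect_equal(karlin_altschul_evalue(200, 300, 1e5, 0.3176, 0.134),
               0.134 * 300 * 1e5 * exp(-0.3176 * 200))
  e1 <- karlin_altschul_evalue(100, 300, 1e5)
  expect_equal(karlin_altschul_evalue(100, 300, 2e5), 2 * e1)
  expect_lt(karlin_altschul_evalue(300, 300, 1e5), e1)
  expect_equal(karlin_altschul_evalue(1e6, 300, 1e5), 0)
})

test_that("the three-part screening rule separates positives from negatives", {
  refdb <- synthetic_nifh_refdb(seed = 2)
  gene <- seq_set("pos", reverse_translate(refdb$seq[3], seed = 3))
  hit <- screen_genes(gene, refdb, "C-x(2)-C-x(2)-C-x(3)-C")
  expect_true(hit$verdict)
  expect_equal(hit$best_ref_id, refdb$id[3])
  expect_equal(hit$frame, "+1")
  expect_lt(hit$evalue, 1e-50)
  # scrambling the motif cysteines kills motif_ok and the verdict
  prot <- refdb$seq[3]
  span <- prosite_scan(prot, "C-x(2)-C-x(2)-C-x(3)-C")
  broken <- prot
  for (k in (span$start[1] + 1):(span$end[1])) substr(broken, k, k) <- "A"
  gene2 <- seq_set("neg_motif", reverse_translate(broken, seed = 4))
  hit2 <- screen_genes(gene2, refdb, "C-x(2)-C-x(2)-C-x(3)-C")
  expect_false(hit2$motif_ok)
  expect_false(hit2$verdict)
  # a random gene of matching length/GC fails on E-value
  set.seed(5)
  rnd <- seq_set("rand", random_dna(nchar(gene$seq)))
  hit3 <- screen_genes(rnd, refdb, "C-x(2)-C-x(2)-C-x(3)-C")
  expect_gt(hit3$evalue, 1e-50)
  expect_false(hit3$verdict)
  expect_error(screen_genes(seq_set("tiny", "AT"), refdb, "C-x(2)-C"))
})

test_that("recruited-read identity recovers the simulated error rate", {
  set.seed(6)
  gene <- seq_set("nif", random_dna(1000))
  mk_reads <- function(n, err, len = 150) {
    if (n == 0) {
      return(data.frame(id = character(0), seq = character(0),
                        stringsAsFactors = FALSE))
    }
    starts <- sample.int(1000 - len + 1, n, replace = TRUE)
    raw <- substring(gene$seq, starts, starts + len - 1)
    if (err > 0) {
      raw <- vapply(raw, function(s) {
        k <- rbinom(1, len, err)
        if (k == 0) return(s)
        pos <- sample.int(len, k)
        ch <- strsplit(s, "")[[1]]
        ch[pos] <- vapply(ch[pos], function(c0)
          sample(setdiff(c("A", "C", "G", "T"), c0), 1), "")
        paste(ch, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    data.frame(id = sprintf("r%03d", seq_len(n)), seq = raw,
               stringsAsFactors = FALSE)
  }
  clean <- recruited_read_identity(gene, mk_reads(50, 0))
  expect_equal(clean$mean_identity, 100)
  noisy <- recruited_read_identity(gene, mk_reads(150, 0.01))
  expect_gte(noisy$mean_identity, 98.5)
  expect_lte(noisy$mean_identity, 99.5)
  # alignments below the 100 nt minimum are excluded entirely
  short <- mk_reads(10, 0, len = 80)
  out <- recruited_read_identity(gene, short, min_align_len = 100)
  expect_equal(out$n_reads, 0L)
  expect_true(is.na(out$mean_identity))
  empty <- recruited_read_identity(gene, mk_reads(0, 0))
  expect_equal(empty$n_reads, 0L)
})
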