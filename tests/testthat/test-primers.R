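test_that("IUPAC expansion is the Cartesian product of code sets", {
  expect_setequal(iupac_expand("AR"), c("AA", "AG"))
  expect_length(iupac_expand("NRY"), 16L)
  expect_equal(iupac_expand("ACGT"), "ACGT")
  expect_error(iupac_expand("AXG"), "invalid IUPAC")
  # degeneracy product holds for a mixed primer
  expect_length(iupac_expand("RYSWKM"), 2^6)
  expect_length(iupac_expand("NNB"), 4 * 4 * 3)
})

test_that("planted primer sites are found on both strands at 0 mismatches", {
  set.seed(1)
  gene <- seq_set("g1", random_dna(600))
  site <- substr(gene$seq, 201, 220)
  hit <- scan_primer(list(name = "fwd", seq = site), gene)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$position, 200L)
  expect_true(hit$compatible)
  rc <- scan_primer(list(name = "rev", seq = revcomp(site)), gene)
  expect_equal(rc$mismatches, 0L)
  expect_equal(rc$strand, "-")
  expect_equal(rc$position, 200L)
  # degenerate codes still match their base sets
  deg <- site
  substr(deg, 5, 5) <- "N"
  substr(deg, 11, 11) <- switch(substr(site, 11, 11),
                                A = "R", G = "R", C = "Y", T = "Y")
  dh <- scan_primer(list(name = "deg", seq = deg), gene)
  expect_equal(dh$mismatches, 0L)
})

test_that("a single mutation at the primer site flips compatibility", {
  set.seed(2)
  gene <- seq_set("g1", random_dna(400))
  site <- substr(gene$seq, 101, 120)
  mut <- gene
  b <- substr(mut$seq, 110, 110)
  substr(mut$seq, 110, 110) <- setdiff(c("A", "C", "G", "T"), b)[1]
  primers <- data.frame(name = "p", seq = site, stringsAsFactors = FALSE)
  rep0 <- compatibility_report(primers, rbind(gene, seq_set("g2", mut$seq)))
  expect_equal(rep0$compatible, c(TRUE, FALSE))
  expect_equal(rep0$mismatches, c(0L, 1L))
  # threshold 1 re-admits the near-miss
  rep1 <- compatibility_report(primers, seq_set("g2", mut$seq),
                               max_mismatch = 1)
  expect_true(rep1$compatible)
})

test_that("report covers every primer x gene pair", {
  set.seed(3)
  genes <- seq_set(c("a", "b", "c"), replicate(3, random_dna(200)))
  primers <- data.frame(name = c("p1", "p2"),
                        seq = c(substr(genes$seq[1], 1, 18), "TGYGAYCCNAARGC"),
                        stringsAsFactors = FALSE)
  rep <- compatibility_report(primers, genes)
  expect_equal(nrow(rep), 6L)
  expect_equal(rep$gene_id, rep(c("a", "b", "c"), 2))
  long <- data.frame(name = "too_long", seq = strrep("A", 300),
                     stringsAsFactors = FALSE)
  lr <- compatibility_report(long, genes)
  expect_false(any(lr$compatible))
  expect_true(all(is.na(lr$mismatches)))
})

test_that("window mismatches equal the min-over-expansion Hamming oracle", {
  set.seed(4)
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "N")
  for (i in 1:60) {
    plen <- sample(6:10, 1)
    primer <- paste(sample(codes, plen, TRUE, prob = c(rep(5, 4), rep(1, 7))),
                    collapse = "")
    if (length(iupac_expand(primer)) > 4096) next
    gene <- seq_set("g", random_dna(40))
    hit <- scan_primer(list(name = "p", seq = primer), gene)
    # oracle: best window over both strands by expansion Hamming distance
    windows_best <- Inf
    for (s in 1:(40 - plen + 1)) {
      w <- substr(gene$seq, s, s + plen - 1)
      windows_best <- min(windows_best,
                          primer_window_oracle(primer, w),
                          primer_window_oracle(revcomp(primer), w))
    }
    expect_equal(hit$mismatches, as.integer(windows_best))
  }
})

test_that("strand symmetry: scanning P on G equals revcomp(P) on revcomp(G)", {
  set.seed(5)
  for (i in 1:20) {
    primer <- list(name = "p", seq = paste(
      sample(c("A", "C", "G", "T", "R", "N"), 8, TRUE), collapse = ""))
    gene <- seq_set("g", random_dna(60))
    gene_rc <- seq_set("g", revcomp(gene$seq))
    h1 <- scan_primer(primer, gene)
    h2 <- scan_primer(list(name = "p", seq = revcomp(primer$seq)), gene_rc)
    expect_equal(h1$mismatches, h2$mismatches)
  }
})

test_that("the bundled synthetic example primer table loads and validates", {
  path <- system.file("extdata", "synthetic_primers.tsv",
                      package = "diazoscan")
  p <- read_primers(path)
  expect_true(all(c("name", "seq") %in% names(p)))
  expect_gte(nrow(p), 4L)
  expect_true(all(vapply(p$seq, function(s)
    length(iupac_expand(s)) >= 1, TRUE)))
})
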