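test_that("identical genomes give ANI 100 over the full length", {
  g <- generate_genome(50000, 0.5, seed = 1, id = "gA")
  g2 <- g; g2$id <- "gB"
  a <- fragment_ani(g, g2)
  expect_equal(a$ani, 100)
  expect_equal(a$aligned_fraction, 1)
  expect_equal(a$n_fragments_aligned, 50L)
})

test_that("fragment ANI tracks the realized divergence of variant pairs", {
  g <- generate_genome(50000, 0.5, seed = 2, id = "gA")
  m <- mutate_genome(g, 0.01, seed = 3, id = "gB")
  a <- fragment_ani(g, m$record)
  expect_lt(abs(a$ani - 100 * (1 - m$divergence)), 0.2)
  expect_gt(a$aligned_fraction, 0.95)
})

test_that("unrelated genomes share no aligned fragments", {
  g1 <- generate_genome(30000, 0.5, seed = 4, id = "x")
  g2 <- generate_genome(30000, 0.5, seed = 5, id = "y")
  a <- fragment_ani(g1, g2)
  expect_equal(a$aligned_fraction, 0)
  expect_true(is.na(a$ani))
})

test_that("Pearson correlation matches the closed form and flags constants", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  # direct sum computation of the product-moment coefficient
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), num / den)
  z <- c(0.2, 0.5, 0.1, 0.9)
  expect_equal(pearson_r(z, z), 1)
  expect_equal(pearson_r(z, -z), -1)
  expect_true(is.na(pearson_r(rep(1, length(z)), z)))
})

test_that("the redundancy rule joins pairs only when all three clauses pass", {
  ab <- rbind(a = c(1, 2, 3, 4, 5), b = c(1.1, 2.1, 2.9, 4.2, 5.1),
              c = c(5, 3, 4, 1, 2))
  ab <- sweep(ab, 2, colSums(ab), "/")
  ani_ok <- data.frame(mag_a = "a", mag_b = "b", ani = 99.5,
                       aligned_fraction = 0.8, stringsAsFactors = FALSE)
  rg <- redundancy_graph(c("a", "b", "c"), ani_ok, ab)
  expect_equal(rg$membership[["a"]], rg$membership[["b"]])
  expect_false(rg$membership[["a"]] == rg$membership[["c"]])
  # correlation clause fails: same ANI evidence, uncorrelated profiles
  ani_c <- data.frame(mag_a = "a", mag_b = "c", ani = 99.5,
                      aligned_fraction = 0.8, stringsAsFactors = FALSE)
  rg2 <- redundancy_graph(c("a", "b", "c"), ani_c, ab)
  expect_false(rg2$membership[["a"]] == rg2$membership[["c"]])
  # threshold edges: ani_min inclusive, the other two strict
  at <- function(ani, frac, rho) {
    abx <- rbind(a = c(1, 2, 3, 4, 5),
                 b = c(1, 2, 3, 4, 5) * rho + (1 - rho) * c(5, 1, 4, 2, 3))
    ani1 <- data.frame(mag_a = "a", mag_b = "b", ani = ani,
                       aligned_fraction = frac, stringsAsFactors = FALSE)
    m <- redundancy_graph(c("a", "b"), ani1, abx)$membership
    m[["a"]] == m[["b"]]
  }
  expect_true(at(99.0, 0.76, 1))     # ANI reaching 99 counts
  expect_false(at(98.99, 0.76, 1))
  expect_false(at(99.5, 0.75, 1))    # > 75% strict
  expect_error(redundancy_graph(c("a", "z"), ani_ok, ab), "missing abundance")
})

test_that("chains merge transitively into one connected group", {
  ab <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4.01), c = c(1, 2.01, 3, 4))
  ani <- data.frame(mag_a = c("a", "b"), mag_b = c("b", "c"),
                    ani = c(99.5, 99.3), aligned_fraction = c(0.9, 0.85),
                    stringsAsFactors = FALSE)
  rg <- redundancy_graph(c("a", "b", "c"), ani, ab)
  expect_equal(length(unique(rg$membership)), 1L)
})

test_that("partitions equal brute-force transitive closure on random tables", {
  set.seed(6)
  for (rep in 1:60) {
    n <- sample(3:12, 1)
    ids <- sprintf("m%02d", seq_len(n))
    pairs <- t(combn(n, 2))
    ani <- data.frame(
      mag_a = ids[pairs[, 1]], mag_b = ids[pairs[, 2]],
      ani = sample(c(98.5, 99.0, 99.6), nrow(pairs), TRUE),
      aligned_fraction = sample(c(0.7, 0.75, 0.8), nrow(pairs), TRUE),
      stringsAsFactors = FALSE)
    # abundance rows: random assignment of MAGs to latent profiles decides r
    latent <- matrix(rnorm(4 * 20), 4)
    ab <- latent[sample.int(4, n, TRUE), , drop = FALSE] +
      matrix(rnorm(n * 20, sd = 0.01), n)
    rownames(ab) <- ids
    rg <- redundancy_graph(ids, ani, ab)
    # oracle: boolean closure over the literal predicate
    pred <- matrix(FALSE, n, n)
    for (k in seq_len(nrow(ani))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      r <- suppressWarnings(cor(ab[i, ], ab[j, ]))
      ok <- ani$ani[k] >= 99 && ani$aligned_fraction[k] > 0.75 &&
        !is.na(r) && r > 0.9
      pred[i, j] <- pred[j, i] <- ok
    }
    labels <- closure_oracle(pred)
    same_impl <- outer(rg$membership, rg$membership, "==")
    same_oracle <- outer(labels, labels, "==")
    expect_equal(unname(same_impl), unname(same_oracle))
  }
})

test_that("representative selection follows completion minus redundancy", {
  stats <- data.frame(
    mag_id = c("ANW", "PON", "PSW", "PSE"),
    completion = c(98.1, 86.8, 98.3, 98.3),
    redundancy = c(5.6, 5.6, 8.7, 7.4),
    total_length = c(5.49e6, 5.56e6, 5.33e6, 5.29e6),
    stringsAsFactors = FALSE)
  expect_equal(select_representative(stats$mag_id, stats, "bacteria"), "ANW")
  s2 <- data.frame(mag_id = c("r1", "r2"), completion = c(97.3, 83.0),
                   redundancy = c(4.6, 4.7), total_length = c(5.86e6, 5.68e6),
                   stringsAsFactors = FALSE)
  expect_equal(select_representative(s2$mag_id, s2, "bacteria"), "r1")
  expect_equal(select_representative("r2", s2, "bacteria"), "r2")
  # eukarya pick the longest genome instead
  expect_equal(select_representative(s2$mag_id, s2, "eukarya"), "r1")
  s3 <- s2; s3$total_length <- c(1e6, 2e6)
  expect_equal(select_representative(s3$mag_id, s3, "eukarya"), "r2")
  expect_error(select_representative(character(0), s2, "bacteria"), "empty")
})
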