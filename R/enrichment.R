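# Regional enrichment statistics: Welch's unequal-variance t-test per
# population comparing one region's samples against the rest, with optional
# Benjamini-Hochberg adjustment. Tests run on raw relative abundances; the
# square-root transform is display-only.

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. When both groups have zero variance the test is
#' undefined and every field is `NA`.
#'
#' @param x,y numeric vectors of length `>= 2`.
#' @return named list: `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      # no variance, no difference: nothing to test, p = 1 by convention
      return(list(t = 0, df = NA_real_, p = 1,
                  mean_x = mean(x), mean_y = mean(y)))
    }
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                mean_x = mean(x), mean_y = mean(y)))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Per-population enrichment table (one region vs the rest)
#'
#' Applies [welch_t()] to every row of the abundance matrix, comparing the
#' samples of `group_a` against those of `group_b`, optionally followed by
#' Benjamini-Hochberg step-up adjustment across populations.
#'
#' @param abundance populations x samples matrix of relative abundances.
#' @param sample_groups named character vector assigning every sample
#'   (column) to a group label; exactly two labels must occur.
#' @param group_a the label of the focal group (e.g. `"Pacific"`); the other
#'   label is the comparison group.
#' @param adjust `"none"` or `"BH"`.
#' @return data.frame with one row per population: `population`, `group_a`,
#'   `group_b`, `mean_a`, `mean_b`, `t_statistic`, `df`, `p_two_sided` and,
#'   when requested, `adjusted_p`.
#' @export
enrichment_table <- function(abundance, sample_groups, group_a = NULL,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(names(sample_groups))) {
    stopifnot(length(sample_groups) == ncol(abundance))
    names(sample_groups) <- colnames(abundance)
  }
  missing_s <- setdiff(colnames(abundance), names(sample_groups))
  if (length(missing_s)) stop("unassigned sample(s): ",
                              paste(missing_s, collapse = ", "))
  groups <- sample_groups[colnames(abundance)]
  labs <- unique(groups)
  if (length(labs) != 2) stop("exactly two sample groups required, got ",
                              length(labs))
  if (is.null(group_a)) group_a <- labs[1]
  group_b <- setdiff(labs, group_a)
  ia <- which(groups == group_a); ib <- which(groups == group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("each group needs at least 2 samples")
  }
  rows <- lapply(rownames(abundance), function(p) {
    w <- welch_t(abundance[p, ia], abundance[p, ib])
    data.frame(population = p, group_a = group_a, group_b = group_b,
               mean_a = w$mean_x, mean_b = w$mean_y,
               t_statistic = w$t, df = w$df, p_two_sided = w$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$adjusted_p <- p.adjust(out$p_two_sided, method = "BH")
  out
}
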