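# Shared statistical kernel: 2x2 contingency tables, odds ratios, exact and
# asymptotic tests, multiple-testing correction, bootstrap CIs.
#
# All carrier/case tables in the package are laid out as
#     a = case carriers      b = case non-carriers
#     c = control carriers   d = control non-carriers

#' Build a 2x2 carrier-by-status contingency table
#'
#' @param case_carriers,case_noncarriers,control_carriers,control_noncarriers
#'   non-negative integer cell counts.
#' @return an object of class `contingency_2x2`.
#' @examples
#' contingency_2x2(10, 90, 5, 95)
#' @export
contingency_2x2 <- function(case_carriers, case_noncarriers,
                            control_carriers, control_noncarriers) {
  cells <- c(a = case_carriers, b = case_noncarriers,
             c = control_carriers, d = control_noncarriers)
  abort_if(any(is.na(cells)) || any(cells < 0),
           "contingency_2x2: all cell counts must be non-negative")
  structure(as.list(cells), class = "contingency_2x2")
}

as_table2x2 <- function(t) {
  if (inherits(t, "contingency_2x2")) return(t)
  abort_if(length(t) != 4, "expected a contingency_2x2 or a length-4 vector")
  contingency_2x2(t[[1]], t[[2]], t[[3]], t[[4]])
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
         dimnames = list(c("case", "control"), c("carrier", "noncarrier")))
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  print(as.matrix(x))
  invisible(x)
}

#' Odds ratio of a 2x2 table
#'
#' Cross-product odds ratio `(a*d)/(b*c)`. With `correction = TRUE` the
#' Haldane-Anscombe correction (+0.5 added to every cell) is applied, but
#' only when at least one cell is zero, so finite tables are untouched and
#' degenerate tables remain finite.
#'
#' @param t a [contingency_2x2()] (or length-4 vector `a, b, c, d`).
#' @param correction apply the Haldane-Anscombe correction to zero tables.
#' @return a positive number.
#' @examples
#' odds_ratio(contingency_2x2(10, 90, 5, 95))  # 2.111...
#' @export
odds_ratio <- function(t, correction = TRUE) {
  t <- as_table2x2(t)
  cells <- c(t$a, t$b, t$c, t$d)
  if (correction && any(cells == 0)) cells <- cells + 0.5
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Exact hypergeometric test: the p-value is the sum, over all tables with
#' the observed margins, of table probabilities no larger than the observed
#' table's probability.
#'
#' @inheritParams odds_ratio
#' @return p-value in `[0, 1]`.
#' @export
fisher_exact_p <- function(t) {
  t <- as_table2x2(t)
  m <- as.matrix(t)
  abort_if(any(rowSums(m) == 0) || any(colSums(m) == 0),
           "fisher_exact_p: table has an empty margin")
  stats::fisher.test(m)$p.value
}

#' Pooled two-proportion z-test on a 2x2 table
#'
#' Compares the carrier fraction in cases against controls using the pooled
#' proportion; the two-sided p-value comes from the normal distribution.
#'
#' @inheritParams odds_ratio
#' @return list with elements `z` and `p`.
#' @export
two_proportion_z <- function(t) {
  t <- as_table2x2(t)
  n1 <- t$a + t$b
  n2 <- t$c + t$d
  abort_if(n1 == 0 || n2 == 0, "two_proportion_z: empty case or control margin")
  p1 <- t$a / n1
  p2 <- t$c / n2
  if (p1 == p2) return(list(z = 0, p = 1))
  pp <- (t$a + t$c) / (n1 + n2)
  abort_if(pp == 0 || pp == 1,
           "two_proportion_z: pooled proportion degenerate (expected counts 0)")
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals numeric vector of raw p-values in `[0, 1]`.
#' @param alpha target false-discovery rate.
#' @return list with `q` (monotone adjusted p-values, same order as input)
#'   and `reject` (logical flags at level `alpha`).
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.5))$reject  # TRUE TRUE TRUE FALSE
#' @export
bh_adjust <- function(pvals, alpha = 0.05) {
  abort_if(any(is.na(pvals)) || any(pvals < 0 | pvals > 1),
           "bh_adjust: p-values must lie in [0, 1]")
  q <- stats::p.adjust(pvals, method = "BH")
  list(q = q, reject = q <= alpha)
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact enumeration when both samples have at most 8 observations and no
#' ties are present; otherwise the tie-corrected normal approximation
#' (without continuity correction). The reported statistic follows the
#' `min(U_x, U_y)` convention.
#'
#' @param x,y numeric vectors (non-empty).
#' @return list with elements `U` and `p`.
#' @export
mann_whitney_u <- function(x, y) {
  abort_if(length(x) == 0 || length(y) == 0,
           "mann_whitney_u: both samples must be non-empty")
  if (stats::var(c(x, y)) == 0) {
    warning("mann_whitney_u: all values tied across both groups; p = 1")
    return(list(U = length(x) * length(y) / 2, p = 1))
  }
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  u <- unname(wt$statistic)
  list(U = min(u, length(x) * length(y) - u), p = wt$p.value)
}

#' Percentile bootstrap confidence interval for a proportion
#'
#' Resamples the binary vector with replacement `n_boot` times and reports
#' the percentile interval of the resampled proportions. The point estimate
#' is the plain sample proportion. Deterministic for a given `seed`.
#'
#' @param flags binary (0/1 or logical) vector, `length >= 1`.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with `point`, `lo`, `hi`.
#' @export
bootstrap_proportion_ci <- function(flags, n_boot = 1000, level = 0.95,
                                    seed = 1L) {
  flags <- as.numeric(flags)
  abort_if(length(flags) == 0, "bootstrap_proportion_ci: empty input")
  abort_if(any(is.na(flags)), "bootstrap_proportion_ci: missing values in flags")
  point <- mean(flags)
  boots <- with_seed(seed, {
    n <- length(flags)
    vapply(seq_len(n_boot),
           function(i) mean(flags[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  qs <- unname(stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2)))
  list(point = point, lo = qs[1], hi = qs[2])
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact test for departure from Hardy-Weinberg proportions at a biallelic
#' locus: conditional on the observed allele counts, sums the probabilities
#' of all genotype configurations whose probability does not exceed that of
#' the observed configuration.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return p-value in `[0, 1]`.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  abort_if(any(c(n_aa, n_ab, n_bb) < 0), "hwe_exact_p: negative counts")
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_b <- 2 * n_bb + n_ab        # minor allele count
  hets <- seq(n_b %% 2, min(n_b, 2 * n - n_b), by = 2)
  # log-probability of each heterozygote count given the allele counts:
  # P(h) = n! / (naa! h! nbb!) * 2^h * n_b! * (2n - n_b)! / (2n)!
  bb <- (n_b - hets) / 2
  aa <- n - bb - hets
  logp <- lfactorial(n) - lfactorial(aa) - lfactorial(hets) - lfactorial(bb) +
    hets * log(2) + lfactorial(n_b) + lfactorial(2 * n - n_b) -
    lfactorial(2 * n)
  logp <- logp - max(logp)
  pr <- exp(logp) / sum(exp(logp))
  obs <- pr[match(n_ab, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}
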