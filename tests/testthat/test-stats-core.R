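# Statistical kernel: each operation is checked against an independent
# oracle (enumeration, closed form, or hand arithmetic).

# independent oracle: two-sided Fisher p by full enumeration of 2x2 tables
# at fixed margins, probabilities from log-factorials
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  x <- lo:hi
  logp <- lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
    lfactorial(r1 + r2 - c1) - lfactorial(r1 + r2) -
    lfactorial(x) - lfactorial(r1 - x) - lfactorial(c1 - x) -
    lfactorial(r2 - c1 + x)
  pr <- exp(logp)
  sum(pr[pr <= pr[match(a, x)] * (1 + 1e-7)])
}

test_that("odds ratio matches cross-product arithmetic, with Haldane correction on zero cells", {
  expect_equal(odds_ratio(contingency_2x2(10, 90, 5, 95)), 950 / 450)
  expect_equal(odds_ratio(contingency_2x2(20, 80, 0, 100)),
               (20.5 * 100.5) / (80.5 * 0.5))
  for (k in c(1, 7, 30)) {
    expect_equal(odds_ratio(contingency_2x2(k, k, k, k)), 1.0)
  }
  # correction only fires on zero cells
  expect_equal(odds_ratio(contingency_2x2(3, 2, 1, 4), correction = TRUE),
               (3 * 4) / (2 * 1))
})

test_that("Fisher exact p agrees with full hypergeometric enumeration", {
  expect_equal(fisher_exact_p(contingency_2x2(1, 9, 9, 1)),
               fisher_oracle(1, 9, 9, 1), tolerance = 1e-12)
  expect_lt(abs(fisher_exact_p(contingency_2x2(1, 9, 9, 1)) - 0.0011), 5e-5)
  set.seed(71)
  for (i in 1:250) {
    n <- sample(4:40, 1)
    t <- as.vector(stats::rmultinom(1, n, runif(4) + 0.05))
    if (any(rowSums(matrix(t, 2, byrow = TRUE)) == 0) ||
        any(colSums(matrix(t, 2, byrow = TRUE)) == 0)) next
    expect_equal(fisher_exact_p(t), fisher_oracle(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-12)
    # label symmetry: swapping the rows leaves p unchanged
    expect_equal(fisher_exact_p(t), fisher_exact_p(t[c(3, 4, 1, 2)]),
                 tolerance = 1e-12)
  }
})

test_that("internal vectorized Fisher equals the scalar implementation", {
  set.seed(5)
  ts <- replicate(60, as.vector(stats::rmultinom(1, sample(10:300, 1),
                                                 runif(4) + 0.02)))
  keep <- colSums(ts[1:2, ]) > 0 & colSums(ts[3:4, ]) > 0 &
    colSums(ts[c(1, 3), ]) > 0 & colSums(ts[c(2, 4), ]) > 0
  ts <- ts[, keep, drop = FALSE]
  pv <- combsig:::fisher_p_many(ts[1, ], ts[2, ], ts[3, ], ts[4, ])
  ps <- apply(ts, 2, fisher_exact_p)
  expect_equal(pv, ps, tolerance = 1e-10)
})

test_that("pooled two-proportion z-test", {
  r <- two_proportion_z(contingency_2x2(5, 5, 5, 5))
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  # cross-check z^2 against the (continuity-uncorrected) chi-squared test
  t <- contingency_2x2(30, 70, 15, 85)
  r <- two_proportion_z(t)
  pt <- suppressWarnings(stats::prop.test(c(30, 15), c(100, 100),
                                          correct = FALSE))
  expect_equal(r$z^2, unname(pt$statistic), tolerance = 1e-10)
  expect_equal(r$p, pt$p.value, tolerance = 1e-10)
  expect_error(two_proportion_z(contingency_2x2(0, 0, 3, 7)), "margin")
})

test_that("Benjamini-Hochberg step-up: hand-applied thresholds and properties", {
  r <- bh_adjust(c(0.01, 0.02, 0.03, 0.5), alpha = 0.05)
  # step-up thresholds 0.0125 / 0.025 / 0.0375 / 0.05: three rejections
  expect_equal(sum(r$reject), 3)
  expect_equal(bh_adjust(rep(1, 10))$reject, rep(FALSE, 10))
  one <- bh_adjust(0.04)
  expect_true(one$reject)
  expect_equal(one$q, 0.04)
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^2
    r <- bh_adjust(p, 0.05)
    # q-values match the explicit step-up rule
    m <- length(p)
    ord <- order(p)
    qmanual <- rev(cummin(rev(p[ord] * m / seq_len(m))))[order(ord)]
    expect_equal(r$q, pmin(1, qmanual))
    # never fewer rejections than Bonferroni
    expect_gte(sum(r$reject), sum(p <= 0.05 / m))
  }
})

test_that("Mann-Whitney U: exact enumeration oracle at small n, convention U = min", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  # oracle: enumerate all rank splits
  mw_oracle <- function(x, y) {
    pooled <- c(x, y)
    n <- length(pooled); nx <- length(x)
    rx <- rank(pooled)[seq_len(nx)]
    u_obs <- sum(rx) - nx * (nx + 1) / 2
    splits <- utils::combn(n, nx)
    r_all <- rank(pooled)
    us <- apply(splits, 2, function(ix) sum(r_all[ix]) - nx * (nx + 1) / 2)
    p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
    min(1, 2 * min(p_le, p_ge))
  }
  set.seed(3)
  for (i in 1:15) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- sample(1:100, nx); y <- sample(setdiff(1:100, x), ny)
    r <- mann_whitney_u(x, y)
    expect_equal(r$p, mw_oracle(x, y), tolerance = 1e-12)
    # two-sidedness: swapping samples leaves p unchanged
    expect_equal(r$p, mann_whitney_u(y, x)$p)
  }
  expect_warning(r <- mann_whitney_u(c(2, 2), c(2, 2, 2)), "tied")
  expect_equal(r$p, 1)
})

test_that("bootstrap proportion CI: plug-in point, determinism, degenerate input", {
  expect_equal(bootstrap_proportion_ci(rep(1, 20), seed = 4),
               list(point = 1, lo = 1, hi = 1))
  flags <- c(rep(1, 30), rep(0, 70))
  a <- bootstrap_proportion_ci(flags, n_boot = 500, seed = 11)
  b <- bootstrap_proportion_ci(flags, n_boot = 500, seed = 11)
  expect_identical(a, b)
  expect_equal(a$point, 0.3)
  expect_true(a$lo <= 0.3 && 0.3 <= a$hi)
})

test_that("bootstrap CI approximately attains nominal coverage", {
  hits <- vapply(1:150, function(i) {
    flags <- with_seed(derive_seed(202, i), stats::rbinom(400, 1, 0.3))
    ci <- bootstrap_proportion_ci(flags, n_boot = 400,
                                  seed = derive_seed(203, i))
    ci$lo <= 0.3 && 0.3 <= ci$hi
  }, logical(1))
  expect_gte(mean(hits), 0.88)
  expect_lte(mean(hits), 0.995)
})

test_that("exact Hardy-Weinberg test matches enumeration and flags gross departures", {
  hwe_oracle <- function(naa, nab, nbb) {
    n <- naa + nab + nbb; nb <- 2 * nbb + nab
    hs <- seq(nb %% 2, min(nb, 2 * n - nb), 2)
    pr <- vapply(hs, function(h) {
      bb <- (nb - h) / 2; aa <- n - bb - h
      exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
            h * log(2) + lfactorial(nb) + lfactorial(2 * n - nb) -
            lfactorial(2 * n))
    }, numeric(1))
    sum(pr[pr <= pr[match(nab, hs)] * (1 + 1e-12)])
  }
  for (t in list(c(50, 0, 50), c(10, 20, 10), c(3, 5, 2), c(88, 10, 2),
                 c(0, 2, 0), c(25, 50, 25))) {
    expect_equal(hwe_exact_p(t[1], t[2], t[3]), hwe_oracle(t[1], t[2], t[3]),
                 tolerance = 1e-12)
  }
  expect_lt(hwe_exact_p(50, 0, 50), 1e-20)
})
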