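# Feature-state matching, combination evaluation, exhaustive and greedy
# search.

test_that("matches follows exact-genotype semantics with missing as non-carrier", {
  s <- c(s1 = 1L, s2 = 2L)
  expect_true(matches(s, feature_states("s1", 1)))
  expect_false(matches(s, feature_states(c("s1", "s2"), c(1, 0))))
  expect_true(matches(s, feature_states(c("s1", "s2"), c(1, 2))))
  expect_false(matches(c(s1 = NA, s2 = 2L), feature_states("s1", 1)))
  expect_true(is.na(matches(c(s1 = NA), feature_states("s1", 1),
                            missing = "na")))
  expect_error(matches(s, feature_states("nope", 1)), "unknown SNP")
})

test_that("evaluate_combination fills exact statistics and carrier sets", {
  # 12/20 cases vs 1/20 controls -> OR = (12*19)/(8*1) = 28.5
  gm <- matrix(0L, 40, 2,
               dimnames = list(sprintf("S%02d", 1:40), c("a", "b")))
  gm[1:12, ] <- 1L          # case carriers
  gm[21, ] <- 1L            # one control carrier
  g <- genotype_matrix(gm, rep(c("case", "control"), each = 20))
  sig <- evaluate_combination(feature_states(c("a", "b"), c(1, 1)), g)
  expect_equal(sig$odds_ratio, 28.5)
  expect_equal(length(sig$case_ids), 12)
  expect_equal(sig$case_prevalence, 0.6)
  # oracle: naive per-sample rescan
  naive <- vapply(rownames(gm), function(s) all(gm[s, ] == 1L), logical(1))
  expect_setequal(c(sig$case_ids, sig$control_ids), names(which(naive)))
  # combination carried by nobody
  none <- evaluate_combination(feature_states(c("a", "b"), c(2, 2)), g)
  expect_equal(none$case_prevalence, 0)
  expect_equal(none$p_value, 1)
})

test_that("evaluate_combination can exclude samples with missing member genotypes", {
  gm <- matrix(c(1L, 1L, NA, 0L), 4, 1,
               dimnames = list(sprintf("S%d", 1:4), "a"))
  g <- genotype_matrix(gm, c("case", "case", "control", "control"))
  noncarrier <- evaluate_combination(feature_states("a", 1), g)
  expect_equal(as.matrix(noncarrier$table)["control", ], c(carrier = 0, noncarrier = 2))
  excl <- evaluate_combination(feature_states("a", 1), g, missing = "exclude")
  expect_equal(sum(as.matrix(excl$table)["control", ]), 1)
})

test_that("exhaustive search finds a planted combination and ranks it first", {
  # 12/20 cases and 1/20 controls carry the 3-state combination; the
  # member states are individually balanced in the remaining samples
  set.seed(21)
  n <- 40
  gm <- matrix(sample(0:2, n * 6, replace = TRUE), n, 6,
               dimnames = list(sprintf("S%02d", 1:n), sprintf("v%d", 1:6)))
  labels <- rep(c("case", "control"), each = 20)
  carrier <- c(1:12, 21)                       # 12 cases + 1 control
  gm[carrier, 1:3] <- matrix(c(1L, 1L, 0L), length(carrier), 3, byrow = TRUE)
  noncarrier <- setdiff(1:n, carrier)
  gm[noncarrier, 1] <- rep(c(1L, 2L), length.out = length(noncarrier))
  gm[noncarrier, 2] <- rep(c(1L, 0L), length.out = length(noncarrier))
  gm[noncarrier, 3] <- rep(c(2L, 0L), length.out = length(noncarrier))
  g <- genotype_matrix(gm, labels)
  ms <- mine_signatures(g, mining_params(max_order = 3,
                                         search_mode = "exhaustive"))
  expect_gt(length(ms), 0)
  # the planted combination leads the ranking; sub-combinations with the
  # identical carrier set tie with it and sort first by lower order
  df <- as.data.frame(ms)
  top <- df[df$p_value == min(df$p_value), ]
  expect_true("v1:1;v2:1;v3:0" %in% top$signature)
  expect_true(all(grepl("v3:0", top$signature)))
  expect_equal(ms[[1]]$p_value, min(df$p_value))
  expect_true(all(vapply(ms, `[[`, integer(1), "order") <= 3))
})

test_that("identical case and control genotype rows mine nothing", {
  set.seed(22)
  half <- matrix(rbinom(40, 2, 0.4), 20, 2)
  gm <- rbind(half, half)
  dimnames(gm) <- list(sprintf("S%02d", 1:40), c("a", "b"))
  g <- genotype_matrix(gm, rep(c("case", "control"), each = 20))
  ms <- mine_signatures(g, mining_params(search_mode = "exhaustive",
                                         max_order = 2))
  expect_equal(length(ms), 0)
})

test_that("every greedy result is found by exhaustive search with identical stats", {
  co <- planted_cohort(33, n_cases = 80, n_snps = 8, or = 5, prev = 0.25)
  mpg <- mining_params(max_order = 3, n_random_starts = 20, seed = 2)
  mpe <- mining_params(max_order = 3, search_mode = "exhaustive")
  greedy <- mine_signatures(co$genotypes, mpg)
  exh <- mine_signatures(co$genotypes, mpe)
  ekeys <- vapply(exh, `[[`, character(1), "key")
  for (s in greedy) {
    i <- match(s$key, ekeys)
    expect_false(is.na(i))
    expect_equal(s$odds_ratio, exh[[i]]$odds_ratio)
    expect_equal(s$p_value, exh[[i]]$p_value)
    expect_setequal(s$case_ids, exh[[i]]$case_ids)
  }
})

test_that("no reported signature exceeds order 5 and all pass the filters", {
  co <- planted_cohort(44, n_cases = 300, n_snps = 40)
  mp <- mining_params(seed = 3)
  ms <- mine_signatures(co$genotypes, mp)
  expect_gt(length(ms), 0)
  df <- as.data.frame(ms)
  expect_true(all(df$order >= 1 & df$order <= 5))
  expect_true(all(df$p_value <= mp$p_max))
  expect_true(all(df$case_prevalence >= mp$min_case_prevalence))
  expect_true(all(df$odds_ratio > 1))
  # deterministic under a fixed seed
  ms2 <- mine_signatures(co$genotypes, mp)
  expect_identical(as.data.frame(ms), as.data.frame(ms2))
})

test_that("adding a state never enlarges a carrier set", {
  co <- planted_cohort(55, n_cases = 100, n_snps = 10)
  g <- co$genotypes
  set.seed(8)
  for (i in 1:25) {
    snps <- sample(snp_ids(g), 3)
    gt <- sample(0:2, 3, replace = TRUE)
    base <- carrier_vector(g, feature_states(snps[1:2], gt[1:2]))
    ext <- carrier_vector(g, feature_states(snps, gt))
    expect_true(all(which(ext) %in% which(base)))
  }
})

test_that("exhaustive search refuses configurations over the combination budget", {
  co <- planted_cohort(66, n_cases = 30, n_snps = 40)
  expect_error(
    mine_signatures(co$genotypes,
                    mining_params(search_mode = "exhaustive", max_order = 5,
                                  combination_budget = 1e5)),
    "budget")
})

test_that("maximal-only reporting returns a subset of layered reporting", {
  co <- planted_cohort(77, n_cases = 200, n_snps = 20)
  all_l <- mine_signatures(co$genotypes, mining_params(seed = 4))
  maxi <- mine_signatures(co$genotypes,
                          mining_params(seed = 4, report = "maximal"))
  expect_true(all(vapply(maxi, `[[`, character(1), "key") %in%
                    vapply(all_l, `[[`, character(1), "key")))
  expect_lte(length(maxi), length(all_l))
})

test_that("signature TSV/JSON serialization round-trips keys and stats", {
  co <- planted_cohort(88, n_cases = 100, n_snps = 10)
  ms <- mine_signatures(co$genotypes, mining_params(seed = 5))
  tsv <- file.path(tempdir(), "sigs.tsv")
  js <- file.path(tempdir(), "sigs.json")
  write_signatures(ms, tsv)
  write_signatures_json(ms, js)
  back <- read.delim(tsv)
  expect_equal(back$signature, vapply(ms, `[[`, character(1), "key"))
  jb <- jsonlite::read_json(js)
  expect_equal(length(jb), length(ms))
  expect_equal(jb[[1]]$odds_ratio, ms[[1]]$odds_ratio)
  # keys parse back into the same states
  st <- parse_state_key(jb[[1]]$signature)
  expect_identical(st$snp_id, ms[[1]]$states$snp_id)
})
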