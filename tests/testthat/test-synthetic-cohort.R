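# Synthetic cohort generator: reproducibility, Hardy-Weinberg background,
# carrier bookkeeping, odds-ratio calibration, infeasibility contracts.

test_that("identical spec and seed give bit-identical cohorts", {
  a <- planted_cohort(31, n_cases = 120, n_snps = 20)
  b <- planted_cohort(31, n_cases = 120, n_snps = 20)
  expect_identical(a, b)
  c_ <- planted_cohort(32, n_cases = 120, n_snps = 20)
  expect_false(identical(a$genotypes$genotypes, c_$genotypes$genotypes))
})

test_that("background SNPs follow Hardy-Weinberg proportions in the combined cohort", {
  co <- planted_cohort(7, n_cases = 3334, n_snps = 40)  # ~10k samples
  g <- co$genotypes
  bg <- setdiff(snp_ids(g), c("rs00001", "rs00002", "rs00003"))
  n <- nrow(g$genotypes)
  worst <- 0
  for (s in bg) {
    m <- g$snp_meta$maf[g$snp_meta$snp_id == s]
    exp_p <- c((1 - m)^2, 2 * m * (1 - m), m^2)
    obs <- tabulate(g$genotypes[, s] + 1L, 3) / n
    zs <- abs(obs - exp_p) / sqrt(exp_p * (1 - exp_p) / n)
    worst <- max(worst, max(zs))
  }
  expect_lt(worst, 4.5)  # binomial sampling error at n ~ 10,000
})

test_that("truth-set carrier counts equal a brute-force rescan of the emitted matrix", {
  co <- planted_cohort(13, n_cases = 150, n_snps = 15, missing_rate = 0.02)
  tr <- co$truth$signatures$sig1
  st <- feature_states(tr$snp_ids, tr$genotype_states)
  g <- co$genotypes
  by_matches <- vapply(rownames(g$genotypes), function(sid) {
    matches(g$genotypes[sid, ], st)
  }, logical(1))
  expect_identical(sort(names(which(by_matches & g$labels == "case"))),
                   sort(tr$case_ids))
  expect_equal(tr$case_carriers, sum(by_matches & g$labels == "case"))
  expect_equal(tr$control_carriers, sum(by_matches & g$labels == "control"))
  # and agree with the vectorized carrier scan
  expect_identical(unname(carrier_vector(g, st)), unname(by_matches))
})

test_that("realized odds ratios are calibrated to the target over seeds", {
  ors <- vapply(1:20, function(s) {
    co <- planted_cohort(s, n_cases = 2000, n_snps = 10, or = 3.0)
    co$truth$signatures$sig1$realized_or
  }, numeric(1))
  expect_gte(mean(ors), 2.7)
  expect_lte(mean(ors), 3.3)
})

test_that("single-cohort realized OR is near target at n_cases = 2000", {
  co <- planted_cohort(101, n_cases = 2000, n_snps = 10, or = 3.7, prev = 0.15)
  expect_lt(abs(co$truth$signatures$sig1$realized_or - 3.7) / 3.7, 0.15)
})

test_that("infeasible targets raise an error naming the signature", {
  # three homozygous-minor states cannot reach the required carrier
  # frequency within the MAF range
  sig <- planted_signature(c("rs00001", "rs00002", "rs00003"), c(2, 2, 2),
                           target_or = 2, target_case_prevalence = 0.4,
                           name = "hard")
  expect_error(
    generate_cohort(cohort_spec(n_cases = 100, n_snps = 5,
                                planted = list(sig), seed = 1)),
    "hard")
})

test_that("null cohorts carry no plantable association", {
  co <- null_cohort(5, n_cases = 200, n_snps = 12)
  gw <- single_snp_gwas(co$genotypes)
  af_or <- (gw$case_alt / gw$case_ref) / (gw$control_alt / gw$control_ref)
  expect_lt(abs(mean(log(af_or))), 0.2)  # allelic ORs centred on 1
  ms <- mine_signatures(co$genotypes,
                        mining_params(max_order = 3, p_max = 1,
                                      search_mode = "exhaustive",
                                      min_case_prevalence = 0.01))
  p <- vapply(ms, `[[`, numeric(1), "p_value")
  if (length(p) > 0) {
    expect_equal(sum(bh_adjust(p, 0.05)$reject), 0)
  }
})

test_that("marginal-free signatures have null single-SNP margins but a real joint effect", {
  sig <- planted_signature(c("rs00001", "rs00002", "rs00003"), c(1, 1, 1),
                           target_or = 4, target_case_prevalence = 0.15,
                           marginal_free = TRUE)
  ors <- numeric(6); af_gap <- numeric(6)
  for (s in 1:6) {
    co <- generate_cohort(cohort_spec(n_cases = 1000, n_snps = 10,
                                      planted = list(sig), seed = 300 + s))
    ors[s] <- co$truth$signatures$sig1$realized_or
    g <- co$genotypes
    isc <- g$labels == "case"
    af_gap[s] <- max(abs(colMeans(g$genotypes[isc, 1:3]) / 2 -
                           colMeans(g$genotypes[!isc, 1:3]) / 2))
  }
  expect_lt(abs(mean(ors) - 4) / 4, 0.2)
  expect_lt(mean(af_gap), 0.02)  # no marginal allele-frequency difference
})

test_that("covariate effects and biomarker shifts are applied to carriers", {
  sig <- planted_signature(c("rs00001", "rs00002", "rs00003"), c(1, 1, 0),
                           target_or = 4, target_case_prevalence = 0.3,
                           covariate_effects = list(stress_event = 2),
                           biomarker_shifts = list(lactate = 1))
  co <- generate_cohort(cohort_spec(n_cases = 800, n_snps = 5,
                                    planted = list(sig), seed = 17))
  carriers <- co$truth$signatures$sig1$case_ids
  cov <- co$covariates
  rownames(cov) <- cov$sample_id
  rest <- setdiff(cov$sample_id[cov$status == "case"], carriers)
  expect_gt(mean(cov[carriers, "stress_event"]),
            mean(cov[rest, "stress_event"]))
  expect_gt(mean(cov[carriers, "lactate"]), mean(cov[rest, "lactate"]) + 0.5)
})

test_that("missing-genotype injection respects the configured rate", {
  co <- planted_cohort(23, n_cases = 200, n_snps = 25, missing_rate = 0.05)
  expect_equal(mean(is.na(co$genotypes$genotypes)), 0.05, tolerance = 0.01)
  co0 <- planted_cohort(23, n_cases = 200, n_snps = 25)
  expect_false(anyNA(co0$genotypes$genotypes))
})

test_that("independently planted communities overlap below 20% of case carriers", {
  planted <- list(
    planted_signature(c("rs00001", "rs00002", "rs00003"), c(1, 1, 0),
                      3.7, 0.15, name = "a"),
    planted_signature(c("rs00011", "rs00012", "rs00013"), c(1, 0, 1),
                      3.7, 0.15, name = "b"))
  co <- generate_cohort(cohort_spec(n_cases = 1000, n_snps = 20,
                                    planted = planted, seed = 9))
  a <- co$truth$signatures$a$case_ids
  b <- co$truth$signatures$b$case_ids
  expect_lt(length(intersect(a, b)) / min(length(a), length(b)), 0.2)
})

test_that("block-LD option induces adjacent-SNP correlation; default has none", {
  co <- generate_cohort(cohort_spec(n_cases = 1000, n_snps = 20,
                                    ld_rho = 0.8, seed = 4))
  g <- co$genotypes$genotypes
  cors <- vapply(1:19, function(j) cor(g[, j], g[, j + 1]), numeric(1))
  expect_gt(mean(cors), 0.3)
  co0 <- generate_cohort(cohort_spec(n_cases = 1000, n_snps = 20, seed = 4))
  g0 <- co0$genotypes$genotypes
  cors0 <- vapply(1:19, function(j) cor(g0[, j], g0[, j + 1]), numeric(1))
  expect_lt(max(abs(cors0)), 0.1)
})
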