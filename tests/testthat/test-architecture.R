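# Disease-architecture graph, community detection, per-community
# statistics, overlap conventions.

arch_sigset <- function(keys, g) {
  sigs <- lapply(keys, function(k) evaluate_combination(parse_state_key(k), g))
  combsig:::signature_set(sigs, mining_params(), g)
}

test_that("one signature induces a clique; disjoint signatures stay disconnected", {
  co <- planted_cohort(41, n_cases = 100, n_snps = 12)
  g <- co$genotypes
  one <- arch_sigset("rs00001:1;rs00002:1;rs00003:0;rs00004:1", g)
  gr <- build_architecture(one)
  expect_equal(igraph::vcount(gr), 4)
  expect_equal(igraph::ecount(gr), 6)      # 4-clique
  two <- arch_sigset(c("rs00001:1;rs00002:1;rs00003:0",
                       "rs00007:2;rs00008:0;rs00009:1"), g)
  gr2 <- build_architecture(two)
  expect_equal(igraph::components(gr2)$no, 2)
})

test_that("edge weights equal brute-force Jaccard of the state case sets", {
  co <- planted_cohort(42, n_cases = 120, n_snps = 10)
  g <- co$genotypes
  set <- arch_sigset(c("rs00001:1;rs00002:1;rs00003:0",
                       "rs00001:1;rs00004:0;rs00005:1"), g)
  gr <- build_architecture(set)
  caseset <- function(lab) {
    hits <- Filter(function(s) lab %in% sig_state_labels(s), unclass(set))
    unique(unlist(lapply(hits, `[[`, "case_ids")))
  }
  el <- igraph::as_data_frame(gr, what = "edges")
  for (i in seq_len(nrow(el))) {
    a <- caseset(el$from[i]); b <- caseset(el$to[i])
    expect_equal(el$weight[i], length(intersect(a, b)) / length(union(a, b)))
  }
})

test_that("detect_communities partitions every node exactly once and separates disjoint families", {
  co <- planted_cohort(43, n_cases = 100, n_snps = 12)
  set <- arch_sigset(c("rs00001:1;rs00002:1;rs00003:0",
                       "rs00007:2;rs00008:0;rs00009:1"), co$genotypes)
  gr <- build_architecture(set)
  for (m in c("modularity", "components")) {
    memb <- detect_communities(gr, method = m, seed = 3)
    expect_equal(sort(names(memb)), sort(igraph::V(gr)$name))
    expect_false(anyNA(memb))
    expect_equal(length(unique(memb)), 2)
    # both member states of a signature share a label
    expect_equal(length(unique(memb[c("rs00001:1", "rs00002:1", "rs00003:0")])), 1)
  }
})

test_that("community labels are invariant to signature insertion order", {
  co <- planted_cohort(44, n_cases = 150, n_snps = 20)
  keys <- c("rs00001:1;rs00002:1;rs00003:0",
            "rs00005:0;rs00006:1;rs00007:1",
            "rs00001:1;rs00002:1;rs00009:0")
  a <- build_architecture(arch_sigset(keys, co$genotypes))
  b <- build_architecture(arch_sigset(rev(keys), co$genotypes))
  ma <- detect_communities(a, seed = 5)
  mb <- detect_communities(b, seed = 5)
  expect_identical(ma[sort(names(ma))], mb[sort(names(mb))])
})

test_that("community statistics equal a naive rescan of the raw matrix", {
  co <- planted_cohort(45, n_cases = 120, n_snps = 12)
  g <- co$genotypes
  keys <- c("rs00001:1;rs00002:1;rs00003:0", "rs00001:1;rs00002:1;rs00005:0")
  set <- arch_sigset(keys, g)
  cs <- community_stats(set, c(1L, 1L), g)
  expect_equal(nrow(cs), 1)
  # oracle: a sample carries the community iff it carries >= 1 member
  carrier <- carrier_vector(g, parse_state_key(keys[1])) |
    carrier_vector(g, parse_state_key(keys[2]))
  a <- sum(carrier & g$labels == "case")
  b <- sum(carrier & g$labels == "control")
  expect_equal(cs$case_carriers, a)
  expect_equal(cs$control_carriers, b)
  n_case <- sum(g$labels == "case")
  n_ctrl <- sum(g$labels == "control")
  expect_equal(cs$odds_ratio,
               odds_ratio(contingency_2x2(a, n_case - a, b, n_ctrl - b)))
  expect_equal(cs$p_value,
               fisher_exact_p(contingency_2x2(a, n_case - a, b, n_ctrl - b)))
  expect_equal(cs$cases_pct, round(100 * a / n_case))
})

test_that("a community carried equally by cases and controls has OR near 1", {
  set.seed(50)
  n <- 600
  gm <- matrix(rbinom(n * 4, 2, 0.4), n, 4,
               dimnames = list(sprintf("S%03d", 1:n), sprintf("v%d", 1:4)))
  g <- genotype_matrix(gm, rep(c("case", "control"), each = n / 2))
  set <- arch_sigset("v1:1;v2:1", g)
  cs <- community_stats(set, 1L, g)
  expect_lt(abs(log(cs$odds_ratio)), 0.5)
})

test_that("overlap matrix follows the min-denominator convention", {
  sets <- list(a = c("x1", "x2", "x3", "x4"),
               b = c("x5", "x6"),
               c = c("x1", "x2"),
               d = c("x1", "x2", "x5"))
  om <- overlap_matrix(sets)
  expect_equal(om["a", "b"], 0)            # disjoint
  expect_equal(om["a", "c"], 1)            # nested: |A n C| / |C|
  expect_equal(om["c", "d"], 1)            # min denominator documents ties
  expect_true(isSymmetric(om))
  expect_equal(unname(diag(om)), rep(1, 4))
  omj <- overlap_matrix(sets, denominator = "union")
  expect_equal(omj["a", "c"], 2 / 4)       # Jaccard alternative
})

test_that("cases_represented is the exact union fraction", {
  co <- planted_cohort(46, n_cases = 100, n_snps = 10)
  g <- co$genotypes
  set <- arch_sigset(c("rs00001:1;rs00002:1;rs00003:0",
                       "rs00005:0;rs00006:0;rs00007:1"), g)
  u <- unique(unlist(lapply(set, `[[`, "case_ids")))
  expect_equal(cases_represented(set, g), length(u) / 100)
  empty <- combsig:::signature_set(list(), mining_params(), g)
  expect_equal(cases_represented(empty, g), 0)
})

test_that("architecture exports edge-list TSV and GraphML", {
  co <- planted_cohort(47, n_cases = 80, n_snps = 10)
  set <- arch_sigset("rs00001:1;rs00002:1;rs00003:0", co$genotypes)
  gr <- build_architecture(set)
  tsv <- file.path(tempdir(), "arch.tsv")
  gml <- file.path(tempdir(), "arch.graphml")
  write_architecture(gr, tsv)
  write_architecture(gr, gml)
  el <- read.delim(tsv)
  expect_equal(nrow(el), igraph::ecount(gr))
  expect_true(file.size(gml) > 0)
})
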