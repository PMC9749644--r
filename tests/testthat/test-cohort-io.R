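# Format round-trips, QC rules, matched control selection.

test_that("genotype TSV round-trips bit-exactly", {
  co <- planted_cohort(3, n_cases = 25, n_snps = 20, missing_rate = 0.03)
  p1 <- file.path(tempdir(), "g1.tsv")
  p2 <- file.path(tempdir(), "g2.tsv")
  write_genotypes(co$genotypes, p1)
  g2 <- read_genotypes(p1)
  expect_identical(g2$genotypes, co$genotypes$genotypes)
  expect_identical(g2$labels, co$genotypes$labels)
  write_genotypes(g2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("VCF write/read round-trips genotypes, missing calls and metadata", {
  skip_if_not_installed("vcfR")
  co <- planted_cohort(4, n_cases = 15, n_snps = 8, missing_rate = 0.05)
  p <- file.path(tempdir(), "g.vcf")
  write_genotypes(co$genotypes, p, format = "vcf")
  g2 <- read_genotypes(p, labels = unname(co$genotypes$labels))
  expect_identical(g2$genotypes, co$genotypes$genotypes)
  expect_identical(g2$snp_meta$pos, co$genotypes$snp_meta$pos)
  expect_identical(g2$snp_meta$ref, co$genotypes$snp_meta$ref)
})

test_that("VCF GT coding is definitional and malformed records are rejected", {
  skip_if_not_installed("vcfR")
  dir <- tempdir()
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB\tC\tD")
  ok <- file.path(dir, "ok.vcf")
  writeLines(c(hdr, "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t./."),
             ok)
  g <- read_genotypes(ok, labels = c("case", "case", "control", "control"))
  expect_equal(unname(g$genotypes[, "rs1"]), c(0L, 1L, 2L, NA))
  multi <- file.path(dir, "multi.vcf")
  writeLines(c(hdr, "1\t100\trs1\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t2/2"),
             multi)
  expect_error(read_genotypes(multi, labels = rep("case", 4)), "multi-allelic")
  dup <- file.path(dir, "dup.vcf")
  writeLines(c(hdr,
               "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",
               "1\t200\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0"), dup)
  expect_error(read_genotypes(dup, labels = rep("case", 4)), "duplicate")
})

make_qc_gm <- function() {
  set.seed(42)
  n <- 200
  gm <- matrix(rbinom(n * 6, 2, 0.3), n, 6)
  colnames(gm) <- sprintf("v%d", 1:6)
  rownames(gm) <- sprintf("S%03d", 1:n)
  gm[, "v2"] <- 0L                               # monomorphic
  gm[1:100, "v3"] <- NA_integer_                 # 50% missing SNP
  gm[, "v4"] <- rep(c(0L, 2L), n / 2)            # no heterozygotes: HWE failure
  gm[1, ] <- NA_integer_                         # sample fully missing
  labels <- rep(c("case", "control"), each = n / 2)
  meta <- data.frame(snp_id = colnames(gm),
                     chrom = c("1", "2", "3", "4", "X", "5"),
                     pos = 1:6 * 1000L, ref = "A", alt = "G", maf = NA_real_,
                     stringsAsFactors = FALSE)
  genotype_matrix(gm, labels, meta)
}

test_that("qc_filter applies each rule and reports removals", {
  g <- make_qc_gm()
  # the half-missing SNP leaves every row 1/6 missing; the per-sample
  # threshold is set above that so only the fully missing sample fails
  res <- qc_filter(g, qc_params(sample_missing_max = 0.3))
  expect_equal(res$report$samples_removed_missingness, 1)
  expect_equal(res$report$snps_removed_non_autosomal, 1)  # chromosome X
  expect_false("v2" %in% snp_ids(res$genotypes))          # MAF 0
  expect_false("v3" %in% snp_ids(res$genotypes))          # missingness
  expect_false("v4" %in% snp_ids(res$genotypes))          # HWE in controls
  expect_true(all(c("v1", "v6") %in% snp_ids(res$genotypes)))
  # HWE oracle: the no-heterozygote SNP has an astronomically small exact p
  ctrl <- g$genotypes[g$labels == "control", "v4"]
  expect_lt(hwe_exact_p(sum(ctrl == 0), sum(ctrl == 1), sum(ctrl == 2)), 1e-6)
})

test_that("qc_filter is idempotent", {
  g <- make_qc_gm()
  once <- qc_filter(g, qc_params(sample_missing_max = 0.3))
  twice <- qc_filter(once$genotypes, qc_params(sample_missing_max = 0.3))
  expect_identical(once$genotypes, twice$genotypes)
  expect_equal(twice$report$snps_removed_maf +
                 twice$report$snps_removed_missingness +
                 twice$report$snps_removed_hwe +
                 twice$report$samples_removed_missingness, 0)
})

test_that("qc_filter errors when everything is removed", {
  gm <- matrix(0L, 10, 2, dimnames = list(sprintf("S%d", 1:10), c("a", "b")))
  g <- genotype_matrix(gm, rep(c("case", "control"), 5))
  expect_error(qc_filter(g, qc_params()), "all SNPs removed")
})

test_that("match_controls: exact ratio per stratum, determinism, shortfall error", {
  set.seed(1)
  cov <- data.frame(
    sample_id = sprintf("S%03d", 1:130),
    sex = rep(c("F", "M"), 65),
    ancestry = "EUR",
    stringsAsFactors = FALSE)
  cases <- cov$sample_id[1:20]
  pool <- cov$sample_id[21:130]
  sel <- match_controls(cov, cases, pool, matching_spec(ratio = 2, seed = 5))
  expect_equal(length(sel), 40)
  # marginal key distributions preserved exactly
  rownames(cov) <- cov$sample_id
  expect_equal(table(cov[sel, "sex"]) / 2, table(cov[cases, "sex"]))
  expect_identical(sel,
                   match_controls(cov, cases, pool, matching_spec(ratio = 2, seed = 5)))
  sel2 <- match_controls(cov, cases, pool, matching_spec(ratio = 2, seed = 6))
  expect_false(identical(sel, sel2))
  # 3 available for 2 cases at ratio 2 -> shortfall names the stratum
  small <- data.frame(sample_id = sprintf("P%d", 1:5),
                      sex = "F", ancestry = "EUR", stringsAsFactors = FALSE)
  expect_error(
    match_controls(small, small$sample_id[1:2], small$sample_id[3:5],
                   matching_spec(ratio = 2)),
    "short by 1")
})

test_that("gene model GFF3 and BED writers round-trip through rtracklayer", {
  skip_if_not_installed("rtracklayer")
  co <- planted_cohort(6, n_cases = 20, n_snps = 10)
  gm <- co$gene_model
  gff <- file.path(tempdir(), "m.gff3")
  bed <- file.path(tempdir(), "m.bed")
  write_gene_model(gm, gff)
  write_gene_model(gm, bed)
  m2 <- suppressWarnings(read_gene_model(gff))
  expect_equal(m2$gene_id, gm$gene_id)
  expect_equal(m2$start, gm$start)
  expect_equal(m2$end, gm$end)
  expect_equal(m2$strand, gm$strand)
  expect_equal(m2$cds_start, as.integer(gm$cds_start))
  m3 <- suppressWarnings(read_gene_model(bed))
  # BED is 0-based half-open on disk; coordinates must survive conversion
  expect_equal(m3$start, gm$start)
  expect_equal(m3$end, gm$end)
})

test_that("write_cohort emits the full artifact set", {
  co <- planted_cohort(8, n_cases = 15, n_snps = 6)
  dir <- file.path(tempdir(), "cohortout")
  write_cohort(co, dir)
  expect_setequal(list.files(dir),
                  c("genotypes.tsv", "genotypes.vcf", "covariates.tsv",
                    "genes.gff3", "genes.bed", "truth.json"))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(tr$signatures$sig1$case_carriers,
               co$truth$signatures$sig1$case_carriers)
})
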