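# Reading/writing the standard formats, genotype QC, and matched control
# selection.
#
# TSV dialect: tab-separated, header row, "NA" for missing. The genotype
# TSV stores samples in rows (first two columns `sample_id`, `status`,
# then one column per SNP with values 0/1/2/NA) and round-trips
# bit-exactly. VCF output follows v4.2 with one biallelic record per SNP
# and a GT field; VCF reading is delegated to vcfR.

#' Write a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    dt <- data.table::data.table(sample_id = rownames(g$genotypes),
                                 status = unname(g$labels))
    dt <- cbind(dt, data.table::as.data.table(g$genotypes))
    data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
    return(invisible(path))
  }
  meta <- g$snp_meta
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=combsig",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(g$genotypes)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(g$genotypes)), function(j) {
    gt <- g$genotypes[, j]
    calls <- ifelse(is.na(gt), "./.", gt_code[gt + 1L])
    paste(c(meta$chrom[j], meta$pos[j], meta$snp_id[j], meta$ref[j],
            meta$alt[j], ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a genotype matrix
#'
#' TSV as written by [write_genotypes()]; VCF v4.2 via vcfR, with genotype
#' dosage = count of alternate alleles and `./.` as missing. Multi-allelic
#' records are rejected. Since VCF carries no phenotype, `labels` must be
#' supplied for VCF input (vector or the path of a covariate TSV with
#' `sample_id` and `status` columns).
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`; guessed from the extension by default.
#' @param labels case/control labels for VCF input.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf"),
                           labels = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
              else "tsv"
  }
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
    abort_if(!all(c("sample_id", "status") %in% names(dt)),
             "genotype TSV must have sample_id and status columns")
    gm <- as.matrix(dt[, -(1:2)])
    rownames(gm) <- dt$sample_id
    return(genotype_matrix(gm, dt$status))
  }
  abort_if(!requireNamespace("vcfR", quietly = TRUE),
           "read_genotypes(format = 'vcf') requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  abort_if(any(multi), "multi-allelic record(s) at line(s): %s",
           paste(utils::head(which(multi), 5), collapse = ", "))
  abort_if(anyDuplicated(fix[, "ID"]) > 0, "duplicate SNP id in VCF: %s",
           fix[, "ID"][anyDuplicated(fix[, "ID"])])
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage[clean %in% c("0/0")] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean %in% c("1/1")] <- 2L
  bad <- !is.na(clean) & !clean %in% c("0/0", "0/1", "1/0", "1/1", "./.")
  abort_if(any(bad), "unparseable GT value '%s'", clean[which(bad)[1]])
  gm <- t(dosage)
  colnames(gm) <- unname(fix[, "ID"])
  if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
    cov <- data.table::fread(labels, sep = "\t", header = TRUE)
    labels <- stats::setNames(cov$status, cov$sample_id)[rownames(gm)]
  }
  abort_if(is.null(labels), "VCF input requires labels (vector or covariate TSV)")
  snp_meta <- data.frame(
    snp_id = unname(fix[, "ID"]), chrom = unname(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]), ref = unname(fix[, "REF"]),
    alt = unname(fix[, "ALT"]), maf = NA_real_, stringsAsFactors = FALSE)
  genotype_matrix(gm, labels, snp_meta)
}

#' Write / read a covariate table
#'
#' Plain TSV with header, `NA` for missing.
#'
#' @param covariates data.frame with a `sample_id` column.
#' @param path file path.
#' @return `path` (write) / data.frame (read).
#' @export
write_covariates <- function(covariates, path) {
  data.table::fwrite(covariates, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = "NA"))
}

#' Genotype quality-control parameters
#'
#' The defaults are field-standard filters (the originating study's exact
#' thresholds are not public): SNPs below 1% MAF, above 5% missingness or
#' failing the exact Hardy-Weinberg test in controls at p < 1e-6 are
#' removed, as are samples with more than 5% missing genotypes, and
#' non-autosomal SNPs.
#'
#' @param maf_min minimum minor-allele frequency (default 0.01).
#' @param snp_missing_max maximum per-SNP missingness (default 0.05).
#' @param sample_missing_max maximum per-sample missingness (default 0.05).
#' @param hwe_p_min Hardy-Weinberg exact-test floor, applied in controls
#'   (default 1e-6).
#' @param autosomes_only drop SNPs outside chromosomes 1-22 (default TRUE).
#' @return an object of class `qc_params`.
#' @export
qc_params <- function(maf_min = 0.01, snp_missing_max = 0.05,
                      sample_missing_max = 0.05, hwe_p_min = 1e-6,
                      autosomes_only = TRUE) {
  vals <- c(maf_min, snp_missing_max, sample_missing_max, hwe_p_min)
  abort_if(any(vals < 0 | vals > 1), "qc_params: thresholds must lie in [0, 1]")
  structure(list(maf_min = maf_min, snp_missing_max = snp_missing_max,
                 sample_missing_max = sample_missing_max,
                 hwe_p_min = hwe_p_min,
                 autosomes_only = isTRUE(autosomes_only)),
            class = "qc_params")
}

#' Apply genotype quality control
#'
#' Filters are applied in a fixed order: samples by missingness, then SNPs
#' by missingness, then MAF, then the exact Hardy-Weinberg test in
#' controls (and the autosome restriction first of all). The procedure is
#' idempotent.
#'
#' @param g a [genotype_matrix()].
#' @param q a [qc_params()].
#' @return list with `genotypes` (filtered matrix) and `report` (counts
#'   removed per rule; serializable to JSON).
#' @export
qc_filter <- function(g, q = qc_params()) {
  abort_if(nrow(g$genotypes) == 0 || ncol(g$genotypes) == 0,
           "qc_filter: empty genotype matrix")
  report <- list(params = unclass(q),
                 n_samples_in = nrow(g$genotypes),
                 n_snps_in = ncol(g$genotypes))
  cur <- g
  # autosome restriction
  if (q$autosomes_only) {
    keep <- cur$snp_meta$chrom %in% as.character(1:22)
    report$snps_removed_non_autosomal <- sum(!keep)
    abort_if(!any(keep), "qc_filter: all SNPs removed")
    cur <- subset_genotypes(cur, snps = which(keep))
  } else report$snps_removed_non_autosomal <- 0L
  # sample missingness
  smiss <- rowMeans(is.na(cur$genotypes))
  keep_s <- smiss <= q$sample_missing_max
  report$samples_removed_missingness <- sum(!keep_s)
  cur <- subset_genotypes(cur, samples = which(keep_s))
  # SNP missingness
  vmiss <- colMeans(is.na(cur$genotypes))
  keep_v <- vmiss <= q$snp_missing_max
  report$snps_removed_missingness <- sum(!keep_v)
  abort_if(!any(keep_v), "qc_filter: all SNPs removed")
  cur <- subset_genotypes(cur, snps = which(keep_v))
  # MAF
  af <- colMeans(cur$genotypes, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep_v <- !is.na(maf) & maf >= q$maf_min
  report$snps_removed_maf <- sum(!keep_v)
  abort_if(!any(keep_v), "qc_filter: all SNPs removed")
  cur <- subset_genotypes(cur, snps = which(keep_v))
  # HWE exact test in controls
  ctrl <- cur$genotypes[cur$labels == "control", , drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(ctrl)), function(j) {
    gt <- ctrl[, j]
    hwe_exact_p(sum(gt == 0, na.rm = TRUE), sum(gt == 1, na.rm = TRUE),
                sum(gt == 2, na.rm = TRUE))
  }, numeric(1))
  keep_v <- hwe_p >= q$hwe_p_min
  report$snps_removed_hwe <- sum(!keep_v)
  abort_if(!any(keep_v), "qc_filter: all SNPs removed")
  cur <- subset_genotypes(cur, snps = which(keep_v))
  report$n_samples_out <- nrow(cur$genotypes)
  report$n_snps_out <- ncol(cur$genotypes)
  list(genotypes = cur, report = report)
}

#' Control-matching specification
#'
#' @param ratio controls per case (integer >= 1, default 2).
#' @param keys categorical covariates defining the matching strata
#'   (default sex and ancestry).
#' @param seed integer seed for the within-stratum draw.
#' @return an object of class `matching_spec`.
#' @export
matching_spec <- function(ratio = 2L, keys = c("sex", "ancestry"), seed = 1L) {
  abort_if(ratio < 1, "matching_spec: ratio must be >= 1")
  structure(list(ratio = as.integer(ratio), keys = keys,
                 seed = as.integer(seed)),
            class = "matching_spec")
}

#' Select matched controls
#'
#' Within each stratum of the matching keys, samples exactly
#' `ratio x (cases in stratum)` controls from the pool without
#' replacement, deterministically for a given seed.
#'
#' @param covariates data.frame with `sample_id` and the key columns.
#' @param case_ids sample ids of the cases.
#' @param pool_ids sample ids of the candidate controls (disjoint from
#'   `case_ids`).
#' @param m a [matching_spec()].
#' @return character vector of selected control ids.
#' @export
match_controls <- function(covariates, case_ids, pool_ids,
                           m = matching_spec()) {
  abort_if(length(intersect(case_ids, pool_ids)) > 0,
           "match_controls: pool overlaps cases")
  abort_if(!all(m$keys %in% names(covariates)),
           "match_controls: missing key column(s): %s",
           paste(setdiff(m$keys, names(covariates)), collapse = ", "))
  rownames(covariates) <- covariates$sample_id
  stratum <- function(ids) {
    apply(covariates[ids, m$keys, drop = FALSE], 1, paste, collapse = "|")
  }
  cs <- stratum(case_ids)
  ps <- stratum(pool_ids)
  selected <- character(0)
  for (s in sort(unique(cs))) {
    need <- m$ratio * sum(cs == s)
    avail <- sort(pool_ids[ps == s])
    abort_if(length(avail) < need,
             "match_controls: stratum '%s' short by %d control(s)",
             s, need - length(avail))
    pick <- with_seed(derive_seed(m$seed, match(s, sort(unique(cs)))),
                      sample(avail, need))
    selected <- c(selected, pick)
  }
  sort(selected)
}

#' Write a full synthetic cohort to disk
#'
#' Emits the genotype TSV and VCF, the covariate TSV, the gene model
#' (GFF3 and BED) and the truth set (JSON) into a directory.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  write_genotypes(cohort$genotypes, file.path(dir, "genotypes.vcf"),
                  format = "vcf")
  write_covariates(cohort$covariates, file.path(dir, "covariates.tsv"))
  write_gene_model(cohort$gene_model, file.path(dir, "genes.gff3"))
  write_gene_model(cohort$gene_model, file.path(dir, "genes.bed"))
  write_truth(cohort$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Serialize a truth set to JSON
#'
#' @param truth a `truth_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
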