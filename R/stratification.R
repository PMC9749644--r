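# Patient-subgroup enrichment profiles, cohort covariate forest data,
# the single-SNP association baseline, and restricted-SNP replication in a
# disjoint cohort.

#' Enrichment profile of a patient subgroup
#'
#' Compares a subgroup of cases against the remaining cases: categorical
#' covariates (binary/logical/character/factor) with the pooled
#' two-proportion z-test per level, continuous covariates with the
#' Mann-Whitney U test; Benjamini-Hochberg correction across all features
#' tested for the subgroup. Missing values are excluded pairwise.
#'
#' @param subgroup_ids case sample ids in the subgroup (a strict,
#'   non-empty subset of the cases).
#' @param covariates data.frame with `sample_id`, `status` and feature
#'   columns.
#' @param features columns to test; defaults to every column except
#'   `sample_id` / `status`.
#' @param alpha FDR level for the reported rejection flags (default 0.05).
#' @return data.frame of class `enrichment_result`: `feature`, `level`,
#'   `type`, `direction`, `subgroup_value`, `rest_value`, `p`, `q`,
#'   `significant`.
#' @export
profile_subgroup <- function(subgroup_ids, covariates, features = NULL,
                             alpha = 0.05) {
  cases <- covariates[covariates$status == "case", , drop = FALSE]
  abort_if(!all(subgroup_ids %in% cases$sample_id),
           "profile_subgroup: subgroup must be a subset of the cases")
  abort_if(length(subgroup_ids) == 0, "profile_subgroup: empty subgroup")
  abort_if(length(subgroup_ids) == nrow(cases),
           "profile_subgroup: subgroup equals all cases; no comparison group")
  features <- features %||% setdiff(names(covariates),
                                    c("sample_id", "status"))
  in_sub <- cases$sample_id %in% subgroup_ids
  rows <- list()
  for (f in features) {
    x <- cases[[f]]
    ok <- !is.na(x)
    if (!any(ok)) next
    if (is.numeric(x) && !all(x[ok] %in% 0:1)) {
      a <- x[ok & in_sub]
      b <- x[ok & !in_sub]
      if (length(a) == 0 || length(b) == 0) next
      mw <- suppressWarnings(mann_whitney_u(a, b))
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, level = NA_character_, type = "continuous",
        direction = if (stats::median(a) >= stats::median(b)) "higher" else "lower",
        subgroup_value = stats::median(a), rest_value = stats::median(b),
        p = mw$p, stringsAsFactors = FALSE)
    } else {
      lv <- if (is.numeric(x) || is.logical(x)) list(`1` = 1) else {
        vals <- sort(unique(as.character(x[ok])))
        stats::setNames(as.list(vals), vals)
      }
      for (lname in names(lv)) {
        hit <- as.character(x) == as.character(lv[[lname]])
        a <- sum(hit[ok & in_sub])
        na <- sum(ok & in_sub)
        b <- sum(hit[ok & !in_sub])
        nb <- sum(ok & !in_sub)
        if (na == 0 || nb == 0) next
        zt <- tryCatch(
          two_proportion_z(contingency_2x2(a, na - a, b, nb - b)),
          error = function(e) list(z = 0, p = 1))
        rows[[length(rows) + 1]] <- data.frame(
          feature = f, level = lname, type = "categorical",
          direction = if (a / na >= b / nb) "higher" else "lower",
          subgroup_value = a / na, rest_value = b / nb,
          p = zt$p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(feature = character(0), level = character(0),
                      type = character(0), direction = character(0),
                      subgroup_value = numeric(0), rest_value = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  }
  bh <- bh_adjust(out$p, alpha)
  out$q <- bh$q
  out$significant <- bh$reject
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Covariate forest-plot data
#'
#' Per group (cases, controls, rest) and binary covariate: the percentage
#' of positive individuals with a percentile bootstrap confidence
#' interval.
#'
#' @param covariates data.frame with `sample_id` and the covariate columns.
#' @param groups named list of disjoint sample-id vectors (conventionally
#'   `cases`, `controls`, `rest`); all must be non-empty.
#' @param features binary covariate columns to summarize.
#' @param n_boot bootstrap iterations (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return data.frame of class `forest_estimate`: `group`, `covariate`,
#'   `percentage`, `ci_low`, `ci_high`.
#' @export
covariate_forest <- function(covariates, groups, features,
                             n_boot = 1000, level = 0.95, seed = 1L) {
  nm <- names(groups)
  abort_if(is.null(nm) || any(nm == ""), "covariate_forest: groups must be named")
  for (i in seq_along(groups)) {
    abort_if(length(groups[[i]]) == 0, "covariate_forest: group '%s' is empty",
             nm[i])
    for (j in seq_along(groups)) {
      if (i < j) abort_if(length(intersect(groups[[i]], groups[[j]])) > 0,
                          "covariate_forest: groups '%s' and '%s' overlap",
                          nm[i], nm[j])
    }
  }
  rownames(covariates) <- covariates$sample_id
  rows <- list()
  for (gi in seq_along(groups)) {
    for (f in features) {
      x <- covariates[groups[[gi]], f]
      x <- x[!is.na(x)]
      ci <- bootstrap_proportion_ci(x, n_boot = n_boot, level = level,
                                    seed = derive_seed(seed, gi, match(f, features)))
      rows[[length(rows) + 1]] <- data.frame(
        group = nm[gi], covariate = f,
        percentage = 100 * ci$point,
        ci_low = 100 * ci$lo, ci_high = 100 * ci$hi,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("forest_estimate", "data.frame")
  out
}

#' Single-SNP association baseline
#'
#' Standard per-SNP allelic case-control test on the 2 x 2 allele-count
#' table (2N alleles): chi-squared (1 df, no continuity correction; the
#' common single-variant default) or Fisher exact. Monomorphic SNPs get
#' p = 1 and a flag.
#'
#' @param g a QC'd [genotype_matrix()].
#' @param test `"allelic_chisq"` (default) or `"fisher"`.
#' @param genome_wide_alpha significance threshold (default 5e-8).
#' @return data.frame of class `gwas_result`: `snp_id`, `chrom`, `pos`,
#'   `case_alt`, `case_ref`, `control_alt`, `control_ref`, `p`,
#'   `monomorphic`, `significant`; the significant SNP set in
#'   `attr(, "significant_snps")`.
#' @export
single_snp_gwas <- function(g, test = c("allelic_chisq", "fisher"),
                            genome_wide_alpha = 5e-8) {
  test <- match.arg(test)
  is_case <- g$labels == "case"
  gm <- g$genotypes
  alt_case <- colSums(gm[is_case, , drop = FALSE], na.rm = TRUE)
  n_case <- colSums(!is.na(gm[is_case, , drop = FALSE]))
  alt_ctrl <- colSums(gm[!is_case, , drop = FALSE], na.rm = TRUE)
  n_ctrl <- colSums(!is.na(gm[!is_case, , drop = FALSE]))
  a <- alt_case; b <- 2 * n_case - alt_case
  c_ <- alt_ctrl; d <- 2 * n_ctrl - alt_ctrl
  mono <- (a + c_ == 0) | (b + d == 0)
  if (test == "allelic_chisq") {
    n <- a + b + c_ + d
    num <- n * (a * d - b * c_)^2
    den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
    chi <- ifelse(den > 0, num / den, 0)
    p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  } else {
    p <- vapply(seq_along(a), function(j) {
      if (mono[j]) return(1)
      fisher_exact_p(contingency_2x2(a[j], b[j], c_[j], d[j]))
    }, numeric(1))
  }
  p[mono] <- 1
  out <- data.frame(
    snp_id = colnames(gm), chrom = g$snp_meta$chrom, pos = g$snp_meta$pos,
    case_alt = a, case_ref = b, control_alt = c_, control_ref = d,
    p = p, monomorphic = mono, significant = p < genome_wide_alpha,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("gwas_result", "data.frame"),
            significant_snps = out$snp_id[out$significant])
}

#' Restricted-SNP replication in a disjoint cohort
#'
#' Re-runs mining plus permutation validation on a second cohort with the
#' search restricted to combinations whose SNPs all belong to a reference
#' set (e.g. the critical SNPs of the discovery cohort). Reference SNPs
#' absent from the second cohort are reported as untestable.
#'
#' @param reference_snps character vector of SNP ids from the discovery
#'   cohort.
#' @param g2 the disjoint replication [genotype_matrix()].
#' @param mining a [mining_params()].
#' @param validation a [validation_params()].
#' @return list of class `replication_report`: `replicated` (reference
#'   SNPs in at least one validated signature of `g2`), `untestable`,
#'   `tested`, `validated` (the validated `signature_set`).
#' @export
replicate_in_cohort <- function(reference_snps, g2,
                                mining = mining_params(),
                                validation = validation_params()) {
  abort_if(length(reference_snps) == 0, "replicate_in_cohort: empty SNP set")
  untestable <- setdiff(reference_snps, snp_ids(g2))
  testable <- setdiff(reference_snps, untestable)
  abort_if(length(testable) == 0,
           "replicate_in_cohort: no reference SNP present in the cohort")
  g_restricted <- subset_genotypes(g2, snps = testable)
  mined <- mine_signatures(g_restricted, mining)
  rep <- compute_p1000(mined, g_restricted, validation, mining)
  validated <- validate_signatures(mined, rep, validation)
  hit <- unique(unlist(lapply(validated, function(s) s$states$snp_id)))
  structure(
    list(replicated = sort(intersect(testable, hit)),
         untestable = sort(untestable),
         tested = sort(testable),
         validated = validated),
    class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf(
    "replication_report: %d/%d reference SNPs replicated (%d untestable)\n",
    length(x$replicated), length(x$tested) + length(x$untestable),
    length(x$untestable)))
  invisible(x)
}
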