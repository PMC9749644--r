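# Permutation-null validation of mined signatures.
#
# The mining procedure is re-run on label-shuffled copies of the cohort
# (same parameters, same case:control ratio). A signature scores a
# "hit" in a permutation iff the permuted result set contains any
# combination at least as strong on both named axes: odds ratio >= the
# signature's observed odds ratio AND case-carrier count >= its observed
# case-carrier count. The per-signature hit count over the permutation
# cycle is the P1000 score (named after the conventional 1000 cycles);
# empirical p-values use the add-one correction and are filtered by
# Benjamini-Hochberg FDR to give the validated signature set.

#' Validation parameters
#'
#' @param n_perm number of label permutations (conventionally 1000;
#'   smaller values scale the procedure down proportionally).
#' @param fdr_alpha Benjamini-Hochberg FDR level for the empirical
#'   p-values (default 0.05).
#' @param p1000_significance_fraction signatures with
#'   `p1000 / n_perm` below this fraction are flagged as
#'   permutation-significant (default 0.05, i.e. the "P1000 < 50 of 1000"
#'   rule).
#' @param seed integer seed; permutation `i` is drawn from a sub-stream
#'   derived from `(seed, i)`, so prefixes of the permutation sequence are
#'   reproducible independently of `n_perm`.
#' @return an object of class `validation_params`.
#' @export
validation_params <- function(n_perm = 1000, fdr_alpha = 0.05,
                              p1000_significance_fraction = 0.05,
                              seed = 1L) {
  abort_if(n_perm < 1, "validation_params: n_perm must be >= 1")
  abort_if(fdr_alpha <= 0 || fdr_alpha >= 1,
           "validation_params: fdr_alpha must lie in (0, 1)")
  structure(
    list(n_perm = as.integer(n_perm), fdr_alpha = fdr_alpha,
         p1000_significance_fraction = p1000_significance_fraction,
         seed = as.integer(seed)),
    class = "validation_params"
  )
}

#' Permute case/control labels
#'
#' Uniform random permutation of the existing labels: the case:control
#' counts are preserved exactly. Deterministic for a given
#' `(seed, iteration)` pair.
#'
#' @param g a [genotype_matrix()].
#' @param seed base seed.
#' @param iteration permutation index (1-based).
#' @return named character vector of permuted labels over samples.
#' @export
permute_labels <- function(g, seed, iteration) {
  lab <- with_seed(derive_seed(seed, 7L, iteration),
                   sample(unname(g$labels)))
  stats::setNames(lab, names(g$labels))
}

#' Permutation score (P1000) for mined signatures
#'
#' Re-runs the mining procedure on `n_perm` label-shuffled copies of the
#' cohort with the same mining parameters, and counts, per observed
#' signature, the permutations containing a combination with odds ratio
#' and case-carrier count both at least as large as observed.
#'
#' @param signatures a `signature_set` from [mine_signatures()] (its
#'   mining parameters travel with it), or a list of `signature` objects
#'   with `mining` supplied.
#' @param g the [genotype_matrix()] the signatures were mined from.
#' @param v a [validation_params()].
#' @param mining a [mining_params()]; defaults to the parameters attached
#'   to `signatures`.
#' @return an object of class `permutation_report`: data.frame with one
#'   row per signature (`signature`, `observed_or`, `observed_case_carriers`,
#'   `p1000`, `n_perm`, `empirical_p`, `p1000_significant`) and a
#'   per-permutation audit log in `attr(, "perm_log")`.
#' @export
compute_p1000 <- function(signatures, g, v = validation_params(),
                          mining = attr(signatures, "params")) {
  abort_if(is.null(mining), "compute_p1000: mining parameters not supplied")
  abort_if(v$n_perm < 1, "compute_p1000: n_perm must be >= 1")
  obs_or <- vapply(signatures, `[[`, numeric(1), "odds_ratio")
  obs_cc <- vapply(signatures, function(s) length(s$case_ids), integer(1))
  keys <- vapply(signatures, `[[`, character(1), "key")

  hits <- integer(length(signatures))
  perm_log <- data.frame(iteration = seq_len(v$n_perm), n_combos = 0L,
                         max_or = NA_real_, max_case_carriers = NA_integer_)
  ctx <- mining_context(g)
  if (2 %in% mining$start_orders && mining$search_mode != "exhaustive") {
    ctx <- ctx_total_cross(ctx)
  }
  for (it in seq_len(v$n_perm)) {
    lab <- permute_labels(g, v$seed, it)
    perm <- mine_with_context(ctx, lab, mining,
                              seed = derive_seed(v$seed, 11L, it),
                              stats_only = TRUE)
    perm_log$n_combos[it] <- nrow(perm)
    if (nrow(perm) > 0) {
      p_or <- perm$odds_ratio
      p_cc <- perm$case_carriers
      perm_log$max_or[it] <- max(p_or)
      perm_log$max_case_carriers[it] <- max(p_cc)
      if (length(signatures) > 0) {
        hit <- vapply(seq_along(signatures), function(i) {
          any(p_or >= obs_or[i] & p_cc >= obs_cc[i])
        }, logical(1))
        hits <- hits + hit
      }
    }
  }
  out <- data.frame(
    signature = keys,
    observed_or = obs_or,
    observed_case_carriers = obs_cc,
    p1000 = hits,
    n_perm = v$n_perm,
    empirical_p = (hits + 1) / (v$n_perm + 1),
    p1000_significant = hits / v$n_perm < v$p1000_significance_fraction,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("permutation_report", "data.frame"),
            perm_log = perm_log, params = v)
}

#' Filter mined signatures by the permutation null
#'
#' Applies Benjamini-Hochberg FDR to the empirical permutation p-values of
#' all mined signatures; survivors must additionally satisfy the
#' case-prevalence floor of the mining run. Signatures whose permutation
#' hit fraction falls below `p1000_significance_fraction` are flagged
#' (`p1000_significant`), but the flag does not filter.
#'
#' @param signatures the mined `signature_set`.
#' @param report the matching [compute_p1000()] report.
#' @param v a [validation_params()].
#' @return a `signature_set` containing the validated subset; the
#'   decision table is attached as `attr(, "validation")`.
#' @export
validate_signatures <- function(signatures, report, v = validation_params()) {
  keys <- vapply(signatures, `[[`, character(1), "key")
  abort_if(!setequal(keys, report$signature) || length(keys) != nrow(report),
           "validate_signatures: report does not cover the signature set")
  if (length(signatures) == 0) {
    out <- signature_set(list(), attr(signatures, "params"), NULL)
    attr(out, "n_cases") <- attr(signatures, "n_cases")
    attr(out, "n_controls") <- attr(signatures, "n_controls")
    attr(out, "validation") <- cbind(report, q = numeric(0), validated = logical(0))
    return(out)
  }
  rep_ord <- report[match(keys, report$signature), ]
  bh <- bh_adjust(rep_ord$empirical_p, v$fdr_alpha)
  min_prev <- attr(signatures, "params")$min_case_prevalence %||% 0.05
  prev <- vapply(signatures, `[[`, numeric(1), "case_prevalence")
  validated <- bh$reject & prev >= min_prev
  decision <- cbind(rep_ord, q = bh$q, case_prevalence = prev,
                    validated = validated)
  out <- structure(unclass(signatures)[validated], class = "signature_set",
                   params = attr(signatures, "params"),
                   n_cases = attr(signatures, "n_cases"),
                   n_controls = attr(signatures, "n_controls"),
                   validation = decision)
  out
}

#' Write a permutation report to TSV or JSON
#'
#' @param report a `permutation_report`.
#' @param path output file; `.json` extension selects JSON (report plus
#'   per-permutation audit log), anything else TSV.
#' @return `path`, invisibly.
#' @export
write_permutation_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(report = as.data.frame(report),
           perm_log = attr(report, "perm_log")),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    data.table::fwrite(as.data.frame(report), path, sep = "\t")
  }
  invisible(path)
}
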