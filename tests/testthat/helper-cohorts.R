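# Shared fixtures, all generated in code.

# Hand-built tiny genotype matrix: explicit values for exact assertions.
tiny_gm <- function() {
  gm <- rbind(
    S1 = c(1L, 2L, 0L, 1L),
    S2 = c(1L, 2L, 0L, 0L),
    S3 = c(1L, 2L, 1L, 2L),
    S4 = c(0L, 1L, 2L, 1L),
    S5 = c(NA, 2L, 0L, 1L),
    S6 = c(1L, 0L, 0L, 0L)
  )
  colnames(gm) <- c("s1", "s2", "s3", "s4")
  genotype_matrix(gm, c("case", "case", "case", "control", "control", "control"))
}

# Cohort with one planted liability-model signature.
planted_cohort <- function(seed, n_cases = 500, n_snps = 50, or = 3.7,
                           prev = 0.15, states = c(1, 1, 0), ...) {
  sig <- planted_signature(c("rs00001", "rs00002", "rs00003"), states,
                           target_or = or, target_case_prevalence = prev)
  generate_cohort(cohort_spec(n_cases = n_cases, n_snps = n_snps,
                              planted = list(sig), seed = seed, ...))
}

# Cohort with no planted signal.
null_cohort <- function(seed, n_cases = 200, n_snps = 30, ...) {
  generate_cohort(cohort_spec(n_cases = n_cases, n_snps = n_snps,
                              planted = list(), seed = seed, ...))
}

planted_states_chr <- c("rs00001:1", "rs00002:1", "rs00003:0")

sig_state_labels <- function(s) {
  sprintf("%s:%d", s$states$snp_id, s$states$genotype)
}

# does any signature in `set` contain all of `labels`?
set_contains_states <- function(set, labels) {
  any(vapply(set, function(s) all(labels %in% sig_state_labels(s)),
             logical(1)))
}
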