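# Synthetic case-control cohorts with planted high-order genotype-state
# signatures, covariates, biomarkers, a synthetic gene model and a
# machine-readable truth set.
#
# Background SNPs are drawn independently per sample from Hardy-Weinberg
# proportions at SNP-specific minor-allele frequencies. Disease risk follows
# a liability (logistic) model:
#
#   log-odds(case) = baseline + sum_s beta_s * I(sample carries signature s)
#
# where "carries" means an exact genotype-state match at every member SNP.
# Each beta_s is solved numerically so that the expected case-control odds
# ratio of signature s equals its target, and member-SNP allele frequencies
# are solved so that the expected carrier fraction among sampled cases
# equals the target case prevalence. Sampling to fixed case/control counts
# is performed by drawing genotypes conditional on status, which is the
# case-control-sampled equivalent of the liability model above.

#' Specify a planted combinatorial signature
#'
#' @param snp_ids 3-5 distinct SNP identifiers.
#' @param genotype_states one ordinal genotype (0, 1 or 2) per SNP; a
#'   sample is a carrier iff it matches every state exactly.
#' @param target_or target case-control odds ratio of carrier status
#'   (must exceed 1; cohort-level defaults centre on 3.7).
#' @param target_case_prevalence target fraction of cases carrying the
#'   signature, in (0.05, 0.5).
#' @param covariate_effects named list: binary covariate name -> log-odds
#'   added for carriers.
#' @param biomarker_shifts named list: continuous covariate name -> additive
#'   mean shift in carriers, in standard-deviation units.
#' @param marginal_free if `TRUE`, the signature is planted with no
#'   single-SNP marginal effect: the member-SNP genotype distribution in
#'   cases has an elevated mass on the exact target state, redistributed
#'   (by iterative proportional fitting) so every member SNP's marginal
#'   genotype distribution matches the control distribution. Such
#'   signatures are invisible to single-SNP association tests by
#'   construction but remain detectable combinatorially.
#' @param name optional label; defaults to `sig1`, `sig2`, ... in the
#'   cohort spec.
#' @return an object of class `planted_signature`.
#' @export
planted_signature <- function(snp_ids, genotype_states, target_or = 3.7,
                              target_case_prevalence = 0.15,
                              covariate_effects = list(),
                              biomarker_shifts = list(),
                              marginal_free = FALSE, name = NULL) {
  abort_if(length(snp_ids) < 3 || length(snp_ids) > 5,
           "planted_signature: 3-5 SNPs required")
  abort_if(anyDuplicated(snp_ids) > 0, "planted_signature: SNP ids must be distinct")
  abort_if(length(genotype_states) != length(snp_ids),
           "planted_signature: one genotype state per SNP required")
  abort_if(!all(genotype_states %in% 0:2),
           "planted_signature: genotype states must be 0, 1 or 2")
  abort_if(!(target_or > 1), "planted_signature: target_or must exceed 1")
  abort_if(target_case_prevalence <= 0.05 || target_case_prevalence >= 0.5,
           "planted_signature: target_case_prevalence must lie in (0.05, 0.5)")
  structure(
    list(snp_ids = as.character(snp_ids),
         genotype_states = as.integer(genotype_states),
         target_or = target_or,
         target_case_prevalence = target_case_prevalence,
         covariate_effects = covariate_effects,
         biomarker_shifts = biomarker_shifts,
         marginal_free = isTRUE(marginal_free),
         name = name),
    class = "planted_signature"
  )
}

#' Default covariate and biomarker schema
#'
#' Binary exposure flags, categorical matching keys, anthropometrics and
#' standardized biomarkers typical of a biobank-derived cohort. Population
#' parameters are the pre-enrichment baselines; planted signatures shift
#' them in their carriers.
#'
#' @return a list of covariate definitions.
#' @export
default_covariate_schema <- function() {
  list(
    list(name = "sex", type = "categorical",
         levels = c("F", "M"), probs = c(0.55, 0.45)),
    list(name = "ancestry", type = "categorical",
         levels = c("EUR", "other"), probs = c(0.92, 0.08)),
    list(name = "age", type = "continuous", mean = 57, sd = 8),
    list(name = "bmi", type = "continuous", mean = 27, sd = 4.5),
    list(name = "stress_event", type = "binary", p = 0.15),
    list(name = "autoimmune_dx", type = "binary", p = 0.08),
    list(name = "lactate", type = "continuous", mean = 0, sd = 1),
    list(name = "phenylalanine", type = "continuous", mean = 0, sd = 1)
  )
}

#' Specify a synthetic case-control cohort
#'
#' Defaults emulate a biobank-scale study: cases matched 2:1 by controls,
#' biallelic SNPs with minor-allele frequencies uniform on
#' `maf_range`, and planted signatures whose odds ratios centre on 3.7.
#'
#' @param n_cases number of cases (study default 2382).
#' @param control_ratio controls per case (default 2).
#' @param n_controls number of controls; defaults to
#'   `control_ratio * n_cases` and must equal it.
#' @param n_snps number of SNPs on the panel.
#' @param maf_range minor-allele-frequency range for background SNPs.
#' @param planted list of [planted_signature()] objects. Signatures may
#'   share SNPs only when `allow_overlap = TRUE` and their shared states
#'   agree.
#' @param baseline_case_logodds baseline log-odds of disease for
#'   non-carriers in the liability model.
#' @param covariate_schema list of covariate definitions; see
#'   [default_covariate_schema()].
#' @param missing_rate fraction of genotype calls set to missing.
#' @param ld_rho optional adjacent-SNP correlation (Gaussian-copula block
#'   LD) for background SNPs; 0 (the default) gives independent SNPs,
#'   matching a panel with no linkage disequilibrium.
#' @param allow_overlap permit planted signatures to share SNPs.
#' @param overlap_damping multiplicative penalty on jointly carrying a
#'   pair of planted signatures (applied per carried pair in the joint
#'   carrier prior). The default 0.5 induces the mild negative dependence
#'   that keeps planted patient subgroups sharing well under 20% of their
#'   case carriers; 1 gives independent carriage.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   cohorts.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 2382, control_ratio = 2,
                        n_controls = control_ratio * n_cases,
                        n_snps = 1000, maf_range = c(0.05, 0.5),
                        planted = list(), baseline_case_logodds = -3,
                        covariate_schema = default_covariate_schema(),
                        missing_rate = 0, ld_rho = 0,
                        allow_overlap = FALSE, overlap_damping = 0.5,
                        seed = 1L) {
  abort_if(n_cases < 1 || n_snps < 1, "cohort_spec: empty cohort")
  abort_if(n_controls != control_ratio * n_cases,
           "cohort_spec: n_controls must equal control_ratio * n_cases")
  abort_if(length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
             maf_range[1] > maf_range[2],
           "cohort_spec: maf_range must satisfy 0 < lo <= hi <= 0.5")
  abort_if(missing_rate < 0 || missing_rate >= 1, "cohort_spec: bad missing_rate")
  if (length(planted) > 0 && inherits(planted, "planted_signature")) {
    planted <- list(planted)
  }
  for (i in seq_along(planted)) {
    abort_if(!inherits(planted[[i]], "planted_signature"),
             "cohort_spec: planted must be a list of planted_signature objects")
    if (is.null(planted[[i]]$name)) planted[[i]]$name <- sprintf("sig%d", i)
  }
  nm <- vapply(planted, `[[`, character(1), "name")
  abort_if(anyDuplicated(nm) > 0, "cohort_spec: duplicate signature names")
  if (!allow_overlap && length(planted) > 1) {
    all_snps <- unlist(lapply(planted, `[[`, "snp_ids"))
    abort_if(anyDuplicated(all_snps) > 0,
             "cohort_spec: planted signatures share SNPs; set allow_overlap = TRUE")
  }
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         control_ratio = control_ratio, n_snps = as.integer(n_snps),
         maf_range = maf_range, planted = planted,
         baseline_case_logodds = baseline_case_logodds,
         covariate_schema = covariate_schema,
         missing_rate = missing_rate, ld_rho = ld_rho,
         allow_overlap = allow_overlap, overlap_damping = overlap_damping,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# ---- internal solvers ------------------------------------------------------

# Expected carrier fraction among sampled cases / controls under the
# liability model, for population carrier frequency q and effect beta.
carrier_freqs_cc <- function(beta, q, b0) {
  pd1 <- stats::plogis(b0 + beta)
  pd0 <- stats::plogis(b0)
  p1 <- q * pd1 / (q * pd1 + (1 - q) * pd0)
  p0 <- q * (1 - pd1) / (q * (1 - pd1) + (1 - q) * (1 - pd0))
  list(p_case = p1, p_control = p0,
       or = (p1 / (1 - p1)) / (p0 / (1 - p0)))
}

# Solve the liability effect beta for a target case-control odds ratio by
# 1-D root finding against the closed-form carrier-frequency expressions
# (tolerance 1e-6 on the OR scale).
solve_beta <- function(target_or, q, b0) {
  f <- function(beta) carrier_freqs_cc(beta, q, b0)$or - target_or
  upper <- log(target_or) + 5
  stats::uniroot(f, lower = 0, upper = upper, tol = 1e-9)$root
}

# Feasible range of a single genotype-state probability given the MAF range.
state_prob_range <- function(state, maf_range) {
  f <- switch(as.character(state),
              "0" = function(m) (1 - m)^2,
              "1" = function(m) 2 * m * (1 - m),
              "2" = function(m) m^2)
  sort(f(maf_range))
}

# MAF giving a required genotype-state probability under HWE.
maf_for_state_prob <- function(state, prob) {
  switch(as.character(state),
         "0" = 1 - sqrt(prob),
         "1" = (1 - sqrt(1 - 2 * prob)) / 2,   # branch with m <= 0.5
         "2" = sqrt(prob))
}

# Allocate per-SNP state probabilities multiplying to q, each within its
# feasible range (water-filling on a common level, clamped per SNP).
allocate_state_probs <- function(states, q, maf_range, sig_name) {
  ranges <- lapply(states, state_prob_range, maf_range = maf_range)
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  abort_if(q > prod(hi) || q < prod(lo),
           paste0("planted signature '%s' infeasible: required population ",
                  "carrier frequency %.4g outside reachable range [%.3g, %.3g] ",
                  "for its genotype states and MAF range"),
           sig_name, q, prod(lo), prod(hi))
  g <- function(t) prod(pmin(hi, pmax(lo, t))) - q
  t <- stats::uniroot(g, lower = 0, upper = 1, tol = 1e-12)$root
  pmin(hi, pmax(lo, t))
}

# Plan one liability-model signature: solve member MAFs, beta, and the
# conditional carrier probabilities.
plan_signature <- function(sig, b0, maf_range) {
  p1 <- sig$target_case_prevalence
  # q giving the target prevalence once beta matches the target OR
  beta0 <- log(sig$target_or)
  pd1 <- stats::plogis(b0 + beta0)
  pd0 <- stats::plogis(b0)
  q_odds <- (p1 / (1 - p1)) * pd0 / pd1
  q <- q_odds / (1 + q_odds)
  pi_s <- allocate_state_probs(sig$genotype_states, q, maf_range, sig$name)
  beta <- solve_beta(sig$target_or, q, b0)
  fr <- carrier_freqs_cc(beta, q, b0)
  abort_if(abs(fr$or - sig$target_or) > 1e-6,
           "planted signature '%s' infeasible: OR solver residual too large",
           sig$name)
  mafs <- mapply(maf_for_state_prob, sig$genotype_states, pi_s)
  list(sig = sig, q = q, beta = beta,
       p_case = fr$p_case, p_control = fr$p_control,
       member_maf = stats::setNames(mafs, sig$snp_ids),
       state_prob = stats::setNames(pi_s, sig$snp_ids))
}

# Plan a marginal-effect-free signature: member genotype joint distribution
# in cases carries an elevated mass on the exact target state; the
# complement cells are refitted by IPF so each member SNP's marginal
# genotype distribution equals the control (HWE) distribution.
plan_marginal_free <- function(sig, maf_range) {
  p1 <- sig$target_case_prevalence
  q_odds <- (p1 / (1 - p1)) / sig$target_or
  q <- q_odds / (1 + q_odds)
  pi_s <- allocate_state_probs(sig$genotype_states, q, maf_range, sig$name)
  mafs <- mapply(maf_for_state_prob, sig$genotype_states, pi_s)
  k <- length(sig$snp_ids)
  # per-SNP HWE genotype distributions
  marg <- lapply(mafs, function(m) c((1 - m)^2, 2 * m * (1 - m), m^2))
  dims <- rep(3, k)
  m0 <- array(1, dim = dims)
  for (i in seq_len(k)) {
    shape <- rep(1, k); shape[i] <- 3
    m0 <- m0 * array(rep(marg[[i]], each = prod(dims[seq_len(i - 1)])), dim = dims)
  }
  target_idx <- matrix(sig$genotype_states + 1L, nrow = 1)
  abort_if(m0[target_idx] < 1e-12, "internal: degenerate target cell")
  # residual marginals after pinning the target cell at p1
  resid <- lapply(seq_len(k), function(i) {
    r <- marg[[i]]
    r[sig$genotype_states[i] + 1L] <- r[sig$genotype_states[i] + 1L] - p1
    abort_if(any(r < 0),
             "planted signature '%s' infeasible: marginal-free prevalence too high",
             sig$name)
    r
  })
  comp <- m0
  comp[target_idx] <- 0
  # IPF on the complement cells
  for (iter in 1:200) {
    maxdev <- 0
    for (i in seq_len(k)) {
      cur <- apply(comp, i, sum)
      scl <- ifelse(cur > 0, resid[[i]] / cur, 0)
      comp <- sweep(comp, i, scl, `*`)
      maxdev <- max(maxdev, max(abs(cur - resid[[i]])))
    }
    if (maxdev < 1e-12) break
  }
  p_case_tab <- comp
  p_case_tab[target_idx] <- p1
  list(sig = sig, q = q, p_case = p1, p_control = q,
       member_maf = stats::setNames(mafs, sig$snp_ids),
       case_table = p_case_tab, control_table = m0,
       beta = log(sig$target_or))
}

# Decode linear indices of a 3^k table into genotype rows.
decode_states <- function(idx, k) {
  out <- matrix(0L, length(idx), k)
  r <- idx - 1L
  for (i in seq_len(k)) {
    out[, i] <- as.integer(r %% 3L)
    r <- r %/% 3L
  }
  out
}

# ---- generator -------------------------------------------------------------

#' Generate a synthetic case-control cohort
#'
#' Produces a [genotype_matrix()], a covariate table, a synthetic gene
#' model and a truth set that records, for every planted signature, its
#' realized carrier sets and odds ratio (recomputed by scanning the emitted
#' matrix, so truth and data can never disagree).
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `genotypes`, `covariates`, `gene_model`,
#'   `truth`.
#' @export
generate_cohort <- function(spec) {
  abort_if(!inherits(spec, "cohort_spec"), "generate_cohort: need a cohort_spec")
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n_case <- spec$n_cases
  n_ctrl <- spec$n_controls
  n <- n_case + n_ctrl
  samples <- sprintf("S%05d", seq_len(n))
  labels <- c(rep("case", n_case), rep("control", n_ctrl))

  planted_snps <- unique(unlist(lapply(spec$planted, `[[`, "snp_ids")))
  abort_if(length(planted_snps) > spec$n_snps,
           "cohort_spec: more planted SNPs than panel SNPs")
  snps <- sprintf("rs%05d", seq_len(spec$n_snps))
  missing_planted <- setdiff(planted_snps, snps)
  abort_if(length(missing_planted) > 0,
           "planted SNP ids not on the panel (%s); use ids rs00001..rs%05d",
           paste(utils::head(missing_planted, 3), collapse = ", "), spec$n_snps)

  # plan planted signatures
  plans <- lapply(spec$planted, function(s) {
    if (s$marginal_free) plan_marginal_free(s, spec$maf_range)
    else plan_signature(s, spec$baseline_case_logodds, spec$maf_range)
  })
  names(plans) <- vapply(spec$planted, `[[`, character(1), "name")

  # with several liability signatures, joint carriage (and its damping)
  # perturbs the single-signature closed forms; recalibrate against the
  # exact joint distribution and re-derive member MAFs
  liab_idx <- which(!vapply(plans, function(p) p$sig$marginal_free,
                            logical(1)))
  if (length(liab_idx) > 1) {
    plans[liab_idx] <- calibrate_joint_plans(
      plans[liab_idx], compat_mask(plans[liab_idx]),
      spec$baseline_case_logodds, spec$overlap_damping %||% 1)
    for (i in liab_idx) {
      pl <- plans[[i]]
      pi_s <- allocate_state_probs(pl$sig$genotype_states, pl$q,
                                   spec$maf_range, pl$sig$name)
      mafs <- mapply(maf_for_state_prob, pl$sig$genotype_states, pi_s)
      plans[[i]]$member_maf <- stats::setNames(mafs, pl$sig$snp_ids)
      plans[[i]]$state_prob <- stats::setNames(pi_s, pl$sig$snp_ids)
    }
  }

  # background MAFs; member SNPs get their solved MAFs
  maf <- stats::runif(spec$n_snps, spec$maf_range[1], spec$maf_range[2])
  names(maf) <- snps
  for (pl in plans) maf[names(pl$member_maf)] <- pl$member_maf

  # background genotypes (HWE; optional AR(1) Gaussian-copula block LD)
  G <- draw_background(n, maf, spec$ld_rho, planted_snps)
  dimnames(G) <- list(samples, snps)

  # carrier assignment and member-SNP genotypes
  liab <- plans[!vapply(plans, function(p) p$sig$marginal_free, logical(1))]
  mfree <- plans[vapply(plans, function(p) p$sig$marginal_free, logical(1))]

  carrier <- matrix(FALSE, n, length(plans),
                    dimnames = list(samples, names(plans)))
  if (length(liab) > 0) {
    carrier[, names(liab)] <- assign_carriers(liab, labels,
                                              spec$baseline_case_logodds,
                                              spec$overlap_damping %||% 1)
    G <- fill_member_genotypes(G, liab, carrier[, names(liab), drop = FALSE], maf)
  }
  for (nm in names(mfree)) {
    pl <- mfree[[nm]]
    k <- length(pl$sig$snp_ids)
    idx_case <- which(labels == "case")
    idx_ctrl <- which(labels == "control")
    draw_case <- sample.int(3^k, length(idx_case), replace = TRUE,
                            prob = as.vector(pl$case_table))
    draw_ctrl <- sample.int(3^k, length(idx_ctrl), replace = TRUE,
                            prob = as.vector(pl$control_table))
    G[idx_case, pl$sig$snp_ids] <- decode_states(draw_case, k)
    G[idx_ctrl, pl$sig$snp_ids] <- decode_states(draw_ctrl, k)
    target <- matrix(pl$sig$genotype_states, n, k, byrow = TRUE)
    carrier[, nm] <- rowSums(G[, pl$sig$snp_ids, drop = FALSE] == target) == k
  }

  # missingness injection
  if (spec$missing_rate > 0) {
    nmiss <- round(spec$missing_rate * length(G))
    G[sample.int(length(G), nmiss)] <- NA_integer_
  }

  # SNP metadata: positions spread over 22 autosomes
  chrom <- as.character(rep_len(1:22, spec$n_snps))
  pos <- integer(spec$n_snps)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos[i] <- as.integer(1e5 + seq_along(i) * 50000L +
                           sample.int(20000L, length(i), replace = TRUE))
  }
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, spec$n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
  snp_meta <- data.frame(snp_id = snps, chrom = chrom, pos = pos,
                         ref = unname(ref), alt = unname(alt), maf = unname(maf),
                         stringsAsFactors = FALSE)

  g <- genotype_matrix(G, labels, snp_meta)

  covariates <- draw_covariates(spec, samples, labels, plans, carrier)
  gene_model <- synth_gene_model(snp_meta, planted_snps)
  truth <- build_truth(g, plans, spec)

  list(genotypes = g, covariates = covariates,
       gene_model = gene_model, truth = truth)
}

draw_background <- function(n, maf, ld_rho, planted_snps) {
  m <- length(maf)
  if (ld_rho == 0) {
    G <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m)
  } else {
    # AR(1) latent Gaussian per sample; thresholds at HWE quantiles
    Z <- matrix(stats::rnorm(n * m), n, m)
    for (j in 2:m) Z[, j] <- ld_rho * Z[, j - 1] + sqrt(1 - ld_rho^2) * Z[, j]
    G <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      q0 <- stats::qnorm((1 - maf[j])^2)
      q1 <- stats::qnorm(1 - maf[j]^2)
      G[, j] <- (Z[, j] > q0) + (Z[, j] > q1)
    }
    # planted member SNPs stay independent of the LD blocks
    for (s in intersect(planted_snps, names(maf))) {
      j <- match(s, names(maf))
      G[, j] <- stats::rbinom(n, 2L, maf[j])
    }
  }
  storage.mode(G) <- "integer"
  G
}

# Exact joint carrier-state distribution for liability-model signatures
# under the damped joint prior: returns the 2^S state table with case and
# control weights.
joint_carrier_weights <- function(qs, betas, compat_ok, b0, overlap_damping) {
  S <- length(qs)
  states <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), S)))
  n_pairs <- choose(rowSums(states), 2)
  base_w <- apply(states, 1, function(cvec) prod(ifelse(cvec, qs, 1 - qs))) *
    overlap_damping^n_pairs * compat_ok
  risk <- stats::plogis(b0 + as.vector(states %*% betas))
  list(states = states,
       w_case = base_w * risk,
       w_ctrl = base_w * (1 - risk))
}

# With several planted signatures and joint-carriage damping, the
# single-signature closed forms no longer hold exactly; fixed-point
# recalibration of (q_s, beta_s) against the exact joint distribution
# restores the target case prevalences and odds ratios in expectation.
calibrate_joint_plans <- function(plans, compat_ok, b0, overlap_damping) {
  qs <- vapply(plans, `[[`, numeric(1), "q")
  betas <- vapply(plans, `[[`, numeric(1), "beta")
  targets_or <- vapply(plans, function(p) p$sig$target_or, numeric(1))
  targets_p1 <- vapply(plans, function(p) p$sig$target_case_prevalence,
                       numeric(1))
  for (iter in 1:50) {
    jw <- joint_carrier_weights(qs, betas, compat_ok, b0, overlap_damping)
    p1 <- as.vector(crossprod(jw$states, jw$w_case)) / sum(jw$w_case)
    p0 <- as.vector(crossprod(jw$states, jw$w_ctrl)) / sum(jw$w_ctrl)
    or <- (p1 / (1 - p1)) / (p0 / (1 - p0))
    if (max(abs(or - targets_or) / targets_or,
            abs(p1 - targets_p1) / targets_p1) < 1e-6) break
    betas <- betas + log(targets_or) - log(or)
    qs <- pmin(0.9, pmax(1e-6, qs * targets_p1 / p1))
  }
  for (i in seq_along(plans)) {
    plans[[i]]$q <- qs[i]
    plans[[i]]$beta <- betas[i]
    plans[[i]]$p_case <- p1[i]
    plans[[i]]$p_control <- p0[i]
  }
  plans
}

# pairwise compatibility mask over the 2^S joint states (signatures
# sharing a SNP with conflicting required states cannot co-occur)
compat_mask <- function(plans) {
  S <- length(plans)
  states <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), S)))
  ok <- rep(TRUE, nrow(states))
  if (S > 1) {
    for (i in seq_len(S - 1)) for (j in (i + 1):S) {
      si <- plans[[i]]$sig; sj <- plans[[j]]$sig
      shared <- intersect(si$snp_ids, sj$snp_ids)
      if (length(shared) > 0) {
        agree <- all(si$genotype_states[match(shared, si$snp_ids)] ==
                       sj$genotype_states[match(shared, sj$snp_ids)])
        if (!agree) ok <- ok & !(states[, i] & states[, j])
      }
    }
  }
  ok
}

# Joint carrier assignment for liability-model signatures, conditional on
# case/control status; enumerates the 2^S joint carrier states.
assign_carriers <- function(plans, labels, b0, overlap_damping = 1) {
  S <- length(plans)
  n <- length(labels)
  qs <- vapply(plans, `[[`, numeric(1), "q")
  betas <- vapply(plans, `[[`, numeric(1), "beta")
  jw <- joint_carrier_weights(qs, betas, compat_mask(plans), b0,
                              overlap_damping)
  states <- jw$states
  colnames(states) <- names(plans)
  out <- matrix(FALSE, n, S, dimnames = list(NULL, names(plans)))
  idx_case <- which(labels == "case")
  idx_ctrl <- which(labels == "control")
  pick_case <- sample.int(nrow(states), length(idx_case), replace = TRUE,
                          prob = jw$w_case)
  pick_ctrl <- sample.int(nrow(states), length(idx_ctrl), replace = TRUE,
                          prob = jw$w_ctrl)
  out[idx_case, ] <- states[pick_case, , drop = FALSE]
  out[idx_ctrl, ] <- states[pick_ctrl, , drop = FALSE]
  out
}

# Overwrite member-SNP genotypes so that carrier flags are realized exactly:
# carriers receive the required states; non-carriers are redrawn from HWE
# until they do not fully match (rejection on the violating rows only).
# SNPs pinned by an overlapping *carried* signature are never redrawn.
fill_member_genotypes <- function(G, plans, carrier, maf) {
  pinned <- matrix(FALSE, nrow(G), ncol(G), dimnames = dimnames(G))
  for (nm in names(plans)) {
    pl <- plans[[nm]]
    snps <- pl$sig$snp_ids
    k <- length(snps)
    target <- pl$sig$genotype_states
    is_carrier <- carrier[, nm]
    G[is_carrier, snps] <- matrix(target, sum(is_carrier), k, byrow = TRUE)
    pinned[is_carrier, snps] <- TRUE
  }
  for (nm in names(plans)) {
    pl <- plans[[nm]]
    snps <- pl$sig$snp_ids
    k <- length(snps)
    target <- pl$sig$genotype_states
    nc <- which(!carrier[, nm])
    for (iter in 1:1000) {
      sub <- G[nc, snps, drop = FALSE]
      bad <- nc[rowSums(sub == matrix(target, length(nc), k, byrow = TRUE)) == k]
      # rows whose member SNPs are all pinned elsewhere cannot be redrawn
      bad <- bad[rowSums(!pinned[bad, snps, drop = FALSE]) > 0]
      if (length(bad) == 0) break
      for (j in seq_len(k)) {
        rd <- bad[!pinned[bad, snps[j]]]
        if (length(rd) > 0) {
          G[rd, snps[j]] <- stats::rbinom(length(rd), 2L, maf[snps[j]])
        }
      }
    }
  }
  G
}

draw_covariates <- function(spec, samples, labels, plans, carrier) {
  n <- length(samples)
  cov <- data.frame(sample_id = samples, status = labels,
                    stringsAsFactors = FALSE)
  for (cs in spec$covariate_schema) {
    if (cs$type == "binary") {
      eta <- rep(stats::qlogis(cs$p), n)
      for (nm in names(plans)) {
        eff <- plans[[nm]]$sig$covariate_effects[[cs$name]]
        if (!is.null(eff)) eta <- eta + eff * carrier[, nm]
      }
      cov[[cs$name]] <- stats::rbinom(n, 1L, stats::plogis(eta))
    } else if (cs$type == "continuous") {
      mu <- rep(cs$mean, n)
      for (nm in names(plans)) {
        sh <- plans[[nm]]$sig$biomarker_shifts[[cs$name]]
        if (!is.null(sh)) mu <- mu + sh * cs$sd * carrier[, nm]
      }
      cov[[cs$name]] <- stats::rnorm(n, mu, cs$sd)
    } else if (cs$type == "categorical") {
      cov[[cs$name]] <- sample(cs$levels, n, replace = TRUE, prob = cs$probs)
    } else {
      abort_if(TRUE, "unknown covariate type '%s'", cs$type)
    }
  }
  cov
}

# Synthetic gene model: every planted SNP gets a named gene placing it in a
# coding region, within the 2 kb upstream window, or within the 0.5 kb
# downstream window (cycling through the three classes); a handful of
# background genes is added so unassigned SNPs exist.
synth_gene_model <- function(snp_meta, planted_snps) {
  classes <- c("coding", "upstream", "downstream")
  genes <- list()
  gi <- 0
  for (i in seq_along(planted_snps)) {
    sm <- snp_meta[snp_meta$snp_id == planted_snps[i], ]
    cls <- classes[(i - 1) %% 3 + 1]
    strand <- if (i %% 2 == 0) "-" else "+"
    gi <- gi + 1
    len <- 4000L
    if (cls == "coding") {
      start <- sm$pos - 1500L
      end <- start + len
      cds_start <- sm$pos - 200L
      cds_end <- sm$pos + 300L
    } else if (cls == "upstream") {
      d <- 1200L  # within the 2 kb upstream window
      if (strand == "+") { start <- sm$pos + d; end <- start + len }
      else { end <- sm$pos - d; start <- end - len }
      cds_start <- start + 500L; cds_end <- end - 500L
    } else {
      d <- 300L   # within the 0.5 kb downstream window
      if (strand == "+") { end <- sm$pos - d; start <- end - len }
      else { start <- sm$pos + d; end <- start + len }
      cds_start <- start + 500L; cds_end <- end - 500L
    }
    genes[[gi]] <- data.frame(
      gene_id = sprintf("GENE%03d", gi), chrom = sm$chrom, strand = strand,
      start = max(1L, start), end = end,
      cds_start = max(1L, cds_start), cds_end = cds_end,
      planted_snp = sm$snp_id, mapping_class = cls,
      stringsAsFactors = FALSE)
  }
  # background genes far from any SNP
  for (ch in c("1", "2")) {
    gi <- gi + 1
    genes[[gi]] <- data.frame(
      gene_id = sprintf("GENE%03d", gi), chrom = ch, strand = "+",
      start = 10L, end = 5010L, cds_start = 510L, cds_end = 4510L,
      planted_snp = NA_character_, mapping_class = NA_character_,
      stringsAsFactors = FALSE)
  }
  gm <- do.call(rbind, genes)
  class(gm) <- c("gene_model", "data.frame")
  gm
}

# Truth set: everything recomputed from the emitted matrix.
build_truth <- function(g, plans, spec) {
  sigs <- lapply(names(plans), function(nm) {
    pl <- plans[[nm]]
    st <- feature_states(pl$sig$snp_ids, pl$sig$genotype_states)
    is_carrier <- carrier_vector(g, st)
    cc <- names(g$labels)[is_carrier & g$labels == "case"]
    ctl <- names(g$labels)[is_carrier & g$labels == "control"]
    tab <- contingency_2x2(length(cc), sum(g$labels == "case") - length(cc),
                           length(ctl), sum(g$labels == "control") - length(ctl))
    list(name = nm, snp_ids = pl$sig$snp_ids,
         genotype_states = pl$sig$genotype_states,
         target_or = pl$sig$target_or,
         target_case_prevalence = pl$sig$target_case_prevalence,
         marginal_free = pl$sig$marginal_free,
         beta = pl$beta,
         expected_p_case = pl$p_case, expected_p_control = pl$p_control,
         case_carriers = length(cc), control_carriers = length(ctl),
         realized_or = odds_ratio(tab),
         realized_case_prevalence = length(cc) / sum(g$labels == "case"),
         case_ids = cc, control_ids = ctl)
  })
  names(sigs) <- names(plans)
  structure(
    list(signatures = sigs,
         community_members = lapply(sigs, `[[`, "case_ids"),
         n_cases = sum(g$labels == "case"),
         n_controls = sum(g$labels == "control"),
         seed = spec$seed),
    class = "truth_set"
  )
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth_set: %d planted signature(s), %d cases / %d controls\n",
              length(x$signatures), x$n_cases, x$n_controls))
  for (s in x$signatures) {
    cat(sprintf(
      "  %s: %s | target OR %.2f -> realized %.2f | case prevalence %.3f%s\n",
      s$name, paste(sprintf("%s:%d", s$snp_ids, s$genotype_states), collapse = ";"),
      s$target_or, s$realized_or, s$realized_case_prevalence,
      if (s$marginal_free) " | marginal-free" else ""))
  }
  invisible(x)
}
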