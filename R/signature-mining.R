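# Mining of 1-5 SNP genotype-state combinations over-represented in cases.
#
# A feature state is a (SNP, ordinal genotype) pair; a signature is a set of
# feature states over distinct SNPs together with its case/control carrier
# statistics. Carrier = exact genotype match at every member SNP; a missing
# genotype at a member SNP makes the sample a non-carrier (configurable to
# excluding the sample in evaluate_combination()).

#' Build a set of feature states
#'
#' @param snp_ids SNP identifiers (distinct).
#' @param genotypes one ordinal genotype (0/1/2) per SNP.
#' @return data.frame of class `feature_states` with columns `snp_id`,
#'   `genotype`.
#' @export
feature_states <- function(snp_ids, genotypes) {
  abort_if(length(snp_ids) != length(genotypes),
           "feature_states: one genotype per SNP required")
  abort_if(anyDuplicated(snp_ids) > 0, "feature_states: SNPs must be distinct")
  abort_if(!all(genotypes %in% 0:2), "feature_states: genotypes must be 0, 1 or 2")
  structure(
    data.frame(snp_id = as.character(snp_ids),
               genotype = as.integer(genotypes),
               stringsAsFactors = FALSE),
    class = c("feature_states", "data.frame")
  )
}

# canonical key, invariant to state order
state_key <- function(states) {
  paste(sort(sprintf("%s:%d", states$snp_id, states$genotype)), collapse = ";")
}

#' Parse a signature key back into feature states
#'
#' Inverse of the `snp:genotype;...` serialization used in TSV output.
#'
#' @param key character scalar like `"rs00001:1;rs00002:2"`.
#' @return a [feature_states()] object.
#' @export
parse_state_key <- function(key) {
  parts <- strsplit(strsplit(key, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  feature_states(vapply(parts, `[`, character(1), 1),
                 as.integer(vapply(parts, `[`, character(1), 2)))
}

#' Does a sample carry a signature?
#'
#' @param sample_genotypes named genotype vector (0/1/2/NA) for one sample.
#' @param states a [feature_states()] object (or a mined signature).
#' @param missing how to treat a missing genotype at a member SNP:
#'   `"noncarrier"` (default) or `"na"` (returns `NA`, used by the
#'   sample-exclusion policy).
#' @return `TRUE` iff the genotype equals the required state at every
#'   member SNP.
#' @export
matches <- function(sample_genotypes, states, missing = c("noncarrier", "na")) {
  missing <- match.arg(missing)
  if (inherits(states, "signature")) states <- states$states
  unknown <- setdiff(states$snp_id, names(sample_genotypes))
  abort_if(length(unknown) > 0, "matches: unknown SNP(s) in signature: %s",
           paste(unknown, collapse = ", "))
  gvals <- sample_genotypes[states$snp_id]
  if (anyNA(gvals)) {
    return(if (missing == "noncarrier") FALSE else NA)
  }
  all(gvals == states$genotype)
}

#' Carrier indicator over all samples of a genotype matrix
#'
#' Vectorized equivalent of applying [matches()] per sample; missing
#' genotypes at member SNPs yield non-carriers.
#'
#' @param g a [genotype_matrix()].
#' @param states a [feature_states()] object.
#' @return named logical vector over samples.
#' @export
carrier_vector <- function(g, states) {
  if (inherits(states, "signature")) states <- states$states
  unknown <- setdiff(states$snp_id, snp_ids(g))
  abort_if(length(unknown) > 0, "carrier_vector: unknown SNP(s): %s",
           paste(unknown, collapse = ", "))
  sub <- g$genotypes[, states$snp_id, drop = FALSE]
  target <- matrix(states$genotype, nrow(sub), length(states$genotype),
                   byrow = TRUE)
  hit <- sub == target
  hit[is.na(hit)] <- FALSE
  stats::setNames(rowSums(hit) == ncol(sub), rownames(sub))
}

#' Mining parameters
#'
#' @param max_order maximum number of SNPs per combination (default 5).
#' @param min_order smallest combination order reported (default 1).
#'   Setting 3 restricts reporting to high-order combinations, the regime
#'   in which combinatorial signal is expected to live; the floor applies
#'   identically to permutation re-mining runs.
#' @param p_max significance ceiling for reported combinations
#'   (default 0.05, exact two-sided Fisher p).
#' @param min_case_prevalence minimum fraction of cases carrying a reported
#'   combination (default 0.05).
#' @param score greedy search score: `"hypergeometric"` (default; minus
#'   log10 of the one-sided enrichment tail, fully vectorized) or
#'   `"fisher"` (minus log10 of the exact two-sided p; slower), or a
#'   function `(a, b, c, d) -> score` on the 2x2 cells.
#' @param search_mode `"greedy_stochastic"` (seeded multi-start greedy
#'   extension, the default) or `"exhaustive"` (full enumeration up to
#'   `max_order`, guarded by `combination_budget`).
#' @param n_random_starts number of greedy starts (default 100); starts are
#'   drawn from singleton and pair states passing the filters, best-scoring
#'   first, with the remainder sampled under `seed`.
#' @param start_orders combination orders used to seed greedy starts
#'   (default `c(1, 2)`: singletons and pairs).
#' @param direction `"risk"` reports case-enriched combinations (OR > 1,
#'   the default); `"protective"` reports control-enriched ones.
#' @param report `"all_layers"` (default) reports every combination
#'   visited along the greedy paths — singletons, pairs, triplets and so
#'   on, mirroring layer-wise search; `"maximal"` reports only the final
#'   combination of each start.
#' @param combination_budget refuse exhaustive runs whose total number of
#'   combination evaluations exceeds this (default 2e6).
#' @param seed integer seed driving the stochastic start selection.
#' @return an object of class `mining_params`.
#' @export
mining_params <- function(max_order = 5, min_order = 1, p_max = 0.05,
                          min_case_prevalence = 0.05,
                          score = "hypergeometric",
                          search_mode = c("greedy_stochastic", "exhaustive"),
                          n_random_starts = 100, start_orders = c(1, 2),
                          direction = c("risk", "protective"),
                          report = c("all_layers", "maximal"),
                          combination_budget = 2e6, seed = 1L) {
  search_mode <- match.arg(search_mode)
  direction <- match.arg(direction)
  report <- match.arg(report)
  abort_if(max_order < 1 || max_order > 5, "mining_params: max_order must be 1-5")
  abort_if(min_order < 1 || min_order > max_order,
           "mining_params: min_order must lie in [1, max_order]")
  abort_if(min_case_prevalence <= 0 || min_case_prevalence >= 1,
           "mining_params: min_case_prevalence must lie in (0, 1)")
  structure(
    list(max_order = as.integer(max_order), min_order = as.integer(min_order),
         p_max = p_max,
         min_case_prevalence = min_case_prevalence, score = score,
         search_mode = search_mode,
         n_random_starts = as.integer(n_random_starts),
         start_orders = as.integer(start_orders), direction = direction,
         report = report,
         combination_budget = combination_budget, seed = as.integer(seed)),
    class = "mining_params"
  )
}

# ---- mining context: per-matrix precomputation -----------------------------

# Logical sample-by-state indicator matrix plus its total crossproduct;
# reused across the permutation runs (only labels change there).
mining_context <- function(g) {
  G <- g$genotypes
  n <- nrow(G)
  m <- ncol(G)
  X <- matrix(FALSE, n, 3L * m)
  state_snp <- rep(seq_len(m), each = 3)
  state_g <- rep(0:2, times = m)
  for (gs in 0:2) {
    hit <- G == gs
    hit[is.na(hit)] <- FALSE
    X[, seq(gs + 1L, 3L * m, by = 3L)] <- hit
  }
  colnames(X) <- sprintf("%s:%d", colnames(G)[state_snp], state_g)
  Xd <- X
  storage.mode(Xd) <- "double"
  list(g = g, X = X, Xd = Xd, Tcross = NULL, col_tot = colSums(X),
       state_snp = state_snp, state_g = state_g,
       snps = colnames(G), n = n)
}

# total state-pair crossproduct and the (upper-triangle, distinct-SNP)
# pair index set; label-independent, so shared across permutations
ctx_total_cross <- function(ctx) {
  if (is.null(ctx$Tcross)) {
    ctx$Tcross <- crossprod(ctx$Xd)
    ut <- upper.tri(ctx$Tcross) &
      outer(ctx$state_snp, ctx$state_snp, `!=`)
    ctx$pair_lin <- which(ut)
    ij <- which(ut, arr.ind = TRUE)
    ctx$pair_i <- ij[, 1]
    ctx$pair_j <- ij[, 2]
  }
  ctx
}

# greedy/enumeration score: larger is better
score_tables <- function(score, a, b, c, d, direction) {
  if (is.function(score)) return(score(a, b, c, d))
  if (identical(score, "hypergeometric")) {
    n_case <- a + b
    n_ctrl <- c + d
    p <- if (direction == "risk") {
      stats::phyper(a - 1, n_case, n_ctrl, a + c, lower.tail = FALSE)
    } else {
      stats::phyper(a, n_case, n_ctrl, a + c, lower.tail = TRUE)
    }
    return(-log10(pmax(p, 1e-300)))
  }
  if (identical(score, "fisher")) {
    p <- mapply(function(a., b., c., d.) {
      stats::fisher.test(matrix(c(a., b., c., d.), 2, byrow = TRUE))$p.value
    }, a, b, c, d)
    return(-log10(pmax(p, 1e-300)))
  }
  abort_if(TRUE, "unknown score '%s'", as.character(score))
}

# ---- signature objects -----------------------------------------------------

new_signature <- function(states, g, carriers = NULL) {
  if (is.null(carriers)) carriers <- carrier_vector(g, states)
  lab <- g$labels
  cc <- names(lab)[carriers & lab == "case"]
  cl <- names(lab)[carriers & lab == "control"]
  n_case <- sum(lab == "case")
  n_ctrl <- sum(lab == "control")
  tab <- contingency_2x2(length(cc), n_case - length(cc),
                         length(cl), n_ctrl - length(cl))
  p <- if (length(cc) + length(cl) == 0 ||
           length(cc) + length(cl) == n_case + n_ctrl) 1 else fisher_exact_p(tab)
  structure(
    list(states = states[order(states$snp_id), , drop = FALSE],
         key = state_key(states),
         order = nrow(states),
         table = tab,
         odds_ratio = odds_ratio(tab),
         p_value = p,
         case_prevalence = length(cc) / n_case,
         case_ids = cc, control_ids = cl),
    class = "signature"
  )
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature %s | order %d | OR %.3g | p %.3g | case prevalence %.3f (%d cases, %d controls)\n",
              x$key, x$order, x$odds_ratio, x$p_value, x$case_prevalence,
              length(x$case_ids), length(x$control_ids)))
  invisible(x)
}

#' Evaluate one combination of feature states on a cohort
#'
#' Full-scan carrier sets plus the 2x2 statistics (odds ratio with the
#' Haldane-Anscombe correction on zero cells, exact two-sided Fisher p).
#'
#' @param states a [feature_states()] object.
#' @param g a [genotype_matrix()].
#' @param missing `"noncarrier"` (default) counts samples with a missing
#'   member genotype as non-carriers; `"exclude"` drops them from the
#'   table and the prevalence denominator.
#' @return an object of class `signature`.
#' @export
evaluate_combination <- function(states, g, missing = c("noncarrier", "exclude")) {
  missing <- match.arg(missing)
  if (missing == "noncarrier") return(new_signature(states, g))
  sub <- g$genotypes[, states$snp_id, drop = FALSE]
  keep <- rownames(sub)[rowSums(is.na(sub)) == 0]
  new_signature(states, subset_genotypes(g, samples = keep))
}

signature_set <- function(sigs, params, g) {
  structure(sigs, class = "signature_set", params = params,
            n_cases = sum(g$labels == "case"),
            n_controls = sum(g$labels == "control"))
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d signature(s)\n", length(x)))
  if (length(x) > 0) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Tabulate a signature set
#'
#' @param x a `signature_set` from [mine_signatures()].
#' @param ... unused.
#' @return data.frame with one row per signature.
#' @export
as.data.frame.signature_set <- function(x, ...) {
  if (length(x) == 0) {
    return(data.frame(signature = character(0), order = integer(0),
                      case_carriers = integer(0), control_carriers = integer(0),
                      odds_ratio = numeric(0), p_value = numeric(0),
                      case_prevalence = numeric(0)))
  }
  data.frame(
    signature = vapply(x, `[[`, character(1), "key"),
    order = vapply(x, `[[`, integer(1), "order"),
    case_carriers = vapply(x, function(s) length(s$case_ids), integer(1)),
    control_carriers = vapply(x, function(s) length(s$control_ids), integer(1)),
    odds_ratio = vapply(x, `[[`, numeric(1), "odds_ratio"),
    p_value = vapply(x, `[[`, numeric(1), "p_value"),
    case_prevalence = vapply(x, `[[`, numeric(1), "case_prevalence"),
    stringsAsFactors = FALSE
  )
}

# ---- search ----------------------------------------------------------------

#' Mine disease signatures from a case-control genotype matrix
#'
#' Finds combinations of 1 to `max_order` SNP genotype states
#' over-represented in cases. In `exhaustive` mode every combination up to
#' `max_order` is enumerated (subject to the combination budget, with
#' subtree pruning on the case-prevalence floor). In `greedy_stochastic`
#' mode, seeded starts taken from singleton and pair states passing the
#' filters are each extended by the single feature state that most improves
#' the search score, stopping when no extension improves it or the maximum
#' order is reached; results are deduplicated by state set.
#'
#' Reported signatures satisfy `p_value <= p_max` (exact two-sided Fisher),
#' `case_prevalence >= min_case_prevalence` and OR > 1 (risk direction),
#' sorted by (p ascending, OR descending, order ascending, key).
#'
#' @param g a [genotype_matrix()].
#' @param params a [mining_params()].
#' @return a `signature_set` (possibly empty).
#' @export
mine_signatures <- function(g, params = mining_params()) {
  ctx <- mining_context(g)
  mine_with_context(ctx, g$labels, params)
}

# internal: mining on a prebuilt context with given labels (the permutation
# null re-mines through this entry point, so observed and permuted runs are
# structurally identical). `stats_only = TRUE` returns only the per-combo
# odds ratios and case-carrier counts (the quantities the permutation hit
# criterion uses), skipping carrier-id materialization.
mine_with_context <- function(ctx, labels, params, seed = params$seed,
                              stats_only = FALSE) {
  is_case <- unname(labels == "case")
  combos <- if (params$search_mode == "exhaustive") {
    search_exhaustive(ctx, is_case, params)
  } else {
    search_greedy(ctx, is_case, params, seed)
  }
  finalize_combos(ctx, is_case, labels, combos, params, stats_only)
}

# Vectorized exact two-sided Fisher p for many 2x2 tables (same definition
# as fisher_exact_p(): sum of hypergeometric probabilities not exceeding
# the observed table's probability).
fisher_p_many <- function(a, b, c, d) {
  n_case <- a + b
  n_ctrl <- c + d
  vapply(seq_along(a), function(i) {
    K <- a[i] + c[i]
    if (K == 0 || K == n_case[i] + n_ctrl[i]) return(1)
    x <- max(0, K - n_ctrl[i]):min(K, n_case[i])
    pr <- stats::dhyper(x, n_case[i], n_ctrl[i], K)
    obs <- pr[match(a[i], x)]
    min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

# combos: list of integer vectors of state-column indices
finalize_combos <- function(ctx, is_case, labels, combos, params,
                            stats_only = FALSE) {
  n_case <- sum(is_case)
  n_ctrl <- sum(!is_case)
  empty_stats <- data.frame(odds_ratio = numeric(0),
                            case_carriers = integer(0))
  g <- NULL
  if (!stats_only) {
    g <- ctx$g
    if (!identical(unname(labels), unname(g$labels))) {
      g <- set_labels(g, labels)
    }
  }
  if (length(combos) == 0) {
    return(if (stats_only) empty_stats else signature_set(list(), params, g))
  }
  keys <- vapply(combos, function(cols) paste(cols, collapse = ","),
                 character(1))
  combos <- combos[!duplicated(keys)]
  combos <- combos[lengths(combos) >= (params$min_order %||% 1L)]
  if (length(combos) == 0) {
    return(if (stats_only) empty_stats else signature_set(list(), params, g))
  }
  min_cc <- params$min_case_prevalence * n_case
  X <- ctx$X
  k <- length(combos)
  a <- integer(k); cc <- integer(k)
  Z <- matrix(FALSE, ctx$n, k)
  for (i in seq_len(k)) {
    cols <- combos[[i]]
    z <- X[, cols[1]]
    for (col in cols[-1]) z <- z & X[, col]
    Z[, i] <- z
    a[i] <- sum(z & is_case)
    cc[i] <- sum(z)
  }
  b <- n_case - a
  c_ <- cc - a
  d <- n_ctrl - c_
  or <- ifelse(a == 0 | b == 0 | c_ == 0 | d == 0,
               ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)),
               (a * d) / (b * c_))
  keep <- a >= min_cc &
    (if (params$direction == "risk") or > 1 else or < 1)
  p <- rep(1, k)
  p[keep] <- fisher_p_many(a[keep], b[keep], c_[keep], d[keep])
  keep <- keep & p <= params$p_max
  if (stats_only) {
    return(data.frame(odds_ratio = or[keep], case_carriers = a[keep]))
  }
  sigs <- lapply(which(keep), function(i) {
    cols <- combos[[i]]
    st <- feature_states(ctx$snps[ctx$state_snp[cols]], ctx$state_g[cols])
    st <- st[order(st$snp_id), , drop = FALSE]
    z <- Z[, i]
    structure(
      list(states = st, key = state_key(st), order = length(cols),
           table = contingency_2x2(a[i], b[i], c_[i], d[i]),
           odds_ratio = or[i], p_value = p[i],
           case_prevalence = a[i] / n_case,
           case_ids = names(g$labels)[z & is_case],
           control_ids = names(g$labels)[z & !is_case]),
      class = "signature")
  })
  if (length(sigs) > 1) {
    df <- data.frame(
      p = vapply(sigs, `[[`, numeric(1), "p_value"),
      or = vapply(sigs, `[[`, numeric(1), "odds_ratio"),
      ord = vapply(sigs, `[[`, integer(1), "order"),
      key = vapply(sigs, `[[`, character(1), "key"))
    sigs <- sigs[order(df$p, -df$or, df$ord, df$key)]
  }
  signature_set(sigs, params, g)
}

search_greedy <- function(ctx, is_case, params, seed) {
  X <- ctx$X
  Xd <- ctx$Xd
  n_case <- sum(is_case)
  n_ctrl <- sum(!is_case)
  min_cc <- params$min_case_prevalence * n_case
  tot <- ctx$col_tot %||% colSums(X)
  a1 <- as.vector(crossprod(as.double(is_case), Xd))
  c1 <- tot - a1
  sc1 <- score_tables(params$score, a1, n_case - a1, c1, n_ctrl - c1,
                      params$direction)
  risk_ok <- if (params$direction == "risk") {
    a1 / n_case > c1 / n_ctrl
  } else a1 / n_case < c1 / n_ctrl
  p_pass1 <- sc1 >= -log10(params$p_max)
  pass1 <- which(a1 >= min_cc & risk_ok & p_pass1)

  starts <- list()
  start_scores <- numeric(0)
  if (1 %in% params$start_orders) {
    starts <- lapply(pass1[order(-sc1[pass1])], function(i) i)
    start_scores <- sc1[pass1][order(-sc1[pass1])]
  }

  if (2 %in% params$start_orders && params$max_order >= 2) {
    ctx <- ctx_total_cross(ctx)
    A2 <- crossprod(Xd[is_case, , drop = FALSE])
    a2 <- A2[ctx$pair_lin]
    c2 <- ctx$Tcross[ctx$pair_lin] - a2
    keep <- which(a2 >= min_cc)
    if (length(keep) > 0) {
      sc2 <- score_tables(params$score, a2[keep], n_case - a2[keep],
                          c2[keep], n_ctrl - c2[keep], params$direction)
      risk2 <- if (params$direction == "risk") {
        a2[keep] / n_case > c2[keep] / n_ctrl
      } else a2[keep] / n_case < c2[keep] / n_ctrl
      pass2 <- which(sc2 >= -log10(params$p_max) & risk2)
      if (length(pass2) > 0) {
        sc2p <- sc2[pass2]
        ord <- order(-sc2p)
        pi_ <- ctx$pair_i[keep][pass2][ord]
        pj_ <- ctx$pair_j[keep][pass2][ord]
        starts <- c(starts,
                    lapply(seq_along(ord), function(i) c(pi_[i], pj_[i])))
        start_scores <- c(start_scores, sc2p[ord])
      }
    }
  }

  if (length(starts) == 0) return(list())
  n_starts <- params$n_random_starts
  if (length(starts) > n_starts) {
    ord <- order(-start_scores)
    n_top <- ceiling(n_starts / 2)
    top <- ord[seq_len(n_top)]
    rest <- ord[-seq_len(n_top)]
    extra <- with_seed(derive_seed(seed, 101L),
                       sample(rest, n_starts - n_top))
    starts <- starts[c(top, extra)]
  }

  # lock-step greedy: every active start is extended by its single best
  # feature state per round (one crossprod per round over all starts)
  S <- length(starts)
  members <- starts
  visited <- if (identical(params$report %||% "all_layers", "all_layers")) {
    lapply(starts, sort)
  } else list()
  Z <- matrix(0, ctx$n, S)
  for (i in seq_len(S)) {
    z <- X[, starts[[i]][1]]
    for (col in starts[[i]][-1]) z <- z & X[, col]
    Z[, i] <- z
  }
  az <- colSums(Z * is_case)
  cz <- colSums(Z) - az
  cur <- score_tables(params$score, az, n_case - az, cz, n_ctrl - cz,
                      params$direction)
  active <- rep(TRUE, S)
  repeat {
    idx <- which(active & lengths(members) < params$max_order)
    if (length(idx) == 0) break
    Za <- Z[, idx, drop = FALSE]
    A <- crossprod(Za * is_case, Xd)          # |idx| x n_states
    Ct <- crossprod(Za, Xd) - A
    sc <- matrix(score_tables(params$score, A, n_case - A, Ct, n_ctrl - Ct,
                              params$direction),
                 nrow = length(idx))
    sc[A < min_cc] <- -Inf
    for (r in seq_along(idx)) {
      snps_in <- ctx$state_snp[members[[idx[r]]]]
      sc[r, ctx$state_snp %in% snps_in] <- -Inf
    }
    best <- max.col(sc, ties.method = "first")
    best_sc <- sc[cbind(seq_along(idx), best)]
    improved <- is.finite(best_sc) & best_sc > cur[idx]
    for (r in which(improved)) {
      i <- idx[r]
      members[[i]] <- c(members[[i]], best[r])
      Z[, i] <- Z[, i] * X[, best[r]]
      cur[i] <- best_sc[r]
      if (identical(params$report %||% "all_layers", "all_layers")) {
        visited[[length(visited) + 1]] <- sort(members[[i]])
      }
    }
    active[idx[!improved]] <- FALSE
    if (!any(improved)) break
  }
  if (identical(params$report %||% "all_layers", "all_layers")) visited
  else lapply(members, sort)
}

search_exhaustive <- function(ctx, is_case, params) {
  m <- length(ctx$snps)
  total <- sum(vapply(seq_len(params$max_order), function(k) {
    choose(m, k) * 3^k
  }, numeric(1)))
  abort_if(total > params$combination_budget,
           paste0("exhaustive search would evaluate %.3g combinations, over ",
                  "the budget of %.3g; reduce the panel/order or raise ",
                  "combination_budget"), total, params$combination_budget)
  n_case <- sum(is_case)
  min_cc <- params$min_case_prevalence * n_case
  X <- ctx$X
  out <- list()
  # depth-first over SNP-ordered state combinations; a subtree is pruned as
  # soon as its case-carrier count falls below the prevalence floor
  # (carrier sets only shrink when states are added)
  rec <- function(z, from_snp, cols) {
    if (length(cols) > 0) out[[length(out) + 1]] <<- cols
    if (length(cols) == params$max_order || from_snp > m) return(invisible())
    for (j in from_snp:m) {
      for (gs in 0:2) {
        col <- (j - 1L) * 3L + gs + 1L
        z2 <- z & X[, col]
        if (sum(z2 & is_case) < min_cc) next
        rec(z2, j + 1L, c(cols, col))
      }
    }
    invisible()
  }
  if (m >= 1) rec(rep(TRUE, ctx$n), 1L, integer(0))
  out
}

#' Write a signature set to TSV
#'
#' One row per signature: states serialized as `snp:genotype;...`, carrier
#' counts, odds ratio and p-value.
#'
#' @param sigs a `signature_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(sigs, path) {
  data.table::fwrite(as.data.frame(sigs), path, sep = "\t")
  invisible(path)
}

#' Serialize a signature set (including carrier id lists) to JSON
#'
#' @param sigs a `signature_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signatures_json <- function(sigs, path) {
  payload <- lapply(unclass(sigs), function(s) {
    list(signature = s$key, order = s$order,
         states = s$states,
         table = unclass(s$table),
         odds_ratio = s$odds_ratio, p_value = s$p_value,
         case_prevalence = s$case_prevalence,
         case_ids = s$case_ids, control_ids = s$control_ids)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
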