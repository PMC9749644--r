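# Evaluation phase: critical SNPs shared across validated signatures,
# random-forest scoring under stratified cross-validation, and cumulative
# gene priorities.

#' Identify critical SNPs
#'
#' A SNP is critical when it appears (with any genotype state) in at least
#' `critical_min` validated signatures.
#'
#' @param signatures validated `signature_set` (non-empty).
#' @param critical_min minimum number of signatures sharing the SNP
#'   (default 2).
#' @return character vector of critical SNP ids, sorted by descending
#'   signature count then id.
#' @export
find_critical_snps <- function(signatures, critical_min = 2) {
  abort_if(length(signatures) == 0, "find_critical_snps: empty signature set")
  snps <- unlist(lapply(signatures, function(s) unique(s$states$snp_id)))
  cnt <- table(snps)
  keep <- cnt[cnt >= critical_min]
  names(keep)[order(-as.integer(keep), names(keep))]
}

#' Count signatures per SNP
#'
#' @param signatures a `signature_set`.
#' @return named integer vector: SNP id -> number of signatures containing it.
#' @export
snp_signature_counts <- function(signatures) {
  snps <- unlist(lapply(signatures, function(s) unique(s$states$snp_id)))
  tab <- table(snps)
  stats::setNames(as.integer(tab), names(tab))
}

#' Score critical SNPs with cross-validated random forests
#'
#' Trains a seeded random forest on the critical-SNP genotype columns
#' (genotypes as factors; missing coded as an explicit level) to predict
#' the case/control split, under stratified `n_folds`-fold
#' cross-validation. The per-SNP score is the mean (over folds) of the
#' Gini impurity-decrease importance, normalized to sum to 1 within each
#' fold; accuracy is pooled over out-of-fold predictions.
#'
#' @param g a [genotype_matrix()].
#' @param critical_snps character vector of SNP ids (length >= 1).
#' @param n_folds folds (default 5).
#' @param n_trees trees per forest (default 500).
#' @param seed integer seed; results are bit-reproducible.
#' @return data.frame of class `critical_snp_scores`: `snp_id`,
#'   `rf_score`, plus the pooled `cv_accuracy` in `attr(, "cv_accuracy")`
#'   and per-fold importances in `attr(, "fold_importance")`.
#' @export
score_critical_snps <- function(g, critical_snps, n_folds = 5,
                                n_trees = 500, seed = 1L) {
  abort_if(length(critical_snps) < 1, "score_critical_snps: no critical SNPs")
  missing_snps <- setdiff(critical_snps, snp_ids(g))
  abort_if(length(missing_snps) > 0, "score_critical_snps: unknown SNP(s): %s",
           paste(missing_snps, collapse = ", "))
  y <- factor(g$labels, levels = c("control", "case"))
  abort_if(min(table(y)) < n_folds,
           "score_critical_snps: a class has fewer members than folds")
  dat <- as.data.frame(lapply(
    as.data.frame(g$genotypes[, critical_snps, drop = FALSE]),
    function(col) factor(ifelse(is.na(col), "miss", as.character(col)),
                         levels = c("0", "1", "2", "miss"))
  ))
  names(dat) <- critical_snps

  with_seed(seed, {
    # stratified fold assignment
    fold <- integer(length(y))
    for (cl in levels(y)) {
      i <- which(y == cl)
      fold[i] <- sample(rep_len(seq_len(n_folds), length(i)))
    }
    imp <- matrix(0, length(critical_snps), n_folds,
                  dimnames = list(critical_snps, NULL))
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      rf <- randomForest::randomForest(
        x = dat[tr, , drop = FALSE], y = y[tr], ntree = n_trees,
        importance = FALSE)
      gi <- rf$importance[, "MeanDecreaseGini"]
      tot <- sum(gi)
      imp[, f] <- if (tot > 0) gi / tot else 0
      pred[!tr] <- stats::predict(rf, dat[!tr, , drop = FALSE])
    }
    out <- data.frame(
      snp_id = critical_snps,
      rf_score = rowMeans(imp),
      stringsAsFactors = FALSE
    )
    out <- out[order(-out$rf_score, out$snp_id), ]
    rownames(out) <- NULL
    structure(out, class = c("critical_snp_scores", "data.frame"),
              cv_accuracy = mean(pred == y),
              fold_importance = imp)
  })
}

#' Summarize critical-SNP evaluation
#'
#' Joins per-SNP signature counts and random-forest scores into the table
#' exported by the pipeline.
#'
#' @param signatures validated `signature_set`.
#' @param scores a `critical_snp_scores` data.frame.
#' @return data.frame with `snp_id`, `n_signatures`, `rf_score`,
#'   `cv_accuracy`.
#' @export
critical_snp_table <- function(signatures, scores) {
  cnt <- snp_signature_counts(signatures)
  data.frame(
    snp_id = scores$snp_id,
    n_signatures = as.integer(cnt[scores$snp_id]),
    rf_score = scores$rf_score,
    cv_accuracy = attr(scores, "cv_accuracy"),
    stringsAsFactors = FALSE
  )
}

#' Rank genes by cumulative critical-SNP score
#'
#' Each gene's priority is the plain sum of the random-forest scores of
#' the critical SNPs assigned to it; a SNP assigned to several genes
#' contributes its full score to each of them.
#'
#' @param scores a `critical_snp_scores` data.frame (or any data.frame
#'   with `snp_id` and `rf_score`).
#' @param assignments data.frame of SNP-to-gene assignments with columns
#'   `snp_id`, `gene_id` (see [map_snp_to_genes()]).
#' @return data.frame: `gene_id`, `cumulative_score`, `n_snps`,
#'   `snp_ids` (semicolon-joined), ranked by descending score then id.
#' @export
prioritize_genes <- function(scores, assignments) {
  merged <- merge(assignments[, c("snp_id", "gene_id")], scores,
                  by = "snp_id")
  if (nrow(merged) == 0) {
    return(data.frame(gene_id = character(0), cumulative_score = numeric(0),
                      n_snps = integer(0), snp_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  merged <- unique(merged[, c("gene_id", "snp_id", "rf_score")])
  agg <- stats::aggregate(rf_score ~ gene_id, merged, sum)
  nsnp <- tapply(merged$snp_id, merged$gene_id, length)
  joined <- tapply(merged$snp_id, merged$gene_id,
                   function(s) paste(sort(s), collapse = ";"))
  out <- data.frame(
    gene_id = agg$gene_id,
    cumulative_score = agg$rf_score,
    n_snps = as.integer(nsnp[agg$gene_id]),
    snp_ids = as.character(joined[agg$gene_id]),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$cumulative_score, out$gene_id), ]
  rownames(out) <- NULL
  out
}
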