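# The samples-by-SNPs ordinal genotype container used by every stage.
# Genotypes are coded 0/1/2 = copies of the minor (alternate) allele,
# NA = missing call.

#' Construct a genotype matrix
#'
#' @param genotypes integer matrix, samples in rows and SNPs in columns,
#'   values in `{0, 1, 2, NA}`; must carry row and column names (sample and
#'   SNP identifiers).
#' @param labels per-sample case/control status: character or factor with
#'   values `"case"` / `"control"`, aligned with matrix rows.
#' @param snp_meta optional data.frame with one row per SNP and columns
#'   `snp_id`, `chrom`, `pos` (1-based), `ref`, `alt`, `maf`. A minimal
#'   placeholder is synthesized when omitted.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, labels, snp_meta = NULL) {
  abort_if(!is.matrix(genotypes), "genotypes must be a matrix")
  abort_if(is.null(rownames(genotypes)) || is.null(colnames(genotypes)),
           "genotypes must have sample (row) and SNP (column) names")
  abort_if(anyDuplicated(colnames(genotypes)) > 0, "duplicate SNP ids")
  abort_if(anyDuplicated(rownames(genotypes)) > 0, "duplicate sample ids")
  storage.mode(genotypes) <- "integer"
  vals <- genotypes[!is.na(genotypes)]
  abort_if(length(vals) > 0 && !all(vals %in% 0:2),
           "genotype values must be 0, 1, 2 or NA")
  labels <- as.character(labels)
  abort_if(length(labels) != nrow(genotypes),
           "labels must align with matrix rows")
  abort_if(!all(labels %in% c("case", "control")),
           "labels must be 'case' or 'control'")
  if (is.null(snp_meta)) {
    snp_meta <- data.frame(
      snp_id = colnames(genotypes),
      chrom = "1",
      pos = seq_len(ncol(genotypes)),
      ref = "A", alt = "B",
      maf = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  abort_if(!all(c("snp_id", "chrom", "pos", "ref", "alt") %in% names(snp_meta)),
           "snp_meta must have columns snp_id, chrom, pos, ref, alt")
  abort_if(!identical(as.character(snp_meta$snp_id), colnames(genotypes)),
           "snp_meta rows must align with genotype columns")
  abort_if(any(snp_meta$pos < 0), "positions must be non-negative")
  if (is.null(snp_meta$maf)) snp_meta$maf <- NA_real_
  structure(
    list(genotypes = genotypes,
         labels = stats::setNames(labels, rownames(genotypes)),
         snp_meta = snp_meta),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples (%d cases / %d controls) x %d SNPs, %.2f%% missing\n",
    nrow(x$genotypes), sum(x$labels == "case"), sum(x$labels == "control"),
    ncol(x$genotypes), 100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Sample and SNP accessors
#' @param g a [genotype_matrix()].
#' @return character vectors of identifiers.
#' @export
sample_ids <- function(g) rownames(g$genotypes)

#' @rdname sample_ids
#' @export
snp_ids <- function(g) colnames(g$genotypes)

#' @rdname sample_ids
#' @export
case_ids <- function(g) names(g$labels)[g$labels == "case"]

#' @rdname sample_ids
#' @export
control_ids <- function(g) names(g$labels)[g$labels == "control"]

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param g a [genotype_matrix()].
#' @param samples,snps identifiers (or logical/integer indices) to keep;
#'   `NULL` keeps everything.
#' @return a new `genotype_matrix`.
#' @export
subset_genotypes <- function(g, samples = NULL, snps = NULL) {
  keep_s <- samples %||% rownames(g$genotypes)
  keep_v <- snps %||% colnames(g$genotypes)
  gm <- g$genotypes[keep_s, keep_v, drop = FALSE]
  meta <- g$snp_meta[match(colnames(gm), g$snp_meta$snp_id), , drop = FALSE]
  rownames(meta) <- NULL
  genotype_matrix(gm, g$labels[rownames(gm)], meta)
}

#' Observed minor-allele frequency per SNP
#'
#' Computed from non-missing genotypes over all samples.
#'
#' @param g a [genotype_matrix()].
#' @return named numeric vector of allele frequencies of the coded
#'   (alternate) allele.
#' @export
observed_maf <- function(g) {
  colMeans(g$genotypes, na.rm = TRUE) / 2
}

#' Relabel a genotype matrix
#'
#' Replaces the case/control labels (used by the permutation null).
#'
#' @param g a [genotype_matrix()].
#' @param labels new label vector aligned with samples.
#' @return a `genotype_matrix` sharing the genotype data.
#' @export
set_labels <- function(g, labels) {
  labels <- as.character(labels)
  abort_if(length(labels) != nrow(g$genotypes), "labels must align with samples")
  abort_if(!all(labels %in% c("case", "control")),
           "labels must be 'case' or 'control'")
  g$labels <- stats::setNames(labels, rownames(g$genotypes))
  g
}
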