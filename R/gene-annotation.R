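# SNP-to-gene assignment by positional cascade:
#   (1) SNPs inside a coding interval are assigned to the gene(s) directly;
#   (2) otherwise, among genes whose strand-aware window
#       [body_start - 2 kb upstream, body_end + 0.5 kb downstream]
#       (mirrored on the - strand) contains the SNP, the closest gene(s)
#       are assigned (all of them on a distance tie);
#   (3) otherwise the SNP is unassigned.
# All internal coordinates are 1-based closed; BED input is converted at
# the boundary.

#' Annotation window parameters
#'
#' @param upstream_window bases upstream of the gene body (default 2000).
#' @param downstream_window bases downstream of the gene body (default 500).
#' @param anchor windows anchor on the gene `"body"` (default) or on the
#'   `"tss"` (transcription start site).
#' @return an object of class `annotation_params`.
#' @export
annotation_params <- function(upstream_window = 2000, downstream_window = 500,
                              anchor = c("body", "tss")) {
  anchor <- match.arg(anchor)
  abort_if(upstream_window < 0 || downstream_window < 0,
           "annotation_params: windows must be non-negative")
  structure(list(upstream_window = upstream_window,
                 downstream_window = downstream_window, anchor = anchor),
            class = "annotation_params")
}

validate_gene_model <- function(model) {
  need <- c("gene_id", "chrom", "strand", "start", "end")
  abort_if(!all(need %in% names(model)),
           "gene model needs columns %s", paste(need, collapse = ", "))
  abort_if(any(model$start > model$end), "gene model: start > end")
  abort_if(!all(model$strand %in% c("+", "-")),
           "gene model: strand must be '+' or '-'")
  if (!is.null(model$cds_start)) {
    has_cds <- !is.na(model$cds_start)
    abort_if(any(model$cds_start[has_cds] > model$cds_end[has_cds]),
             "gene model: cds_start > cds_end")
  }
  invisible(model)
}

#' Read a gene model from GFF3 or BED
#'
#' GFF3: `gene` features define gene bodies and `CDS` features (grouped by
#' `Parent` or `gene_id`) the coding intervals. BED (6+ columns): each
#' record becomes one gene whose body doubles as its coding interval;
#' BED's 0-based half-open coordinates are converted to 1-based closed.
#' Parsing is delegated to `rtracklayer`.
#'
#' @param path input file.
#' @param format `"gff3"` or `"bed"`; guessed from the extension by
#'   default.
#' @return a `gene_model` data.frame with columns `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `cds_start`, `cds_end`.
#' @export
read_gene_model <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  abort_if(!requireNamespace("rtracklayer", quietly = TRUE),
           "read_gene_model requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  df <- as.data.frame(gr)
  if (format == "bed") {
    # rtracklayer already converts BED to 1-based closed coordinates
    out <- data.frame(
      gene_id = as.character(df$name),
      chrom = as.character(df$seqnames),
      strand = ifelse(as.character(df$strand) == "-", "-", "+"),
      start = df$start, end = df$end,
      cds_start = df$start, cds_end = df$end,
      stringsAsFactors = FALSE)
  } else {
    genes <- df[df$type == "gene", , drop = FALSE]
    abort_if(nrow(genes) == 0, "no gene features in %s", path)
    gid <- as.character(genes$ID %||% genes$gene_id %||% genes$Name)
    cds <- df[df$type == "CDS", , drop = FALSE]
    cds_parent <- if (nrow(cds) > 0) {
      as.character(unlist(lapply(cds$Parent, `[`, 1)))
    } else character(0)
    cds_s <- tapply(cds$start, cds_parent, min)
    cds_e <- tapply(cds$end, cds_parent, max)
    out <- data.frame(
      gene_id = gid,
      chrom = as.character(genes$seqnames),
      strand = ifelse(as.character(genes$strand) == "-", "-", "+"),
      start = genes$start, end = genes$end,
      cds_start = as.integer(cds_s[gid]),
      cds_end = as.integer(cds_e[gid]),
      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("gene_model", "data.frame")
  validate_gene_model(out)
}

#' Write a gene model as GFF3 or BED
#'
#' @param model a `gene_model` data.frame.
#' @param path output file.
#' @param format `"gff3"` (gene + CDS features) or `"bed"` (0-based
#'   half-open, gene bodies); guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(model, path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  validate_gene_model(model)
  if (format == "bed") {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     model$chrom, model$start - 1L, model$end,
                     model$gene_id, model$strand)
  } else {
    lines <- c("##gff-version 3",
               sprintf("%s\tcombsig\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       model$chrom, model$start, model$end, model$strand,
                       model$gene_id))
    has_cds <- !is.null(model$cds_start) & !is.na(model$cds_start %||% NA)
    cds <- model[which(has_cds), , drop = FALSE]
    if (nrow(cds) > 0) {
      lines <- c(lines,
                 sprintf("%s\tcombsig\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
                         cds$chrom, cds$cds_start, cds$cds_end, cds$strand,
                         cds$gene_id, cds$gene_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# distance from a position to a gene body (0 inside)
body_distance <- function(pos, start, end) {
  ifelse(pos < start, start - pos, ifelse(pos > end, pos - end, 0L))
}

#' Map one SNP to gene(s) via the annotation cascade
#'
#' @param chrom,pos SNP chromosome and 1-based position.
#' @param model a `gene_model` data.frame.
#' @param params an [annotation_params()].
#' @return data.frame with columns `gene_id`, `mapping_class`
#'   (`"coding"` or `"proximal"`), `distance` (bases to the gene body;
#'   0 for coding); zero rows when the SNP is unassigned.
#' @export
map_snp_to_genes <- function(chrom, pos, model, params = annotation_params()) {
  validate_gene_model(model)
  cand <- model[model$chrom == as.character(chrom), , drop = FALSE]
  empty <- data.frame(gene_id = character(0), mapping_class = character(0),
                      distance = integer(0), stringsAsFactors = FALSE)
  if (nrow(cand) == 0) return(empty)
  # (1) coding containment
  if (!is.null(cand$cds_start)) {
    in_cds <- !is.na(cand$cds_start) & pos >= cand$cds_start &
      pos <= cand$cds_end
    if (any(in_cds)) {
      g <- cand$gene_id[in_cds]
      return(data.frame(gene_id = g[order(g)], mapping_class = "coding",
                        distance = 0L, stringsAsFactors = FALSE))
    }
  }
  # (2) proximal window, strand-aware, inclusive at the boundary
  if (params$anchor == "tss") {
    tss <- ifelse(cand$strand == "+", cand$start, cand$end)
    lo <- ifelse(cand$strand == "+", tss - params$upstream_window,
                 tss - params$downstream_window)
    hi <- ifelse(cand$strand == "+", tss + params$downstream_window,
                 tss + params$upstream_window)
  } else {
    lo <- ifelse(cand$strand == "+", cand$start - params$upstream_window,
                 cand$start - params$downstream_window)
    hi <- ifelse(cand$strand == "+", cand$end + params$downstream_window,
                 cand$end + params$upstream_window)
  }
  in_win <- pos >= lo & pos <= hi
  if (!any(in_win)) return(empty)
  cand <- cand[in_win, , drop = FALSE]
  d <- body_distance(pos, cand$start, cand$end)
  dmin <- min(d)
  hit <- which(d == dmin)
  g <- cand$gene_id[hit]
  ord <- order(g)
  data.frame(gene_id = g[ord], mapping_class = "proximal",
             distance = as.integer(d[hit][ord]), stringsAsFactors = FALSE)
}

#' Annotate signature SNPs with genes
#'
#' Runs the cascade for every distinct SNP of a signature set (or an
#' explicit SNP list) and reports assignments and unassigned SNPs.
#'
#' @param signatures a `signature_set`, or a character vector of SNP ids.
#' @param g a [genotype_matrix()] providing SNP coordinates.
#' @param model a `gene_model`.
#' @param params an [annotation_params()].
#' @return list with `assignments` (data.frame `snp_id`, `gene_id`,
#'   `mapping_class`, `distance`) and `unassigned` (character vector).
#' @export
annotate_signatures <- function(signatures, g, model,
                                params = annotation_params()) {
  snps <- if (is.character(signatures)) unique(signatures) else {
    unique(unlist(lapply(signatures, function(s) s$states$snp_id)))
  }
  snps <- sort(snps)
  meta <- g$snp_meta[match(snps, g$snp_meta$snp_id), , drop = FALSE]
  abort_if(anyNA(meta$snp_id), "annotate_signatures: SNP(s) missing from matrix")
  rows <- lapply(seq_along(snps), function(i) {
    hit <- map_snp_to_genes(meta$chrom[i], meta$pos[i], model, params)
    if (nrow(hit) == 0) return(NULL)
    cbind(snp_id = snps[i], hit, stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  if (is.null(assignments)) {
    assignments <- data.frame(snp_id = character(0), gene_id = character(0),
                              mapping_class = character(0),
                              distance = integer(0), stringsAsFactors = FALSE)
  }
  list(assignments = assignments,
       unassigned = setdiff(snps, assignments$snp_id))
}
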