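# Disease architecture: the graph of disease-associated feature states
# linked by co-occurrence in validated signatures, partitioned into
# communities (patient subgroups) by case co-occurrence.

#' Build the disease-architecture graph
#'
#' Nodes are the feature states of the validated signatures; every
#' signature induces a clique over its states. Edge weights are the
#' Jaccard similarity of the case sets attached to the two states (a
#' state's case set is the union of the case carriers of the validated
#' signatures containing it). Node and edge order are canonicalized so the
#' graph is independent of signature insertion order.
#'
#' @param signatures validated `signature_set` (non-empty).
#' @return an `igraph` graph; vertex attributes `snp_id`, `genotype`,
#'   `case_ids` (list), edge attribute `weight`.
#' @export
build_architecture <- function(signatures) {
  abort_if(length(signatures) == 0, "build_architecture: empty signature set")
  state_lab <- function(s) sprintf("%s:%d", s$states$snp_id, s$states$genotype)
  labs <- sort(unique(unlist(lapply(signatures, state_lab))))
  case_sets <- stats::setNames(vector("list", length(labs)), labs)
  for (s in signatures) {
    for (l in state_lab(s)) {
      case_sets[[l]] <- union(case_sets[[l]], s$case_ids)
    }
  }
  edges <- unique(do.call(rbind, lapply(signatures, function(s) {
    l <- sort(state_lab(s))
    if (length(l) < 2) return(NULL)
    t(utils::combn(l, 2))
  })))
  gr <- igraph::make_empty_graph(n = length(labs), directed = FALSE)
  gr <- igraph::set_vertex_attr(gr, "name", value = labs)
  parts <- strsplit(labs, ":", fixed = TRUE)
  gr <- igraph::set_vertex_attr(gr, "snp_id",
                                value = vapply(parts, `[`, character(1), 1))
  gr <- igraph::set_vertex_attr(gr, "genotype",
                                value = as.integer(vapply(parts, `[`, character(1), 2)))
  igraph::V(gr)$case_ids <- unname(case_sets)
  if (!is.null(edges)) {
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    w <- vapply(seq_len(nrow(edges)), function(i) {
      a <- case_sets[[edges[i, 1]]]
      b <- case_sets[[edges[i, 2]]]
      u <- length(union(a, b))
      if (u == 0) 0 else length(intersect(a, b)) / u
    }, numeric(1))
    gr <- igraph::add_edges(gr, t(edges), weight = w)
  }
  gr
}

#' Detect communities of feature states
#'
#' Seeded modularity-maximizing partition (multilevel/Louvain, resolution
#' 1) of the architecture graph, or plain connected components. Community
#' labels are canonicalized by descending total case count (community 1
#' carries the most cases), making the labelling invariant to node
#' insertion order.
#'
#' @param graph an architecture graph from [build_architecture()].
#' @param method `"modularity"` (default) or `"components"`.
#' @param seed integer seed for the modularity heuristic.
#' @return named integer vector: feature-state label -> community id.
#' @export
detect_communities <- function(graph, method = c("modularity", "components"),
                               seed = 1L) {
  method <- match.arg(method)
  abort_if(igraph::vcount(graph) == 0, "detect_communities: empty graph")
  membership <- if (method == "modularity") {
    cl <- with_seed(seed, igraph::cluster_louvain(graph, resolution = 1))
    igraph::membership(cl)
  } else {
    igraph::components(graph)$membership
  }
  # canonical relabeling: by descending community case count, ties by the
  # lexicographically smallest member state
  case_ids <- igraph::V(graph)$case_ids
  nm <- igraph::V(graph)$name
  sizes <- vapply(split(seq_along(membership), membership), function(i) {
    length(unique(unlist(case_ids[i])))
  }, numeric(1))
  firsts <- vapply(split(nm, membership), min, character(1))
  ord <- order(-sizes, firsts)
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  stats::setNames(as.integer(relabel[as.character(membership)]), nm)
}

#' Group validated signatures into communities
#'
#' A signature is assigned to the community holding most of its feature
#' states, with each state's vote weighted by the number of validated
#' signatures containing it: a signature follows its canonical (widely
#' shared) states rather than its private noise states. Ties go to the
#' smaller community id.
#'
#' @param signatures validated `signature_set`.
#' @param membership community labels from [detect_communities()].
#' @return integer vector: community id per signature.
#' @export
signature_communities <- function(signatures, membership) {
  all_labs <- unlist(lapply(signatures, function(s) {
    sprintf("%s:%d", s$states$snp_id, s$states$genotype)
  }))
  mult <- table(all_labs)
  vapply(signatures, function(s) {
    labs <- sprintf("%s:%d", s$states$snp_id, s$states$genotype)
    votes <- tapply(as.numeric(mult[labs]), membership[labs], sum)
    as.integer(names(votes)[which.max(votes)])
  }, integer(1))
}

#' Per-community carrier statistics
#'
#' A sample carries a community iff it carries at least one member
#' signature; the odds ratio and Fisher p-value come from the resulting
#' carrier-by-status table.
#'
#' @param signatures validated `signature_set`.
#' @param community_of integer vector from [signature_communities()].
#' @param g the [genotype_matrix()].
#' @return data.frame of class `community_stats`: one row per community
#'   with `community`, `n_signatures`, `n_snps`, `case_carriers`,
#'   `control_carriers`, `cases_pct`, `odds_ratio`, `p_value`. Case sets
#'   are attached as `attr(, "case_sets")`.
#' @export
community_stats <- function(signatures, community_of, g) {
  abort_if(length(signatures) == 0, "community_stats: empty signature set")
  abort_if(length(community_of) != length(signatures),
           "community_stats: one community id per signature required")
  n_case <- sum(g$labels == "case")
  n_ctrl <- sum(g$labels == "control")
  ids <- sort(unique(community_of))
  case_sets <- list()
  rows <- lapply(ids, function(cid) {
    member <- which(community_of == cid)
    cset <- unique(unlist(lapply(signatures[member], `[[`, "case_ids")))
    ctlset <- unique(unlist(lapply(signatures[member], `[[`, "control_ids")))
    case_sets[[as.character(cid)]] <<- cset
    tab <- contingency_2x2(length(cset), n_case - length(cset),
                           length(ctlset), n_ctrl - length(ctlset))
    snps <- unique(unlist(lapply(signatures[member],
                                 function(s) s$states$snp_id)))
    data.frame(
      community = cid,
      n_signatures = length(member),
      n_snps = length(snps),
      case_carriers = length(cset),
      control_carriers = length(ctlset),
      cases_pct = round(100 * length(cset) / n_case),
      odds_ratio = odds_ratio(tab),
      p_value = if (length(cset) + length(ctlset) == 0) 1
                else fisher_exact_p(tab)
    )
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("community_stats", "data.frame"),
            case_sets = case_sets)
}

#' Pairwise patient overlap between communities
#'
#' `overlap(i, j) = |cases_i intersect cases_j| / min(|cases_i|, |cases_j|)`
#' (the smaller community is the denominator; configurable to the Jaccard
#' convention). Symmetric with unit diagonal.
#'
#' @param stats a `community_stats` object (case sets attached), or a
#'   named list of case-id vectors.
#' @param denominator `"min"` (default) or `"union"` (Jaccard).
#' @return symmetric numeric matrix of overlap fractions.
#' @export
overlap_matrix <- function(stats, denominator = c("min", "union")) {
  denominator <- match.arg(denominator)
  sets <- if (inherits(stats, "community_stats")) attr(stats, "case_sets")
          else stats
  abort_if(length(sets) < 2, "overlap_matrix: need at least two communities")
  k <- length(sets)
  out <- matrix(1, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    den <- if (denominator == "min") min(length(sets[[i]]), length(sets[[j]]))
           else length(union(sets[[i]], sets[[j]]))
    out[i, j] <- out[j, i] <- if (den == 0) 0 else inter / den
  }
  out
}

#' Fraction of cases represented by the disease architecture
#'
#' The union of the case-carrier sets of all validated signatures,
#' divided by the number of cases.
#'
#' @param signatures validated `signature_set`.
#' @param g the [genotype_matrix()].
#' @return fraction in `[0, 1]`.
#' @export
cases_represented <- function(signatures, g) {
  n_case <- sum(g$labels == "case")
  if (length(signatures) == 0) return(0)
  length(unique(unlist(lapply(signatures, `[[`, "case_ids")))) / n_case
}

#' Export the architecture graph
#'
#' @param graph an architecture graph.
#' @param path output file; `.graphml` selects GraphML, anything else an
#'   edge-list TSV (`from`, `to`, `weight`).
#' @return `path`, invisibly.
#' @export
write_architecture <- function(graph, path) {
  if (grepl("\\.graphml$", path)) {
    g2 <- igraph::delete_vertex_attr(graph, "case_ids")
    igraph::write_graph(g2, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(graph, what = "edges")
    data.table::fwrite(el, path, sep = "\t")
  }
  invisible(path)
}
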