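#' Build the pair graph from filtered reciprocal pairs
#'
#' @param pairs A tibble with `id_a`, `id_b` and (optionally) a
#'   `passed_reciprocal` column; when present, only passing rows become
#'   edges.
#' @return An igraph undirected simple graph whose edges are the filtered
#'   reciprocal pairs.
#' @export
pair_graph <- function(pairs) {
  if ("passed_reciprocal" %in% names(pairs)) {
    pairs <- dplyr::filter(pairs, .data$passed_reciprocal)
  }
  if (nrow(pairs) == 0) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  el <- as.matrix(pairs[, c("id_a", "id_b")])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)
}

#' Stringent double-linkage clusters
#'
#' Three proteins A, B, C cluster together only when all three pairwise
#' reciprocal links exist, i.e. clusters are maximal cliques of the pair
#' graph. A lone edge not contained in any triangle is itself a maximal
#' clique and becomes a 2-member cluster. At this stage a protein may
#' belong to several clusters.
#'
#' @param g A [pair_graph()].
#' @param max_size Cap on clique size; larger cliques are kept but trigger
#'   a warning (guards against pathological blowup).
#' @return A tibble with `cluster_id`, `members` (list column of protein
#'   IDs) and `size`.
#' @export
double_linkage_clusters <- function(g, max_size = 500) {
  if (igraph::vcount(g) == 0 || igraph::ecount(g) == 0) {
    return(tibble::tibble(
      cluster_id = integer(), members = list(), size = integer()
    ))
  }
  cl <- igraph::max_cliques(g, min = 2)
  members <- purrr::map(cl, function(x) sort(igraph::V(g)$name[x]))
  sizes <- lengths(members)
  if (any(sizes > max_size)) {
    warning("clique(s) larger than max_size = ", max_size, " encountered")
  }
  ord <- order(purrr::map_chr(members, function(m) paste(m, collapse = ",")))
  tibble::tibble(
    cluster_id = seq_along(members),
    members = members[ord],
    size = sizes[ord]
  )
}

#' Merge overlapping clusters into superclusters
#'
#' Single-linkage union of clusters sharing any member, iterated to a fixed
#' point, so that each protein ends up in exactly one family. Families
#' produced by a merge are tagged `"supercluster"`; untouched clusters
#' stay `"double_linkage"`.
#'
#' @param clusters Output of [double_linkage_clusters()].
#' @return A tibble with `family_id`, `members` (list column, sorted),
#'   `size` and `kind`.
#' @export
merge_superclusters <- function(clusters) {
  if (nrow(clusters) == 0) {
    return(tibble::tibble(
      family_id = integer(), members = list(),
      size = integer(), kind = character()
    ))
  }
  # connected components of the cluster-overlap graph via union-find
  all_ids <- sort(unique(unlist(clusters$members)))
  parent <- stats::setNames(seq_along(all_ids), all_ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (m in clusters$members) {
    r <- find(match(m[1], all_ids))
    for (x in m[-1]) {
      rx <- find(match(x, all_ids))
      if (rx != r) parent[rx] <- r
    }
  }
  roots <- vapply(seq_along(all_ids), find, integer(1))
  comp <- split(all_ids, roots)
  n_clusters_per_comp <- purrr::map_int(comp, function(mem) {
    sum(purrr::map_lgl(clusters$members, function(m) m[1] %in% mem))
  })
  members <- purrr::map(comp, sort)
  ord <- order(purrr::map_chr(members, function(m) paste(m, collapse = ",")))
  tibble::tibble(
    family_id = seq_along(members),
    members = unname(members[ord]),
    size = unname(lengths(members)[ord]),
    kind = unname(ifelse(n_clusters_per_comp[ord] > 1,
      "supercluster", "double_linkage"
    ))
  )
}

#' Gene-conversion exclusion filter
#'
#' Gene conversion concentrates in large families; genes with many
#' identifying matches are excluded by removing every node whose degree in
#' the ORIGINAL pair graph exceeds `max_matches` (single pass over original
#' degrees), together with all incident edges.
#'
#' @param g A [pair_graph()].
#' @param max_matches Maximum allowed number of matches; nodes with degree
#'   strictly greater are removed (default 5).
#' @return The induced subgraph.
#' @export
gene_conversion_filter <- function(g, max_matches = 5) {
  if (igraph::vcount(g) == 0) {
    return(g)
  }
  keep <- igraph::degree(g) <= max_matches
  igraph::induced_subgraph(g, which(keep))
}

#' Proportion of the genome that is duplicated
#'
#' @param families Output of [merge_superclusters()].
#' @param total_genes Total number of genes in the genome.
#' @return Fraction of genes belonging to some family.
#' @export
duplication_proportion <- function(families, total_genes) {
  if (total_genes == 0) stop("total_genes must be positive")
  n_dup <- length(unique(unlist(families$members)))
  stopifnot(total_genes >= n_dup)
  n_dup / total_genes
}

#' Number of gene families
#'
#' @param families Output of [merge_superclusters()].
#' @return Family count.
#' @export
family_count <- function(families) nrow(families)
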