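# Score-thresholded PPI subnetworks over a gene universe, degree-based hub
# screening, and MCODE-style dense-module detection.
#
# The module detector follows the three MCODE phases: (1) vertex weighting
# by the core-clustering coefficient (density of the highest k-core of the
# closed neighbourhood) times that core's k; (2) greedy complex growth from
# the highest-weight unseen seed, admitting vertices whose weight is within
# `node_score_cutoff` of the seed weight; (3) post-processing with a 2-core
# filter and an optional haircut. Cluster score = density x node count,
# density = 2E / (V(V-1)). Cytoscape-plugin defaults are adopted (degree
# cutoff 2, node score cutoff 0.2, k-core 2, haircut on, fluff off).

#' Build a score-thresholded PPI graph
#'
#' Keeps edges whose confidence is at least `score_min` and whose endpoints
#' both lie in `gene_universe`; isolated nodes are dropped; parallel edges
#' collapse to the maximum score.
#'
#' @param edge_table Data frame with `protein_a`, `protein_b`,
#'   `combined_score` (see [read_ppi_table()]).
#' @param gene_universe Symbols to retain (e.g. the top up- or
#'   down-regulated DE mRNAs); `NULL` keeps all.
#' @param score_min Confidence cutoff (default 0.7, inclusive).
#' @return An undirected simple [igraph::graph] with edge attribute `score`
#'   and graph attributes `n_nodes`, `n_edges`, `mean_degree`.
#' @export
build_ppi <- function(edge_table, gene_universe = NULL, score_min = 0.7) {
  df <- edge_table[edge_table$combined_score >= score_min, , drop = FALSE]
  if (!is.null(gene_universe))
    df <- df[df$protein_a %in% gene_universe &
             df$protein_b %in% gene_universe, , drop = FALSE]
  df <- df[df$protein_a != df$protein_b, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = df$protein_a, to = df$protein_b,
               score = df$combined_score), directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(score = "max"))
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  g <- igraph::set_graph_attr(g, "n_nodes", igraph::vcount(g))
  g <- igraph::set_graph_attr(g, "n_edges", igraph::ecount(g))
  g <- igraph::set_graph_attr(g, "mean_degree",
                              if (igraph::vcount(g)) mean(igraph::degree(g)) else 0)
  g
}

#' Degree hubs of a PPI graph
#'
#' @param graph An igraph object.
#' @param min_degree Minimum neighbour count (default 5, inclusive).
#' @return Data frame `gene`, `degree`, sorted by degree descending then
#'   name ascending.
#' @export
degree_hubs <- function(graph, min_degree = 5L) {
  deg <- igraph::degree(graph)
  keep <- deg >= min_degree
  out <- data.frame(gene = names(deg)[keep], degree = unname(deg[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# MCODE phase 1: weight(v) = k * density(highest k-core of G[N[v] + v]);
# vertices below the degree cutoff get weight 0.
mcode_vertex_weights <- function(graph, degree_cutoff = 2L) {
  n <- igraph::vcount(graph)
  w <- numeric(n)
  deg <- igraph::degree(graph)
  for (v in seq_len(n)) {
    if (deg[v] < degree_cutoff) next
    nb <- c(v, as.integer(igraph::neighbors(graph, v)))
    sub <- igraph::induced_subgraph(graph, nb)
    cores <- igraph::coreness(sub)
    k <- max(cores)
    core_sub <- igraph::induced_subgraph(sub, which(cores >= k))
    nv <- igraph::vcount(core_sub)
    dens <- if (nv > 1) 2 * igraph::ecount(core_sub) / (nv * (nv - 1)) else 0
    w[v] <- k * dens
  }
  w
}

#' MCODE-style dense module detection
#'
#' @param graph Undirected simple igraph.
#' @param degree_cutoff Vertices below this degree are never weighted or
#'   seeded (default 2).
#' @param node_score_cutoff Admission band below the seed weight as a
#'   fraction (default 0.2): a vertex joins if
#'   `weight >= seed_weight * (1 - node_score_cutoff)`.
#' @param k_core Discard complexes without a `k_core`-core (default 2).
#' @param score_min Keep clusters with score strictly above this (default 0).
#' @param haircut Trim the final complex to its 2-core (default `TRUE`).
#' @return List of clusters, each a list with `members`, `seed`, `score`,
#'   `density`, sorted by score descending. Vertices belong to at most one
#'   cluster.
#' @export
mcode_clusters <- function(graph, degree_cutoff = 2L, node_score_cutoff = 0.2,
                           k_core = 2L, score_min = 0, haircut = TRUE) {
  n <- igraph::vcount(graph)
  if (n == 0L) return(list())
  w <- mcode_vertex_weights(graph, degree_cutoff)
  names_v <- igraph::V(graph)$name
  order_seeds <- order(-w, names_v)
  seen <- logical(n)
  clusters <- list()
  adj <- igraph::adjacent_vertices(graph, igraph::V(graph))
  for (seed in order_seeds) {
    if (seen[seed] || w[seed] <= 0) next
    threshold <- w[seed] * (1 - node_score_cutoff)
    members <- seed
    seen[seed] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in as.integer(adj[[v]])) {
          if (!seen[u] && w[u] >= threshold) {
            seen[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    sub <- igraph::induced_subgraph(graph, members)
    cores <- igraph::coreness(sub)
    if (max(cores) < k_core) next          # no k-core: not a complex
    keep <- if (haircut) which(cores >= 2L) else seq_along(members)
    sub2 <- igraph::induced_subgraph(sub, keep)
    comp <- igraph::components(sub2)
    # keep the component containing the seed (or the largest if trimmed away)
    seed_name <- names_v[seed]
    cid <- if (seed_name %in% igraph::V(sub2)$name)
      comp$membership[[seed_name]] else which.max(comp$csize)
    final <- igraph::induced_subgraph(
      sub2, which(comp$membership == cid))
    nv <- igraph::vcount(final)
    if (nv < 2L) next
    dens <- 2 * igraph::ecount(final) / (nv * (nv - 1))
    score <- dens * nv
    if (score <= score_min) next
    clusters[[length(clusters) + 1L]] <- list(
      members = sort(igraph::V(final)$name), seed = seed_name,
      score = score, density = dens)
  }
  clusters[order(-vapply(clusters, `[[`, 0, "score"))]
}

#' Flatten MCODE clusters into a data frame
#' @param clusters List from [mcode_clusters()].
#' @export
mcode_table <- function(clusters) {
  if (!length(clusters))
    return(data.frame(cluster = integer(0), seed = character(0),
                      score = numeric(0), n_members = integer(0),
                      members = character(0), stringsAsFactors = FALSE))
  data.frame(
    cluster = seq_along(clusters),
    seed = vapply(clusters, `[[`, "", "seed"),
    score = vapply(clusters, `[[`, 0, "score"),
    n_members = vapply(clusters, function(cl) length(cl$members), 0L),
    members = vapply(clusters, function(cl) paste(cl$members, collapse = ","), ""),
    stringsAsFactors = FALSE)
}
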