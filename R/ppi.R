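#' @title Protein-protein interaction subnetworks and hubs
#' @description Build a confidence-thresholded interaction graph from a
#'   STRING-style edge list, detect densely connected subnetworks with an
#'   MCODE-style algorithm (core-clustering-coefficient vertex weights,
#'   seeded greedy expansion, k-core post-processing) and call hub genes by
#'   normalized betweenness centrality.
#' @name ppi_network
NULL

#' Build an interaction graph from an edge table
#'
#' @param edges data.frame with columns `node1`, `node2`, `combined_score`
#'   (STRING-style combined confidence, 0-1000).
#' @param threshold minimum combined score for an edge to be retained
#'   (default 400, STRING's "medium confidence").
#' @return simple undirected [igraph::graph] with edge attribute `score` and
#'   graph attribute `score_threshold`; self-loops and duplicate edges are
#'   removed (duplicates keep the highest score) and isolated nodes are not
#'   represented.
#' @export
interaction_graph <- function(edges, threshold = 400) {
  stop_if_not_df(edges, c("node1", "node2", "combined_score"), "edges")
  score <- suppressWarnings(as.numeric(edges$combined_score))
  bad <- is.na(score) | is.na(edges$node1) | is.na(edges$node2) |
    !nzchar(as.character(edges$node1)) | !nzchar(as.character(edges$node2))
  if (any(bad))
    warning("skipping malformed edge row(s): ",
            paste(utils::head(which(bad), 10), collapse = ", "), call. = FALSE)
  e <- edges[!bad, , drop = FALSE]
  score <- score[!bad]
  loop <- as.character(e$node1) == as.character(e$node2)
  if (any(loop)) warning(sum(loop), " self-loop row(s) dropped", call. = FALSE)
  keep <- !loop & score >= threshold
  e <- e[keep, , drop = FALSE]
  score <- score[keep]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$node1), to = as.character(e$node2),
               score = score, stringsAsFactors = FALSE),
    directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(score = "max"))
  g <- igraph::set_graph_attr(g, "score_threshold", threshold)
  message(sprintf("interaction graph: %d nodes, %d edges (score >= %d)",
                  igraph::vcount(g), igraph::ecount(g), threshold))
  g
}

#' Read a STRING-style TSV edge list
#'
#' @param path TSV with header columns `node1`, `node2`, `combined_score`.
#' @inheritParams interaction_graph
#' @export
read_edge_list <- function(path, threshold = 400) {
  interaction_graph(utils::read.delim(path, stringsAsFactors = FALSE), threshold)
}

#' MCODE parameter set
#'
#' Numeric defaults follow the standard parameterization for complex
#' detection in interaction networks: degree cutoff 2, node density cutoff
#' 0.3, node score cutoff 0.2, k-core 4, max depth 100.
#'
#' @param degree_cutoff minimum degree for a node to receive a weight.
#' @param node_density_cutoff neighbourhood-density bound used by `fluff`.
#' @param node_score_cutoff fraction below the seed weight still admitted
#'   during expansion.
#' @param k_core clusters must contain a k-core of this order.
#' @param max_depth maximum breadth-first expansion depth from the seed.
#' @param haircut drop singly-connected cluster members (default TRUE).
#' @param fluff add boundary nodes with dense neighbourhoods (default FALSE).
#' @return object of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2, node_density_cutoff = 0.3,
                         node_score_cutoff = 0.2, k_core = 4, max_depth = 100,
                         haircut = TRUE, fluff = FALSE) {
  stopifnot(degree_cutoff > 0, node_density_cutoff > 0, node_score_cutoff > 0,
            k_core > 0, max_depth > 0)
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_density_cutoff = node_density_cutoff,
                 node_score_cutoff = node_score_cutoff,
                 k_core = as.integer(k_core),
                 max_depth = as.integer(max_depth),
                 haircut = isTRUE(haircut), fluff = isTRUE(fluff)),
            class = "mcode_params")
}

.subgraph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weights
#'
#' For each node with degree >= `degree_cutoff`, the weight is the density
#' of the highest k-core of the node's closed neighbourhood multiplied by
#' that core's order k (the core-clustering coefficient scheme). Other nodes
#' weigh 0.
#'
#' @param g interaction graph.
#' @param params an [mcode_params()].
#' @return numeric vector named by node.
#' @export
mcode_vertex_weights <- function(g, params = mcode_params()) {
  deg <- igraph::degree(g)
  w <- stats::setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  for (v in which(deg >= params$degree_cutoff)) {
    nb <- igraph::neighborhood(g, order = 1, nodes = v)[[1]]
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    core_sub <- igraph::induced_subgraph(sub, which(core == kmax))
    w[v] <- kmax * .subgraph_density(core_sub)
  }
  w
}

#' Detect dense subnetworks (MCODE-style)
#'
#' Seeds are taken in decreasing vertex-weight order (ties by node id).
#' From each unused seed, a breadth-first expansion (depth <= `max_depth`)
#' admits unused neighbours whose weight is at least
#' `seed weight * (1 - node_score_cutoff)`; each node joins at most one
#' cluster. Clusters whose members do not contain a k-core of order
#' `k_core` are discarded; `haircut` then removes singly-connected members
#' (single pass) and `fluff` optionally adds boundary nodes whose closed
#' neighbourhood in the full graph is denser than `node_density_cutoff`.
#' Clusters are scored by subgraph density times size and returned in
#' decreasing score order.
#'
#' @inheritParams mcode_vertex_weights
#' @return object of class `mcode_clusters`: list of clusters, each a list
#'   with `members`, `seed`, `score`, `size`, `n_edges`.
#' @export
mcode_clusters <- function(g, params = mcode_params()) {
  n <- igraph::vcount(g)
  if (n == 0)
    return(structure(list(), class = "mcode_clusters"))
  w <- mcode_vertex_weights(g, params)
  nm <- igraph::V(g)$name
  used <- logical(n)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  clusters <- list()
  for (seed in order(-w, nm)) {
    if (used[seed] || w[seed] <= 0) next
    thr <- w[seed] * (1 - params$node_score_cutoff)
    members <- seed
    used[seed] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) && depth < params$max_depth) {
      nbrs <- unique(unlist(lapply(adj[frontier], as.integer)))
      nbrs <- nbrs[!used[nbrs] & w[nbrs] >= thr]
      if (!length(nbrs)) break
      used[nbrs] <- TRUE
      members <- c(members, nbrs)
      frontier <- nbrs
      depth <- depth + 1
    }
    clusters[[length(clusters) + 1]] <- list(seed = seed, members = members)
  }
  out <- list()
  for (cl in clusters) {
    sub <- igraph::induced_subgraph(g, cl$members)
    if (max(igraph::coreness(sub)) < params$k_core) next
    members <- cl$members
    if (params$haircut) {
      keep <- igraph::degree(sub) >= 2
      members <- members[keep]
      sub <- igraph::induced_subgraph(g, members)
    }
    if (params$fluff) {
      # boundary nodes join when their open neighbourhood (the candidate
      # itself excluded) is dense: a sparse hub's star would otherwise pass
      # on its own spokes
      boundary <- setdiff(unique(unlist(lapply(adj[members], as.integer))), members)
      dens_ok <- vapply(boundary, function(v) {
        nb <- setdiff(as.integer(adj[[v]]), v)
        .subgraph_density(igraph::induced_subgraph(g, nb)) > params$node_density_cutoff
      }, logical(1))
      members <- c(members, boundary[dens_ok])
      sub <- igraph::induced_subgraph(g, members)
    }
    if (length(members) < 2) next
    out[[length(out) + 1]] <- list(
      members = sort(nm[members]),
      seed = nm[cl$seed],
      score = .subgraph_density(sub) * length(members),
      size = length(members),
      n_edges = igraph::ecount(sub))
  }
  if (length(out)) {
    ord <- order(-vapply(out, `[[`, numeric(1), "score"),
                 vapply(out, `[[`, character(1), "seed"))
    out <- out[ord]
  }
  structure(out, class = "mcode_clusters")
}

#' @export
print.mcode_clusters <- function(x, ...) {
  cat(sprintf("MCODE subnetworks: %d cluster(s)\n", length(x)))
  for (i in seq_along(x)) {
    cl <- x[[i]]
    cat(sprintf("  [%d] score %.2f, %d nodes / %d edges, seed %s\n",
                i, cl$score, cl$size, cl$n_edges, cl$seed))
  }
  invisible(x)
}

#' Normalized betweenness centrality
#'
#' Raw betweenness divided, within each connected component of size n, by
#' `(n - 1)(n - 2) / 2` (undirected), so values lie in [0, 1]. Nodes in
#' components smaller than 3 score 0.
#'
#' @param g interaction graph.
#' @return numeric vector named by node.
#' @export
betweenness_centrality <- function(g) {
  raw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  comp <- igraph::components(g)
  csize <- comp$csize[comp$membership]
  norm <- ifelse(csize > 2, raw / ((csize - 1) * (csize - 2) / 2), 0)
  stats::setNames(as.numeric(norm), igraph::V(g)$name)
}

#' Hub-calling configuration
#'
#' @param candidate_threshold normalized betweenness above which a node is a
#'   candidate hub (default 0.5).
#' @param scope `"whole_graph"` (default) computes betweenness on the full
#'   network; `"per_cluster"` recomputes it within each cluster subgraph.
#' @return object of class `hub_config`.
#' @export
hub_config <- function(candidate_threshold = 0.5,
                       scope = c("whole_graph", "per_cluster")) {
  scope <- match.arg(scope)
  if (candidate_threshold <= 0 || candidate_threshold >= 1)
    stop("`candidate_threshold` must lie in (0, 1)", call. = FALSE)
  structure(list(candidate_threshold = candidate_threshold, scope = scope),
            class = "hub_config")
}

#' Call candidate hubs and per-cluster main hubs
#'
#' Candidates are nodes whose normalized betweenness exceeds the threshold
#' within the configured scope; each cluster's main hub is the member with
#' the highest betweenness (ties broken by lower node id).
#'
#' @param g interaction graph.
#' @param clusters optional [mcode_clusters()] result.
#' @param cfg a [hub_config()].
#' @return list with `betweenness` (whole-graph normalized scores),
#'   `candidates` (character vector) and `main_hubs` (one per cluster).
#' @export
betweenness_hubs <- function(g, clusters = NULL, cfg = hub_config()) {
  stopifnot(inherits(cfg, "hub_config"))
  bc <- betweenness_centrality(g)
  cluster_bc <- function(cl) {
    if (cfg$scope == "whole_graph") bc[cl$members]
    else betweenness_centrality(igraph::induced_subgraph(g, cl$members))
  }
  main_hubs <- character(0)
  if (length(clusters)) {
    main_hubs <- vapply(clusters, function(cl) {
      b <- cluster_bc(cl)
      names(b)[order(-b, names(b))][1]
    }, character(1))
  }
  candidates <- if (cfg$scope == "whole_graph") {
    sort(names(bc)[bc > cfg$candidate_threshold])
  } else {
    sort(unique(unlist(lapply(clusters, function(cl) {
      b <- cluster_bc(cl)
      names(b)[b > cfg$candidate_threshold]
    }))))
  }
  list(betweenness = bc, candidates = candidates, main_hubs = main_hubs)
}
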