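# Ring-system co-occurrence networks: nodes are ring systems, an edge joins
# two ring systems that occur together in at least one molecule. Graphs are
# simple and undirected; repeated co-occurrence raises the edge weight.
# Built on igraph; community structure via edge-betweenness (Girvan-Newman)
# with the best-modularity cut as default.

#' Build the scaffold co-occurrence graph
#'
#' @param rings The `rings` data.frame from [fragment_library()].
#' @param records Optional library data.frame (`id`, `phase`) used to
#'   annotate nodes with the highest phase in which each ring occurs.
#' @return An `igraph` object; vertex attributes `name` (ring key),
#'   `frequency` (number of molecules containing the ring) and
#'   `highest_phase`; edge attribute `weight` (number of molecules
#'   containing both endpoints).
#' @export
build_scaffold_graph <- function(rings, records = NULL) {
  keys <- unique(rings$ring_key)
  by_mol <- lapply(split(rings$ring_key, rings$molecule_id), unique)
  pairs <- list()
  for (rs in by_mol) {
    if (length(rs) < 2L) next
    rs <- sort(rs)
    cmb <- utils::combn(rs, 2)
    pairs[[length(pairs) + 1L]] <- data.frame(a = cmb[1, ], b = cmb[2, ],
                                              stringsAsFactors = FALSE)
  }
  if (length(pairs)) {
    ed <- do.call(rbind, pairs)
    key <- paste(ed$a, ed$b, sep = "\r")
    w <- table(key)
    uk <- strsplit(names(w), "\r", fixed = TRUE)
    edges <- data.frame(a = vapply(uk, `[`, character(1), 1),
                        b = vapply(uk, `[`, character(1), 2),
                        weight = as.integer(w), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(a = character(), b = character(),
                        weight = integer(), stringsAsFactors = FALSE)
  }
  freq <- vapply(split(rings$molecule_id, rings$ring_key),
                 function(m) length(unique(m)), integer(1))
  hp <- rep(NA_character_, length(keys))
  names(hp) <- keys
  if (!is.null(records)) {
    ph <- stats::setNames(records$phase, records$id)
    for (k in keys) {
      mols <- unique(rings$molecule_id[rings$ring_key == k])
      pr <- phase_rank(ph[mols])
      if (any(!is.na(pr))) hp[k] <- PHASE_LEVELS[max(pr, na.rm = TRUE)]
    }
  }
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = keys,
                          frequency = as.integer(freq[keys]),
                          highest_phase = unname(hp),
                          stringsAsFactors = FALSE))
}

#' Density of a simple undirected graph from its node and edge counts
#'
#' `2E / (N (N - 1))`; 0 when fewer than two nodes. Vectorized, so printed
#' node/edge count tables can be converted to densities directly.
#'
#' @param n_nodes,n_edges Node and edge counts.
#' @return Numeric vector of densities.
#' @export
graph_density <- function(n_nodes, n_edges) {
  ifelse(n_nodes >= 2, 2 * n_edges / (n_nodes * (n_nodes - 1)), 0)
}

#' Network statistics
#'
#' @param graph An igraph scaffold graph.
#' @return A list of class `network_stats`: `n_nodes`, `n_edges`,
#'   `isolated_fraction`, `density` and `density_x100` (the density scaled
#'   by 100 for table parity).
#' @export
network_stats <- function(graph) {
  n <- igraph::vcount(graph)
  e <- igraph::ecount(graph)
  dens <- graph_density(n, e)
  iso <- if (n > 0) sum(igraph::degree(graph) == 0) / n else 0
  structure(list(n_nodes = n, n_edges = e,
                 isolated_fraction = iso,
                 density = dens, density_x100 = 100 * dens),
            class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("nodes %d  edges %d  isolated %.2f  density %.4g (%.2f x10^-2)\n",
              x$n_nodes, x$n_edges, x$isolated_fraction, x$density,
              x$density_x100))
  invisible(x)
}

#' Girvan-Newman clustering of a scaffold graph
#'
#' Divisive community detection by repeated removal of the highest
#' edge-betweenness edge. By default the partition with maximal modularity
#' along the removal hierarchy is returned; `n_clusters` requests a
#' specific number of communities instead. Isolated nodes become singleton
#' clusters. Clusters are numbered by decreasing size (cluster 1 is the
#' largest).
#'
#' @param graph An igraph scaffold graph.
#' @param n_clusters Optional number of communities to cut the hierarchy
#'   at; must be at least the number of connected components.
#' @return A data.frame with columns `ring_key`, `cluster`.
#' @export
cluster_girvan_newman <- function(graph, n_clusters = NULL) {
  g <- graph
  if ("weight" %in% igraph::edge_attr_names(g)) {
    g <- igraph::delete_edge_attr(g, "weight")  # clustering is unweighted
  }
  if (igraph::ecount(g) == 0L) {
    member <- seq_len(igraph::vcount(g))
  } else {
    comm <- igraph::cluster_edge_betweenness(g)
    member <- if (is.null(n_clusters)) igraph::membership(comm) else
      igraph::cut_at(comm, no = n_clusters)
  }
  sizes <- table(member)
  # renumber clusters by decreasing size (ties by first label)
  rank <- match(as.character(member),
                names(sort(sizes, decreasing = TRUE)))
  data.frame(ring_key = igraph::V(graph)$name,
             cluster = as.integer(rank),
             stringsAsFactors = FALSE)
}

#' Centrality ranking of ring systems
#'
#' Ranks nodes by degree, eigenvector or betweenness centrality. Ties are
#' broken by ascending molecular weight of the ring system, then by
#' lexicographic ring key, mirroring the convention of ranking by
#' descending frequency of connections and then ascending molecular weight.
#'
#' @param graph An igraph scaffold graph.
#' @param kind One of `"degree"`, `"eigenvector"`, `"betweenness"`.
#' @return A data.frame ordered by rank: `ring_key`, `score`, `rank`.
#' @export
scaffold_centrality <- function(graph,
                                kind = c("degree", "eigenvector",
                                         "betweenness")) {
  kind <- match.arg(kind)
  g <- graph
  if ("weight" %in% igraph::edge_attr_names(g)) {
    g <- igraph::delete_edge_attr(g, "weight")
  }
  score <- switch(kind,
    degree = igraph::degree(g),
    eigenvector = {
      if (igraph::ecount(g) == 0L) {
        stop("eigenvector centrality requires a graph with at least one edge")
      }
      ec <- igraph::eigen_centrality(g)
      if (!is.null(ec$options) && !is.null(ec$options$info) &&
          ec$options$info != 0) {
        stop("eigenvector centrality did not converge (ARPACK info = ",
             ec$options$info, ", iterations = ", ec$options$iter, ")")
      }
      ec$vector
    },
    betweenness = igraph::betweenness(g))
  keys <- igraph::V(graph)$name
  mols <- parse_smiles(keys)
  mw <- vapply(mols, function(m) if (is.null(m)) Inf else mol_weight(m),
               numeric(1))
  ord <- order(-score, mw, keys)
  data.frame(ring_key = keys[ord], score = unname(score[ord]),
             rank = seq_along(keys), stringsAsFactors = FALSE)
}

#' Flag target-specific ring systems
#'
#' A ring system is target-specific when strictly more than half of the
#' molecules it appears in carry the target label.
#'
#' @param rings The `rings` data.frame from [fragment_library()].
#' @param records Library data.frame with `id` and `target_classes`
#'   (`;`-separated labels).
#' @param target Target-class label (e.g. `"kinase"`).
#' @return A data.frame: `ring_key`, `n_molecules`, `n_target`,
#'   `target_specific`.
#' @export
label_target_specific <- function(rings, records, target) {
  tc <- strsplit(records$target_classes, ";", fixed = TRUE)
  has <- vapply(tc, function(x) target %in% trimws(x), logical(1))
  names(has) <- records$id
  by_ring <- split(rings$molecule_id, rings$ring_key)
  out <- data.frame(
    ring_key = names(by_ring),
    n_molecules = vapply(by_ring, function(m) length(unique(m)), integer(1)),
    n_target = vapply(by_ring, function(m) sum(has[unique(m)], na.rm = TRUE),
                      integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out$target_specific <- out$n_target > out$n_molecules / 2
  out
}

#' Export a scaffold graph
#'
#' Writes GraphML plus a node/edge CSV pair (and a JSON export when
#' jsonlite is available). A cluster membership column is included when
#' `clusters` is supplied.
#'
#' @param graph An igraph scaffold graph.
#' @param prefix Output path prefix; files `<prefix>.graphml`,
#'   `<prefix>_nodes.csv`, `<prefix>_edges.csv` (and `<prefix>.json`) are
#'   written.
#' @param clusters Optional data.frame from [cluster_girvan_newman()].
#' @return Invisibly, the vector of files written.
#' @export
export_scaffold_graph <- function(graph, prefix, clusters = NULL) {
  nodes <- data.frame(ring_key = igraph::V(graph)$name,
                      frequency = igraph::V(graph)$frequency,
                      highest_phase = igraph::V(graph)$highest_phase,
                      degree = igraph::degree(graph),
                      stringsAsFactors = FALSE)
  if (!is.null(clusters)) {
    nodes$cluster <- clusters$cluster[match(nodes$ring_key,
                                            clusters$ring_key)]
  }
  el <- igraph::as_data_frame(graph, what = "edges")
  files <- c(paste0(prefix, ".graphml"), paste0(prefix, "_nodes.csv"),
             paste0(prefix, "_edges.csv"))
  igraph::write_graph(graph, files[1], format = "graphml")
  utils::write.csv(nodes, files[2], row.names = FALSE)
  utils::write.csv(el, files[3], row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jf <- paste0(prefix, ".json")
    jsonlite::write_json(list(nodes = nodes, edges = el), jf,
                         dataframe = "rows", auto_unbox = TRUE)
    files <- c(files, jf)
  }
  invisible(files)
}
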