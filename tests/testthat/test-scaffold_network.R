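# A small fragmented library with two ring "communities" bridged by nothing:
# molecules m1-m3 combine rings A/B/C, molecules m4-m6 combine D/E/F.
toy_rings <- function() {
  keyify <- function(x) canonical_smiles(x)
  A <- keyify("c1ccccc1"); B <- keyify("c1ccncc1"); C <- keyify("C1CCNCC1")
  D <- keyify("C1COC1");   E <- keyify("C1CSC1");   F <- keyify("C1CCOC1")
  rings <- data.frame(
    molecule_id = c("m1", "m1", "m2", "m2", "m3", "m3",
                    "m4", "m4", "m5", "m5", "m6", "m6", "m7"),
    ring_key = c(A, B, B, C, A, C,
                 D, E, E, F, D, F, A),
    stringsAsFactors = FALSE)
  list(rings = rings, keys = c(A = A, B = B, C = C, D = D, E = E, F = F))
}

toy_records <- function() {
  data.frame(id = sprintf("m%d", 1:7),
             phase = c("drug", "phase1", "phase2", "phase3",
                       "phase1", "phase1", "drug"),
             target_classes = c("kinase", "kinase", "", "kinase",
                                "", "", "kinase"),
             stringsAsFactors = FALSE)
}

test_that("scaffold graph has co-occurrence edges and annotated nodes", {
  t <- toy_rings()
  g <- build_scaffold_graph(t$rings, toy_records())
  expect_equal(igraph::vcount(g), 6L)
  expect_equal(igraph::ecount(g), 6L)  # two triangles
  expect_true(igraph::are_adjacent(g, t$keys["A"], t$keys["B"]))
  expect_false(igraph::are_adjacent(g, t$keys["A"], t$keys["D"]))
  vA <- igraph::V(g)[t$keys["A"]]
  expect_equal(vA$frequency, 3L)      # m1, m3, m7
  expect_equal(vA$highest_phase, "drug")
  expect_equal(igraph::V(g)[t$keys["D"]]$highest_phase, "phase3")
  # repeated co-occurrence raises the weight
  rings2 <- rbind(t$rings,
                  data.frame(molecule_id = c("m8", "m8"),
                             ring_key = c(t$keys["A"], t$keys["B"]),
                             stringsAsFactors = FALSE))
  g2 <- build_scaffold_graph(rings2)
  eid <- igraph::get_edge_ids(g2, c(t$keys["A"], t$keys["B"]))
  expect_equal(igraph::E(g2)$weight[eid], 2L)
})

test_that("network_stats computes density and isolated fraction", {
  t <- toy_rings()
  rings <- rbind(t$rings,
                 data.frame(molecule_id = "m9",
                            ring_key = canonical_smiles("C1CC1"),
                            stringsAsFactors = FALSE))
  st <- network_stats(build_scaffold_graph(rings))
  expect_equal(st$n_nodes, 7L)
  expect_equal(st$n_edges, 6L)
  expect_equal(st$density, 2 * 6 / (7 * 6))
  expect_equal(st$density_x100, 100 * st$density)
  expect_equal(st$isolated_fraction, 1 / 7)
})

test_that("graph_density follows 2E/(N(N-1)) and handles tiny graphs", {
  expect_equal(graph_density(4, 3), 0.5)
  expect_equal(graph_density(1, 0), 0)
  expect_equal(graph_density(c(4, 1), c(3, 0)), c(0.5, 0))
})

test_that("Girvan-Newman separates the two planted communities", {
  t <- toy_rings()
  cl <- cluster_girvan_newman(build_scaffold_graph(t$rings))
  expect_equal(sort(unique(cl$cluster)), 1:2)
  grp <- split(cl$ring_key, cl$cluster)
  expect_true(setequal(grp[[1]], t$keys[c("A", "B", "C")]) ||
                setequal(grp[[1]], t$keys[c("D", "E", "F")]))
})

test_that("cluster count can be forced and clusters are size-ordered", {
  t <- toy_rings()
  rings <- t$rings[t$rings$molecule_id %in% c("m1", "m2", "m3", "m4"), ]
  g <- build_scaffold_graph(rings)  # triangle ABC plus edge DE
  cl <- cluster_girvan_newman(g)
  sizes <- table(cl$cluster)
  expect_equal(as.integer(sizes), sort(as.integer(sizes), decreasing = TRUE))
  expect_equal(sum(cl$cluster == 1), 3L)  # largest first
  cl4 <- cluster_girvan_newman(g, n_clusters = 3)
  expect_equal(length(unique(cl4$cluster)), 3L)
  # edgeless graph: all singletons
  g0 <- build_scaffold_graph(data.frame(molecule_id = c("x", "y"),
                                        ring_key = t$keys[c("A", "B")],
                                        stringsAsFactors = FALSE))
  expect_equal(sort(cluster_girvan_newman(g0)$cluster), 1:2)
})

test_that("centrality rankings order by score with MW tie-break", {
  t <- toy_rings()
  rings <- rbind(t$rings,
                 data.frame(molecule_id = "m10",
                            ring_key = c(t$keys["A"], t$keys["D"]),
                            stringsAsFactors = FALSE))
  g <- build_scaffold_graph(rings)
  deg <- scaffold_centrality(g, "degree")
  # A (benzene) and D (oxetane) are tied at degree 3; the lighter oxetane
  # wins the ascending-MW tie-break
  expect_equal(deg$ring_key[1:2], unname(t$keys[c("D", "A")]))
  expect_equal(deg$rank, seq_len(nrow(deg)))
  expect_equal(deg$score, sort(deg$score, decreasing = TRUE))
  bet <- scaffold_centrality(g, "betweenness")
  expect_true(bet$ring_key[1] %in% t$keys[c("A", "D")])
  eig <- scaffold_centrality(g, "eigenvector")
  expect_equal(nrow(eig), igraph::vcount(g))
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g0)$name <- c("a", "b", "c")
  expect_error(scaffold_centrality(g0, "eigenvector"), "edge")
})

test_that("target-specific labeling uses the strict majority rule", {
  t <- toy_rings()
  lab <- label_target_specific(t$rings, toy_records(), "kinase")
  # A in m1(k), m3(-), m7(k): 2/3 -> specific
  expect_true(lab$target_specific[lab$ring_key == t$keys["A"]])
  # C in m2(-), m3(k): exactly half -> not specific (strict >)
  expect_false(lab$target_specific[lab$ring_key == t$keys["C"]])
  # D in m4(k), m6(-): half -> not specific
  expect_false(lab$target_specific[lab$ring_key == t$keys["D"]])
  # B in m1(k), m2(k): 2/2 -> specific
  expect_true(lab$target_specific[lab$ring_key == t$keys["B"]])
})

test_that("graph export writes GraphML, CSV and JSON artifacts", {
  t <- toy_rings()
  g <- build_scaffold_graph(t$rings, toy_records())
  cl <- cluster_girvan_newman(g)
  prefix <- file.path(withr::local_tempdir(), "net")
  files <- export_scaffold_graph(g, prefix, clusters = cl)
  expect_true(all(file.exists(files)))
  nodes <- read.csv(paste0(prefix, "_nodes.csv"), stringsAsFactors = FALSE)
  expect_setequal(nodes$ring_key, unname(t$keys))
  expect_true("cluster" %in% names(nodes))
  edges <- read.csv(paste0(prefix, "_edges.csv"), stringsAsFactors = FALSE)
  expect_equal(nrow(edges), 6L)
  g2 <- igraph::read_graph(paste0(prefix, ".graphml"), format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
})
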