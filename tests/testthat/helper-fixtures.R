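# toy graph builders shared across test files

path_graph <- function(nodes = c("s", "v", "t"), weight = 1) {
  n <- length(nodes)
  gene_network(data.frame(from = nodes[-n], to = nodes[-1],
                          weight = rep(weight, n - 1)))
}

# connected random weighted graph on <= 8 nodes for oracle comparisons
random_toy_graph <- function(n, p = 0.45) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::ecount(g) >= n - 1 && igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- letters[seq_len(n)]
  igraph::E(g)$weight <- round(stats::runif(igraph::ecount(g), 0.1, 1), 2)
  g
}

# random subnetwork with seed/linker roles for ranking-score tests
random_subnetwork <- function(n_nodes = 8, n_seeds = 3, p = 0.5) {
  g <- random_toy_graph(n_nodes, p)
  nodes <- igraph::V(g)$name
  seeds <- sample(nodes, n_seeds)
  roles <- ifelse(nodes %in% seeds, "seed", "linker")
  names(roles) <- nodes
  structure(list(graph = g, roles = roles), class = "subnetwork")
}

# independent RS oracle: adjacency-matrix row sums with a seed multiplier
rs_oracle <- function(sub) {
  A <- igraph::as_adjacency_matrix(sub$graph, attr = "weight",
                                   sparse = FALSE)
  nodes <- rownames(A)
  mult <- ifelse(sub$roles[nodes] == "seed", 2, 1)
  linkers <- nodes[sub$roles[nodes] == "linker"]
  sapply(linkers, function(g) sum(A[g, ] * mult))
}

write_toy_expression <- function(mat, path = tempfile(fileext = ".tsv")) {
  write_expression_matrix(mat, path)
  path
}
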