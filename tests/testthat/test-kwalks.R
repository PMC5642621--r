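test_that("transition models are weight-proportional and row-stochastic", {
  g <- path_graph(c("A", "B", "C"))
  tm <- build_transition(g, "A", "C")
  P <- as.matrix(tm$P)
  expect_equal(P["A", "B"], 1)
  expect_equal(P["B", "A"], 0.5)
  expect_equal(P["B", "C"], 0.5)
  expect_equal(sum(P["C", ]), 0)  # absorbing

  star <- gene_network(data.frame(from = "hub", to = c("x", "y", "z"),
                                  weight = 1))
  tm2 <- build_transition(star, "hub", "z")
  expect_equal(unname(as.matrix(tm2$P)["hub", c("x", "y", "z")]),
               rep(1 / 3, 3))

  tri <- gene_network(data.frame(from = c("A", "A"), to = c("B", "C"),
                                 weight = c(0.2, 0.8)))
  tm3 <- build_transition(tri, "A", "B")
  expect_equal(as.matrix(tm3$P)["A", "B"], 0.2)
  expect_equal(as.matrix(tm3$P)["A", "C"], 0.8)

  iso <- gene_network(data.frame(from = "A", to = "B", weight = 1),
                      nodes = "Z")
  expect_error(build_transition(iso, "Z", "A"), "isolated")
  expect_error(build_transition(g, "A", character(0)))
  expect_error(build_transition(g, "A", "A"), "absorbing")
})

test_that("path-graph relevances match hand-enumerated walks", {
  g <- path_graph(c("s", "v", "t"))
  r <- limited_kwalks_relevance(g, c("s", "t"), L = 2)
  # only absorbed 2-step walk is s-v-t (prob 0.5 from v): both edges
  # traversed once, absorption mass 0.5 per start
  expect_equal(r$edge_relevance$relevance, c(1, 1))
  expect_equal(unname(r$absorption_mass), c(0.5, 0.5))

  r4 <- limited_kwalks_relevance(g, c("s", "t"), L = 4)
  # walks svt (p=.5) and svsvt (p=.25): Z = 0.75
  expect_equal(unname(r4$absorption_mass), c(0.75, 0.75))

  # sum of edge relevances = conditional expected walk length
  len2 <- sum(r$edge_relevance$relevance)
  expect_equal(len2, 2)
  len4 <- sum(r4$edge_relevance$relevance)
  expect_equal(len4, (0.5 * 2 + 0.25 * 4) / 0.75)

  expect_error(limited_kwalks_relevance(g, c("s", "t"), L = 1),
               "increase L")
})

test_that("recursion matches the exhaustive-walk oracle on random graphs", {
  set.seed(101)
  n_checked <- 0
  for (i in 1:60) {
    g <- random_toy_graph(sample(4:8, 1), 0.45)
    seeds <- sample(igraph::V(g)$name, sample(2:3, 1))
    L <- sample(1:8, 1)
    a <- tryCatch(limited_kwalks_relevance(g, seeds, L),
                  error = function(e) "unabsorbed")
    b <- tryCatch(brute_force_relevance(g, seeds, L),
                  error = function(e) "unabsorbed")
    expect_identical(is.character(a), is.character(b))
    if (is.character(a)) next
    n_checked <- n_checked + 1
    expect_equal(a$edge_relevance$relevance, b$edge_relevance$relevance,
                 tolerance = 1e-9)
    expect_equal(a$node_relevance,
                 b$node_relevance[names(a$node_relevance)],
                 tolerance = 1e-9)
    expect_equal(a$absorption_mass, b$absorption_mass, tolerance = 1e-9)
  }
  expect_gte(n_checked, 30)
})

test_that("absorption mass is nondecreasing in the walk budget", {
  set.seed(202)
  for (i in 1:10) {
    g <- random_toy_graph(6, 0.5)
    seeds <- sample(igraph::V(g)$name, 2)
    z <- sapply(2:8, function(L) {
      limited_kwalks_relevance(g, seeds, L)$absorption_mass
    })
    expect_true(all(diff(t(z)) >= -1e-12))
  }
})

test_that("relevance is equivariant under node relabeling", {
  set.seed(303)
  g <- random_toy_graph(6, 0.5)
  seeds <- sample(igraph::V(g)$name, 2)
  r1 <- limited_kwalks_relevance(g, seeds, L = 5)

  relabel <- setNames(paste0("N", sample(6)), igraph::V(g)$name)
  ed <- network_edges(g)
  g2 <- gene_network(data.frame(from = unname(relabel[ed$from]),
                                to = unname(relabel[ed$to]),
                                weight = ed$weight))
  r2 <- limited_kwalks_relevance(g2, unname(relabel[seeds]), L = 5)
  expect_equal(unname(r2$node_relevance[relabel[names(r1$node_relevance)]]),
               unname(r1$node_relevance), tolerance = 1e-12)
  k1 <- setNames(r1$edge_relevance$relevance,
                 edge_key(relabel[r1$edge_relevance$from],
                          relabel[r1$edge_relevance$to]))
  k2 <- setNames(r2$edge_relevance$relevance,
                 edge_key(r2$edge_relevance$from, r2$edge_relevance$to))
  expect_equal(k2[names(k1)], k1, tolerance = 1e-12)
})

test_that("subnetwork extraction connects seeds through linkers", {
  g <- path_graph(c("s", "v", "t"))
  r <- limited_kwalks_relevance(g, c("s", "t"), L = 4)
  sub <- extract_subnetwork(g, r, c("s", "t"))
  expect_equal(igraph::ecount(sub$graph), 2)
  expect_equal(unname(sub$roles[c("s", "v", "t")]),
               c("seed", "linker", "seed"))
  # every linker lies on a selected edge; node count = seeds + linkers
  expect_equal(igraph::vcount(sub$graph),
               sum(sub$roles == "seed") + sum(sub$roles == "linker"))
  expect_true(all(igraph::degree(sub$graph)[sub$roles == "linker"] >= 1))
})

test_that("disconnected seeds stay isolated with a warning", {
  g <- gene_network(rbind(
    data.frame(from = c("s", "v"), to = c("v", "t"), weight = 1),
    data.frame(from = "p", to = "q", weight = 1)))
  r <- limited_kwalks_relevance(g, c("s", "t", "q"), L = 4)
  expect_warning(sub <- extract_subnetwork(g, r, c("s", "t", "q")),
                 "isolated")
  expect_true("q" %in% igraph::V(sub$graph)$name)
  expect_equal(igraph::components(sub$graph)$no, 2)
})

test_that("a high-relevance bridge node is recruited as the linker", {
  # two seeds joined only through b; decoy chain has lower weights
  g <- gene_network(data.frame(
    from = c("s1", "b", "s1", "c", "d"),
    to = c("b", "s2", "c", "d", "s2"),
    weight = c(0.9, 0.9, 0.2, 0.2, 0.2)))
  r <- limited_kwalks_relevance(g, c("s1", "s2"), L = 6)
  sub <- extract_subnetwork(g, r, c("s1", "s2"))
  expect_true("b" %in% names(sub$roles)[sub$roles == "linker"])
  # exhaustive check: among connecting subgraphs of the same edge count,
  # the chosen one maximizes total relevance
  ed <- r$edge_relevance
  n_sel <- igraph::ecount(sub$graph)
  combos <- combn(nrow(ed), n_sel)
  best <- -Inf; chosen <- sum(network_edges(sub$graph)$weight)
  sel_rel <- sum(ed$relevance[paste(ed$from, ed$to) %in%
    paste(network_edges(sub$graph)$from, network_edges(sub$graph)$to)])
  for (k in seq_len(ncol(combos))) {
    rows <- combos[, k]
    gg <- igraph::graph_from_data_frame(ed[rows, c("from", "to")],
                                        directed = FALSE)
    if (all(c("s1", "s2") %in% igraph::V(gg)$name) &&
        igraph::components(gg)$membership["s1"] ==
        igraph::components(gg)$membership["s2"]) {
      best <- max(best, sum(ed$relevance[rows]))
    }
  }
  expect_equal(sel_rel, best, tolerance = 1e-12)
})

test_that("max_edges caps the subnetwork size", {
  set.seed(404)
  g <- random_toy_graph(8, 0.6)
  seeds <- sample(igraph::V(g)$name, 3)
  r <- limited_kwalks_relevance(g, seeds, L = 6)
  sub <- suppressWarnings(extract_subnetwork(g, r, seeds, max_edges = 2))
  expect_lte(igraph::ecount(sub$graph), 2)
})
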