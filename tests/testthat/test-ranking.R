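test_that("ranking score doubles seed edges and sums the rest", {
  g <- gene_network(data.frame(from = c("g", "g"), to = c("s", "h"),
                               weight = c(0.4, 0.3)))
  sub <- structure(list(graph = g,
                        roles = c(g = "linker", s = "seed", h = "linker")),
                   class = "subnetwork")
  rk <- ranking_score(sub)
  expect_equal(rk$rs[rk$gene == "g"], 2 * 0.4 + 0.3)
  expect_equal(rk$rs[rk$gene == "h"], 0.3)

  # linker with no seed edges
  g2 <- gene_network(data.frame(from = c("g", "g"), to = c("a", "b"),
                                weight = c(0.2, 0.3)))
  sub2 <- structure(list(graph = g2,
                         roles = c(g = "linker", a = "linker",
                                   b = "linker")),
                    class = "subnetwork")
  rk2 <- ranking_score(sub2)
  expect_equal(rk2$rs[rk2$gene == "g"], 0.5)
})

test_that("ranking score equals the adjacency-scan oracle", {
  set.seed(55)
  for (i in 1:25) {
    sub <- random_subnetwork(sample(5:8, 1), sample(2:3, 1))
    rk <- ranking_score(sub)
    oracle <- rs_oracle(sub)
    expect_equal(setNames(rk$rs, rk$gene)[names(oracle)], oracle,
                 tolerance = 1e-12)
    # ranks are 1..n with RS nonincreasing, alphabetical within ties
    expect_equal(rk$rank, seq_len(nrow(rk)))
    expect_true(all(diff(rk$rs) <= 1e-12))
  }
})

test_that("RS responds additively to edge removal and role promotion", {
  set.seed(66)
  sub <- random_subnetwork(7, 2)
  rk <- ranking_score(sub)
  ed <- network_edges(sub$graph)
  linkers <- names(sub$roles)[sub$roles == "linker"]
  k <- which(ed$from %in% linkers | ed$to %in% linkers)[1]
  gtouch <- if (ed$from[k] %in% linkers) ed$from[k] else ed$to[k]
  other <- setdiff(c(ed$from[k], ed$to[k]), gtouch)[1]
  m <- if (sub$roles[other] == "seed") 2 else 1

  sub_less <- sub
  sub_less$graph <- igraph::delete_edges(
    sub$graph, igraph::get_edge_ids(sub$graph, c(ed$from[k], ed$to[k])))
  rk_less <- ranking_score(sub_less)
  delta <- setNames(rk$rs, rk$gene)[gtouch] -
    setNames(rk_less$rs, rk_less$gene)[gtouch]
  expect_equal(unname(delta), m * ed$weight[k], tolerance = 1e-12)

  # promoting a linker neighbor to seed adds exactly w
  if (sub$roles[other] == "linker") {
    sub_prom <- sub
    sub_prom$roles[other] <- "seed"
    rk_prom <- ranking_score(sub_prom)
    d2 <- setNames(rk_prom$rs, rk_prom$gene)[gtouch] -
      setNames(rk$rs, rk$gene)[gtouch]
    expect_equal(unname(d2), ed$weight[k], tolerance = 1e-12)
  }
})

test_that("candidate selection applies a strict cutoff or top-k", {
  rt <- load_reference_tables()
  ranked <- data.frame(gene = names(rt$linker_rs),
                       rs = unname(rt$linker_rs))
  ranked <- ranked[order(-ranked$rs, ranked$gene), ]
  ranked$rank <- seq_len(nrow(ranked))
  sel <- select_candidates(ranked, rs_cutoff = 1)
  expect_setequal(sel, c("KRT19", "BARD1", "MST1R", "S100A14",
                         "LGALS1", "RNF168"))
  expect_false(any(c("TFF1", "SPEN") %in% sel))  # RS exactly 1 excluded

  expect_length(select_candidates(ranked, rs_cutoff = max(ranked$rs)), 0)

  set.seed(77)
  rnd <- data.frame(gene = paste0("G", 1:10), rs = runif(10))
  rnd <- rnd[order(-rnd$rs, rnd$gene), ]
  rnd$rank <- 1:10
  expect_equal(select_candidates(rnd, top_k = 3),
               rnd$gene[order(-rnd$rs)][1:3])
  expect_error(select_candidates(rnd), "exactly one")
})

test_that("minimal connecting subnetwork handles canonical topologies", {
  p <- path_graph(c("a", "b", "c", "d", "e"), weight = 0.5)
  mcs <- minimal_connecting_subnetwork(p, c("a", "c", "e"))
  expect_equal(igraph::ecount(mcs$graph), 4)  # the whole path
  expect_setequal(igraph::V(mcs$graph)$name, letters[1:5])

  star <- gene_network(data.frame(from = "hub", to = c("x", "y", "z"),
                                  weight = 0.9))
  mstar <- minimal_connecting_subnetwork(star, c("x", "y", "z"))
  expect_setequal(names(mstar$roles)[mstar$roles == "steiner"], "hub")
  expect_equal(igraph::ecount(mstar$graph), 3)
})

test_that("steiner approximation matches exhaustive search on a toy", {
  # 9 nodes, 4 targets; equal weights so node count is the objective
  set.seed(88)
  g <- random_toy_graph(9 - 1, 0.45)  # 8 named nodes a..h
  ed <- network_edges(g)
  ed$weight <- 0.5
  g <- gene_network(ed[, c("from", "to", "weight")])
  targets <- sample(igraph::V(g)$name, 4)
  mcs <- minimal_connecting_subnetwork(g, targets)
  got_nodes <- igraph::vcount(mcs$graph)

  # exhaustive minimum-node connected subgraph containing all targets
  nodes <- igraph::V(g)$name
  optional <- setdiff(nodes, targets)
  best <- Inf
  for (k in 0:length(optional)) {
    if (length(targets) + k >= best) break
    sets <- if (k == 0) list(character(0)) else
      asplit(combn(optional, k), 2)
    for (s in sets) {
      vs <- c(targets, unlist(s))
      sg <- igraph::induced_subgraph(g, vs)
      if (igraph::is_connected(sg)) {
        best <- min(best, length(vs))
        break
      }
    }
  }
  expect_equal(got_nodes, best)
  # all targets present and connected
  expect_true(all(targets %in% igraph::V(mcs$graph)$name))
  expect_true(igraph::is_connected(mcs$graph))
})

test_that("targets in separate components give a partial result", {
  g <- gene_network(rbind(data.frame(from = "a", to = "b", weight = 0.5),
                          data.frame(from = "x", to = "y", weight = 0.5)))
  expect_warning(mcs <- minimal_connecting_subnetwork(g, c("a", "x")),
                 "separate component")
  expect_setequal(names(mcs$roles)[mcs$roles == "target"], c("a", "x"))
})
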