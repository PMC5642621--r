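#' Absorbing Markov transition model for one start seed
#'
#' Transition probabilities are proportional to edge weights,
#' P(i -> j) = w_ij / sum_k w_ik, rows of transient nodes are stochastic
#' and absorbing nodes (the remaining seeds) have no outgoing
#' probability. This is the chain a bounded walk follows from `start`
#' until it hits any absorbing seed.
#'
#' @param graph igraph gene network with positive weights.
#' @param start start node (a seed).
#' @param absorbing character vector of absorbing nodes (the other
#'   seeds); must not contain `start`.
#' @return list with `P` (sparse row-stochastic matrix, absorbing rows
#'   zero), `nodes`, `start`, `absorbing`, `transient`.
#' @export
build_transition <- function(graph, start, absorbing) {
  nodes <- igraph::V(graph)$name
  stopifnot(start %in% nodes, length(absorbing) >= 1)
  absorbing <- unique(absorbing)
  if (start %in% absorbing) stop("start node cannot be absorbing")
  if (!all(absorbing %in% nodes)) stop("absorbing node not in graph")
  if (igraph::degree(graph, start) == 0) {
    stop("start node '", start, "' is isolated")
  }
  W <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = TRUE)
  W <- methods::as(W, "CsparseMatrix")
  deg <- Matrix::rowSums(W)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  P <- Matrix::Diagonal(x = inv) %*% W
  abs_idx <- match(absorbing, nodes)
  P[abs_idx, ] <- 0
  P <- Matrix::drop0(P)
  dimnames(P) <- list(nodes, nodes)
  list(P = P, nodes = nodes, start = start, absorbing = absorbing,
       transient = setdiff(nodes, absorbing))
}

#' Edge and node relevance by the limited k-walks algorithm
#'
#' Bounded random walks start at one seed and are absorbed at any other
#' seed; the relevance of an edge is the expected number of times an
#' absorbed walk of length at most `L` traverses it, conditioned on
#' absorption. With forward masses `a_l(i)` (probability the walk sits
#' unabsorbed at transient node i after l steps) and backward masses
#' `b_m(j)` (probability of absorption within m further steps from j,
#' with b_m = 1 on absorbing nodes), the per-start relevance of the
#' undirected edge (i, j) is
#'
#'   E_s(i,j) = (1/Z_s) * sum_{l=0}^{L-1}
#'              a_l(i) P(i,j) b_{L-l-1}(j) + a_l(j) P(j,i) b_{L-l-1}(i)
#'
#' where Z_s = b_L(start) is the absorption mass of the start. Node
#' relevance is half the sum of incident edge relevances, plus 1 for the
#' start node. Final relevances average E_s over all starts with
#' positive absorption mass.
#'
#' @param graph igraph gene network.
#' @param seeds a `seed_set` or character vector; >= 2 must be in the
#'   graph.
#' @param L walk length budget (steps), >= 1. Default 50.
#' @return object of class `relevance_scores`: list with
#'   `edge_relevance` (data.frame from, to, weight, relevance),
#'   `node_relevance` (named numeric), `absorption_mass` (named numeric,
#'   one entry per start seed), and `L`.
#' @export
limited_kwalks_relevance <- function(graph, seeds, L = 50) {
  seeds <- as_seed_genes(seeds, graph)
  stopifnot(length(seeds) >= 2, L >= 1)
  nodes <- igraph::V(graph)$name
  n <- length(nodes)
  ed <- network_edges(graph)
  i_idx <- match(ed$from, nodes)
  j_idx <- match(ed$to, nodes)

  W <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = TRUE)
  W <- methods::as(W, "CsparseMatrix")
  deg <- Matrix::rowSums(W)
  Pfull <- Matrix::Diagonal(x = ifelse(deg > 0, 1 / deg, 0)) %*% W
  dimnames(Pfull) <- list(nodes, nodes)

  edge_acc <- numeric(nrow(ed))
  node_acc <- stats::setNames(numeric(n), nodes)
  zmass <- stats::setNames(numeric(length(seeds)), seeds)
  n_used <- 0L

  for (s in seeds) {
    absorbing <- setdiff(seeds, s)
    abs_idx <- match(absorbing, nodes)
    P <- Pfull
    P[abs_idx, ] <- 0

    # forward masses a_l over l = 0..L-1 (columns), transient only
    A <- matrix(0, n, L)
    a <- numeric(n)
    a[match(s, nodes)] <- 1
    A[, 1] <- a
    if (L >= 2) {
      for (l in 2:L) {
        a <- as.numeric(Matrix::crossprod(P, a))
        a[abs_idx] <- 0
        A[, l] <- a
      }
    }
    # backward masses b_m over m = 0..L (columns 1..L+1)
    B <- matrix(0, n, L + 1)
    b <- numeric(n)
    b[abs_idx] <- 1
    B[, 1] <- b
    for (m in 1:L) {
      b <- as.numeric(P %*% b)
      b[abs_idx] <- 1
      B[, m + 1] <- b
    }
    Z <- B[match(s, nodes), L + 1]
    zmass[s] <- Z
    if (Z <= 0) next
    n_used <- n_used + 1L

    # align: column l of A is a_{l-1}; need b_{L-l} -> column L-l+1 of B
    Brev <- B[, L:1, drop = FALSE]
    pij <- Pfull[cbind(i_idx, j_idx)]
    pji <- Pfull[cbind(j_idx, i_idx)]
    # walks cannot leave absorbing nodes for this start
    pij[i_idx %in% abs_idx] <- 0
    pji[j_idx %in% abs_idx] <- 0
    fwd <- rowSums(A[i_idx, , drop = FALSE] * Brev[j_idx, , drop = FALSE])
    bwd <- rowSums(A[j_idx, , drop = FALSE] * Brev[i_idx, , drop = FALSE])
    e_rel <- (pij * fwd + pji * bwd) / Z
    edge_acc <- edge_acc + e_rel

    half <- 0.5 * e_rel
    node_contrib <- stats::setNames(numeric(n), nodes)
    add <- tapply(c(half, half), c(i_idx, j_idx), sum)
    node_contrib[as.integer(names(add))] <- add
    node_contrib[match(s, nodes)] <- node_contrib[match(s, nodes)] + 1
    node_acc <- node_acc + node_contrib
  }

  if (n_used == 0L) {
    stop("no start seed reaches another seed within L = ", L,
         " steps; increase L or check connectivity")
  }
  ed$relevance <- edge_acc / n_used
  structure(list(edge_relevance = ed,
                 node_relevance = node_acc / n_used,
                 absorption_mass = zmass, L = L),
            class = "relevance_scores")
}

#' Exhaustive-walk oracle for the limited k-walks relevance
#'
#' Enumerates every walk from each start seed that is absorbed by another
#' seed within `L` steps, weights each by its path probability, and
#' tallies edge passages — the defining quantity the dynamic-programming
#' recursion of [limited_kwalks_relevance()] computes. Intended for
#' verification on small instances only.
#'
#' @param graph igraph gene network with at most 8 nodes.
#' @param seeds a `seed_set` or character vector of seeds in the graph.
#' @param L walk budget, at most 8.
#' @return object of class `relevance_scores` (same aggregation as the
#'   main routine).
#' @export
brute_force_relevance <- function(graph, seeds, L) {
  seeds <- as_seed_genes(seeds, graph)
  nodes <- igraph::V(graph)$name
  if (length(nodes) > 8 || L > 8) {
    stop("enumeration guard: at most 8 nodes and L <= 8")
  }
  ed <- network_edges(graph)
  ekey <- edge_key(ed$from, ed$to)
  eid <- stats::setNames(seq_len(nrow(ed)), ekey)
  W <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = FALSE)
  deg <- rowSums(W)
  P <- W / ifelse(deg > 0, deg, 1)
  dimnames(P) <- list(nodes, nodes)

  edge_acc <- numeric(nrow(ed))
  node_start_acc <- stats::setNames(numeric(length(nodes)), nodes)
  zmass <- stats::setNames(numeric(length(seeds)), seeds)
  n_used <- 0L

  for (s in seeds) {
    absorbing <- setdiff(seeds, s)
    env <- new.env()
    env$edge <- numeric(nrow(ed))
    env$Z <- 0
    recurse <- function(node, prob, steps, path) {
      nbr <- nodes[P[node, ] > 0]
      for (j in nbr) {
        q <- prob * P[node, j]
        id <- eid[[edge_key(node, j)]]
        if (j %in% absorbing) {
          env$Z <- env$Z + q
          tab <- tabulate(c(path, id), nbins = nrow(ed))
          env$edge <- env$edge + q * tab
        } else if (steps + 1 < L) {
          recurse(j, q, steps + 1, c(path, id))
        }
      }
    }
    recurse(s, 1, 0, integer(0))
    zmass[s] <- env$Z
    if (env$Z > 0) {
      n_used <- n_used + 1L
      edge_acc <- edge_acc + env$edge / env$Z
      node_start_acc[s] <- node_start_acc[s] + 1
    }
  }
  if (n_used == 0L) stop("no walk is absorbed within L = ", L, " steps")
  ed$relevance <- edge_acc / n_used
  node_rel <- stats::setNames(numeric(length(nodes)), nodes)
  for (k in seq_len(nrow(ed))) {
    node_rel[ed$from[k]] <- node_rel[ed$from[k]] + ed$relevance[k] / 2
    node_rel[ed$to[k]] <- node_rel[ed$to[k]] + ed$relevance[k] / 2
  }
  node_rel <- node_rel + node_start_acc / n_used
  structure(list(edge_relevance = ed, node_relevance = node_rel,
                 absorption_mass = zmass, L = L),
            class = "relevance_scores")
}

#' Extract the seed-connecting subnetwork from relevance scores
#'
#' Edges enter in decreasing relevance order (ties broken
#' lexicographically by endpoint pair) until every group of mutually
#' reachable seeds shares one connected component; edges tied with the
#' relevance at which connection was achieved are then also included
#' (plateau rule), subject to `max_edges`. Seeds unreachable from every
#' other seed are kept as isolated nodes with a warning. Every node gets
#' a role: `seed` or `linker`.
#'
#' @param graph the network relevance was computed on.
#' @param relevance a `relevance_scores` object for `graph`.
#' @param seeds a `seed_set` or character vector.
#' @param max_edges optional hard cap on the number of edges.
#' @return object of class `subnetwork`: list with `graph` (igraph,
#'   weights from the parent network) and `roles` (named character).
#' @export
extract_subnetwork <- function(graph, relevance, seeds, max_edges = NULL) {
  stopifnot(inherits(relevance, "relevance_scores"))
  seeds <- as_seed_genes(seeds, graph)
  nodes <- igraph::V(graph)$name
  ed <- relevance$edge_relevance
  ed <- ed[ed$relevance > 0, , drop = FALSE]
  ed <- ed[order(-ed$relevance, ed$from, ed$to), , drop = FALSE]

  # seeds mutually reachable through positive-relevance edges must end
  # up in one component; group them by component of that subgraph
  gpos <- gene_network(ed[, c("from", "to", "weight")], nodes = nodes)
  comp <- igraph::components(gpos)$membership[seeds]
  groups <- split(seeds, comp)
  groups <- groups[lengths(groups) >= 2]
  lone <- setdiff(seeds, unlist(groups))
  if (length(lone) > 0) {
    warning("seed(s) unreachable from all other seeds, kept isolated: ",
            paste(lone, collapse = ", "))
  }

  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  groups_idx <- lapply(groups, match, nodes)
  connected <- function() {
    all(vapply(groups_idx, function(g) {
      length(unique(vapply(g, find, integer(1)))) == 1
    }, logical(1)))
  }

  cap <- if (is.null(max_edges)) nrow(ed) else min(max_edges, nrow(ed))
  n_sel <- 0L
  conn_rel <- NA_real_
  done <- length(groups_idx) == 0  # no multi-seed group: nothing to connect
  if (done) cap <- 0L
  for (k in seq_len(cap)) {
    if (done && ed$relevance[k] < conn_rel) break
    ra <- find(match(ed$from[k], nodes))
    rb <- find(match(ed$to[k], nodes))
    if (ra != rb) parent[ra] <- rb
    n_sel <- k
    if (!done && connected()) {
      done <- TRUE
      conn_rel <- ed$relevance[k]
    }
  }
  if (!done && is.null(max_edges)) {
    warning("seed groups could not be fully connected with the available ",
            "positive-relevance edges")
  }
  sel <- ed[seq_len(n_sel), , drop = FALSE]
  sub <- gene_network(sel[, c("from", "to", "weight")], nodes = lone)
  roles <- ifelse(igraph::V(sub)$name %in% seeds, "seed", "linker")
  names(roles) <- igraph::V(sub)$name
  structure(list(graph = sub, roles = roles), class = "subnetwork")
}

# Accept a seed_set or a character vector; keep only seeds in the graph.
as_seed_genes <- function(seeds, graph) {
  genes <- if (inherits(seeds, "seed_set")) seeds$genes else trim_ids(seeds)
  genes[genes %in% igraph::V(graph)$name]
}
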