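#' Ranking score (RS) of linker genes in a subnetwork
#'
#' For each linker gene g, RS(g) is the sum of the weights of all its
#' subnetwork edges, with edges to seed genes counted twice: the link
#' between a seed and a linker carries more evidence than one between
#' two linkers. Seeds themselves are not scored. A larger RS marks a
#' gene more likely to be disease-relevant.
#'
#' @param sub a `subnetwork` (graph plus roles) from
#'   [extract_subnetwork()].
#' @return data.frame with columns `gene`, `rs`, `rank` (1 = highest RS;
#'   ties broken alphabetically), sorted by rank.
#' @export
ranking_score <- function(sub) {
  stopifnot(inherits(sub, "subnetwork"))
  roles <- sub$roles
  linkers <- names(roles)[roles == "linker"]
  if (length(linkers) == 0) {
    warning("subnetwork contains no linker genes")
    return(data.frame(gene = character(0), rs = numeric(0),
                      rank = integer(0)))
  }
  ed <- network_edges(sub$graph)
  rs <- stats::setNames(numeric(length(linkers)), linkers)
  for (k in seq_len(nrow(ed))) {
    a <- ed$from[k]; b <- ed$to[k]; w <- ed$weight[k]
    if (a %in% linkers) {
      rs[a] <- rs[a] + w * (if (roles[b] == "seed") 2 else 1)
    }
    if (b %in% linkers) {
      rs[b] <- rs[b] + w * (if (roles[a] == "seed") 2 else 1)
    }
  }
  ord <- order(-rs, names(rs))
  data.frame(gene = names(rs)[ord], rs = unname(rs[ord]),
             rank = seq_along(rs), row.names = NULL)
}

#' Select candidate genes from a ranked list
#'
#' Either keeps genes with RS strictly greater than `rs_cutoff` (the
#' published selection used RS > 1, which excludes genes sitting exactly
#' at 1), or the `top_k` highest-ranked genes.
#'
#' @param ranked data.frame from [ranking_score()] (columns gene, rs,
#'   rank).
#' @param rs_cutoff strict lower bound on RS.
#' @param top_k alternative rule: keep the first k ranks. Exactly one
#'   rule may be given.
#' @return character vector of selected gene symbols (rank order).
#' @export
select_candidates <- function(ranked, rs_cutoff = NULL, top_k = NULL) {
  stopifnot(nrow(ranked) > 0)
  if (is.null(rs_cutoff) == is.null(top_k)) {
    stop("give exactly one of rs_cutoff or top_k")
  }
  if (!is.null(rs_cutoff)) {
    ranked$gene[ranked$rs > rs_cutoff]
  } else {
    ranked$gene[seq_len(min(top_k, nrow(ranked)))]
  }
}

#' Smallest subnetwork connecting a set of target genes
#'
#' Steiner-style approximation: edge length is 1 - weight (floored at
#' 1e-6 so unit-weight edges still cost something), shortest paths are
#' computed between all target pairs with deterministic lexicographic
#' tie-breaking, a minimum spanning tree is built on the resulting
#' target-to-target distances (Prim, lexicographic ties), and the union
#' of the realized paths is returned. Targets in different components
#' yield a partial result with a warning.
#'
#' @param graph igraph gene network.
#' @param targets character vector of genes to connect (subset of the
#'   graph's nodes).
#' @return object of class `subnetwork`; roles are `target` for the
#'   input genes and `steiner` for recruited connector nodes.
#' @export
minimal_connecting_subnetwork <- function(graph, targets) {
  nodes <- igraph::V(graph)$name
  targets <- sort(unique(trim_ids(targets)))
  if (!all(targets %in% nodes)) {
    stop("target(s) not in graph: ",
         paste(setdiff(targets, nodes), collapse = ", "))
  }
  ed <- network_edges(graph)
  len <- pmax(1 - ed$weight, 1e-6)
  adj <- build_length_adjacency(nodes, ed, len)

  nt <- length(targets)
  dist_tt <- matrix(Inf, nt, nt, dimnames = list(targets, targets))
  paths <- vector("list", nt)
  for (i in seq_len(nt)) {
    sp <- dijkstra_paths(nodes, adj, targets[i])
    dist_tt[i, ] <- sp$dist[targets]
    paths[[i]] <- sp$prev
  }

  comp_warned <- FALSE
  in_tree <- 1L
  sel_edges <- new.env()
  sel_nodes <- targets[1]
  remaining <- setdiff(seq_len(nt), in_tree)
  while (length(remaining) > 0) {
    best <- NULL
    for (j in remaining) {
      for (i in in_tree) {
        d <- dist_tt[i, j]
        if (is.null(best) || d < best$d - 1e-15 ||
            (abs(d - best$d) <= 1e-15 &&
             (targets[i] < targets[best$i] ||
              (targets[i] == targets[best$i] && targets[j] < targets[best$j])))) {
          best <- list(d = d, i = i, j = j)
        }
      }
    }
    if (!is.finite(best$d)) {
      if (!comp_warned) {
        warning("target(s) in a separate component; result is partial: ",
                paste(targets[remaining], collapse = ", "))
        comp_warned <- TRUE
      }
      sel_nodes <- c(sel_nodes, targets[remaining])
      break
    }
    path <- trace_path(paths[[best$i]], nodes, targets[best$i],
                       targets[best$j])
    for (k in seq_len(length(path) - 1)) {
      assign(edge_key(path[k], path[k + 1]), TRUE, envir = sel_edges)
    }
    sel_nodes <- c(sel_nodes, path)
    in_tree <- c(in_tree, best$j)
    remaining <- setdiff(remaining, best$j)
  }

  keys <- edge_key(ed$from, ed$to)
  keep <- keys %in% ls(sel_edges, all.names = TRUE)
  sub <- gene_network(ed[keep, c("from", "to", "weight")],
                      nodes = unique(sel_nodes))
  roles <- ifelse(igraph::V(sub)$name %in% targets, "target", "steiner")
  names(roles) <- igraph::V(sub)$name
  structure(list(graph = sub, roles = roles), class = "subnetwork")
}

# adjacency list of (neighbor index, length) per node, neighbors in
# lexicographic order so Dijkstra ties resolve deterministically
build_length_adjacency <- function(nodes, ed, len) {
  n <- length(nodes)
  adj <- vector("list", n)
  i_idx <- match(ed$from, nodes)
  j_idx <- match(ed$to, nodes)
  for (k in seq_along(i_idx)) {
    adj[[i_idx[k]]] <- rbind(adj[[i_idx[k]]], c(j_idx[k], len[k]))
    adj[[j_idx[k]]] <- rbind(adj[[j_idx[k]]], c(i_idx[k], len[k]))
  }
  for (v in seq_len(n)) {
    if (!is.null(adj[[v]])) {
      adj[[v]] <- adj[[v]][order(nodes[adj[[v]][, 1]]), , drop = FALSE]
    }
  }
  adj
}

# Dijkstra with lexicographic predecessor tie-break: among equal-length
# paths the one whose predecessor name sorts first wins.
dijkstra_paths <- function(nodes, adj, source) {
  n <- length(nodes)
  dist <- rep(Inf, n)
  prev <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  src <- match(source, nodes)
  dist[src] <- 0
  for (iter in seq_len(n)) {
    cand <- which(!visited & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[order(dist[cand], nodes[cand])][1]
    visited[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]
      nd <- dist[u] + nb[r, 2]
      if (nd < dist[v] - 1e-15 ||
          (abs(nd - dist[v]) <= 1e-15 && !is.na(prev[v]) &&
           nodes[u] < nodes[prev[v]])) {
        dist[v] <- nd
        prev[v] <- u
      }
    }
  }
  list(dist = stats::setNames(dist, nodes), prev = prev)
}

trace_path <- function(prev, nodes, source, target) {
  cur <- match(target, nodes)
  src <- match(source, nodes)
  path <- cur
  while (cur != src) {
    cur <- prev[cur]
    path <- c(cur, path)
  }
  nodes[path]
}
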