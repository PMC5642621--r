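#' Construct a weighted gene network
#'
#' Builds the undirected, simple, weighted graph used throughout the
#' pipeline (PPI network, co-expression network, common network,
#' extracted subnetwork). The container is an [igraph::igraph] object
#' with a `weight` edge attribute in (0, 1] and an optional `sign`
#' attribute in {-1, +1} carrying the direction of the underlying
#' correlation.
#'
#' @param edges data.frame with columns `from`, `to`, `weight` and
#'   optionally `sign`. Reciprocal duplicates (`A-B` and `B-A`) are
#'   collapsed to one undirected edge; exact duplicates are an error if
#'   their weights disagree.
#' @param nodes optional character vector of node names; defaults to the
#'   endpoints occurring in `edges`. Extra names add isolated nodes.
#' @return an undirected `igraph` graph with `weight` (and possibly
#'   `sign`) edge attributes.
#' @export
gene_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  required <- c("from", "to", "weight")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0) {
    stop("edge table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  edges$from <- trim_ids(as.character(edges$from))
  edges$to <- trim_ids(as.character(edges$to))
  if (nrow(edges) > 0) {
    if (any(edges$from == edges$to)) {
      stop("self-loops are not allowed in a gene network")
    }
    if (any(!is.finite(edges$weight) | edges$weight <= 0 | edges$weight > 1)) {
      stop("edge weights must be finite, > 0 and <= 1")
    }
    key <- edge_key(edges$from, edges$to)
    if (anyDuplicated(key)) {
      first <- !duplicated(key)
      w_first <- edges$weight[first][match(key, key[first])]
      if (any(abs(w_first - edges$weight) > 1e-12)) {
        stop("duplicate undirected edges with conflicting weights")
      }
      edges <- edges[first, , drop = FALSE]
    }
  }
  node_names <- sort(unique(c(edges$from, edges$to, trim_ids(nodes))))
  g <- igraph::make_empty_graph(n = length(node_names), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = node_names)
  if (nrow(edges) > 0) {
    ord <- order(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    edges <- edges[ord, , drop = FALSE]
    ep <- rbind(edges$from, edges$to)
    g <- igraph::add_edges(g, as.vector(ep), weight = edges$weight)
    if (!is.null(edges$sign)) {
      stopifnot(all(edges$sign %in% c(-1, 1)))
      g <- igraph::set_edge_attr(g, "sign", value = edges$sign)
    }
  }
  g
}

#' Extract the edge table of a gene network
#'
#' @param graph an igraph gene network.
#' @return data.frame with `from`, `to` (lexicographically ordered within
#'   each row, rows sorted), `weight`, and `sign` if present, suitable
#'   for deterministic output.
#' @export
network_edges <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::ecount(graph) == 0) {
    out <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0))
    return(out)
  }
  el <- igraph::as_edgelist(graph, names = TRUE)
  from <- pmin(el[, 1], el[, 2])
  to <- pmax(el[, 1], el[, 2])
  out <- data.frame(from = from, to = to,
                    weight = igraph::E(graph)$weight,
                    stringsAsFactors = FALSE)
  if ("sign" %in% igraph::edge_attr_names(graph)) {
    out$sign <- igraph::E(graph)$sign
  }
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop isolated nodes from a network
#'
#' Degree-0 nodes carry no interaction information and are excluded from
#' all networks so node counts reflect connected genes only.
#'
#' @param graph an igraph gene network.
#' @return the graph restricted to nodes with degree >= 1.
#' @export
drop_isolated <- function(graph) {
  keep <- igraph::degree(graph) > 0
  igraph::induced_subgraph(graph, which(keep))
}

# canonical undirected edge identifier
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

trim_ids <- function(x) {
  if (is.null(x)) return(character(0))
  x <- trimws(as.character(x))
  if (any(!nzchar(x))) stop("empty gene identifier")
  x
}
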