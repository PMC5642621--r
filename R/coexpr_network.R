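#' Weighted co-expression network from an expression matrix
#'
#' For every retained gene pair the Pearson correlation r is computed
#' over pairwise-complete samples and transformed to a soft-threshold
#' adjacency a = |r|^beta (the adjacency step of weighted correlation
#' network analysis; no topological overlap or module detection). An
#' edge is kept either when a meets an absolute threshold or, with
#' `target_edge_count`, for the largest `target_edge_count` adjacencies
#' (ties broken lexicographically by endpoint pair). The edge weight is
#' a; the sign of r is kept as edge metadata.
#'
#' Genes with zero variance or more than 50% missing values are excluded
#' (reported via message); a pair with fewer than 3 complete samples is
#' skipped.
#'
#' @param expr numeric matrix, genes x samples, >= 3 samples.
#' @param beta soft-threshold power (default 1: weights are |r|).
#' @param abs_r_threshold keep edges with adjacency >= this value.
#' @param target_edge_count alternative edge rule: keep this many top
#'   adjacencies. Exactly one of the two rules may be given.
#' @return igraph gene network with `weight` and `sign` edge attributes.
#' @export
correlation_adjacency <- function(expr, beta = 1, abs_r_threshold = 0.5,
                                  target_edge_count = NULL) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3, beta > 0)
  if (!is.null(target_edge_count) && !missing(abs_r_threshold)) {
    stop("give either abs_r_threshold or target_edge_count, not both")
  }
  miss_frac <- rowMeans(is.na(expr))
  vars <- apply(expr, 1, stats::var, na.rm = TRUE)
  keep <- miss_frac <= 0.5 & !is.na(vars) & vars > 0
  if (!any(keep)) stop("all genes are constant or too sparse to correlate")
  if (any(!keep)) {
    message(sum(!keep), " gene(s) excluded: zero variance or >50% missing")
  }
  x <- expr[keep, , drop = FALSE]
  r <- suppressWarnings(stats::cor(t(x), use = "pairwise.complete.obs"))
  # pairs with < 3 complete observations are unreliable: mask them
  obs <- !is.na(x)
  npair <- tcrossprod(obs * 1)
  r[npair < 3] <- NA
  diag(r) <- NA

  g <- rownames(x)
  ut <- upper.tri(r)
  idx <- which(ut & !is.na(r), arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(gene_network(data.frame(from = character(0), to = character(0),
                                   weight = numeric(0))))
  }
  rr <- r[idx]
  a <- abs(rr)^beta
  ed <- data.frame(from = g[idx[, 1]], to = g[idx[, 2]],
                   weight = a, sign = ifelse(rr >= 0, 1, -1),
                   stringsAsFactors = FALSE)
  if (!is.null(target_edge_count)) {
    stopifnot(target_edge_count >= 1)
    ord <- order(-ed$weight, pmin(ed$from, ed$to), pmax(ed$from, ed$to))
    ed <- ed[ord[seq_len(min(target_edge_count, nrow(ed)))], , drop = FALSE]
  } else {
    ed <- ed[ed$weight >= abs_r_threshold, , drop = FALSE]
  }
  # correlations of exactly +/-1 are kept; weights must stay in (0, 1]
  ed <- ed[ed$weight > 0, , drop = FALSE]
  ed$weight <- pmin(ed$weight, 1)
  drop_isolated(gene_network(ed))
}

#' Intersect a PPI network with a co-expression network
#'
#' The common network keeps exactly the undirected edges present in both
#' inputs. Each retained edge carries the co-expression weight (the
#' correlation-derived adjacency), since downstream walk transitions and
#' ranking scores are driven by co-expression strength; the PPI score
#' only gates membership. Nodes are the endpoints of retained edges.
#'
#' @param ppi igraph gene network (protein-protein interactions).
#' @param coexpr igraph gene network from [correlation_adjacency()].
#' @return igraph gene network (the common network).
#' @export
intersect_networks <- function(ppi, coexpr) {
  ep <- network_edges(ppi)
  ec <- network_edges(coexpr)
  common <- merge(ep[, c("from", "to")], ec, by = c("from", "to"))
  if (nrow(common) == 0) {
    stop("PPI and co-expression networks share no edge; ",
         "relax the correlation threshold or the PPI score cutoff")
  }
  drop_isolated(gene_network(common))
}
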