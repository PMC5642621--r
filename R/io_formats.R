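#' Read a STRING-style protein links file
#'
#' Parses the whitespace-separated dialect used by the STRING database
#' (`protein1 protein2 combined_score`, one header line, scores on a
#' 0-1000 scale, each interaction usually listed in both directions).
#' Scores are normalized by 1000 so all networks share a weight scale in
#' (0, 1]; reciprocal rows collapse to one undirected edge and degree-0
#' nodes are dropped.
#'
#' @param path links file.
#' @param score_min minimum combined score (0-1000) an edge must reach to
#'   be kept. Default 0 keeps every scored edge.
#' @param id_map optional two-column TSV (no header: raw id, gene symbol)
#'   mapping protein identifiers (e.g. taxon-prefixed STRING ids) to gene
#'   symbols; identifiers absent from the map are skipped with a message.
#'   Default is the identity mapping.
#' @return an igraph gene network with `weight` edge attribute.
#' @export
read_string_links <- function(path, score_min = 0, id_map = NULL) {
  stopifnot(score_min >= 0, score_min <= 1000)
  lines <- readLines(path)
  if (length(lines) < 1) stop("links file is empty: ", path)
  body <- lines[-1]
  body_idx <- which(nzchar(trimws(body)))
  body <- body[body_idx]
  if (length(body) == 0) {
    return(gene_network(data.frame(from = character(0), to = character(0),
                                   weight = numeric(0))))
  }
  tok <- strsplit(trimws(body), "[ \t]+")
  nfield <- lengths(tok)
  if (any(nfield != 3)) {
    bad <- body_idx[which(nfield != 3)[1]] + 1L
    stop("malformed links line ", bad, ": expected 3 fields")
  }
  m <- matrix(unlist(tok), ncol = 3, byrow = TRUE)
  score <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(score)) {
    bad <- body_idx[which(is.na(score))[1]] + 1L
    stop("malformed links line ", bad, ": non-numeric combined_score")
  }
  a <- m[, 1]
  b <- m[, 2]
  if (!is.null(id_map)) {
    map <- utils::read.table(id_map, header = FALSE, sep = "\t",
                             col.names = c("raw", "symbol"),
                             colClasses = "character", quote = "")
    lut <- stats::setNames(map$symbol, map$raw)
    a2 <- lut[a]
    b2 <- lut[b]
    unmapped <- is.na(a2) | is.na(b2)
    if (any(unmapped)) {
      message(sum(unmapped), " edge(s) skipped: unmapped identifier")
    }
    keep <- !unmapped
    a <- a2[keep]; b <- b2[keep]; score <- score[keep]
  }
  keep <- score >= score_min & a != b
  edges <- data.frame(from = a[keep], to = b[keep],
                      weight = score[keep] / 1000,
                      stringsAsFactors = FALSE)
  edges <- edges[edges$weight > 0, , drop = FALSE]
  drop_isolated(gene_network(edges))
}

#' Read a gene expression matrix from TSV
#'
#' First column holds gene identifiers, remaining columns one sample
#' each. Missing values are encoded as `NA` and kept as missing, never
#' coerced to zero.
#'
#' @param path TSV file.
#' @return numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames).
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          na.strings = "NA")
  if (ncol(df) < 2) stop("expression TSV needs a gene column and >=1 sample")
  genes <- trim_ids(df[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- !is.na(vals) & is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-numeric expression value for gene ", genes[idx[1]],
         ", sample ", colnames(vals)[idx[2]])
  }
  dimnames(num) <- list(genes, colnames(vals))
  num
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()] (round-trip identical).
#'
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path output file.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a seed gene list and restrict it to a network
#'
#' One gene symbol per line. Seeds absent from the network are set aside
#' (the study dropped 11 of 63 collected disease genes this way) and
#' reported with a warning.
#'
#' @param path seed list file.
#' @param network igraph gene network the seeds must belong to.
#' @return object of class `seed_set`: list with `genes` (seeds present
#'   in the network, input order) and `dropped` (seeds absent).
#' @export
read_seed_list <- function(path, network) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("seed list is empty: ", path)
  seeds <- unique(lines)
  present <- seeds %in% igraph::V(network)$name
  dropped <- seeds[!present]
  if (length(dropped) > 0) {
    warning(length(dropped), " seed(s) absent from the network: ",
            paste(dropped, collapse = ", "))
  }
  seed_set(seeds[present], dropped)
}

#' Construct a seed set
#'
#' @param genes seeds present in the working network.
#' @param dropped seeds set aside because absent from the network.
#' @return object of class `seed_set`.
#' @export
seed_set <- function(genes, dropped = character(0)) {
  genes <- trim_ids(genes)
  dropped <- if (length(dropped)) trim_ids(dropped) else character(0)
  if (length(intersect(genes, dropped)) > 0) {
    stop("a seed cannot be both retained and dropped")
  }
  structure(list(genes = unique(genes), dropped = unique(dropped)),
            class = "seed_set")
}

#' Packaged reference tables: seed genes and published linker scores
#'
#' Loads the two tables shipped with the package: the 52 pancreatic
#' cancer seed genes (literature-curated disease genes present in the
#' study's common network) and the 82 linker genes of the published
#' extracted subnetwork with their ranking scores (RS).
#'
#' @return list with `seeds` (character, 52 symbols) and `linker_rs`
#'   (named numeric, 82 RS values).
#' @export
load_reference_tables <- function() {
  seed_path <- system.file("extdata", "seed_genes.txt", package = "pancnet",
                           mustWork = TRUE)
  rs_path <- system.file("extdata", "linker_ranking_scores.tsv",
                         package = "pancnet", mustWork = TRUE)
  seeds <- trimws(readLines(seed_path))
  seeds <- seeds[nzchar(seeds)]
  rs_df <- utils::read.table(rs_path, header = TRUE, sep = "\t",
                             quote = "", stringsAsFactors = FALSE)
  if (length(seeds) != 52 || anyDuplicated(seeds)) {
    stop("seed gene fixture corrupt: expected 52 unique symbols")
  }
  if (nrow(rs_df) != 82 || anyDuplicated(rs_df$gene)) {
    stop("linker RS fixture corrupt: expected 82 unique genes")
  }
  if (any(rs_df$rs <= 0 | rs_df$rs > 2)) {
    stop("linker RS fixture corrupt: RS out of (0, 2]")
  }
  list(seeds = seeds, linker_rs = stats::setNames(rs_df$rs, rs_df$gene))
}

#' Read a clinical table from TSV
#'
#' Columns: `sample`, `os_days` (overall survival, days), `event`
#' (1 = death, 0 = censored), and the covariates `gender`, `alcohol`,
#' `smoking`. Any field except `sample` may be missing (`NA`).
#'
#' @param path TSV file.
#' @return data.frame with one row per sample.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, na.strings = "NA")
  required <- c("sample", "os_days", "event")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("clinical table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$sample)) stop("duplicate sample id in clinical table")
  if (any(df$os_days < 0, na.rm = TRUE)) stop("negative survival time")
  if (!all(df$event %in% c(0, 1, NA))) stop("event indicator must be 0/1")
  df
}

#' Write a gene network to file
#'
#' Supported formats: `edge_tsv` (columns gene_a, gene_b, weight; the
#' round-trippable interchange format), `sif` (Cytoscape simple
#' interaction format, one `cx` interaction type), and `graphml` (carries
#' edge weights plus any node attributes). Rows are ordered
#' lexicographically by endpoint pair so output is deterministic.
#'
#' @param graph igraph gene network.
#' @param path output file.
#' @param format one of `"edge_tsv"`, `"sif"`, `"graphml"`.
#' @param node_attrs optional named list of per-node attribute vectors
#'   (each named by gene), written to GraphML only.
#' @export
write_network <- function(graph, path,
                          format = c("edge_tsv", "sif", "graphml"),
                          node_attrs = NULL) {
  format <- match.arg(format)
  ed <- network_edges(graph)
  if (format == "edge_tsv") {
    out <- data.frame(gene_a = ed$from, gene_b = ed$to, weight = ed$weight)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "sif") {
    writeLines(paste(ed$from, "cx", ed$to), path)
  } else {
    write_graphml(graph, ed, path, node_attrs)
  }
  invisible(path)
}

#' Read a gene network from edge TSV
#'
#' @param path file written by [write_network()] with format
#'   `"edge_tsv"` (columns gene_a, gene_b, weight).
#' @return igraph gene network.
#' @export
read_network <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  gene_network(data.frame(from = df$gene_a, to = df$gene_b,
                          weight = df$weight))
}

write_graphml <- function(graph, ed, path, node_attrs = NULL) {
  nodes <- sort(igraph::V(graph)$name)
  xml_esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>'
  )
  attr_names <- names(node_attrs)
  for (i in seq_along(node_attrs)) {
    lines <- c(lines, sprintf(
      '  <key id="na%d" for="node" attr.name="%s" attr.type="string"/>',
      i, xml_esc(attr_names[i])))
  }
  lines <- c(lines, '  <graph edgedefault="undirected">')
  for (v in nodes) {
    data <- character(0)
    for (i in seq_along(node_attrs)) {
      val <- node_attrs[[i]][v]
      if (!is.na(val)) {
        data <- c(data, sprintf('      <data key="na%d">%s</data>',
                                i, xml_esc(as.character(val))))
      }
    }
    if (length(data) > 0) {
      lines <- c(lines, sprintf('    <node id="%s">', xml_esc(v)),
                 data, "    </node>")
    } else {
      lines <- c(lines, sprintf('    <node id="%s"/>', xml_esc(v)))
    }
  }
  if (nrow(ed) > 0) {
    lines <- c(lines, sprintf(
      '    <edge source="%s" target="%s"><data key="w">%s</data></edge>',
      xml_esc(ed$from), xml_esc(ed$to),
      format(ed$weight, digits = 15, scientific = FALSE)))
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  writeLines(lines, path)
  invisible(path)
}
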