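#' Assemble a pipeline configuration
#'
#' Collects input paths and stage parameters for [run_pipeline()].
#'
#' @param ppi path to a STRING-dialect links file.
#' @param expression path to the expression TSV.
#' @param clinical path to the clinical TSV (optional; survival and
#'   covariate stages are skipped without it).
#' @param seeds path to the seed list.
#' @param out_dir output directory for all artifacts.
#' @param id_map optional protein-to-symbol mapping TSV.
#' @param score_min PPI combined-score cutoff (0-1000).
#' @param beta soft-threshold power for the co-expression adjacency.
#' @param abs_r_threshold co-expression edge threshold on |r|^beta.
#' @param target_edge_count alternative co-expression edge rule.
#' @param L walk-length budget of the limited k-walks algorithm.
#' @param rs_cutoff strict ranking-score cutoff for candidate selection.
#' @param top_k alternative selection rule (overrides rs_cutoff if set).
#' @param signature explicit signature gene list; default uses the
#'   selected candidates.
#' @param rng_seed recorded seed for any stochastic stage (the pipeline
#'   itself is deterministic).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(ppi, expression, clinical = NULL, seeds,
                            out_dir, id_map = NULL, score_min = 0,
                            beta = 1, abs_r_threshold = 0.5,
                            target_edge_count = NULL, L = 50,
                            rs_cutoff = 1, top_k = NULL,
                            signature = NULL, rng_seed = 1) {
  cfg <- list(ppi = ppi, expression = expression, clinical = clinical,
              seeds = seeds, out_dir = out_dir, id_map = id_map,
              score_min = score_min, beta = beta,
              abs_r_threshold = abs_r_threshold,
              target_edge_count = target_edge_count, L = L,
              rs_cutoff = rs_cutoff, top_k = top_k,
              signature = signature, rng_seed = rng_seed)
  for (f in c("ppi", "expression", "seeds")) {
    if (!file.exists(cfg[[f]])) stop("input file not found: ", cfg[[f]])
  }
  if (!is.null(clinical) && !file.exists(clinical)) {
    stop("input file not found: ", clinical)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the candidate-gene discovery pipeline end to end
#'
#' Executes the three-step workflow: (1) build the co-expression network
#' from expression data and intersect it with the PPI network into the
#' common network; (2) filter the seed list to the common network and
#' extract the seed-connecting subnetwork with the edge-weighted limited
#' k-walks algorithm; (3) rank linker genes by ranking score, select
#' candidates, and connect them by a smallest connecting subnetwork.
#' When a clinical table is supplied, seed-candidate correlations,
#' covariate t-tests, and median-split survival stratification of the
#' candidate signature are added. Every intermediate artifact is written
#' under `out_dir` and a manifest JSON records input digests, parameters
#' and per-stage counts.
#'
#' @param config a `pipeline_config`.
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  set.seed(config$rng_seed)
  stage <- "read_inputs"
  manifest <- list(
    parameters = config[setdiff(names(config), "out_dir")],
    inputs = as.list(tools::md5sum(stats::na.omit(unlist(
      config[c("ppi", "expression", "clinical", "seeds")])))),
    stages = list())
  record <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }
  fail <- function(e) {
    manifest$error <<- list(stage = stage, message = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  }

  tryCatch({
    ppi <- read_string_links(config$ppi, score_min = config$score_min,
                             id_map = config$id_map)
    expr <- read_expression_matrix(config$expression)
    clinical <- if (!is.null(config$clinical)) {
      read_clinical_table(config$clinical)
    }
    record("read_inputs", ppi_nodes = igraph::vcount(ppi),
           ppi_edges = igraph::ecount(ppi),
           genes = nrow(expr), samples = ncol(expr),
           clinical_samples = if (is.null(clinical)) 0L else nrow(clinical))

    stage <- "coexpression_network"
    coexpr <- if (is.null(config$target_edge_count)) {
      correlation_adjacency(expr, beta = config$beta,
                            abs_r_threshold = config$abs_r_threshold)
    } else {
      correlation_adjacency(expr, beta = config$beta,
                            target_edge_count = config$target_edge_count)
    }
    write_network(coexpr, file.path(out, "coexpression_network.tsv"))
    record("coexpression_network", nodes = igraph::vcount(coexpr),
           edges = igraph::ecount(coexpr))

    stage <- "common_network"
    common <- intersect_networks(ppi, coexpr)
    write_network(common, file.path(out, "common_network.tsv"))
    record("common_network", nodes = igraph::vcount(common),
           edges = igraph::ecount(common))

    stage <- "seed_filter"
    seeds <- withCallingHandlers(
      read_seed_list(config$seeds, common),
      warning = function(w) invokeRestart("muffleWarning"))
    record("seed_filter", seeds_retained = length(seeds$genes),
           seeds_dropped = length(seeds$dropped),
           dropped = seeds$dropped)

    stage <- "kwalks_relevance"
    relevance <- limited_kwalks_relevance(common, seeds, L = config$L)
    rel_tab <- relevance$edge_relevance
    utils::write.table(rel_tab, file.path(out, "edge_relevance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("kwalks_relevance", L = config$L,
           starts_absorbed = sum(relevance$absorption_mass > 0),
           mean_absorption = mean(relevance$absorption_mass))

    stage <- "subnetwork_extraction"
    sub <- extract_subnetwork(common, relevance, seeds)
    write_network(sub$graph, file.path(out, "subnetwork.tsv"))
    write_network(sub$graph, file.path(out, "subnetwork.sif"),
                  format = "sif")
    write_network(sub$graph, file.path(out, "subnetwork.graphml"),
                  format = "graphml", node_attrs = list(role = sub$roles))
    n_linkers <- sum(sub$roles == "linker")
    record("subnetwork_extraction",
           nodes = igraph::vcount(sub$graph),
           edges = igraph::ecount(sub$graph),
           seeds = sum(sub$roles == "seed"), linkers = n_linkers)

    stage <- "ranking"
    ranked <- ranking_score(sub)
    utils::write.table(
      data.frame(gene = ranked$gene, rs = round(ranked$rs, 1),
                 rs_full = ranked$rs, rank = ranked$rank),
      file.path(out, "ranked_linkers.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    record("ranking", linkers_ranked = nrow(ranked),
           max_rs = if (nrow(ranked)) max(ranked$rs) else NA)

    stage <- "candidate_selection"
    candidates <- if (nrow(ranked) == 0) {
      character(0)
    } else if (!is.null(config$top_k)) {
      select_candidates(ranked, top_k = config$top_k)
    } else {
      select_candidates(ranked, rs_cutoff = config$rs_cutoff)
    }
    writeLines(candidates, file.path(out, "candidates.txt"))
    record("candidate_selection", candidates = length(candidates),
           genes = candidates)

    stage <- "minimal_connecting_subnetwork"
    if (length(candidates) >= 2) {
      mcs <- minimal_connecting_subnetwork(common, candidates)
      write_network(mcs$graph, file.path(out, "candidate_subnetwork.sif"),
                    format = "sif")
      write_network(mcs$graph, file.path(out, "candidate_subnetwork.tsv"))
      record("minimal_connecting_subnetwork",
             nodes = igraph::vcount(mcs$graph),
             edges = igraph::ecount(mcs$graph))
    } else {
      record("minimal_connecting_subnetwork", skipped = TRUE)
    }

    stage <- "correlation_stats"
    sub_ed <- network_edges(sub$graph)
    is_sc <- (sub_ed$from %in% seeds$genes & sub_ed$to %in% candidates) |
      (sub_ed$to %in% seeds$genes & sub_ed$from %in% candidates)
    if (any(is_sc)) {
      sc <- sub_ed[is_sc, c("from", "to")]
      cor_tab <- pairwise_correlation(expr, sc)
      utils::write.table(cor_tab,
                         file.path(out, "seed_candidate_correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      record("correlation_stats", pairs = nrow(cor_tab),
             significant_raw = sum(cor_tab$p < 0.05, na.rm = TRUE))
    } else {
      record("correlation_stats", pairs = 0L)
    }

    stage <- "covariate_stats"
    if (!is.null(clinical) && length(candidates) > 0) {
      cov_rows <- list()
      for (cv in intersect(c("gender", "alcohol", "smoking"),
                           names(clinical))) {
        cov_rows[[cv]] <- withCallingHandlers(
          covariate_tests(expr, clinical, candidates, cv),
          warning = function(w) invokeRestart("muffleWarning"))
      }
      cov_tab <- do.call(rbind, unname(cov_rows))
      if (!is.null(cov_tab) && nrow(cov_tab) > 0) {
        utils::write.table(cov_tab, file.path(out, "covariate_tests.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      record("covariate_stats",
             tests = if (is.null(cov_tab)) 0L else nrow(cov_tab))
    } else {
      record("covariate_stats", skipped = TRUE)
    }

    stage <- "survival"
    signature <- if (!is.null(config$signature)) config$signature else
      candidates
    if (!is.null(clinical) && length(signature) > 0) {
      scores <- risk_score(expr, signature)
      strat <- stratify_and_test(scores, clinical)
      km <- do.call(rbind, lapply(names(strat$km_curves), function(gname) {
        cbind(group = gname, strat$km_curves[[gname]])
      }))
      utils::write.table(km, file.path(out, "km_curves.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      summary_json <- list(signature = signature,
                           n_retained = strat$n_retained,
                           n_excluded = strat$n_excluded,
                           threshold = strat$threshold,
                           logrank_chisq = strat$logrank_chisq,
                           logrank_p = strat$logrank_p)
      jsonlite::write_json(summary_json,
                           file.path(out, "survival_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      record("survival", n_retained = strat$n_retained,
             n_excluded = strat$n_excluded,
             logrank_chisq = strat$logrank_chisq,
             logrank_p = strat$logrank_p)
    } else {
      record("survival", skipped = TRUE)
    }
  }, error = fail)

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
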