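#' Parameters for the synthetic cohort generator
#'
#' Defaults describe the study conditions the pipeline is exercised
#' under: a co-expressed module of 5 seed genes and 5 planted linker
#' genes (target within-module Pearson correlation 0.8) against 300
#' independent background genes, profiled in 100 samples; a sparse PPI
#' graph in which the planted seed-linker interactions are present with
#' probability 0.95 over a 1% background edge rate; and a clinical table
#' whose hazard triples for samples in the upper half of the module's
#' latent factor, with independent censoring and the study's fraction of
#' missing clinical records (16 of 179).
#'
#' @param n_genes total number of genes.
#' @param n_samples number of samples.
#' @param n_seeds number of seed genes (module members).
#' @param n_planted_linkers number of planted linker genes (module
#'   members that are not seeds; the recovery targets).
#' @param module_corr target pairwise Pearson correlation within the
#'   module, in (0, 1).
#' @param background_edge_prob PPI edge probability outside the planted
#'   pairs.
#' @param ppi_cover_prob probability each planted seed-linker pair is
#'   present in the PPI graph.
#' @param hazard_ratio hazard multiplier for high-factor samples.
#' @param censor_rate target probability of censoring (under unit hazard
#'   ratio).
#' @param missing_clinical_frac fraction of samples whose survival
#'   fields are missing.
#' @param median_survival_days baseline median overall survival.
#' @param rng_seed integer seed; the full bundle is reproducible from it.
#' @return list of class `synth_params`.
#' @export
synth_params <- function(n_genes = 310, n_samples = 100, n_seeds = 5,
                         n_planted_linkers = 5, module_corr = 0.8,
                         background_edge_prob = 0.01,
                         ppi_cover_prob = 0.95, hazard_ratio = 3,
                         censor_rate = 0.3,
                         missing_clinical_frac = 16 / 179,
                         median_survival_days = 600, rng_seed = 1) {
  p <- list(n_genes = n_genes, n_samples = n_samples, n_seeds = n_seeds,
            n_planted_linkers = n_planted_linkers,
            module_corr = module_corr,
            background_edge_prob = background_edge_prob,
            ppi_cover_prob = ppi_cover_prob, hazard_ratio = hazard_ratio,
            censor_rate = censor_rate,
            missing_clinical_frac = missing_clinical_frac,
            median_survival_days = median_survival_days,
            rng_seed = rng_seed)
  stopifnot(p$n_seeds + p$n_planted_linkers <= p$n_genes,
            p$module_corr > 0, p$module_corr < 1,
            p$background_edge_prob > 0, p$background_edge_prob < 1,
            p$ppi_cover_prob > 0, p$ppi_cover_prob <= 1,
            p$hazard_ratio > 0,
            p$censor_rate >= 0, p$censor_rate < 1,
            p$missing_clinical_frac >= 0, p$missing_clinical_frac < 1,
            p$n_samples >= 3)
  class(p) <- "synth_params"
  p
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Expression follows a one-factor Gaussian model inside the planted
#' module: for module gene g, x_g = lambda * f + eps with f ~ N(0,1) per
#' sample, eps ~ N(0,1), and lambda = sqrt(rho / (1 - rho)) so the
#' expected pairwise module correlation is rho = `module_corr`.
#' Background genes are independent N(0,1). The PPI graph contains each
#' planted seed-linker pair with probability `ppi_cover_prob` (the
#' premise under study: candidate linkers interact with disease seeds)
#' plus Bernoulli background edges; seed-seed interactions are left to
#' the background rate so seeds connect through linkers, as in the
#' disease-network setting the pipeline targets. Survival is exponential
#' with the hazard multiplied by `hazard_ratio` for samples in the upper
#' half of the latent factor; censoring is independent exponential
#' calibrated so P(censored) = `censor_rate` at unit hazard ratio; a
#' fixed count round(`missing_clinical_frac` * n) of samples lacks
#' os_days/event. Covariates (gender, alcohol, smoking) are independent
#' of expression.
#'
#' @param params a `synth_params` object.
#' @return list with `ppi` (igraph), `expr` (matrix), `seeds`
#'   (character), `clinical` (data.frame), `truth` (list:
#'   planted_linkers, module_genes, factor, high_risk, params).
#' @export
generate_cohort <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$rng_seed)
  n_mod <- params$n_seeds + params$n_planted_linkers
  seeds <- sprintf("SEED%02d", seq_len(params$n_seeds))
  linkers <- sprintf("LNK%02d", seq_len(params$n_planted_linkers))
  n_bg <- params$n_genes - n_mod
  background <- if (n_bg > 0) sprintf("BG%04d", seq_len(n_bg)) else character(0)
  genes <- c(seeds, linkers, background)
  samples <- sprintf("S%03d", seq_len(params$n_samples))

  lambda <- sqrt(params$module_corr / (1 - params$module_corr))
  f <- stats::rnorm(params$n_samples)
  expr <- matrix(stats::rnorm(params$n_genes * params$n_samples),
                 nrow = params$n_genes,
                 dimnames = list(genes, samples))
  module <- c(seeds, linkers)
  expr[module, ] <- expr[module, ] +
    matrix(lambda * f, nrow = n_mod, ncol = params$n_samples, byrow = TRUE)

  # PPI: planted seed x linker pairs, then background pairs
  planted <- expand.grid(from = seeds, to = linkers,
                         stringsAsFactors = FALSE)
  planted <- planted[stats::runif(nrow(planted)) <= params$ppi_cover_prob, ]
  planted$weight <- round(stats::runif(nrow(planted), 700, 999)) / 1000
  all_pairs <- utils::combn(genes, 2)
  pkey <- edge_key(all_pairs[1, ], all_pairs[2, ])
  is_planted_slot <- pkey %in% edge_key(planted$from, planted$to)
  bg_draw <- stats::runif(ncol(all_pairs)) <= params$background_edge_prob
  bg_idx <- which(bg_draw & !is_planted_slot)
  bg <- data.frame(from = all_pairs[1, bg_idx], to = all_pairs[2, bg_idx],
                   weight = round(stats::runif(length(bg_idx), 150, 999)) / 1000,
                   stringsAsFactors = FALSE)
  ppi <- drop_isolated(gene_network(rbind(planted, bg)))

  high_risk <- f > stats::median(f)
  clinical <- simulate_clinical(samples, high_risk,
                                hazard_ratio = params$hazard_ratio,
                                censor_rate = params$censor_rate,
                                missing_frac = params$missing_clinical_frac,
                                median_survival_days =
                                  params$median_survival_days)

  truth <- list(planted_linkers = linkers, module_genes = module,
                factor = stats::setNames(f, samples),
                high_risk = samples[high_risk], params = unclass(params))
  list(ppi = ppi, expr = expr, seeds = seeds, clinical = clinical,
       truth = truth)
}

#' Simulate a clinical survival table
#'
#' Exponential survival times with a two-level proportional hazard:
#' baseline hazard log(2)/`median_survival_days`, multiplied by
#' `hazard_ratio` for `high_risk` samples. Censoring times are drawn from
#' an independent exponential whose rate gives P(censored) =
#' `censor_rate` under unit hazard ratio. A fixed count
#' round(`missing_frac` * n) of samples has os_days and event set to NA.
#' Covariates are balanced Bernoulli draws independent of risk.
#'
#' @param samples character vector of sample ids.
#' @param high_risk logical vector (same length) marking the
#'   elevated-hazard group.
#' @param hazard_ratio hazard multiplier for the high-risk group.
#' @param censor_rate target censoring probability.
#' @param missing_frac fraction of samples with missing survival fields.
#' @param median_survival_days baseline median survival.
#' @return clinical data.frame (sample, os_days, event, gender, alcohol,
#'   smoking).
#' @export
simulate_clinical <- function(samples, high_risk, hazard_ratio = 1,
                              censor_rate = 0.3, missing_frac = 0,
                              median_survival_days = 600) {
  n <- length(samples)
  stopifnot(length(high_risk) == n)
  h0 <- log(2) / median_survival_days
  rate <- h0 * ifelse(high_risk, hazard_ratio, 1)
  t_event <- stats::rexp(n, rate)
  os <- t_event
  event <- rep(1L, n)
  if (censor_rate > 0) {
    c_rate <- h0 * censor_rate / (1 - censor_rate)
    t_cens <- stats::rexp(n, c_rate)
    event <- as.integer(t_event <= t_cens)
    os <- pmin(t_event, t_cens)
  }
  os <- round(os, 1)
  n_missing <- round(missing_frac * n)
  if (n_missing > 0) {
    drop <- sample.int(n, n_missing)
    os[drop] <- NA
    event[drop] <- NA
  }
  data.frame(sample = samples, os_days = os, event = event,
             gender = sample(c("male", "female"), n, replace = TRUE),
             alcohol = sample(c("yes", "no"), n, replace = TRUE),
             smoking = sample(c("yes", "no"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Write a synthetic cohort as an on-disk input bundle
#'
#' Files use exactly the external formats the readers consume: a
#' STRING-dialect links file (header `protein1 protein2 combined_score`,
#' every edge listed in both directions, scores on the 0-1000 scale), an
#' expression TSV, a clinical TSV, a seed list, and a truth JSON
#' documenting the planted structure.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return named character vector of the file paths written.
#' @export
write_fixture_bundle <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(ppi = file.path(dir, "ppi_links.txt"),
             expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             seeds = file.path(dir, "seeds.txt"),
             truth = file.path(dir, "truth.json"))
  ed <- network_edges(cohort$ppi)
  score <- as.integer(round(ed$weight * 1000))
  links <- c("protein1 protein2 combined_score",
             paste(ed$from, ed$to, score),
             paste(ed$to, ed$from, score))
  writeLines(links, paths["ppi"])
  write_expression_matrix(cohort$expr, paths["expression"])
  utils::write.table(cohort$clinical, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(cohort$seeds, paths["seeds"])
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Precision of planted-linker recovery at a rank cutoff
#'
#' Fraction of the top-k ranked genes that are planted linkers, with the
#' denominator the number of genes actually retrieved (min(k, list
#' length)): the extracted subnetwork may contain fewer than k linkers
#' when few suffice to connect the seeds, and the quantity of interest
#' is whether planted linkers rank above background ones.
#'
#' @param ranked_genes character vector in rank order (e.g. the `gene`
#'   column of [ranking_score()] output).
#' @param planted character vector of planted linker genes.
#' @param k rank cutoff.
#' @return precision in [0, 1], or NA if nothing was retrieved.
#' @export
precision_at_k <- function(ranked_genes, planted, k) {
  top <- utils::head(ranked_genes, k)
  if (length(top) == 0) return(NA_real_)
  sum(top %in% planted) / length(top)
}
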