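#' Pearson correlation for a list of gene pairs
#'
#' Computes the Pearson correlation over pairwise-complete samples for
#' each supplied pair, with the two-sided p-value from the t reference
#' distribution on n - 2 degrees of freedom, and appends
#' Benjamini-Hochberg adjusted p-values across the supplied pairs.
#' Constant genes are flagged (`NA` statistic) rather than tested.
#'
#' @param expr numeric matrix, genes x samples.
#' @param pairs data.frame or 2-column matrix of gene symbols
#'   (gene_a, gene_b).
#' @return data.frame: gene_a, gene_b, n, r, p, p_adj.
#' @export
pairwise_correlation <- function(expr, pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(ncol(pairs) >= 2)
  ga <- as.character(pairs[[1]])
  gb <- as.character(pairs[[2]])
  missing_genes <- setdiff(c(ga, gb), rownames(expr))
  if (length(missing_genes) > 0) {
    stop("gene(s) absent from expression matrix: ",
         paste(unique(missing_genes), collapse = ", "))
  }
  out <- data.frame(gene_a = ga, gene_b = gb, n = NA_integer_,
                    r = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(ga)) {
    x <- expr[ga[k], ]
    y <- expr[gb[k], ]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    out$n[k] <- n
    if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    r <- stats::cor(x[ok], y[ok])
    out$r[k] <- r
    if (abs(r) >= 1) {
      out$p[k] <- P_FLOOR
    } else {
      tval <- r * sqrt((n - 2) / (1 - r^2))
      out$p[k] <- max(2 * stats::pt(-abs(tval), df = n - 2), P_FLOOR)
    }
  }
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Welch t-tests of candidate expression against a clinical covariate
#'
#' For each gene, the samples are grouped by a two-level covariate
#' (gender, alcohol history, or smoking history); a Welch two-sample
#' t-test compares expression between the levels. Samples missing the
#' covariate are dropped per test; a gene is skipped (with a warning)
#' when either level has fewer than 2 samples.
#'
#' @param expr numeric matrix, genes x samples (columns named by sample).
#' @param clinical data.frame from [read_clinical_table()].
#' @param genes genes to test.
#' @param covariate one of `"gender"`, `"alcohol"`, `"smoking"` (must
#'   exist in `clinical` with exactly 2 non-missing levels).
#' @return data.frame: gene, covariate, level_a, level_b, n_a, n_b,
#'   t, p.
#' @export
covariate_tests <- function(expr, clinical, genes, covariate) {
  stopifnot(covariate %in% names(clinical))
  cov <- clinical[[covariate]]
  levels_present <- sort(unique(cov[!is.na(cov)]))
  if (length(levels_present) != 2) {
    stop("covariate '", covariate, "' must have exactly 2 non-missing ",
         "levels, found ", length(levels_present))
  }
  idx <- match(clinical$sample, colnames(expr))
  rows <- list()
  for (g in genes) {
    if (!g %in% rownames(expr)) stop("gene absent from expression: ", g)
    vals <- expr[g, idx]
    ok <- !is.na(vals) & !is.na(cov)
    xa <- vals[ok & cov == levels_present[1]]
    xb <- vals[ok & cov == levels_present[2]]
    if (length(xa) < 2 || length(xb) < 2) {
      warning("gene ", g, " skipped: a covariate level has < 2 samples")
      next
    }
    tt <- stats::t.test(xa, xb)  # Welch by default
    rows[[g]] <- data.frame(gene = g, covariate = covariate,
                            level_a = as.character(levels_present[1]),
                            level_b = as.character(levels_present[2]),
                            n_a = length(xa), n_b = length(xb),
                            t = unname(tt$statistic),
                            p = max(tt$p.value, P_FLOOR),
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  out
}

#' Per-sample risk score of an expression signature
#'
#' The risk score of a sample is the sum of its expression values over
#' the signature genes (the published signature uses six genes). Missing
#' values are excluded from the sum; the count of missing values per
#' sample is attached as an attribute.
#'
#' @param expr numeric matrix, genes x samples.
#' @param signature character vector of signature genes; every gene must
#'   be present.
#' @return named numeric vector of scores (one per sample), with
#'   attribute `n_missing`.
#' @export
risk_score <- function(expr, signature) {
  absent <- setdiff(signature, rownames(expr))
  if (length(absent) > 0) {
    stop("signature gene(s) absent from expression matrix: ",
         paste(absent, collapse = ", "))
  }
  sub <- expr[signature, , drop = FALSE]
  scores <- colSums(sub, na.rm = TRUE)
  attr(scores, "n_missing") <- colSums(is.na(sub))
  scores
}

#' Median-split survival stratification and log-rank test
#'
#' Samples lacking survival time or event status are excluded first and
#' counted. The remainder are split at the median risk score: strictly
#' below the median is the low group; ties at the median join the low
#' group. Kaplan-Meier curves are computed per group and the two groups
#' are compared with the log-rank test obtained as the score test of a
#' single-covariate Cox proportional-hazards fit on the group indicator.
#'
#' @param scores named numeric vector from [risk_score()].
#' @param clinical data.frame with columns sample, os_days, event.
#' @return object of class `risk_stratification`: list with `labels`
#'   (named character, low/high), `n_retained`, `n_excluded`,
#'   `threshold` (the median), `logrank_chisq`, `logrank_p`, and
#'   `km_curves` (per-group data.frame of time, surv).
#' @export
stratify_and_test <- function(scores, clinical) {
  m <- match(clinical$sample, names(scores))
  if (anyNA(m)) {
    stop("clinical sample(s) without a risk score: ",
         paste(clinical$sample[is.na(m)], collapse = ", "))
  }
  complete <- !is.na(clinical$os_days) & !is.na(clinical$event)
  cl <- clinical[complete, , drop = FALSE]
  sc <- scores[cl$sample]
  n_excluded <- sum(!complete)

  med <- stats::median(sc)
  labels <- ifelse(sc > med, "high", "low")
  names(labels) <- cl$sample
  if (length(unique(labels)) < 2) {
    stop("median split left one group empty (", sum(sc == med),
         " score(s) tied at the median of ", length(sc), ")")
  }
  grp <- factor(labels, levels = c("low", "high"))
  if (min(table(grp)) < 2) {
    stop("a risk group has fewer than 2 samples after the median split")
  }

  surv <- survival::Surv(cl$os_days, cl$event)
  fit <- survival::coxph(surv ~ grp)
  sc_test <- summary(fit)$sctest
  km <- survival::survfit(surv ~ grp)
  km_sum <- summary(km, censored = TRUE)
  strata <- sub("^grp=", "", as.character(km_sum$strata))
  km_curves <- split(data.frame(time = km_sum$time, surv = km_sum$surv),
                     strata)

  structure(list(labels = labels,
                 n_retained = nrow(cl),
                 n_excluded = n_excluded,
                 threshold = med,
                 logrank_chisq = unname(sc_test["test"]),
                 logrank_p = max(unname(sc_test["pvalue"]), P_FLOOR),
                 km_curves = km_curves),
            class = "risk_stratification")
}

# reporting floor to keep p-values strictly positive in output files
P_FLOOR <- 1e-300
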