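test_that("pair correlations match the t-distribution closed form", {
  set.seed(9)
  n <- 30
  x <- rnorm(n)
  # construct y with exact sample correlation 0.6
  y0 <- rnorm(n)
  y0 <- residuals(lm(y0 ~ x))
  xs <- scale(x)[, 1]; ys <- scale(y0)[, 1]
  r_target <- 0.6
  y <- r_target * xs + sqrt(1 - r_target^2) * ys
  m <- rbind(A = x, B = y)
  colnames(m) <- paste0("S", 1:n)
  out <- pairwise_correlation(m, data.frame(a = "A", b = "B"))
  expect_equal(out$r, 0.6, tolerance = 1e-12)
  tval <- 0.6 * sqrt((n - 2) / (1 - 0.36))
  expect_equal(out$p, 2 * pt(-tval, n - 2), tolerance = 1e-9)
  # cross-check against the stats package route
  ct <- cor.test(x, y)
  expect_equal(out$p, ct$p.value, tolerance = 1e-9)
})

test_that("degenerate correlations are flagged or floored", {
  x <- 1:10
  m <- rbind(A = x, B = x, C = rep(2, 10))
  colnames(m) <- paste0("S", 1:10)
  out <- pairwise_correlation(m, data.frame(a = c("A", "A"),
                                            b = c("B", "C")))
  expect_equal(out$r[1], 1)
  expect_gt(out$p[1], 0)            # underflow-safe floor
  expect_true(is.na(out$r[2]))      # constant gene flagged
  expect_true(is.na(out$p[2]))

  # orthogonal vectors: r = 0 gives the p = 1 boundary
  y <- rnorm(10)
  y <- residuals(lm(y ~ x))
  m2 <- rbind(A = x, B = y)
  colnames(m2) <- paste0("S", 1:10)
  out2 <- pairwise_correlation(m2, data.frame(a = "A", b = "B"))
  expect_equal(out2$r, 0, tolerance = 1e-12)
  expect_equal(out2$p, 1, tolerance = 1e-9)
  expect_equal(out2$p_adj, 1, tolerance = 1e-9)
})

test_that("covariate tests reproduce the Welch statistic", {
  xa <- c(5.1, 4.8, 6.0, 5.5, 5.2)
  xb <- c(4.0, 4.4, 3.9, 4.6, 4.2, 4.1)
  clinical <- data.frame(
    sample = paste0("S", 1:11),
    os_days = 100, event = 1,
    gender = c(rep("male", 5), rep("female", 6)))
  m <- matrix(c(xa, xb), nrow = 1,
              dimnames = list("G1", paste0("S", 1:11)))
  out <- covariate_tests(m, clinical, "G1", "gender")
  # textbook Welch formula
  se <- sqrt(var(xb) / 6 + var(xa) / 5)
  t_hand <- (mean(xb) - mean(xa)) / se  # levels sort female < male
  expect_equal(out$t, t_hand, tolerance = 1e-9)
  df <- se^4 / ((var(xb) / 6)^2 / 5 + (var(xa) / 5)^2 / 4)
  expect_equal(out$p, 2 * pt(-abs(t_hand), df), tolerance = 1e-9)
})

test_that("covariate tests handle identical and separated groups", {
  clinical <- data.frame(sample = paste0("S", 1:10), os_days = 1,
                         event = 1,
                         smoking = rep(c("yes", "no"), each = 5))
  same <- matrix(rep(c(1, 2, 3, 4, 5), 2), nrow = 1,
                 dimnames = list("G1", paste0("S", 1:10)))
  out <- covariate_tests(same, clinical, "G1", "smoking")
  expect_equal(out$t, 0, tolerance = 1e-12)
  expect_equal(out$p, 1, tolerance = 1e-12)

  sep <- matrix(c(rnorm(5), rnorm(5) + 10), nrow = 1,
                dimnames = list("G1", paste0("S", 1:10)))
  out2 <- covariate_tests(sep, clinical, "G1", "smoking")
  expect_lt(out2$p, 1e-4)

  clinical$smoking[1:4] <- NA
  expect_warning(out3 <- covariate_tests(same, clinical, "G1", "smoking"),
                 "skipped")
  expect_null(out3)
})

test_that("risk scores are signature sums over samples", {
  m <- matrix(c(1, 2.5, 0, 0, 3, 4), nrow = 2,
              dimnames = list(c("A", "B"), c("S1", "S2", "S3")))
  sc <- risk_score(m, c("A", "B"))
  expect_equal(as.numeric(sc), c(3.5, 0, 7))
  expect_error(risk_score(m, c("A", "Z")), "Z")

  set.seed(12)
  m6 <- matrix(rnorm(6 * 20), nrow = 6,
               dimnames = list(paste0("G", 1:6), paste0("S", 1:20)))
  expect_equal(as.numeric(risk_score(m6, rownames(m6))),
               unname(colSums(m6)))
  zero <- m6 * 0
  expect_true(all(risk_score(zero, rownames(zero)) == 0))
})

test_that("stratification excludes incomplete records and splits at the median", {
  set.seed(13)
  n <- 20
  clinical <- data.frame(sample = paste0("S", 1:n),
                         os_days = round(rexp(n, 1 / 500)),
                         event = rbinom(n, 1, 0.7))
  clinical$os_days[1:3] <- NA
  scores <- setNames(rnorm(n), clinical$sample)
  st <- stratify_and_test(scores, clinical)
  expect_equal(st$n_retained, 17)
  expect_equal(st$n_excluded, 3)
  expect_equal(st$threshold, median(scores[clinical$sample[-(1:3)]]))
  # median tie goes to the low group
  expect_equal(unname(st$labels[names(which(scores == st$threshold))]),
               "low")
  # invariance under a strictly monotone transform
  st2 <- stratify_and_test(exp(scores), clinical)
  expect_identical(st$labels, st2$labels)
  expect_equal(st$logrank_p, st2$logrank_p)
})

test_that("identical survival in both groups gives a null log-rank", {
  os <- rep(c(100, 200, 300, 400, 500), 2)
  ev <- rep(c(1, 1, 0, 1, 0), 2)
  clinical <- data.frame(sample = paste0("S", 1:10), os_days = os,
                         event = ev)
  scores <- setNames(c(1:5, 6:10), clinical$sample)  # split 5/5
  st <- stratify_and_test(scores, clinical)
  expect_equal(st$logrank_p, 1, tolerance = 1e-6)
  expect_equal(st$logrank_chisq, 0, tolerance = 1e-9)
})

test_that("cox score test agrees with the classical log-rank statistic", {
  set.seed(14)
  for (i in 1:5) {
    n <- 40
    grp_high <- rep(c(FALSE, TRUE), each = n / 2)
    cl <- simulate_clinical(paste0("S", 1:n), grp_high, hazard_ratio = 2,
                            censor_rate = 0.2)
    scores <- setNames(ifelse(grp_high, 1, 0), cl$sample)
    st <- stratify_and_test(scores, cl)
    sd <- survival::survdiff(
      survival::Surv(cl$os_days, cl$event) ~ grp_high)
    expect_equal(st$logrank_chisq, unname(sd$chisq), tolerance = 1e-6)
  }
})

test_that("KM curves start at 1, are nonincreasing, drop at event times", {
  set.seed(15)
  n <- 30
  cl <- simulate_clinical(paste0("S", 1:n), rep(c(TRUE, FALSE), n / 2),
                          hazard_ratio = 2, censor_rate = 0.3)
  scores <- setNames(rnorm(n), cl$sample)
  st <- stratify_and_test(scores, cl)
  ev_times <- cl$os_days[cl$event == 1]
  for (curve in st$km_curves) {
    expect_lte(max(curve$surv), 1)
    expect_true(all(diff(curve$surv) <= 1e-12))
    drops <- curve$time[c(curve$surv[1] < 1, diff(curve$surv) < 0)]
    expect_true(all(drops %in% ev_times))
  }
})
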