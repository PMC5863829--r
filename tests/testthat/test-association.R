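test_that("ellipse area matches the quoted formula and its properties", {
  expect_equal(ellipse_area(2, 2), pi)
  # at the mean axes: product of means, deliberately not the mean area
  expect_equal(ellipse_area(18.60, 17.24), 251.8489, tolerance = 1e-4)
  expect_equal(ellipse_area(3, 7), ellipse_area(7, 3))  # symmetry
  # strictly increasing in each axis
  expect_true(ellipse_area(10.1, 9) > ellipse_area(10, 9))
  expect_true(ellipse_area(10, 9.1) > ellipse_area(10, 9))
  expect_error(ellipse_area(0, 5), "positive")
  expect_error(ellipse_area(5, -1), "positive")
})

test_that("standardization is exact, records its scale, and is idempotent", {
  z <- standardize(c(-1, 1))
  expect_equal(as.numeric(z), c(-1, 1) / sqrt(2))
  expect_equal(attr(z, "source_sd"), sqrt(2))

  expect_error(standardize(rep(0.3, 5)), "zero-variance")
  expect_error(standardize(c(1, NA, NA)), "two non-missing")

  # explicit scale: the published case-group CpG 11 example
  expect_equal(as.numeric(standardize(0.49, center = 0.37, scale = 0.10)),
               1.2)

  # missing entries stay missing; mean/SD invariants
  x <- c(rnorm(50), NA)
  z <- standardize(x)
  expect_true(is.na(z[51]))
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-10)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-10)

  # idempotence up to floating tolerance
  z2 <- standardize(as.numeric(z))
  expect_equal(as.numeric(z2), as.numeric(z), tolerance = 1e-12)
})

test_that("group comparison reproduces pooled-variance t and chi-squared", {
  # placental weight summaries: t derived by hand from the group moments
  cohort <- tibble::tibble(
    case_status = rep(c(1L, 0L), c(86, 79)),
    placental_weight = c(vector_with_moments(86, 466.24, 54.58),
                         vector_with_moments(79, 504.80, 56.07)))
  out <- compare_groups(cohort, "placental_weight")
  expect_equal(abs(out$statistic), 4.4745, tolerance = 1e-3)
  expect_lt(out$p, 1e-4)

  # identical groups: t = 0, p = 1
  same <- tibble::tibble(case_status = rep(c(1L, 0L), each = 10),
                         v = rep(c(1, 2, 5, 7, 9), 4))
  res <- compare_groups(same, "v")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # identical proportions: chi-squared = 0
  cat_same <- tibble::tibble(case_status = rep(c(1L, 0L), each = 40),
                             flag = rep(c(1L, 0L), 40))
  res2 <- compare_groups(cat_same, "flag")
  expect_equal(res2$type, "categorical")
  expect_equal(unname(res2$statistic), 0)

  expect_error(compare_groups(same, "absent_var"), "not in cohort")
})

test_that("logistic fits equal the contingency-table cross-product OR", {
  # 30 exposed cases, 10 exposed controls, 20 unexposed cases,
  # 40 unexposed controls -> OR = (30*40)/(10*20) = 6
  outcome <- rep(c(1L, 0L, 1L, 0L), c(30, 10, 20, 40))
  exposed <- rep(c(1, 1, 0, 0), c(30, 10, 20, 40))
  fit <- fit_logistic(outcome, tibble::tibble(exposed = exposed))
  expect_equal(fit$or[fit$term == "exposed"], 6, tolerance = 1e-6)

  # independence: OR = 1
  outcome2 <- rep(c(1L, 0L, 1L, 0L), each = 25)
  exposed2 <- rep(c(1, 1, 0, 0), each = 25)
  fit2 <- fit_logistic(outcome2, tibble::tibble(exposed = exposed2))
  expect_equal(fit2$or[fit2$term == "exposed"], 1, tolerance = 1e-8)

  expect_error(fit_logistic(outcome, tibble::tibble(k = rep(1, 100))),
               "constant")
  expect_error(fit_logistic(rep(2, 100), tibble::tibble(x = rnorm(100))),
               "binary")
  # complete separation is a diagnostic error naming the term
  y <- rep(c(0L, 1L), each = 20)
  expect_error(fit_logistic(y, tibble::tibble(x = as.numeric(y))),
               "separation.*x")
})

test_that("linear fits are exact OLS with Wald intervals", {
  x <- rnorm(30)
  fit <- suppressWarnings(fit_linear(x, tibble::tibble(x = x)))
  row <- fit[fit$term == "x", ]
  expect_equal(row$estimate, 1)
  expect_equal(row$se, 0, tolerance = 1e-12)

  set.seed(1)
  y <- rnorm(10000); z <- rnorm(10000)
  fit2 <- fit_linear(y, tibble::tibble(z = z))
  row2 <- fit2[fit2$term == "z", ]
  expect_lt(abs(row2$estimate), 3 * row2$se)  # null recovery
  expect_true(row2$ci_low <= row2$estimate &&
                row2$estimate <= row2$ci_high)

  expect_error(fit_linear(y, tibble::tibble(z = z, z2 = 2 * z)),
               "rank-deficient")
})

test_that("the association scan covers strata, toggles, and row order", {
  p <- generative_params(n_subjects = 5000, seed = 14,
                         design = "case_control", n_cases = 120,
                         n_controls = 120)
  co <- generate_cohort(p)
  bm <- beta_matrix(generate_epityper_plates(co),
                    fragment_map = default_fragment_map())
  scan <- association_scan(bm, co)
  # 5 CpGs x 3 strata x 2 models
  expect_equal(nrow(scan), 30L)
  expect_setequal(unique(scan$model), c("logistic", "linear"))

  # per-CpG n differs with per-CpG missingness
  ns <- scan$n[scan$stratum == "all" & scan$model == "logistic"]
  expect_gt(length(unique(ns)), 1L)

  # row order of inputs does not change results
  perm <- sample(nrow(bm))
  scan2 <- association_scan(bm[perm, ], co[sample(nrow(co)), ])
  expect_equal(scan2$estimate, scan$estimate, tolerance = 1e-10)

  # sensitivity toggles change the fitted models as documented
  scan_ets <- association_scan(bm, co, drop_ets = TRUE,
                               strata = "all")
  expect_equal(nrow(scan_ets), 10L)
  scan_alc <- association_scan(bm, co, exclude_alcohol = TRUE,
                               strata = "all")
  expect_true(all(scan_alc$n <= scan$n[scan$stratum == "all"],
                  na.rm = TRUE))
})

test_that("parameter recovery: adjusted estimates bracket the truths", {
  p <- generative_params(n_subjects = 20000, seed = 15)
  co <- generate_cohort(p)
  co$z_meth <- as.numeric(standardize(co$meth_CpG_11))
  co$z_area <- as.numeric(standardize(co$placental_area))
  covs <- co[, scan_covariates()]

  lin <- fit_linear(co$z_area,
                    dplyr::bind_cols(tibble::tibble(z_meth = co$z_meth),
                                     covs))
  lrow <- lin[lin$term == "z_meth", ]
  expect_lt(abs(lrow$estimate - p$beta1), 3 * lrow$se)

  logit <- fit_logistic(co$case_status,
                        dplyr::bind_cols(tibble::tibble(
                          z_meth = co$z_meth, z_area = co$z_area), covs))
  expect_lt(abs(logit$estimate[logit$term == "z_area"] - p$theta2),
            3 * logit$se[logit$term == "z_area"])
  expect_lt(abs(logit$estimate[logit$term == "z_meth"] - p$theta1_prime),
            3 * logit$se[logit$term == "z_meth"])
})

test_that("correlation blocks reproduce the printed two-block structure", {
  skip_if_not_installed("MASS")
  cpgs <- c("CpG_2", "CpG_3.4", "CpG_5", "CpG_7", "CpG_11")
  R <- diag(5)
  dimnames(R) <- list(cpgs, cpgs)
  R["CpG_2", "CpG_3.4"] <- R["CpG_3.4", "CpG_2"] <- 0.66
  R["CpG_5", "CpG_7"] <- R["CpG_7", "CpG_5"] <- 0.36
  R["CpG_5", "CpG_11"] <- R["CpG_11", "CpG_5"] <- 0.52
  R["CpG_7", "CpG_11"] <- R["CpG_11", "CpG_7"] <- 0.44
  R[1:2, 3:5] <- R[3:5, 1:2] <- 0.15
  diag(R) <- 1
  set.seed(99)
  X <- MASS::mvrnorm(200, mu = rep(0, 5), Sigma = R, empirical = TRUE)
  colnames(X) <- cpgs
  part <- correlation_blocks(X, cutoff = 0.30)
  expect_length(part$blocks, 2L)
  expect_setequal(part$blocks[[which(vapply(part$blocks, length,
                                            1L) == 2L)]],
                  c("CpG_2", "CpG_3.4"))
  expect_equal(bonferroni_threshold(0.05, part), 0.025)

  # degenerate partitions
  lo <- correlation_blocks(matrix(rnorm(400), 100, 4,
                                  dimnames = list(NULL, letters[1:4])),
                           cutoff = 0.99)
  expect_length(lo$blocks, 4L)
  hi <- correlation_blocks(X, cutoff = 0.10)
  expect_length(hi$blocks, 1L)
})

test_that("the Bonferroni threshold divides alpha by the block count", {
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_equal(bonferroni_threshold(0.1, 1), 0.1)
  expect_error(bonferroni_threshold(0.05, 0), "at least one block")
})
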