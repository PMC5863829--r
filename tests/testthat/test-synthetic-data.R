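test_that("degenerate sizes and determinism contracts hold", {
  p0 <- generative_params(n_subjects = 0)
  empty <- generate_cohort(p0)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("subject_id", "case_status", "placental_area",
                    "meth_CpG_11") %in% names(empty)))

  p <- generative_params(n_subjects = 300, seed = 9)
  expect_identical(generate_cohort(p), generate_cohort(p))

  # different seed, different draw
  p2 <- generative_params(n_subjects = 300, seed = 10)
  expect_false(identical(generate_cohort(p)$meth_CpG_11,
                         generate_cohort(p2)$meth_CpG_11))
})

test_that("an indefinite CpG correlation matrix is rejected", {
  # three mutually negative correlations of -0.9 cannot coexist
  expect_error(
    generative_params(cpg_block_corr = list(within = c(0.2, -0.9),
                                            between = 0)),
    "positive semi-definite")
  expect_error(
    generative_params(cpg_block_corr = list(within = c(1.5, 0.4),
                                            between = 0.1)),
    "\\[-1, 1\\]")
})

test_that("cohort invariants hold: ellipse identity, full-term range", {
  co <- generate_cohort(generative_params(n_subjects = 500, seed = 3))
  expect_true(all(co$placental_major_axis > 0))
  expect_true(all(co$placental_minor_axis > 0))
  expect_equal(co$placental_area,
               round(ellipse_area(co$placental_major_axis,
                                  co$placental_minor_axis), 2))
  expect_true(all(co$gestational_age >= 37 & co$gestational_age <= 42))
  expect_true(all(co$sex %in% c("female", "male")))
})

test_that("marginal beta means and SDs are calibrated at large n", {
  p <- generative_params(n_subjects = 50000, seed = 21)
  co <- generate_cohort(p)
  for (cpg in names(p$cpg_means)) {
    x <- co[[paste0("meth_", cpg)]]
    se_mean <- p$cpg_sds[[cpg]] / sqrt(nrow(co))
    se_sd <- p$cpg_sds[[cpg]] / sqrt(2 * nrow(co))
    expect_lt(abs(mean(x) - p$cpg_means[[cpg]]), 3 * se_mean)
    expect_lt(abs(sd(x) - p$cpg_sds[[cpg]]), 3 * se_sd)
  }
  # block correlation structure is reproduced
  Z <- as.matrix(co[, paste0("meth_", names(p$cpg_means))])
  C <- cor(Z)
  expect_equal(C["meth_CpG_2", "meth_CpG_3.4"], 0.66, tolerance = 0.02)
  expect_equal(C["meth_CpG_5", "meth_CpG_11"], 0.44, tolerance = 0.02)
  expect_lt(abs(C["meth_CpG_2", "meth_CpG_11"]), 0.30)
})

test_that("a null generator shows no methylation-outcome association", {
  p <- generative_params(n_subjects = 50000, seed = 5, beta1 = 0,
                         theta1_prime = 0)
  co <- generate_cohort(p)
  z <- as.numeric(standardize(co$meth_CpG_11))
  fit <- fit_logistic(co$case_status, tibble::tibble(z_meth = z))
  row <- fit[fit$term == "z_meth", ]
  expect_lt(abs(row$estimate), 3 * row$se)   # OR ~ 1 within MC error
})

test_that("the mediator model recovers beta1 at large n", {
  p <- generative_params(n_subjects = 10000, seed = 13)
  co <- generate_cohort(p)
  co$z_meth <- as.numeric(standardize(co$meth_CpG_11))
  co$z_area <- as.numeric(standardize(co$placental_area))
  fit <- fit_linear(co$z_area,
                    dplyr::bind_cols(tibble::tibble(z_meth = co$z_meth),
                                     co[, scan_covariates()]))
  row <- fit[fit$term == "z_meth", ]
  expect_lt(abs(row$estimate - p$beta1), 3 * row$se)
})

test_that("closed-form expected effects match direct evaluation", {
  # no mediated path
  p <- generative_params(beta1 = 0)
  eff <- true_effects(p)
  expect_equal(eff$nie_or, 1)
  expect_equal(eff$proportion_mediated, 0)

  # fully mediated
  p <- generative_params(theta1_prime = 0, beta1 = -0.4, theta2 = -0.8)
  eff <- true_effects(p)
  expect_equal(eff$nde_or, 1)
  expect_equal(eff$proportion_mediated, 100)

  # girls-calibrated truths evaluate to the headline decomposition
  p <- generative_params(beta1 = -0.3816, theta2 = -0.8440,
                         theta1_prime = 0.3436)
  eff <- true_effects(p)
  expect_equal(eff$nie_or, exp(-0.3816 * -0.8440))
  expect_equal(eff$nie_or, 1.380, tolerance = 5e-4)
  expect_equal(eff$nde_or, 1.410, tolerance = 5e-4)
  expect_equal(eff$te_or, eff$nde_or * eff$nie_or)
  expect_equal(eff$proportion_mediated, 48.4, tolerance = 1e-2)

  # high-prevalence intercept triggers the rare-outcome warning
  expect_warning(true_effects(generative_params(prevalence_intercept = 0)),
                 "prevalence")
})

test_that("plate simulation honours noise, counts, and concordance", {
  co <- generate_cohort(generative_params(n_subjects = 2000, seed = 2,
                                          design = "case_control",
                                          n_cases = 24, n_controls = 24))
  clean <- assay_params(missing_rate = 0, measurement_noise_sd = 0,
                        censor_low_rate = 0, censor_high_rate = 0)
  pl <- generate_epityper_plates(co, clean, fragment_map = NULL)
  prim <- pl$entries[!pl$entries$is_repeat &
                       !pl$entries$is_conversion_control, ]
  for (cpg in sub("^meth_", "", grep("^meth_", names(co), value = TRUE))) {
    sub <- prim[prim$cpg_id == cpg, ]
    latent <- co[[paste0("meth_", cpg)]][match(sub$sample_id,
                                               co$subject_id)]
    expect_equal(sub$beta, pmin(pmax(latent, 0), 1))
  }
  expect_equal(nrow(pl$ledger), 0L)

  # one repeat event per plate
  reps <- unique(pl$entries[pl$entries$is_repeat,
                            c("batch_id", "sample_id")])
  expect_equal(nrow(reps), length(unique(prim$batch_id)))

  # one conversion control per plate, within the configured range
  conv <- pl$entries[pl$entries$is_conversion_control, ]
  expect_equal(sort(conv$batch_id), sort(unique(prim$batch_id)))
  expect_true(all(conv$beta >= clean$conversion_efficiency_range[1] &
                    conv$beta <= clean$conversion_efficiency_range[2]))

  # plates are half cases / half controls while both groups last
  comp <- table(prim$batch_id[prim$cpg_id == "CpG_11"],
                prim$case_status[prim$cpg_id == "CpG_11"])
  expect_true(all(abs(comp[, 1] - comp[, 2]) <= 1))

  expect_error(generate_epityper_plates(co, clean, cpg_ids = character()),
               "at least one CpG")
  expect_error(generate_epityper_plates(co[0, ], clean), "non-empty")
})

test_that("repeat pairs are concordant at realistic assay noise", {
  co <- generate_cohort(generative_params(n_subjects = 600, seed = 4))
  pl <- generate_epityper_plates(
    co, assay_params(measurement_noise_sd = 0.01, missing_rate = 0,
                     censor_low_rate = 0, censor_high_rate = 0),
    fragment_map = NULL)
  e <- pl$entries
  prim <- e[!e$is_repeat & !e$is_conversion_control, ]
  reps <- e[e$is_repeat, ]
  m <- dplyr::inner_join(reps[, c("sample_id", "cpg_id", "beta")],
                         prim[, c("sample_id", "cpg_id", "beta")],
                         by = c("sample_id", "cpg_id"),
                         suffix = c("_rep", "_orig"))
  frac_ok <- mean(abs(m$beta_rep - m$beta_orig) < 0.05)
  expect_gt(frac_ok, 0.99)
})

test_that("the case-control design subsamples to the requested sizes", {
  p <- generative_params(n_subjects = 6000, seed = 8,
                         design = "case_control",
                         n_cases = 86, n_controls = 79)
  co <- generate_cohort(p)
  expect_equal(sum(co$case_status == 1L), 86L)
  expect_equal(sum(co$case_status == 0L), 79L)
  expect_identical(attr(co, "sampling_design"), "case_control")
  expect_error(
    generate_cohort(generative_params(n_subjects = 100, seed = 8,
                                      design = "case_control")),
    "pool too small")
})
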