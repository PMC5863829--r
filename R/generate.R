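#' Generative parameters of the synthetic mother-baby cohort
#'
#' Bundles the true path coefficients and nuisance parameters of the
#' synthetic cohort.  The causal structure is:
#' standardized methylation at `causal_cpg` (z) shifts standardized
#' placental surface area by `beta1` SD per SD; area and methylation act
#' on the log-odds of full-term low birth weight (FT-LBW) with
#' coefficients `theta2` and `theta1_prime` respectively; covariates act
#' on both the mediator and the outcome through `covariate_effects`.
#'
#' Defaults reproduce the study conditions used throughout the package:
#' five CpG units in two correlation blocks (CpG 2 with CpG 3.4; CpG 5,
#' 7 and 11), per-CpG means and SDs on the beta scale matching the
#' observed case/control pooled values, path coefficients on the
#' girls-calibrated scale (`exp(theta1_prime) = 1.41`,
#' `exp(beta1 * theta2) = 1.38`), and an intercept giving roughly 5%
#' outcome prevalence in a cohort design.
#'
#' @param n_subjects number of mother-baby pairs to draw (cohort pool).
#' @param prevalence_intercept log-odds intercept of the outcome model.
#' @param theta1_prime direct-path log odds ratio per SD methylation.
#' @param theta2 log odds ratio per SD placental area.
#' @param beta1 SD-area change per SD methylation (mediator path).
#' @param covariate_effects named list; each element is
#'   `c(mediator = , outcome = )` giving the covariate's coefficient on
#'   the standardized mediator and its log-OR on the outcome.  Covariates
#'   enter centred (binary ones at their Bernoulli probability,
#'   continuous ones as z-scores) so the intercept controls prevalence.
#' @param cpg_means,cpg_sds named numeric vectors of per-CpG beta means
#'   (in (0,1)) and SDs (> 0).
#' @param cpg_blocks list of character vectors partitioning the CpGs into
#'   correlation blocks.
#' @param cpg_block_corr list with elements `within` (numeric vector, one
#'   correlation per block, recycled) and `between` (single correlation
#'   across blocks).
#' @param mediator_residual_sd SD of the mediator residual on the
#'   standardized scale; `NULL` (default) auto-calibrates to
#'   `sqrt(1 - beta1^2 - var(covariate mediator terms))` so that the
#'   latent standardized area has variance close to 1.
#' @param girl_fraction proportion of girls.
#' @param causal_cpg name of the CpG carrying the causal effect.
#' @param girls_only_effect if `TRUE`, `theta1_prime` and `beta1` apply
#'   in girls only (boys get zero), emulating a sex-specific effect.
#' @param area_mean,area_sd location/scale (cm^2) used to back-transform
#'   the standardized area.
#' @param aspect_ratio_mean,aspect_ratio_sd distribution of the placental
#'   major/minor axis ratio used to decompose area into axes.
#' @param design `"cohort"` (keep everyone) or `"case_control"`
#'   (subsample `n_cases` cases and `n_controls` controls from the pool).
#' @param n_cases,n_controls case-control subsample sizes (used only when
#'   `design = "case_control"`; defaults mirror the 86:79 study design).
#' @param seed integer seed; identical parameter sets (including seed)
#'   give bit-identical cohorts.
#'
#' @return an object of class `generative_params` (a validated list).
#' @export
generative_params <- function(n_subjects = 2000,
                              prevalence_intercept = -3.4,
                              theta1_prime = 0.3436,
                              theta2 = -0.8440,
                              beta1 = -0.3816,
                              covariate_effects = default_covariate_effects(),
                              cpg_means = default_cpg_means(),
                              cpg_sds = default_cpg_sds(),
                              cpg_blocks = default_cpg_blocks(),
                              cpg_block_corr = list(within = c(0.66, 0.44),
                                                    between = 0.15),
                              mediator_residual_sd = NULL,
                              girl_fraction = 0.588,
                              causal_cpg = "CpG_11",
                              girls_only_effect = FALSE,
                              area_mean = 275,
                              area_sd = 55,
                              aspect_ratio_mean = 1.08,
                              aspect_ratio_sd = 0.04,
                              design = c("cohort", "case_control"),
                              n_cases = 86,
                              n_controls = 79,
                              seed = 1L) {
  design <- match.arg(design)
  assert_number(n_subjects, "n_subjects", lower = 0)
  assert_number(prevalence_intercept, "prevalence_intercept")
  assert_number(theta1_prime, "theta1_prime")
  assert_number(theta2, "theta2")
  assert_number(beta1, "beta1")
  assert_number(girl_fraction, "girl_fraction", 0, 1)
  assert_number(area_mean, "area_mean", lower = 1)
  assert_number(area_sd, "area_sd", lower = 0)
  assert_flag(girls_only_effect, "girls_only_effect")
  assert_number(seed, "seed")

  if (is.null(names(cpg_means)) || is.null(names(cpg_sds)) ||
      !setequal(names(cpg_means), names(cpg_sds))) {
    stop("`cpg_means` and `cpg_sds` must be named over the same CpGs",
         call. = FALSE)
  }
  if (any(cpg_means <= 0 | cpg_means >= 1)) {
    stop("`cpg_means` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(cpg_sds <= 0)) stop("`cpg_sds` must be > 0", call. = FALSE)
  if (!setequal(unlist(cpg_blocks), names(cpg_means))) {
    stop("`cpg_blocks` must partition the CpGs named in `cpg_means`",
         call. = FALSE)
  }
  if (!causal_cpg %in% names(cpg_means)) {
    stop("`causal_cpg` ('", causal_cpg, "') is not among the CpGs",
         call. = FALSE)
  }
  corr_all <- c(cpg_block_corr$within, cpg_block_corr$between)
  if (any(abs(corr_all) > 1)) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  for (eff in covariate_effects) {
    if (length(eff) != 2L || !all(c("mediator", "outcome") %in% names(eff))) {
      stop("each covariate effect must be c(mediator = , outcome = )",
           call. = FALSE)
    }
  }

  # implied CpG correlation matrix must be PSD (psd_sqrt errors otherwise)
  R <- build_cpg_correlation(names(cpg_means), cpg_blocks, cpg_block_corr)
  psd_sqrt(R)

  if (is.null(mediator_residual_sd)) {
    var_med_cov <- covariate_term_variance(covariate_effects, "mediator",
                                           girl_fraction)
    mediator_residual_sd <- sqrt(max(0.05, 1 - beta1^2 - var_med_cov))
  }
  assert_number(mediator_residual_sd, "mediator_residual_sd", lower = 1e-8)

  structure(
    list(n_subjects = as.integer(n_subjects),
         prevalence_intercept = prevalence_intercept,
         theta1_prime = theta1_prime,
         theta2 = theta2,
         beta1 = beta1,
         covariate_effects = covariate_effects,
         cpg_means = cpg_means,
         cpg_sds = cpg_sds,
         cpg_blocks = cpg_blocks,
         cpg_block_corr = cpg_block_corr,
         mediator_residual_sd = mediator_residual_sd,
         girl_fraction = girl_fraction,
         causal_cpg = causal_cpg,
         girls_only_effect = girls_only_effect,
         area_mean = area_mean,
         area_sd = area_sd,
         aspect_ratio_mean = aspect_ratio_mean,
         aspect_ratio_sd = aspect_ratio_sd,
         design = design,
         n_cases = as.integer(n_cases),
         n_controls = as.integer(n_controls),
         seed = as.integer(seed)),
    class = "generative_params")
}

#' @rdname generative_params
#' @export
default_cpg_means <- function() {
  c(CpG_2 = 0.36, CpG_3.4 = 0.365, CpG_5 = 0.48, CpG_7 = 0.185,
    CpG_11 = 0.37)
}

#' @rdname generative_params
#' @export
default_cpg_sds <- function() {
  c(CpG_2 = 0.21, CpG_3.4 = 0.08, CpG_5 = 0.13, CpG_7 = 0.12,
    CpG_11 = 0.10)
}

#' @rdname generative_params
#' @export
default_cpg_blocks <- function() {
  list(block1 = c("CpG_2", "CpG_3.4"),
       block2 = c("CpG_5", "CpG_7", "CpG_11"))
}

#' Default covariate effects of the synthetic cohort
#'
#' Modest effects of maternal education (college or above), low family
#' income, environmental tobacco smoke (ETS) exposure, maternal age,
#' gestational age and newborn sex on the standardized mediator and on
#' the outcome log-odds.  Covariates do not influence methylation, so
#' they are precision variables, not exposure confounders.
#'
#' @return named list of `c(mediator = , outcome = )` vectors.
#' @export
default_covariate_effects <- function() {
  list(education       = c(mediator =  0.10, outcome = -0.25),
       income_low      = c(mediator = -0.10, outcome =  0.30),
       ets_exposure    = c(mediator = -0.12, outcome =  0.30),
       maternal_age    = c(mediator =  0.05, outcome = -0.05),
       gestational_age = c(mediator =  0.08, outcome = -0.10),
       sex_girl        = c(mediator =  0.00, outcome =  0.00))
}

# marginal distribution constants of the simulated covariates
COV_PROBS <- c(education = 0.41, income_low = 0.55, ets_exposure = 0.30,
               alcohol_use = 0.042, parity_primi = 0.727)
AGE_MEAN <- 28; AGE_SD <- 5
GA_MEAN <- 38.03; GA_SD <- 0.97

covariate_term_variance <- function(effects, which, girl_fraction) {
  v <- 0
  for (nm in names(effects)) {
    coefv <- effects[[nm]][[which]]
    varx <- switch(nm,
      education = COV_PROBS[["education"]] * (1 - COV_PROBS[["education"]]),
      income_low = COV_PROBS[["income_low"]] * (1 - COV_PROBS[["income_low"]]),
      ets_exposure = COV_PROBS[["ets_exposure"]] *
        (1 - COV_PROBS[["ets_exposure"]]),
      maternal_age = 1,     # enters as z-score
      gestational_age = 1,  # enters as z-score
      sex_girl = girl_fraction * (1 - girl_fraction),
      stop("unknown covariate '", nm, "' in covariate_effects",
           call. = FALSE))
    v <- v + coefv^2 * varx
  }
  v
}

build_cpg_correlation <- function(cpgs, blocks, corr) {
  k <- length(cpgs)
  R <- matrix(corr$between, k, k, dimnames = list(cpgs, cpgs))
  within <- rep_len(corr$within, length(blocks))
  for (b in seq_along(blocks)) {
    idx <- match(blocks[[b]], cpgs)
    R[idx, idx] <- within[b]
  }
  diag(R) <- 1
  R
}

# centred covariate design used in both the mediator and outcome linear
# predictors; centring keeps the intercept interpretable as the log-odds
# at covariate means
centred_covariates <- function(cohort, girl_fraction) {
  list(education = cohort$education - COV_PROBS[["education"]],
       income_low = cohort$income_low - COV_PROBS[["income_low"]],
       ets_exposure = cohort$ets_exposure - COV_PROBS[["ets_exposure"]],
       maternal_age = (cohort$maternal_age - AGE_MEAN) / AGE_SD,
       gestational_age = (cohort$gestational_age - GA_MEAN) / GA_SD,
       sex_girl = as.numeric(cohort$sex == "female") - girl_fraction)
}

covariate_lp <- function(cohort, effects, which, girl_fraction) {
  xs <- centred_covariates(cohort, girl_fraction)
  lp <- numeric(nrow(cohort))
  for (nm in names(effects)) lp <- lp + effects[[nm]][[which]] * xs[[nm]]
  lp
}

#' Generate a synthetic mother-baby cohort with known causal structure
#'
#' Draws, in a fixed documented order, (1) covariates column by column
#' (sex, maternal age, education, income, ETS, alcohol, parity,
#' gestational age), (2) the latent standardized methylation matrix with
#' the block correlation structure, (3) the mediator residual, (4) the
#' outcome uniforms, (5) the placental aspect ratio, and (6) placental
#' weight noise.  The standardized area is
#' `beta1 * z_meth + covariate terms + Normal(0, mediator_residual_sd)`;
#' the outcome is Bernoulli on
#' `plogis(intercept + theta1_prime * z_meth + theta2 * z_area + covariate terms)`.
#' The area is back-transformed to cm^2 and decomposed into major/minor
#' axes (rounded to 0.1 cm) so that the recorded area equals the ellipse
#' formula applied to the recorded axes.
#'
#' Per-CpG methylation columns (`meth_*`) hold *latent* beta values
#' (mean + SD * z); they are not clipped to `[0, 1]` — clipping happens
#' at the assay stage in [generate_epityper_plates()] — so marginal
#' means and SDs are exactly calibrated.
#'
#' @param params a [generative_params()] object.
#' @return a tibble with one row per subject: identifiers, covariates,
#'   outcome flag, placental measures, and `meth_<CpG>` columns.  The
#'   generating parameters and sampling design are attached as
#'   attributes `params` and `sampling_design`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "generative_params"))
  n <- params$n_subjects
  cpgs <- names(params$cpg_means)

  if (n == 0L) {
    empty <- empty_cohort(cpgs)
    attr(empty, "params") <- params
    attr(empty, "sampling_design") <- params$design
    return(empty)
  }

  set.seed(params$seed)

  # (1) covariates, column by column
  sex <- ifelse(stats::runif(n) < params$girl_fraction, "female", "male")
  maternal_age <- round(rtruncnorm(n, AGE_MEAN, AGE_SD, 18, 45), 1)
  education <- as.integer(stats::runif(n) < COV_PROBS[["education"]])
  income_low <- as.integer(stats::runif(n) < COV_PROBS[["income_low"]])
  ets_exposure <- as.integer(stats::runif(n) < COV_PROBS[["ets_exposure"]])
  alcohol_use <- as.integer(stats::runif(n) < COV_PROBS[["alcohol_use"]])
  parity <- as.integer(stats::runif(n) < COV_PROBS[["parity_primi"]])
  gestational_age <- round(rtruncnorm(n, GA_MEAN, GA_SD, 37, 42), 1)

  cohort <- tibble::tibble(
    subject_id = sprintf("S%06d", seq_len(n)),
    sex = sex, maternal_age = maternal_age, education = education,
    income_low = income_low, ets_exposure = ets_exposure,
    alcohol_use = alcohol_use, parity = parity,
    gestational_age = gestational_age)

  # (2) latent standardized methylation with block correlation
  R <- build_cpg_correlation(cpgs, params$cpg_blocks, params$cpg_block_corr)
  Z <- matrix(stats::rnorm(n * length(cpgs)), n, length(cpgs)) %*%
    t(psd_sqrt(R))
  colnames(Z) <- cpgs
  z_causal <- Z[, params$causal_cpg]

  effect_on <- if (params$girls_only_effect) {
    as.numeric(sex == "female")
  } else {
    rep(1, n)
  }

  # (3) mediator: standardized placental area
  med_lp <- covariate_lp(cohort, params$covariate_effects, "mediator",
                         params$girl_fraction)
  z_area <- params$beta1 * effect_on * z_causal + med_lp +
    stats::rnorm(n, 0, params$mediator_residual_sd)

  # (4) outcome
  out_lp <- params$prevalence_intercept +
    params$theta1_prime * effect_on * z_causal +
    params$theta2 * z_area +
    covariate_lp(cohort, params$covariate_effects, "outcome",
                 params$girl_fraction)
  case_status <- as.integer(stats::runif(n) < stats::plogis(out_lp))

  # (5) back-transform area and decompose into axes
  area_latent <- pmax(50, params$area_mean + params$area_sd * z_area)
  ratio <- rtruncnorm(n, params$aspect_ratio_mean, params$aspect_ratio_sd,
                      1, 1.3)
  minor <- round(sqrt(4 * area_latent / (pi * ratio)), 1)
  major <- round(ratio * sqrt(4 * area_latent / (pi * ratio)), 1)
  placental_area <- round(ellipse_area(major, minor), 2)

  # (6) placental weight loosely tracks area
  placental_weight <- round(231.6 + 0.92 * area_latent +
                              stats::rnorm(n, 0, 40), 1)

  cohort$case_status <- case_status
  cohort$placental_major_axis <- major
  cohort$placental_minor_axis <- minor
  cohort$placental_area <- placental_area
  cohort$placental_weight <- placental_weight

  B <- sweep(sweep(Z, 2, params$cpg_sds[cpgs], `*`), 2,
             params$cpg_means[cpgs], `+`)
  colnames(B) <- paste0("meth_", cpgs)
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(B))

  design <- params$design
  if (design == "case_control") {
    case_idx <- which(cohort$case_status == 1L)
    ctrl_idx <- which(cohort$case_status == 0L)
    if (length(case_idx) < params$n_cases ||
        length(ctrl_idx) < params$n_controls) {
      stop("cohort pool too small for the requested case-control ",
           "subsample (", length(case_idx), " cases / ", length(ctrl_idx),
           " controls available); increase n_subjects", call. = FALSE)
    }
    keep <- sort(c(case_idx[seq_len(params$n_cases)],
                   ctrl_idx[seq_len(params$n_controls)]))
    cohort <- cohort[keep, ]
  }

  attr(cohort, "params") <- params
  attr(cohort, "sampling_design") <- design
  cohort
}

empty_cohort <- function(cpgs) {
  base <- tibble::tibble(
    subject_id = character(), sex = character(), maternal_age = numeric(),
    education = integer(), income_low = integer(),
    ets_exposure = integer(), alcohol_use = integer(), parity = integer(),
    gestational_age = numeric(), case_status = integer(),
    placental_major_axis = numeric(), placental_minor_axis = numeric(),
    placental_area = numeric(), placental_weight = numeric())
  for (cpg in cpgs) base[[paste0("meth_", cpg)]] <- numeric()
  base
}

#' Assay parameters for the EpiTYPER-style plate simulator
#'
#' @param batch_size samples per plate (must be even: each plate is half
#'   cases and half controls as far as the cohort allows).
#' @param repeat_per_batch number of samples per plate re-assayed as
#'   internal repeats.
#' @param conversion_efficiency_range interval from which each plate's
#'   bisulfite conversion efficiency is drawn.
#' @param missing_rate probability that a readout is missing ("poor
#'   readout").
#' @param measurement_noise_sd SD of assay noise on the beta scale.
#' @param censor_low_rate,censor_high_rate probability that a readout is
#'   forced below 0.05 / above 0.95, exercising the detection-limit
#'   censoring filter; all injected events are recorded in the plate
#'   set's ledger.
#' @param seed integer seed of the assay draws.
#' @return an object of class `assay_params`.
#' @export
assay_params <- function(batch_size = 24,
                         repeat_per_batch = 1,
                         conversion_efficiency_range = c(0.985, 0.999),
                         missing_rate = 0.05,
                         measurement_noise_sd = 0.01,
                         censor_low_rate = 0.02,
                         censor_high_rate = 0.005,
                         seed = 100L) {
  assert_number(batch_size, "batch_size", lower = 2)
  if (batch_size %% 2 != 0) stop("`batch_size` must be even", call. = FALSE)
  assert_number(repeat_per_batch, "repeat_per_batch", lower = 0)
  assert_number(missing_rate, "missing_rate", 0, 1)
  assert_number(measurement_noise_sd, "measurement_noise_sd", lower = 0)
  assert_number(censor_low_rate, "censor_low_rate", 0, 1)
  assert_number(censor_high_rate, "censor_high_rate", 0, 1)
  if (length(conversion_efficiency_range) != 2L ||
      any(conversion_efficiency_range < 0 | conversion_efficiency_range > 1) ||
      diff(conversion_efficiency_range) < 0) {
    stop("`conversion_efficiency_range` must be an increasing interval in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(batch_size = as.integer(batch_size),
         repeat_per_batch = as.integer(repeat_per_batch),
         conversion_efficiency_range = conversion_efficiency_range,
         missing_rate = missing_rate,
         measurement_noise_sd = measurement_noise_sd,
         censor_low_rate = censor_low_rate,
         censor_high_rate = censor_high_rate,
         seed = as.integer(seed)),
    class = "assay_params")
}

#' Default fragment map of the assayed amplicon
#'
#' CpG 3 and CpG 4 sit on mass-overlapping fragments and are reported as
#' the composite unit "CpG 3.4" (the mean of the two fragments); the
#' plate simulator emits the member fragments, and
#' [aggregate_fragments()] recombines them.
#'
#' @return named list mapping composite CpG id to member fragment ids.
#' @export
default_fragment_map <- function() {
  list(CpG_3.4 = c("CpG_3", "CpG_4"))
}

#' Simulate EpiTYPER-style methylation plates from a cohort
#'
#' Assigns subjects to plates alternating case/control so each plate is
#' as close to half cases / half controls as the cohort allows, then
#' emits one long-format readout per sample and assay unit: latent beta
#' plus Normal noise, clipped to `[0, 1]`.  Composite CpGs listed in
#' `fragment_map` are emitted as their member fragments (each an
#' independently noisy copy of the latent composite value).  Missingness
#' and detection-limit censoring are injected at the configured rates
#' and recorded in an event ledger.  Each plate carries
#' `repeat_per_batch` re-assayed samples and one bisulfite conversion
#' control entry.
#'
#' @param cohort a cohort from [generate_cohort()] (non-empty).
#' @param assay an [assay_params()] object.
#' @param cpg_ids CpG units to assay; defaults to the cohort's `meth_*`
#'   columns.
#' @param fragment_map composite-to-fragment mapping (see
#'   [default_fragment_map()]); `NULL` emits every unit directly.
#' @return an object of class `plate_set`: a list with `entries` (tibble:
#'   `sample_id, cpg_id, batch_id, beta, is_repeat,
#'   is_conversion_control, case_status`) and `ledger` (tibble of
#'   injected missing/censoring events).
#' @export
generate_epityper_plates <- function(cohort, assay = assay_params(),
                                     cpg_ids = NULL,
                                     fragment_map = default_fragment_map()) {
  stopifnot(inherits(assay, "assay_params"))
  if (nrow(cohort) == 0L) stop("`cohort` must be non-empty", call. = FALSE)
  meth_cols <- grep("^meth_", names(cohort), value = TRUE)
  if (is.null(cpg_ids)) cpg_ids <- sub("^meth_", "", meth_cols)
  if (length(cpg_ids) == 0L) {
    stop("`cpg_ids` must name at least one CpG unit", call. = FALSE)
  }
  missing_units <- setdiff(cpg_ids, sub("^meth_", "", meth_cols))
  if (length(missing_units) > 0L) {
    stop("cohort has no methylation column for: ",
         paste(missing_units, collapse = ", "), call. = FALSE)
  }

  set.seed(assay$seed)

  # plate assignment: alternate cases and controls
  case_ids <- cohort$subject_id[cohort$case_status == 1L]
  ctrl_ids <- cohort$subject_id[cohort$case_status == 0L]
  ord <- character(0)
  i <- j <- 1L
  while (i <= length(case_ids) || j <= length(ctrl_ids)) {
    if (i <= length(case_ids)) { ord <- c(ord, case_ids[i]); i <- i + 1L }
    if (j <= length(ctrl_ids)) { ord <- c(ord, ctrl_ids[j]); j <- j + 1L }
  }
  batch_of <- stats::setNames(
    sprintf("plate_%02d", ceiling(seq_along(ord) / assay$batch_size)), ord)
  n_batches <- length(unique(batch_of))

  # assay units: fragments replace their composite
  units <- unlist(lapply(cpg_ids, function(cpg) {
    if (!is.null(fragment_map) && cpg %in% names(fragment_map)) {
      fragment_map[[cpg]]
    } else {
      cpg
    }
  }), use.names = FALSE)
  latent_of <- stats::setNames(rep(cpg_ids, vapply(cpg_ids, function(cpg) {
    if (!is.null(fragment_map) && cpg %in% names(fragment_map)) {
      length(fragment_map[[cpg]])
    } else {
      1L
    }
  }, integer(1))), units)

  n <- nrow(cohort)
  latent <- as.matrix(cohort[, paste0("meth_", latent_of[units]),
                             drop = FALSE])
  colnames(latent) <- units

  entries <- list()
  ledger <- list()
  # draws column-wise per unit: noise, then missing mask, then censor masks
  for (u in units) {
    beta <- as.numeric(clip01(latent[, u] +
                                stats::rnorm(n, 0,
                                             assay$measurement_noise_sd)))
    miss <- stats::runif(n) < assay$missing_rate
    cen_lo <- !miss & (stats::runif(n) < assay$censor_low_rate)
    cen_hi <- !miss & !cen_lo & (stats::runif(n) < assay$censor_high_rate)
    beta[cen_lo] <- stats::runif(sum(cen_lo), 0.005, 0.045)
    beta[cen_hi] <- stats::runif(sum(cen_hi), 0.955, 0.995)
    beta[miss] <- NA_real_
    entries[[u]] <- tibble::tibble(
      sample_id = cohort$subject_id, cpg_id = u,
      batch_id = unname(batch_of[cohort$subject_id]),
      beta = beta, is_repeat = FALSE, is_conversion_control = FALSE,
      case_status = cohort$case_status)
    ev <- c(rep("missing", sum(miss)), rep("censor_low", sum(cen_lo)),
            rep("censor_high", sum(cen_hi)))
    if (length(ev) > 0L) {
      ledger[[u]] <- tibble::tibble(
        sample_id = c(cohort$subject_id[miss], cohort$subject_id[cen_lo],
                      cohort$subject_id[cen_hi]),
        cpg_id = u, event = ev)
    }
  }
  entries <- dplyr::bind_rows(entries)
  ledger <- if (length(ledger) > 0L) {
    dplyr::bind_rows(ledger)
  } else {
    tibble::tibble(sample_id = character(), cpg_id = character(),
                   event = character())
  }

  # internal repeats: re-assay whole samples (all units) with fresh noise
  batches <- sort(unique(entries$batch_id))
  repeats <- list()
  for (b in batches) {
    in_batch <- names(batch_of)[batch_of == b]
    k <- min(assay$repeat_per_batch, length(in_batch))
    if (k == 0L) next
    picked <- sample(in_batch, k)
    for (sid in picked) {
      ridx <- match(sid, cohort$subject_id)
      repeats[[paste(b, sid)]] <- tibble::tibble(
        sample_id = sid, cpg_id = units, batch_id = b,
        beta = as.numeric(clip01(latent[ridx, units] +
                                   stats::rnorm(length(units), 0,
                                                assay$measurement_noise_sd))),
        is_repeat = TRUE, is_conversion_control = FALSE,
        case_status = cohort$case_status[ridx])
    }
  }

  conv <- tibble::tibble(
    sample_id = paste0("CONV_", batches), cpg_id = "conversion_control",
    batch_id = batches,
    beta = stats::runif(n_batches, assay$conversion_efficiency_range[1],
                        assay$conversion_efficiency_range[2]),
    is_repeat = FALSE, is_conversion_control = TRUE,
    case_status = NA_integer_)

  entries <- dplyr::bind_rows(entries, dplyr::bind_rows(repeats), conv)
  structure(list(entries = entries, ledger = ledger), class = "plate_set")
}

#' Closed-form expected natural effects implied by generative parameters
#'
#' Under a rare outcome the logistic model is approximately log-linear,
#' so the natural direct effect is `exp(theta1_prime)`, the natural
#' indirect effect is `exp(beta1 * theta2)`, the total effect is their
#' product, and the proportion mediated is
#' `100 * ln(NIE) / ln(TE)`.  Used as the independent oracle for the
#' simulation-based estimator.  A warning is raised when the prevalence
#' implied by the intercept exceeds `prevalence_warn` (default 10%),
#' where the rare-outcome approximation degrades.
#'
#' @param params a [generative_params()] object.
#' @param prevalence_warn prevalence above which a warning is issued.
#' @return list with `nde_or`, `nie_or`, `te_or`, `proportion_mediated`.
#' @export
true_effects <- function(params, prevalence_warn = 0.10) {
  stopifnot(inherits(params, "generative_params"))
  prev <- stats::plogis(params$prevalence_intercept)
  if (prev > prevalence_warn) {
    warning("implied baseline prevalence ", signif(prev, 3),
            " exceeds ", prevalence_warn,
            "; rare-outcome closed forms are approximate", call. = FALSE)
  }
  nde <- exp(params$theta1_prime)
  nie <- exp(params$beta1 * params$theta2)
  te <- nde * nie
  lte <- log(te)
  prop <- if (abs(log(nie)) < 1e-12) {
    0
  } else if (abs(lte) < 1e-12) {
    stop("proportion mediated is undefined: total effect OR is 1 ",
         "with a non-null indirect effect", call. = FALSE)
  } else {
    100 * log(nie) / lte
  }
  list(nde_or = nde, nie_or = nie, te_or = te, proportion_mediated = prop)
}
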