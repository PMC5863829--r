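#' Sobel test of the mediated (indirect) path
#'
#' Tests the product of the exposure-to-mediator coefficient (`beta1`)
#' and the mediator-to-outcome log-OR (`theta2`):
#' `z = beta1 * theta2 / sqrt(beta1^2 * se_theta2^2 + theta2^2 * se_beta1^2)`
#' with a two-sided p-value from the standard normal.
#'
#' @param beta1,se_beta1 exposure-to-mediator coefficient and SE.
#' @param theta2,se_theta2 mediator-to-outcome log-OR and SE.
#' @return list with `z` and `p`.
#' @export
sobel_test <- function(beta1, se_beta1, theta2, se_theta2) {
  assert_number(beta1, "beta1"); assert_number(theta2, "theta2")
  assert_number(se_beta1, "se_beta1", lower = 0)
  assert_number(se_theta2, "se_theta2", lower = 0)
  if (se_beta1 <= 0 || se_theta2 <= 0) {
    stop("standard errors must be > 0", call. = FALSE)
  }
  denom2 <- beta1^2 * se_theta2^2 + theta2^2 * se_beta1^2
  if (denom2 == 0) {
    stop("Sobel statistic undefined: both path coefficients are zero",
         call. = FALSE)
  }
  z <- beta1 * theta2 / sqrt(denom2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Estimate the four mediation path coefficients
#'
#' Fits the three regressions behind the mediation-condition checks:
#' the outcome on exposure and covariates (`theta1`), the outcome on
#' exposure, mediator, and covariates (`theta1_prime`, `theta2`; both
#' log-ORs), and the mediator on exposure and covariates (`beta1`,
#' linear, SD units when both sides are standardized).
#'
#' @param data subject-level data frame.
#' @param outcome name of the binary outcome column.
#' @param exposure,mediator names of the standardized exposure and
#'   mediator columns.
#' @param covariates covariate column names.
#' @return object of class `mediation_paths`: list with elements
#'   `theta1`, `theta1_prime`, `theta2`, `beta1`, each
#'   `list(estimate, se, p)`, plus per-model `n`.
#' @export
estimate_mediation_paths <- function(data, outcome = "case_status",
                                     exposure, mediator,
                                     covariates = character()) {
  pull_term <- function(tab, term) {
    r <- tab[tab$term == term, ]
    list(estimate = r$estimate, se = r$se, p = r$p, n = r$n[1])
  }
  terms_x <- data[, c(exposure, covariates), drop = FALSE]
  terms_xm <- data[, c(exposure, mediator, covariates), drop = FALSE]
  m_total <- fit_logistic(data[[outcome]], terms_x)
  m_full <- fit_logistic(data[[outcome]], terms_xm)
  m_med <- fit_linear(data[[mediator]], terms_x)
  structure(
    list(theta1 = pull_term(m_total, exposure),
         theta1_prime = pull_term(m_full, exposure),
         theta2 = pull_term(m_full, mediator),
         beta1 = pull_term(m_med, exposure),
         exposure = exposure, mediator = mediator,
         covariates = covariates),
    class = "mediation_paths")
}

star_for <- function(p) {
  if (is.na(p)) "" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' @export
print.mediation_paths <- function(x, ...) {
  cat("Mediation path estimates (", x$exposure, " -> ", x$mediator,
      " -> outcome)\n", sep = "")
  for (nm in c("theta1", "theta1_prime", "theta2", "beta1")) {
    e <- x[[nm]]
    cat(sprintf("  %-12s % .4f (se %.4f)%s\n", nm, e$estimate, e$se,
                star_for(e$p)))
  }
  cat("  * p < 0.05; ** p < 0.01\n")
  invisible(x)
}

#' Check the four mediation-presence conditions
#'
#' Mediation is considered present when (a) the exposure is associated
#' with the mediator (`beta1` significant), (b) the exposure is
#' associated with the outcome without adjusting for the mediator
#' (`theta1` significant), (c) the mediator is associated with the
#' outcome (`theta2` significant), and (d) the exposure-outcome
#' association becomes weaker once the mediator enters the model
#' (strict attenuation `|theta1_prime| < |theta1|`).  The attenuation
#' percentage `100 * (1 - |theta1_prime| / |theta1|)` is reported.
#'
#' @param paths a [estimate_mediation_paths()] object (or a list with
#'   the same structure).
#' @param alpha significance level for conditions (a)-(c).
#' @return object of class `condition_report`: flags `a`-`d`, the
#'   overall `verdict` (all four true), `attenuation_pct`, `alpha`, and
#'   the supporting estimates.
#' @export
check_mediation_conditions <- function(paths, alpha = 0.05) {
  assert_number(alpha, "alpha", 1e-12, 1)
  need <- c("theta1", "theta1_prime", "theta2", "beta1")
  for (nm in need) {
    e <- paths[[nm]]
    if (is.null(e) || is.null(e$estimate) || is.null(e$p)) {
      stop("incomplete path estimates: missing '", nm, "'", call. = FALSE)
    }
  }
  a <- paths$beta1$p < alpha
  b <- paths$theta1$p < alpha
  c_ <- paths$theta2$p < alpha
  d <- abs(paths$theta1_prime$estimate) < abs(paths$theta1$estimate)
  attenuation <- if (paths$theta1$estimate == 0) {
    NA_real_
  } else {
    100 * (1 - abs(paths$theta1_prime$estimate) /
             abs(paths$theta1$estimate))
  }
  structure(
    list(a = a, b = b, c = c_, d = d, verdict = a && b && c_ && d,
         attenuation_pct = attenuation, alpha = alpha, paths = paths),
    class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  lab <- c(a = "exposure -> mediator significant",
           b = "exposure -> outcome (no mediator) significant",
           c = "mediator -> outcome significant",
           d = "attenuation |theta1'| < |theta1|")
  cat("Mediation conditions (alpha =", x$alpha, "):\n")
  for (f in names(lab)) {
    cat(sprintf("  (%s) %-46s %s\n", f, lab[[f]],
                if (isTRUE(x[[f]])) "yes" else "no"))
  }
  cat("  verdict:", if (x$verdict) "mediation present" else "not present",
      "\n")
  if (is.finite(x$attenuation_pct)) {
    cat(sprintf("  attenuation: %.1f%%\n", x$attenuation_pct))
  }
  invisible(x)
}

#' Counterfactual exposure expansion for the natural-effects model
#'
#' Replicates each row once per grid offset, carrying `x_direct =
#' x + offset` (the hypothetical exposure routed through the direct
#' path) and `x_indirect = x` (the observed exposure whose mediator
#' value the row keeps).  Mediator and covariates are unchanged;
#' `.source_row` links replicas to their source subject.
#'
#' @param data subject-level data frame.
#' @param exposure name of the (standardized) exposure column.
#' @param offsets numeric grid of exposure offsets; the default
#'   `c(0, -1)` makes the fitted effects per-one-SD contrasts.
#' @return expanded tibble with `x_direct`, `x_indirect`, `.offset`,
#'   `.source_row`.
#' @export
expand_counterfactual <- function(data, exposure, offsets = c(0, -1)) {
  if (length(offsets) == 0L) {
    stop("`offsets` grid must not be empty", call. = FALSE)
  }
  if (!exposure %in% names(data)) {
    stop("exposure column '", exposure, "' not found", call. = FALSE)
  }
  x <- data[[exposure]]
  if (!is.numeric(x)) stop("exposure must be numeric", call. = FALSE)
  out <- lapply(offsets, function(d) {
    rep_i <- tibble::as_tibble(data)
    rep_i$x_direct <- x + d
    rep_i$x_indirect <- x
    rep_i$.offset <- d
    rep_i$.source_row <- seq_len(nrow(data))
    rep_i
  })
  dplyr::bind_rows(out)
}

check_standardized_col <- function(x, name) {
  m <- mean(x); s <- stats::sd(x)
  if (abs(m) > 0.1 || s < 0.9 || s > 1.1) {
    stop("column '", name, "' does not look standardized (mean ",
         signif(m, 3), ", sd ", signif(s, 3),
         "); apply standardize() first", call. = FALSE)
  }
}

#' Imputation-based natural-effects decomposition (point estimates)
#'
#' Decomposes the total exposure-outcome odds ratio into natural direct
#' (NDE) and natural indirect (NIE) components:
#' 1. fit the working logistic model
#'    `outcome ~ exposure + mediator + covariates`;
#' 2. expand each subject over the counterfactual exposure grid
#'    ([expand_counterfactual()]);
#' 3. impute, for each expanded row, the expected outcome from the
#'    working model evaluated at (`x_direct`, observed mediator,
#'    covariates);
#' 4. fit the natural-effects logistic model of the imputed outcome
#'    probabilities on `x_direct + x_indirect + covariates`
#'    (quasibinomial, each expanded row weighted equally);
#' 5. `NDE = exp(coef(x_direct))`, `NIE = exp(coef(x_indirect))`,
#'    `TE = NDE * NIE` (exact, since coefficients add on the log
#'    scale).
#'
#' Estimates from a case-control sample are interpretable as
#' population ORs only under the rare-outcome assumption.
#'
#' @param data subject-level data frame (complete cases used).
#' @param outcome binary outcome column name.
#' @param exposure,mediator standardized exposure and mediator column
#'   names.
#' @param covariates covariate column names.
#' @param offsets counterfactual exposure grid.
#' @param check_standardized verify that exposure and mediator look
#'   standardized (loose check on mean/SD); disable for internal
#'   refits on resampled data.
#' @return object of class `mediation_result` with `nde_or`, `nie_or`,
#'   `te_or`, `proportion_mediated` (percent, log-OR scale), `n`,
#'   `offsets`.
#' @export
fit_natural_effects <- function(data, outcome = "case_status", exposure,
                                mediator, covariates = character(),
                                offsets = c(0, -1),
                                check_standardized = TRUE) {
  cols <- c(outcome, exposure, mediator, covariates)
  absent <- setdiff(cols, names(data))
  if (length(absent) > 0L) {
    stop("column(s) not in data: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(data)[, cols]
  df <- df[stats::complete.cases(df), ]
  if (!all(df[[outcome]] %in% c(0, 1))) {
    stop("`outcome` must be binary 0/1", call. = FALSE)
  }
  if (check_standardized) {
    check_standardized_col(df[[exposure]], exposure)
    check_standardized_col(df[[mediator]], mediator)
  }

  working <- stats::glm(
    stats::reformulate(c(exposure, mediator, covariates),
                       response = outcome),
    data = df, family = stats::binomial())
  if (!working$converged) {
    stop("working outcome model failed to converge", call. = FALSE)
  }

  expanded <- expand_counterfactual(df, exposure, offsets)
  newdata <- expanded
  newdata[[exposure]] <- expanded$x_direct
  expanded$.y_imp <- as.numeric(stats::predict(working, newdata = newdata,
                                               type = "response"))

  ne_fit <- stats::glm(
    stats::reformulate(c("x_direct", "x_indirect", covariates),
                       response = ".y_imp"),
    data = expanded, family = stats::quasibinomial())
  if (!ne_fit$converged) {
    stop("natural-effects model failed to converge", call. = FALSE)
  }
  co <- coef(ne_fit)
  nde <- exp(unname(co["x_direct"]))
  nie <- exp(unname(co["x_indirect"]))
  te <- nde * nie
  prop <- tryCatch(proportion_mediated(nde, nie), error = function(e) NA_real_)
  structure(
    list(nde_or = nde, nie_or = nie, te_or = te,
         proportion_mediated = prop, n = nrow(df), offsets = offsets,
         exposure = exposure, mediator = mediator,
         covariates = covariates, boot = NULL),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  fmt <- function(v, ci) {
    if (is.null(ci)) sprintf("%.3f", v) else {
      sprintf("%.3f [%.3f, %.3f]", v, ci[1], ci[2])
    }
  }
  b <- x$boot
  cat("Natural-effects decomposition (n =", x$n, ")\n")
  cat("  NDE OR:", fmt(x$nde_or, b$nde_ci), "\n")
  cat("  NIE OR:", fmt(x$nie_or, b$nie_ci), "\n")
  cat("  TE  OR:", fmt(x$te_or, b$te_ci), "\n")
  cat(sprintf("  proportion mediated: %.2f%%\n", x$proportion_mediated))
  if (!is.null(b)) {
    cat("  bootstrap:", b$reps_used, "replicates (", b$failures,
        "failed )\n")
  }
  invisible(x)
}

#' Bootstrap confidence intervals for the natural-effects decomposition
#'
#' Nonparametric resampling of subjects (never of expanded replica
#' rows: the counterfactual expansion happens inside each refit), with
#' percentile confidence intervals for NDE, NIE, TE, and the proportion
#' mediated.  Replicate failures are counted; more than 10% failures
#' aborts with an unstable-estimate error.
#'
#' @inheritParams fit_natural_effects
#' @param reps number of bootstrap replicates.
#' @param seed integer seed; fixed seed gives identical output.
#' @param conf_level confidence level of the percentile intervals.
#' @return a `mediation_result` whose `boot` element carries the CIs,
#'   the replicate count, and the failure count.
#' @export
bootstrap_mediation <- function(data, outcome = "case_status", exposure,
                                mediator, covariates = character(),
                                offsets = c(0, -1), reps = 1000,
                                seed = NULL, conf_level = 0.95) {
  assert_number(reps, "reps", lower = 1)
  point <- fit_natural_effects(data, outcome, exposure, mediator,
                               covariates, offsets)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  log_nde <- log_nie <- rep(NA_real_, reps)
  failures <- 0L
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- tryCatch(
      fit_natural_effects(data[idx, ], outcome, exposure, mediator,
                          covariates, offsets,
                          check_standardized = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) {
      failures <- failures + 1L
    } else {
      log_nde[r] <- log(fit$nde_or)
      log_nie[r] <- log(fit$nie_or)
    }
  }
  if (failures > 0.10 * reps) {
    stop("unstable estimate: ", failures, " of ", reps,
         " bootstrap replicates failed", call. = FALSE)
  }
  pr <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  log_te <- log_nde + log_nie
  props <- ifelse(abs(log_te) < 1e-12, NA_real_, 100 * log_nie / log_te)
  point$boot <- list(
    nde_ci = exp(stats::quantile(log_nde, pr, na.rm = TRUE, names = FALSE)),
    nie_ci = exp(stats::quantile(log_nie, pr, na.rm = TRUE, names = FALSE)),
    te_ci = exp(stats::quantile(log_te, pr, na.rm = TRUE, names = FALSE)),
    proportion_ci = stats::quantile(props, pr, na.rm = TRUE, names = FALSE),
    reps_used = as.integer(reps), failures = failures,
    conf_level = conf_level, seed = seed)
  point
}

#' Proportion of the total effect transmitted through the mediator
#'
#' Computed on the log odds ratio scale:
#' `100 * ln(NIE) / (ln(NDE) + ln(NIE))`.  With the reported natural
#' direct effect OR 1.41 and indirect effect OR 1.38 this gives 48.38%.
#'
#' @param nde_or natural direct effect odds ratio (> 0).
#' @param nie_or natural indirect effect odds ratio (> 0).
#' @return proportion mediated, in percent.
#' @export
proportion_mediated <- function(nde_or, nie_or) {
  assert_number(nde_or, "nde_or", lower = 1e-300)
  assert_number(nie_or, "nie_or", lower = 1e-300)
  l_nie <- log(nie_or)
  l_te <- log(nde_or) + l_nie
  if (abs(l_nie) < 1e-12) return(0)
  if (abs(l_te) < 1e-12) {
    stop("proportion mediated undefined: total effect OR is 1",
         call. = FALSE)
  }
  100 * l_nie / l_te
}
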