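#' Area of an ellipse from its axes
#'
#' The placental surface is treated as an ellipse with the maximal
#' surface diameter as major axis and its perpendicular bisecting
#' diameter as minor axis; the surface area is
#' `major * minor * pi / 4` (axes are full diameters, in cm).
#'
#' @param major_axis,minor_axis axis lengths in cm (vectorized, > 0).
#' @return area in cm^2.
#' @export
ellipse_area <- function(major_axis, minor_axis) {
  if (!is.numeric(major_axis) || !is.numeric(minor_axis)) {
    stop("axes must be numeric", call. = FALSE)
  }
  if (any(major_axis <= 0, na.rm = TRUE) ||
      any(minor_axis <= 0, na.rm = TRUE)) {
    stop("axes must be strictly positive", call. = FALSE)
  }
  major_axis * minor_axis * pi / 4
}

#' Standard scores (z-scores) with recorded source scale
#'
#' Computes `z = (x - mu) / sigma` using the sample mean and SD of the
#' non-missing entries (or an explicitly supplied scale), so that
#' regression coefficients are per-SD effects.  Missing entries stay
#' missing.
#'
#' @param x numeric vector with at least two non-missing values.
#' @param center,scale optional explicit mu and sigma; both or neither.
#' @return numeric vector of z-scores with attributes `source_mean` and
#'   `source_sd`.
#' @export
standardize <- function(x, center = NULL, scale = NULL) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (is.null(center) != is.null(scale)) {
    stop("supply both `center` and `scale`, or neither", call. = FALSE)
  }
  if (is.null(center)) {
    if (sum(!is.na(x)) < 2L) {
      stop("need at least two non-missing values to standardize",
           call. = FALSE)
    }
    center <- mean(x, na.rm = TRUE)
    scale <- stats::sd(x, na.rm = TRUE)
  }
  if (!is.finite(scale) || scale <= 0) {
    stop("cannot standardize a zero-variance (constant) series",
         call. = FALSE)
  }
  z <- (x - center) / scale
  attr(z, "source_mean") <- center
  attr(z, "source_sd") <- scale
  z
}

#' Descriptive comparison of cases and controls
#'
#' Continuous variables are summarised as group mean (SD) and compared
#' with the pooled-variance two-sample t test; categorical variables as
#' count (%) and compared with Pearson's chi-squared test (no
#' continuity correction).
#'
#' @param cohort subject table with a binary `case_status` column.
#' @param variables character vector of column names to compare.
#' @param types optional named character vector forcing
#'   `"continuous"`/`"categorical"` per variable; by default numeric
#'   columns with more than two distinct values are continuous.
#' @return tibble with one row per variable: type, per-group summary
#'   strings, test statistic and p-value.
#' @export
compare_groups <- function(cohort, variables, types = NULL) {
  absent <- setdiff(variables, names(cohort))
  if (length(absent) > 0L) {
    stop("variable(s) not in cohort: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  grp <- cohort$case_status
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    type <- if (!is.null(types) && v %in% names(types)) {
      types[[v]]
    } else if (is.numeric(x) && length(unique(stats::na.omit(x))) > 2L) {
      "continuous"
    } else {
      "categorical"
    }
    if (type == "continuous") {
      x1 <- x[grp == 1L]; x0 <- x[grp == 0L]
      tt <- stats::t.test(x1, x0, var.equal = TRUE)
      tibble::tibble(
        variable = v, type = type,
        summary_case = sprintf("%.2f (%.2f)", mean(x1, na.rm = TRUE),
                               stats::sd(x1, na.rm = TRUE)),
        summary_control = sprintf("%.2f (%.2f)", mean(x0, na.rm = TRUE),
                                  stats::sd(x0, na.rm = TRUE)),
        statistic = unname(tt$statistic), p = tt$p.value)
    } else {
      tab <- table(factor(grp, levels = c(1L, 0L)), x)
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      lvl <- colnames(tab)[ncol(tab)]
      tibble::tibble(
        variable = v, type = type,
        summary_case = sprintf("%d (%.2f%%)", tab[1L, lvl],
                               100 * tab[1L, lvl] / sum(tab[1L, ])),
        summary_control = sprintf("%d (%.2f%%)", tab[2L, lvl],
                                  100 * tab[2L, lvl] / sum(tab[2L, ])),
        statistic = unname(ct$statistic), p = ct$p.value)
    }
  })
  dplyr::bind_rows(rows)
}

check_terms_df <- function(terms) {
  terms <- tibble::as_tibble(terms)
  if (ncol(terms) == 0L) stop("no predictor terms supplied", call. = FALSE)
  terms
}

regression_tibble <- function(fit, n, family, conf_level) {
  sm <- summary(fit)
  co <- sm$coefficients
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- co[, 1]; se <- co[, 2]; p <- co[, 4]
  is_logit <- family == "binomial"
  tibble::tibble(
    term = rownames(co), estimate = unname(est), se = unname(se),
    ci_low = unname(est - zc * se), ci_high = unname(est + zc * se),
    p = unname(p), n = n, family = family,
    or = if (is_logit) unname(exp(est)) else NA_real_,
    or_low = if (is_logit) unname(exp(est - zc * se)) else NA_real_,
    or_high = if (is_logit) unname(exp(est + zc * se)) else NA_real_)
}

#' Adjusted logistic regression with Wald inference
#'
#' Maximum-likelihood logistic regression (fitted by iteratively
#' reweighted least squares through [stats::glm()]; convergence when the
#' relative deviance change falls below `1e-8`, at most 100 iterations),
#' returning one row per model term with coefficient (log-OR), standard
#' error from the observed information, symmetric Wald confidence
#' interval, Wald p-value, and the odds ratio with its CI.
#'
#' @param outcome binary (0/1) outcome vector.
#' @param terms data frame of predictors (standardized exposures,
#'   covariates); complete cases are used.
#' @param conf_level confidence level for the Wald interval.
#' @return tibble of per-term results (intercept included, term
#'   `"(Intercept)"`).
#' @export
fit_logistic <- function(outcome, terms, conf_level = 0.95) {
  terms <- check_terms_df(terms)
  df <- dplyr::bind_cols(tibble::tibble(.outcome = outcome), terms)
  df <- df[stats::complete.cases(df), ]
  if (!all(df$.outcome %in% c(0, 1))) {
    stop("`outcome` must be binary 0/1", call. = FALSE)
  }
  if (nrow(df) < ncol(terms) + 2L) {
    stop("too few complete cases (", nrow(df), ") to fit ", ncol(terms),
         " term(s)", call. = FALSE)
  }
  for (nm in names(terms)) {
    v <- df[[nm]]
    if (length(unique(v)) < 2L) {
      stop("predictor '", nm, "' is constant over the analysis sample",
           call. = FALSE)
    }
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.outcome ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) {
    worst <- names(which.max(abs(coef(fit))[-1]))
    stop("logistic model failed to converge (largest coefficient: '",
         worst, "')", call. = FALSE)
  }
  # separation inflates coefficients without bound; with standardized or
  # binary predictors a |log-OR| above 15 is never a real effect
  if (separation || any(abs(coef(fit))[-1] > 15, na.rm = TRUE)) {
    worst <- names(which.max(abs(coef(fit))[-1]))
    stop("(quasi-)complete separation detected for term '", worst, "'",
         call. = FALSE)
  }
  regression_tibble(fit, nrow(df), "binomial", conf_level)
}

#' Adjusted linear regression (ordinary least squares)
#'
#' When both response and exposure are standardized the coefficient is
#' an SD-per-SD effect.  Inference uses normal-approximation Wald
#' intervals on the OLS standard errors, matching the logistic side.
#'
#' @param response numeric response vector.
#' @param terms data frame of predictors; complete cases are used.
#' @param conf_level confidence level.
#' @return tibble of per-term results (`or` columns are `NA`).
#' @export
fit_linear <- function(response, terms, conf_level = 0.95) {
  terms <- check_terms_df(terms)
  df <- dplyr::bind_cols(tibble::tibble(.response = as.numeric(response)),
                         terms)
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) <= ncol(terms) + 1L) {
    stop("too few complete cases (", nrow(df), ") to fit ", ncol(terms),
         " term(s)", call. = FALSE)
  }
  fit <- stats::lm(.response ~ ., data = df)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; aliased term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  regression_tibble(fit, nrow(df), "gaussian", conf_level)
}

default_scan_covariates <- function() {
  c("maternal_age", "education", "income_low", "ets_exposure",
    "gestational_age", "sex")
}

#' Per-CpG adjusted association scan
#'
#' For every QC-retained CpG and stratum, fits (i) the adjusted logistic
#' model FT-LBW ~ z-methylation + covariates and (ii) the adjusted
#' linear model z-area ~ z-methylation + covariates, and reports the
#' z-methylation term.  Methylation and area are standardized within
#' the stratum over all QC-valid values before model-specific
#' complete-case restriction.  Sex strata drop the sex covariate.
#' Sensitivity toggles: `drop_ets` removes the ETS covariate;
#' `exclude_alcohol` drops alcohol-exposed pairs.  A stratum too small
#' to fit yields a diagnostic note; the scan continues.
#'
#' @param beta wide beta matrix from [beta_matrix()] (`sample_id` +
#'   one column per CpG).
#' @param cohort subject table; `subject_id` must match `sample_id`.
#' @param covariates covariate column names (default
#'   [default_scan_covariates()]).
#' @param strata subset of `c("all", "girls", "boys")`.
#' @param drop_ets,exclude_alcohol sensitivity-analysis toggles.
#' @param conf_level confidence level.
#' @return tibble with columns `cpg, stratum, model, term, n, estimate,
#'   se, ci_low, ci_high, p, or, or_low, or_high, note`.
#' @export
association_scan <- function(beta, cohort,
                             covariates = default_scan_covariates(),
                             strata = c("all", "girls", "boys"),
                             drop_ets = FALSE, exclude_alcohol = FALSE,
                             conf_level = 0.95) {
  strata <- match.arg(strata, several.ok = TRUE)
  cpg_cols <- setdiff(names(beta), c("sample_id", "case_status"))
  if (drop_ets) covariates <- setdiff(covariates, "ets_exposure")
  dat <- dplyr::inner_join(beta[, c("sample_id", cpg_cols)], cohort,
                           by = c(sample_id = "subject_id"))
  if (exclude_alcohol) dat <- dat[dat$alcohol_use == 0L, ]

  rows <- list()
  for (st in strata) {
    sub <- switch(st,
                  all = dat,
                  girls = dat[dat$sex == "female", ],
                  boys = dat[dat$sex == "male", ])
    covs <- if (st == "all") covariates else setdiff(covariates, "sex")
    z_area <- tryCatch(standardize(sub$placental_area),
                       error = function(e) NULL)
    for (cpg in cpg_cols) {
      z_meth <- tryCatch(standardize(sub[[cpg]]), error = function(e) NULL)
      base <- tibble::tibble(cpg = cpg, stratum = st)
      if (is.null(z_meth)) {
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          base, tibble::tibble(model = c("logistic", "linear"),
                               note = "degenerate methylation series"))
        next
      }
      terms <- dplyr::bind_cols(tibble::tibble(z_meth = as.numeric(z_meth)),
                                sub[, covs])
      logit_row <- tryCatch({
        r <- fit_logistic(sub$case_status, terms, conf_level)
        r <- r[r$term == "z_meth", ]
        dplyr::bind_cols(base, tibble::tibble(model = "logistic"), r,
                         tibble::tibble(note = NA_character_))
      }, error = function(e) {
        dplyr::bind_cols(base, tibble::tibble(model = "logistic",
                                              note = conditionMessage(e)))
      })
      lin_row <- if (is.null(z_area)) {
        dplyr::bind_cols(base, tibble::tibble(
          model = "linear", note = "degenerate area series"))
      } else {
        tryCatch({
          r <- fit_linear(as.numeric(z_area), terms, conf_level)
          r <- r[r$term == "z_meth", ]
          dplyr::bind_cols(base, tibble::tibble(model = "linear"), r,
                           tibble::tibble(note = NA_character_))
        }, error = function(e) {
          dplyr::bind_cols(base, tibble::tibble(model = "linear",
                                                note = conditionMessage(e)))
        })
      }
      rows[[length(rows) + 1L]] <- dplyr::bind_rows(logit_row, lin_row)
    }
  }
  dplyr::bind_rows(rows)
}

#' Partition CpGs into correlation blocks
#'
#' Computes Pearson correlations over pairwise-complete observations and
#' groups CpGs by single linkage: two CpGs share a block whenever they
#' are connected through a chain of pairwise `|r| >= cutoff` links.
#' Each correlation block is then treated as one independent test for
#' Bonferroni correction.
#'
#' @param beta wide beta matrix ([beta_matrix()]) or numeric matrix with
#'   one column per CpG.
#' @param cutoff absolute-correlation threshold joining a block.
#' @return object of class `block_partition`: list with `blocks` (list
#'   of CpG-id character vectors), `cutoff`, and the correlation matrix.
#' @export
correlation_blocks <- function(beta, cutoff = 0.30) {
  if (is.data.frame(beta)) {
    beta <- beta[, setdiff(names(beta), c("sample_id", "case_status"))]
  }
  M <- as.matrix(beta)
  if (ncol(M) < 2L) {
    stop("need at least two CpGs to partition", call. = FALSE)
  }
  npair <- crossprod(!is.na(M))
  isolated <- colnames(M)[vapply(seq_len(ncol(M)), function(j) {
    all(npair[j, -j] < 3L)
  }, logical(1))]
  if (length(isolated) > 0L) {
    warning("CpG(s) with <3 pairwise-complete observations against all ",
            "others form isolated blocks: ",
            paste(isolated, collapse = ", "), call. = FALSE)
  }
  C <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
  A <- abs(C) >= cutoff
  A[is.na(A)] <- FALSE
  diag(A) <- TRUE
  # connected components by label propagation (single linkage)
  comp <- seq_len(ncol(M))
  repeat {
    changed <- FALSE
    for (j in seq_len(ncol(M))) {
      nb <- which(A[j, ])
      m <- min(comp[nb])
      if (any(comp[nb] != m)) {
        comp[nb] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  blocks <- lapply(unique(comp), function(cid) colnames(M)[comp == cid])
  structure(list(blocks = blocks, cutoff = cutoff, correlations = C),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat("Correlation-block partition (|r| >=", x$cutoff, "):\n")
  for (i in seq_along(x$blocks)) {
    cat("  block", i, ":", paste(x$blocks[[i]], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Block-wise Bonferroni significance threshold
#'
#' Divides `alpha` by the number of independent correlation blocks: with
#' the study's two blocks and alpha 0.05 the threshold is 0.025.
#'
#' @param alpha family-wise error rate.
#' @param partition a [correlation_blocks()] partition, or a block count.
#' @return the per-test significance threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, partition) {
  assert_number(alpha, "alpha", 1e-12, 1)
  k <- if (inherits(partition, "block_partition")) {
    length(partition$blocks)
  } else {
    as.integer(partition)
  }
  if (is.na(k) || k < 1L) {
    stop("partition must contain at least one block", call. = FALSE)
  }
  alpha / k
}
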