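#' Pipeline configuration
#'
#' Bundles everything a full generate -> QC -> associate -> mediate run
#' needs.  Either `cohort_path`/`plates_path` point at CSV inputs, or
#' the bundled generator/assay parameters are used to simulate them.
#'
#' @param generator a [generative_params()] object (used when no input
#'   paths are given).
#' @param assay an [assay_params()] object.
#' @param cohort_path,plates_path optional CSV inputs (see
#'   [read_cohort()] and [read_plate_entries()]).
#' @param thresholds a [qc_thresholds()] object.
#' @param fragment_map composite CpG map (see [default_fragment_map()]).
#' @param covariates covariate set of the adjusted models.
#' @param drop_ets,exclude_alcohol sensitivity toggles forwarded to the
#'   scan.
#' @param strata strata to analyse.
#' @param alpha family-wise error rate for the discovery scan (block
#'   Bonferroni is applied to it).
#' @param mediation_alpha significance level inside the mediation
#'   condition checks.
#' @param bootstrap_reps bootstrap replicates for mediation CIs.
#' @param output_dir optional directory for artifacts.
#' @param seed global seed; overrides the generator/assay seeds so one
#'   number reproduces the whole run.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generative_params(),
                            assay = assay_params(),
                            cohort_path = NULL, plates_path = NULL,
                            thresholds = qc_thresholds(),
                            fragment_map = default_fragment_map(),
                            covariates = default_scan_covariates(),
                            drop_ets = FALSE, exclude_alcohol = FALSE,
                            strata = c("all", "girls", "boys"),
                            alpha = 0.05, mediation_alpha = 0.05,
                            bootstrap_reps = 200, output_dir = NULL,
                            seed = 1L) {
  assert_number(alpha, "alpha", 1e-12, 1)
  assert_number(mediation_alpha, "mediation_alpha", 1e-12, 1)
  assert_number(bootstrap_reps, "bootstrap_reps", lower = 1)
  assert_number(seed, "seed")
  for (p in c(cohort_path, plates_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input path does not exist: ", p, call. = FALSE)
    }
  }
  stopifnot(inherits(generator, "generative_params"),
            inherits(assay, "assay_params"),
            inherits(thresholds, "qc_thresholds"))
  structure(
    list(generator = generator, assay = assay,
         cohort_path = cohort_path, plates_path = plates_path,
         thresholds = thresholds, fragment_map = fragment_map,
         covariates = covariates, drop_ets = drop_ets,
         exclude_alcohol = exclude_alcohol, strata = strata,
         alpha = alpha, mediation_alpha = mediation_alpha,
         bootstrap_reps = as.integer(bootstrap_reps),
         output_dir = output_dir, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read and write pipeline configurations as JSON
#'
#' The JSON round-trips through the parameter constructors, so reading
#' re-validates every field (a light-weight schema check).
#'
#' @param path JSON file path.
#' @param config a [pipeline_config()] object.
#' @return `read_pipeline_config()` returns a validated
#'   `pipeline_config`; `write_pipeline_config()` returns `path`
#'   invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  gp <- raw$generator %||% list()
  gp$covariate_effects <- if (is.null(gp$covariate_effects)) {
    default_covariate_effects()
  } else {
    lapply(gp$covariate_effects, function(e) unlist(e))
  }
  for (nm in c("cpg_means", "cpg_sds")) {
    if (!is.null(gp[[nm]])) gp[[nm]] <- unlist(gp[[nm]])
  }
  if (!is.null(gp$cpg_blocks)) gp$cpg_blocks <- lapply(gp$cpg_blocks, unlist)
  if (!is.null(gp$cpg_block_corr)) {
    gp$cpg_block_corr <- lapply(gp$cpg_block_corr, unlist)
  }
  generator <- do.call(generative_params, gp)
  assay <- do.call(assay_params, raw$assay %||% list())
  thresholds <- do.call(qc_thresholds, raw$thresholds %||% list())
  fragment_map <- if (is.null(raw$fragment_map)) {
    default_fragment_map()
  } else {
    lapply(raw$fragment_map, unlist)
  }
  path_or_null <- function(x) if (length(x) == 0L) NULL else x
  pipeline_config(
    generator = generator, assay = assay,
    cohort_path = path_or_null(raw$cohort_path),
    plates_path = path_or_null(raw$plates_path),
    thresholds = thresholds, fragment_map = fragment_map,
    covariates = raw$covariates %||% default_scan_covariates(),
    drop_ets = raw$drop_ets %||% FALSE,
    exclude_alcohol = raw$exclude_alcohol %||% FALSE,
    strata = raw$strata %||% c("all", "girls", "boys"),
    alpha = raw$alpha %||% 0.05,
    mediation_alpha = raw$mediation_alpha %||% 0.05,
    bootstrap_reps = raw$bootstrap_reps %||% 200,
    output_dir = raw$output_dir, seed = raw$seed %||% 1L)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  payload <- list(
    generator = unclass(config$generator),
    assay = unclass(config$assay),
    cohort_path = config$cohort_path, plates_path = config$plates_path,
    thresholds = unclass(config$thresholds),
    fragment_map = config$fragment_map, covariates = config$covariates,
    drop_ets = config$drop_ets, exclude_alcohol = config$exclude_alcohol,
    strata = config$strata, alpha = config$alpha,
    mediation_alpha = config$mediation_alpha,
    bootstrap_reps = config$bootstrap_reps,
    output_dir = config$output_dir, seed = config$seed)
  payload$generator$covariate_effects <-
    lapply(payload$generator$covariate_effects, as.list)
  # named atomic vectors must be JSON objects, not arrays, to keep names
  for (nm in c("cpg_means", "cpg_sds")) {
    payload$generator[[nm]] <- as.list(payload$generator[[nm]])
  }
  payload <- payload[!vapply(payload, is.null, logical(1))]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

cohort_required_cols <- function() {
  c("subject_id", "sex", "maternal_age", "education", "income_low",
    "ets_exposure", "alcohol_use", "parity", "gestational_age",
    "case_status", "placental_major_axis", "placental_minor_axis",
    "placental_area", "placental_weight")
}

#' Read and validate a cohort CSV
#'
#' Expects one row per mother-baby pair with the documented column
#' dictionary (covariates, outcome flag, placental measures, and
#' optional `meth_*` latent methylation columns).  Validation errors
#' name the offending row and column: non-positive axes, gestational
#' age outside the full-term range 37-42 weeks, or a non-binary outcome
#' flag.
#'
#' @param path CSV file path.
#' @return validated cohort tibble.
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(cohort_required_cols(), names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_row <- function(mask, what) {
    if (any(mask, na.rm = TRUE)) {
      stop("invalid cohort record: ", what, " in row ",
           which(mask)[1], call. = FALSE)
    }
  }
  for (nm in c("education", "income_low", "ets_exposure", "alcohol_use",
               "parity", "case_status")) {
    cohort[[nm]] <- as.integer(cohort[[nm]])
  }
  bad_row(!cohort$case_status %in% c(0L, 1L), "case_status not 0/1")
  bad_row(cohort$placental_major_axis <= 0 |
            cohort$placental_minor_axis <= 0, "non-positive placental axis")
  bad_row(cohort$gestational_age < 37 | cohort$gestational_age > 42,
          "gestational age outside the full-term range [37, 42] weeks")
  cohort
}

#' @rdname read_cohort
#' @param cohort cohort tibble to write.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

#' Read and write long-format methylation plate entries
#'
#' The long CSV carries one readout per row: `sample_id, cpg_id,
#' batch_id, beta, is_repeat, is_conversion_control` (and optionally
#' `case_status`).  A beta outside `[0, 1]` raises a validation error
#' naming the row and CpG.
#'
#' @param path CSV file path.
#' @return entries tibble.
#' @export
read_plate_entries <- function(path) {
  entries <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  entries <- as_entries(entries)
  if (!"case_status" %in% names(entries)) {
    entries$case_status <- NA_integer_
  }
  bad <- which(!is.na(entries$beta) &
                 (entries$beta < 0 | entries$beta > 1))
  if (length(bad) > 0L) {
    stop("beta value out of [0, 1] at row ", bad[1], " (sample '",
         entries$sample_id[bad[1]], "', CpG '", entries$cpg_id[bad[1]],
         "'): ", entries$beta[bad[1]], call. = FALSE)
  }
  entries$is_repeat <- as.logical(entries$is_repeat)
  entries$is_conversion_control <- as.logical(entries$is_conversion_control)
  entries
}

#' @rdname read_plate_entries
#' @param entries plate entries tibble or `plate_set` to write.
#' @export
write_plate_entries <- function(entries, path) {
  readr::write_csv(as_entries(entries), path, progress = FALSE)
  invisible(path)
}

#' Run the full generate -> QC -> associate -> mediate pipeline
#'
#' Stages run in order: simulate (or read) the cohort and plates;
#' quality control; descriptive case/control comparison; the adjusted
#' per-CpG association scan; correlation blocks and the
#' block-Bonferroni threshold; then mediation, attempted only for
#' CpG-stratum combinations whose adjusted logistic p-value passes the
#' corrected threshold.  For each triggered combination the condition
#' checks (at `mediation_alpha`), Sobel test, and bootstrap
#' natural-effects decomposition are reported.  With a fixed config
#' seed the run (and its scan/mediation JSON artifacts) is exactly
#' reproducible.
#'
#' @param config a [pipeline_config()] object.
#' @return an object of class `run_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  log_it <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  stage <- "input"
  report <- tryCatch({
    if (is.null(config$cohort_path)) {
      gp <- config$generator
      gp$seed <- config$seed
      cohort <- generate_cohort(gp)
      log_it("simulate: generated ", nrow(cohort), " subjects (design ",
             attr(cohort, "sampling_design"), ")")
    } else {
      cohort <- read_cohort(config$cohort_path)
      log_it("input: read ", nrow(cohort), " subjects from ",
             config$cohort_path)
    }
    if (is.null(config$plates_path)) {
      ap <- config$assay
      ap$seed <- config$seed + 1L
      plates <- generate_epityper_plates(cohort, ap,
                                         fragment_map = config$fragment_map)
      log_it("simulate: ", nrow(plates$entries), " plate entries")
    } else {
      plates <- read_plate_entries(config$plates_path)
      log_it("input: read ", nrow(plates), " plate entries from ",
             config$plates_path)
    }

    stage <- "qc"
    qc <- qc_report(plates, config$thresholds,
                    fragment_map = config$fragment_map)
    bm <- beta_matrix(plates, config$thresholds,
                      fragment_map = config$fragment_map)
    log_it("qc: retained ", length(qc$retained_cpgs), " of ",
           nrow(qc$per_cpg), " CpGs")

    stage <- "descriptives"
    desc_vars <- intersect(
      c("maternal_age", "education", "income_low", "ets_exposure",
        "alcohol_use", "parity", "gestational_age", "placental_weight",
        "placental_major_axis", "placental_minor_axis", "placental_area"),
      names(cohort))
    descriptives <- compare_groups(cohort, desc_vars)

    stage <- "association"
    scan <- association_scan(bm, cohort, covariates = config$covariates,
                             strata = config$strata,
                             drop_ets = config$drop_ets,
                             exclude_alcohol = config$exclude_alcohol)
    for (i in seq_len(nrow(scan))) {
      log_it("scan: ", scan$cpg[i], " [", scan$stratum[i], ", ",
             scan$model[i], "] n=", scan$n[i] %||% NA)
    }

    stage <- "blocks"
    partition <- correlation_blocks(bm, cutoff = 0.30)
    threshold <- bonferroni_threshold(config$alpha, partition)
    log_it("blocks: ", length(partition$blocks),
           " correlation blocks; threshold ", signif(threshold, 4))

    stage <- "mediation"
    hits <- scan[scan$model == "logistic" & !is.na(scan$p) &
                   scan$p < threshold, ]
    mediation <- list()
    if (nrow(hits) == 0L) {
      log_it("mediation: not triggered (no CpG passed the corrected ",
             "threshold)")
    }
    for (i in seq_len(nrow(hits))) {
      cpg <- hits$cpg[i]; st <- hits$stratum[i]
      sub <- dplyr::inner_join(bm[, c("sample_id", cpg)], cohort,
                               by = c(sample_id = "subject_id"))
      if (config$exclude_alcohol) sub <- sub[sub$alcohol_use == 0L, ]
      sub <- switch(st, all = sub,
                    girls = sub[sub$sex == "female", ],
                    boys = sub[sub$sex == "male", ])
      covs <- if (st == "all") config$covariates else {
        setdiff(config$covariates, "sex")
      }
      if (config$drop_ets) covs <- setdiff(covs, "ets_exposure")
      sub <- sub[stats::complete.cases(sub[, c(cpg, "placental_area",
                                               "case_status", covs)]), ]
      sub$z_meth <- as.numeric(standardize(sub[[cpg]]))
      sub$z_area <- as.numeric(standardize(sub$placental_area))
      entry <- tryCatch({
        paths <- estimate_mediation_paths(sub, "case_status", "z_meth",
                                          "z_area", covs)
        cond <- check_mediation_conditions(paths, config$mediation_alpha)
        sob <- sobel_test(paths$beta1$estimate, paths$beta1$se,
                          paths$theta2$estimate, paths$theta2$se)
        med <- if (cond$verdict) {
          bootstrap_mediation(sub, "case_status", "z_meth", "z_area",
                              covs, reps = config$bootstrap_reps,
                              seed = config$seed + 17L)
        } else {
          NULL
        }
        log_it("mediation: ", cpg, " [", st, "] n=", nrow(sub),
               " verdict=", cond$verdict)
        list(cpg = cpg, stratum = st, n = nrow(sub), paths = paths,
             conditions = cond, sobel = sob, result = med)
      }, error = function(e) {
        log_it("mediation: ", cpg, " [", st, "] failed: ",
               conditionMessage(e))
        list(cpg = cpg, stratum = st, error = conditionMessage(e))
      })
      mediation[[paste(cpg, st, sep = ":")]] <- entry
    }

    structure(
      list(cohort = cohort, qc = qc, descriptives = descriptives,
           scan = scan, partition = partition, threshold = threshold,
           mediation = mediation,
           mediation_triggered = length(mediation) > 0L,
           config = config,
           version = as.character(utils::packageVersion("placmed")),
           config_checksum = config_checksum(config),
           log = log_lines),
      class = "run_report")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$output_dir)) {
    write_run_report(report, config$output_dir)
  }
  report
}

config_checksum <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_pipeline_config(config, tmp)
  s <- paste(readLines(tmp, warn = FALSE), collapse = "\n")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251)) %% 2147483647
}

mediation_json_payload <- function(mediation) {
  lapply(mediation, function(m) {
    if (!is.null(m$error)) {
      return(list(cpg = m$cpg, stratum = m$stratum, error = m$error))
    }
    res <- m$result
    list(cpg = m$cpg, stratum = m$stratum, n = m$n,
         paths = lapply(m$paths[c("theta1", "theta1_prime", "theta2",
                                  "beta1")],
                        function(e) e[c("estimate", "se", "p")]),
         conditions = m$conditions[c("a", "b", "c", "d", "verdict",
                                     "attenuation_pct", "alpha")],
         sobel = m$sobel,
         result = if (is.null(res)) NULL else {
           list(nde_or = res$nde_or, nie_or = res$nie_or,
                te_or = res$te_or,
                proportion_mediated = res$proportion_mediated,
                nde_ci = res$boot$nde_ci, nie_ci = res$boot$nie_ci,
                te_ci = res$boot$te_ci,
                proportion_ci = res$boot$proportion_ci,
                reps = res$boot$reps_used,
                failures = res$boot$failures)
         })
  })
}

#' Write a run report's artifacts to a directory
#'
#' Emits `cohort.csv`, `qc_report.json`, `descriptives.tsv`,
#' `scan.tsv`, `blocks.json`, `mediation.json`, `run_log.txt`, and
#' `run_report.json`.  The JSON artifacts contain no timestamps, so a
#' rerun with the same config and seed is byte-identical.
#'
#' @param report a [run_pipeline()] report.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(report$cohort, file.path(dir, "cohort.csv"))
  write_qc_report(report$qc, file.path(dir, "qc_report.json"))
  readr::write_tsv(report$descriptives, file.path(dir, "descriptives.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$scan, file.path(dir, "scan.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(blocks = report$partition$blocks,
         cutoff = report$partition$cutoff,
         alpha = report$config$alpha, threshold = report$threshold),
    file.path(dir, "blocks.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  jsonlite::write_json(mediation_json_payload(report$mediation),
                       file.path(dir, "mediation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$log, file.path(dir, "run_log.txt"))
  jsonlite::write_json(
    list(version = report$version,
         config_checksum = report$config_checksum,
         n_subjects = nrow(report$cohort),
         retained_cpgs = report$qc$retained_cpgs,
         threshold = report$threshold,
         mediation_triggered = report$mediation_triggered,
         n_mediation_entries = length(report$mediation)),
    file.path(dir, "run_report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("placmed run report (version", x$version, ")\n")
  cat("  subjects:", nrow(x$cohort), "| retained CpGs:",
      length(x$qc$retained_cpgs), "\n")
  cat("  blocks:", length(x$partition$blocks), "| threshold:",
      signif(x$threshold, 4), "\n")
  if (x$mediation_triggered) {
    for (m in x$mediation) {
      if (!is.null(m$error)) {
        cat("  mediation", m$cpg, "[", m$stratum, "]: failed\n")
      } else {
        cat("  mediation", m$cpg, "[", m$stratum, "]: verdict",
            m$conditions$verdict, "\n")
      }
    }
  } else {
    cat("  mediation: not triggered\n")
  }
  invisible(x)
}
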