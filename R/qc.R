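#' Quality-control thresholds for EpiTYPER-style beta values
#'
#' Detection-limit bounds, the minimum valid-sample fraction for a CpG
#' to be retained, the repeat-concordance bound, and the minimum
#' bisulfite conversion efficiency.  Boundary semantics follow a literal
#' reading of the filtering rules: readouts *strictly* below
#' `beta_lower` or strictly above `beta_upper` are censored (0.05 and
#' 0.95 themselves are kept); CpGs with valid fraction `>=`
#' `min_valid_fraction` are retained; repeat pairs fail at `|diff| >=
#' repeat_max_diff`; conversion passes only strictly above
#' `min_conversion`.
#'
#' @param beta_lower,beta_upper detection-limit censoring bounds.
#' @param min_valid_fraction minimum fraction of valid samples per CpG.
#' @param repeat_max_diff maximum tolerated absolute repeat difference.
#' @param min_conversion minimum bisulfite conversion efficiency.
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(beta_lower = 0.05, beta_upper = 0.95,
                          min_valid_fraction = 0.75,
                          repeat_max_diff = 0.05, min_conversion = 0.98) {
  assert_number(beta_lower, "beta_lower", 0, 1)
  assert_number(beta_upper, "beta_upper", 0, 1)
  if (beta_lower >= beta_upper) {
    stop("`beta_lower` must be < `beta_upper`", call. = FALSE)
  }
  assert_number(min_valid_fraction, "min_valid_fraction", 1e-12, 1)
  assert_number(repeat_max_diff, "repeat_max_diff", 0, 1)
  assert_number(min_conversion, "min_conversion", 0, 1)
  structure(list(beta_lower = beta_lower, beta_upper = beta_upper,
                 min_valid_fraction = min_valid_fraction,
                 repeat_max_diff = repeat_max_diff,
                 min_conversion = min_conversion),
            class = "qc_thresholds")
}

as_entries <- function(x) {
  if (inherits(x, "plate_set")) return(x$entries)
  required <- c("sample_id", "cpg_id", "batch_id", "beta", "is_repeat",
                "is_conversion_control")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("plate entries lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (!"case_status" %in% names(x)) x$case_status <- NA_integer_
  x
}

is_primary <- function(entries) {
  !entries$is_repeat & !entries$is_conversion_control
}

#' Aggregate fragment readouts into composite CpG units
#'
#' EpiTYPER fragments whose masses overlap cannot be resolved
#' independently; their methylation is reported as a composite unit
#' equal to the unweighted mean of the member fragments.  The composite
#' is missing whenever any member readout is missing.  Member rows are
#' replaced by a single composite row (grouping by sample, batch and
#' repeat status, so repeats aggregate within themselves).
#'
#' @param entries long-format plate entries (or a `plate_set`).
#' @param fragment_map named list mapping composite id to member
#'   fragment ids, e.g. [default_fragment_map()].
#' @return entries tibble with member fragments replaced by composites.
#' @export
aggregate_fragments <- function(entries, fragment_map) {
  entries <- as_entries(entries)
  if (is.null(fragment_map) || length(fragment_map) == 0L) return(entries)
  members_all <- unlist(fragment_map, use.names = FALSE)
  unknown <- setdiff(members_all, unique(entries$cpg_id))
  if (length(unknown) > 0L) {
    stop("fragment_map references unknown fragment id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- entries[!entries$cpg_id %in% members_all, ]
  for (comp in names(fragment_map)) {
    members <- fragment_map[[comp]]
    sub <- entries[entries$cpg_id %in% members, ]
    if (nrow(sub) == 0L) next
    agg <- sub |>
      dplyr::group_by(.data$sample_id, .data$batch_id, .data$is_repeat,
                      .data$is_conversion_control, .data$case_status) |>
      dplyr::summarise(
        beta = if (dplyr::n() < length(members) || anyNA(.data$beta)) {
          NA_real_
        } else {
          mean(.data$beta)
        },
        .groups = "drop")
    agg$cpg_id <- comp
    out <- dplyr::bind_rows(out, agg[, names(entries)])
  }
  out
}

#' Flag per-CpG sample readouts as valid, missing, or censored
#'
#' For each CpG independently: missing (poor-readout) entries are
#' flagged `removed_missing`; entries strictly below `beta_lower` or
#' strictly above `beta_upper` — the assay's detection limits — are
#' flagged `removed_censored`; everything else is `valid`.  Repeat and
#' conversion-control entries are flagged `not_assessed`.  The status is
#' recomputed from scratch, so the operation is idempotent.
#'
#' @param entries long-format plate entries (or a `plate_set`).
#' @param thresholds a [qc_thresholds()] object.
#' @return entries tibble with a `qc_status` column.
#' @export
filter_sample_readouts <- function(entries, thresholds = qc_thresholds()) {
  entries <- as_entries(entries)
  entries$qc_status <- NULL
  status <- rep("not_assessed", nrow(entries))
  p <- is_primary(entries)
  status[p & is.na(entries$beta)] <- "removed_missing"
  cens <- p & !is.na(entries$beta) &
    (entries$beta < thresholds$beta_lower |
       entries$beta > thresholds$beta_upper)
  status[cens] <- "removed_censored"
  status[p & !is.na(entries$beta) & !cens] <- "valid"
  entries$qc_status <- status
  entries
}

#' Retain CpGs with a sufficient fraction of valid samples
#'
#' A CpG is retained iff its valid-sample fraction is at least
#' `min_valid_fraction`.  The denominator is the number of samples
#' assayed for that CpG (primary entries), not the cohort size, because
#' per-CpG assay coverage can differ.
#'
#' @param entries plate entries; `qc_status` is computed if absent.
#' @param thresholds a [qc_thresholds()] object.
#' @return character vector of retained CpG ids (order of first
#'   appearance), with the per-CpG valid fractions as the
#'   `valid_fraction` attribute.
#' @export
filter_cpgs <- function(entries, thresholds = qc_thresholds()) {
  entries <- as_entries(entries)
  if (!"qc_status" %in% names(entries)) {
    entries <- filter_sample_readouts(entries, thresholds)
  }
  prim <- entries[is_primary(entries), ]
  cpgs <- unique(prim$cpg_id)
  frac <- vapply(cpgs, function(cpg) {
    s <- prim$qc_status[prim$cpg_id == cpg]
    mean(s == "valid")
  }, numeric(1))
  retained <- cpgs[frac >= thresholds$min_valid_fraction]
  attr(retained, "valid_fraction") <- stats::setNames(frac, cpgs)
  retained
}

#' Check per-plate repeat concordance and conversion controls
#'
#' A plate fails the repeat check if any repeat pair differs by at least
#' `repeat_max_diff` in beta; it fails the conversion check if any
#' conversion-control efficiency is at or below `min_conversion`.
#'
#' @param entries plate entries including repeat and conversion-control
#'   rows.
#' @param thresholds a [qc_thresholds()] object.
#' @return tibble with one row per batch: repeat-pair count, maximum
#'   absolute repeat difference, minimum conversion efficiency, and a
#'   `status` of `PASS`, `FAIL-repeat`, `FAIL-conversion`, or
#'   `FAIL-both`.
#' @export
validate_plate_controls <- function(entries, thresholds = qc_thresholds()) {
  entries <- as_entries(entries)
  batches <- sort(unique(entries$batch_id[!is.na(entries$batch_id)]))
  rows <- lapply(batches, function(b) {
    eb <- entries[entries$batch_id == b, ]
    conv <- eb$beta[eb$is_conversion_control]
    if (length(conv) == 0L) {
      stop("batch '", b, "' has no conversion-control entry",
           call. = FALSE)
    }
    reps <- eb[eb$is_repeat, ]
    diffs <- numeric(0)
    if (nrow(reps) > 0L) {
      prim <- eb[is_primary(eb), ]
      m <- dplyr::inner_join(
        reps[, c("sample_id", "cpg_id", "beta")],
        prim[, c("sample_id", "cpg_id", "beta")],
        by = c("sample_id", "cpg_id"), suffix = c("_rep", "_orig"))
      diffs <- abs(m$beta_rep - m$beta_orig)
      diffs <- diffs[!is.na(diffs)]
    }
    repeat_ok <- !any(diffs >= thresholds$repeat_max_diff)
    conv_ok <- all(conv > thresholds$min_conversion, na.rm = TRUE)
    tibble::tibble(
      batch_id = b, n_repeat_pairs = length(diffs),
      max_repeat_diff = if (length(diffs)) max(diffs) else NA_real_,
      repeat_pass = repeat_ok,
      min_conversion = min(conv, na.rm = TRUE),
      conversion_pass = conv_ok,
      status = if (repeat_ok && conv_ok) {
        "PASS"
      } else if (!repeat_ok && !conv_ok) {
        "FAIL-both"
      } else if (!repeat_ok) {
        "FAIL-repeat"
      } else {
        "FAIL-conversion"
      })
  })
  dplyr::bind_rows(rows)
}

#' Full quality-control report for a plate set
#'
#' Runs fragment aggregation (if a map is given), readout filtering,
#' CpG retention, and plate-control validation, and returns per-CpG
#' counts satisfying the conservation identity
#' `input = removed_missing + removed_censored + valid`.
#' A failing plate is flagged but its samples are kept unless
#' `strict = TRUE`, in which case all entries of failing plates are
#' dropped before counting.
#'
#' @param entries plate entries or a `plate_set`.
#' @param thresholds a [qc_thresholds()] object.
#' @param fragment_map optional composite map applied first.
#' @param strict drop entries of plates failing control checks.
#' @return an object of class `qc_report`: list with `per_cpg` counts,
#'   `retained_cpgs`, `batch_controls`, `thresholds`, `strict`, and the
#'   filtered `entries`.
#' @export
qc_report <- function(entries, thresholds = qc_thresholds(),
                      fragment_map = NULL, strict = FALSE) {
  entries <- as_entries(entries)
  # entries without any control rows (e.g. an external beta table) skip
  # plate validation; a batch missing its control while others have one
  # still errors via validate_plate_controls
  batch_controls <- if (!any(entries$is_conversion_control)) {
    tibble::tibble(batch_id = character(), n_repeat_pairs = integer(),
                   max_repeat_diff = numeric(), repeat_pass = logical(),
                   min_conversion = numeric(),
                   conversion_pass = logical(), status = character())
  } else {
    validate_plate_controls(entries, thresholds)
  }
  if (strict && nrow(batch_controls) > 0L) {
    bad <- batch_controls$batch_id[batch_controls$status != "PASS"]
    entries <- entries[!entries$batch_id %in% bad, ]
  }
  entries <- aggregate_fragments(entries, fragment_map)
  entries <- filter_sample_readouts(entries, thresholds)
  prim <- entries[is_primary(entries), ]
  cpgs <- unique(prim$cpg_id)
  per_cpg <- dplyr::bind_rows(lapply(cpgs, function(cpg) {
    s <- prim[prim$cpg_id == cpg, ]
    valid <- s$qc_status == "valid"
    tibble::tibble(
      cpg_id = cpg,
      n_input = nrow(s),
      n_removed_missing = sum(s$qc_status == "removed_missing"),
      n_removed_censored = sum(s$qc_status == "removed_censored"),
      n_valid = sum(valid),
      n_valid_cases = sum(valid & s$case_status == 1L, na.rm = TRUE),
      n_valid_controls = sum(valid & s$case_status == 0L, na.rm = TRUE),
      valid_fraction = if (nrow(s)) mean(valid) else NA_real_)
  }))
  if (nrow(per_cpg) == 0L) {
    per_cpg <- tibble::tibble(
      cpg_id = character(), n_input = integer(),
      n_removed_missing = integer(), n_removed_censored = integer(),
      n_valid = integer(), n_valid_cases = integer(),
      n_valid_controls = integer(), valid_fraction = numeric())
  }
  retained <- as.character(
    per_cpg$cpg_id[per_cpg$valid_fraction >= thresholds$min_valid_fraction])
  structure(
    list(per_cpg = per_cpg, retained_cpgs = retained,
         batch_controls = batch_controls, thresholds = thresholds,
         strict = strict, entries = entries),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("EpiTYPER-style QC report\n")
  cat("  CpGs assayed:", nrow(x$per_cpg),
      "| retained:", length(x$retained_cpgs), "\n")
  if (nrow(x$per_cpg) > 0L) print(x$per_cpg, n = Inf)
  if (nrow(x$batch_controls) > 0L) {
    cat("  plates failing controls:",
        sum(x$batch_controls$status != "PASS"), "of",
        nrow(x$batch_controls), "\n")
  }
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report a [qc_report()] object.
#' @param path output file path.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  payload <- list(per_cpg = report$per_cpg,
                  retained_cpgs = report$retained_cpgs,
                  batch_controls = report$batch_controls,
                  thresholds = unclass(report$thresholds),
                  strict = report$strict)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' QC-filtered beta matrix in wide format
#'
#' Applies fragment aggregation and readout/CpG filtering, then pivots
#' the valid primary readouts to a samples-by-CpGs matrix; removed
#' readouts become `NA`.
#'
#' @param entries plate entries or a `plate_set`.
#' @param thresholds a [qc_thresholds()] object.
#' @param fragment_map optional composite map.
#' @param retained_only keep only CpGs passing the valid-fraction filter.
#' @return tibble with `sample_id`, `case_status`, and one beta column
#'   per CpG.
#' @export
beta_matrix <- function(entries, thresholds = qc_thresholds(),
                        fragment_map = NULL, retained_only = TRUE) {
  rep_obj <- qc_report(entries, thresholds, fragment_map = fragment_map)
  prim <- rep_obj$entries[is_primary(rep_obj$entries), ]
  if (retained_only) {
    prim <- prim[prim$cpg_id %in% rep_obj$retained_cpgs, ]
  }
  prim$beta[prim$qc_status != "valid"] <- NA_real_
  wide <- tidyr::pivot_wider(
    prim[, c("sample_id", "case_status", "cpg_id", "beta")],
    names_from = "cpg_id", values_from = "beta")
  wide
}
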