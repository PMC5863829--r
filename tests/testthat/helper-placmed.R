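# shared fixture builders (all data generated in code)

# numeric vector of length n with exactly the requested mean and SD
vector_with_moments <- function(n, mean, sd) {
  base <- seq_len(n)
  z <- (base - mean(base)) / stats::sd(base)
  mean + sd * z
}

# minimal long-format plate entries table
make_entries <- function(sample_id, cpg_id, beta,
                         batch_id = "plate_01",
                         is_repeat = FALSE,
                         is_conversion_control = FALSE,
                         case_status = 0L) {
  tibble::tibble(sample_id = sample_id, cpg_id = cpg_id,
                 batch_id = batch_id, beta = beta,
                 is_repeat = is_repeat,
                 is_conversion_control = is_conversion_control,
                 case_status = case_status)
}

conversion_row <- function(batch_id = "plate_01", efficiency = 0.99) {
  make_entries(paste0("CONV_", batch_id), "conversion_control",
               efficiency, batch_id = batch_id,
               is_conversion_control = TRUE,
               case_status = NA_integer_)
}

# small cohort with standardized exposure/mediator columns ready for the
# mediation engine
make_mediation_data <- function(n = 1500, seed = 42, beta1 = -0.38,
                                theta1_prime = 0.34, theta2 = -0.84,
                                intercept = -3.0) {
  set.seed(seed)
  x <- stats::rnorm(n)
  m <- beta1 * x + stats::rnorm(n, 0, sqrt(1 - beta1^2))
  y <- as.integer(stats::runif(n) <
                    stats::plogis(intercept + theta1_prime * x +
                                    theta2 * m))
  tibble::tibble(case_status = y,
                 z_meth = as.numeric(standardize(x)),
                 z_area = as.numeric(standardize(m)))
}

scan_covariates <- function() {
  c("maternal_age", "education", "income_low", "ets_exposure",
    "gestational_age", "sex")
}
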