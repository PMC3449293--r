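# Published group-average results for the four flanker data sets (I-IV,
# n = 25/19/25/18, 87 participants total).  These printed values serve as
# inputs: the parameter averages seed the synthetic-data generator at a
# realistic scale, and the selection weights/counts feed the
# model-selection arithmetic that the package reconstructs.

#' Group-average LBA parameter estimates for the four data sets
#'
#' Mean best-fitting parameter values per model (V1, V2, B1, B2) and data
#' set (I-IV), averaged across participants.  Thresholds are reported as
#' `b` (absolute); V models estimated a single threshold, B models one per
#' condition (B2 via the low-conflict cells and the shift `db`).  Drifts
#' `v_*` are the correct-response accumulator means; in B models drift
#' varies with congruency only (`v_con_low`/`v_inc_low` columns hold the
#' congruent/incongruent values).  `NA` marks parameters a model does not
#' estimate.
#'
#' @return Data frame with columns `model`, `dataset`, `s`, `A`, `b`,
#'   `b_con_low`, `b_inc_low`, `b_con_high`, `b_inc_high`, `db`, `t0`,
#'   `v_con_low`, `v_inc_low`, `v_con_high`, `v_inc_high`, `dv`.
#' @export
reference_parameter_averages <- function() {
  rows <- rbind(
    # model, dataset, s, A, b, bCL, bIL, bCH, bIH, db, t0, vCL, vIL, vCH, vIH, dv
    c("V1", "I",   0.18, 0.14, 0.48, NA, NA, NA, NA, NA, 0.14, 0.79, 0.64, 0.77, 0.66, NA),
    c("V1", "II",  0.15, 0.09, 0.36, NA, NA, NA, NA, NA, 0.13, 0.78, 0.63, 0.75, 0.65, NA),
    c("V1", "III", 0.13, 0.09, 0.37, NA, NA, NA, NA, NA, 0.08, 0.73, 0.58, 0.71, 0.60, NA),
    c("V1", "IV",  0.17, 0.15, 0.46, NA, NA, NA, NA, NA, 0.08, 0.77, 0.62, 0.75, 0.64, NA),
    c("V2", "I",   0.18, 0.14, 0.48, NA, NA, NA, NA, NA, 0.14, 0.79, 0.64, NA, NA, 0.02),
    c("V2", "II",  0.15, 0.09, 0.36, NA, NA, NA, NA, NA, 0.13, 0.78, 0.63, NA, NA, 0.02),
    c("V2", "III", 0.13, 0.10, 0.37, NA, NA, NA, NA, NA, 0.08, 0.73, 0.59, NA, NA, 0.02),
    c("V2", "IV",  0.17, 0.15, 0.46, NA, NA, NA, NA, NA, 0.08, 0.77, 0.62, NA, NA, 0.02),
    c("B1", "I",   0.19, 0.16, NA, 0.43, 0.48, 0.41, 0.47, NA, 0.19, 0.77, 0.70, NA, NA, NA),
    c("B1", "II",  0.17, 0.10, NA, 0.32, 0.36, 0.33, 0.35, NA, 0.17, 0.76, 0.70, NA, NA, NA),
    c("B1", "III", 0.14, 0.10, NA, 0.36, 0.37, 0.37, 0.37, NA, 0.11, 0.73, 0.61, NA, NA, NA),
    c("B1", "IV",  0.19, 0.18, NA, 0.42, 0.47, 0.43, 0.47, NA, 0.13, 0.77, 0.69, NA, NA, NA),
    c("B2", "I",   0.19, 0.17, NA, 0.43, 0.48, NA, NA, 0.01, 0.20, 0.78, 0.70, NA, NA, NA),
    c("B2", "II",  0.17, 0.10, NA, 0.32, 0.37, NA, NA, 0.01, 0.17, 0.76, 0.69, NA, NA, NA),
    c("B2", "III", 0.14, 0.11, NA, 0.36, 0.37, NA, NA, 0.01, 0.12, 0.75, 0.62, NA, NA, NA),
    c("B2", "IV",  0.18, 0.20, NA, 0.43, 0.47, NA, NA, 0.01, 0.14, 0.79, 0.70, NA, NA, NA)
  )
  out <- data.frame(
    model = rows[, 1], dataset = rows[, 2],
    apply(rows[, 3:16], 2, as.numeric),
    stringsAsFactors = FALSE
  )
  names(out) <- c(
    "model", "dataset", "s", "A", "b", "b_con_low", "b_inc_low",
    "b_con_high", "b_inc_high", "db", "t0", "v_con_low", "v_inc_low",
    "v_con_high", "v_inc_high", "dv"
  )
  out
}

#' Reference free-parameter vector for a model and data set
#'
#' Converts a row of [reference_parameter_averages()] into the named theta
#' vector used by [build_condition_params()], translating absolute
#' thresholds into distances `d = b - A`.  Useful as a realistic generating
#' point for simulation and recovery studies.
#'
#' @inheritParams model_param_names
#' @param dataset `"I"`, `"II"`, `"III"` or `"IV"`.
#' @return Named numeric parameter vector.
#' @examples
#' reference_theta("B2", "I")
#' @export
reference_theta <- function(model_id, dataset = "I") {
  model_id <- match.arg(model_id, c("V1", "V2", "B1", "B2"))
  dataset <- match.arg(dataset, c("I", "II", "III", "IV"))
  tab <- reference_parameter_averages()
  r <- tab[tab$model == model_id & tab$dataset == dataset, ]
  common <- c(s = r$s, A = r$A, t0 = r$t0)
  switch(model_id,
    V1 = c(common, d = r$b - r$A,
      v_con_low = r$v_con_low, v_inc_low = r$v_inc_low,
      v_con_high = r$v_con_high, v_inc_high = r$v_inc_high),
    V2 = c(common, d = r$b - r$A,
      v_con_low = r$v_con_low, v_inc_low = r$v_inc_low, dv = r$dv),
    B1 = c(common,
      d_con_low = r$b_con_low - r$A, d_inc_low = r$b_inc_low - r$A,
      d_con_high = r$b_con_high - r$A, d_inc_high = r$b_inc_high - r$A,
      v_con = r$v_con_low, v_inc = r$v_inc_low),
    B2 = c(common,
      d_con_low = r$b_con_low - r$A, d_inc_low = r$b_inc_low - r$A,
      db = r$db, v_con = r$v_con_low, v_inc = r$v_inc_low)
  )
}

#' Published model-selection weights and best-fit counts
#'
#' AIC and BIC model weights (3 decimals) and the number of participants
#' best fit by each model, per data set.  These are the inputs from which
#' the pooled best-fit percentages and the threshold-vs-drift ("B vs V")
#' evidence ratios are reconstructed.
#'
#' @return Data frame with columns `criterion` (`"AIC"`/`"BIC"`), `model`,
#'   `dataset`, `weight`, `n_best`.
#' @export
reference_selection_weights <- function() {
  datasets <- c("I", "II", "III", "IV")
  models <- c("V1", "V2", "B1", "B2")
  w_aic <- c(
    0.059, 0.050, 0.185, 0.152,
    0.106, 0.094, 0.119, 0.116,
    0.412, 0.498, 0.468, 0.419,
    0.422, 0.358, 0.228, 0.313
  )
  n_aic <- c(0, 0, 4, 2, 4, 2, 3, 2, 8, 9, 12, 8, 13, 8, 6, 6)
  w_bic <- c(
    0.027, 0.015, 0.129, 0.085,
    0.313, 0.221, 0.389, 0.337,
    0.123, 0.255, 0.216, 0.153,
    0.537, 0.509, 0.267, 0.425
  )
  n_bic <- c(0, 0, 3, 1, 8, 5, 10, 7, 3, 4, 4, 1, 14, 10, 8, 9)
  grid <- expand.grid(dataset = datasets, model = models,
    stringsAsFactors = FALSE)
  rbind(
    data.frame(criterion = "AIC", grid[, c("model", "dataset")],
      weight = w_aic, n_best = n_aic, stringsAsFactors = FALSE),
    data.frame(criterion = "BIC", grid[, c("model", "dataset")],
      weight = w_bic, n_best = n_bic, stringsAsFactors = FALSE)
  )
}
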