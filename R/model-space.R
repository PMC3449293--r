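# Model parameterizations for the CSPC flanker design.  Four conditions
# (context high/low conflict x flanker congruent/incongruent); the competing
# models differ in whether context is allowed to move the mean drift rate
# (V models) or the threshold distance b - A (B models).

#' @keywords internal
CSPC_CONDITIONS <- c("con_low", "inc_low", "con_high", "inc_high")

.headline_models <- c("V1", "V2", "B1", "B2")
.all_models <- c(.headline_models, "VB", "T0")

#' Free-parameter names of a model parameterization
#'
#' All models share the across-trial drift SD `s`, the start-point range `A`
#' and (except `T0`) a common non-decision time `t0`.  Thresholds enter as
#' distances `d = b - A` from the top of the start-point distribution, which
#' keeps `b >= A` under box constraints.
#'
#' * `V1`: one threshold distance, a separate mean drift per condition.
#' * `V2`: one threshold distance, drifts `v_con_low`, `v_inc_low` and a
#'   context shift `dv` (high-conflict drifts are `v_inc_low + dv` and
#'   `v_con_low - dv`).
#' * `B1`: a threshold distance per condition, drifts varying with
#'   congruency only (`v_con`, `v_inc`).
#' * `B2`: distances `d_con_low`, `d_inc_low` and a context shift `db`
#'   (high-conflict distances are `d_inc_low - db` and `d_con_low + db`),
#'   drifts by congruency only.
#' * `VB`: both drift and threshold distance free per condition.
#' * `T0`: congruency-only drifts, one threshold distance, and non-decision
#'   time varying by condition via `t0_con_low`, `t0_inc_low`, `dt0`.
#'
#' Positive `dv`/`db` produce the standard CSPC pattern (smaller
#' interference in the high-conflict context); their sign is unrestricted.
#'
#' @param model_id One of `"V1"`, `"V2"`, `"B1"`, `"B2"`, `"VB"`, `"T0"`.
#' @return Character vector of parameter names.
#' @export
model_param_names <- function(model_id) {
  model_id <- match.arg(model_id, .all_models)
  common <- c("s", "A", "t0")
  switch(model_id,
    V1 = c(common, "d", "v_con_low", "v_inc_low", "v_con_high", "v_inc_high"),
    V2 = c(common, "d", "v_con_low", "v_inc_low", "dv"),
    B1 = c(common, "d_con_low", "d_inc_low", "d_con_high", "d_inc_high",
      "v_con", "v_inc"),
    B2 = c(common, "d_con_low", "d_inc_low", "db", "v_con", "v_inc"),
    VB = c(common, "d_con_low", "d_inc_low", "d_con_high", "d_inc_high",
      "v_con_low", "v_inc_low", "v_con_high", "v_inc_high"),
    T0 = c("s", "A", "d", "v_con", "v_inc", "t0_con_low", "t0_inc_low", "dt0")
  )
}

#' Number of free parameters of a model
#'
#' `V1` and `B2` have 8, `V2` 7, `B1` 9; each threshold model uses one more
#' parameter than its matching drift model.
#'
#' @inheritParams model_param_names
#' @return Integer count.
#' @export
free_parameter_count <- function(model_id) {
  length(model_param_names(model_id))
}

#' Headline model identifiers
#'
#' The four parameterizations compared in the main model selection
#' (`V1`, `V2`, `B1`, `B2`).  `VB` and `T0` are extension models kept for
#' recovery completeness.
#'
#' @param extensions Include `VB` and `T0`?
#' @return Character vector of model ids.
#' @export
model_ids <- function(extensions = FALSE) {
  if (extensions) .all_models else .headline_models
}

.check_theta <- function(model_id, theta) {
  wanted <- model_param_names(model_id)
  if (!all(wanted %in% names(theta))) {
    stop("model ", model_id, " is missing parameter(s): ",
      paste(setdiff(wanted, names(theta)), collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(theta), wanted)
  if (length(extra)) {
    stop("model ", model_id, " has unknown parameter(s): ",
      paste(extra, collapse = ", "), call. = FALSE)
  }
  theta[wanted]
}

#' Expand a free-parameter vector into per-condition race parameters
#'
#' Maps a model's named parameter vector to the four experimental conditions,
#' returning one [lba_race()] per condition.  The error accumulator's mean
#' drift is `1 - v` (sum-to-one convention), and both accumulators share
#' `b`, `A`, `s` within a condition.
#'
#' For `B2`, the default `"verbal"` mapping sets the high-conflict distances
#' to `d_inc_low - db` (incongruent) and `d_con_low + db` (congruent), so a
#' positive `db` yields the standard CSPC effect; `"literal"` applies the
#' alternative reading `d_inc_low + db` / `d_inc_low - db` for both
#' high-conflict cells.
#'
#' @param model_id Model identifier, see [model_param_names()].
#' @param theta Named numeric vector of free parameters.
#' @param b2_mapping `"verbal"` (default) or `"literal"`, see Details.
#' @return Named list of [lba_race()] objects
#'   (`con_low`, `inc_low`, `con_high`, `inc_high`).
#' @examples
#' th <- c(s = 0.19, A = 0.17, t0 = 0.20, d_con_low = 0.26, d_inc_low = 0.31,
#'         db = 0.01, v_con = 0.78, v_inc = 0.70)
#' races <- build_condition_params("B2", th)
#' races$inc_high$correct$b  # A + d_inc_low - db = 0.47
#' @export
build_condition_params <- function(model_id, theta,
                                   b2_mapping = c("verbal", "literal")) {
  model_id <- match.arg(model_id, .all_models)
  b2_mapping <- match.arg(b2_mapping)
  th <- as.list(.check_theta(model_id, theta))

  d_by_cond <- switch(model_id,
    V1 = ,
    V2 = ,
    T0 = rep(list(th$d), 4L),
    B1 = ,
    VB = list(th$d_con_low, th$d_inc_low, th$d_con_high, th$d_inc_high),
    B2 = if (b2_mapping == "verbal") {
      list(th$d_con_low, th$d_inc_low,
        th$d_con_low + th$db, th$d_inc_low - th$db)
    } else {
      list(th$d_con_low, th$d_inc_low,
        th$d_inc_low - th$db, th$d_inc_low + th$db)
    }
  )
  names(d_by_cond) <- CSPC_CONDITIONS

  v_by_cond <- switch(model_id,
    V1 = ,
    VB = list(th$v_con_low, th$v_inc_low, th$v_con_high, th$v_inc_high),
    V2 = list(th$v_con_low, th$v_inc_low,
      th$v_con_low - th$dv, th$v_inc_low + th$dv),
    B1 = ,
    B2 = ,
    T0 = list(th$v_con, th$v_inc, th$v_con, th$v_inc)
  )
  names(v_by_cond) <- CSPC_CONDITIONS

  t0_by_cond <- if (model_id == "T0") {
    list(con_low = th$t0_con_low, inc_low = th$t0_inc_low,
      con_high = th$t0_con_low + th$dt0, inc_high = th$t0_inc_low - th$dt0)
  } else {
    stats::setNames(rep(list(th$t0), 4L), CSPC_CONDITIONS)
  }

  races <- lapply(CSPC_CONDITIONS, function(cond) {
    d <- d_by_cond[[cond]]
    if (d <= 0) {
      stop("threshold distance for condition ", cond, " is not positive",
        call. = FALSE)
    }
    t0 <- t0_by_cond[[cond]]
    if (t0 < 0) stop("non-decision time for condition ", cond,
      " is negative", call. = FALSE)
    v <- v_by_cond[[cond]]
    b <- th$A + d
    lba_race(
      correct = lba_accumulator(b = b, A = th$A, v = v, s = th$s),
      error = lba_accumulator(b = b, A = th$A, v = 1 - v, s = th$s),
      t0 = t0
    )
  })
  stats::setNames(races, CSPC_CONDITIONS)
}

#' Box bounds for a model's free parameters
#'
#' Generous brackets around the scales seen in group-average fits:
#' `s`, `A` and threshold distances in `(0.001, 2]`, drifts in `[0, 2]`,
#' context shifts `dv`/`db`/`dt0` in `[-1, 1]`, and non-decision times in
#' `(0.001, rt_min)` where `rt_min` is the participant's fastest retained RT
#' (a `t0` at or above it makes every density vanish).
#'
#' @inheritParams model_param_names
#' @param rt_min Smallest RT (seconds) in the data to be fitted.
#' @return List with named numeric vectors `lower` and `upper`.
#' @export
model_param_bounds <- function(model_id, rt_min) {
  nm <- model_param_names(model_id)
  lower <- upper <- stats::setNames(numeric(length(nm)), nm)
  t0_hi <- max(rt_min - 1e-3, 0.05)
  for (p in nm) {
    if (p %in% c("s", "A") || startsWith(p, "d_") || p == "d") {
      lower[p] <- 0.001; upper[p] <- 2
    } else if (startsWith(p, "v")) {
      lower[p] <- 0; upper[p] <- 2
    } else if (p %in% c("dv", "db", "dt0")) {
      lower[p] <- -1; upper[p] <- 1
    } else if (startsWith(p, "t0")) {
      lower[p] <- 0.001; upper[p] <- t0_hi
    } else {
      stop("unhandled parameter ", p)
    }
  }
  list(lower = lower, upper = upper)
}
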