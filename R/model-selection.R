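# Information-criterion model comparison: AIC/BIC, Akaike-style weights,
# per-participant best-model tallies, and the threshold-vs-drift ("B vs V")
# evidence ratio.  Also the distribution summaries used to display fit
# quality: defective RT quantiles and model-predicted moments.

#' AIC and BIC from a log-likelihood
#'
#' `AIC = 2k - 2*logLik`, `BIC = k*log(N) - 2*logLik`, with `k` free
#' parameters and `N` data points (trials).  Their penalties cross at
#' `log(N) = 2`: for any realistic trial count BIC penalizes complexity
#' more heavily.
#'
#' @param loglik Maximized log-likelihood (natural log).
#' @param k Number of free parameters.
#' @param n Number of data points used in the likelihood.
#' @return Named numeric vector `c(AIC = , BIC = )`.
#' @export
information_criteria <- function(loglik, k, n) {
  stopifnot(n >= 1, k >= 0, is.finite(loglik))
  c(AIC = 2 * k - 2 * loglik, BIC = k * log(n) - 2 * loglik)
}

#' Information-criterion weights
#'
#' Transforms IC values into model weights: subtract the smallest IC to get
#' `dIC`, then `w_i = exp(-dIC_i / 2) / sum_k exp(-dIC_k / 2)`.  Weights sum
#' to one and are invariant to adding a constant to every IC; they are read
#' as the probability that each model is the true one among those compared.
#'
#' @param ic Numeric vector of IC values (one per model), optionally named.
#' @return Numeric vector of weights, same names as `ic`.
#' @examples
#' ic_weights(c(V1 = 210, V2 = 212, B1 = 208, B2 = 208))
#' @export
ic_weights <- function(ic) {
  stopifnot(length(ic) >= 2, all(is.finite(ic)))
  d <- ic - min(ic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Threshold-vs-drift evidence ratio
#'
#' How much more likely a response-threshold (B-class) model is to be the
#' true model than a drift (V-class) model:
#' `(w_B1 + w_B2) / (w_V1 + w_V2)`.  A ratio of 1 means the classes tie.
#'
#' @param weights Named numeric vector (or list) holding weights for
#'   `V1`, `V2`, `B1`, `B2`.
#' @return Positive ratio; `NaN` with a warning if the drift-class weight
#'   is zero.
#' @export
b_vs_v_ratio <- function(weights) {
  w <- unlist(weights)
  stopifnot(all(c("V1", "V2", "B1", "B2") %in% names(w)))
  denom <- w[["V1"]] + w[["V2"]]
  if (denom == 0) {
    warning("drift-class weight is zero; ratio undefined")
    return(NaN)
  }
  (w[["B1"]] + w[["B2"]]) / denom
}

#' Per-participant selection records from fit results
#'
#' Computes, for each participant and criterion, the IC deltas, weights and
#' best model from a table of per-model fits.
#'
#' @param fits Data frame with one row per participant x model, columns
#'   `participant`, `model`, `AIC`, `BIC` (e.g. rows of [fit_participant()]
#'   results bound together).
#' @return Data frame with columns `participant`, `criterion`, `model`,
#'   `ic`, `delta`, `weight`, `best` (logical; ties all flagged).
#' @export
selection_records <- function(fits) {
  stopifnot(all(c("participant", "model", "AIC", "BIC") %in% names(fits)))
  out <- list()
  for (crit in c("AIC", "BIC")) {
    for (pid in unique(fits$participant)) {
      sub <- fits[fits$participant == pid, ]
      ic <- stats::setNames(sub[[crit]], sub$model)
      w <- ic_weights(ic)
      d <- ic - min(ic)
      out[[length(out) + 1L]] <- data.frame(
        participant = pid, criterion = crit, model = sub$model,
        ic = unname(ic), delta = unname(d), weight = unname(w),
        best = unname(d == 0), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Aggregate best-fit counts and pooled percentages
#'
#' Tallies how many participants each model fits best (per criterion and
#' grouping), splitting ties equally, and pools the counts into percentages
#' of all participants.
#'
#' @param records Output of [selection_records()], optionally with an extra
#'   grouping column (e.g. `dataset`).
#' @param group Name of the grouping column, or `NULL` to pool everything.
#' @return List with `counts` (criterion x model x group best-fit counts)
#'   and `pooled` (criterion x model pooled counts and `pct` of all
#'   participants).
#' @export
aggregate_best_fit <- function(records, group = NULL) {
  stopifnot(is.null(group) || group %in% names(records))
  models <- unique(records$model)
  grp_of <- function(df) if (is.null(group)) "all" else df[[group]]
  rows <- list()
  for (crit in unique(records$criterion)) {
    sub <- records[records$criterion == crit, ]
    for (pid in unique(sub$participant)) {
      p <- sub[sub$participant == pid, ]
      ties <- p$model[p$best]
      share <- 1 / length(ties)
      for (m in ties) {
        rows[[length(rows) + 1L]] <- data.frame(
          criterion = crit, group = grp_of(p)[1], model = m,
          count = share, stringsAsFactors = FALSE
        )
      }
    }
  }
  long <- do.call(rbind, rows)
  counts <- stats::aggregate(count ~ criterion + group + model, long, sum)
  pooled <- stats::aggregate(count ~ criterion + model, long, sum)
  n_per_crit <- tapply(records$participant, records$criterion,
    function(x) length(unique(x)))
  pooled$pct <- 100 * pooled$count / as.numeric(n_per_crit[pooled$criterion])
  list(counts = counts, pooled = pooled)
}

#' Pooled best-fit percentages from per-group counts
#'
#' Direct arithmetic for published count tables: pools per-data-set
#' best-fit counts and expresses each model's total as a percentage of all
#' participants.
#'
#' @param counts Numeric vector of per-group best-fit counts for one model.
#' @param n_total Total number of participants across groups.
#' @return Percentage (0-100).
#' @examples
#' pooled_best_fit_pct(c(8, 9, 12, 8), 87)  # B1 under AIC
#' @export
pooled_best_fit_pct <- function(counts, n_total) {
  100 * sum(counts) / n_total
}

#' Defective RT quantile summary for one condition cell
#'
#' Summarises a cell's RT distributions separately for correct and error
#' responses: within-class quantiles (default 10/30/50/70/90%) and their
#' cumulative heights scaled by the class's response proportion, so the two
#' classes' heights sum toward 1.  Classes with fewer than `min_n`
#' responses are flagged unreliable but still summarised.
#'
#' @param rt Numeric vector of RTs (any fixed unit).
#' @param correct Logical vector, same length, response correctness.
#' @param probs Within-class quantile probabilities.
#' @param min_n Reliability cutoff for a response class.
#' @return Data frame with columns `class`, `prob`, `rt_q`,
#'   `cum_height`, `n`, `reliable`.
#' @export
quantile_summary <- function(rt, correct, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                             min_n = 5L) {
  stopifnot(length(rt) == length(correct), length(rt) > 0)
  out <- lapply(c(TRUE, FALSE), function(ch) {
    cls <- if (ch) "correct" else "error"
    x <- rt[correct == ch]
    prop <- length(x) / length(rt)
    if (length(x) == 0L) {
      return(data.frame(class = cls, prob = probs, rt_q = NA_real_,
        cum_height = probs * prop, n = 0L, reliable = FALSE))
    }
    data.frame(
      class = cls, prob = probs,
      rt_q = unname(stats::quantile(x, probs, type = 7)),
      cum_height = probs * prop,
      n = length(x), reliable = length(x) >= min_n
    )
  })
  do.call(rbind, out)
}

#' Model-predicted defective RT quantiles
#'
#' Within-class RT quantiles implied by the closed-form defective
#' distribution of an [lba_race()]: inverts
#' `P(RT <= t, class) / P(class) = p` numerically.
#'
#' @param race An [lba_race()].
#' @param probs Within-class quantile probabilities.
#' @return Data frame with `class`, `prob`, `rt_q` (seconds),
#'   `cum_height`.
#' @export
predicted_quantiles <- function(race, probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  p_resp <- lba_response_prob(race)
  def_cdf <- function(t, ch) {
    vapply(t, function(tt) {
      if (tt <= race$t0) return(0)
      stats::integrate(function(u) lba_defective_density(u, ch, race),
        lower = race$t0, upper = tt, rel.tol = 1e-8,
        subdivisions = 400L)$value
    }, numeric(1))
  }
  out <- lapply(c("correct", "error"), function(ch) {
    pr <- p_resp[[ch]]
    q <- vapply(probs, function(p) {
      target <- p * pr
      stats::uniroot(function(tt) def_cdf(tt, ch) - target,
        lower = race$t0 + 1e-6, upper = race$t0 + 30,
        tol = 1e-6)$root
    }, numeric(1))
    data.frame(class = ch, prob = probs, rt_q = q,
      cum_height = probs * pr / sum(p_resp))
  })
  do.call(rbind, out)
}

#' Model-predicted mean RT and accuracy per condition
#'
#' Quadrature over the defective densities: per condition, the probability
#' of a correct response and the mean RT of each response class (seconds).
#'
#' @param races Named list of [lba_race()] objects (e.g. from
#'   [build_condition_params()]).
#' @return Data frame with columns `condition`, `p_correct`,
#'   `mean_rt_correct`, `mean_rt_error`, `mean_rt` (all responses).
#' @export
predicted_moments <- function(races) {
  one <- function(cond) {
    race <- races[[cond]]
    pr <- lba_response_prob(race)
    m <- vapply(c("correct", "error"), function(ch) {
      stats::integrate(
        function(u) (u + race$t0) *
          lba_defective_density(u + race$t0, ch, race),
        lower = 0, upper = 30, rel.tol = 1e-9, subdivisions = 400L
      )$value
    }, numeric(1))
    p_tot <- sum(pr)
    data.frame(
      condition = cond,
      p_correct = pr[["correct"]] / p_tot,
      mean_rt_correct = m[["correct"]] / pr[["correct"]],
      mean_rt_error = m[["error"]] / pr[["error"]],
      mean_rt = sum(m) / p_tot
    )
  }
  do.call(rbind, lapply(names(races), one))
}
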