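# Closed-form distribution functions for the linear ballistic accumulator
# (LBA): a single accumulator starts at a uniform random point in [0, A],
# rises linearly at a drift sampled once per trial from Normal(v, s), and
# triggers its response on reaching threshold b.  Times are decision times in
# seconds (non-decision time t0 is handled at the race level).

# guard for the ts denominator near t = 0
.TS_FLOOR <- 1e-10
# below this A the uniform start point is treated as degenerate at 0
.A_FLOOR <- 1e-8
# density floor applied before taking logs so the likelihood stays finite
.DENSITY_FLOOR <- 1e-10

#' Single-accumulator specification
#'
#' Bundles the four parameters of one LBA accumulator: response threshold
#' `b`, upper bound `A` of the uniform start-point distribution, mean drift
#' rate `v`, and across-trial drift SD `s`.  Evidence units are arbitrary;
#' time is in seconds, so drifts are evidence units per second.
#'
#' @param b Response threshold; must satisfy `b >= A`.
#' @param A Maximum start point (uniform on `[0, A]`); `A >= 0`.
#' @param v Mean drift rate.
#' @param s Across-trial SD of the drift rate; `s > 0`.
#' @return An object of class `"lba_accumulator"` (a named list).
#' @examples
#' acc <- lba_accumulator(b = 0.48, A = 0.14, v = 0.64, s = 0.18)
#' lba_cdf(0.5, acc)
#' @export
lba_accumulator <- function(b, A, v, s) {
  stopifnot(is.numeric(b), is.numeric(A), is.numeric(v), is.numeric(s))
  if (A < 0) stop("start-point range A must be >= 0", call. = FALSE)
  if (b < A) stop("threshold b must be >= A", call. = FALSE)
  if (s <= 0) stop("drift SD s must be > 0", call. = FALSE)
  structure(list(b = b, A = A, v = v, s = s), class = "lba_accumulator")
}

#' Accumulator pair racing for the two responses
#'
#' The race that generates one behavioral response: a `correct` accumulator
#' (the response matching the target) and an `error` accumulator, plus the
#' shared non-decision time `t0` (seconds) added to the winning decision
#' time.  Both accumulators share `b`, `A` and `s` within a condition; only
#' the mean drifts differ.
#'
#' @param correct,error `lba_accumulator` objects.
#' @param t0 Non-decision time in seconds, `t0 >= 0`.
#' @return An object of class `"lba_race"`.
#' @export
lba_race <- function(correct, error, t0) {
  stopifnot(inherits(correct, "lba_accumulator"), inherits(error, "lba_accumulator"))
  if (t0 < 0) stop("non-decision time t0 must be >= 0", call. = FALSE)
  structure(list(correct = correct, error = error, t0 = t0), class = "lba_race")
}

#' Single-accumulator threshold-crossing CDF
#'
#' Probability that one LBA accumulator has reached threshold by decision
#' time `t`.  The distribution is defective: as `t` grows it tends to
#' `pnorm(v / s)`, the probability of a positive drift draw.  For
#' (numerically) zero `A` the start point is degenerate and the crossing
#' time is `b / drift`, giving `pnorm((v - b / t) / s)`.
#'
#' @param t Decision time(s) in seconds; values `<= 0` return 0.
#' @param acc An `lba_accumulator`.
#' @return Vector of probabilities in `[0, 1]`.
#' @export
lba_cdf <- function(t, acc) {
  b <- acc$b; A <- acc$A; v <- acc$v; s <- acc$s
  out <- numeric(length(t))
  pos <- which(t > 0)
  if (!length(pos)) return(out)
  tp <- t[pos]
  ts <- pmax(tp * s, .TS_FLOOR)
  if (A < .A_FLOOR) {
    f <- stats::pnorm((tp * v - b) / ts)
  } else {
    z1 <- (b - A - tp * v) / ts
    z2 <- (b - tp * v) / ts
    f <- 1 +
      ((b - A - tp * v) / A) * stats::pnorm(z1) -
      ((b - tp * v) / A) * stats::pnorm(z2) +
      (ts / A) * stats::dnorm(z1) -
      (ts / A) * stats::dnorm(z2)
  }
  out[pos] <- pmin(pmax(f, 0), 1)
  out
}

#' Single-accumulator threshold-crossing density
#'
#' Derivative of [lba_cdf()] with respect to decision time.  Shares the
#' degenerate-start-point branch for `A` near zero.
#'
#' @inheritParams lba_cdf
#' @return Vector of nonnegative densities.
#' @export
lba_pdf <- function(t, acc) {
  b <- acc$b; A <- acc$A; v <- acc$v; s <- acc$s
  out <- numeric(length(t))
  pos <- which(t > 0)
  if (!length(pos)) return(out)
  tp <- t[pos]
  ts <- pmax(tp * s, .TS_FLOOR)
  if (A < .A_FLOOR) {
    f <- (b / tp^2) * stats::dnorm((tp * v - b) / ts) / s
  } else {
    z1 <- (b - A - tp * v) / ts
    z2 <- (b - tp * v) / ts
    f <- (-v * stats::pnorm(z1) + s * stats::dnorm(z1) +
      v * stats::pnorm(z2) - s * stats::dnorm(z2)) / A
  }
  out[pos] <- pmax(f, 0)
  out
}

#' Defective density of a response at an observed RT
#'
#' Density that the named response wins the race at observed time `rt`
#' (seconds): the winning accumulator's crossing density at the decision
#' time `rt - t0`, times the probability the other accumulator has not yet
#' crossed.  Integrates over `rt` to the probability of that response, so
#' the two choices jointly integrate to the probability that at least one
#' drift draw is positive (no renormalization; the complement is
#' negligible at fitted scales).  Zero for `rt <= t0`.
#'
#' @param rt Observed response time(s) in seconds.
#' @param choice `"correct"` or `"error"`: which accumulator won.
#' @param race An [lba_race()].
#' @return Vector of nonnegative densities.
#' @export
lba_defective_density <- function(rt, choice, race) {
  choice <- match.arg(choice, c("correct", "error"))
  td <- rt - race$t0
  winner <- if (choice == "correct") race$correct else race$error
  loser <- if (choice == "correct") race$error else race$correct
  dens <- lba_pdf(td, winner) * (1 - lba_cdf(td, loser))
  dens[td <= 0] <- 0
  dens
}

#' Probability of each response under the race
#'
#' Integrates the defective densities over all response times by adaptive
#' quadrature.
#'
#' @param race An [lba_race()].
#' @param upper Upper integration limit (seconds past `t0`).
#' @return Named numeric vector `c(correct = , error = )`.
#' @export
lba_response_prob <- function(race, upper = 30) {
  vapply(c("correct", "error"), function(ch) {
    stats::integrate(function(u) lba_defective_density(u + race$t0, ch, race),
      lower = 0, upper = upper, rel.tol = 1e-9, subdivisions = 400L
    )$value
  }, numeric(1))
}

#' Closed-form CDF of the winning time of the race
#'
#' `P(response by time rt, either choice)`: one minus the product of the two
#' accumulators' survival functions (the accumulators are independent).
#' Used to check the simulator against the analytic distribution.
#'
#' @param rt Observed time(s) in seconds.
#' @param race An [lba_race()].
#' @return Probabilities (defective: bounded by `1 - P(both drifts <= 0)`).
#' @export
lba_race_cdf <- function(rt, race) {
  td <- rt - race$t0
  p <- 1 - (1 - lba_cdf(td, race$correct)) * (1 - lba_cdf(td, race$error))
  p[td <= 0] <- 0
  p
}

#' Trial log-likelihood for one participant
#'
#' Sum over trials of the log defective density of the observed
#' (choice, RT) pair under the condition's race parameters.  Densities are
#' floored at `1e-10` before the log so the objective stays finite
#' everywhere inside the optimizer's box.
#'
#' @param trials Data frame with columns `condition` (character, matching
#'   names of `races`), `correct` (logical: response matched the target) and
#'   `rt` (seconds).
#' @param races Named list of [lba_race()] objects, one per condition.
#' @return Scalar log-likelihood (0 for an empty trial list).
#' @export
lba_log_likelihood <- function(trials, races) {
  if (nrow(trials) == 0L) return(0)
  missing_cond <- setdiff(unique(trials$condition), names(races))
  if (length(missing_cond)) {
    stop("no race parameters mapped for condition(s): ",
      paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  ll <- 0
  for (cond in unique(trials$condition)) {
    sub <- trials[trials$condition == cond, ]
    race <- races[[cond]]
    for (ch in c(TRUE, FALSE)) {
      rts <- sub$rt[sub$correct == ch]
      if (!length(rts)) next
      dens <- lba_defective_density(rts, if (ch) "correct" else "error", race)
      ll <- ll + sum(log(pmax(dens, .DENSITY_FLOOR)))
    }
  }
  ll
}

#' Simulate trials from an LBA race
#'
#' Draws start points uniform on `[0, A]` and drifts from Normal(v, s)
#' independently for the two accumulators; the response is the accumulator
#' with the smaller crossing time `(b - start) / drift` (positive drifts
#' only), and `rt = t0 +` that time.  Trials on which both drift draws are
#' nonpositive are redrawn.  Uses R's global RNG stream; call `set.seed()`
#' for reproducibility.
#'
#' @param n Number of trials.
#' @param race An [lba_race()].
#' @return Data frame with columns `correct` (logical) and `rt` (seconds).
#' @export
lba_simulate <- function(n, race) {
  draw_hit <- function(acc, m) {
    start <- stats::runif(m, 0, acc$A)
    drift <- stats::rnorm(m, acc$v, acc$s)
    ifelse(drift > 0, (acc$b - start) / drift, Inf)
  }
  hit_c <- draw_hit(race$correct, n)
  hit_e <- draw_hit(race$error, n)
  bad <- which(!is.finite(hit_c) & !is.finite(hit_e))
  while (length(bad)) {
    hit_c[bad] <- draw_hit(race$correct, length(bad))
    hit_e[bad] <- draw_hit(race$error, length(bad))
    bad <- bad[!is.finite(hit_c[bad]) & !is.finite(hit_e[bad])]
  }
  data.frame(
    correct = hit_c <= hit_e,
    rt = race$t0 + pmin(hit_c, hit_e)
  )
}
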