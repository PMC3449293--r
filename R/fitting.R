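# Per-participant maximum-likelihood estimation.  The likelihood surface of
# an LBA parameterization is smooth but multimodal, so the search combines
# a global particle swarm (constriction-style coefficients, restarts) with
# a bounded quasi-Newton polish from the swarm's best point.

.PENALTY <- -1e12  # objective value outside the valid parameter region

#' Optimizer configuration
#'
#' Settings for the particle swarm search and local polish.  Defaults are
#' standard constriction-type values: 40 particles, 500 iterations, inertia
#' 0.72, cognitive = social = 1.49, 3 restarts, followed by an L-BFGS-B
#' polish of the best particle.  Reduced budgets (fewer particles,
#' iterations and restarts) are adequate for simulation studies because the
#' polish recovers the local optimum precisely.
#'
#' @param swarm Number of particles.
#' @param iterations Iterations per restart.
#' @param inertia,cognitive,social PSO velocity coefficients.
#' @param restarts Independent swarm restarts (best result kept).
#' @param polish Run a bounded local optimization from the swarm optimum?
#' @param seed Integer seed controlling the whole search.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(swarm = 40L, iterations = 500L, inertia = 0.72,
                       cognitive = 1.49, social = 1.49, restarts = 3L,
                       polish = TRUE, seed = 1L) {
  stopifnot(swarm >= 2, iterations >= 1, restarts >= 1)
  structure(
    list(swarm = as.integer(swarm), iterations = as.integer(iterations),
      inertia = inertia, cognitive = cognitive, social = social,
      restarts = as.integer(restarts), polish = isTRUE(polish),
      seed = as.integer(seed)),
    class = "fit_config"
  )
}

#' Read an optimizer configuration from a key = value text file
#'
#' Plain-text lines `key = value` (one per line, `#` comments allowed) for
#' any [fit_config()] argument; unspecified keys keep their defaults.
#'
#' @param path File path.
#' @return A `"fit_config"` object.
#' @export
read_fit_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("cannot parse config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    args[[key]] <- if (key == "polish") as.logical(val) else as.numeric(val)
  }
  do.call(fit_config, args)
}

#' Prepare raw trial records for likelihood fitting
#'
#' Drops response omissions (trials without a recorded response/RT),
#' converts RTs from milliseconds to seconds, and attaches the condition
#' label.  No RT-window trimming is applied for fitting; the stricter
#' trimming used for descriptive statistics ([trim_trials()]) is a separate
#' accounting.
#'
#' @param trials Data frame with columns `context` (`"high"`/`"low"`),
#'   `congruency` (`"con"`/`"inc"`), `correct` (logical, `NA` for
#'   omissions) and `rt_ms` (`NA` for omissions).
#' @return Data frame with columns `condition`, `correct`, `rt` (seconds).
#' @export
prepare_fit_data <- function(trials) {
  keep <- !is.na(trials$correct) & !is.na(trials$rt_ms)
  if (!any(keep)) stop("no valid trials after removing omissions", call. = FALSE)
  t <- trials[keep, ]
  data.frame(
    condition = condition_label(t$context, t$congruency),
    correct = t$correct,
    rt = t$rt_ms / 1000
  )
}

#' Condition label from context and congruency
#'
#' @param context `"high"` or `"low"` (conflict frequency of the side).
#' @param congruency `"con"` or `"inc"`.
#' @return Character vector like `"inc_high"`, matching the names used by
#'   [build_condition_params()].
#' @export
condition_label <- function(context, congruency) {
  paste(congruency, context, sep = "_")
}

# Pre-split trials into (condition x choice) RT groups so the objective
# avoids data-frame subsetting in the inner loop.
.ll_groups <- function(prepared) {
  groups <- list()
  for (cond in unique(prepared$condition)) {
    for (ch in c(TRUE, FALSE)) {
      rts <- prepared$rt[prepared$condition == cond & prepared$correct == ch]
      if (length(rts)) {
        groups[[length(groups) + 1L]] <-
          list(condition = cond, correct = ch, rt = rts)
      }
    }
  }
  groups
}

.ll_from_groups <- function(groups, races) {
  ll <- 0
  for (g in groups) {
    race <- races[[g$condition]]
    dens <- lba_defective_density(g$rt, if (g$correct) "correct" else "error",
      race)
    ll <- ll + sum(log(pmax(dens, .DENSITY_FLOOR)))
  }
  ll
}

# Fused defective log-density sum for one (condition x choice) group, used
# in the optimizer's inner loop.  Exploits the shared b, A, s of the two
# accumulators within a condition; numerically identical to
# lba_defective_density + log + floor.
.ll_group_fast <- function(rt, b, A, v_win, v_lose, s, t0) {
  td <- rt - t0
  pos <- td > 0
  n_bad <- sum(!pos)
  td <- td[pos]
  if (!length(td)) return(n_bad * log(.DENSITY_FLOOR))
  ts <- pmax(td * s, .TS_FLOOR)
  zw1 <- (b - A - td * v_win) / ts
  zw2 <- (b - td * v_win) / ts
  pdf <- (-v_win * stats::pnorm(zw1) + s * stats::dnorm(zw1) +
    v_win * stats::pnorm(zw2) - s * stats::dnorm(zw2)) / A
  zl1 <- (b - A - td * v_lose) / ts
  zl2 <- (b - td * v_lose) / ts
  cdf <- 1 + ((b - A - td * v_lose) / A) * stats::pnorm(zl1) -
    ((b - td * v_lose) / A) * stats::pnorm(zl2) +
    (ts / A) * stats::dnorm(zl1) - (ts / A) * stats::dnorm(zl2)
  dens <- pmax(pdf, 0) * (1 - pmin(pmax(cdf, 0), 1))
  sum(log(pmax(dens, .DENSITY_FLOOR))) + n_bad * log(.DENSITY_FLOOR)
}

.ll_from_groups_fast <- function(groups, races) {
  ll <- 0
  for (g in groups) {
    race <- races[[g$condition]]
    win <- if (g$correct) race$correct else race$error
    lose <- if (g$correct) race$error else race$correct
    ll <- ll + .ll_group_fast(g$rt, win$b, win$A, win$v, lose$v, win$s,
      race$t0)
  }
  ll
}

# Allocation-light expansion of a parameter vector to per-condition race
# parameters for the optimizer; returns NULL where the constructor-based
# build_condition_params() would throw (invalid derived distances / times).
.fast_races <- function(model_id, th, b2_mapping) {
  d <- switch(model_id,
    V1 = , V2 = , T0 = rep(th[["d"]], 4L),
    B1 = , VB = c(th[["d_con_low"]], th[["d_inc_low"]],
      th[["d_con_high"]], th[["d_inc_high"]]),
    B2 = if (b2_mapping == "verbal") {
      c(th[["d_con_low"]], th[["d_inc_low"]],
        th[["d_con_low"]] + th[["db"]], th[["d_inc_low"]] - th[["db"]])
    } else {
      c(th[["d_con_low"]], th[["d_inc_low"]],
        th[["d_inc_low"]] - th[["db"]], th[["d_inc_low"]] + th[["db"]])
    }
  )
  if (any(d <= 0)) return(NULL)
  v <- switch(model_id,
    V1 = , VB = c(th[["v_con_low"]], th[["v_inc_low"]],
      th[["v_con_high"]], th[["v_inc_high"]]),
    V2 = c(th[["v_con_low"]], th[["v_inc_low"]],
      th[["v_con_low"]] - th[["dv"]], th[["v_inc_low"]] + th[["dv"]]),
    B1 = , B2 = , T0 = c(th[["v_con"]], th[["v_inc"]],
      th[["v_con"]], th[["v_inc"]])
  )
  t0 <- if (model_id == "T0") {
    c(th[["t0_con_low"]], th[["t0_inc_low"]],
      th[["t0_con_low"]] + th[["dt0"]], th[["t0_inc_low"]] - th[["dt0"]])
  } else {
    rep(th[["t0"]], 4L)
  }
  if (any(t0 < 0)) return(NULL)
  A <- th[["A"]]
  s <- th[["s"]]
  races <- lapply(1:4, function(i) {
    b <- A + d[i]
    list(
      correct = list(b = b, A = A, v = v[i], s = s),
      error = list(b = b, A = A, v = 1 - v[i], s = s),
      t0 = t0[i]
    )
  })
  names(races) <- CSPC_CONDITIONS
  races
}

.make_objective <- function(groups, model_id, b2_mapping) {
  function(theta_vec, names_vec) {
    th <- stats::setNames(theta_vec, names_vec)
    races <- .fast_races(model_id, th, b2_mapping)
    if (is.null(races)) return(.PENALTY)
    ll <- .ll_from_groups_fast(groups, races)
    if (!is.finite(ll)) .PENALTY else ll
  }
}

# Data-informed starting point: non-decision time just under the fastest
# RT, threshold distance sized so mean drift covers the median decision
# time, drifts at the scale typical of flanker fits.  One particle per
# restart starts here; the rest are random.
.heuristic_start <- function(names_vec, prepared, lower, upper) {
  t0h <- 0.8 * min(prepared$rt)
  med_dt <- max(stats::median(prepared$rt) - t0h, 0.1)
  start <- vapply(names_vec, function(p) {
    if (p == "s") 0.15
    else if (p == "A") 0.15
    else if (p == "d" || startsWith(p, "d_")) max(0.75 * med_dt - 0.15, 0.05)
    else if (p %in% c("db", "dv", "dt0")) 0
    else if (startsWith(p, "v")) 0.75
    else if (startsWith(p, "t0")) t0h
    else stop("unhandled parameter ", p)
  }, numeric(1))
  pmin(pmax(start, lower + 1e-6), upper - 1e-6)
}

# One particle-swarm run inside box bounds; returns the best position and
# value, plus the best-so-far trace (nondecreasing by construction).
.pso_run <- function(obj, lower, upper, config, init = NULL) {
  npar <- length(lower)
  n <- config$swarm
  span <- upper - lower
  pos <- matrix(stats::runif(n * npar), n, npar)
  pos <- sweep(sweep(pos, 2, span, "*"), 2, lower, "+")
  if (!is.null(init)) pos[1, ] <- init
  vel <- sweep(matrix(stats::runif(n * npar, -1, 1), n, npar), 2, span / 10, "*")
  val <- apply(pos, 1, obj)
  pbest <- pos
  pbest_val <- val
  g <- which.max(val)
  gbest <- pos[g, ]
  gbest_val <- val[g]
  vmax <- span / 2
  trace <- numeric(config$iterations)
  for (it in seq_len(config$iterations)) {
    r1 <- matrix(stats::runif(n * npar), n, npar)
    r2 <- matrix(stats::runif(n * npar), n, npar)
    gmat <- matrix(gbest, n, npar, byrow = TRUE)
    vel <- config$inertia * vel +
      config$cognitive * r1 * (pbest - pos) +
      config$social * r2 * (gmat - pos)
    vel <- pmin(pmax(vel, matrix(-vmax, n, npar, byrow = TRUE)),
      matrix(vmax, n, npar, byrow = TRUE))
    pos <- pos + vel
    pos <- pmin(pmax(pos, matrix(lower, n, npar, byrow = TRUE)),
      matrix(upper, n, npar, byrow = TRUE))
    val <- apply(pos, 1, obj)
    improved <- val > pbest_val
    pbest[improved, ] <- pos[improved, ]
    pbest_val[improved] <- val[improved]
    g <- which.max(pbest_val)
    if (pbest_val[g] > gbest_val) {
      gbest <- pbest[g, ]
      gbest_val <- pbest_val[g]
    }
    trace[it] <- gbest_val
  }
  list(par = gbest, value = gbest_val, trace = trace)
}

#' Fit one model to one participant by maximum likelihood
#'
#' Maximizes the summed trial log-likelihood over the model's box bounds
#' with a seeded particle swarm (several restarts) and an optional bounded
#' local polish.  The reported log-likelihood is re-evaluated at the
#' returned parameters; rerunning with the same configuration reproduces
#' the result exactly.
#'
#' @param prepared Output of [prepare_fit_data()] (columns `condition`,
#'   `correct`, `rt` in seconds).
#' @param model_id Model to fit, see [model_param_names()].
#' @param config A [fit_config()].
#' @param b2_mapping Passed to [build_condition_params()].
#' @return An object of class `"lba_fit"`: list with `model`, `theta`
#'   (named vector), `loglik`, `k`, `n`, `AIC`, `BIC`, `seed` and
#'   `convergence` (per-restart best values and best-so-far trace).
#' @export
fit_participant <- function(prepared, model_id, config = fit_config(),
                            b2_mapping = c("verbal", "literal")) {
  b2_mapping <- match.arg(b2_mapping)
  stopifnot(nrow(prepared) > 0)
  nm <- model_param_names(model_id)
  bounds <- model_param_bounds(model_id, rt_min = min(prepared$rt))
  groups <- .ll_groups(prepared)
  obj_named <- .make_objective(groups, model_id, b2_mapping)
  obj <- function(x) obj_named(x, nm)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  set.seed(config$seed)
  start <- .heuristic_start(nm, prepared, bounds$lower, bounds$upper)
  polish <- function(par, value) {
    pol <- tryCatch(
      stats::optim(par, function(x) -obj(x), method = "L-BFGS-B",
        lower = bounds$lower + 1e-9, upper = bounds$upper - 1e-9,
        control = list(maxit = 150, factr = 1e8)),
      error = function(e) NULL
    )
    if (!is.null(pol) && -pol$value > value) {
      list(par = pol$par, value = -pol$value)
    } else {
      list(par = par, value = value)
    }
  }
  best <- NULL
  restart_vals <- numeric(config$restarts)
  trace <- NULL
  for (r in seq_len(config$restarts)) {
    run <- .pso_run(obj, bounds$lower, bounds$upper, config, init = start)
    if (config$polish && run$value > .PENALTY) {
      run[c("par", "value")] <- polish(run$par, run$value)
    }
    restart_vals[r] <- run$value
    if (is.null(best) || run$value > best$value) {
      best <- run
      trace <- run$trace
    }
  }

  theta <- stats::setNames(best$par, nm)
  ll <- obj(unname(theta))
  k <- free_parameter_count(model_id)
  n <- nrow(prepared)
  ic <- information_criteria(ll, k, n)
  structure(
    list(model = model_id, theta = theta, loglik = ll, k = k, n = n,
      AIC = ic[["AIC"]], BIC = ic[["BIC"]], seed = config$seed,
      convergence = list(restart_values = restart_vals,
        best_so_far = trace)),
    class = "lba_fit"
  )
}

#' @export
print.lba_fit <- function(x, ...) {
  cat("LBA fit: model", x$model, " (k =", x$k, ", N =", x$n, ")\n")
  cat(sprintf("  logLik = %.3f  AIC = %.2f  BIC = %.2f\n",
    x$loglik, x$AIC, x$BIC))
  print(round(x$theta, 4))
  invisible(x)
}

#' Flatten a fit to a one-row data frame
#'
#' Parameter values become columns prefixed `par_`, suitable for binding
#' across participants and models and writing as delimited text.
#'
#' @param fit An `"lba_fit"`.
#' @param participant Optional participant identifier to prepend.
#' @return One-row data frame.
#' @export
fit_row <- function(fit, participant = NA) {
  pars <- as.list(fit$theta)
  names(pars) <- paste0("par_", names(pars))
  cbind(
    data.frame(participant = participant, model = fit$model,
      loglik = fit$loglik, k = fit$k, n = fit$n, AIC = fit$AIC,
      BIC = fit$BIC, seed = fit$seed, stringsAsFactors = FALSE),
    as.data.frame(pars)
  )
}

#' Fit several models to a cohort of participants
#'
#' Convenience loop over participants and models.  Each participant/model
#' pair gets a deterministic seed derived from `config$seed`, so any single
#' fit is reproducible in isolation.  Failures are caught, reported, and
#' tallied rather than aborting the cohort.
#'
#' @param cohort Named list of raw trial data frames (one per participant,
#'   format of [prepare_fit_data()] input).
#' @param models Character vector of model ids.
#' @param config Base [fit_config()].
#' @return List with `fits` (nested list participant -> model),
#'   `table` (data frame of [fit_row()]s with AIC/BIC), and `failures`.
#' @export
fit_cohort <- function(cohort, models = model_ids(), config = fit_config()) {
  fits <- list()
  rows <- list()
  failures <- character()
  ids <- names(cohort)
  if (is.null(ids)) ids <- as.character(seq_along(cohort))
  for (i in seq_along(cohort)) {
    pid <- ids[i]
    prepared <- tryCatch(prepare_fit_data(cohort[[i]]), error = function(e) e)
    if (inherits(prepared, "error")) {
      failures <- c(failures,
        paste0(pid, ": ", conditionMessage(prepared)))
      next
    }
    fits[[pid]] <- list()
    for (m in models) {
      cfg <- config
      cfg$seed <- (config$seed + 7919L * i + 104729L * match(m, models)) %%
        .Machine$integer.max
      res <- tryCatch(fit_participant(prepared, m, cfg),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, paste0(pid, "/", m, ": ", conditionMessage(res)))
        next
      }
      fits[[pid]][[m]] <- res
      rows[[length(rows) + 1L]] <- fit_row(res, participant = pid)
    }
  }
  list(fits = fits, table = rbind_fill(rows), failures = failures)
}

#' Row-bind data frames with unequal columns
#'
#' Missing columns are filled with `NA`, so fits of models with different
#' parameter sets can share one table.
#'
#' @param rows List of data frames.
#' @return A single data frame.
#' @export
rbind_fill <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) {
    for (col in setdiff(cols, names(r))) r[[col]] <- NA
    r[cols]
  }))
}
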