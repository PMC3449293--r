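# Synthetic flanker-task cohorts with the study's statistical structure:
# 448 trials per participant (4 x 112 or 7 x 64 blocks), stimulus location
# left/right of fixation, one side 75% incongruent (high-conflict context)
# and the other 75% congruent, RTs generated from an LBA race.  Used for
# parameter- and model-recovery studies and full-pipeline runs.

#' Design specification for a synthetic flanker session
#'
#' Proportions are realized exactly per block (counterbalanced allocation,
#' then a seeded shuffle), so they must be achievable in integers: each
#' block is split evenly between sides and
#' `prop_inc_high * trials_per_block / 2` must be whole.
#'
#' @param n_blocks Number of blocks (4 for the scanner protocol, 7 for the
#'   behavioral protocol).
#' @param trials_per_block Trials per block (112 or 64 respectively).
#' @param high_side Which side of fixation carries frequent conflict.
#' @param prop_inc_high Proportion of incongruent trials on the
#'   high-conflict side (the low-conflict side gets its complement).
#' @param omission_rate Probability a trial's response is omitted
#'   (default 0.7%, matching a mean of about 445 valid trials of 448).
#' @return List of class `"design_spec"`.
#' @export
design_spec <- function(n_blocks = 4L, trials_per_block = 112L,
                        high_side = c("left", "right"),
                        prop_inc_high = 0.75, omission_rate = 0.007) {
  high_side <- match.arg(high_side)
  stopifnot(n_blocks >= 1, trials_per_block >= 2,
    prop_inc_high > 0, prop_inc_high < 1,
    omission_rate >= 0, omission_rate < 1)
  per_side <- trials_per_block / 2
  if (per_side != round(per_side)) {
    stop("trials_per_block must be even", call. = FALSE)
  }
  n_inc_high <- prop_inc_high * per_side
  if (abs(n_inc_high - round(n_inc_high)) > 1e-9) {
    stop("prop_inc_high * trials_per_block / 2 must be an integer",
      call. = FALSE)
  }
  structure(
    list(n_blocks = as.integer(n_blocks),
      trials_per_block = as.integer(trials_per_block),
      high_side = high_side, prop_inc_high = prop_inc_high,
      omission_rate = omission_rate),
    class = "design_spec"
  )
}

#' Generate a trial sequence from a design specification
#'
#' Allocates exact per-side congruency counts within each block and
#' shuffles trial order with the given seed.  Context follows location:
#' the `high_side` is the high-conflict (frequent-incongruent) context.
#'
#' @param spec A [design_spec()].
#' @param seed Integer seed for the shuffle.
#' @return Data frame with columns `block`, `trial`, `location`, `context`,
#'   `congruency`.
#' @export
generate_design <- function(spec = design_spec(), seed = 1L) {
  force(seed)  # evaluate caller expressions before the RNG state is saved
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  per_side <- spec$trials_per_block %/% 2L
  n_inc_high <- as.integer(round(spec$prop_inc_high * per_side))
  sides <- c("left", "right")
  blocks <- lapply(seq_len(spec$n_blocks), function(b) {
    rows <- do.call(rbind, lapply(sides, function(side) {
      high <- side == spec$high_side
      n_inc <- if (high) n_inc_high else per_side - n_inc_high
      data.frame(
        location = side,
        context = if (high) "high" else "low",
        congruency = rep(c("inc", "con"), c(n_inc, per_side - n_inc)),
        stringsAsFactors = FALSE
      )
    }))
    rows <- rows[sample.int(nrow(rows)), ]
    cbind(data.frame(block = b, trial = seq_len(nrow(rows))), rows)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Simulate a cohort of participants from an LBA parameterization
#'
#' Each participant receives a freshly shuffled design and LBA-generated
#' choices and RTs (ms) per condition; omissions are injected at the
#' design's rate.  A master seed spawns one sub-seed per participant, so
#' any participant can be regenerated in isolation.
#'
#' @param model_id Generating model, see [model_param_names()].
#' @param theta Named generating parameter vector (e.g.
#'   [reference_theta()]).
#' @param n_participants Cohort size.
#' @param spec A [design_spec()].
#' @param seed Master integer seed.
#' @param b2_mapping Passed to [build_condition_params()].
#' @return List of class `"cspc_cohort"`: `trials` (named list of
#'   per-participant data frames with `participant`, `block`, `trial`,
#'   `location`, `context`, `congruency`, `correct`, `rt_ms`), and
#'   `truth` (generating `model`, `theta`, `seed`, per-participant seeds).
#' @export
simulate_participants <- function(model_id, theta, n_participants,
                                  spec = design_spec(), seed = 1L,
                                  b2_mapping = c("verbal", "literal")) {
  b2_mapping <- match.arg(b2_mapping)
  force(seed)  # evaluate caller expressions before the RNG state is saved
  races <- build_condition_params(model_id, theta, b2_mapping = b2_mapping)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_participants)
  trials <- lapply(seq_len(n_participants), function(i) {
    set.seed(sub_seeds[i])
    des <- generate_design(spec, seed = sample.int(.Machine$integer.max, 1))
    des$participant <- sprintf("P%03d", i)
    des$correct <- NA
    des$rt_ms <- NA_real_
    cond <- condition_label(des$context, des$congruency)
    for (cl in unique(cond)) {
      idx <- which(cond == cl)
      sim <- lba_simulate(length(idx), races[[cl]])
      des$correct[idx] <- sim$correct
      des$rt_ms[idx] <- sim$rt * 1000
    }
    if (spec$omission_rate > 0) {
      om <- stats::runif(nrow(des)) < spec$omission_rate
      des$correct[om] <- NA
      des$rt_ms[om] <- NA_real_
    }
    des[c("participant", "block", "trial", "location", "context",
      "congruency", "correct", "rt_ms")]
  })
  names(trials) <- vapply(trials, function(d) d$participant[1], character(1))
  structure(
    list(trials = trials,
      truth = list(model = model_id, theta = theta, seed = seed,
        participant_seeds = sub_seeds, b2_mapping = b2_mapping)),
    class = "cspc_cohort"
  )
}

#' Write / read a cohort as delimited text
#'
#' One tab-separated file of all trials (participant column included); the
#' generating truth, if present, goes to a `*.truth.tsv` sidecar of
#' `parameter  value` pairs.
#'
#' @param cohort A `"cspc_cohort"` (or plain list of trial data frames).
#' @param path Output file path for the trial table.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns a named list of per-participant data frames.
#' @export
write_trials <- function(cohort, path) {
  trials <- if (inherits(cohort, "cspc_cohort")) cohort$trials else cohort
  all <- do.call(rbind, trials)
  utils::write.table(all, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (inherits(cohort, "cspc_cohort")) {
    truth <- cohort$truth
    side <- data.frame(
      parameter = c("model", "seed", names(truth$theta)),
      value = c(truth$model, truth$seed, unname(truth$theta)),
      stringsAsFactors = FALSE
    )
    utils::write.table(side, paste0(path, ".truth.tsv"), sep = "\t",
      row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  all <- utils::read.delim(path, stringsAsFactors = FALSE)
  all$correct <- as.logical(all$correct)
  split(all, all$participant)
}

#' Parameter-recovery summary
#'
#' Per-parameter bias, RMSE and (for the context shifts `db`/`dv`/`dt0`)
#' the sign-recovery rate of a set of fits against the generating truth.
#'
#' @param fits List of `"lba_fit"` objects for the generating model.
#' @param true_theta Named generating parameter vector.
#' @return Data frame with columns `parameter`, `true`, `mean_est`, `bias`,
#'   `rmse`, `sign_rate` (`NA` for non-shift parameters).
#' @export
recovery_report <- function(fits, true_theta) {
  stopifnot(length(fits) > 0)
  est <- do.call(rbind, lapply(fits, function(f) f$theta[names(true_theta)]))
  rows <- lapply(names(true_theta), function(p) {
    e <- est[, p]
    tr <- true_theta[[p]]
    data.frame(
      parameter = p, true = tr, mean_est = mean(e), bias = mean(e) - tr,
      rmse = sqrt(mean((e - tr)^2)),
      sign_rate = if (p %in% c("db", "dv", "dt0") && tr != 0) {
        mean(sign(e) == sign(tr))
      } else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Model-recovery confusion summary
#'
#' Tallies, per criterion, which model class (threshold `B` vs drift `V`)
#' best fits each simulated participant, given the generating model.
#'
#' @param records Output of [selection_records()] for fits of all candidate
#'   models to data from one generating model.
#' @param generating Generating model id.
#' @return Data frame with `criterion`, `generating`, `best_class`,
#'   `n` (tie-split counts).
#' @export
model_recovery_summary <- function(records, generating) {
  rows <- list()
  for (crit in unique(records$criterion)) {
    sub <- records[records$criterion == crit, ]
    tally <- c(B = 0, V = 0)
    for (pid in unique(sub$participant)) {
      p <- sub[sub$participant == pid, ]
      ties <- p$model[p$best]
      for (m in ties) {
        cls <- substr(m, 1, 1)
        tally[cls] <- tally[cls] + 1 / length(ties)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      criterion = crit, generating = generating,
      best_class = names(tally), n = unname(tally),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
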