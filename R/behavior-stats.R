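# Conventional descriptive analysis of the flanker data: trial trimming,
# condition cell means, the CSPC contrast, and context-transition labels.
# Inferential tests (repeated-measures ANOVAs) are deliberately not
# reproduced; the cell means and contrasts they were built on are.

#' Trim trials for conventional behavioral analysis
#'
#' Removes the first trial of each block (identified by its recorded
#' within-block index, so trimming is idempotent), response omissions, and
#' trials with RTs outside `[150, 2000]` ms.  Adds a logical
#' `post_error_correct` column flagging correct trials whose preceding
#' retained trial (same participant and block) was an error; these are
#' excluded from RT means but kept for accuracy.
#'
#' @param trials Data frame with columns `participant`, `block`, `trial`
#'   (within-block index starting at 1), `context`, `congruency`, `correct`
#'   (logical, `NA` = omission), `rt_ms`.
#' @param rt_window Inclusive RT bounds in ms.
#' @return Trimmed data frame with `post_error_correct` added.
#' @export
trim_trials <- function(trials, rt_window = c(150, 2000)) {
  keep <- trials$trial != 1L &
    !is.na(trials$correct) & !is.na(trials$rt_ms) &
    trials$rt_ms >= rt_window[1] & trials$rt_ms <= rt_window[2]
  out <- trials[keep, ]
  out <- out[order(out$participant, out$block, out$trial), ]
  prev_correct <- c(NA, out$correct[-nrow(out)])
  same_run <- c(FALSE,
    out$participant[-1] == out$participant[-nrow(out)] &
      out$block[-1] == out$block[-nrow(out)])
  out$post_error_correct <- out$correct & same_run & !prev_correct
  out$post_error_correct[is.na(out$post_error_correct)] <- FALSE
  out
}

#' Label context transitions
#'
#' Marks each retained trial as a context `"repetition"` or `"switch"`
#' relative to the previous retained trial of the same participant and
#' block; the first retained trial of a block gets `NA`.
#'
#' @param trials Trimmed, ordered trial data frame (see [trim_trials()]).
#' @return The data frame with a `transition` column added.
#' @export
label_transitions <- function(trials) {
  out <- trials[order(trials$participant, trials$block, trials$trial), ]
  n <- nrow(out)
  prev_context <- c(NA, out$context[-n])
  same_run <- c(FALSE,
    out$participant[-1] == out$participant[-n] &
      out$block[-1] == out$block[-n])
  out$transition <- ifelse(!same_run, NA_character_,
    ifelse(out$context == prev_context, "repetition", "switch"))
  out
}

#' Condition cell means
#'
#' Mean correct-trial RT (excluding post-error correct trials), error rate
#' and trial count per context x congruency cell, optionally split further
#' (e.g. by `transition`).
#'
#' @param trials Trimmed data frame from [trim_trials()] (with
#'   `post_error_correct`), optionally piped through [label_transitions()].
#' @param by Extra grouping column names, e.g. `"transition"`.
#' @return Data frame with columns `context`, `congruency`, any `by`
#'   columns, `mean_rt_ms`, `error_pct`, `n`.
#' @export
cell_means <- function(trials, by = character()) {
  stopifnot(all(by %in% names(trials)))
  key_cols <- c("context", "congruency", by)
  keys <- trials[key_cols]
  key <- do.call(paste, c(keys, sep = "\r"))
  drop <- Reduce(`|`, lapply(keys, is.na), FALSE)
  trials <- trials[!drop, ]
  key <- key[!drop]
  rows <- lapply(unique(key), function(k) {
    sub <- trials[key == k, ]
    rt_sub <- sub$rt_ms[sub$correct & !sub$post_error_correct]
    cbind(
      sub[1, key_cols, drop = FALSE],
      data.frame(
        mean_rt_ms = mean(rt_sub),
        error_pct = 100 * mean(!sub$correct),
        n = nrow(sub)
      )
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$context, out$congruency), ]
}

#' Interference (congruency) effect per context
#'
#' Incongruent minus congruent mean RT (ms) and error rate (percentage
#' points) within each context.
#'
#' @param cells Output of [cell_means()] (no extra grouping).
#' @return Data frame with columns `context`, `rt_ms`, `error_pct`.
#' @export
interference_effects <- function(cells) {
  rows <- lapply(unique(cells$context), function(cx) {
    inc <- cells[cells$context == cx & cells$congruency == "inc", ]
    con <- cells[cells$context == cx & cells$congruency == "con", ]
    if (nrow(inc) != 1 || nrow(con) != 1) {
      stop("missing condition cell for context ", cx, call. = FALSE)
    }
    data.frame(context = cx,
      rt_ms = inc$mean_rt_ms - con$mean_rt_ms,
      error_pct = inc$error_pct - con$error_pct)
  })
  do.call(rbind, rows)
}

#' Context-specific proportion congruent (CSPC) contrast
#'
#' Interference in the low-conflict context minus interference in the
#' high-conflict context, for RT (ms) and error rate (percentage points).
#' Positive values are the standard CSPC effect: interference shrinks where
#' conflict is frequent.
#'
#' @param cells Output of [cell_means()] with all four context x
#'   congruency cells.
#' @return Named numeric vector `c(rt_ms = , error_pct = )`.
#' @examples
#' # interference 121 ms (low) vs 88 ms (high) gives a 33 ms CSPC effect
#' @export
cspc_statistic <- function(cells) {
  eff <- interference_effects(cells)
  lo <- eff[eff$context == "low", ]
  hi <- eff[eff$context == "high", ]
  if (nrow(lo) != 1 || nrow(hi) != 1) {
    stop("need both high- and low-conflict contexts", call. = FALSE)
  }
  c(rt_ms = lo$rt_ms - hi$rt_ms, error_pct = lo$error_pct - hi$error_pct)
}
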