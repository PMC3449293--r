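# Shared fixtures: random-but-valid parameter draws on the scale of the
# group-average fits, and small simulated cohorts.

random_accumulator <- function() {
  A <- runif(1, 0.05, 0.3)
  lba_accumulator(
    b = A + runif(1, 0.05, 0.4),
    A = A,
    v = runif(1, 0.5, 0.9),
    s = runif(1, 0.1, 0.25)
  )
}

random_race <- function() {
  A <- runif(1, 0.05, 0.3)
  d <- runif(1, 0.1, 0.4)
  v <- runif(1, 0.55, 0.85)
  s <- runif(1, 0.12, 0.22)
  lba_race(
    correct = lba_accumulator(b = A + d, A = A, v = v, s = s),
    error = lba_accumulator(b = A + d, A = A, v = 1 - v, s = s),
    t0 = runif(1, 0.1, 0.3)
  )
}

random_theta <- function(model_id) {
  nm <- model_param_names(model_id)
  th <- vapply(nm, function(p) {
    if (p == "s") runif(1, 0.1, 0.25)
    else if (p == "A") runif(1, 0.05, 0.3)
    else if (p == "d" || startsWith(p, "d_")) runif(1, 0.15, 0.45)
    else if (startsWith(p, "v")) runif(1, 0.55, 0.85)
    else if (p %in% c("db", "dv", "dt0")) runif(1, -0.03, 0.03)
    else if (startsWith(p, "t0")) runif(1, 0.1, 0.3)
    else stop("unhandled ", p)
  }, numeric(1))
  names(th) <- nm
  th
}

# reduced optimizer budget for simulation studies in the tests; the local
# polish recovers the optimum from the swarm's basin
test_fit_config <- function(seed = 1L) {
  fit_config(swarm = 24L, iterations = 80L, restarts = 2L, seed = seed)
}

tiny_trials <- function(n = 40, seed = 1) {
  set.seed(seed)
  race <- build_condition_params("B2", reference_theta("B2", "I"))
  conds <- sample(names(race), n, replace = TRUE)
  do.call(rbind, lapply(seq_len(n), function(i) {
    sim <- lba_simulate(1, race[[conds[i]]])
    data.frame(condition = conds[i], correct = sim$correct, rt = sim$rt)
  }))
}
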