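# Maximum-likelihood machinery: data preparation, the particle-swarm
# objective, determinism, and a small-scale recovery sanity check.

test_that("omissions are removed and RTs converted to seconds", {
  set.seed(41)
  raw <- data.frame(
    context = sample(c("high", "low"), 448, TRUE),
    congruency = sample(c("con", "inc"), 448, TRUE),
    correct = TRUE, rt_ms = runif(448, 300, 900)
  )
  om <- sample(448, 3)
  raw$correct[om] <- NA
  raw$rt_ms[om] <- NA
  prep <- prepare_fit_data(raw)
  expect_equal(nrow(prep), 445)
  expect_true(all(prep$rt < 2))
  expect_setequal(unique(prep$condition),
    c("con_low", "inc_low", "con_high", "inc_high"))

  clean <- raw[-om, ]
  expect_equal(nrow(prepare_fit_data(clean)), 445)
  all_om <- raw
  all_om$correct <- NA
  all_om$rt_ms <- NA
  expect_error(prepare_fit_data(all_om), "no valid trials")
})

test_that("objective is finite everywhere inside the box bounds", {
  prep <- tiny_trials(60, seed = 2)
  groups <- cspclba:::.ll_groups(prep)
  obj <- cspclba:::.make_objective(groups, "B2", "verbal")
  nm <- model_param_names("B2")
  bounds <- model_param_bounds("B2", rt_min = min(prep$rt))
  set.seed(6)
  for (i in 1:200) {
    x <- runif(length(nm), bounds$lower, bounds$upper)
    val <- obj(x, nm)
    expect_true(is.finite(val))
  }
})

test_that("optimizer fast path agrees with the reference likelihood", {
  prep <- tiny_trials(120, seed = 8)
  groups <- cspclba:::.ll_groups(prep)
  set.seed(19)
  for (m in model_ids(extensions = TRUE)) {
    obj <- cspclba:::.make_objective(groups, m, "verbal")
    nm <- model_param_names(m)
    for (i in 1:10) {
      th <- random_theta(m)
      expect_equal(obj(unname(th[nm]), nm),
        lba_log_likelihood(prep, build_condition_params(m, th)),
        tolerance = 1e-10)
    }
  }
})

test_that("refitting with the same seed reproduces the result exactly", {
  prep <- tiny_trials(80, seed = 3)
  cfg <- fit_config(swarm = 10, iterations = 20, restarts = 1, seed = 9)
  f1 <- fit_participant(prep, "V2", cfg)
  f2 <- fit_participant(prep, "V2", cfg)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("best-so-far objective is monotone and grows with the budget", {
  prep <- tiny_trials(80, seed = 4)
  short <- fit_participant(prep, "B2",
    fit_config(swarm = 12, iterations = 25, restarts = 1, polish = FALSE,
      seed = 10))
  long <- fit_participant(prep, "B2",
    fit_config(swarm = 12, iterations = 60, restarts = 1, polish = FALSE,
      seed = 10))
  tr_s <- short$convergence$best_so_far
  tr_l <- long$convergence$best_so_far
  expect_true(all(diff(tr_s) >= 0))
  expect_true(all(diff(tr_l) >= 0))
  # same seed: the longer run extends the same trajectory
  expect_gte(tr_l[60], tr_s[25])
})

test_that("reported criteria are consistent with the reported likelihood", {
  prep <- tiny_trials(80, seed = 5)
  f <- fit_participant(prep, "V2",
    fit_config(swarm = 10, iterations = 20, restarts = 1, seed = 2))
  expect_equal(f$AIC, 2 * f$k - 2 * f$loglik)
  expect_equal(f$BIC, f$k * log(f$n) - 2 * f$loglik)
  expect_equal(f$loglik,
    lba_log_likelihood(prep, build_condition_params("V2", f$theta)))
  expect_equal(f$n, nrow(prep))
})

test_that("fitting recovers generating drift rates on simulated data", {
  # scaled-down recovery: 3 simulated participants, reduced swarm budget
  th <- reference_theta("B2", "I")
  cfg <- test_fit_config()
  errs <- sapply(1:3, function(i) {
    coh <- simulate_participants("B2", th, 1, seed = 300 + i)
    prep <- prepare_fit_data(coh$trials[[1]])
    c2 <- cfg
    c2$seed <- i
    f <- fit_participant(prep, "B2", c2)
    gen_ll <- lba_log_likelihood(prep, build_condition_params("B2", th))
    c(e_con = abs(f$theta[["v_con"]] - th[["v_con"]]),
      e_inc = abs(f$theta[["v_inc"]] - th[["v_inc"]]),
      gap = f$loglik - gen_ll)
  })
  # the optimum must not fall meaningfully below the generating parameters
  expect_true(all(errs["gap", ] >= -1))
  expect_lt(median(errs[c("e_con", "e_inc"), ]), 0.1)
})

test_that("optimizer configuration round-trips through a text file", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c(
    "# demo optimizer settings",
    "swarm = 12",
    "iterations = 30",
    "restarts = 1",
    "polish = TRUE",
    "seed = 42"
  ), path)
  cfg <- read_fit_config(path)
  expect_identical(cfg$swarm, 12L)
  expect_identical(cfg$iterations, 30L)
  expect_identical(cfg$seed, 42L)
  expect_true(cfg$polish)
  expect_equal(cfg$inertia, 0.72)
})

test_that("cohort fitting tolerates per-participant failures", {
  th <- reference_theta("B2", "I")
  coh <- simulate_participants("B2", th, 1, seed = 55)
  broken <- coh$trials[[1]]
  broken$correct <- NA
  broken$rt_ms <- NA
  cohort <- list(ok = coh$trials[[1]], broken = broken)
  res <- fit_cohort(cohort, models = "V2",
    fit_config(swarm = 8, iterations = 10, restarts = 1, seed = 1))
  expect_equal(nrow(res$table), 1)
  expect_length(res$failures, 1)
  expect_match(res$failures, "broken")
})
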