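# Closed-form LBA distribution functions against independent oracles:
# Monte-Carlo simulation, quadrature, and finite differences.

test_that("constructor rejects invalid accumulator parameters", {
  expect_error(lba_accumulator(b = 0.1, A = 0.2, v = 0.5, s = 0.1), "b must be >= A")
  expect_error(lba_accumulator(b = 0.5, A = 0.2, v = 0.5, s = 0), "s must be > 0")
  expect_error(lba_accumulator(b = 0.5, A = -0.1, v = 0.5, s = 0.1), ">= 0")
  expect_error(lba_race(lba_accumulator(0.5, 0.2, 0.7, 0.2),
    lba_accumulator(0.5, 0.2, 0.3, 0.2), t0 = -1), "t0")
})

test_that("crossing CDF is 0 at t <= 0 and has the degenerate-A limit", {
  acc <- lba_accumulator(b = 0.48, A = 0.14, v = 0.64, s = 0.18)
  expect_identical(lba_cdf(c(-1, 0), acc), c(0, 0))
  # with A ~ 0 the crossing time is b / drift: at t = b / v the CDF is 1/2
  acc0 <- lba_accumulator(b = 0.48, A = 1e-9, v = 0.75, s = 0.15)
  expect_equal(lba_cdf(0.64, acc0), 0.5, tolerance = 1e-9)
  expect_equal(lba_cdf(0.64, acc0), pnorm((0.75 - 0.48 / 0.64) / 0.15),
    tolerance = 1e-9)
})

test_that("crossing CDF matches Monte-Carlo start-point/drift simulation", {
  # group-average threshold-model parameters, data set I scale
  b <- 0.43; A <- 0.17; v <- 0.78; s <- 0.19; t <- 0.5
  acc <- lba_accumulator(b = b, A = A, v = v, s = s)
  set.seed(42)
  m <- 1e6
  start <- runif(m, 0, A)
  drift <- rnorm(m, v, s)
  hit <- ifelse(drift > 0, (b - start) / drift, Inf)
  p_mc <- mean(hit <= t)
  se <- sqrt(p_mc * (1 - p_mc) / m)
  expect_lt(abs(lba_cdf(t, acc) - p_mc), 3 * se)
})

test_that("crossing density integrates to the CDF and differentiates it", {
  acc <- lba_accumulator(b = 0.48, A = 0.14, v = 0.64, s = 0.18)
  # quadrature over (0, 5] vs closed-form CDF
  grid <- seq(1e-6, 5, length.out = 20001)
  f <- lba_pdf(grid, acc)
  trap <- sum((f[-1] + f[-length(f)]) / 2 * diff(grid))
  expect_lt(abs(trap - lba_cdf(5, acc)), 1e-4)
  # central finite difference of the CDF at t = 0.6
  h <- 1e-5
  fd <- (lba_cdf(0.6 + h, acc) - lba_cdf(0.6 - h, acc)) / (2 * h)
  expect_lt(abs(fd - lba_pdf(0.6, acc)), 1e-5)
})

test_that("CDF is nondecreasing and within [0, 1]; density is nonnegative", {
  set.seed(7)
  grid <- seq(0.01, 6, length.out = 400)
  for (i in 1:100) {
    acc <- random_accumulator()
    p <- lba_cdf(grid, acc)
    expect_true(all(diff(p) >= -1e-12))
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(lba_pdf(grid, acc) >= 0))
  }
})

test_that("degenerate-A branch continues the general formula", {
  set.seed(8)
  grid <- c(0.2, 0.5, 0.8, 1.5, 3)
  for (i in 1:20) {
    b <- runif(1, 0.2, 0.6); v <- runif(1, 0.4, 0.9); s <- runif(1, 0.1, 0.25)
    gen <- lba_accumulator(b = b, A = 1e-7, v = v, s = s)   # general branch
    lim <- lba_accumulator(b = b, A = 1e-9, v = v, s = s)   # limiting branch
    expect_lt(max(abs(lba_cdf(grid, gen) - lba_cdf(grid, lim))), 1e-6)
    expect_lt(max(abs(lba_pdf(grid, gen) - lba_pdf(grid, lim))), 1e-4)
    # the limit itself is the degenerate-start-point crossing law
    expect_equal(lba_cdf(grid, lim), pnorm((v - b / grid) / s),
      tolerance = 1e-9)
  }
})

test_that("defective density is zero before t0 and integrates to response probabilities", {
  th <- reference_theta("B2", "I")
  race <- build_condition_params("B2", th)$con_low
  expect_identical(
    lba_defective_density(c(0.05, race$t0), "correct", race), c(0, 0))
  p <- lba_response_prob(race)
  # Monte-Carlo race oracle
  set.seed(99)
  sim <- lba_simulate(1e6, race)
  p_mc <- mean(sim$correct)
  se <- sqrt(p_mc * (1 - p_mc) / 1e6)
  # simulator renormalizes the (tiny) both-negative-drift event
  expect_lt(abs(p[["correct"]] / sum(p) - p_mc), 3 * se)
  # both choices jointly integrate to P(at least one positive drift draw)
  p_any <- 1 - pnorm(-race$correct$v / race$correct$s) *
    pnorm(-race$error$v / race$error$s)
  expect_lt(abs(sum(p) - p_any), 1e-3)
})

test_that("symmetric accumulators give equal response probabilities", {
  acc <- lba_accumulator(b = 0.45, A = 0.15, v = 0.5, s = 0.18)
  race <- lba_race(acc, acc, t0 = 0.2)
  p <- lba_response_prob(race)
  expect_equal(p[["correct"]], p[["error"]], tolerance = 1e-6)
})

test_that("log-likelihood matches its definition and handles edge cases", {
  races <- build_condition_params("B2", reference_theta("B2", "I"))
  empty <- data.frame(condition = character(), correct = logical(),
    rt = numeric())
  expect_identical(lba_log_likelihood(empty, races), 0)
  one <- data.frame(condition = "inc_high", correct = FALSE, rt = 0.8)
  expect_equal(lba_log_likelihood(one, races),
    log(lba_defective_density(0.8, "error", races$inc_high)))
  bad <- data.frame(condition = "nope", correct = TRUE, rt = 0.5)
  expect_error(lba_log_likelihood(bad, races), "no race parameters")
})

test_that("generating parameters beat perturbed ones in likelihood", {
  th <- reference_theta("B2", "I")
  races <- build_condition_params("B2", th)
  th_shift <- th
  th_shift[["v_con"]] <- th[["v_con"]] - 0.3
  th_shift[["v_inc"]] <- th[["v_inc"]] - 0.3
  races_shift <- build_condition_params("B2", th_shift)
  set.seed(123)
  wins <- 0
  for (r in 1:100) {
    conds <- sample(names(races), 100, replace = TRUE)
    trials <- do.call(rbind, lapply(unique(conds), function(cl) {
      sim <- lba_simulate(sum(conds == cl), races[[cl]])
      data.frame(condition = cl, correct = sim$correct, rt = sim$rt)
    }))
    if (lba_log_likelihood(trials, races) >
        lba_log_likelihood(trials, races_shift)) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("simulator is reproducible and respects the deterministic limit", {
  fast <- lba_race(
    lba_accumulator(b = 0.5, A = 1e-12, v = 1, s = 1e-6),
    lba_accumulator(b = 0.5, A = 1e-12, v = 0.01, s = 1e-6),
    t0 = 0.2
  )
  set.seed(3)
  sim <- lba_simulate(50, fast)
  expect_true(all(sim$correct))
  expect_equal(sim$rt, rep(0.7, 50), tolerance = 1e-3)

  race <- random_race()
  set.seed(11); a <- lba_simulate(1000, race)
  set.seed(11); b <- lba_simulate(1000, race)
  expect_identical(a, b)
  expect_true(all(a$rt > race$t0))
})

test_that("simulated RTs follow the closed-form race CDF", {
  set.seed(21)
  for (i in 1:3) {
    race <- random_race()
    sim <- lba_simulate(1e5, race)
    p_renorm <- 1 - pnorm(-race$correct$v / race$correct$s) *
      pnorm(-race$error$v / race$error$s)
    ks <- max(abs(ecdf(sim$rt)(sim$rt) - lba_race_cdf(sim$rt, race) / p_renorm))
    expect_lt(ks, 0.01)
  }
})
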