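# Information-criterion arithmetic, weights, evidence ratios, and the
# distribution summaries used for fit display.

test_that("AIC/BIC formulas and their penalty relation", {
  ic <- information_criteria(-100, k = 8, n = 445)
  expect_equal(ic[["AIC"]], 216)
  expect_equal(ic[["BIC"]], 8 * log(445) + 200)
  expect_equal(ic[["BIC"]] - ic[["AIC"]], 8 * (log(445) - 2))
  # no complexity penalty at k = 0
  ic0 <- information_criteria(-100, k = 0, n = 445)
  expect_equal(unname(ic0), c(200, 200))
  # BIC penalizes more exactly when log(N) > 2
  expect_gt(information_criteria(0, 1, 8)[["BIC"]],
    information_criteria(0, 1, 8)[["AIC"]])
  expect_lt(information_criteria(0, 1, 7)[["BIC"]],
    information_criteria(0, 1, 7)[["AIC"]])
})

test_that("IC weights normalize, respect the closed form, and shift-invariance", {
  expect_equal(unname(ic_weights(c(5, 5, 5, 5))), rep(0.25, 4))
  w <- ic_weights(c(0, 2))
  expect_equal(unname(w), c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  ic <- c(V1 = 210.3, V2 = 204.9, B1 = 208.2, B2 = 203.1)
  expect_equal(ic_weights(ic), ic_weights(ic + 1000), tolerance = 1e-12)
  expect_equal(sum(ic_weights(ic)), 1, tolerance = 1e-12)
})

test_that("threshold-vs-drift ratio reproduces published cells", {
  # data set I weights
  expect_equal(b_vs_v_ratio(c(V1 = 0.059, V2 = 0.106, B1 = 0.412, B2 = 0.422)),
    5.06, tolerance = 0.002)
  expect_equal(b_vs_v_ratio(c(V1 = 0.027, V2 = 0.313, B1 = 0.123, B2 = 0.537)),
    1.94, tolerance = 0.002)
  expect_equal(b_vs_v_ratio(c(V1 = 0.25, V2 = 0.25, B1 = 0.25, B2 = 0.25)), 1)
  expect_warning(r <- b_vs_v_ratio(c(V1 = 0, V2 = 0, B1 = 0.6, B2 = 0.4)),
    "undefined")
  expect_true(is.nan(r))
})

test_that("selection records have unit weight mass and a zero-delta best model", {
  set.seed(12)
  fits <- expand.grid(participant = paste0("P", 1:6),
    model = c("V1", "V2", "B1", "B2"), stringsAsFactors = FALSE)
  fits$AIC <- rnorm(nrow(fits), 200, 10)
  fits$BIC <- fits$AIC + 5
  rec <- selection_records(fits)
  for (crit in c("AIC", "BIC")) {
    for (p in unique(rec$participant)) {
      sub <- rec[rec$criterion == crit & rec$participant == p, ]
      expect_equal(sum(sub$weight), 1, tolerance = 1e-12)
      expect_equal(min(sub$delta), 0)
      expect_true(all(sub$delta[sub$best] == 0))
    }
  }
})

test_that("pooled best-fit percentages match published count arithmetic", {
  expect_equal(pooled_best_fit_pct(c(8, 9, 12, 8), 87), 42.5, tolerance = 0.05)
  expect_equal(pooled_best_fit_pct(c(14, 10, 8, 9), 87), 47.1, tolerance = 0.05)
  # degenerate: everyone best fit by one model
  fits <- data.frame(
    participant = rep(paste0("P", 1:5), each = 2),
    model = rep(c("V2", "B2"), 5),
    AIC = rep(c(210, 200), 5), BIC = rep(c(210, 200), 5)
  )
  agg <- aggregate_best_fit(selection_records(fits))
  b2 <- agg$pooled[agg$pooled$model == "B2" & agg$pooled$criterion == "AIC", ]
  expect_equal(b2$pct, 100)
})

test_that("best-model ties are split equally across tied models", {
  fits <- data.frame(
    participant = "P1", model = c("V1", "V2", "B1", "B2"),
    AIC = c(210, 200, 200, 220), BIC = c(210, 200, 200, 220)
  )
  agg <- aggregate_best_fit(selection_records(fits))
  pooled <- agg$pooled[agg$pooled$criterion == "AIC", ]
  expect_equal(pooled$count[pooled$model == "V2"], 0.5)
  expect_equal(pooled$count[pooled$model == "B1"], 0.5)
})

test_that("defective quantile summary scales heights by response proportion", {
  rt <- seq(400, 800, length.out = 100)
  qs <- quantile_summary(rt, rep(TRUE, 100))
  cor <- qs[qs$class == "correct", ]
  expect_equal(cor$cum_height, c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_equal(qs[qs$class == "error", "n"], rep(0L, 5))
  # 80% correct: heights shrink accordingly
  qs2 <- quantile_summary(c(rt, seq(300, 900, length.out = 25)),
    rep(c(TRUE, FALSE), c(100, 25)))
  expect_equal(qs2$cum_height[qs2$class == "correct"],
    c(0.08, 0.24, 0.40, 0.56, 0.72))
  # small error cell flagged but kept
  qs3 <- quantile_summary(c(rt, 500, 600), rep(c(TRUE, FALSE), c(100, 2)))
  err <- qs3[qs3$class == "error", ]
  expect_false(any(err$reliable))
  expect_true(all(is.finite(err$rt_q)))
})

test_that("model-predicted quantiles agree with large-sample simulation", {
  race <- build_condition_params("B2", reference_theta("B2", "I"))$inc_low
  pq <- predicted_quantiles(race)
  set.seed(77)
  sim <- lba_simulate(1e5, race)
  emp <- quantile(sim$rt[sim$correct], c(0.1, 0.3, 0.5, 0.7, 0.9))
  pred <- pq$rt_q[pq$class == "correct"]
  expect_lt(max(abs(pred - emp)), 0.005)  # within 5 ms
})

test_that("predicted moments match simulation and order with threshold", {
  races <- build_condition_params("B2", reference_theta("B2", "I"))
  mom <- predicted_moments(races["con_low"])
  set.seed(13)
  sim <- lba_simulate(1e6, races$con_low)
  expect_lt(abs(mom$mean_rt - mean(sim$rt)), 0.002)  # within 2 ms
  expect_lt(abs(mom$p_correct - mean(sim$correct)), 3 * sqrt(0.03 / 1e6) + 1e-3)

  # shared parameters -> identical predictions
  same <- predicted_moments(list(a = races$con_low, b = races$con_low))
  expect_equal(same$mean_rt[1], same$mean_rt[2])

  # raising b slows responses and raises accuracy (speed-accuracy tradeoff)
  lo <- races$con_low
  hi <- lba_race(
    lba_accumulator(lo$correct$b + 0.1, lo$correct$A, lo$correct$v, lo$correct$s),
    lba_accumulator(lo$error$b + 0.1, lo$error$A, lo$error$v, lo$error$s),
    t0 = lo$t0
  )
  m2 <- predicted_moments(list(lo = lo, hi = hi))
  expect_gt(m2$mean_rt[2], m2$mean_rt[1])
  expect_gt(m2$p_correct[2], m2$p_correct[1])
})
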