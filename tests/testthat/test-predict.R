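# a small fitted model shared across prediction tests
pred_fit <- local({
  cfg <- small_sim(seed = 21, n_vessels = 30, years = 2010:2012, days = 30,
    em_fraction = 0.5
  )
  eff <- generate_fleet_effort(cfg)
  em <- simulate_bycatch(eff, true_params(), seed = 22)
  list(
    fit = suppressWarnings(fit_bycatch_glmm(em, bycatch_model_spec(random = "year"))),
    eff = eff, em = em
  )
})

test_that("per-row predictions honour the link and the latent modes", {
  fit <- pred_fit$fit
  em <- pred_fit$em
  mu <- predict_bycatch(fit, em)
  comp <- linkscale_components(fit, em)
  expect_equal(log(mu), comp$eta_total, ignore_attr = TRUE)
  # reference row with no latent contribution gives exp(intercept)
  ref <- toy_rows(1)
  ref$soak_time_h <- 1
  ref$net_length_m <- 1
  ref$depth_m <- 1
  ref$year <- 1999L # unseen year level
  mu_ref <- predict_bycatch(fit, ref, re_mode = "marginal")
  sig_y <- fit$sigma[["year"]]
  s_new <- sig_y^2 + fit$sigma_s^2 # year and spatial group both unseen
  expect_equal(
    unname(mu_ref), exp(unname(coef(fit)[1]) + 0.5 * s_new)
  )
  # conditional prediction refuses unseen levels
  expect_error(predict_bycatch(fit, ref), "unseen")
  # unseen fixed-effect level is an error in both modes
  bad <- pred_fit$em[1, ]
  bad$mesh_class <- "tiny"
  expect_error(predict_bycatch(fit, bad, re_mode = "marginal"), "tiny")
})

test_that("bias-corrected totals match a Monte-Carlo oracle on a toy posterior", {
  # three rows sharing one Gaussian latent: T = sum_i exp(eta_i + s_i/2)
  eta <- c(-1.2, -0.7, -2.0)
  u_hat <- 0.35
  q_var <- 0.2^2
  t_cf <- sum(exp(eta + u_hat + q_var / 2))
  set.seed(99)
  draws <- rnorm(1e6, u_hat, sqrt(q_var))
  t_mc <- mean(colSums(exp(outer(eta, draws, "+"))))
  expect_equal(t_cf, t_mc, tolerance = 0.01)

  # and through the fitted-model path: aggregate >= plugin, groups add up
  fit <- pred_fit$fit
  eff <- pred_fit$eff
  agg <- aggregate_bycatch(fit, eff, grouping = "year")
  expect_true(all(agg$t_hat >= agg$plugin))
  grand <- aggregate_bycatch(fit, eff, grouping = character(0))
  expect_equal(sum(agg$t_hat), grand$t_hat)
  expect_equal(sum(agg$plugin), grand$plugin)
  # per-row correction factor for an unseen level is exp(sigma^2/2)
  new_row <- pred_fit$em[1, ]
  new_row$year <- 1998L
  a1 <- aggregate_bycatch(fit, new_row, grouping = character(0))
  s_new <- fit$sigma[["year"]]^2 + fit$sigma_s^2
  expect_equal(a1$t_hat / a1$plugin, exp(s_new / 2))
})

test_that("plugin equals bias-corrected when there are no random effects", {
  em <- small_em(seed = 41, n_vessels = 12, years = 2010, days = 25)
  fit0 <- fit_bycatch_glmm(
    em, bycatch_model_spec(random = character(0), spatial_grouping = "none")
  )
  agg <- aggregate_bycatch(fit0, em, grouping = character(0))
  expect_equal(agg$t_hat, agg$plugin)
  expect_equal(agg$t_hat, sum(exp(drop(fit0$design$X %*% coef(fit0)))))
})

test_that("parametric bootstrap intervals are deterministic and calibrated-shaped", {
  fit <- pred_fit$fit
  eff <- pred_fit$eff
  b1 <- bootstrap_prediction_ci(fit, eff, grouping = "year", B = 200, seed = 5)
  b2 <- bootstrap_prediction_ci(fit, eff, grouping = "year", B = 200, seed = 5)
  expect_equal(b1$ci_low, b2$ci_low)
  expect_equal(b1$ci_high, b2$ci_high)
  expect_true(all(b1$ci_low <= b1$t_hat & b1$t_hat <= b1$ci_high))
  # interval width shrinks towards zero as the joint precision grows
  fit_tight <- fit
  fit_tight$state$w <- fit$state$w * 1e6
  fit_tight$state$H <- fit$state$H * 1e6
  fit_tight$state$chol <- Matrix::update(fit$state$chol, fit_tight$state$H)
  b3 <- bootstrap_prediction_ci(fit_tight, eff, grouping = "year",
    B = 200, seed = 5
  )
  expect_lt(
    max((b3$ci_high - b3$ci_low) / b3$t_hat), 0.01
  )
})

test_that("standardization splits the predictor and keeps the product identity", {
  fit <- pred_fit$fit
  eff <- pred_fit$eff
  comp <- linkscale_components(fit, eff)
  # per-row product identity on the link scale, at machine precision
  expect_equal(comp$eta_effort + comp$eta_porpoise, comp$eta_total)
  se <- standardized_effort(fit, eff, by = "year")
  sb <- standardized_bpue(fit, eff, by = "year")
  # doubling the fleet doubles the standardized-effort index exactly
  se2 <- standardized_effort(fit, rbind(eff, eff), by = "year",
    constant = se$constant[1]
  )
  expect_equal(se2$value, 2 * se$value)
  # identical effort rows across years give identical index values
  flat <- toy_rows(40, year = rep(c(2010L, 2011L), each = 20))
  sef <- standardized_effort(fit, flat, by = "year", constant = 0)
  expect_equal(sef$value[1], sef$value[2])
  # the index is invariant (up to a common factor) to the frozen constant
  sb2 <- standardized_bpue(fit, eff, by = "year", constant = 1)
  expect_equal(
    sb2$value / sb$value,
    rep(exp(1 - sb$constant[1]), nrow(sb))
  )
  # hand computation on a 4-row table
  hand <- toy_rows(4, year = rep(c(2010L, 2011L), each = 2))
  hand$soak_time_h <- c(10, 20, 30, 40)
  seh <- standardized_effort(fit, hand, by = "year", constant = 0)
  colt <- attr(pred_fit$fit$design$X, "assign_terms")
  grouping <- default_term_grouping()
  Xh <- embycatch:::.fixed_design_matrix(hand, fit$spec$fixed)
  keep <- attr(Xh, "assign_terms") %in% grouping$effort
  eta_h <- drop(Xh[, keep] %*% coef(fit)[keep])
  expect_equal(
    seh$value[2] / seh$value[1],
    sum(exp(eta_h[3:4])) / sum(exp(eta_h[1:2]))
  )
})

test_that("pinger scenarios never increase bycatch and subtract exactly", {
  fit <- pred_fit$fit
  eff <- pred_fit$eff
  ps <- suppressMessages(
    pinger_scenarios(fit, eff, default_pinger_rules(), grouping = "year")
  )
  wide <- split(ps$t_hat, ps$scenario)
  expect_true(all(wide$pinger_removed <= wide$all_effort + 1e-9))
  # empty rules: identical scenarios
  ps0 <- pinger_scenarios(fit, eff, NULL, grouping = "year")
  w0 <- split(ps0$t_hat, ps0$scenario)
  expect_equal(w0$pinger_removed, w0$all_effort)
  # monotonicity across random rule sets
  set.seed(77)
  for (i in 1:25) {
    rules <- tibble::tibble(
      ices_area = sample(c("IVb", "IIIa20", "IIIa21", "IIIc22", "IIIb23"), 2),
      vessel_classes = sample(
        c("*", ">15 m", "<8 m;8-10 m", "10-12 m;12-15 m"), 2, TRUE
      ),
      mesh_classes = sample(c("*", "<120 mm", "120-200;>200 mm"), 2, TRUE),
      quarters = sample(c("*", "1;2", "3", "2;3;4"), 2, TRUE)
    )
    psi <- suppressMessages(
      pinger_scenarios(fit, eff, rules, grouping = character(0))
    )
    wi <- split(psi$t_hat, psi$scenario)
    expect_lte(wi$pinger_removed, wi$all_effort + 1e-9)
  }
  # a rule removing one whole stratum subtracts that stratum's total
  rules1 <- tibble::tibble(
    ices_area = "IVb", vessel_classes = "*", mesh_classes = "*", quarters = "*"
  )
  agg_area <- aggregate_bycatch(fit, eff, grouping = "ices_area")
  psa <- suppressMessages(
    pinger_scenarios(fit, eff, rules1, grouping = character(0))
  )
  wa <- split(psa$t_hat, psa$scenario)
  expect_equal(
    unname(wa$all_effort - wa$pinger_removed),
    agg_area$t_hat[agg_area$ices_area == "IVb"]
  )
})
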