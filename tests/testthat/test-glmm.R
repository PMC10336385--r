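test_that("design matrices use fixed treatment coding and log transforms", {
  em <- small_em(seed = 2, n_vessels = 12, years = 2010:2011, days = 15)
  d <- build_design(em, bycatch_model_spec())
  X <- d$X
  expect_equal(sum(attr(X, "assign_terms") == "mesh_class"), 2)
  expect_equal(sum(attr(X, "assign_terms") == "vessel_class"), 4)
  expect_equal(X[, "log_soak_time"], log(em$soak_time_h), ignore_attr = TRUE)
  # interaction columns are contrast x log-soak, column by column
  m2 <- as.numeric(em$mesh_class == "120-200")
  m3 <- as.numeric(em$mesh_class == ">200 mm")
  expect_equal(X[, "mesh_class120-200:log_soak_time"],
    m2 * log(em$soak_time_h),
    ignore_attr = TRUE
  )
  expect_equal(X[, "mesh_class>200 mm:log_soak_time"],
    m3 * log(em$soak_time_h),
    ignore_attr = TRUE
  )
  expect_equal(unname(X[1, "(Intercept)"]), 1)
  # zero soak is rejected (log undefined)
  em2 <- em
  em2$soak_time_h[1] <- 0
  expect_error(build_design(em2, bycatch_model_spec()), "soak_time_h")
  # interaction requires both mains
  expect_error(
    bycatch_model_spec(fixed = c("mesh_class", "mesh_class:log_soak_time")),
    "main effects"
  )
})

test_that("nb2_loglik matches special cases and an independent pmf", {
  expect_equal(nb2_loglik(0, 1, 1), log(0.5))
  # Poisson limit
  y <- 0:10
  expect_equal(nb2_loglik(y, 2, 1e9), sum(dpois(y, 2, log = TRUE)),
    tolerance = 1e-5
  )
  # log-gamma identity, written out independently of dnbinom
  nb_manual <- function(y, mu, th) {
    sum(lgamma(y + th) - lgamma(th) - lfactorial(y) +
      th * log(th / (th + mu)) + y * log(mu / (th + mu)))
  }
  for (case in list(
    list(y = c(0L, 3L, 7L), mu = 1.7, th = 0.6),
    list(y = c(2L, 2L, 0L), mu = 0.3, th = 3.2),
    list(y = 11L, mu = 8.5, th = 1.1)
  )) {
    expect_equal(
      nb2_loglik(case$y, case$mu, case$th),
      nb_manual(case$y, case$mu, case$th)
    )
  }
  expect_error(nb2_loglik(0.5, 1, 1), "integer")
  expect_error(nb2_loglik(1, -1, 1), "mu")
  expect_error(nb2_loglik(1, 1, 0), "theta")
})

test_that("laplace_nll reduces to the fixed-effects likelihood without latents", {
  em <- small_em(seed = 3, n_vessels = 10, years = 2010, days = 20)
  d <- build_design(
    em, bycatch_model_spec(random = character(0), spatial_grouping = "none")
  )
  b <- c(-2.5, rep(0.1, d$p - 1))
  v <- laplace_nll(d, b, 0.9)
  expect_equal(
    as.numeric(v),
    -nb2_loglik(em$bycatch_count, exp(drop(d$X %*% b)), 0.9)
  )
  # zero variance components drop the corresponding blocks exactly
  d2 <- build_design(
    em, bycatch_model_spec(random = "year", spatial_grouping = "none")
  )
  v2 <- laplace_nll(d2, b, 0.9, sigma = c(year = 0))
  expect_equal(as.numeric(v2), as.numeric(v))
})

test_that("laplace is exact for the Gaussian toy family", {
  set.seed(42)
  n <- 60
  toy <- toy_rows(n, year = sample(2010:2014, n, TRUE))
  toy$soak_time_h <- rlnorm(n, 3, 0.3)
  toy$response <- rnorm(n)
  sp <- bycatch_model_spec(
    fixed = "log_soak_time", random = "year",
    spatial_grouping = "none", family = "gaussian"
  )
  d <- build_design(toy, sp)
  beta <- c(0.3, -0.1)
  sd_e <- 0.8
  sig <- 0.5
  v <- laplace_nll(d, beta, sd_e, sigma = c(year = sig))
  Z <- t(as.matrix(d$Zt))
  V <- diag(sd_e^2, n) + sig^2 * tcrossprod(Z)
  r <- toy$response - drop(d$X %*% beta)
  ll <- -0.5 * (n * log(2 * pi) + as.numeric(determinant(V)$modulus) +
    drop(r %*% solve(V, r)))
  expect_equal(as.numeric(v), -ll, tolerance = 1e-9)
})

test_that("laplace matches 1-D quadrature for a one-intercept count toy", {
  set.seed(9)
  n <- 20
  toy <- toy_rows(n, year = rep(2010:2011, each = 10))
  toy$soak_time_h <- rlnorm(n, 3, 0.3)
  mu0 <- 150
  th <- 30
  sg <- 0.4
  toy$bycatch_count <- rnbinom(n, mu = mu0, size = th)
  sp <- bycatch_model_spec(
    fixed = "log_soak_time", random = "year", spatial_grouping = "none"
  )
  d <- build_design(toy, sp)
  beta <- c(log(mu0), 0)
  v <- laplace_nll(d, beta, th, sigma = c(year = sg))
  # oracle: per-group 1-D integral on a fine grid with log-sum-exp
  eta0 <- drop(d$X %*% beta)
  ll <- 0
  for (g in unique(toy$year)) {
    sel <- toy$year == g
    logpost <- function(u) {
      vapply(u, function(ui) {
        sum(dnbinom(toy$bycatch_count[sel],
          size = th,
          mu = exp(eta0[sel] + ui), log = TRUE
        )) + dnorm(ui, 0, sg, log = TRUE)
      }, numeric(1))
    }
    coarse <- seq(-4, 4, length.out = 2001)
    m0 <- coarse[which.max(logpost(coarse))]
    grid <- seq(m0 - 2, m0 + 2, length.out = 40001)
    lv <- logpost(grid)
    M <- max(lv)
    ll <- ll + M + log(sum(exp(lv - M)) * (grid[2] - grid[1]))
  }
  expect_equal(as.numeric(v), -ll, tolerance = 1e-3)
})

test_that("fit without random terms matches an independent NB GLM", {
  skip_if_not_installed("MASS")
  em <- small_em(seed = 13, n_vessels = 20, years = 2010:2011, days = 30)
  fit <- fit_bycatch_glmm(
    em, bycatch_model_spec(random = character(0), spatial_grouping = "none")
  )
  df <- data.frame(
    y = em$bycatch_count,
    mesh = factor(em$mesh_class, c("<120 mm", "120-200", ">200 mm")),
    vc = factor(em$vessel_class, c("<8 m", "8-10 m", "10-12 m", "12-15 m", ">15 m")),
    pop = factor(em$population),
    ln = log(em$net_length_m), ls = log(em$soak_time_h), ld = log(em$depth_m)
  )
  g <- MASS::glm.nb(y ~ mesh + vc + pop + ln + ls + ld + mesh:ls, data = df)
  se <- summary(g)$coefficients[, 2]
  expect_lt(max(abs(unname(coef(fit)) - unname(coef(g))) / se), 0.05)
  expect_equal(fit$theta, g$theta, tolerance = 1e-3)
  expect_equal(fit$logLik, as.numeric(logLik(g)), tolerance = 1e-5)
})

test_that("mixed fit agrees with an independent mixed-model engine", {
  skip_if_not_installed("glmmTMB")
  em <- small_em(seed = 7, n_vessels = 17, years = 2010:2012, days = 40)
  fit <- fit_bycatch_glmm(
    em, bycatch_model_spec(random = c("vessel", "year"),
      spatial_grouping = "none"
    )
  )
  df <- data.frame(
    y = em$bycatch_count, vid = em$vessel_id, fyear = factor(em$year),
    mesh = factor(em$mesh_class, c("<120 mm", "120-200", ">200 mm")),
    vc = factor(em$vessel_class, c("<8 m", "8-10 m", "10-12 m", "12-15 m", ">15 m")),
    pop = factor(em$population),
    ln = log(em$net_length_m), ls = log(em$soak_time_h), ld = log(em$depth_m)
  )
  g <- glmmTMB::glmmTMB(
    y ~ mesh + vc + pop + ln + ls + ld + mesh:ls + (1 | vid) + (1 | fyear),
    family = glmmTMB::nbinom2, data = df
  )
  expect_equal(fit$logLik, as.numeric(logLik(g)), tolerance = 1e-3)
  expect_lt(max(abs(unname(coef(fit)) - unname(glmmTMB::fixef(g)$cond))), 0.05)
  expect_equal(fit$theta, glmmTMB::sigma(g), tolerance = 0.02)
  sds <- sqrt(c(
    glmmTMB::VarCorr(g)$cond$vid[1, 1], glmmTMB::VarCorr(g)$cond$fyear[1, 1]
  ))
  expect_equal(unname(fit$sigma), sds, tolerance = 0.05)
})

test_that("fitting is deterministic and flags convergence", {
  em <- small_em(seed = 19, n_vessels = 12, years = 2010:2011, days = 25)
  sp <- bycatch_model_spec(random = "year", spatial_grouping = "none")
  f1 <- suppressWarnings(fit_bycatch_glmm(em, sp))
  f2 <- suppressWarnings(fit_bycatch_glmm(em, sp))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-8)
  expect_true(is.finite(f1$convergence$max_grad))
  expect_lt(f1$convergence$max_grad, 1e-3)
})

test_that("AICc follows the small-sample formula and its limits", {
  expect_equal(aicc_value(-100, 5, 100), 210 + 60 / 94)
  expect_equal(aicc_value(-100, 5, 1e9), 210, tolerance = 1e-6)
  expect_error(aicc_value(-100, 5, 6), "exceed")
  # nested-fit difference matches hand arithmetic
  em <- small_em(seed = 23, n_vessels = 12, years = 2010:2011, days = 25)
  sp1 <- bycatch_model_spec(random = character(0), spatial_grouping = "none")
  sp0 <- bycatch_model_spec(
    fixed = c("mesh_class", "log_soak_time"),
    random = character(0), spatial_grouping = "none"
  )
  f1 <- fit_bycatch_glmm(em, sp1)
  f0 <- fit_bycatch_glmm(em, sp0)
  d_hand <- (-2 * f1$logLik + 2 * f1$n_params +
    2 * f1$n_params * (f1$n_params + 1) / (f1$n_obs - f1$n_params - 1)) -
    (-2 * f0$logLik + 2 * f0$n_params +
      2 * f0$n_params * (f0$n_params + 1) / (f0$n_obs - f0$n_params - 1))
  expect_equal(aicc(f1) - aicc(f0), d_hand)
})

test_that("model selection ranks by AICc and keeps failures visible", {
  em <- small_em(seed = 29, n_vessels = 12, years = 2010:2011, days = 25)
  sp <- bycatch_model_spec(random = character(0), spatial_grouping = "none")
  tab1 <- select_bycatch_model(em, list(only = sp))
  expect_equal(nrow(tab1), 1)
  expect_equal(tab1$delta_aicc, 0)
  tab2 <- select_bycatch_model(em, list(a = sp, b = sp))
  expect_equal(tab2$aicc[1], tab2$aicc[2])
  expect_true(all(diff(tab2$aicc) >= 0))
})

test_that("quantile residuals are deterministic and detect gross misfit", {
  em <- small_em(seed = 31, n_vessels = 12, years = 2010:2011, days = 25)
  fit <- fit_bycatch_glmm(
    em, bycatch_model_spec(random = character(0), spatial_grouping = "none")
  )
  r1 <- quantile_residuals(fit, n_sim = 150, seed = 4)
  r2 <- quantile_residuals(fit, n_sim = 150, seed = 4)
  expect_identical(r1$residuals, r2$residuals)
  expect_true(all(r1$residuals > 0 & r1$residuals < 1))
  # all-zero response under a large, nearly-Poisson fitted mean:
  # residuals collapse near zero
  fit0 <- fit
  fit0$design$y <- rep(0L, fit$n_obs)
  fit0$state$eta <- rep(log(10), fit$n_obs)
  fit0$theta <- 100
  r0 <- quantile_residuals(fit0, n_sim = 150, seed = 5)
  expect_lt(max(r0$residuals), 0.05)
  expect_lt(r0$ks$p.value, 1e-6)
})
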