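#' Fit the bycatch mixed model by maximum (Laplace) likelihood
#'
#' Maximizes the Laplace-approximated marginal likelihood over the fixed
#' effects and the log-transformed dispersion, random-intercept SDs,
#' spatial-field SD and range, using a bounded quasi-Newton optimizer
#' ([stats::nlminb()]) with the latent modes warm-started between
#' evaluations. Initial values: Poisson-GLM coefficients for `beta`,
#' `log(theta) = 0`, SDs of 0.1, and `rho` at the median pairwise distance
#' between rectangle centroids. Fits ending near the lower variance boundary
#' are restarted (up to `restarts` times) from perturbed, deterministically
#' chosen starts, and flagged.
#'
#' @param em EMTable (see [simulate_bycatch()] / [collapse_to_strata()]).
#' @param spec A [bycatch_model_spec()].
#' @param options List of optional controls: `iter_max` (outer iterations,
#'   default 400), `grad_tol` (scaled gradient max-norm declaring
#'   convergence, default 1e-3), `restarts` (default 2), `trace` (default 0).
#' @return An object of class `bycatch_glmm`: estimates (`beta`, `theta`,
#'   `sigma`, `sigma_s`, `rho`), latent modes `u_hat`, `logLik`, `aicc`,
#'   convergence diagnostics, and the internal state needed for prediction.
#' @export
fit_bycatch_glmm <- function(em, spec = bycatch_model_spec(), options = list()) {
  opts <- modifyList(
    list(
      iter_max = 400L, grad_tol = 1e-3, restarts = 2L, trace = 0L,
      polish = TRUE
    ),
    options
  )
  design <- build_design(em, spec)
  n <- design$n
  p <- design$p
  iid_names <- names(design$blocks)[vapply(
    design$blocks, function(b) b$type == "iid", logical(1)
  )]
  has_spatial <- "spatial" %in% names(design$blocks)

  # outer parameters (the fixed effects are profiled out by the inner
  # Newton): log_disp, log_sigma (iid blocks), log_sigma_s, log_rho
  n_iid <- length(iid_names)
  n_var <- n_iid + if (has_spatial) 2L else 0L
  unpack <- function(par) {
    sigma <- NULL
    sigma_s <- 0
    rho <- NULL
    if (n_iid > 0) sigma <- setNames(exp(par[1L + seq_len(n_iid)]), iid_names)
    if (has_spatial) {
      sigma_s <- exp(par[1L + n_iid + 1L])
      rho <- exp(par[1L + n_iid + 2L])
    }
    list(
      disp = unname(exp(par[1L])), sigma = sigma,
      sigma_s = unname(sigma_s), rho = unname(rho)
    )
  }

  cache <- if (design$q > 0) {
    .design_cache(design)
  } else {
    new.env(parent = emptyenv())
  }
  cache$q <- design$q
  cache$u_warm <- NULL

  # initial values: Poisson GLM for beta (guarded for sparse counts)
  beta0 <- tryCatch(
    {
      fit0 <- suppressWarnings(
        glm.fit(design$X, design$y, family = poisson())
      )
      b <- coef(fit0)
      b[!is.finite(b)] <- 0
      pmin(pmax(b, -20), 20)
    },
    error = function(e) {
      b <- numeric(p)
      b[1] <- log(max(mean(design$y), 1e-3))
      b
    }
  )
  cache$beta_warm <- beta0
  objective <- function(par) {
    pr <- unpack(par)
    out <- tryCatch(
      .laplace_profile_nll(design, cache, cache$beta_warm, pr$disp,
        sigma = pr$sigma, sigma_s = pr$sigma_s, rho = pr$rho
      ),
      error = function(e) NULL
    )
    if (is.null(out) || !is.finite(out$nll) || !out$state$converged) {
      return(1e10)
    }
    cache$beta_warm <- out$state$beta
    as.numeric(out$nll)
  }

  rho0 <- if (has_spatial) {
    D <- design$blocks$spatial$D
    max(median(D[upper.tri(D)]), 1)
  } else {
    NULL
  }
  start <- c(0, rep(log(0.1), n_iid), if (has_spatial) c(log(0.1), log(rho0)))
  lower <- c(-5, rep(-7, n_iid), if (has_spatial) c(-7, log(0.5)))
  upper <- c(10, rep(3, n_iid), if (has_spatial) c(3, log(5000)))

  run_once <- function(st) {
    cache$u_warm <- NULL
    cache$beta_warm <- beta0
    optim(st, objective,
      method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(maxit = opts$iter_max, factr = 1e6)
    )
  }
  opt <- run_once(start)
  opt$objective <- opt$value
  boundary <- function(o) {
    vp <- o$par[-1L]
    any(n_var > 0 & vp < lower[-1L] + 0.2)
  }
  n_restarts_used <- 0L
  if (n_var > 0 && boundary(opt)) {
    warning("variance component at boundary; restarting from perturbed starts",
      call. = FALSE
    )
    for (r in seq_len(opts$restarts)) {
      st2 <- pmin(pmax(start + 0.75 * r * (-1)^r, lower + 0.1), upper - 0.1)
      o2 <- run_once(st2)
      o2$objective <- o2$value
      n_restarts_used <- n_restarts_used + 1L
      if (o2$objective < opt$objective - 1e-6) opt <- o2
      if (!boundary(opt)) break
    }
  }

  # profile solution
  pr <- unpack(opt$par)
  fin <- .laplace_profile_nll(design, cache, cache$beta_warm, pr$disp,
    sigma = pr$sigma, sigma_s = pr$sigma_s, rho = pr$rho
  )
  pr$beta <- fin$state$beta

  # polish: full-dimension quasi-Newton over (beta, log disp, log variance
  # params) on the exact marginal objective, warm-started at the profile
  # solution (the profile step ignores the beta-dependence of log det H)
  full_obj <- function(fp) {
    b <- fp[seq_len(p)]
    vp <- unpack(fp[-seq_len(p)])
    val <- tryCatch(
      laplace_nll(design, b, vp$disp,
        sigma = vp$sigma, sigma_s = vp$sigma_s,
        rho = vp$rho, u_init = cache$u_warm, cache = cache
      ),
      error = function(e) NULL
    )
    if (is.null(val) || !is.finite(val)) {
      return(1e10)
    }
    cache$u_warm <- attr(val, "state")$u
    as.numeric(val)
  }
  full_gr <- function(fp) {
    f0 <- full_obj(fp)
    h <- 1e-6
    vapply(seq_along(fp), function(j) {
      fpj <- fp
      fpj[j] <- fpj[j] + h
      (full_obj(fpj) - f0) / h
    }, numeric(1))
  }
  full_start <- c(pr$beta, opt$par)
  if (isTRUE(opts$polish)) {
    po <- optim(full_start, full_obj, full_gr,
      method = "L-BFGS-B",
      lower = c(rep(-Inf, p), lower), upper = c(rep(Inf, p), upper),
      control = list(maxit = opts$iter_max, factr = 1e7)
    )
    if (po$value <= as.numeric(fin$nll)) {
      pr <- unpack(po$par[-seq_len(p)])
      pr$beta <- po$par[seq_len(p)]
      opt$par <- po$par[-seq_len(p)]
    }
  }

  # final state at the optimum
  val <- laplace_nll(design, pr$beta, pr$disp,
    sigma = pr$sigma,
    sigma_s = pr$sigma_s, rho = pr$rho, u_init = cache$u_warm, cache = cache
  )
  st <- attr(val, "state")
  st$beta <- pr$beta
  st$design_used <- if (design$q > 0) st$design_used else design
  st$cache <- cache
  opt$objective <- as.numeric(val)

  # scaled gradient max-norm of the marginal likelihood over all parameters
  # (fixed effects included) at the reported optimum, by central differences
  full_par <- c(pr$beta, opt$par)
  h <- 1e-5
  gr <- vapply(seq_along(full_par), function(j) {
    pp <- full_par
    pm <- full_par
    pp[j] <- pp[j] + h
    pm[j] <- pm[j] - h
    (full_obj(pp) - full_obj(pm)) / (2 * h)
  }, numeric(1))
  max_grad <- max(abs(gr)) / max(1, abs(opt$objective))

  k <- p + 1L + n_var
  u_hat <- list()
  if (design$q > 0) {
    du <- st$design_used
    for (nm in names(du$blocks)) {
      b <- du$blocks[[nm]]
      vals <- st$u[b$idx]
      names(vals) <- if (b$type == "iid") {
        b$levels
      } else {
        as.vector(outer(b$rect, b$groups, function(rr, gg) paste(gg, rr, sep = "@")))
      }
      u_hat[[nm]] <- vals
    }
  }
  out <- structure(
    list(
      beta = setNames(pr$beta, colnames(design$X)),
      theta = pr$disp, sigma = pr$sigma, sigma_s = pr$sigma_s, rho = pr$rho,
      u_hat = u_hat,
      logLik = -opt$objective, n_obs = n, n_params = k,
      aicc = aicc_value(-opt$objective, k, n),
      convergence = list(
        code = opt$convergence, message = opt$message,
        iterations = opt$iterations, max_grad = max_grad,
        converged = max_grad < opts$grad_tol,
        boundary = n_var > 0 && boundary(opt),
        restarts = n_restarts_used
      ),
      spec = spec, design = design, state = st, par = opt$par
    ),
    class = "bycatch_glmm"
  )
  out
}

#' @export
print.bycatch_glmm <- function(x, ...) {
  cat("Negative-binomial (NB2) mixed model, Laplace-approximated ML\n")
  cat(sprintf(
    "  n = %d, logLik = %.3f, AICc = %.3f, theta = %.3f\n",
    x$n_obs, x$logLik, x$aicc, x$theta
  ))
  if (length(x$sigma) > 0) {
    cat("  random-intercept SDs:",
      paste(sprintf("%s = %.3f", names(x$sigma), x$sigma), collapse = ", "),
      "\n"
    )
  }
  if (!is.null(x$rho)) {
    cat(sprintf(
      "  spatial field: sigma_s = %.3f, range rho = %.1f km (%s)\n",
      x$sigma_s, x$rho, x$spec$spatial_grouping
    ))
  }
  cat("  fixed effects:\n")
  print(round(x$beta, 4))
  if (!x$convergence$converged) {
    cat("  WARNING: scaled gradient max-norm",
      format(x$convergence$max_grad), "exceeds tolerance\n"
    )
  }
  invisible(x)
}

#' @export
logLik.bycatch_glmm <- function(object, ...) {
  structure(object$logLik,
    df = object$n_params, nobs = object$n_obs,
    class = "logLik"
  )
}

#' @export
coef.bycatch_glmm <- function(object, ...) object$beta

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`, with `k` counting fixed
#' effects, the dispersion, and all variance/range parameters.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations; must exceed `k + 1`.
#' @return Scalar AICc.
#' @export
aicc_value <- function(loglik, k, n) {
  if (n <= k + 1) {
    stop("AICc undefined: n must exceed k + 1 (n = ", n, ", k = ", k, ")",
      call. = FALSE
    )
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc_value
#' @param fit A `bycatch_glmm` object.
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "bycatch_glmm"))
  fit$aicc
}

#' Rank candidate model structures by AICc
#'
#' Fits each candidate specification to the same data and returns the table
#' sorted by AICc with differences to the best model. Candidates whose fit
#' fails are kept in the table and flagged rather than dropped.
#'
#' @param em EMTable.
#' @param candidates Named list of [bycatch_model_spec()] objects.
#' @param options Passed to [fit_bycatch_glmm()].
#' @return Tibble with columns `model`, `aicc`, `delta_aicc`, `logLik`, `k`,
#'   `converged`, `error`, sorted by AICc, plus the fits in attribute
#'   `"fits"`.
#' @export
select_bycatch_model <- function(em, candidates, options = list()) {
  stopifnot(length(candidates) >= 1)
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("model", seq_along(candidates))
  }
  fits <- lapply(candidates, function(sp) {
    tryCatch(fit_bycatch_glmm(em, sp, options), error = function(e) e)
  })
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) stop("all candidate fits failed", call. = FALSE)
  tab <- tibble::tibble(
    model = names(candidates),
    aicc = unname(vapply(fits, function(f) {
      if (inherits(f, "error")) NA_real_ else f$aicc
    }, numeric(1))),
    logLik = unname(vapply(fits, function(f) {
      if (inherits(f, "error")) NA_real_ else f$logLik
    }, numeric(1))),
    k = unname(vapply(fits, function(f) {
      if (inherits(f, "error")) NA_integer_ else f$n_params
    }, integer(1))),
    converged = unname(vapply(fits, function(f) {
      if (inherits(f, "error")) FALSE else f$convergence$converged
    }, logical(1))),
    error = unname(vapply(fits, function(f) {
      if (inherits(f, "error")) conditionMessage(f) else NA_character_
    }, character(1)))
  )
  tab <- tab[order(tab$aicc), ]
  tab$delta_aicc <- tab$aicc - min(tab$aicc, na.rm = TRUE)
  tab <- tab[, c(
    "model", "aicc", "delta_aicc", "logLik", "k", "converged",
    "error"
  )]
  attr(tab, "fits") <- fits
  tab
}
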