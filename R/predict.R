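# map newdata rows onto the fitted latent layout --------------------------

# returns X (m x p), and per active block an integer vector of latent
# indices (NA = level unseen at fit time)
.newdata_map <- function(fit, newdata) {
  X <- .fixed_design_matrix(newdata, fit$spec$fixed)
  if (!identical(colnames(X), names(fit$beta))) {
    stop("newdata design columns do not match the fitted model", call. = FALSE)
  }
  du <- if (fit$design$q > 0) fit$state$design_used else NULL
  idx <- list()
  if (!is.null(du)) {
    for (nm in names(du$blocks)) {
      b <- du$blocks[[nm]]
      if (b$type == "iid") {
        key <- if (nm == "vessel") {
          as.character(newdata$vessel_id)
        } else {
          as.character(newdata$year)
        }
        idx[[nm]] <- b$idx[match(key, b$levels)]
      } else {
        gr <- .spatial_group(newdata, fit$spec$spatial_grouping)
        gi <- match(gr, b$groups)
        ri <- match(newdata$rectangle_code, b$rect)
        idx[[nm]] <- b$idx[1] - 1L + (gi - 1L) * length(b$rect) + ri
      }
    }
  }
  list(X = X, idx = idx, m = nrow(X))
}

.block_sd <- function(fit, nm) {
  if (nm == "spatial") fit$sigma_s else fit$sigma[[nm]]
}

#' Natural-scale per-row predictions
#'
#' Predicted mean bycatch per fishing day for each row of `newdata`.
#' `re_mode = "conditional"` uses the estimated latent effects and errors on
#' random-effect levels unseen at fit time; `re_mode = "marginal"` replaces
#' each unseen level's contribution by its log-normal mean correction
#' `sigma^2/2` (levels seen at fit time still use their conditional modes).
#'
#' @param fit A `bycatch_glmm` fit.
#' @param newdata EffortTable-like data frame.
#' @param re_mode `"conditional"` or `"marginal"`.
#' @return Numeric vector of means, one per row.
#' @export
predict_bycatch <- function(fit, newdata,
                            re_mode = c("conditional", "marginal")) {
  re_mode <- match.arg(re_mode)
  map <- .newdata_map(fit, newdata)
  eta <- drop(map$X %*% fit$beta)
  for (nm in names(map$idx)) {
    ii <- map$idx[[nm]]
    new <- is.na(ii)
    if (any(new) && re_mode == "conditional") {
      stop(
        "newdata has levels of '", nm,
        "' unseen at fit time; use re_mode = \"marginal\"",
        call. = FALSE
      )
    }
    contrib <- numeric(map$m)
    contrib[!new] <- fit$state$u[ii[!new]]
    contrib[new] <- 0.5 * .block_sd(fit, nm)^2
    eta <- eta + contrib
  }
  exp(eta)
}

# joint (beta, u) precision at the optimum, conditional on the variance
# parameters: [[X'WX, X'WZ'], [ZWX, H]]
.joint_precision <- function(fit) {
  X <- Matrix::Matrix(fit$design$X, sparse = TRUE)
  if (fit$design$q == 0) {
    eta <- fitted_eta(fit)
    w <- fit$design$family$weight(fit$design$y, eta, fit$theta)
    return(forceSymmetric(Matrix::crossprod(X * sqrt(w))))
  }
  w <- fit$state$w
  Zt <- fit$state$design_used$Zt
  XtW <- Matrix::t(X * w)
  J <- rbind(
    cbind(XtW %*% X, XtW %*% Matrix::t(Zt)),
    cbind(Zt %*% (X * w), fit$state$H)
  )
  forceSymmetric(J)
}

# per-row posterior variance of the latent part z_i' H^{-1} z_i plus the
# new-level variance, and the latent incidence matrix for newdata
.latent_variance <- function(fit, map) {
  m <- map$m
  s_obs <- numeric(m)
  s_new <- numeric(m)
  Znew <- NULL
  if (fit$design$q > 0) {
    ii <- integer(0)
    jj <- integer(0)
    for (nm in names(map$idx)) {
      ok <- !is.na(map$idx[[nm]])
      ii <- c(ii, map$idx[[nm]][ok])
      jj <- c(jj, which(ok))
      s_new[!ok] <- s_new[!ok] + .block_sd(fit, nm)^2
    }
    Znew <- sparseMatrix(
      i = ii, j = jj, x = 1,
      dims = c(fit$design$q, m)
    )
    y1 <- solve(fit$state$chol, Znew, system = "P")
    y2 <- solve(fit$state$chol, y1, system = "L")
    s_obs <- Matrix::colSums(y2^2)
  }
  list(s = s_obs + s_new, s_new = s_new, Znew = Znew)
}

#' Bias-corrected aggregation of natural-scale predictions
#'
#' Expected total bycatch per group of `newdata` rows. Because the total on
#' the natural scale is a convex function of the Gaussian latent effects, the
#' plug-in sum `sum(exp(eta_hat))` underestimates the expectation; the
#' bias-corrected total adds half the posterior variance of each row's latent
#' contribution, `T = sum_i exp(x_i beta + z_i u_hat + z_i' Q z_i / 2 +
#' sigma_new^2 / 2)`, with `Q` the Laplace posterior covariance of the latent
#' vector and `sigma_new^2` covering random-effect levels unseen at fit time.
#' Standard errors use the delta method under the joint Gaussian
#' approximation of (fixed effects, latents); intervals are log-normal.
#'
#' @param fit A `bycatch_glmm` fit.
#' @param newdata EffortTable-like data frame of prediction rows.
#' @param grouping Character vector of `newdata` columns to aggregate by
#'   (default `"year"`); use `character(0)` for one grand total.
#' @param scenario Label stored in the `scenario` column.
#' @return Tibble with the grouping columns, `n_rows`, `plugin`,
#'   `t_hat` (bias-corrected), `se`, `ci_low`, `ci_high`, `method`,
#'   `scenario`.
#' @export
aggregate_bycatch <- function(fit, newdata, grouping = "year",
                              scenario = "all_effort") {
  stopifnot(inherits(fit, "bycatch_glmm"))
  map <- .newdata_map(fit, newdata)
  eta <- drop(map$X %*% fit$beta)
  for (nm in names(map$idx)) {
    ii <- map$idx[[nm]]
    ok <- !is.na(ii)
    contrib <- numeric(map$m)
    contrib[ok] <- fit$state$u[ii[ok]]
    eta <- eta + contrib
  }
  lv <- .latent_variance(fit, map)
  t_row <- exp(eta + 0.5 * lv$s)
  plug_row <- exp(eta)

  key <- if (length(grouping) == 0) {
    rep("total", map$m)
  } else {
    do.call(paste, c(newdata[grouping], sep = "\r"))
  }
  uk <- unique(key)

  J <- .joint_precision(fit)
  chJ <- Cholesky(J, LDL = FALSE, perm = TRUE)
  p <- fit$design$p
  q <- fit$design$q

  res <- lapply(uk, function(k) {
    sel <- key == k
    T_g <- sum(t_row[sel])
    # delta-method gradient in (beta, u)
    g_beta <- drop(crossprod(map$X[sel, , drop = FALSE], t_row[sel]))
    g <- if (q > 0) {
      g_u <- as.vector(lv$Znew[, sel, drop = FALSE] %*% t_row[sel])
      c(g_beta, g_u)
    } else {
      g_beta
    }
    v <- as.numeric(crossprod(g, solve(chJ, g)))
    # variance from new-level draws adds var(exp) of the log-normal factor
    sel_new <- sel & lv$s_new > 0
    v <- v + sum(t_row[sel_new]^2 * (exp(lv$s_new[sel_new]) - 1))
    se <- sqrt(max(v, 0))
    if (T_g > 0 && se > 0) {
      z <- qnorm(0.975) * sqrt(log(1 + (se / T_g)^2))
      gm <- T_g / sqrt(1 + (se / T_g)^2)
      ci <- c(gm * exp(-z), gm * exp(z))
    } else {
      ci <- c(T_g, T_g)
    }
    tibble::tibble(
      .key = k, n_rows = sum(sel), plugin = sum(plug_row[sel]),
      t_hat = T_g, se = se, ci_low = ci[1], ci_high = ci[2]
    )
  })
  out <- dplyr::bind_rows(res)
  if (length(grouping) > 0) {
    kk <- do.call(rbind, strsplit(out$.key, "\r", fixed = TRUE))
    for (j in seq_along(grouping)) {
      out[[grouping[j]]] <- utils::type.convert(kk[, j], as.is = TRUE)
    }
  } else {
    out$group <- out$.key
  }
  out$.key <- NULL
  out$method <- "bias_corrected"
  out$scenario <- scenario
  dplyr::relocate(
    out, dplyr::any_of(c(grouping, "group")), .before = "n_rows"
  )
}

#' Parametric-bootstrap intervals for aggregated predictions
#'
#' Draws `B` joint (fixed effects, latents) vectors from the Gaussian
#' approximation at the fitted variance parameters, adds fresh draws for
#' random-effect levels unseen at fit time, recomputes the natural-scale
#' group totals for every draw, and reports percentile 95% intervals around
#' the bias-corrected point estimate.
#'
#' @inheritParams aggregate_bycatch
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param chunk Draws evaluated per block to bound memory.
#' @return Tibble as [aggregate_bycatch()] plus `ci_low`/`ci_high` from the
#'   bootstrap and an attribute `"draws"` with the per-group draw matrix.
#' @export
bootstrap_prediction_ci <- function(fit, newdata, grouping = "year",
                                    B = 1000L, seed = 1L, chunk = 250L) {
  stopifnot(B >= 1)
  set.seed(seed)
  point <- aggregate_bycatch(fit, newdata, grouping)
  map <- .newdata_map(fit, newdata)
  p <- fit$design$p
  q <- fit$design$q
  gamma_hat <- c(fit$beta, if (q > 0) fit$state$u else numeric(0))
  J <- .joint_precision(fit)
  chJ <- Cholesky(J, LDL = FALSE, perm = TRUE)

  # incidence of newdata rows on (beta, u)
  Arows <- Matrix::Matrix(map$X, sparse = TRUE)
  if (q > 0) {
    lv <- .latent_variance(fit, map)
    Arows <- cbind(Arows, Matrix::t(lv$Znew))
  }
  # distinct unseen levels share one draw per replicate
  new_keys <- list()
  for (nm in names(map$idx)) {
    ii <- map$idx[[nm]]
    if (anyNA(ii)) {
      key <- if (nm == "vessel") {
        as.character(newdata$vessel_id)
      } else if (nm == "year") {
        as.character(newdata$year)
      } else {
        paste(.spatial_group(newdata, fit$spec$spatial_grouping),
          newdata$rectangle_code,
          sep = "@"
        )
      }
      new_keys[[nm]] <- ifelse(is.na(ii), key, NA_character_)
    }
  }
  key_grp <- if (length(grouping) == 0) {
    rep("total", map$m)
  } else {
    do.call(paste, c(newdata[grouping], sep = "\r"))
  }
  uk <- unique(key_grp)
  grp_i <- match(key_grp, uk)

  draws <- matrix(NA_real_, length(uk), B)
  done <- 0L
  while (done < B) {
    nb <- min(chunk, B - done)
    z <- matrix(rnorm((p + q) * nb), p + q, nb)
    gam <- as.matrix(solve(chJ, solve(chJ, z, system = "Lt"), system = "Pt")) +
      gamma_hat
    eta <- as.matrix(Arows %*% gam)
    for (nm in names(new_keys)) {
      kk <- new_keys[[nm]]
      lev <- unique(kk[!is.na(kk)])
      if (length(lev) == 0) next
      u_new <- matrix(
        rnorm(length(lev) * nb, 0, .block_sd(fit, nm)),
        length(lev), nb
      )
      hit <- !is.na(kk)
      eta[hit, ] <- eta[hit, ] + u_new[match(kk[hit], lev), , drop = FALSE]
    }
    tot <- rowsum(exp(eta), grp_i)
    draws[as.integer(rownames(tot)), done + seq_len(nb)] <- tot
    done <- done + nb
  }
  qs <- t(apply(draws, 1, quantile, probs = c(0.025, 0.975), names = FALSE))
  point$ci_low <- qs[match(if (length(grouping) == 0) "total" else
    do.call(paste, c(point[grouping], sep = "\r")), uk), 1]
  point$ci_high <- qs[match(if (length(grouping) == 0) "total" else
    do.call(paste, c(point[grouping], sep = "\r")), uk), 2]
  point$method <- "bias_corrected"
  attr(point, "B") <- B
  attr(point, "draws") <- draws
  point
}

#' Bycatch totals with and without mandatory-pinger effort
#'
#' Aggregates predicted bycatch over the full effort table (scenario
#' `all_effort`: pingers assumed absent) and over the table with
#' mandatory-pinger rows removed (scenario `pinger_removed`: full compliance
#' and 100% pinger efficacy), on the same grouping. The removed scenario can
#' never exceed the full-effort scenario within a group.
#'
#' @inheritParams aggregate_bycatch
#' @param rules Pinger rules table (see [filter_pinger_mandatory()]).
#' @param B If > 0, bootstrap CIs with this many replicates (else delta CIs).
#' @param seed Seed for the bootstrap.
#' @return Tibble of both scenarios, stacked.
#' @export
pinger_scenarios <- function(fit, newdata, rules, grouping = "year",
                             B = 0L, seed = 1L) {
  reduced <- filter_pinger_mandatory(newdata, rules)
  agg <- function(dat, label, sd_seed) {
    if (B > 0) {
      out <- bootstrap_prediction_ci(fit, dat, grouping, B = B, seed = sd_seed)
      out$scenario <- label
      out
    } else {
      aggregate_bycatch(fit, dat, grouping, scenario = label)
    }
  }
  dplyr::bind_rows(
    agg(newdata, "all_effort", seed),
    agg(reduced, "pinger_removed", seed + 1L)
  )
}
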