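# Laplace-approximated marginal likelihood for the NB2 mixed model.
#
# Latent layout: iid random-intercept blocks (vessel, year), then one
# spatial block per temporal group, each over the same set of rectangle
# centroids, with prior covariance sigma_s^2 * exp(-D/rho) shared across
# groups. The marginal log-likelihood is approximated as
#   l(y | u_hat) - u_hat' Q u_hat / 2 - log|Sigma|/2 - log|H|/2
# with u_hat the conditional mode (inner Newton), Q the prior precision and
# H = Z'WZ + Q the negative joint Hessian in u (the 2*pi terms cancel).
#
# Hot-path layout: the sparsity patterns of Q, Z'WZ and the Cholesky factor
# are fixed while the active blocks are fixed, so the triplet index vectors
# and the CHOLMOD symbolic analysis are computed once and cached; per
# evaluation only the numeric values are refreshed.

# prior precision triplets (lower triangle) and log|Sigma|
.prior_structure <- function(design) {
  ii <- integer(0)
  jj <- integer(0)
  spatial_tpl <- NULL
  for (b in design$blocks) {
    if (b$type == "iid") {
      ii <- c(ii, b$idx)
      jj <- c(jj, b$idx)
    } else {
      r <- length(b$rect)
      lower <- which(row(matrix(0, r, r)) >= col(matrix(0, r, r)))
      li <- ((lower - 1L) %% r) + 1L
      lj <- ((lower - 1L) %/% r) + 1L
      for (g in seq_along(b$groups)) {
        off <- b$idx[1] - 1L + (g - 1L) * r
        ii <- c(ii, off + li)
        jj <- c(jj, off + lj)
      }
      spatial_tpl <- list(sel = cbind(li, lj), G = length(b$groups), r = r)
    }
  }
  list(i = ii, j = jj, spatial = spatial_tpl)
}

.prior_values <- function(design, ps, sigma, sigma_s, rho, jitter = 1e-8) {
  vals <- numeric(0)
  logdet <- 0
  for (b in design$blocks) {
    if (b$type == "iid") {
      s <- sigma[[b$name]]
      if (!is.finite(s) || s <= 0) {
        stop("sigma for block '", b$name, "' must be > 0 (drop the block for 0)",
          call. = FALSE
        )
      }
      vals <- c(vals, rep(1 / s^2, length(b$levels)))
      logdet <- logdet + 2 * length(b$levels) * log(s)
    } else {
      if (!is.finite(sigma_s) || sigma_s <= 0 || !is.finite(rho) || rho <= 0) {
        stop("spatial block requires sigma_s > 0 and rho > 0", call. = FALSE)
      }
      C <- exp(-b$D / rho)
      diag(C) <- diag(C) + jitter
      ch <- tryCatch(chol(C), error = function(e) {
        stop("spatial correlation matrix not positive definite after jitter: ",
          conditionMessage(e),
          call. = FALSE
        )
      })
      Cinv <- chol2inv(ch)
      tpl <- ps$spatial
      vals <- c(vals, rep(Cinv[tpl$sel] / sigma_s^2, tpl$G))
      logdet <- logdet + tpl$G *
        (2 * tpl$r * log(sigma_s) + 2 * sum(log(diag(ch))))
    }
  }
  list(vals = vals, logdet_sigma = logdet)
}

# per-observation latent indices (one per block) and the lower-triangle
# triplet pattern of Z'WZ
.z_structure <- function(design) {
  n <- design$n
  bidx <- lapply(design$blocks, function(b) {
    # recover each row's latent index from the sparse incidence matrix
    integer(n)
  })
  Tz <- as(design$Zt, "TsparseMatrix")
  lat <- Tz@i + 1L
  obs <- Tz@j + 1L
  # assign each entry to its block
  starts <- vapply(design$blocks, function(b) b$idx[1], integer(1))
  ends <- vapply(design$blocks, function(b) b$idx[length(b$idx)], integer(1))
  for (k in seq_along(design$blocks)) {
    sel <- lat >= starts[k] & lat <= ends[k]
    v <- integer(n)
    v[obs[sel]] <- lat[sel]
    bidx[[k]] <- v
  }
  nb <- length(bidx)
  # all ordered pairs of blocks (incl. self) per observation, lower triangle
  pi <- integer(0)
  pj <- integer(0)
  po <- integer(0)
  for (a in seq_len(nb)) {
    for (b2 in seq_len(a)) {
      i1 <- bidx[[a]]
      i2 <- bidx[[b2]]
      lo <- pmin(i1, i2)
      hi <- pmax(i1, i2)
      pi <- c(pi, hi)
      pj <- c(pj, lo)
      po <- c(po, seq_len(n))
    }
  }
  list(bidx = bidx, pair_i = pi, pair_j = pj, pair_obs = po)
}

# drop latent blocks whose variance parameter is exactly zero
.reduce_design <- function(design, drop) {
  keep_blocks <- design$blocks[setdiff(names(design$blocks), drop)]
  keep_idx <- unlist(lapply(keep_blocks, function(b) b$idx), use.names = FALSE)
  offset <- 0L
  for (nm in names(keep_blocks)) {
    k <- length(keep_blocks[[nm]]$idx)
    keep_blocks[[nm]]$idx <- offset + seq_len(k)
    offset <- offset + k
  }
  design$Zt <- if (length(keep_idx) > 0) {
    design$Zt[keep_idx, , drop = FALSE]
  } else {
    NULL
  }
  design$blocks <- keep_blocks
  design$q <- offset
  design
}

# build the fixed sparsity pattern of H = Z'WZ + Q and the maps from the
# (repeating) triplet contributions into positions of the pattern's @x slot
.h_pattern <- function(cc, q) {
  ps <- cc$ps
  zs <- cc$zs
  tpl <- sparseMatrix(
    i = c(ps$i, zs$pair_i), j = c(ps$j, zs$pair_j),
    x = 1, dims = c(q, q), symmetric = TRUE
  )
  cols <- rep(seq_len(q), diff(tpl@p))
  keys_tpl <- (tpl@i + 1) + as.numeric(q) * (cols - 1)
  key_of <- function(hi, lo) {
    if (tpl@uplo == "U") lo + as.numeric(q) * (hi - 1) else
      hi + as.numeric(q) * (lo - 1)
  }
  cc$H_tpl <- tpl
  cc$pos_prior <- match(key_of(pmax(ps$i, ps$j), pmin(ps$i, ps$j)), keys_tpl)
  pos_pair <- match(key_of(zs$pair_i, zs$pair_j), keys_tpl)
  # aggregation operator: nnz(H) x n, entry (pos, obs) = 1, so that the
  # numeric slot of Z'WZ is Agg %*% w
  cc$Agg <- sparseMatrix(
    i = pos_pair, j = zs$pair_obs, x = 1,
    dims = c(length(tpl@x), design_n_from_cc(cc))
  )
  invisible(cc)
}

design_n_from_cc <- function(cc) length(cc$zs$bidx[[1]])

# numeric refresh of the fixed H pattern: x = prior part + Agg %*% w
.make_H <- function(cc, x_base, w) {
  H <- cc$H_tpl
  H@x <- x_base + as.vector(cc$Agg %*% w)
  H
}

# linear predictor eta = X beta + sum of each block's latent per row
.eta_of <- function(eta_fix, bidx, u) {
  eta <- eta_fix
  for (v in bidx) eta <- eta + u[v]
  eta
}

# inner Newton maximization of the joint log-density in u; `cc` is the
# per-design cache environment holding patterns and the symbolic Cholesky
.inner_newton <- function(design, cc, beta, disp, prior, u0 = NULL,
                          tol = 1e-9, maxit = 100L) {
  fam <- design$family
  y <- design$y
  q <- design$q
  zs <- cc$zs
  Qp <- sparseMatrix(
    i = cc$ps$i, j = cc$ps$j, x = prior$vals, dims = c(q, q),
    symmetric = TRUE
  )
  if (is.null(cc$H_tpl)) .h_pattern(cc, q)
  x_base <- numeric(length(cc$H_tpl@x))
  x_base[cc$pos_prior] <- prior$vals
  eta_fix <- drop(design$X %*% beta)
  u <- if (is.null(u0) || length(u0) != q) numeric(q) else u0
  eta <- .eta_of(eta_fix, zs$bidx, u)
  f <- fam$loglik(y, eta, disp) - 0.5 * sum(u * as.vector(Qp %*% u))
  if (!is.finite(f)) { # reset a bad warm start
    u <- numeric(q)
    eta <- eta_fix
    f <- fam$loglik(y, eta, disp)
  }
  conv <- FALSE
  H <- NULL
  for (it in seq_len(maxit)) {
    g <- as.vector(design$Zt %*% fam$d1(y, eta, disp)) - as.vector(Qp %*% u)
    H <- .make_H(cc, x_base, fam$weight(y, eta, disp))
    if (is.null(cc$chol_tpl)) {
      cc$chol_tpl <- Cholesky(H, LDL = FALSE, perm = TRUE)
    }
    ch <- Matrix::update(cc$chol_tpl, H)
    if (max(abs(g)) < tol * (1 + abs(f))) {
      conv <- TRUE
      break
    }
    step <- as.vector(solve(ch, g))
    alpha <- 1
    repeat {
      u_new <- u + alpha * step
      eta_new <- .eta_of(eta_fix, zs$bidx, u_new)
      f_new <- fam$loglik(y, eta_new, disp) -
        0.5 * sum(u_new * as.vector(Qp %*% u_new))
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) break
    }
    if (alpha < 1e-10) break
    u <- u_new
    eta <- eta_new
    if (abs(f_new - f) < 1e-12 * (1 + abs(f))) {
      f <- f_new
      g <- as.vector(design$Zt %*% fam$d1(y, eta, disp)) - as.vector(Qp %*% u)
      conv <- max(abs(g)) < sqrt(tol) * (1 + abs(f))
      if (conv) break
    }
    f <- f_new
  }
  w <- fam$weight(y, eta, disp)
  H <- .make_H(cc, x_base, w)
  ch <- Matrix::update(cc$chol_tpl, H)
  logdet_H <- 2 * as.numeric(determinant(ch, sqrt = TRUE)$modulus)
  list(
    u = u, eta = eta, w = w, H = H, chol = ch, logdet_H = logdet_H,
    loglik_cond = fam$loglik(y, eta, disp),
    quad = 0.5 * sum(u * as.vector(Qp %*% u)), Qp = Qp,
    converged = conv, iterations = it
  )
}

# joint Newton over (beta, u): maximizes l(X beta + Z'u) - u'Q u/2. Used to
# profile the fixed effects out of the outer optimization; the Newton system
# is solved by Schur complement on beta so the sparse Cholesky of
# H = Z'WZ + Q (cached pattern) is reused.
.inner_newton_joint <- function(design, cc, beta0, disp, prior,
                                u0 = NULL, tol = 1e-9, maxit = 200L) {
  fam <- design$family
  y <- design$y
  q <- design$q
  p <- design$p
  X <- design$X
  zs <- cc$zs
  Qp <- sparseMatrix(
    i = cc$ps$i, j = cc$ps$j, x = prior$vals, dims = c(q, q),
    symmetric = TRUE
  )
  if (is.null(cc$H_tpl)) .h_pattern(cc, q)
  x_base <- numeric(length(cc$H_tpl@x))
  x_base[cc$pos_prior] <- prior$vals
  beta <- beta0
  u <- if (is.null(u0) || length(u0) != q) numeric(q) else u0
  value <- function(beta, u, eta) {
    fam$loglik(y, eta, disp) - 0.5 * sum(u * as.vector(Qp %*% u))
  }
  eta <- .eta_of(drop(X %*% beta), zs$bidx, u)
  f <- value(beta, u, eta)
  if (!is.finite(f)) {
    beta <- numeric(p)
    beta[1] <- log(max(mean(y), 1e-3))
    u <- numeric(q)
    eta <- .eta_of(drop(X %*% beta), zs$bidx, u)
    f <- value(beta, u, eta)
  }
  conv <- FALSE
  for (it in seq_len(maxit)) {
    d1 <- fam$d1(y, eta, disp)
    w <- fam$weight(y, eta, disp)
    g_beta <- drop(crossprod(X, d1))
    g_u <- as.vector(design$Zt %*% d1) - as.vector(Qp %*% u)
    if (max(abs(c(g_beta, g_u))) < tol * (1 + abs(f))) {
      conv <- TRUE
      break
    }
    H <- .make_H(cc, x_base, w)
    if (is.null(cc$chol_tpl)) {
      cc$chol_tpl <- Cholesky(H, LDL = FALSE, perm = TRUE)
    }
    ch <- Matrix::update(cc$chol_tpl, H)
    Xw <- X * w
    B <- design$Zt %*% Xw # q x p
    HinvB <- solve(ch, B) # q x p
    A <- crossprod(X, Xw) # p x p
    S <- A - as.matrix(crossprod(B, HinvB))
    rhs <- g_beta - as.vector(crossprod(HinvB, g_u))
    d_beta <- tryCatch(solve(S, rhs), error = function(e) NULL)
    if (is.null(d_beta)) {
      d_beta <- numeric(p)
    }
    d_u <- as.vector(solve(ch, g_u)) - as.vector(HinvB %*% d_beta)
    alpha <- 1
    repeat {
      beta_new <- beta + alpha * d_beta
      u_new <- u + alpha * d_u
      eta_new <- .eta_of(drop(X %*% beta_new), zs$bidx, u_new)
      f_new <- value(beta_new, u_new, eta_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) break
    }
    if (alpha < 1e-10) break
    beta <- beta_new
    u <- u_new
    eta <- eta_new
    f <- f_new
  }
  w <- fam$weight(y, eta, disp)
  H <- .make_H(cc, x_base, w)
  if (is.null(cc$chol_tpl)) {
    cc$chol_tpl <- Cholesky(H, LDL = FALSE, perm = TRUE)
  }
  ch <- Matrix::update(cc$chol_tpl, H)
  logdet_H <- 2 * as.numeric(determinant(ch, sqrt = TRUE)$modulus)
  list(
    beta = beta, u = u, eta = eta, w = w, H = H, chol = ch,
    logdet_H = logdet_H,
    loglik_cond = fam$loglik(y, eta, disp),
    quad = 0.5 * sum(u * as.vector(Qp %*% u)), Qp = Qp,
    converged = conv, iterations = it
  )
}

# profile negative marginal log-likelihood: beta maximized jointly with u
# inside the inner Newton, outer parameters are only the dispersion and the
# variance/range parameters. Used by the fitting driver; `laplace_nll()`
# itself evaluates the marginal at fixed beta.
.laplace_profile_nll <- function(design, cache, beta_init, disp, sigma,
                                 sigma_s, rho) {
  if (design$q == 0) {
    # plain Newton over beta (no latents to integrate)
    fam <- design$family
    y <- design$y
    X <- design$X
    beta <- beta_init
    eta <- drop(X %*% beta)
    f <- fam$loglik(y, eta, disp)
    if (!is.finite(f)) {
      beta <- numeric(design$p)
      beta[1] <- log(max(mean(y), 1e-3))
      eta <- drop(X %*% beta)
      f <- fam$loglik(y, eta, disp)
    }
    conv <- FALSE
    for (it in seq_len(200L)) {
      g <- drop(crossprod(X, fam$d1(y, eta, disp)))
      if (max(abs(g)) < 1e-9 * (1 + abs(f))) {
        conv <- TRUE
        break
      }
      w <- fam$weight(y, eta, disp)
      step <- tryCatch(solve(crossprod(X, X * w), g), error = function(e) NULL)
      if (is.null(step)) break
      alpha <- 1
      repeat {
        beta_new <- beta + alpha * step
        eta_new <- drop(X %*% beta_new)
        f_new <- fam$loglik(y, eta_new, disp)
        if (is.finite(f_new) && f_new >= f - 1e-12) break
        alpha <- alpha / 2
        if (alpha < 1e-10) break
      }
      if (alpha < 1e-10) break
      beta <- beta_new
      eta <- eta_new
      f <- f_new
    }
    return(list(
      nll = -f,
      state = list(beta = beta, u = numeric(0), eta = eta, converged = conv)
    ))
  }
  prior <- .prior_values(
    design, cache$ps, sigma,
    sigma_s = sigma_s, rho = if (is.null(rho)) 1 else rho
  )
  st <- .inner_newton_joint(design, cache, beta_init, disp, prior,
    u0 = cache$u_warm
  )
  cache$u_warm <- st$u
  nll <- -(st$loglik_cond - st$quad - 0.5 * prior$logdet_sigma -
    0.5 * st$logdet_H)
  list(nll = nll, state = c(st, list(prior = prior)))
}

# per-design cache of sparsity patterns and the symbolic factorization
.design_cache <- function(design) {
  cc <- new.env(parent = emptyenv())
  cc$ps <- .prior_structure(design)
  cc$zs <- .z_structure(design)
  cc$chol_tpl <- NULL
  cc
}

#' Laplace-approximated negative marginal log-likelihood
#'
#' Evaluates the marginal negative log-likelihood of the mixed model at given
#' parameter values by profiling out the latent effects with an inner Newton
#' solve and applying the Laplace correction `log det(H)/2`. With no random
#' terms (or all variance parameters zero) this is exactly the fixed-effects
#' negative log-likelihood. For the Gaussian toy family the approximation is
#' exact.
#'
#' @param design A [build_design()] object.
#' @param beta Fixed-effect vector (in design-column order).
#' @param theta Dispersion: NB2 `theta`, or residual SD for the Gaussian
#'   family.
#' @param sigma Named vector of random-intercept SDs (one per iid block;
#'   0 drops a block).
#' @param sigma_s,rho Spatial-field SD and range (km); `sigma_s = 0` drops
#'   the field.
#' @param u_init Optional warm start for the latent vector.
#' @param cache Optional environment from a previous call on the same design
#'   (reuses sparsity patterns and the symbolic Cholesky).
#' @return Scalar negative log-likelihood, with the inner state in attribute
#'   `"state"`.
#' @export
laplace_nll <- function(design, beta, theta, sigma = NULL, sigma_s = 0,
                        rho = NULL, u_init = NULL, cache = NULL) {
  stopifnot(inherits(design, "bycatch_design"))
  if (length(beta) != design$p) {
    stop("beta has length ", length(beta), ", expected ", design$p,
      call. = FALSE
    )
  }
  iid_names <- names(design$blocks)[vapply(design$blocks, function(b) {
    b$type == "iid"
  }, logical(1))]
  if (length(iid_names) > 0) {
    if (is.null(sigma)) {
      stop("sigma required for blocks: ", paste(iid_names, collapse = ", "),
        call. = FALSE
      )
    }
    if (is.null(names(sigma))) names(sigma) <- iid_names
  }
  drop_blocks <- character(0)
  if (length(iid_names) > 0) {
    drop_blocks <- iid_names[sigma[iid_names] == 0]
  }
  if ("spatial" %in% names(design$blocks) &&
    (is.null(sigma_s) || sigma_s == 0)) {
    drop_blocks <- c(drop_blocks, "spatial")
  }
  if (length(drop_blocks) > 0) design <- .reduce_design(design, drop_blocks)

  if (design$q == 0) {
    eta <- drop(design$X %*% beta)
    nll <- -design$family$loglik(design$y, eta, theta)
    attr(nll, "state") <- list(eta = eta, u = numeric(0))
    return(nll)
  }
  if (is.null(cache) || !identical(cache$q, design$q)) {
    cache <- .design_cache(design)
    cache$q <- design$q
  }
  prior <- .prior_values(
    design, cache$ps, sigma,
    sigma_s = sigma_s, rho = if (is.null(rho)) 1 else rho
  )
  st <- .inner_newton(design, cache, beta, theta, prior, u0 = u_init)
  if (!st$converged) {
    stop("inner Newton did not converge (", st$iterations, " iterations)",
      call. = FALSE
    )
  }
  nll <- -(st$loglik_cond - st$quad - 0.5 * prior$logdet_sigma -
    0.5 * st$logdet_H)
  attr(nll, "state") <- c(st, list(
    prior = prior, design_used = design,
    cache = cache
  ))
  nll
}
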