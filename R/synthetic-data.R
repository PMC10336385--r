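#' Configuration of the synthetic gillnet fleet
#'
#' Builds the configuration object consumed by [generate_fleet_effort()] and
#' [simulate_bycatch()]. The defaults emulate the monitored Danish set-gillnet
#' fishery: an eleven-year record (2010-2020), four quarters, a fleet fishing
#' a fixed set of ICES rectangles spread over the five ICES areas of the study
#' region, and an EM-monitored subset of vessels. Soak-time and net-length are
#' log-normal; mesh-size and vessel-length classes are drawn from fixed
#' probabilities over the reporting classes.
#'
#' @param n_vessels Number of vessels in the fleet.
#' @param years Integer vector of calendar years.
#' @param rectangles Data frame with columns `rectangle_code`, `ices_area`,
#'   `depth_m` (mean rectangle depth, m). Centroids are derived from the code.
#' @param n_days_per_vessel_year Fishing days per vessel per year.
#' @param em_fraction Proportion of vessels carrying EM systems, in (0, 1].
#' @param mesh_probs Probabilities of the three mesh-size classes.
#' @param vessel_class_probs Probabilities of the five vessel-length classes
#'   (a vessel keeps its class for the whole series).
#' @param soak_meanlog,soak_sdlog Log-normal parameters of soak-time (hours).
#' @param net_meanlog,net_sdlog Log-normal parameters of net-length (metres).
#' @param seed Integer seed; every draw in the generator flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_vessels = 100,
                       years = 2010:2020,
                       rectangles = default_rectangles(),
                       n_days_per_vessel_year = 33,
                       em_fraction = 0.17,
                       mesh_probs = c(0.40, 0.40, 0.20),
                       vessel_class_probs = c(0.15, 0.30, 0.25, 0.20, 0.10),
                       soak_meanlog = log(20), soak_sdlog = 0.4,
                       net_meanlog = log(2000), net_sdlog = 0.6,
                       seed = 1L) {
  stopifnot(
    n_vessels >= 0, length(years) >= 1, n_days_per_vessel_year >= 0,
    em_fraction > 0, em_fraction <= 1,
    length(mesh_probs) == 3, length(vessel_class_probs) == 5
  )
  if (abs(sum(mesh_probs) - 1) > 1e-12 ||
    abs(sum(vessel_class_probs) - 1) > 1e-12) {
    stop("class probabilities must sum to 1", call. = FALSE)
  }
  if (nrow(rectangles) == 0) {
    stop("configuration error: rectangle list is empty", call. = FALSE)
  }
  geo <- ices_rect_geometry(rectangles$rectangle_code)
  if (any(!is.finite(geo$lon)) || any(!is.finite(geo$lat))) {
    stop("rectangle centroids must be finite", call. = FALSE)
  }
  .check_positive(rectangles$depth_m, "depth_m")
  structure(
    list(
      n_vessels = as.integer(n_vessels), years = as.integer(years),
      rectangles = dplyr::left_join(rectangles,
        geo[, c("rectangle_code", "lon", "lat")],
        by = "rectangle_code"
      ),
      n_days_per_vessel_year = as.integer(n_days_per_vessel_year),
      em_fraction = em_fraction, mesh_probs = mesh_probs,
      vessel_class_probs = vessel_class_probs,
      soak_meanlog = soak_meanlog, soak_sdlog = soak_sdlog,
      net_meanlog = net_meanlog, net_sdlog = net_sdlog,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default rectangle set of the study region
#'
#' Fifteen ICES rectangles spanning the North Sea (IVb), Skagerrak (IIIa20),
#' Kattegat (IIIa21), Belt Seas (IIIc22) and the Sound (IIIb23), with
#' plausible mean depths. Synthetic stand-in for the bathymetry-derived
#' rectangle table of the real fishery.
#'
#' @return Tibble with `rectangle_code`, `ices_area`, `depth_m`.
#' @export
default_rectangles <- function() {
  tibble::tribble(
    ~rectangle_code, ~ices_area, ~depth_m,
    "39F7", "IVb", 35,
    "40F6", "IVb", 42,
    "41F6", "IVb", 55,
    "42F7", "IVb", 60,
    "43F8", "IIIa20", 120,
    "44F9", "IIIa20", 200,
    "43G0", "IIIa20", 90,
    "42G1", "IIIa21", 40,
    "41G1", "IIIa21", 30,
    "41G2", "IIIa21", 25,
    "40G1", "IIIc22", 22,
    "39G0", "IIIc22", 18,
    "38G0", "IIIc22", 20,
    "40G2", "IIIb23", 15,
    "39G1", "IIIc22", 24
  )
}

#' True parameters of the synthetic bycatch-generating model
#'
#' Parameters of the NB2 log-link mixed model that [simulate_bycatch()] draws
#' from: fixed-effect coefficients (treatment coding against reference levels
#' `"<120 mm"`, `"<8 m"`, `"North Sea Population"`), NB2 dispersion `theta`
#' (variance mu + mu^2/theta), random-intercept standard deviations for
#' vessel and year, and the spatial-field parameters (`sigma_s`, range `rho`
#' in km, exponential covariance). The default intercept is set so that the
#' marginal mean bycatch rate is about 0.085 porpoises per fishing day, the
#' order observed in the monitored fishery.
#'
#' @param beta Named numeric vector of fixed effects. Names must follow the
#'   design-column naming of [build_design()].
#' @param theta NB2 dispersion, > 0.
#' @param sigma_vessel,sigma_year Random-intercept SDs, >= 0.
#' @param sigma_s Spatial-field SD, >= 0.
#' @param rho Spatial range (km), > 0.
#' @return A list of class `true_params`.
#' @export
true_params <- function(beta = NULL, theta = 1.0,
                        sigma_vessel = 0.4, sigma_year = 0.3,
                        sigma_s = 0.6, rho = 40) {
  if (is.null(beta)) {
    beta <- c(
      `(Intercept)` = -7.35,
      `mesh_class120-200` = 0.8,
      `mesh_class>200 mm` = 1.2,
      `vessel_class8-10 m` = 0.2,
      `vessel_class10-12 m` = 0.4,
      `vessel_class12-15 m` = 0.5,
      `vessel_class>15 m` = 0.6,
      `populationWestern Baltic Population` = -0.4,
      log_net_length = 0.25,
      log_soak_time = 0.35,
      log_depth = 0.15,
      `mesh_class120-200:log_soak_time` = 0.15,
      `mesh_class>200 mm:log_soak_time` = 0.25
    )
  }
  stopifnot(theta > 0, sigma_vessel >= 0, sigma_year >= 0, sigma_s >= 0, rho > 0)
  structure(
    list(
      beta = beta, theta = theta, sigma_vessel = sigma_vessel,
      sigma_year = sigma_year, sigma_s = sigma_s, rho = rho
    ),
    class = "true_params"
  )
}

#' Generate a synthetic fleet effort table
#'
#' One row per vessel per fishing day per ICES rectangle, with the
#' operational covariates of the analysis resolution. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An EffortTable tibble (columns `vessel_id`, `year`, `quarter`,
#'   `rectangle_code`, `lon`, `lat`, `ices_area`, `mesh_class`,
#'   `vessel_class`, `population`, `soak_time_h`, `net_length_m`, `depth_m`,
#'   `fishing_days`, `pinger_mandatory`, plus `em_monitored`).
#' @export
generate_fleet_effort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  empty <- tibble::tibble(
    vessel_id = character(), year = integer(), quarter = integer(),
    rectangle_code = character(), lon = double(), lat = double(),
    ices_area = character(), mesh_class = character(),
    vessel_class = character(), population = character(),
    soak_time_h = double(), net_length_m = double(), depth_m = double(),
    fishing_days = double(), pinger_mandatory = logical(),
    em_monitored = logical()
  )
  n_rows <- config$n_vessels * length(config$years) *
    config$n_days_per_vessel_year
  if (n_rows == 0) {
    return(empty)
  }
  set.seed(config$seed)
  vessels <- sprintf("V%03d", seq_len(config$n_vessels))
  # quota allocation of vessel-length classes (largest-remainder), shuffled:
  # keeps the class composition at its target shares in every fleet size
  quota <- config$vessel_class_probs * config$n_vessels
  counts <- floor(quota)
  rem <- config$n_vessels - sum(counts)
  if (rem > 0) {
    top <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  vclass <- sample(rep(.vessel_levels, counts))
  # EM vessels drawn stratified over vessel classes so the monitored subset
  # is representative of the fleet composition (at least one per class when
  # the monitored count allows)
  n_em <- max(1L, round(config$em_fraction * config$n_vessels))
  by_class <- split(seq_len(config$n_vessels), vclass)
  em_ids <- integer(0)
  cls_order <- order(lengths(by_class), decreasing = TRUE)
  while (length(em_ids) < n_em) {
    for (k in cls_order) {
      pool <- setdiff(by_class[[k]], em_ids)
      if (length(pool) > 0 && length(em_ids) < n_em) {
        em_ids <- c(em_ids, if (length(pool) == 1) pool else sample(pool, 1))
      }
    }
  }
  em_vessels <- vessels[em_ids]

  grid <- expand.grid(
    day = seq_len(config$n_days_per_vessel_year),
    year = config$years,
    vessel = seq_len(config$n_vessels),
    KEEP.OUT.ATTRS = FALSE
  )
  n <- nrow(grid)
  rect_idx <- sample.int(nrow(config$rectangles), n, replace = TRUE)
  rect <- config$rectangles[rect_idx, ]
  out <- tibble::tibble(
    vessel_id = vessels[grid$vessel],
    year = as.integer(grid$year),
    quarter = sample(1:4, n, replace = TRUE),
    rectangle_code = rect$rectangle_code,
    lon = rect$lon, lat = rect$lat,
    ices_area = rect$ices_area,
    mesh_class = sample(.mesh_levels, n, replace = TRUE,
      prob = config$mesh_probs
    ),
    vessel_class = vclass[grid$vessel],
    population = population_of_area(rect$ices_area),
    soak_time_h = rlnorm(n, config$soak_meanlog, config$soak_sdlog),
    net_length_m = rlnorm(n, config$net_meanlog, config$net_sdlog),
    depth_m = rect$depth_m,
    fishing_days = 1,
    pinger_mandatory = FALSE,
    em_monitored = vessels[grid$vessel] %in% em_vessels
  )
  out[order(out$vessel_id, out$year, out$quarter, out$rectangle_code), ]
}

#' Draw a zero-mean Gaussian spatial field with exponential covariance
#'
#' Cov(i, j) = `sigma_s^2 * exp(-d_ij / rho)` with `d_ij` the great-circle
#' distance in km. Independent realizations are drawn for each level of
#' `group`; all groups share the same (`sigma_s`, `rho`).
#'
#' @param lon,lat Positions (decimal degrees), typically rectangle centroids.
#' @param sigma_s Field standard deviation, >= 0.
#' @param rho Range parameter (km), > 0.
#' @param group Factor-like vector, one entry per position; positions with the
#'   same group value come from one realization.
#' @param seed Optional integer seed (omit to use the current RNG stream).
#' @return Numeric vector of field values, one per position.
#' @export
sample_spatial_field <- function(lon, lat, sigma_s, rho, group = NULL,
                                 seed = NULL) {
  stopifnot(sigma_s >= 0, rho > 0, length(lon) == length(lat))
  if (!is.null(seed)) set.seed(seed)
  n <- length(lon)
  if (n == 0) {
    return(numeric(0))
  }
  if (is.null(group)) group <- rep(1L, n)
  out <- numeric(n)
  for (g in unique(group)) {
    idx <- which(group == g)
    if (sigma_s == 0) {
      out[idx] <- 0
      next
    }
    d <- .distance_km(lon[idx], lat[idx])
    cov <- sigma_s^2 * exp(-d / rho)
    ch <- tryCatch(
      chol(cov + diag(1e-8, nrow(cov))),
      error = function(e) {
        stop(
          "spatial covariance not positive definite after jitter (",
          length(idx), " positions, rho = ", rho, "): ", conditionMessage(e),
          call. = FALSE
        )
      }
    )
    out[idx] <- drop(rnorm(length(idx)) %*% ch)
  }
  out
}

#' Simulate EM-observed bycatch counts on an effort table
#'
#' Adds NB2 bycatch counts to (the EM-monitored subset of) an effort table
#' under the full generative model: log mu = fixed effects + vessel and year
#' random intercepts + a spatial field realized independently for each
#' quarter-within-year group at the rectangle centroids, and
#' count ~ NB2(mu, theta) with variance mu + mu^2/theta.
#'
#' @param effort EffortTable, e.g. from [generate_fleet_effort()].
#' @param params A [true_params()].
#' @param seed Integer seed.
#' @param em_only If `TRUE` (default) counts are attached only to rows with
#'   `em_monitored == TRUE`; otherwise to all rows.
#' @return An EMTable: the selected rows plus `bycatch_count`, with the
#'   realized latent values in attributes `"latents"`.
#' @export
simulate_bycatch <- function(effort, params, seed = 1L, em_only = TRUE) {
  stopifnot(inherits(params, "true_params"))
  need <- setdiff(.effort_cols, c("fishing_days", "pinger_mandatory"))
  .check_effort_table(effort, need, "effort table")
  for (cc in need) {
    if (anyNA(effort[[cc]])) {
      stop("missing covariate: column '", cc, "', row(s) ",
        paste(head(which(is.na(effort[[cc]])), 5L), collapse = ", "),
        call. = FALSE
      )
    }
  }
  em <- if (em_only && "em_monitored" %in% names(effort)) {
    effort[effort$em_monitored, , drop = FALSE]
  } else {
    effort
  }
  if (nrow(em) == 0) {
    em$bycatch_count <- integer(0)
    return(em)
  }
  set.seed(seed)

  X <- .fixed_design_matrix(em)
  beta <- params$beta
  miss <- setdiff(colnames(X), names(beta))
  if (length(miss) > 0) {
    stop("true_params$beta lacks coefficient(s): ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  eta <- drop(X %*% beta[colnames(X)])

  # vessel and year random intercepts
  vl <- sort(unique(em$vessel_id))
  yl <- sort(unique(em$year))
  b_vessel <- setNames(rnorm(length(vl), 0, params$sigma_vessel), vl)
  b_year <- setNames(rnorm(length(yl), 0, params$sigma_year), as.character(yl))
  eta <- eta + b_vessel[em$vessel_id] + b_year[as.character(em$year)]

  # one spatial realization per quarter-within-year group over the distinct
  # rectangle centroids present in that group
  gr <- paste(em$year, em$quarter, sep = ":")
  key <- paste(gr, em$rectangle_code, sep = "@")
  uk <- !duplicated(key)
  s_vals <- sample_spatial_field(
    em$lon[uk], em$lat[uk], params$sigma_s, params$rho,
    group = gr[uk]
  )
  names(s_vals) <- key[uk]
  eta <- eta + s_vals[key]

  mu <- exp(unname(eta))
  em$bycatch_count <- rnbinom(nrow(em), size = params$theta, mu = mu)
  attr(em, "latents") <- list(
    b_vessel = b_vessel, b_year = b_year, spatial = s_vals, mu = mu
  )
  em
}
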