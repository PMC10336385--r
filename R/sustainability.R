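# rounding half away from zero, the convention that reproduces every printed
# limit in the assessment table (base round() is banker's rounding)
.round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Area-corrected abundance
#'
#' Abundance re-estimated from a survey density over the surface actually
#' sampled for bycatch: the Kattegat (20 536 km2), the Sound (2 281 km2) and
#' the Belt Seas (17 862 km2) by default.
#'
#' @param density Individuals per km2, >= 0.
#' @param areas Named numeric vector of surface areas (km2), > 0.
#' @return Integer abundance `round(density * sum(areas))`.
#' @export
#' @examples
#' area_corrected_abundance(0.41) # 16678
area_corrected_abundance <- function(density, areas = western_baltic_areas()) {
  if (any(density < 0)) stop("density must be >= 0", call. = FALSE)
  stopifnot(all(areas > 0))
  .round_half_up(density * sum(areas))
}

#' @rdname area_corrected_abundance
#' @export
western_baltic_areas <- function() {
  c(Kattegat = 20536, Sound = 2281, `Belt Seas` = 17862)
}

#' Minimum population estimate
#'
#' The 20th-percentile abundance of the PBR framework:
#' `N_min = N / exp(z * sqrt(log(1 + CV^2)))` with `z = 0.842`.
#'
#' @param N Abundance estimate, >= 0.
#' @param CV Coefficient of variation of `N`, > 0.
#' @param z Standard-normal percentile factor (default 0.842, the 20th
#'   percentile).
#' @return Integer `N_min`.
#' @export
#' @examples
#' n_min(16678, 0.2) # 14116
n_min <- function(N, CV, z = 0.842) {
  if (any(CV <= 0)) stop("CV must be > 0", call. = FALSE)
  if (any(N < 0)) stop("N must be >= 0", call. = FALSE)
  .round_half_up(N / exp(z * sqrt(log(1 + CV^2))))
}

#' PBR / mPBR removal limit
#'
#' `limit = N_min * Rmax/2 * Fr`, rounded half away from zero. `Fr = 0.5` or
#' `1.0` gives the classical PBR thresholds; the retuned (restoration
#' objective) mPBR variants use smaller recovery factors such as 0.15 or
#' 0.35.
#'
#' @param N_min Minimum population estimate, > 0.
#' @param R_max Maximum net recruitment rate (default 0.04 for harbour
#'   porpoise).
#' @param F_r Recovery factor, > 0; values above 1 trigger a warning.
#' @return Integer removal limit (animals per year).
#' @export
#' @examples
#' removal_limit(26330, 0.04, 0.5) # 263
removal_limit <- function(N_min, R_max = 0.04, F_r = 0.5) {
  stopifnot(all(N_min > 0), all(R_max > 0), all(F_r > 0))
  if (any(F_r > 1)) {
    warning("recovery factor above 1 is outside the usual (0, 1] range",
      call. = FALSE
    )
  }
  .round_half_up(N_min * 0.5 * R_max * F_r)
}

#' Removal-limit table for a series of abundance surveys
#'
#' Computes abundance (area-corrected unless given), `N_min`, and the four
#' PBR/mPBR thresholds per survey year.
#'
#' @param surveys Data frame with `year`, `CV`, and either `density`
#'   (individuals/km2) or `N` (abundance taken as given).
#' @param areas Surface areas used for area correction.
#' @param R_max Maximum net recruitment rate.
#' @param z Percentile factor for `N_min`.
#' @return Tibble with `year`, `N`, `CV`, `N_min`, `PBR_Fr0.5`,
#'   `mPBR_Fr0.15`, `PBR_Fr1.0`, `mPBR_Fr0.35`.
#' @export
removal_limits_table <- function(surveys, areas = western_baltic_areas(),
                                 R_max = 0.04, z = 0.842) {
  stopifnot(all(c("year", "CV") %in% names(surveys)))
  N <- vapply(seq_len(nrow(surveys)), function(i) {
    if (!is.null(surveys$N) && !is.na(surveys$N[i])) {
      as.numeric(surveys$N[i])
    } else {
      area_corrected_abundance(surveys$density[i], areas)
    }
  }, numeric(1))
  Nm <- n_min(N, surveys$CV, z)
  tibble::tibble(
    year = surveys$year, N = N, CV = surveys$CV, N_min = Nm,
    PBR_Fr0.5 = removal_limit(Nm, R_max, 0.5),
    mPBR_Fr0.15 = removal_limit(Nm, R_max, 0.15),
    PBR_Fr1.0 = removal_limit(Nm, R_max, 1.0),
    mPBR_Fr0.35 = removal_limit(Nm, R_max, 0.35)
  )
}

#' Compare a bycatch estimate with removal limits
#'
#' Per-limit verdict for a matched year: whether the point estimate exceeds
#' the limit, and where the limit sits relative to the estimate's confidence
#' interval.
#'
#' @param estimate One-row data frame (or list) with `year`, `t_hat`,
#'   `ci_low`, `ci_high` for the assessed area.
#' @param limits One row of [removal_limits_table()] for the same year.
#' @return Tibble with one row per limit scheme: `scheme`, `limit`,
#'   `exceeds_point`, `limit_below_ci`, `limit_within_ci`.
#' @export
assess_sustainability <- function(estimate, limits) {
  if (!isTRUE(estimate$year == limits$year)) {
    stop("estimate year (", estimate$year, ") does not match limits year (",
      limits$year, ")",
      call. = FALSE
    )
  }
  schemes <- c("PBR_Fr0.5", "mPBR_Fr0.15", "PBR_Fr1.0", "mPBR_Fr0.35")
  est <- estimate$t_hat
  lo <- estimate$ci_low
  hi <- estimate$ci_high
  lim <- unname(vapply(schemes, function(s) as.numeric(limits[[s]]), numeric(1)))
  tibble::tibble(
    year = limits$year,
    scheme = schemes,
    limit = lim,
    estimate = est,
    exceeds_point = est > lim,
    limit_below_ci = lim < lo,
    limit_within_ci = lim >= lo & lim <= hi
  )
}
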