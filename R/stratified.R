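#' Stratified bycatch per unit effort from EM data
#'
#' Per-stratum ratio of summed observed bycatch to summed observed fishing
#' days, with strata defined by quarter and ICES area (the resolution of the
#' classical scaling-up estimator).
#'
#' @param em EMTable with `quarter`, `ices_area`, `bycatch_count`,
#'   `fishing_days`.
#' @param strata Character vector of stratification columns.
#' @return BPUE tibble: stratum columns, `observed_days`,
#'   `observed_bycatch`, `bpue` (`NaN` where no days observed, with a
#'   warning).
#' @export
compute_bpue <- function(em, strata = c("quarter", "ices_area")) {
  .check_effort_table(em, c(strata, "bycatch_count", "fishing_days"), "EM table")
  out <- em |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
    dplyr::summarise(
      observed_days = sum(.data$fishing_days),
      observed_bycatch = sum(.data$bycatch_count),
      .groups = "drop"
    )
  out$bpue <- out$observed_bycatch / out$observed_days
  if (any(out$observed_days == 0)) {
    warning("stratum with zero observed days yields NaN BPUE", call. = FALSE)
  }
  out
}

#' Raise stratified BPUE to fleet-level total bycatch
#'
#' Multiplies each stratum's EM bycatch rate by the fleet fishing days in
#' that stratum and sums. Fleet strata without a defined BPUE are a hard
#' error unless `unobserved = "zero"` treats them as zero-bycatch.
#'
#' @param bpue Output of [compute_bpue()].
#' @param effort Fleet EffortTable.
#' @param strata Stratification columns (must match `bpue`).
#' @param unobserved `"error"` (default) or `"zero"`.
#' @return List with `total` (point estimate), and `by_stratum` tibble
#'   (`fleet_days`, `bpue`, `expected_bycatch`).
#' @export
raise_to_fleet <- function(bpue, effort, strata = c("quarter", "ices_area"),
                           unobserved = c("error", "zero")) {
  unobserved <- match.arg(unobserved)
  fleet <- effort |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
    dplyr::summarise(fleet_days = sum(.data$fishing_days), .groups = "drop")
  tab <- dplyr::left_join(fleet, bpue, by = strata)
  bad <- is.na(tab$bpue) | is.nan(tab$bpue)
  if (any(bad)) {
    if (unobserved == "error") {
      stop(
        "fleet strata without EM-observed BPUE: ",
        paste(do.call(paste, tab[bad, strata]), collapse = "; "),
        "; set unobserved = \"zero\" to zero-fill",
        call. = FALSE
      )
    }
    tab$bpue[bad] <- 0
  }
  tab$expected_bycatch <- tab$bpue * tab$fleet_days
  list(total = sum(tab$expected_bycatch), by_stratum = tab)
}

#' Non-parametric bootstrap interval for the raised total
#'
#' Resamples EM fishing-day rows with replacement within each stratum,
#' recomputes the raised fleet total `B` times, and reports the percentile
#' 2.5/97.5% interval. Strata with a single EM row resample trivially (their
#' contribution has no resampling variance) and are flagged with a warning.
#'
#' @param em EMTable.
#' @param effort Fleet EffortTable.
#' @param B Number of bootstrap replicates (>= 1; the reporting default in
#'   this field is 1e5, tests use far fewer).
#' @param seed Integer seed.
#' @param strata Stratification columns.
#' @param unobserved Passed to [raise_to_fleet()].
#' @param block_by_vessel If `TRUE`, resample whole vessels within stratum
#'   instead of fishing-day rows.
#' @return A raised-estimate list: `total`, `ci_low`, `ci_high`,
#'   `n_bootstrap`, `by_stratum`, `boot_totals`.
#' @export
bootstrap_raised_ci <- function(em, effort, B = 5000L, seed = 1L,
                                strata = c("quarter", "ices_area"),
                                unobserved = c("error", "zero"),
                                block_by_vessel = FALSE) {
  stopifnot(B >= 1)
  unobserved <- match.arg(unobserved)
  point <- raise_to_fleet(compute_bpue(em, strata), effort, strata, unobserved)
  set.seed(seed)
  skey <- do.call(paste, c(em[strata], sep = "\r"))
  fleet <- point$by_stratum
  fkey <- do.call(paste, c(fleet[strata], sep = "\r"))
  boot <- numeric(B)
  singletons <- FALSE
  for (s in unique(skey)) {
    rows <- which(skey == s)
    fd <- fleet$fleet_days[match(s, fkey)]
    if (is.na(fd) || fd == 0) next
    if (block_by_vessel) {
      counts <- as.vector(rowsum(em$bycatch_count[rows], em$vessel_id[rows]))
      days <- as.vector(rowsum(em$fishing_days[rows], em$vessel_id[rows]))
    } else {
      counts <- em$bycatch_count[rows]
      days <- em$fishing_days[rows]
    }
    n_s <- length(counts)
    if (n_s == 1) singletons <- TRUE
    idx <- matrix(sample.int(n_s, n_s * B, replace = TRUE), n_s, B)
    num <- colSums(matrix(counts[idx], n_s, B))
    den <- colSums(matrix(days[idx], n_s, B))
    boot <- boot + fd * num / den
  }
  if (singletons) {
    warning("stratum with a single EM row: trivial resampling", call. = FALSE)
  }
  ci <- unname(quantile(boot, c(0.025, 0.975)))
  list(
    total = point$total, ci_low = ci[1], ci_high = ci[2],
    n_bootstrap = B, by_stratum = point$by_stratum, boot_totals = boot
  )
}
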