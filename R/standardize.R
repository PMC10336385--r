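# term-grouping used to split the linear predictor into an effort-related
# part (what the fleet does) and a porpoise-related part (where and when the
# animals are). Depth is grouped with the porpoise terms by default since
# rectangle depth proxies habitat rather than gear; the grouping is a plain
# character-vector argument and can be reassigned.

#' Default term grouping for standardization
#' @return Named list with `effort` and `porpoise` character vectors covering
#'   fixed terms, the intercept, and the random terms (`vessel`, `year`,
#'   `spatial`).
#' @export
default_term_grouping <- function() {
  list(
    effort = c(
      "(Intercept)", "mesh_class", "vessel_class", "log_net_length",
      "log_soak_time", "mesh_class:log_soak_time", "vessel"
    ),
    porpoise = c("population", "log_depth", "year", "spatial")
  )
}

#' Link-scale decomposition of predictions into effort and porpoise parts
#'
#' Splits each row's linear predictor `eta = eta_effort + eta_porpoise`
#' according to a term grouping. Latent terms use their conditional modes;
#' levels unseen at fit time contribute 0. By construction
#' `exp(eta_effort) * exp(eta_porpoise) = exp(eta)`, the (plug-in)
#' unstandardized prediction.
#'
#' @param fit A `bycatch_glmm` fit.
#' @param newdata EffortTable-like data frame.
#' @param grouping Named list as [default_term_grouping()].
#' @return Tibble with `eta_effort`, `eta_porpoise`, `eta_total`.
#' @export
linkscale_components <- function(fit, newdata,
                                 grouping = default_term_grouping()) {
  all_terms <- c("(Intercept)", fit$spec$fixed, names(fit$u_hat))
  missing_terms <- setdiff(all_terms, c(grouping$effort, grouping$porpoise))
  if (length(missing_terms) > 0) {
    stop("term grouping does not cover: ",
      paste(missing_terms, collapse = ", "),
      call. = FALSE
    )
  }
  map <- .newdata_map(fit, newdata)
  col_term <- attr(map$X, "assign_terms")
  eta_e <- drop(map$X[, col_term %in% grouping$effort, drop = FALSE] %*%
    fit$beta[col_term %in% grouping$effort])
  eta_p <- drop(map$X[, col_term %in% grouping$porpoise, drop = FALSE] %*%
    fit$beta[col_term %in% grouping$porpoise])
  for (nm in names(map$idx)) {
    ii <- map$idx[[nm]]
    contrib <- numeric(map$m)
    contrib[!is.na(ii)] <- fit$state$u[ii[!is.na(ii)]]
    if (nm %in% grouping$effort) {
      eta_e <- eta_e + contrib
    } else {
      eta_p <- eta_p + contrib
    }
  }
  tibble::tibble(
    eta_effort = eta_e, eta_porpoise = eta_p,
    eta_total = eta_e + eta_p
  )
}

#' Standardized effort index
#'
#' Predicted bycatch with all porpoise-related terms frozen at a constant
#' (default: the median of the rows' porpoise-part linear predictor), summed
#' by axis. The result is proportional to the bycatch the observed effort
#' would inflict per unit of porpoise density: a relative index, meaningful
#' only up to a common factor.
#'
#' @param fit A `bycatch_glmm` fit.
#' @param effort EffortTable of the rows to standardize over.
#' @param by Character vector of columns defining the index axis.
#' @param constant Link-scale constant for the frozen porpoise part (default
#'   the median of its per-row values).
#' @param grouping Term grouping, as [default_term_grouping()].
#' @return Tibble with the axis columns, `value`, `kind`, `constant`.
#' @export
standardized_effort <- function(fit, effort, by = "year", constant = NULL,
                                grouping = default_term_grouping()) {
  comp <- linkscale_components(fit, effort, grouping)
  if (is.null(constant)) constant <- median(comp$eta_porpoise)
  key <- do.call(paste, c(effort[by], sep = "\r"))
  vals <- rowsum(exp(comp$eta_effort + constant), key)
  out <- .axis_tibble(rownames(vals), by)
  out$value <- as.vector(vals)
  out$kind <- "standardized_effort"
  out$constant <- constant
  out
}

#' Standardized BPUE (relative porpoise density) index
#'
#' The complement of [standardized_effort()]: the effort-related terms are
#' frozen at a constant (default the median of the rows' effort-part linear
#' predictor) and the porpoise-related part varies, giving a relative index
#' of porpoise bycatch rate per unit effort over years and/or space.
#'
#' @inheritParams standardized_effort
#' @param grid EffortTable-like rows (e.g. one per year x rectangle) at which
#'   to evaluate the index.
#' @param average If `TRUE` (default) the index is the group mean rather than
#'   the group sum, so an axis cell's value does not scale with how many rows
#'   represent it.
#' @return Tibble with the axis columns, `value`, `kind`, `constant`.
#' @export
standardized_bpue <- function(fit, grid, by = c("year"), constant = NULL,
                              grouping = default_term_grouping(),
                              average = TRUE) {
  comp <- linkscale_components(fit, grid, grouping)
  if (is.null(constant)) constant <- median(comp$eta_effort)
  key <- do.call(paste, c(grid[by], sep = "\r"))
  vals <- rowsum(exp(comp$eta_porpoise + constant), key)
  if (average) vals <- vals / as.vector(table(key)[rownames(vals)])
  out <- .axis_tibble(rownames(vals), by)
  out$value <- as.vector(vals)
  out$kind <- "standardized_bpue"
  out$constant <- constant
  out
}

.axis_tibble <- function(keys, by) {
  kk <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- tibble::tibble(.rows = length(keys))
  for (j in seq_along(by)) {
    out[[by[j]]] <- utils::type.convert(kk[, j], as.is = TRUE)
  }
  out
}
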