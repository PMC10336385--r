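#' Specify a bycatch model
#'
#' Declares the structure of the NB2 log-link mixed model: which fixed terms
#' enter, which random intercepts (vessel and/or year), and how the spatial
#' random field is grouped in time. `spatial_grouping = "quarter_within_year"`
#' gives one independent field realization per quarter of each year (up to 44
#' groups over an eleven-year series), all sharing one (`sigma_s`, `rho`).
#'
#' @param fixed Character vector of fixed-effect terms, a subset of
#'   `mesh_class`, `vessel_class`, `population`, `log_net_length`,
#'   `log_soak_time`, `log_depth`, `mesh_class:log_soak_time`.
#' @param random Character vector of random intercepts, a subset of
#'   `c("vessel", "year")`.
#' @param spatial_grouping One of `"none"`, `"year"`, `"quarter"`,
#'   `"quarter_within_year"`.
#' @param family `"nb2"` (the bycatch model) or `"gaussian"` (identity-link
#'   toy family used for validating the Laplace machinery).
#' @return A list of class `bycatch_model_spec`.
#' @export
bycatch_model_spec <- function(fixed = c(
                                 "mesh_class", "vessel_class", "population",
                                 "log_net_length", "log_soak_time",
                                 "log_depth", "mesh_class:log_soak_time"
                               ),
                               random = "year",
                               spatial_grouping = "quarter_within_year",
                               family = "nb2") {
  allowed_fixed <- c(
    "mesh_class", "vessel_class", "population", "log_net_length",
    "log_soak_time", "log_depth", "mesh_class:log_soak_time"
  )
  bad <- setdiff(fixed, allowed_fixed)
  if (length(bad) > 0) {
    stop("unknown fixed term(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("mesh_class:log_soak_time" %in% fixed &&
    !all(c("mesh_class", "log_soak_time") %in% fixed)) {
    stop("the mesh_class:log_soak_time interaction requires both main effects",
      call. = FALSE
    )
  }
  bad <- setdiff(random, c("vessel", "year"))
  if (length(bad) > 0) {
    stop("unknown random term(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  spatial_grouping <- match.arg(
    spatial_grouping,
    c("none", "year", "quarter", "quarter_within_year")
  )
  structure(
    list(
      fixed = fixed, random = random, spatial_grouping = spatial_grouping,
      family = match.arg(family, c("nb2", "gaussian"))
    ),
    class = "bycatch_model_spec"
  )
}

# fixed-effects model matrix with fixed factor levels and treatment coding;
# reference levels: "<120 mm", "<8 m", "North Sea Population"
.fixed_design_matrix <- function(data, fixed = c(
                                   "mesh_class", "vessel_class", "population",
                                   "log_net_length", "log_soak_time",
                                   "log_depth", "mesh_class:log_soak_time"
                                 )) {
  df <- data.frame(row.names = seq_len(nrow(data)))
  fac_specs <- list(
    mesh_class = .mesh_levels, vessel_class = .vessel_levels,
    population = .population_levels
  )
  log_specs <- c(
    log_net_length = "net_length_m", log_soak_time = "soak_time_h",
    log_depth = "depth_m"
  )
  vars <- unique(unlist(strsplit(fixed, ":", fixed = TRUE)))
  for (v in vars) {
    if (v %in% names(fac_specs)) {
      vals <- data[[v]]
      unseen <- setdiff(unique(as.character(vals)), fac_specs[[v]])
      if (length(unseen) > 0) {
        stop("unknown level(s) in '", v, "': ",
          paste(unseen, collapse = ", "),
          call. = FALSE
        )
      }
      df[[v]] <- factor(vals, levels = fac_specs[[v]])
    } else if (v %in% names(log_specs)) {
      raw <- data[[log_specs[[v]]]]
      .check_positive(raw, log_specs[[v]])
      df[[v]] <- log(raw)
    } else {
      stop("unknown design variable: ", v, call. = FALSE)
    }
  }
  if (length(fixed) == 0) {
    return(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")))
  }
  form <- stats::as.formula(paste("~", paste(fixed, collapse = " + ")))
  X <- model.matrix(form, df)
  attr(X, "assign_terms") <- c("(Intercept)", fixed)[attr(X, "assign") + 1L]
  X
}

# spatial group label per row, or NULL when the spec has no field
.spatial_group <- function(data, grouping) {
  switch(grouping,
    none = NULL,
    year = as.character(data$year),
    quarter = paste0("Q", data$quarter),
    quarter_within_year = paste0(data$year, ":Q", data$quarter)
  )
}

#' Build design matrices for the bycatch mixed model
#'
#' Constructs the response vector, the treatment-coded fixed-effects matrix
#' (continuous covariates entered on the log scale), the sparse random-effects
#' incidence matrix, and the latent-block layout (iid intercept blocks, then
#' one spatial block per grouping level over the distinct rectangle centroids,
#' with their great-circle distance matrix).
#'
#' @param em EMTable with `bycatch_count` (or a `response` column for the
#'   Gaussian toy family).
#' @param spec A [bycatch_model_spec()].
#' @return A list of class `bycatch_design` with elements `y`, `X`, `Zt`,
#'   `blocks`, `n`, `p`, `q`, `spec`, and per-block metadata.
#' @export
build_design <- function(em, spec = bycatch_model_spec()) {
  stopifnot(inherits(spec, "bycatch_model_spec"))
  resp_col <- if (spec$family == "nb2") "bycatch_count" else "response"
  if (!resp_col %in% names(em)) {
    stop("response column '", resp_col, "' not found", call. = FALSE)
  }
  y <- em[[resp_col]]
  if (spec$family == "nb2" && (any(y < 0) || any(y != round(y)))) {
    stop("bycatch_count must be non-negative integers", call. = FALSE)
  }
  X <- .fixed_design_matrix(em, spec$fixed)
  if (qr(X)$rank < ncol(X)) {
    stop("fixed-effects design matrix is rank deficient", call. = FALSE)
  }
  n <- nrow(X)

  blocks <- list()
  zi <- integer(0) # latent index of each Z entry
  zj <- integer(0) # row index
  offset <- 0L
  for (term in spec$random) {
    key <- if (term == "vessel") {
      as.character(em$vessel_id)
    } else {
      as.character(em$year)
    }
    lev <- sort(unique(key))
    blocks[[term]] <- list(
      type = "iid", name = term, levels = lev,
      idx = offset + seq_along(lev)
    )
    zi <- c(zi, offset + match(key, lev))
    zj <- c(zj, seq_len(n))
    offset <- offset + length(lev)
  }
  if (spec$spatial_grouping != "none") {
    gr <- .spatial_group(em, spec$spatial_grouping)
    groups <- sort(unique(gr))
    rect <- sort(unique(em$rectangle_code))
    cent <- em[match(rect, em$rectangle_code), c("lon", "lat")]
    D <- .distance_km(cent$lon, cent$lat)
    r <- length(rect)
    # latent layout: all rectangles for group 1, then group 2, ...
    blocks[["spatial"]] <- list(
      type = "spatial", name = "spatial", groups = groups, rect = rect,
      lon = cent$lon, lat = cent$lat, D = D,
      idx = offset + seq_len(r * length(groups))
    )
    zi <- c(zi, offset + (match(gr, groups) - 1L) * r +
      match(em$rectangle_code, rect))
    zj <- c(zj, seq_len(n))
    offset <- offset + r * length(groups)
  }
  Zt <- if (offset > 0) {
    sparseMatrix(
      i = zi, j = zj, x = 1,
      dims = c(offset, n)
    )
  } else {
    NULL
  }
  structure(
    list(
      y = y, X = X, Zt = Zt, blocks = blocks,
      n = n, p = ncol(X), q = offset, spec = spec,
      family = .get_family(spec$family)
    ),
    class = "bycatch_design"
  )
}
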