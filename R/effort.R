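#' Bin mesh sizes and vessel lengths into reporting classes
#'
#' Mesh classes: `"<120 mm"` = [0, 120), `"120-200"` = [120, 200],
#' `">200 mm"` = (200, Inf). Vessel classes are half-open on the left:
#' [8, 10), [10, 12), [12, 15). The printed class labels leave the boundary
#' assignment open; these conventions are fixed here and documented.
#'
#' @param mesh_size_mm,vessel_length_m Numeric vectors.
#' @return Character vector of class labels.
#' @export
mesh_class_of <- function(mesh_size_mm) {
  stopifnot(all(mesh_size_mm > 0))
  cut(mesh_size_mm,
    breaks = c(0, 120, 200 + 1e-9, Inf), right = FALSE,
    labels = .mesh_levels
  ) |> as.character()
}

#' @rdname mesh_class_of
#' @export
vessel_class_of <- function(vessel_length_m) {
  stopifnot(all(vessel_length_m > 0))
  cut(vessel_length_m,
    breaks = c(0, 8, 10, 12, 15, Inf), right = FALSE,
    labels = .vessel_levels
  ) |> as.character()
}

#' Collapse raw landing lines to the vessel-day-rectangle resolution
#'
#' Applies the harmonization rules of the effort census: one output row per
#' unique (vessel, date, rectangle); when several mesh sizes are reported for
#' the same stratum only the mesh of the main target (largest summed landed
#' weight) is kept, soak-time is averaged, and net-length is summed. Weight
#' ties go to the larger mesh. Quarter is derived from the calendar month.
#'
#' @param raw Data frame of raw records: `vessel_id`, `date` (ISO-8601),
#'   `rectangle_code`, `mesh_size_mm`, `landed_weight_kg`, `soak_time_h`,
#'   `net_length_m`, `vessel_length_m`; optional `ices_area`.
#' @param area_map Optional data frame `rectangle_code` -> `ices_area` used
#'   when `raw` lacks `ices_area`.
#' @return EffortTable rows (without `depth_m`, which [assign_depth()] adds;
#'   `pinger_mandatory` initialized to `FALSE`).
#' @export
collapse_to_strata <- function(raw, area_map = NULL) {
  need <- c(
    "vessel_id", "date", "rectangle_code", "mesh_size_mm",
    "landed_weight_kg", "vessel_length_m"
  )
  .check_effort_table(raw, need, "raw effort table")
  date <- as.Date(raw$date)
  if (anyNA(date)) stop("unparseable date(s) in raw effort", call. = FALSE)
  stopifnot(all(raw$mesh_size_mm > 0), all(raw$landed_weight_kg >= 0))
  if (!"soak_time_h" %in% names(raw)) raw$soak_time_h <- NA_real_
  if (!"net_length_m" %in% names(raw)) raw$net_length_m <- NA_real_
  raw$date <- date

  out <- raw |>
    dplyr::group_by(.data$vessel_id, .data$date, .data$rectangle_code) |>
    dplyr::summarise(
      mesh_size_mm = {
        w <- tapply(.data$landed_weight_kg, .data$mesh_size_mm, sum)
        cand <- as.numeric(names(w)[w == max(w)])
        max(cand) # tie: keep the larger mesh
      },
      soak_time_h = if (all(is.na(.data$soak_time_h))) NA_real_ else
        mean(.data$soak_time_h, na.rm = TRUE),
      net_length_m = if (all(is.na(.data$net_length_m))) NA_real_ else
        sum(.data$net_length_m, na.rm = TRUE),
      vessel_length_m = .data$vessel_length_m[1],
      .groups = "drop"
    )
  geo <- ices_rect_geometry(out$rectangle_code)
  out$lon <- geo$lon
  out$lat <- geo$lat
  if (!"ices_area" %in% names(raw)) {
    if (is.null(area_map)) {
      stop("provide 'ices_area' in raw or an area_map", call. = FALSE)
    }
    out$ices_area <- area_map$ices_area[
      match(out$rectangle_code, area_map$rectangle_code)
    ]
  } else {
    key <- paste(raw$vessel_id, raw$date, raw$rectangle_code)
    out$ices_area <- raw$ices_area[
      match(paste(out$vessel_id, out$date, out$rectangle_code), key)
    ]
  }
  tibble::tibble(
    vessel_id = out$vessel_id,
    year = as.integer(format(out$date, "%Y")),
    quarter = (as.integer(format(out$date, "%m")) - 1L) %/% 3L + 1L,
    date = out$date,
    rectangle_code = out$rectangle_code,
    lon = out$lon, lat = out$lat,
    ices_area = out$ices_area,
    mesh_class = mesh_class_of(out$mesh_size_mm),
    vessel_class = vessel_class_of(out$vessel_length_m),
    population = population_of_area(out$ices_area),
    soak_time_h = out$soak_time_h,
    net_length_m = out$net_length_m,
    fishing_days = 1,
    pinger_mandatory = FALSE
  )
}

#' Fill missing soak-time and net-length from an EM reference fleet
#'
#' Vessels without reported gear details inherit the stratum means
#' (stratum = mesh class x vessel class) of the EM-monitored reference
#' records; strata absent from the reference fall back to a table of expert
#' values. A `soak_source` / `net_source` provenance column records where
#' each value came from (`reported`, `reference`, `fallback`).
#'
#' @param effort EffortTable possibly with `NA` soak/net values.
#' @param reference_em EMTable (or EffortTable) of the reference fleet with
#'   reported `soak_time_h` and `net_length_m`.
#' @param fallback Optional data frame `mesh_class`, `vessel_class`,
#'   `soak_time_h`, `net_length_m` of expert values.
#' @return EffortTable with complete soak/net columns plus provenance.
#' @export
impute_effort_covariates <- function(effort, reference_em, fallback = NULL) {
  if (nrow(reference_em) == 0) {
    stop("reference EM table is empty", call. = FALSE)
  }
  ref <- reference_em |>
    dplyr::group_by(.data$mesh_class, .data$vessel_class) |>
    dplyr::summarise(
      ref_soak = mean(.data$soak_time_h, na.rm = TRUE),
      ref_net = mean(.data$net_length_m, na.rm = TRUE),
      .groups = "drop"
    )
  out <- dplyr::left_join(effort, ref, by = c("mesh_class", "vessel_class"))
  if (!is.null(fallback)) {
    fb <- dplyr::rename(fallback,
      fb_soak = "soak_time_h",
      fb_net = "net_length_m"
    )
    out <- dplyr::left_join(out, fb, by = c("mesh_class", "vessel_class"))
  } else {
    out$fb_soak <- NA_real_
    out$fb_net <- NA_real_
  }
  fill <- function(x, ref, fb) {
    src <- rep("reported", length(x))
    use_ref <- is.na(x) & !is.na(ref)
    x[use_ref] <- ref[use_ref]
    src[use_ref] <- "reference"
    use_fb <- is.na(x) & !is.na(fb)
    x[use_fb] <- fb[use_fb]
    src[use_fb] <- "fallback"
    list(x = x, src = src)
  }
  s <- fill(out$soak_time_h, out$ref_soak, out$fb_soak)
  n <- fill(out$net_length_m, out$ref_net, out$fb_net)
  if (anyNA(s$x) || anyNA(n$x)) {
    bad <- unique(paste(out$mesh_class, out$vessel_class)[
      is.na(s$x) | is.na(n$x)
    ])
    stop("no reference or fallback value for strata: ",
      paste(bad, collapse = "; "),
      call. = FALSE
    )
  }
  out$soak_time_h <- s$x
  out$net_length_m <- n$x
  out$soak_source <- s$src
  out$net_source <- n$src
  out$ref_soak <- out$ref_net <- out$fb_soak <- out$fb_net <- NULL
  out
}

#' Assign rectangle mean depths
#'
#' @param effort EffortTable.
#' @param bathymetry Data frame `rectangle_code`, `depth_m` (mean rectangle
#'   depth, m, > 0).
#' @return EffortTable with `depth_m` set.
#' @export
assign_depth <- function(effort, bathymetry) {
  i <- match(effort$rectangle_code, bathymetry$rectangle_code)
  if (anyNA(i)) {
    stop("no depth for rectangle(s): ",
      paste(unique(effort$rectangle_code[is.na(i)]), collapse = ", "),
      call. = FALSE
    )
  }
  d <- bathymetry$depth_m[i]
  .check_positive(d, "depth_m")
  effort$depth_m <- d
  effort
}

#' Expand monthly declarations to home-harbour fishing-day rows
#'
#' Small vessels reporting monthly totals without positions have their
#' effort allocated to the rectangle of their home harbour: a record with
#' `n` fishing days becomes `n` daily rows in that rectangle.
#'
#' @param monthly Data frame with `vessel_id`, `year`, `month`,
#'   `fishing_days`, `home_harbour_rectangle`, plus any covariate columns to
#'   carry through (e.g. `mesh_class`, `vessel_class`).
#' @return Tibble of day rows with `rectangle_code` set to the home-harbour
#'   rectangle, `quarter` derived from the month, and `fishing_days = 1`.
#' @export
allocate_home_harbour <- function(monthly) {
  need <- c("vessel_id", "year", "month", "fishing_days",
    "home_harbour_rectangle")
  .check_effort_table(monthly, need, "monthly declaration table")
  if (anyNA(monthly$home_harbour_rectangle)) {
    stop("missing home harbour rectangle", call. = FALSE)
  }
  idx <- rep(seq_len(nrow(monthly)), monthly$fishing_days)
  out <- tibble::as_tibble(monthly[idx, , drop = FALSE])
  out$rectangle_code <- out$home_harbour_rectangle
  out$quarter <- (out$month - 1L) %/% 3L + 1L
  out$fishing_days <- if (nrow(out) > 0) 1 else numeric(0)
  geo <- ices_rect_geometry(out$rectangle_code)
  out$lon <- geo$lon
  out$lat <- geo$lat
  out$home_harbour_rectangle <- NULL
  out
}

#' Remove effort rows where pinger use is mandatory
#'
#' The pinger regulations are encoded as data, not code: each rule row scopes
#' an ICES area, a set of vessel classes, a set of mesh classes and a set of
#' quarters (semicolon-separated, `*` = any). Rows matching any rule are
#' removed (assuming compliant pinger use eliminates bycatch on them); the
#' removed count is reported via a message.
#'
#' @param effort EffortTable.
#' @param rules Data frame with columns `ices_area`, `vessel_classes`,
#'   `mesh_classes`, `quarters`; see [default_pinger_rules()].
#' @return The subset of `effort` with mandatory-pinger rows removed and
#'   `pinger_mandatory` updated on the attribute `"removed"`.
#' @export
filter_pinger_mandatory <- function(effort, rules) {
  if (is.null(rules) || nrow(rules) == 0) {
    return(effort)
  }
  split_set <- function(s) strsplit(as.character(s), ";", fixed = TRUE)[[1]]
  hit <- rep(FALSE, nrow(effort))
  for (r in seq_len(nrow(rules))) {
    m <- effort$ices_area == rules$ices_area[r]
    vc <- split_set(rules$vessel_classes[r])
    if (!identical(vc, "*")) m <- m & effort$vessel_class %in% vc
    mc <- split_set(rules$mesh_classes[r])
    if (!identical(mc, "*")) m <- m & effort$mesh_class %in% mc
    qq <- split_set(rules$quarters[r])
    if (!identical(qq, "*")) m <- m & effort$quarter %in% as.integer(qq)
    hit <- hit | m
  }
  message(sum(hit), " of ", nrow(effort),
    " effort rows fall under mandatory pinger rules and were removed"
  )
  out <- effort[!hit, , drop = FALSE]
  attr(out, "removed") <- sum(hit)
  out
}

#' Shipped approximation of the EU pinger-regulation scope
#'
#' An editable encoding of the mandatory acoustic-deterrent scope (large
#' vessels in the North Sea and Skagerrak gillnet fisheries); adjust to the
#' legal text in force before operational use.
#'
#' @return Rules tibble for [filter_pinger_mandatory()].
#' @export
default_pinger_rules <- function() {
  tibble::tribble(
    ~ices_area, ~vessel_classes, ~mesh_classes, ~quarters,
    "IVb", "12-15 m;>15 m", "*", "*",
    "IIIa20", "12-15 m;>15 m", "*", "3;4"
  )
}
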