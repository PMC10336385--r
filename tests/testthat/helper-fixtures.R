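# shared fixtures: small synthetic fleets and toy tables built in code

small_sim <- function(seed = 7, n_vessels = 17, years = 2010:2012,
                      days = 40, em_fraction = 1) {
  sim_config(
    n_vessels = n_vessels, years = years,
    n_days_per_vessel_year = days, em_fraction = em_fraction, seed = seed
  )
}

small_em <- function(seed = 7, sim_seed = 3, ...) {
  cfg <- small_sim(seed = seed, ...)
  simulate_bycatch(generate_fleet_effort(cfg), true_params(), seed = sim_seed)
}

# minimal effort-like frame with constant covariates, for toy designs
toy_rows <- function(n, year = 2010L, quarter = 1L, soak = NULL,
                     rect = "39F7") {
  geo <- ices_rect_geometry(rect)
  tibble::tibble(
    vessel_id = "V1", year = year, quarter = quarter,
    rectangle_code = rect, lon = geo$lon[1], lat = geo$lat[1],
    ices_area = "IVb", mesh_class = "<120 mm", vessel_class = "<8 m",
    population = "North Sea Population",
    soak_time_h = if (is.null(soak)) rep(20, n) else soak,
    net_length_m = 1000, depth_m = 30, fishing_days = 1,
    pinger_mandatory = FALSE
  )
}
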