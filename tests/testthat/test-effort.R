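test_that("ICES rectangle geometry follows the coding rule", {
  g <- ices_rect_geometry("37F7")
  expect_equal(g$lat_min, 54.0)
  expect_equal(g$lat_max, 54.5)
  expect_equal(g$lon_min, 7)
  expect_equal(g$lon_max, 8)
  expect_equal(g$lon, 7.5)
  expect_equal(g$lat, 54.25)
  # round trip through the centroid
  expect_equal(ices_rect_code(g$lon, g$lat), "37F7")
  rects <- default_rectangles()$rectangle_code
  gg <- ices_rect_geometry(rects)
  expect_equal(ices_rect_code(gg$lon, gg$lat), rects)
  # the letter I is skipped: J continues east of H
  expect_equal(ices_rect_geometry("40J0")$lon_min, 30)
  expect_error(ices_rect_geometry("00Z9"), "malformed")
  expect_error(ices_rect_geometry("7F37"), "malformed")
  expect_error(ices_rect_code(7.5, 20), "latitude")
})

test_that("collapse keeps the dominant-landings mesh and pools gear", {
  raw <- tibble::tibble(
    vessel_id = "A", date = "2015-05-03", rectangle_code = "39F7",
    mesh_size_mm = c(110, 130), landed_weight_kg = c(40, 60),
    soak_time_h = c(20, 30), net_length_m = c(1000, 2000),
    vessel_length_m = 9.5, ices_area = "IVb"
  )
  s <- collapse_to_strata(raw)
  expect_equal(nrow(s), 1)
  expect_equal(s$mesh_class, "120-200")
  expect_equal(s$soak_time_h, 25)
  expect_equal(s$net_length_m, 3000)
  expect_equal(s$vessel_class, "8-10 m")
  expect_equal(s$quarter, 2L)
  # weight tie goes to the larger mesh
  raw$landed_weight_kg <- c(50, 50)
  expect_equal(collapse_to_strata(raw)$mesh_class, "120-200")
  # single record is unchanged apart from binning
  s1 <- collapse_to_strata(raw[1, ])
  expect_equal(s1$mesh_class, "<120 mm")
  expect_equal(s1$soak_time_h, 20)
  # class boundaries: 120 inclusive below, 200 inclusive, 200+ above
  expect_equal(mesh_class_of(c(119.9, 120, 200, 200.1)),
    c("<120 mm", "120-200", "120-200", ">200 mm")
  )
  expect_equal(vessel_class_of(c(7.9, 8, 10, 12, 15, 15.1)),
    c("<8 m", "8-10 m", "10-12 m", "12-15 m", ">15 m", ">15 m")
  )
})

test_that("collapse conserves fishing days per vessel", {
  set.seed(5)
  n <- 60
  raw <- tibble::tibble(
    vessel_id = sample(c("A", "B", "C"), n, TRUE),
    date = as.character(as.Date("2015-01-01") + sample(0:9, n, TRUE)),
    rectangle_code = sample(c("39F7", "40F6"), n, TRUE),
    mesh_size_mm = sample(c(100, 130, 220), n, TRUE),
    landed_weight_kg = runif(n, 0, 100),
    soak_time_h = runif(n, 10, 40), net_length_m = runif(n, 500, 3000),
    vessel_length_m = 9, ices_area = "IVb"
  )
  s <- collapse_to_strata(raw)
  days_raw <- nrow(unique(raw[, c("vessel_id", "date", "rectangle_code")]))
  expect_equal(sum(s$fishing_days), days_raw)
  expect_equal(nrow(s), days_raw)
})

test_that("reference-fleet imputation fills by stratum with provenance", {
  eff <- toy_rows(3)
  eff$mesh_class <- c("<120 mm", "<120 mm", ">200 mm")
  eff$soak_time_h <- c(18, NA, NA)
  eff$net_length_m <- c(900, NA, NA)
  ref <- toy_rows(4)
  ref$soak_time_h <- c(20, 28, 30, 18) # stratum mean 24 for <120 mm x <8 m
  ref$net_length_m <- 2000
  fb <- tibble::tibble(
    mesh_class = ">200 mm", vessel_class = "<8 m",
    soak_time_h = 12, net_length_m = 500
  )
  out <- impute_effort_covariates(eff, ref, fb)
  expect_equal(out$soak_time_h, c(18, 24, 12))
  expect_equal(out$soak_source, c("reported", "reference", "fallback"))
  expect_equal(out$net_length_m, c(900, 2000, 500))
  # hard error when neither reference nor fallback covers a stratum
  expect_error(impute_effort_covariates(eff, ref), ">200 mm")
  expect_error(impute_effort_covariates(eff, ref[0, ], fb), "empty")
})

test_that("depth assignment validates the bathymetry map", {
  eff <- toy_rows(2, rect = "37G1")
  out <- assign_depth(eff, data.frame(rectangle_code = "37G1", depth_m = 25))
  expect_equal(out$depth_m, c(25, 25))
  expect_error(
    assign_depth(eff, data.frame(rectangle_code = "37G1", depth_m = 0)),
    "depth_m"
  )
  expect_error(
    assign_depth(eff, data.frame(rectangle_code = "40F6", depth_m = 10)),
    "37G1"
  )
})

test_that("home-harbour allocation expands and conserves fishing days", {
  mon <- tibble::tibble(
    vessel_id = c("B", "C"), year = 2015L, month = c(4L, 11L),
    fishing_days = c(8L, 0L), home_harbour_rectangle = "38G1",
    mesh_class = "<120 mm", vessel_class = "<8 m"
  )
  out <- allocate_home_harbour(mon)
  expect_equal(nrow(out), 8)
  expect_true(all(out$rectangle_code == "38G1"))
  expect_equal(unique(out$quarter), 2L)
  expect_equal(sum(out$fishing_days), sum(mon$fishing_days))
  mon$home_harbour_rectangle[1] <- NA
  expect_error(allocate_home_harbour(mon), "home harbour")
})

test_that("pinger filter removes exactly the scoped rows", {
  eff <- generate_fleet_effort(small_sim(seed = 3, n_vessels = 25, days = 10))
  expect_identical(filter_pinger_mandatory(eff, NULL), eff)
  all_rules <- tibble::tibble(
    ices_area = unique(eff$ices_area), vessel_classes = "*",
    mesh_classes = "*", quarters = "*"
  )
  expect_equal(
    nrow(suppressMessages(filter_pinger_mandatory(eff, all_rules))), 0
  )
  one <- tibble::tibble(
    ices_area = "IVb", vessel_classes = ">15 m",
    mesh_classes = "*", quarters = "*"
  )
  out <- suppressMessages(filter_pinger_mandatory(eff, one))
  removed <- dplyr::anti_join(eff, out, by = names(eff))
  expect_true(all(removed$ices_area == "IVb" & removed$vessel_class == ">15 m"))
  expect_equal(
    nrow(out),
    nrow(eff) - sum(eff$ices_area == "IVb" & eff$vessel_class == ">15 m")
  )
})

test_that("assessment-unit mapping is deterministic in the ICES area", {
  expect_equal(
    population_of_area(c("IVb", "IIIa20", "IIIa21", "IIIc22", "IIIb23")),
    c(rep("North Sea Population", 2), rep("Western Baltic Population", 3))
  )
  expect_error(population_of_area("27.3.a"), "unknown")
})
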