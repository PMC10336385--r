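#' ICES statistical rectangle geometry
#'
#' ICES statistical rectangles are 0.5 degree latitude by 1 degree longitude
#' reporting cells coded as two digits plus a letter plus a digit
#' (e.g. `"39F7"`). The two digits give the latitude band, counted in half
#' degrees northwards from 36 degrees N (band `01` spans 36.0-36.5 N). The
#' letter gives a 10-degree longitude block (`A` is special-cased to
#' 44-40 W with digits 0-3; `B` starts at 40 W; `I` is skipped), and the final
#' digit the 1-degree cell within the block, so `F7` spans 7-8 E.
#'
#' @param code Character vector of rectangle codes.
#' @return `ices_rect_geometry()`: a tibble with one row per code and columns
#'   `rectangle_code`, `lon`, `lat` (centroid), `lon_min`, `lon_max`,
#'   `lat_min`, `lat_max`.
#' @export
#' @examples
#' ices_rect_geometry("37F7") # centroid (7.5, 54.25)
ices_rect_geometry <- function(code) {
  code <- toupper(as.character(code))
  ok <- grepl("^[0-9]{2}[A-HJ-M][0-9]$", code)
  if (any(!ok)) {
    stop("malformed ICES rectangle code(s): ",
      paste(unique(code[!ok]), collapse = ", "),
      call. = FALSE
    )
  }
  band <- as.integer(substr(code, 1, 2))
  letter <- substr(code, 3, 3)
  cell <- as.integer(substr(code, 4, 4))
  if (any(band < 1L | band > 99L)) {
    stop("latitude band out of range (01-99) in code(s): ",
      paste(unique(code[band < 1L | band > 99L]), collapse = ", "),
      call. = FALSE
    )
  }
  lat_min <- 36 + (band - 1L) * 0.5
  # letters A..M skipping I; A covers 44W-40W (digits 0-3 only)
  letters_seq <- c("A", "B", "C", "D", "E", "F", "G", "H", "J", "K", "L", "M")
  block <- match(letter, letters_seq)
  lon_min <- ifelse(letter == "A", -44 + cell, -40 + (block - 2L) * 10 + cell)
  if (any(letter == "A" & cell > 3L)) {
    stop("rectangle code(s) in block A must have digit 0-3: ",
      paste(unique(code[letter == "A" & cell > 3L]), collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    rectangle_code = code,
    lon = lon_min + 0.5,
    lat = lat_min + 0.25,
    lon_min = lon_min,
    lon_max = lon_min + 1,
    lat_min = lat_min,
    lat_max = lat_min + 0.5
  )
}

#' @rdname ices_rect_geometry
#' @param lon,lat Numeric vectors of positions (decimal degrees).
#' @return `ices_rect_code()`: the character vector of codes containing the
#'   positions (the inverse of the centroid lookup).
#' @export
ices_rect_code <- function(lon, lat) {
  if (any(lat < 36 | lat >= 85.5)) {
    stop("latitude outside the ICES rectangle grid (36N-85.5N)", call. = FALSE)
  }
  if (any(lon < -44 | lon >= 70)) {
    stop("longitude outside the ICES rectangle grid", call. = FALSE)
  }
  band <- floor((lat - 36) / 0.5) + 1L
  letters_seq <- c("A", "B", "C", "D", "E", "F", "G", "H", "J", "K", "L", "M")
  block <- ifelse(lon < -40, 1L, floor((lon + 40) / 10) + 2L)
  letter <- letters_seq[block]
  cell <- ifelse(lon < -40, floor(lon + 44), floor(lon - (-40 + (block - 2L) * 10)))
  sprintf("%02d%s%d", band, letter, cell)
}

# great-circle distance matrix (km) between positions
.distance_km <- function(lon, lat) {
  pts <- cbind(lon, lat)
  n <- nrow(pts)
  d <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      d[i, (i + 1):n] <- geosphere::distHaversine(
        pts[i, , drop = FALSE], pts[(i + 1):n, , drop = FALSE]
      ) / 1000
    }
    d <- d + t(d)
  }
  d
}
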