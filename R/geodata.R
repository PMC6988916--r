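## Reading unit tables, plain-text geometry, UTM projection, areas/centroids.

#' Read jurisdictional units from attribute and geometry tables
#'
#' Joins a per-unit attribute table to (optional) geometry. Geometry is
#' supplied as plain text: either a `wkt` column holding `POLYGON` strings,
#' or `lon`/`lat` (geographic) or `x`/`y` (projected metres) centroid
#' columns. Attribute tables are CSV/TSV (or Excel when the readxl package
#' is installed).
#'
#' @param attribute_path Path to the attribute table (one row per unit).
#' @param geometry_path Optional path to a geometry table with the join key
#'   and a `wkt`, `lon`/`lat`, or `x`/`y` column. When `NULL` the attribute
#'   table itself must carry the geometry columns.
#' @param join_key Name of the key column present in both tables.
#' @return A tibble of units with attribute columns and geometry columns,
#'   with an `exclusions` attribute listing unmatched rows (the rejects
#'   report, a tibble with the key and a reason).
#' @export
read_units <- function(attribute_path, geometry_path = NULL,
                       join_key = "unit_id") {
  attrs <- read_table_any(attribute_path)
  if (!join_key %in% names(attrs)) {
    abort(paste0("join key '", join_key, "' not found in attribute table"))
  }
  if (anyDuplicated(attrs[[join_key]])) {
    dup <- unique(attrs[[join_key]][duplicated(attrs[[join_key]])])
    abort(paste0("duplicate join keys in attribute table: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  rejects <- tibble(key = character(), reason = character())
  if (!is.null(geometry_path)) {
    geom <- read_table_any(geometry_path)
    if (!join_key %in% names(geom)) {
      abort(paste0("join key '", join_key, "' not found in geometry table"))
    }
    if (anyDuplicated(geom[[join_key]])) {
      abort("duplicate join keys in geometry table")
    }
    matched <- attrs[[join_key]] %in% geom[[join_key]]
    if (any(!matched)) {
      rejects <- tibble(key = as.character(attrs[[join_key]][!matched]),
                        reason = "no geometry for attribute row")
      warn(paste0(sum(!matched), " attribute row(s) had no matching geometry",
                  " and were rejected"))
    }
    extra <- !(geom[[join_key]] %in% attrs[[join_key]])
    if (any(extra)) {
      rejects <- dplyr::bind_rows(
        rejects,
        tibble(key = as.character(geom[[join_key]][extra]),
               reason = "geometry without attribute row"))
      warn(paste0(sum(extra), " geometry row(s) had no attribute row"))
    }
    units <- dplyr::inner_join(attrs, geom, by = join_key)
  } else {
    units <- attrs
  }
  names(rejects)[1] <- join_key
  attr(units, "rejects") <- rejects
  units
}

read_table_any <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("reading Excel files requires the 'readxl' package")
    }
    return(as_tibble(readxl::read_excel(path)))
  }
  delim <- if (ext == "tsv") "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Rejects report of a `read_units()` result
#' @param units A tibble returned by [read_units()].
#' @return Tibble of rejected keys and reasons.
#' @export
unit_rejects <- function(units) {
  attr(units, "rejects") %||% tibble(unit_id = character(),
                                     reason = character())
}

## ---- UTM projection (WGS84 ellipsoidal transverse Mercator) --------------

#' UTM zone defaults per country
#'
#' Zambia, Ecuador and the Philippines are projected to UTM zones 35S, 17S
#' and 51N respectively.
#' @param country One of "ZAM", "ECU", "PHI".
#' @return List with `zone` (integer) and `south` (logical).
#' @export
utm_zone_for <- function(country) {
  switch(toupper(country),
         ZAM = list(zone = 35L, south = TRUE),
         ECU = list(zone = 17L, south = TRUE),
         PHI = list(zone = 51L, south = FALSE),
         abort(paste0("no default UTM zone for country '", country, "'")))
}

#' Project geographic coordinates to UTM (WGS84)
#'
#' Ellipsoidal transverse Mercator forward projection (series expansion,
#' sub-metre accuracy within a zone).
#'
#' @param lon,lat Numeric vectors, degrees.
#' @param zone UTM zone number (1-60).
#' @param south Logical; southern-hemisphere false northing of 10,000 km.
#' @return Tibble with `x` (easting) and `y` (northing) in metres.
#' @export
utm_project <- function(lon, lat, zone, south = FALSE) {
  stopifnot(length(lon) == length(lat), zone >= 1, zone <= 60)
  a <- 6378137
  f <- 1 / 298.257223563
  k0 <- 0.9996
  e2 <- f * (2 - f)
  ep2 <- e2 / (1 - e2)
  lam0 <- (6 * zone - 183) * pi / 180
  phi <- lat * pi / 180
  lam <- lon * pi / 180

  n_rad <- a / sqrt(1 - e2 * sin(phi)^2)
  t2 <- tan(phi)^2
  c2 <- ep2 * cos(phi)^2
  aa <- (lam - lam0) * cos(phi)

  m <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
              (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
              (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
              (35 * e2^3 / 3072) * sin(6 * phi))

  x <- 500000 + k0 * n_rad *
    (aa + (1 - t2 + c2) * aa^3 / 6 +
       (5 - 18 * t2 + t2^2 + 72 * c2 - 58 * ep2) * aa^5 / 120)
  y <- k0 * (m + n_rad * tan(phi) *
               (aa^2 / 2 + (5 - t2 + 9 * c2 + 4 * c2^2) * aa^4 / 24 +
                  (61 - 58 * t2 + t2^2 + 600 * c2 - 330 * ep2) * aa^6 / 720))
  if (south) y <- y + 1e7
  tibble(x = x, y = y)
}

## ---- plain-text polygon geometry -----------------------------------------

## Parse a WKT POLYGON string into a list of ring matrices (lon/lat or x/y).
parse_wkt_polygon <- function(wkt) {
  s <- trimws(wkt)
  if (!grepl("^POLYGON", s, ignore.case = TRUE)) {
    abort("only POLYGON WKT geometries are supported")
  }
  body <- sub("^POLYGON\\s*\\(", "", s, ignore.case = TRUE)
  body <- sub("\\)$", "", body)
  rings <- regmatches(body, gregexpr("\\(([^()]*)\\)", body))[[1]]
  lapply(rings, function(r) {
    r <- gsub("[()]", "", r)
    pts <- strsplit(trimws(strsplit(r, ",")[[1]]), "\\s+")
    m <- do.call(rbind, lapply(pts, function(p) as.numeric(p[1:2])))
    colnames(m) <- c("x", "y")
    m
  })
}

## Shoelace signed area and centroid of one ring (planar coordinates).
ring_area_centroid <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  n <- nrow(m)
  if (x[1] != x[n] || y[1] != y[n]) { x <- c(x, x[1]); y <- c(y, y[1]) }
  cr <- x[-length(x)] * y[-1] - x[-1] * y[-length(y)]
  area <- sum(cr) / 2
  if (abs(area) < .Machine$double.eps) {
    return(list(area = 0, cx = mean(m[, 1]), cy = mean(m[, 2])))
  }
  cx <- sum((x[-length(x)] + x[-1]) * cr) / (6 * area)
  cy <- sum((y[-length(y)] + y[-1]) * cr) / (6 * area)
  list(area = area, cx = cx, cy = cy)
}

## Area (m^2, holes subtracted) and centroid of a ring list.
polygon_area_centroid <- function(rings) {
  parts <- lapply(rings, ring_area_centroid)
  areas <- vapply(parts, `[[`, numeric(1), "area")
  ## first ring is the shell; signs of inner rings are forced negative
  a <- abs(areas[1])
  w <- a
  cx <- parts[[1]]$cx * a
  cy <- parts[[1]]$cy * a
  if (length(parts) > 1) {
    for (i in seq(2, length(parts))) {
      ai <- -abs(areas[i])
      w <- w + ai
      cx <- cx + parts[[i]]$cx * ai
      cy <- cy + parts[[i]]$cy * ai
    }
  }
  list(area = w, cx = cx / w, cy = cy / w)
}

#' Project units and measure areas and centroids
#'
#' Projects geometry to the country's UTM zone (or an explicit zone) and
#' computes polygon areas in hectares and centroids in projected metres.
#' Units carrying a `wkt` column get both; units carrying only `lon`/`lat`
#' get projected centroids; units already carrying `x`/`y` pass through.
#' For pantropical pooled samples (mixed countries) geographic coordinates
#' are retained and downstream distances are geodesic, since no single UTM
#' zone spans the three countries.
#'
#' @param units Tibble of units (needs `country` unless `zone` is given).
#' @param zone,south Optional explicit UTM zone overriding country defaults.
#' @return The units tibble with `x`, `y` centroid columns (metres) and,
#'   when polygons are present, an `area_ha` column.
#' @export
project_and_measure <- function(units, zone = NULL, south = FALSE) {
  units <- as_tibble(units)
  has_wkt <- "wkt" %in% names(units)
  has_ll <- all(c("lon", "lat") %in% names(units))
  has_xy <- all(c("x", "y") %in% names(units))
  if (!has_wkt && !has_ll && has_xy) {
    return(units)
  }
  if (!has_wkt && !has_ll) {
    abort("units carry no geometry: need 'wkt', 'lon'/'lat', or 'x'/'y'")
  }
  zone_of <- function(cty) {
    if (!is.null(zone)) return(list(zone = zone, south = south))
    utm_zone_for(cty)
  }
  if (has_wkt) {
    out <- purrr::pmap(
      list(units$wkt, units$country, units$unit_id),
      function(wkt, cty, id) {
        rings <- parse_wkt_polygon(wkt)
        z <- zone_of(cty)
        proj <- lapply(rings, function(m) {
          p <- utm_project(m[, 1], m[, 2], z$zone, z$south)
          cbind(x = p$x, y = p$y)
        })
        g <- polygon_area_centroid(proj)
        if (g$area <= 0) {
          abort(paste0("unit '", id, "' degenerates to zero area"))
        }
        tibble(x = g$cx, y = g$cy, area_ha = g$area / 1e4)
      })
    units <- dplyr::bind_cols(dplyr::select(units, -dplyr::any_of(c("x", "y", "area_ha"))),
                              dplyr::bind_rows(out))
  } else {
    proj <- purrr::map2(units$lon, units$lat, ~NULL)
    z <- purrr::map(units$country, zone_of)
    xy <- purrr::pmap(list(units$lon, units$lat, z), function(lo, la, zz) {
      utm_project(lo, la, zz$zone, zz$south)
    })
    xy <- dplyr::bind_rows(xy)
    units$x <- xy$x
    units$y <- xy$y
  }
  stopifnot(all(is.finite(units$x)), all(is.finite(units$y)))
  units
}

#' Area-weighted mean
#'
#' Weighted mean of pixel or patch values with their areas as weights,
#' used to aggregate coarse index grids (e.g. crop suitability) to units.
#'
#' @param values Numeric vector of values.
#' @param areas Numeric vector of non-negative areas, at least one positive.
#' @return `sum(values * areas) / sum(areas)`.
#' @export
area_weighted_mean <- function(values, areas) {
  stopifnot(length(values) == length(areas))
  if (any(areas < 0)) abort("areas must be non-negative")
  if (sum(areas) <= 0) abort("all areas are zero")
  sum(values * areas) / sum(areas)
}

#' Validate the raw unit attribute invariants
#'
#' Checks `FA >= 0`, `FA_pot >= FA`, `A_TOT >= FA_pot`, `CSI` in \[0, 100\],
#' and finite centroids. Violations raise an error naming the units.
#'
#' @param units Tibble of unit records.
#' @return `units`, invisibly.
#' @export
validate_units <- function(units) {
  bad <- character()
  chk <- function(cond, what) {
    if (any(!cond, na.rm = TRUE)) {
      ids <- units$unit_id[which(!cond)]
      bad <<- c(bad, paste0(what, ": ", paste(head(ids, 5), collapse = ", ")))
    }
  }
  chk(units$FA >= 0, "FA < 0")
  chk(units$FA_pot >= units$FA, "FA_pot < FA")
  chk(units$A_TOT >= units$FA_pot, "A_TOT < FA_pot")
  if ("CSI" %in% names(units)) {
    chk(units$CSI >= 0 & units$CSI <= 100, "CSI outside [0, 100]")
  }
  if (all(c("x", "y") %in% names(units))) {
    chk(is.finite(units$x) & is.finite(units$y), "non-finite centroid")
  }
  if (length(bad)) abort(paste0("invalid unit records — ",
                                paste(bad, collapse = "; ")))
  invisible(units)
}

#' Write a unit table (and its rejects report) to CSV
#' @param units Unit tibble (possibly with a rejects attribute).
#' @param path Output CSV path; rejects go to `<path>_rejects.csv` when any.
#' @return `path`, invisibly.
#' @export
write_units <- function(units, path) {
  readr::write_csv(units, path, progress = FALSE)
  rej <- unit_rejects(units)
  if (nrow(rej)) {
    readr::write_csv(rej, sub("\\.csv$", "_rejects.csv", path),
                     progress = FALSE)
  }
  invisible(path)
}
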