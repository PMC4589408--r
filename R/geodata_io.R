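#' @useDynLib careshed, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rlnorm rnorm runif setNames fft
#' @importFrom utils read.csv write.csv modifyList
NULL

# ---------------------------------------------------------------------------
# Grid geometry ------------------------------------------------------------
#
# All gridded layers (terrain, land use, population) share one geometry
# convention: a numeric/integer matrix whose row 1 is the NORTHERN edge,
# plus a cell size in metres and the projected x,y of the grid's lower-left
# corner. Cell centres are at
#   x = origin_x + (col - 0.5) * cell_size
#   y = origin_y + (nrow - row + 0.5) * cell_size
# Analysis is only defined in a projected metric CRS; geographic (degree)
# rasters are refused, not silently reprojected.

EPSG_GEOGRAPHIC <- c("EPSG:4326", "EPSG:4269", "EPSG:4267", "EPSG:4258",
                     "EPSG:4210", "EPSG:21096")

new_grid <- function(values, cell_size, origin, crs, subclass) {
  stopifnot(is.matrix(values), length(origin) == 2)
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("cell_size must be a single positive number")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), crs = crs),
    class = c(subclass, "careshed_grid"))
}

assert_projected_crs <- function(crs) {
  if (is.null(crs) || is.na(crs) || !nzchar(crs))
    stop("raster has no coordinate reference system; supply a projected ",
         "metric CRS (e.g. crs = \"EPSG:32736\")")
  if (toupper(crs) %in% EPSG_GEOGRAPHIC || grepl("longlat|4326", crs,
                                                 ignore.case = TRUE))
    stop("geographic (degree-based) CRS '", crs, "' is not supported; ",
         "reproject the raster to a projected metric CRS (e.g. the ",
         "local UTM zone, EPSG:32736) before reading")
  invisible(TRUE)
}

#' Terrain model: gridded elevations in metres
#'
#' The cost-surface substrate: a rectangular elevation grid with square
#' cells (nominally 90 m, matching SRTM-class elevation models), origin at
#' the lower-left corner, in a projected metric CRS. `NA` cells are nodata.
#'
#' @param elevations numeric matrix, metres above sea level; row 1 is north.
#' @param cell_size cell edge length in metres (> 0).
#' @param origin numeric length-2, projected x,y of the lower-left corner.
#' @param crs projected CRS identifier, e.g. `"EPSG:32736"`.
#' @return A `terrain_model` object.
#' @export
terrain_model <- function(elevations, cell_size = 90, origin = c(0, 0),
                          crs = "EPSG:32736") {
  assert_projected_crs(crs)
  storage.mode(elevations) <- "double"
  if (any(!is.finite(elevations) & !is.na(elevations)))
    stop("non-finite elevations present outside the nodata mask")
  new_grid(elevations, cell_size, origin, crs, "terrain_model")
}

LANDUSE_LEVELS <- c("open", "bushy", "forest", "barrier")

#' Land-use grid paired with a terrain model
#'
#' Per-cell land-use category (`open`, `bushy`, `forest`, `barrier`) on the
#' same geometry as its terrain model. `barrier` cells (lakes, swamps) are
#' impassable on foot. The season tag selects the land-use friction column.
#'
#' @param categories character or factor matrix with the four levels.
#' @param season `"dry"` or `"wet"`.
#' @inheritParams terrain_model
#' @return A `landuse_grid` object.
#' @export
landuse_grid <- function(categories, season = c("dry", "wet"), cell_size = 90,
                         origin = c(0, 0), crs = "EPSG:32736") {
  season <- match.arg(season)
  assert_projected_crs(crs)
  if (is.character(categories)) {
    bad <- !is.na(categories) & !(categories %in% LANDUSE_LEVELS)
    if (any(bad)) stop("unknown land-use categories: ",
                       paste(unique(categories[bad]), collapse = ", "))
  }
  g <- new_grid(categories, cell_size, origin, crs, "landuse_grid")
  g$season <- season
  g
}

#' Gridded population counts
#'
#' Persons per cell (WorldPop-style), aligned to a terrain model. Values
#' may be fractional; the recorded total equals the cell sum.
#'
#' @param persons non-negative numeric matrix.
#' @inheritParams terrain_model
#' @return A `population_grid` object.
#' @export
population_grid <- function(persons, cell_size = 90, origin = c(0, 0),
                            crs = "EPSG:32736") {
  assert_projected_crs(crs)
  storage.mode(persons) <- "double"
  if (any(persons < 0, na.rm = TRUE)) stop("population values must be >= 0")
  g <- new_grid(persons, cell_size, origin, crs, "population_grid")
  g$total_population <- sum(persons, na.rm = TRUE)
  g
}

grid_geometry <- function(g) {
  list(dim = dim(g$values), cell_size = g$cell_size, origin = g$origin,
       crs = g$crs)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    all(abs(a$origin - b$origin) < tol) &&
    identical(a$crs, b$crs)
}

#' Cell-centre coordinates of a grid
#'
#' @param g a grid object.
#' @param rows,cols cell indices (vectorized).
#' @return list with `x` and `y` of the cell centres.
#' @export
cell_xy <- function(g, rows, cols) {
  nr <- nrow(g$values)
  list(x = g$origin[1] + (cols - 0.5) * g$cell_size,
       y = g$origin[2] + (nr - rows + 0.5) * g$cell_size)
}

#' Map projected coordinates to grid cells
#'
#' @param g a grid object.
#' @param x,y projected coordinates.
#' @return list with `row` and `col`; `NA` for points outside the grid.
#' @export
xy_cell <- function(g, x, y) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  col <- floor((x - g$origin[1]) / g$cell_size) + 1
  row <- nr - floor((y - g$origin[2]) / g$cell_size)
  bad <- col < 1 | col > nc | row < 1 | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' @export
print.careshed_grid <- function(x, ...) {
  cat(sprintf("<%s> %d x %d cells of %.7g m, origin (%.7g, %.7g), %s\n",
              class(x)[1], nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2], x$crs))
  invisible(x)
}

# ---------------------------------------------------------------------------
# ESRI ASCII grid IO --------------------------------------------------------
#
# Rasters are exchanged as ESRI ASCII grids (.asc): a plain-text,
# georeferenced single-band format readable by every GIS. The CRS travels
# in a .prj sidecar holding an EPSG identifier. Land-use categories are
# coded 1=open 2=bushy 3=forest 4=barrier.

LANDUSE_CODES <- setNames(seq_along(LANDUSE_LEVELS), LANDUSE_LEVELS)

#' Read a georeferenced ASCII raster
#'
#' Reads an ESRI ASCII grid into a terrain, land-use or population grid.
#' The CRS is taken from `crs`, else from a `.prj` sidecar next to the
#' file; degree-based CRSs are refused with guidance to reproject, and a
#' missing georeference (malformed header) is an error.
#'
#' @param path path to a `.asc` file.
#' @param what one of `"terrain"`, `"landuse"`, `"population"`.
#' @param crs CRS override; default reads `<path>.prj` (sans .asc).
#' @param season season tag for land-use grids.
#' @return A grid object of the requested class.
#' @export
read_raster <- function(path, what = c("terrain", "landuse", "population"),
                        crs = NULL, season = "dry") {
  what <- match.arg(what)
  if (!file.exists(path)) stop("no such raster: ", path)
  lines <- readLines(path, n = 7)
  hdr <- list()
  i <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[2]))))
      break
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("raster ", path, " is missing georeference header fields: ",
         paste(setdiff(req, names(hdr)), collapse = ", "))
  if (is.null(crs)) {
    prj <- sub("\\.asc$", ".prj", path)
    if (file.exists(prj)) crs <- trimws(readLines(prj, n = 1))
  }
  assert_projected_crs(crs)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(path, skip = i, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("raster body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  org <- c(hdr$xllcorner, hdr$yllcorner)
  switch(what,
    terrain = terrain_model(m, hdr$cellsize, org, crs),
    population = population_grid(m, hdr$cellsize, org, crs),
    landuse = {
      cats <- matrix(LANDUSE_LEVELS[m], nrow = nr, ncol = nc)
      landuse_grid(cats, season, hdr$cellsize, org, crs)
    })
}

#' Write a grid as a georeferenced ASCII raster
#'
#' Inverse of [read_raster()]: values and geometry round-trip losslessly at
#' full double precision. `NA` and non-finite cells are written as the
#' nodata value; the CRS goes to a `.prj` sidecar.
#'
#' @param g a grid object.
#' @param path output `.asc` path.
#' @param nodata nodata sentinel written to the file.
#' @return `path`, invisibly.
#' @export
write_raster <- function(g, path, nodata = -9999) {
  m <- g$values
  if (inherits(g, "landuse_grid") && !is.numeric(m))
    m <- matrix(LANDUSE_CODES[m], nrow = nrow(m), ncol = ncol(m))
  storage.mode(m) <- "double"
  m[!is.finite(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", format(g$origin[1], digits = 17)),
    paste("yllcorner", format(g$origin[2], digits = 17)),
    paste("cellsize", format(g$cell_size, digits = 17)),
    paste("NODATA_value", nodata)), con)
  write.table(format(m, digits = 17, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(g$crs, sub("\\.asc$", ".prj", path))
  invisible(path)
}

# ---------------------------------------------------------------------------
# Population operations -----------------------------------------------------

#' Rescale a population grid to a census total
#'
#' Applies one multiplicative adjustment factor so the grid sums to the
#' census total without changing the spatial distribution: every cell's
#' share of the total is preserved exactly.
#'
#' @param pop a [population_grid()].
#' @param census_total positive target total.
#' @return A rescaled `population_grid`.
#' @export
rescale_population <- function(pop, census_total) {
  stopifnot(inherits(pop, "population_grid"))
  if (!is.numeric(census_total) || length(census_total) != 1 ||
      !is.finite(census_total) || census_total <= 0)
    stop("census_total must be a single positive number")
  if (pop$total_population <= 0) stop("population grid sums to zero")
  population_grid(pop$values * (census_total / pop$total_population),
                  pop$cell_size, pop$origin, pop$crs)
}

#' Align grids onto a primary grid's geometry
#'
#' Brings land-use and population grids onto the geometry of the primary
#' terrain model. Only integer-factor resolution changes are supported:
#' population is disaggregated (equal split) or aggregated (sum) so total
#' mass is conserved; land use uses nearest-cell assignment. Grids already
#' on the primary geometry are returned unchanged.
#'
#' @param primary a [terrain_model()] defining the target geometry.
#' @param ... further grid objects to align.
#' @return List of aligned grids, in input order.
#' @export
align_grids <- function(primary, ...) {
  others <- list(...)
  lapply(others, function(g) {
    if (!identical(g$crs, primary$crs))
      stop("CRS mismatch: ", g$crs, " vs ", primary$crs)
    overlap_x <- min(g$origin[1] + ncol(g$values) * g$cell_size,
                     primary$origin[1] + ncol(primary$values) * primary$cell_size) -
      max(g$origin[1], primary$origin[1])
    overlap_y <- min(g$origin[2] + nrow(g$values) * g$cell_size,
                     primary$origin[2] + nrow(primary$values) * primary$cell_size) -
      max(g$origin[2], primary$origin[2])
    if (overlap_x <= 0 || overlap_y <= 0)
      stop("grid extents are disjoint; cannot align")
    if (same_geometry(g, primary)) return(g)
    if (any(abs(g$origin - primary$origin) > 1e-6))
      stop("only origin-aligned integer-factor resampling is supported")
    ratio <- g$cell_size / primary$cell_size
    if (abs(ratio - round(ratio)) < 1e-9 && ratio > 1) {
      f <- as.integer(round(ratio))        # coarse -> fine
      fine <- resample_finer(g, f, primary)
      return(fine)
    }
    inv <- primary$cell_size / g$cell_size
    if (abs(inv - round(inv)) < 1e-9 && inv > 1) {
      f <- as.integer(round(inv))          # fine -> coarse
      return(resample_coarser(g, f, primary))
    }
    stop("unsupported resampling ratio ", ratio)
  })
}

resample_finer <- function(g, f, primary) {
  nr <- nrow(primary$values); nc <- ncol(primary$values)
  src_row <- ceiling(seq_len(nr) / f); src_col <- ceiling(seq_len(nc) / f)
  src_row <- pmin(src_row, nrow(g$values)); src_col <- pmin(src_col, ncol(g$values))
  m <- g$values[src_row, src_col, drop = FALSE]
  if (inherits(g, "population_grid")) {
    m <- m / (f * f)                       # equal split conserves mass
    population_grid(m, primary$cell_size, primary$origin, primary$crs)
  } else if (inherits(g, "landuse_grid")) {
    landuse_grid(m, g$season, primary$cell_size, primary$origin, primary$crs)
  } else {
    terrain_model(m, primary$cell_size, primary$origin, primary$crs)
  }
}

resample_coarser <- function(g, f, primary) {
  nr <- nrow(primary$values); nc <- ncol(primary$values)
  if (inherits(g, "population_grid")) {
    m <- matrix(0, nr, nc)
    src <- g$values
    src[is.na(src)] <- 0
    for (r in seq_len(nrow(src))) {
      for (cc in seq_len(ncol(src))) {
        m[min(ceiling(r / f), nr), min(ceiling(cc / f), nc)] <-
          m[min(ceiling(r / f), nr), min(ceiling(cc / f), nc)] + src[r, cc]
      }
    }
    population_grid(m, primary$cell_size, primary$origin, primary$crs)
  } else {
    idx_r <- pmin((seq_len(nr) - 1L) * f + 1L, nrow(g$values))
    idx_c <- pmin((seq_len(nc) - 1L) * f + 1L, ncol(g$values))
    m <- g$values[idx_r, idx_c, drop = FALSE]
    if (inherits(g, "landuse_grid"))
      landuse_grid(m, g$season, primary$cell_size, primary$origin, primary$crs)
    else terrain_model(m, primary$cell_size, primary$origin, primary$crs)
  }
}

# ---------------------------------------------------------------------------
# Facility tables -----------------------------------------------------------

FACILITY_LEVELS <- c("dispensary", "health_centre", "hospital")

#' Construct a facility table
#'
#' Canonical facility record set: id, name, level (dispensary /
#' health_centre / hospital), projected coordinates, skilled-birth-attendant
#' count, annual delivery caseload (`NA` when not reported) and whether the
#' facility offers delivery care.
#'
#' @param df data.frame with columns `id, name, level, x, y, sba_count,
#'   deliveries, offers_delivery` (`name` and `offers_delivery` optional).
#' @return A `facility_table` (a validated data.frame).
#' @export
facility_table <- function(df) {
  if (!is.data.frame(df) || nrow(df) == 0) stop("facility table is empty")
  if (is.null(df$name)) df$name <- as.character(df$id)
  if (is.null(df$offers_delivery)) df$offers_delivery <- TRUE
  need <- c("id", "name", "level", "x", "y", "sba_count", "deliveries",
            "offers_delivery")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing facility columns: ", paste(miss, collapse = ", "))
  df <- df[, need]
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("facility ids must be unique")
  if (!all(df$level %in% FACILITY_LEVELS))
    stop("facility level must be one of: ", paste(FACILITY_LEVELS, collapse = ", "))
  if (any(df$sba_count < 0, na.rm = TRUE) ||
      any(df$deliveries < 0, na.rm = TRUE))
    stop("sba_count and deliveries must be non-negative")
  class(df) <- c("facility_table", "data.frame")
  df
}

#' Read a facility CSV
#'
#' Fixed dialect: header row, comma separator, UTF-8, missing deliveries
#' encoded as an empty field.
#'
#' @param path CSV path.
#' @return A [facility_table()].
#' @export
read_facilities <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                 na.strings = "")
  facility_table(df)
}

#' Write a facility CSV
#'
#' @param ft a [facility_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_facilities <- function(ft, path) {
  write.csv(ft, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Road networks (GeoJSON) ---------------------------------------------------

ROAD_CLASSES <- c("tarmac", "loose_surface", "dry_weather", "motorable",
                  "footpath")
MOTORABLE_CLASSES <- c("tarmac", "loose_surface", "dry_weather", "motorable")

#' Construct a road network
#'
#' @param segments list of numeric matrices (one polyline each, columns
#'   x,y, >= 2 vertices) in the projected CRS.
#' @param road_class character vector, one of the five road classes per
#'   segment.
#' @param crs projected CRS identifier.
#' @return A `road_network` object.
#' @export
road_network <- function(segments, road_class, crs = "EPSG:32736") {
  stopifnot(is.list(segments), length(segments) == length(road_class))
  for (s in segments)
    if (!is.matrix(s) || ncol(s) != 2 || nrow(s) < 2)
      stop("each road segment must be an x,y matrix with >= 2 vertices")
  if (length(road_class) && !all(road_class %in% ROAD_CLASSES))
    stop("unknown road class; expected one of: ",
         paste(ROAD_CLASSES, collapse = ", "))
  structure(list(segments = segments, road_class = road_class, crs = crs),
            class = "road_network")
}

#' Read a road network from GeoJSON
#'
#' Expects a FeatureCollection of LineStrings with a `road_class` property,
#' coordinates in the projected CRS named by the `crs` argument.
#'
#' @param path GeoJSON path.
#' @param crs projected CRS the coordinates are in.
#' @return A [road_network()].
#' @export
read_roads <- function(path, crs = "EPSG:32736") {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- gj$features
  segs <- list(); cls <- character(0)
  for (f in feats) {
    if (!identical(f$geometry$type, "LineString")) next
    coords <- do.call(rbind, lapply(f$geometry$coordinates,
                                    function(p) c(p[[1]], p[[2]])))
    segs[[length(segs) + 1]] <- coords
    cls <- c(cls, f$properties$road_class)
  }
  road_network(segs, cls, crs)
}

#' Write a road network as GeoJSON
#'
#' @param roads a [road_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roads <- function(roads, path) {
  feats <- lapply(seq_along(roads$segments), function(i) {
    m <- roads$segments[[i]]
    list(type = "Feature",
         properties = list(road_class = roads$road_class[i]),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(m)),
                                              function(r) c(m[r, 1], m[r, 2]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Run configuration ---------------------------------------------------------

#' Run configuration
#'
#' Bundles the knobs every stage shares: season, travel mode, isochrone
#' band width and access thresholds (minutes), mesh side (metres) and the
#' random seed. The band width must divide the largest threshold so that
#' threshold rows are exact band boundaries.
#'
#' @param season `"dry"` or `"wet"`.
#' @param mode `"pedestrian"` or `"multimodal"`.
#' @param band_width band width in minutes.
#' @param thresholds strictly increasing access thresholds in minutes.
#' @param mesh_side mesh node spacing in metres.
#' @param connectivity raster move neighbourhood, 8 or 16.
#' @param seed integer random seed.
#' @param overrides named list of friction/road-speed overrides (keys like
#'   `friction_slope_40-60`, `friction_dry_open`, `roadspeed_tarmac`).
#' @return A `run_config` object.
#' @export
run_config <- function(season = "dry", mode = "pedestrian", band_width = 20,
                       thresholds = c(60, 120), mesh_side = 223,
                       connectivity = 16, seed = 1, overrides = list()) {
  season <- match.arg(season, c("dry", "wet"))
  mode <- match.arg(mode, c("pedestrian", "multimodal"))
  if (band_width <= 0) stop("band_width must be positive")
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  if (max(thresholds) %% band_width != 0)
    stop("band_width must divide the maximum threshold")
  if (!connectivity %in% c(8, 16)) stop("connectivity must be 8 or 16")
  structure(list(season = season, mode = mode, band_width = band_width,
                 thresholds = thresholds, mesh_side = mesh_side,
                 connectivity = connectivity, seed = as.integer(seed),
                 overrides = overrides),
            class = "run_config")
}

#' Read a run configuration file
#'
#' Plain-text `key = value` lines mapped 1:1 onto [run_config()]; `#`
#' starts a comment; `thresholds` is comma-separated. Keys prefixed
#' `friction_` or `roadspeed_` collect into the overrides list.
#'
#' @param path config file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  args <- list(); overrides <- list()
  for (p in kv) {
    if (length(p) != 2) stop("malformed config line: ", paste(p, collapse = "="))
    key <- p[1]; val <- p[2]
    if (grepl("^(friction|roadspeed)_", key)) {
      overrides[[key]] <- as.numeric(val)
    } else if (key == "thresholds") {
      args$thresholds <- as.numeric(strsplit(val, ",")[[1]])
    } else if (key %in% c("band_width", "mesh_side", "connectivity", "seed")) {
      args[[key]] <- as.numeric(val)
    } else if (key %in% c("season", "mode")) {
      args[[key]] <- val
    } else stop("unknown config key: ", key)
  }
  args$overrides <- overrides
  do.call(run_config, args)
}

#' Write a run configuration file
#'
#' @param cfg a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  lines <- c(paste("season =", cfg$season),
             paste("mode =", cfg$mode),
             paste("band_width =", cfg$band_width),
             paste("thresholds =", paste(cfg$thresholds, collapse = ",")),
             paste("mesh_side =", cfg$mesh_side),
             paste("connectivity =", cfg$connectivity),
             paste("seed =", cfg$seed))
  for (k in names(cfg$overrides))
    lines <- c(lines, paste(k, "=", cfg$overrides[[k]]))
  writeLines(lines, path)
  invisible(path)
}
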