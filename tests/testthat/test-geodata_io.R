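test_that("raster IO round-trips values and geometry and honours nodata", {
  z <- matrix(rnorm(30, 100, 5), 5, 6)
  z[c(2, 9, 17)] <- NA
  tm <- terrain_model(z, 90, c(5000, 8000), "EPSG:32736")
  path <- file.path(tempdir(), "rt.asc")
  write_raster(tm, path)
  back <- read_raster(path, "terrain")
  expect_equal(back$values, tm$values, tolerance = 1e-12)
  expect_identical(sum(is.na(back$values)), 3L)
  expect_equal(back$cell_size, 90)
  expect_equal(back$origin, c(5000, 8000))
  expect_identical(back$crs, "EPSG:32736")

  lu <- landuse_grid(matrix(c("open", "bushy", "forest", "barrier"), 4, 5),
                     "wet", 90, c(0, 0))
  lp <- file.path(tempdir(), "lu.asc")
  write_raster(lu, lp)
  lb <- read_raster(lp, "landuse", season = "wet")
  expect_identical(lb$values, lu$values)
  expect_identical(lb$season, "wet")
})

test_that("identity read: uniform raster and nodata mask counts", {
  tm <- terrain_model(matrix(100, 10, 10), 90)
  p <- file.path(tempdir(), "flat.asc")
  write_raster(tm, p)
  back <- read_raster(p, "terrain")
  expect_identical(sum(!is.na(back$values)), 100L)
  expect_true(all(back$values == 100))
})

test_that("geographic CRS and missing georeference are refused", {
  expect_error(terrain_model(matrix(0, 2, 2), 90, crs = "EPSG:4326"),
               "reproject")
  p <- file.path(tempdir(), "nohdr.asc")
  writeLines(c("1 2 3", "4 5 6"), p)
  expect_error(read_raster(p, "terrain", crs = "EPSG:32736"),
               "georeference")
  p2 <- file.path(tempdir(), "nocrs.asc")
  write_raster(terrain_model(matrix(0, 2, 2), 90), p2)
  file.remove(sub("asc$", "prj", p2))
  expect_error(read_raster(p2, "terrain"), "coordinate reference")
})

test_that("rescale_population scales uniformly and conserves shares", {
  pop <- population_grid(matrix(c(1, 3, 6, 10), 2, 2), 90)
  out <- rescale_population(pop, 8)
  expect_equal(out$values[1:2], c(0.4, 1.2))
  expect_equal(out$total_population, 8)
  shares_before <- pop$values / sum(pop$values)
  shares_after <- out$values / sum(out$values)
  expect_equal(shares_before, shares_after, tolerance = 1e-9)
  # identity and hand-arithmetic cases
  expect_equal(rescale_population(pop, sum(pop$values))$values, pop$values)
  p2 <- population_grid(matrix(c(1, 3), 1, 2), 90)
  expect_equal(as.vector(rescale_population(p2, 8)$values), c(2, 6))
  expect_error(rescale_population(pop, 0), "positive")
})

test_that("align_grids conserves population mass across resolutions", {
  tm <- terrain_model(matrix(0, 8, 8), 90)
  coarse <- population_grid(matrix(runif(16, 0, 50), 4, 4), 180)
  out <- align_grids(tm, coarse)[[1]]
  expect_identical(dim(out$values), c(8L, 8L))
  expect_equal(sum(out$values), sum(coarse$values), tolerance = 1e-6)
  # aligned input unchanged; CRS mismatch errors; disjoint extents error
  pop <- population_grid(matrix(1, 8, 8), 90)
  expect_identical(align_grids(tm, pop)[[1]]$values, pop$values)
  bad <- population_grid(matrix(1, 8, 8), 90, crs = "EPSG:32737")
  expect_error(align_grids(tm, bad), "CRS mismatch")
  far <- population_grid(matrix(1, 8, 8), 90, c(1e6, 1e6))
  expect_error(align_grids(tm, far), "disjoint")
})

test_that("facility CSV round-trips with empty-field missing values", {
  ft <- facility_table(data.frame(
    id = c("a", "b"), level = c("dispensary", "hospital"),
    x = c(0, 100), y = c(0, 100), sba_count = c(1L, 9L),
    deliveries = c(NA, 500)))
  p <- file.path(tempdir(), "fac.csv")
  write_facilities(ft, p)
  expect_true(any(grepl(",,", readLines(p))))  # empty field for NA
  back <- read_facilities(p)
  expect_equal(back$deliveries, ft$deliveries)
  expect_identical(back$id, ft$id)
  expect_error(facility_table(data.frame(id = c("a", "a"),
                                         level = "dispensary", x = 0, y = 0,
                                         sba_count = 0, deliveries = 1)),
               "unique")
})

test_that("road GeoJSON round-trips geometry and class", {
  roads <- road_network(list(cbind(c(0, 500, 900), c(0, 200, 900)),
                             cbind(c(10, 20), c(30, 40))),
                        c("tarmac", "footpath"))
  p <- file.path(tempdir(), "roads.geojson")
  write_roads(roads, p)
  back <- read_roads(p)
  expect_equal(back$segments[[1]], roads$segments[[1]], ignore_attr = TRUE)
  expect_identical(back$road_class, roads$road_class)
  expect_error(road_network(list(cbind(1, 2)), "tarmac"), "vertices")
})

test_that("run config round-trips and validates invariants", {
  cfg <- run_config(season = "wet", band_width = 30, thresholds = c(60, 120),
                    mesh_side = 200, seed = 7,
                    overrides = list(roadspeed_tarmac = 80))
  p <- file.path(tempdir(), "run.cfg")
  write_run_config(cfg, p)
  back <- read_run_config(p)
  expect_equal(unclass(back), unclass(cfg))
  tabs <- apply_overrides(back)
  expect_equal(unname(tabs$roads$speeds["tarmac"]), 80)
  expect_error(run_config(band_width = 50, thresholds = c(60, 120)),
               "divide")
  expect_error(run_config(thresholds = c(120, 60)), "increasing")
})
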