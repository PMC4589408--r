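# ---------------------------------------------------------------------------
# Seeded synthetic districts -------------------------------------------------
#
# Generates districts with the statistical structure the analysis assumes:
# smooth hilly terrain with lakes, land use stratified by elevation,
# clustered village population, a spanning road graph with classed links,
# and facility tables whose staffing and caseload distributions mimic
# first-line rural facilities (right-skewed caseloads with ~70-80% under
# 100 annual deliveries, hospitals absorbing a 30-70% share). Everything is
# deterministic under the spec seed.

#' Synthetic district specification
#'
#' @param extent_km square district edge length, km.
#' @param cell_size raster cell size, metres.
#' @param relief_amplitude_m peak-to-valley relief, metres.
#' @param base_elevation_m elevation offset, metres.
#' @param smoothness terrain autocorrelation length as a fraction of the
#'   extent (larger = smoother hills).
#' @param water_fraction fraction of cells carved into barrier lakes.
#' @param n_villages number of villages.
#' @param population_total district population.
#' @param clustering_dispersion_km s.d. of the village settlement kernel, km.
#' @param n_dispensaries,n_health_centres,n_hospitals facility counts.
#' @param staffing_fractions fractions of first-line facilities with
#'   0 / 1 / >=2 skilled birth attendants (sums to 1).
#' @param caseload_meanlog,caseload_sdlog log-scale location/spread of the
#'   first-line annual delivery caseload.
#' @param hospital_delivery_share fraction of all deliveries absorbed by
#'   hospitals.
#' @param missing_caseload_fraction fraction of first-line facilities with
#'   unreported caseload.
#' @param road_density_km_per_km2 target road density.
#' @param season season tag for the land-use grid.
#' @param seed integer random seed.
#' @return A `district_spec` list.
#' @export
district_spec <- function(extent_km = 27, cell_size = 90,
                          relief_amplitude_m = 900, base_elevation_m = 1100,
                          smoothness = 0.15, water_fraction = 0.03,
                          n_villages = 90, population_total = 120000,
                          clustering_dispersion_km = 1.0,
                          n_dispensaries = 16, n_health_centres = 3,
                          n_hospitals = 1,
                          staffing_fractions = c(0.15, 0.5, 0.35),
                          caseload_meanlog = log(50), caseload_sdlog = 0.85,
                          hospital_delivery_share = 0.4,
                          missing_caseload_fraction = 0.05,
                          road_density_km_per_km2 = 0.13,
                          season = "dry", seed = 42) {
  stopifnot(extent_km > 0, cell_size > 0, relief_amplitude_m >= 0,
            water_fraction >= 0, water_fraction < 1,
            n_villages > 0, population_total > 0,
            abs(sum(staffing_fractions) - 1) < 1e-9,
            all(staffing_fractions >= 0),
            hospital_delivery_share >= 0, hospital_delivery_share < 1,
            missing_caseload_fraction >= 0, missing_caseload_fraction <= 1,
            n_dispensaries >= 0, n_health_centres >= 0, n_hospitals >= 0)
  structure(as.list(environment()), class = "district_spec")
}

# Smooth correlated random field in [0,1] via FFT-filtered white noise.
smooth_field <- function(n, smoothness) {
  noise <- matrix(rnorm(n * n), n, n)
  fx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  k2 <- outer(fx^2, fx^2, "+")
  sigma <- max(smoothness * n, 1)
  filt <- exp(-2 * pi^2 * sigma^2 * k2)
  f <- Re(fft(fft(noise) * filt, inverse = TRUE)) / (n * n)
  (f - min(f)) / (max(f) - min(f))
}

#' Generate synthetic terrain and land use
#'
#' Spectrally filtered Gaussian noise scaled to the relief amplitude;
#' lakes are carved below the elevation quantile matching the water
#' fraction and labelled barrier; land use follows elevation terciles
#' perturbed by a second noise field (valley floors open, mid-slopes
#' bushy, uplands forest).
#'
#' @param spec a [district_spec()].
#' @return List with `terrain` ([terrain_model()]) and `landuse`
#'   ([landuse_grid()]).
#' @export
make_terrain <- function(spec) {
  set.seed(spec$seed)
  n <- round(spec$extent_km * 1000 / spec$cell_size)
  f <- smooth_field(n, spec$smoothness)
  z <- spec$base_elevation_m + spec$relief_amplitude_m * f
  terrain <- terrain_model(z, spec$cell_size, c(0, 0))
  cats <- matrix("bushy", n, n)
  g <- smooth_field(n, spec$smoothness / 2)
  mix <- if (spec$relief_amplitude_m > 0) 0.7 * f + 0.3 * g else g
  qs <- quantile(mix, c(0.35, 0.75))
  cats[mix <= qs[1]] <- "open"
  cats[mix > qs[2]] <- "forest"
  if (spec$water_fraction > 0) {
    lvl <- quantile(z, spec$water_fraction)
    cats[z <= lvl] <- "barrier"
  }
  landuse <- landuse_grid(cats, spec$season, spec$cell_size, c(0, 0))
  list(terrain = terrain, landuse = landuse)
}

#' Place villages and spread population
#'
#' Village centres are drawn on non-barrier, low-slope cells with a
#' minimum spacing; village sizes are right-skewed (log-normal); people
#' are spread around each centre with a truncated Gaussian kernel
#' (s.d. = the clustering dispersion), masked off barriers, and the grid
#' is normalized to the spec total.
#'
#' @param spec a [district_spec()].
#' @param terrain a [terrain_model()].
#' @param landuse the paired [landuse_grid()].
#' @return List with `pop` ([population_grid()]) and `villages`
#'   (data.frame id, x, y, size_weight).
#' @export
make_settlements <- function(spec, terrain, landuse) {
  set.seed(spec$seed + 1L)
  n <- nrow(terrain$values)
  sl <- slope_grid(terrain)
  ok <- which(landuse$values != "barrier" & sl < 40)
  if (length(ok) < spec$n_villages * 4)
    stop("too many villages for the available habitable cells")
  wt <- 1 / (1 + sl[ok])
  min_space <- max(2, round(n / sqrt(spec$n_villages) / 3))
  rows <- ((ok - 1L) %% n) + 1L; cols <- ((ok - 1L) %/% n) + 1L
  sel <- integer(0)
  cand <- order(stats::rexp(length(ok)) / wt)  # weighted permutation
  for (i in cand) {
    if (length(sel) >= spec$n_villages) break
    if (!length(sel) ||
        min(abs(rows[i] - rows[sel]) + abs(cols[i] - cols[sel])) >= min_space)
      sel <- c(sel, i)
  }
  if (length(sel) < spec$n_villages)
    stop("could not place the requested number of villages at the ",
         "required spacing")
  vr <- rows[sel]; vc <- cols[sel]
  xy <- cell_xy(terrain, vr, vc)
  size <- rlnorm(spec$n_villages, meanlog = 0, sdlog = 0.8)
  villages <- data.frame(id = seq_len(spec$n_villages), x = xy$x, y = xy$y,
                         row = vr, col = vc, size_weight = size)

  sigma_cells <- spec$clustering_dispersion_km * 1000 / terrain$cell_size
  rad <- ceiling(3 * sigma_cells)
  pop <- matrix(0, n, n)
  off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  off <- off[off$dr^2 + off$dc^2 <= rad^2, ]
  kern <- exp(-(off$dr^2 + off$dc^2) / (2 * sigma_cells^2))
  for (v in seq_len(spec$n_villages)) {
    r <- vr[v] + off$dr; cc <- vc[v] + off$dc
    inb <- r >= 1 & r <= n & cc >= 1 & cc <= n
    idx <- cbind(r[inb], cc[inb])
    pop[idx] <- pop[idx] + size[v] * kern[inb]
  }
  pop[landuse$values == "barrier"] <- 0
  pop <- pop / sum(pop) * spec$population_total
  list(pop = population_grid(pop, terrain$cell_size, terrain$origin,
                             terrain$crs),
       villages = villages)
}

#' Build roads and the facility table
#'
#' Roads are a minimum-spanning tree over village centres (Euclidean
#' Prim), extended with the shortest non-tree links until the target road
#' density is reached. Classes follow link importance: the trunk between
#' the two largest villages is tarmac, links touching large villages are
#' loose-surface or dry-weather, the rest motorable. Facilities sit at
#' villages: the hospital at the largest, health centres at the next
#' largest, dispensaries at a seeded sample of the rest. Staffing is
#' multinomial over the spec fractions; caseloads are log-normal
#' (right-skewed, range ~2-300 at defaults) with hospitals absorbing the
#' spec'd share of all deliveries.
#'
#' @param spec a [district_spec()].
#' @param villages the village table from [make_settlements()].
#' @return List with `roads` ([road_network()]) and `facilities`
#'   ([facility_table()]).
#' @export
make_roads_facilities <- function(spec, villages) {
  set.seed(spec$seed + 2L)
  nv <- nrow(villages)
  n_fac <- spec$n_dispensaries + spec$n_health_centres + spec$n_hospitals
  if (n_fac > nv) stop("more facilities than villages")
  d <- as.matrix(dist(villages[, c("x", "y")]))
  # Prim MST
  in_tree <- c(TRUE, rep(FALSE, nv - 1))
  mst <- matrix(0L, nv - 1, 2)
  for (k in seq_len(nv - 1)) {
    dd <- d[in_tree, !in_tree, drop = FALSE]
    pick <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    a <- which(in_tree)[pick[1]]; b <- which(!in_tree)[pick[2]]
    mst[k, ] <- c(a, b); in_tree[b] <- TRUE
  }
  edges <- mst
  area <- spec$extent_km^2
  total_len <- sum(d[mst]) / 1000
  # add shortest non-tree links until the density target
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  key <- paste(pmin(mst[, 1], mst[, 2]), pmax(mst[, 1], mst[, 2]))
  pairs <- pairs[order(d[pairs])[seq_len(min(3L * nv, nrow(pairs)))], ,
                 drop = FALSE]
  for (p in seq_len(nrow(pairs))) {
    if (total_len / area >= spec$road_density_km_per_km2) break
    pk <- paste(pmin(pairs[p, 1], pairs[p, 2]),
                pmax(pairs[p, 1], pairs[p, 2]))
    if (pk %in% key) next
    edges <- rbind(edges, pairs[p, ])
    key <- c(key, pk)
    total_len <- total_len + d[pairs[p, , drop = FALSE]] / 1000
  }
  size <- villages$size_weight
  big2 <- order(-size)[1:2]
  # class by importance of endpoints; the trunk between the two largest
  # villages (tree path approximated by direct link membership) is tarmac
  imp <- size[edges[, 1]] + size[edges[, 2]]
  cls <- rep("motorable", nrow(edges))
  cls[imp >= quantile(imp, 0.6)] <- "dry_weather"
  cls[imp >= quantile(imp, 0.85)] <- "loose_surface"
  trunk <- (edges[, 1] %in% big2 & edges[, 2] %in% big2)
  cls[trunk] <- "tarmac"
  segs <- lapply(seq_len(nrow(edges)), function(i)
    rbind(as.numeric(villages[edges[i, 1], c("x", "y")]),
          as.numeric(villages[edges[i, 2], c("x", "y")])))
  roads <- road_network(segs, cls)

  ord <- order(-size)
  hosp_v <- ord[seq_len(spec$n_hospitals)]
  hc_v <- ord[spec$n_hospitals + seq_len(spec$n_health_centres)]
  rest <- setdiff(seq_len(nv), c(hosp_v, hc_v))
  disp_v <- sort(sample(rest, spec$n_dispensaries))
  lev <- c(rep("hospital", length(hosp_v)),
           rep("health_centre", length(hc_v)),
           rep("dispensary", length(disp_v)))
  vidx <- c(hosp_v, hc_v, disp_v)
  nfl <- length(hc_v) + length(disp_v)
  sba_class <- sample(c(0L, 1L, 2L), nfl, replace = TRUE,
                      prob = spec$staffing_fractions)
  sba_fl <- ifelse(sba_class == 2L, 2L + rpois_compat(nfl, 0.8), sba_class)
  sba <- c(rep(8L, length(hosp_v)) + rpois_compat(length(hosp_v), 4), sba_fl)
  case_fl <- pmax(2, round(rlnorm(nfl, spec$caseload_meanlog,
                                  spec$caseload_sdlog)))
  miss <- runif(nfl) < spec$missing_caseload_fraction
  case_fl[miss] <- NA
  fl_total <- sum(case_fl, na.rm = TRUE)
  s <- spec$hospital_delivery_share
  hosp_total <- if (length(hosp_v)) round(fl_total * s / (1 - s)) else 0
  hosp_case <- if (length(hosp_v))
    diff(round(seq(0, hosp_total, length.out = length(hosp_v) + 1))) else
      integer(0)
  ft <- facility_table(data.frame(
    id = sprintf("F%03d", seq_along(vidx)),
    name = paste0("facility_", seq_along(vidx)),
    level = lev,
    x = villages$x[vidx], y = villages$y[vidx],
    sba_count = sba,
    deliveries = c(hosp_case, case_fl),
    offers_delivery = TRUE))
  list(roads = roads, facilities = ft)
}

rpois_compat <- function(n, lambda) {
  if (n == 0) return(integer(0))
  stats::rpois(n, lambda)
}

#' Generate a full synthetic district
#'
#' Runs terrain, settlement and road/facility generation in sequence under
#' the spec seed. Fully deterministic: the same spec yields bit-identical
#' outputs.
#'
#' @param spec a [district_spec()].
#' @return List: `spec`, `terrain`, `landuse`, `pop`, `villages`, `roads`,
#'   `facilities`.
#' @export
make_district <- function(spec = district_spec()) {
  tl <- make_terrain(spec)
  st <- make_settlements(spec, tl$terrain, tl$landuse)
  rf <- make_roads_facilities(spec, st$villages)
  list(spec = spec, terrain = tl$terrain, landuse = tl$landuse,
       pop = st$pop, villages = st$villages, roads = rf$roads,
       facilities = rf$facilities)
}

#' The packaged reference district
#'
#' The fixture all end-to-end acceptance properties run against: the
#' default [district_spec()] at seed 42 (27 x 27 km, 90 m cells, 90
#' villages, 120k people, 20 delivery facilities of which one hospital).
#'
#' @param seed seed override.
#' @return A district list from [make_district()].
#' @export
reference_district <- function(seed = 42) {
  make_district(district_spec(seed = seed))
}

#' Write a district to disk in the exchange formats
#'
#' Terrain/land-use/population as ASCII rasters, roads as GeoJSON,
#' facilities as CSV.
#'
#' @param district a [make_district()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the paths written.
#' @export
write_district <- function(district, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    terrain = file.path(dir, "terrain.asc"),
    landuse = file.path(dir, "landuse.asc"),
    population = file.path(dir, "population.asc"),
    roads = file.path(dir, "roads.geojson"),
    facilities = file.path(dir, "facilities.csv"))
  write_raster(district$terrain, paths["terrain"])
  write_raster(district$landuse, paths["landuse"])
  write_raster(district$pop, paths["population"])
  write_roads(district$roads, paths["roads"])
  write_facilities(district$facilities, paths["facilities"])
  paths
}
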