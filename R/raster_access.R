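# ---------------------------------------------------------------------------
# Raster cost-surface engine -------------------------------------------------
#
# Anisotropic accumulated-cost analysis on the elevation grid. Each legal
# move between adjacent cells gets a crossing time from the walking rule
# (signed slope along the move) and the mean friction coefficients of the
# two cells; accumulated times from the facility set are exact multi-source
# shortest-path distances (priority-queue Dijkstra, not a scan
# approximation). Because the rule is asymmetric, accumulation runs over
# the transposed move graph so a cell's value is the time to *reach* the
# nearest facility, not to be reached from it.

#' Horn slope of a terrain model, in percent
#'
#' Standard 3x3 finite-difference (Horn) stencil. Edge cells use replicated
#' borders; masked neighbours fall back on the centre cell's elevation, and
#' masked cells themselves stay masked.
#'
#' @param terrain a [terrain_model()].
#' @return Matrix of slopes in percent (`100 * rise/run`), `NA` where
#'   masked.
#' @export
slope_grid <- function(terrain) {
  z <- terrain$values
  nr <- nrow(z); nc <- ncol(z)
  if (sum(!is.na(z)) < 4 || nr < 2 || nc < 2)
    stop("need at least a 2x2 block of non-masked cells for slope")
  zp <- matrix(NA_real_, nr + 2, nc + 2)
  zp[2:(nr + 1), 2:(nc + 1)] <- z
  zp[1, ] <- zp[2, ]; zp[nr + 2, ] <- zp[nr + 1, ]
  zp[, 1] <- zp[, 2]; zp[, nc + 2] <- zp[, nc + 1]
  ctr <- zp[2:(nr + 1), 2:(nc + 1)]
  nb <- function(dr, dc) {
    m <- zp[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    m[is.na(m)] <- ctr[is.na(m)]
    m
  }
  a <- nb(-1, -1); b <- nb(-1, 0); cc <- nb(-1, 1)
  d <- nb(0, -1);                  f <- nb(0, 1)
  g <- nb(1, -1);  h <- nb(1, 0);  i <- nb(1, 1)
  cs <- terrain$cell_size
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * cs)
  s <- 100 * sqrt(dzdx^2 + dzdy^2)
  s[is.na(z)] <- NA_real_
  s
}

#' Cost context for the raster engine
#'
#' @param terrain a [terrain_model()].
#' @param landuse a [landuse_grid()] on the same geometry.
#' @param rule a [speed_rule()].
#' @param friction a [friction_table()].
#' @param connectivity 8 (queen moves) or 16 (queen + knight moves).
#' @return A `cost_context` object (slope grid and per-cell coefficients
#'   precomputed).
#' @export
cost_context <- function(terrain, landuse, rule = speed_rule(),
                         friction = friction_table(), connectivity = 16) {
  if (!same_geometry(terrain, landuse))
    stop("terrain and landuse grids are not aligned")
  if (!connectivity %in% c(8, 16)) stop("connectivity must be 8 or 16")
  sl <- slope_grid(terrain)
  scoef <- matrix(slope_class_coeff(as.vector(sl), friction),
                  nrow(sl), ncol(sl))
  lcoef <- matrix(landuse_coeff(as.vector(landuse$values), landuse$season,
                                friction),
                  nrow(sl), ncol(sl))
  structure(list(terrain = terrain, landuse = landuse, rule = rule,
                 friction = friction, connectivity = connectivity,
                 slope_pct = sl, slope_coeff = scoef, landuse_coeff = lcoef),
            class = "cost_context")
}

move_offsets <- function(connectivity) {
  queen <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                 dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  if (connectivity == 8) return(queen)
  knight <- cbind(dr = c(-2, -2, -1, -1, 1, 1, 2, 2),
                  dc = c(-1, 1, -2, 2, -2, 2, -1, 1))
  rbind(queen, knight)
}

#' Minutes for a single move between adjacent cells
#'
#' Signed slope along the move feeds the walking rule; slope-class and
#' land-use coefficients are the arithmetic mean of the two cells'. A
#' barrier at either end is impassable (`Inf`).
#'
#' @param ctx a [cost_context()].
#' @param from,to cells as `c(row, col)`.
#' @return Minutes for the move from `from` to `to`.
#' @export
move_time <- function(ctx, from, to) {
  dr <- to[1] - from[1]; dc <- to[2] - from[2]
  off <- move_offsets(ctx$connectivity)
  if (!any(off[, 1] == dr & off[, 2] == dc))
    stop("cells are not adjacent under ", ctx$connectivity, "-connectivity")
  z <- ctx$terrain$values
  z1 <- z[from[1], from[2]]; z2 <- z[to[1], to[2]]
  if (is.na(z1) || is.na(z2)) stop("masked cell in move")
  if (abs(dr) + abs(dc) == 3) {   # knight moves blocked by barriers en route
    m1 <- from + c(trunc(dr / 2), trunc(dc / 2))
    m2 <- from + c(dr - trunc(dr / 2), dc - trunc(dc / 2))
    for (m in list(m1, m2))
      if (is.na(z[m[1], m[2]]) ||
          !is.finite(ctx$landuse_coeff[m[1], m[2]])) return(Inf)
  }
  dist <- ctx$terrain$cell_size * sqrt(dr^2 + dc^2)
  lc <- (ctx$landuse_coeff[from[1], from[2]] +
         ctx$landuse_coeff[to[1], to[2]]) / 2
  sc <- (ctx$slope_coeff[from[1], from[2]] +
         ctx$slope_coeff[to[1], to[2]]) / 2
  sp <- walking_speed((z2 - z1) / dist, ctx$rule)
  cell_crossing_time(sp, dist, sc, lc)
}

# Build the directed move-edge list for a context. Returns from/to cell
# indices (column-major) and the move time from -> to. Barrier or masked
# endpoints yield no edge.
build_move_edges <- function(ctx) {
  z <- ctx$terrain$values
  nr <- nrow(z); nc <- ncol(z)
  cs <- ctx$terrain$cell_size
  lc <- ctx$landuse_coeff; sc <- ctx$slope_coeff
  off <- move_offsets(ctx$connectivity)
  froms <- tos <- integer(0); wts <- numeric(0)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  for (k in seq_len(nrow(off))) {
    dr <- off[k, 1]; dc <- off[k, 2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    from <- as.vector(idx[r1, c1, drop = FALSE])
    to <- as.vector(idx[r1 + dr, c1 + dc, drop = FALSE])
    ok <- !is.na(z[from]) & !is.na(z[to]) &
      is.finite(lc[from]) & is.finite(lc[to])
    if (abs(dr) + abs(dc) == 3) {   # knight moves must not leap barriers
      m1r <- trunc(dr / 2); m1c <- trunc(dc / 2)
      mid1 <- as.vector(idx[r1 + m1r, c1 + m1c, drop = FALSE])
      mid2 <- as.vector(idx[r1 + (dr - m1r), c1 + (dc - m1c), drop = FALSE])
      ok <- ok & !is.na(z[mid1]) & is.finite(lc[mid1]) &
        !is.na(z[mid2]) & is.finite(lc[mid2])
    }
    from <- from[ok]; to <- to[ok]
    if (!length(from)) next
    dist <- cs * sqrt(dr^2 + dc^2)
    sp <- walking_speed((z[to] - z[from]) / dist, ctx$rule)
    w <- (dist / 1000) / sp * 60 * ((sc[from] + sc[to]) / 2) *
      ((lc[from] + lc[to]) / 2)
    froms <- c(froms, from); tos <- c(tos, to); wts <- c(wts, w)
  }
  list(from = froms, to = tos, w = wts)
}

facility_cells <- function(grid, facilities) {
  rc <- xy_cell(grid, facilities$x, facilities$y)
  if (any(is.na(rc$row)))
    stop("facilities outside the grid extent: ",
         paste(facilities$id[is.na(rc$row)], collapse = ", "))
  cbind(row = rc$row, col = rc$col)
}

#' Accumulated travel time to the nearest facility
#'
#' Multi-source shortest-path accumulation over the move graph: each cell
#' receives the minimum over facilities of the least-time path *to* that
#' facility. Barrier and masked cells (and cells cut off by barriers) are
#' `Inf`.
#'
#' @param ctx a [cost_context()].
#' @param sources a [facility_table()], or an integer matrix of
#'   `row, col` source cells.
#' @param mode label recorded on the surface (raster travel is on foot).
#' @return A `travel_time_surface`: minutes matrix plus geometry, source
#'   ids, mode and band width metadata.
#' @export
accumulate <- function(ctx, sources, mode = "pedestrian") {
  z <- ctx$terrain$values
  nr <- nrow(z); nc <- ncol(z)
  if (inherits(sources, "facility_table")) {
    cells <- facility_cells(ctx$terrain, sources)
    ids <- sources$id
  } else {
    cells <- sources
    ids <- paste0("src", seq_len(nrow(cells)))
  }
  src_idx <- (cells[, 2] - 1L) * nr + cells[, 1L]
  valid <- !is.na(z[src_idx]) & is.finite(ctx$landuse_coeff[src_idx])
  if (!any(valid))
    stop("all sources fall on masked or barrier cells")
  edges <- build_move_edges(ctx)
  # transpose: Dijkstra from facilities over reversed moves yields
  # cell -> facility times under the asymmetric rule
  minutes <- cpp_dijkstra(nr * nc, edges$to, edges$from, edges$w,
                          src_idx[valid])
  m <- matrix(minutes, nr, nc)
  m[is.na(z) | !is.finite(ctx$landuse_coeff)] <- Inf
  m[src_idx[valid]] <- 0
  structure(list(minutes = m, cell_size = ctx$terrain$cell_size,
                 origin = ctx$terrain$origin, crs = ctx$terrain$crs,
                 source_ids = ids[valid], mode = mode, band_width = 20),
            class = "travel_time_surface")
}

#' Isochrone band index
#'
#' Band `k` covers times in `((k-1) * width, k * width]`; time 0 (the
#' source itself) is in band 1, and a time exactly on a boundary belongs
#' to the lower band, so "within 2 hours" includes exactly 120 minutes.
#' Times beyond `max` (including `Inf`) are `NA` (beyond range).
#'
#' @param x a `travel_time_surface`, or a numeric vector/matrix of minutes.
#' @param width band width in minutes.
#' @param max largest banded time; must be a multiple of `width`.
#' @return Integer band indices with the shape of the input.
#' @export
band <- function(x, width = 20, max = 120) {
  if (width <= 0) stop("width must be positive")
  if (max %% width != 0) stop("max must be a multiple of width")
  t <- if (inherits(x, "travel_time_surface")) x$minutes else x
  k <- ceiling(unclass(t) / width)
  k[which(t == 0)] <- 1L
  k[which(!is.finite(t) | t > max)] <- NA
  storage.mode(k) <- "integer"
  if (is.matrix(t)) k <- matrix(k, nrow(t), ncol(t))
  k
}

#' Write a travel-time surface as an ASCII raster
#'
#' Minutes per cell; `Inf` (unreachable/barrier) becomes nodata.
#'
#' @param surface a `travel_time_surface`.
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  g <- new_grid(surface$minutes, surface$cell_size, surface$origin,
                surface$crs, "terrain_model")
  write_raster(g, path)
}

#' @export
print.travel_time_surface <- function(x, ...) {
  fin <- x$minutes[is.finite(x$minutes)]
  cat(sprintf(
    "<travel_time_surface> %d x %d cells, %d sources, mode %s\n",
    nrow(x$minutes), ncol(x$minutes), length(x$source_ids), x$mode))
  if (length(fin))
    cat(sprintf("  reachable: %d cells, median %.1f min, max %.1f min\n",
                length(fin), median(fin), max(fin)))
  invisible(x)
}
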