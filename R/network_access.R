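# ---------------------------------------------------------------------------
# Virtual mesh network engine ------------------------------------------------
#
# Where no digital path network exists, pedestrian movement is modelled on
# a virtual mesh: hexagons subdivided into six equilateral triangles, i.e.
# a triangular lattice of nodes with spacing equal to the configured side
# (<= 223 m by default), every edge exactly one side long. The mapped road
# network is merged in (densified, snapped, or tied to surrounding mesh
# nodes), edges carry direction-dependent pedestrian times from the walking
# rule plus symmetric vehicular times on motorable classes, and service
# areas come from exact multi-source shortest paths toward the facilities.

#' Generate a hexagonal/triangular virtual mesh
#'
#' Nodes form a triangular lattice (hexagon vertices + centres) with
#' spacing `side`; each node links to its six neighbours, so every mesh
#' edge has length exactly `side`. Node elevations are sampled from the
#' terrain model; nodes falling on barrier or masked cells, or outside the
#' terrain, are removed together with their edges.
#'
#' @param extent `c(xmin, ymin, xmax, ymax)` in projected metres.
#' @param side node spacing in metres (the mesh side).
#' @param terrain a [terrain_model()].
#' @param landuse a [landuse_grid()] aligned with `terrain`.
#' @return A `mesh_graph`: `nodes` (id, x, y, elev) and `edges` (from, to,
#'   length, kind, road_class, ped/veh flags, times once weighted).
#' @export
generate_mesh <- function(extent, side = 223, terrain, landuse) {
  stopifnot(length(extent) == 4, side > 0)
  if (extent[3] - extent[1] < 2 * side || extent[4] - extent[2] < 2 * side)
    stop("extent is smaller than one hexagon (needs >= 2 sides each way)")
  if (!same_geometry(terrain, landuse))
    stop("terrain and landuse grids are not aligned")
  dy <- side * sqrt(3) / 2
  n_rows <- floor((extent[4] - extent[2]) / dy) + 1
  xs <- list(); ys <- list(); ri <- list(); ci <- list()
  for (i in seq_len(n_rows) - 1L) {
    offset <- (i %% 2) * side / 2
    n_cols <- floor((extent[3] - extent[1] - offset) / side) + 1
    if (n_cols < 1) next
    j <- seq_len(n_cols) - 1L
    xs[[i + 1]] <- extent[1] + offset + j * side
    ys[[i + 1]] <- rep(extent[2] + i * dy, n_cols)
    ri[[i + 1]] <- rep(i, n_cols); ci[[i + 1]] <- j
  }
  x <- unlist(xs); y <- unlist(ys)
  row <- unlist(ri); col <- unlist(ci)
  rc <- xy_cell(terrain, x, y)
  inside <- !is.na(rc$row)
  elev <- rep(NA_real_, length(x))
  lu <- rep(NA_character_, length(x))
  ii <- which(inside)
  cell <- (rc$col[ii] - 1L) * nrow(terrain$values) + rc$row[ii]
  elev[ii] <- terrain$values[cell]
  lu[ii] <- as.vector(landuse$values)[cell]
  keep <- inside & !is.na(elev) & lu != "barrier"
  if (!any(keep)) stop("no mesh nodes remain (all-barrier or empty extent)")

  id <- integer(length(x)); id[keep] <- seq_len(sum(keep))
  key <- paste(row, col)
  lookup <- new.env(hash = TRUE, size = length(x))
  for (k in which(keep)) assign(key[k], k, envir = lookup)
  neighbour <- function(k, drow, dcol) {
    nk <- mget(paste(row[k] + drow, col[k] + dcol), envir = lookup,
               ifnotfound = NA)
    unlist(nk, use.names = FALSE)
  }
  kk <- which(keep)
  ef <- integer(0); et <- integer(0)
  # east neighbour, plus the two upward neighbours (j, j-1 from even rows;
  # j, j+1 from odd rows): each undirected lattice edge emitted once
  up_shift <- ifelse(row[kk] %% 2 == 0, -1L, 1L)
  cand <- cbind(neighbour(kk, 0, 1), neighbour(kk, 1, 0),
                neighbour(kk, rep(1, length(kk)), up_shift))
  for (cix in 1:3) {
    to_raw <- cand[, cix]
    ok <- !is.na(to_raw)
    ef <- c(ef, id[kk[ok]]); et <- c(et, id[to_raw[ok]])
  }
  nodes <- data.frame(id = seq_len(sum(keep)), x = x[keep], y = y[keep],
                      elev = elev[keep])
  edges <- data.frame(from = ef, to = et, length = rep(side, length(ef)),
                      kind = "mesh", road_class = NA_character_,
                      ped = TRUE, veh = FALSE,
                      time_fwd = NA_real_, time_rev = NA_real_,
                      time_veh = NA_real_)
  structure(list(nodes = nodes, edges = edges, side = side,
                 crs = terrain$crs),
            class = "mesh_graph")
}

#' @export
print.mesh_graph <- function(x, ...) {
  cat(sprintf("<mesh_graph> %d nodes, %d edges (%d road), side %.6g m\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$kind == "road"), x$side))
  invisible(x)
}

#' Merge the real road network into a mesh graph
#'
#' Road polylines are densified so no segment exceeds the mesh side, then
#' stitched in: vertices within `snap_tolerance` of an existing node reuse
#' it; otherwise a new node is inserted and tied to its nearest mesh nodes
#' (up to three within one side) so the graph stays connected. Road edges
#' are walkable by everyone and drivable when the class is motorable. Road
#' edges may cross barrier water (mapped roads imply crossings); mesh edges
#' never do.
#'
#' @param graph a [generate_mesh()] result.
#' @param roads a [road_network()].
#' @param terrain terrain model used to sample elevations of new nodes.
#' @param snap_tolerance snap distance in metres.
#' @return The augmented `mesh_graph`.
#' @export
merge_roads <- function(graph, roads, terrain, snap_tolerance = 20) {
  if (length(roads$segments) == 0) return(graph)
  nodes <- graph$nodes; edges <- graph$edges
  side <- graph$side
  sample_elev <- function(x, y) {
    rc <- xy_cell(terrain, x, y)
    ifelse(is.na(rc$row), NA_real_,
           terrain$values[cbind(rc$row, rc$col)])
  }
  new_edge_chunks <- list()
  for (s in seq_along(roads$segments)) {
    seg <- densify_polyline(roads$segments[[s]], side)
    cls <- roads$road_class[s]
    hit <- cpp_nearest_point(seg[, 1], seg[, 2], nodes$x, nodes$y,
                             snap_tolerance)
    node_ids <- ifelse(is.na(hit), NA_integer_, nodes$id[hit])
    fresh <- which(is.na(node_ids))
    if (length(fresh)) {
      nid <- nrow(nodes) + seq_along(fresh)
      ez <- sample_elev(seg[fresh, 1], seg[fresh, 2])
      ez[is.na(ez)] <- mean(nodes$elev, na.rm = TRUE)
      # tie each inserted node to its surrounding mesh nodes (<= 3 within
      # one side) so road vertices stay attached to the walkable mesh
      anchor_from <- integer(0); anchor_to <- integer(0)
      anchor_len <- numeric(0)
      for (w in seq_along(fresh)) {
        v <- fresh[w]
        d2 <- (nodes$x - seg[v, 1])^2 + (nodes$y - seg[v, 2])^2
        near <- order(d2)[1:min(3, length(d2))]
        near <- near[d2[near] <= side^2 & d2[near] > 0]
        if (length(near)) {
          anchor_from <- c(anchor_from, rep(nid[w], length(near)))
          anchor_to <- c(anchor_to, nodes$id[near])
          anchor_len <- c(anchor_len, sqrt(d2[near]))
        }
      }
      nodes <- rbind(nodes, data.frame(id = nid, x = seg[fresh, 1],
                                       y = seg[fresh, 2], elev = ez))
      node_ids[fresh] <- nid
      if (length(anchor_from))
        new_edge_chunks[[length(new_edge_chunks) + 1]] <- data.frame(
          from = anchor_from, to = anchor_to, length = anchor_len,
          kind = "mesh", road_class = NA_character_, ped = TRUE,
          veh = FALSE, time_fwd = NA_real_, time_rev = NA_real_,
          time_veh = NA_real_)
    }
    fr <- node_ids[-length(node_ids)]; to <- node_ids[-1]
    dup <- fr == to
    fr <- fr[!dup]; to <- to[!dup]
    if (length(fr)) {
      len <- sqrt((nodes$x[fr] - nodes$x[to])^2 +
                  (nodes$y[fr] - nodes$y[to])^2)
      new_edge_chunks[[length(new_edge_chunks) + 1]] <- data.frame(
        from = fr, to = to, length = len, kind = "road", road_class = cls,
        ped = TRUE, veh = cls %in% MOTORABLE_CLASSES,
        time_fwd = NA_real_, time_rev = NA_real_, time_veh = NA_real_)
    }
  }
  if (length(new_edge_chunks))
    edges <- do.call(rbind, c(list(edges), new_edge_chunks))
  graph$nodes <- nodes
  graph$edges <- edges
  graph
}

densify_polyline <- function(m, max_len) {
  out <- m[1, , drop = FALSE]
  for (v in 2:nrow(m)) {
    a <- m[v - 1, ]; b <- m[v, ]
    len <- sqrt(sum((b - a)^2))
    npts <- max(1, ceiling(len / max_len))
    frac <- seq_len(npts) / npts
    out <- rbind(out, cbind(a[1] + frac * (b[1] - a[1]),
                            a[2] + frac * (b[2] - a[2])))
  }
  out
}

#' Assign direction-dependent travel times to graph edges
#'
#' Pedestrian times evaluate the walking rule on each edge's signed slope,
#' separately per direction, multiplied by the slope-class coefficient of
#' the edge grade and (for mesh edges) the mean land-use coefficient of the
#' two endpoint cells; road edges are treated as cleared corridors
#' (land-use coefficient 1). Vehicular times are symmetric
#' `length / vehicle_speed(class)` on motorable road edges.
#'
#' @param graph a `mesh_graph` with node elevations populated.
#' @param rule a [speed_rule()].
#' @param friction a [friction_table()].
#' @param roads a [road_speed_table()].
#' @param landuse the [landuse_grid()] supplying per-node land-use.
#' @return The graph with `time_fwd`, `time_rev` (pedestrian minutes) and
#'   `time_veh` (vehicular minutes, `NA` on non-drivable edges) set.
#' @export
weight_edges <- function(graph, rule = speed_rule(),
                         friction = friction_table(),
                         roads = road_speed_table(), landuse) {
  nodes <- graph$nodes; e <- graph$edges
  if (any(is.na(nodes$elev))) stop("node elevations missing; cannot weight")
  rc <- xy_cell(landuse, nodes$x, nodes$y)
  lu <- rep("open", nrow(nodes))
  ok <- !is.na(rc$row)
  lu[ok] <- landuse$values[cbind(rc$row[ok], rc$col[ok])]
  lu[is.na(lu) | lu == "barrier"] <- "open"  # road nodes over water
  lcoef <- landuse_coeff(lu, landuse$season, friction)

  dz <- nodes$elev[e$to] - nodes$elev[e$from]
  slope <- dz / e$length
  scoef <- slope_class_coeff(100 * abs(slope), friction)
  lc <- ifelse(e$kind == "road", 1, (lcoef[e$from] + lcoef[e$to]) / 2)
  e$time_fwd <- cell_crossing_time(walking_speed(slope, rule), e$length,
                                   scoef, lc)
  e$time_rev <- cell_crossing_time(walking_speed(-slope, rule), e$length,
                                   scoef, lc)
  e$time_veh <- NA_real_
  drivable <- which(e$veh)
  if (length(drivable))
    e$time_veh[drivable] <- (e$length[drivable] / 1000) /
      vehicle_speed(e$road_class[drivable], roads) * 60
  graph$edges <- e
  graph
}

#' Map point locations to their nearest mesh nodes
#'
#' @param graph a `mesh_graph`.
#' @param x,y projected coordinates.
#' @param max_dist maximum allowed snap distance (default one mesh side).
#' @return Integer node ids; errors if any point is farther than
#'   `max_dist` from every node.
#' @export
map_to_node <- function(graph, x, y, max_dist = graph$side) {
  hit <- cpp_nearest_point(x, y, graph$nodes$x, graph$nodes$y, max_dist)
  if (any(is.na(hit)))
    stop("point(s) farther than ", max_dist, " m from any graph node")
  graph$nodes$id[hit]
}

directed_edge_list <- function(graph, mode) {
  e <- graph$edges
  wf <- e$time_fwd; wr <- e$time_rev
  if (mode == "multimodal" && !is.null(e$time_veh)) {
    wf <- pmin(wf, e$time_veh, na.rm = TRUE)
    wr <- pmin(wr, e$time_veh, na.rm = TRUE)
  }
  list(from = c(e$from, e$to), to = c(e$to, e$from), w = c(wf, wr))
}

#' Shortest travel times from every node to the nearest facility
#'
#' Exact multi-source shortest paths with directionally correct edge times
#' (the value at a node is the time to walk *to* the nearest facility).
#' Multimodal mode takes the minimum of walking and riding on every edge,
#' with free transfer at nodes: riding is allowed only on motorable-class
#' road edges, so multimodal times are a lower envelope of pedestrian
#' times.
#'
#' @param graph a weighted `mesh_graph`.
#' @param facilities a [facility_table()] (or data.frame with x, y, id).
#' @param mode `"pedestrian"` or `"multimodal"`.
#' @return Numeric vector of minutes per node (`Inf` if unreachable), with
#'   attribute `facility_nodes` naming each facility's graph node.
#' @export
shortest_times <- function(graph, facilities, mode = c("pedestrian",
                                                       "multimodal")) {
  mode <- match.arg(mode)
  if (any(is.na(graph$edges$time_fwd)))
    stop("graph is not weighted; call weight_edges() first")
  fnodes <- map_to_node(graph, facilities$x, facilities$y)
  el <- directed_edge_list(graph, mode)
  # transposed graph: sources expand along reversed edges so each node
  # gets its to-facility time under the asymmetric rule
  minutes <- cpp_dijkstra(nrow(graph$nodes), el$to, el$from, el$w, fnodes)
  attr(minutes, "facility_nodes") <- setNames(fnodes, facilities$id)
  attr(minutes, "mode") <- mode
  minutes
}

#' Service area of one facility by travel-time bands
#'
#' Bands use the same boundary convention as the raster engine: band `k`
#' covers `((k-1) * width, k * width]`, the facility node is in band 1,
#' times beyond `max` are beyond-range. Bands are nested by construction.
#'
#' @param graph a weighted `mesh_graph`.
#' @param facility single-row facility (x, y, id).
#' @param band_width band width in minutes.
#' @param max largest banded time in minutes.
#' @param mode travel mode.
#' @return A `service_area`: facility id, per-node minutes, per-node band
#'   index and the list of node-id sets per band.
#' @export
service_area <- function(graph, facility, band_width = 20, max = 120,
                         mode = "pedestrian") {
  minutes <- shortest_times(graph, facility[1, , drop = FALSE], mode)
  bd <- band(as.numeric(minutes), band_width, max)
  nb <- max %/% band_width
  bands <- lapply(seq_len(nb), function(k)
    graph$nodes$id[!is.na(bd) & bd <= k])
  structure(list(facility_id = facility$id[1], minutes = as.numeric(minutes),
                 band_index = bd, bands = bands, band_width = band_width,
                 max = max),
            class = "service_area")
}

#' Serialize a mesh graph
#'
#' Writes the edge list as CSV (node coordinates joined on) and the edges
#' as a GeoJSON FeatureCollection of LineStrings with time attributes.
#'
#' @param graph a `mesh_graph`.
#' @param csv_path,geojson_path output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_mesh <- function(graph, csv_path = NULL, geojson_path = NULL) {
  e <- graph$edges; n <- graph$nodes
  out <- character(0)
  if (!is.null(csv_path)) {
    df <- cbind(e, x1 = n$x[e$from], y1 = n$y[e$from],
                x2 = n$x[e$to], y2 = n$y[e$to])
    write.csv(df, csv_path, row.names = FALSE, na = "")
    out <- c(out, csv_path)
  }
  if (!is.null(geojson_path)) {
    feats <- lapply(seq_len(nrow(e)), function(i) {
      list(type = "Feature",
           properties = list(kind = e$kind[i], road_class = e$road_class[i],
                             time_fwd = e$time_fwd[i],
                             time_rev = e$time_rev[i]),
           geometry = list(type = "LineString",
                           coordinates = list(c(n$x[e$from[i]], n$y[e$from[i]]),
                                              c(n$x[e$to[i]], n$y[e$to[i]]))))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         geojson_path, auto_unbox = TRUE, digits = NA)
    out <- c(out, geojson_path)
  }
  invisible(out)
}
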