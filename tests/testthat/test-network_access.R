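make_flat_world <- function(n = 20, cell = 90) {
  list(terrain = terrain_model(matrix(500, n, n), cell),
       landuse = landuse_grid(matrix("open", n, n), "dry", cell))
}

test_that("generate_mesh matches the closed-form lattice counts", {
  w <- make_flat_world(12)
  ext <- c(0, 0, 1000, 1000)
  side <- 223
  mesh <- generate_mesh(ext, side, w$terrain, w$landuse)
  # closed form: rows at spacing side*sqrt(3)/2; even rows n1 nodes,
  # odd rows (offset side/2) n2 nodes
  dy <- side * sqrt(3) / 2
  nrow_lat <- floor(1000 / dy) + 1
  n_even <- floor(1000 / side) + 1
  n_odd <- floor((1000 - side / 2) / side) + 1
  want_nodes <- sum(ifelse((seq_len(nrow_lat) - 1) %% 2 == 0, n_even, n_odd))
  expect_identical(nrow(mesh$nodes), as.integer(want_nodes))
  expect_true(all(mesh$edges$length <= side + 1e-9))
  # every node has <= 6 mesh neighbours
  degree <- tabulate(c(mesh$edges$from, mesh$edges$to), nrow(mesh$nodes))
  expect_true(all(degree <= 6))
  expect_error(generate_mesh(c(0, 0, 300, 300), 223, w$terrain, w$landuse),
               "hexagon")
})

test_that("generate_mesh drops barrier nodes; all-barrier extents error", {
  n <- 12
  cats <- matrix("open", n, n); cats[, 5:7] <- "barrier"
  terrain <- terrain_model(matrix(500, n, n), 90)
  landuse <- landuse_grid(cats, "dry", 90)
  mesh <- generate_mesh(c(0, 0, n * 90, n * 90), 100, terrain, landuse)
  rc <- xy_cell(landuse, mesh$nodes$x, mesh$nodes$y)
  expect_true(all(landuse$values[cbind(rc$row, rc$col)] != "barrier"))
  allbar <- landuse_grid(matrix("barrier", n, n), "dry", 90)
  expect_error(generate_mesh(c(0, 0, n * 90, n * 90), 100, terrain, allbar),
               "no mesh nodes")
})

test_that("weight_edges: level and sloped edges, vehicular times", {
  w <- make_flat_world(30)
  mesh <- generate_mesh(c(0, 0, 2000, 2000), 200, w$terrain, w$landuse)
  mesh <- weight_edges(mesh, landuse = w$landuse)
  # level 200 m open dry edge: 0.2/4*60 * 0.98 * 0.95 (both directions)
  expect_equal(unique(round(mesh$edges$time_fwd, 10)),
               round(0.2 / 4 * 60 * 0.98 * 0.95, 10))
  expect_equal(mesh$edges$time_fwd, mesh$edges$time_rev)

  # climbing edge: forward slower than reverse
  z <- matrix(500, 30, 30)
  z[, 16:30] <- 540
  terrain2 <- terrain_model(z, 90)
  mesh2 <- generate_mesh(c(0, 0, 2000, 2000), 200, terrain2, w$landuse)
  mesh2 <- weight_edges(mesh2, landuse = w$landuse)
  asym <- abs(mesh2$edges$time_fwd - mesh2$edges$time_rev)
  expect_true(any(asym > 1e-9))
  up <- which(mesh2$nodes$elev[mesh2$edges$to] >
                mesh2$nodes$elev[mesh2$edges$from])
  expect_true(all(mesh2$edges$time_fwd[up] > mesh2$edges$time_rev[up]))

  # tarmac road edge, 1 km at 75 km/h -> 0.8 min
  road <- road_network(list(cbind(c(0, 1000), c(905, 905))), "tarmac")
  mesh3 <- merge_roads(mesh, road, w$terrain)
  mesh3 <- weight_edges(mesh3, landuse = w$landuse)
  veh <- mesh3$edges$time_veh[mesh3$edges$kind == "road"]
  expect_equal(sum(veh, na.rm = TRUE), 1000 / 1000 / 75 * 60,
               tolerance = 1e-9)
})

test_that("merge_roads snaps, densifies and keeps the graph connected", {
  w <- make_flat_world(30)
  mesh <- generate_mesh(c(0, 0, 2500, 2500), 223, w$terrain, w$landuse)
  n0 <- nrow(mesh$nodes)
  # endpoint within tolerance of an existing node: snapped, no new node
  nd <- mesh$nodes[5, ]
  tiny <- road_network(list(cbind(c(nd$x + 1, nd$x + 150),
                                  c(nd$y, nd$y + 10))), "motorable")
  m2 <- merge_roads(mesh, tiny, w$terrain, snap_tolerance = 5)
  expect_true(any(m2$edges$kind == "road"))
  expect_true(all(m2$edges$length[m2$edges$kind == "road"] <= 223 + 1e-9))
  # long diagonal road: densified into <= side pieces, graph connected
  rd <- road_network(list(cbind(c(30, 2470), c(40, 2460))), "loose_surface")
  m3 <- merge_roads(mesh, rd, w$terrain)
  m3 <- weight_edges(m3, landuse = w$landuse)
  fac <- data.frame(id = "f", x = 1200, y = 1200)
  mins <- shortest_times(m3, fac)
  expect_true(all(is.finite(mins)))
  # empty road set returned unchanged
  empty <- road_network(list(), character(0))
  expect_identical(merge_roads(mesh, empty, w$terrain), mesh)
})

test_that("roads bridge barrier water that blocks the mesh", {
  n <- 21
  cats <- matrix("open", n, n)
  cats[, 10:12] <- "barrier"   # a lake strip splitting the district
  terrain <- terrain_model(matrix(500, n, n), 90)
  landuse <- landuse_grid(cats, "dry", 90)
  ext <- c(0, 0, n * 90, n * 90)
  mesh <- generate_mesh(ext, 150, terrain, landuse)
  mesh_w <- weight_edges(mesh, landuse = landuse)
  fac <- data.frame(id = "f", x = 200, y = 900)
  east_nodes <- mesh$nodes$x > 12 * 90
  expect_true(all(!is.finite(shortest_times(mesh_w, fac)[east_nodes])))
  bridge <- road_network(list(cbind(c(200, 1700), c(900, 900))), "motorable")
  m2 <- merge_roads(mesh, bridge, terrain)
  m2 <- weight_edges(m2, landuse = landuse)
  mins <- shortest_times(m2, fac)
  expect_true(all(is.finite(mins[east_nodes])))
})

test_that("shortest_times equals the dense oracle; multimodal dominates", {
  for (seed in c(5, 17)) {
    g <- random_mesh_fixture(seed)
    expect_lte(nrow(g$nodes), 200)
    fac <- data.frame(id = c("a", "b"),
                      x = g$nodes$x[c(3, nrow(g$nodes) - 2)],
                      y = g$nodes$y[c(3, nrow(g$nodes) - 2)])
    for (mode in c("pedestrian", "multimodal")) {
      got <- as.numeric(shortest_times(g, fac, mode))
      fn <- map_to_node(g, fac$x, fac$y)
      want <- oracle_graph_minutes(g, fn, mode)
      expect_equal(got, want, tolerance = 1e-9)
    }
    ped <- as.numeric(shortest_times(g, fac, "pedestrian"))
    mm <- as.numeric(shortest_times(g, fac, "multimodal"))
    expect_true(all(mm <= ped + 1e-9))
  }
})

test_that("facility mapping errors beyond one mesh side; single-edge path", {
  w <- make_flat_world(30)
  mesh <- generate_mesh(c(100, 100, 2300, 2300), 200, w$terrain, w$landuse)
  mesh <- weight_edges(mesh, landuse = w$landuse)
  expect_error(map_to_node(mesh, 1e6, 1e6), "farther")
  # facility at a node: adjacent level open-dry 200 m neighbour takes
  # 0.2/4*60*0.95*0.98 minutes
  nd <- mesh$nodes[10, ]
  mins <- shortest_times(mesh, data.frame(id = "f", x = nd$x, y = nd$y))
  adj <- mesh$edges$to[mesh$edges$from == nd$id]
  expect_equal(unname(mins[adj[1]]), 0.2 / 4 * 60 * 0.95 * 0.98)
})

test_that("service areas are nested rings; isolated components beyond range", {
  w <- make_flat_world(40)
  mesh <- generate_mesh(c(0, 0, 3500, 3500), 200, w$terrain, w$landuse)
  mesh <- weight_edges(mesh, landuse = w$landuse)
  ctr <- mesh$nodes[which.min((mesh$nodes$x - 1750)^2 +
                                (mesh$nodes$y - 1750)^2), ]
  fac <- data.frame(id = "f", x = ctr$x, y = ctr$y)
  sa <- service_area(mesh, fac, band_width = 5, max = 30)
  for (k in seq_len(length(sa$bands) - 1))
    expect_true(all(sa$bands[[k]] %in% sa$bands[[k + 1]]))
  expect_identical(sa$minutes[ctr$id], 0)
  # flat uniform mesh: minutes = hex graph distance * single-edge time,
  # so bands are concentric hexagonal rings
  t_edge <- 0.2 / 4 * 60 * 0.95 * 0.98
  hops <- round(sa$minutes / t_edge)
  expect_equal(sa$minutes, hops * t_edge, tolerance = 1e-9)
  # ring radii: nodes in hop ring k sit within the k-th hex annulus
  d <- sqrt((mesh$nodes$x - ctr$x)^2 + (mesh$nodes$y - ctr$y)^2)
  fin <- is.finite(sa$minutes)
  expect_true(all(d[fin] <= hops[fin] * 200 + 1e-6))
  expect_true(all(d[fin] >= hops[fin] * 200 * sqrt(3) / 2 - 1e-6))
})
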