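# Independent oracles and small fixtures. The oracles re-derive move times
# from first principles (scalar loops, if-chains, Bellman-Ford relaxation)
# so they share no code path with the package's vectorized/Rcpp engines.

# Langmuir rule, scalar re-derivation -----------------------------------------
o_minutes_per_km <- function(slope) {
  base <- 15
  rise <- slope * 1000
  ang <- atan(slope) * 180 / pi
  if (slope > 0) return(base + 0.1 * rise)
  if (ang < -5 && ang >= -12) return(base - 0.03 * abs(rise))
  if (ang < -12) return(base + 0.03 * abs(rise))
  base
}

o_slope_coeff <- function(pct) {
  s <- abs(pct)
  if (s < 20) 0.98 else if (s < 40) 1.00 else if (s < 60) 1.20 else
    if (s < 80) 1.04 else if (s < 100) 1.06 else 1.08
}

o_lu_coeff <- function(cat, season) {
  tab <- list(dry = c(open = 0.95, bushy = 1.00, forest = 1.05),
              wet = c(open = 1.00, bushy = 1.05, forest = 1.10))
  if (cat == "barrier") return(Inf)
  unname(tab[[season]][cat])
}

# Horn slope percent, scalar loops with edge replication and masked
# neighbours falling back on the centre cell.
o_horn_slope <- function(z, cs) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  at <- function(r, c, ctr) {
    r <- min(max(r, 1), nr); c <- min(max(c, 1), nc)
    v <- z[r, c]
    if (is.na(v)) ctr else v
  }
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    ctr <- z[r, c]
    if (is.na(ctr)) next
    a <- at(r - 1, c - 1, ctr); b <- at(r - 1, c, ctr); cc <- at(r - 1, c + 1, ctr)
    d <- at(r, c - 1, ctr);                              f <- at(r, c + 1, ctr)
    g <- at(r + 1, c - 1, ctr); h <- at(r + 1, c, ctr); i <- at(r + 1, c + 1, ctr)
    dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
    dzdy <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * cs)
    out[r, c] <- 100 * sqrt(dzdx^2 + dzdy^2)
  }
  out
}

# Brute-force accumulated to-facility minutes on a grid: build every move
# from first principles, then Bellman-Ford until fixpoint.
oracle_grid_minutes <- function(z, lucat, season, cs, sources_rc,
                                connectivity = 16) {
  nr <- nrow(z); nc <- ncol(z)
  sl <- o_horn_slope(z, cs)
  scoef <- matrix(NA_real_, nr, nc); lcoef <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!is.na(sl[r, c])) scoef[r, c] <- o_slope_coeff(sl[r, c])
    lcoef[r, c] <- o_lu_coeff(lucat[r, c], season)
  }
  offs <- rbind(cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                      dc = c(-1, 0, 1, -1, 1, -1, 0, 1)))
  if (connectivity == 16)
    offs <- rbind(offs, cbind(dr = c(-2, -2, -1, -1, 1, 1, 2, 2),
                              dc = c(-1, 1, -2, 2, -2, 2, -1, 1)))
  cap <- nr * nc * nrow(offs)
  ef <- integer(cap); et <- integer(cap); ew <- numeric(cap)
  ne <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(z[r, c]) || !is.finite(lcoef[r, c])) next
    for (k in seq_len(nrow(offs))) {
      r2 <- r + offs[k, 1]; c2 <- c + offs[k, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(z[r2, c2]) || !is.finite(lcoef[r2, c2])) next
      if (abs(offs[k, 1]) + abs(offs[k, 2]) == 3) {
        mr <- trunc(offs[k, 1] / 2); mc <- trunc(offs[k, 2] / 2)
        blocked <- FALSE
        for (mm in list(c(r + mr, c + mc),
                        c(r + offs[k, 1] - mr, c + offs[k, 2] - mc))) {
          if (is.na(z[mm[1], mm[2]]) || !is.finite(lcoef[mm[1], mm[2]]))
            blocked <- TRUE
        }
        if (blocked) next
      }
      dist <- cs * sqrt(offs[k, 1]^2 + offs[k, 2]^2)
      slope <- (z[r2, c2] - z[r, c]) / dist
      tmin <- o_minutes_per_km(slope) * dist / 1000 *
        ((scoef[r, c] + scoef[r2, c2]) / 2) *
        ((lcoef[r, c] + lcoef[r2, c2]) / 2)
      ne <- ne + 1L
      ef[ne] <- (c - 1L) * nr + r; et[ne] <- (c2 - 1L) * nr + r2
      ew[ne] <- tmin
    }
  }
  ef <- ef[seq_len(ne)]; et <- et[seq_len(ne)]; ew <- ew[seq_len(ne)]
  d <- rep(Inf, nr * nc)
  for (i in seq_len(nrow(sources_rc))) {
    idx <- (sources_rc[i, 2] - 1L) * nr + sources_rc[i, 1]
    if (!is.na(z[idx]) && is.finite(lcoef[idx])) d[idx] <- 0
  }
  repeat {                                    # relax reversed edges: d(u) via u->v
    nd <- pmin(d, unname(tapply(d[et] + ew, ef, min)[as.character(seq_len(nr * nc))]),
               na.rm = TRUE)
    nd[is.na(nd)] <- Inf
    if (all(nd == d | (!is.finite(nd) & !is.finite(d)))) break
    d <- nd
  }
  matrix(d, nr, nc)
}

# Plain O(V^2) Dijkstra on a dense adjacency matrix (minutes), single source.
oracle_dijkstra_dense <- function(A, source) {
  n <- nrow(A)
  dist <- rep(Inf, n); dist[source] <- 0
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    u <- which(!done & dist == min(dist[!done]))[1]
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    for (v in which(is.finite(A[u, ]))) {
      if (dist[u] + A[u, v] < dist[v]) dist[v] <- dist[u] + A[u, v]
    }
  }
  dist
}

# To-facility node minutes by brute force: dense adjacency of min edge time
# per direction, transposed, multi-source via a virtual run per source.
oracle_graph_minutes <- function(graph, source_nodes, mode = "pedestrian") {
  e <- graph$edges
  n <- nrow(graph$nodes)
  A <- matrix(Inf, n, n)
  for (i in seq_len(nrow(e))) {
    wf <- e$time_fwd[i]; wr <- e$time_rev[i]
    if (mode == "multimodal" && !is.na(e$time_veh[i])) {
      wf <- min(wf, e$time_veh[i]); wr <- min(wr, e$time_veh[i])
    }
    A[e$from[i], e$to[i]] <- min(A[e$from[i], e$to[i]], wf)
    A[e$to[i], e$from[i]] <- min(A[e$to[i], e$from[i]], wr)
  }
  best <- rep(Inf, n)
  for (s in source_nodes)
    best <- pmin(best, oracle_dijkstra_dense(t(A), s))
  best
}

# Fixtures --------------------------------------------------------------------

# Random rugged terrain + mixed land use with barrier blobs, <= 30x30.
random_grid_fixture <- function(seed, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(8:30, 1)
  z <- 1000 + 40 * matrix(rnorm(n * n), n, n)
  # smooth a little so slopes stay plausible
  for (pass in 1:2) {
    zp <- z
    zp[2:(n - 1), 2:(n - 1)] <- (z[1:(n - 2), 2:(n - 1)] + z[3:n, 2:(n - 1)] +
                                 z[2:(n - 1), 1:(n - 2)] + z[2:(n - 1), 3:n] +
                                 z[2:(n - 1), 2:(n - 1)]) / 5
    z <- zp
  }
  cats <- matrix(sample(c("open", "bushy", "forest"), n * n, replace = TRUE,
                        prob = c(0.4, 0.4, 0.2)), n, n)
  nbar <- rpois(1, n / 3)
  if (nbar > 0) {
    ctr <- cbind(sample(n, nbar, replace = TRUE), sample(n, nbar, replace = TRUE))
    for (b in seq_len(nbar)) {
      rr <- pmax(1, pmin(n, ctr[b, 1] + (-1:1)))
      cc <- pmax(1, pmin(n, ctr[b, 2] + (-1:1)))
      cats[rr, cc] <- "barrier"
    }
  }
  season <- sample(c("dry", "wet"), 1)
  src <- NULL
  for (tries in 1:50) {
    cand <- cbind(sample(n, 1), sample(n, 1))
    if (cats[cand] != "barrier") { src <- cand; break }
  }
  terrain <- terrain_model(z, 90)
  landuse <- landuse_grid(cats, season, 90)
  list(terrain = terrain, landuse = landuse, sources = src, season = season,
       n = n)
}

# Small weighted mesh+roads graph (<= ~200 nodes) on random terrain.
random_mesh_fixture <- function(seed) {
  set.seed(seed)
  n <- 20
  z <- 1000 + 30 * matrix(rnorm(n * n), n, n)
  terrain <- terrain_model(z, 90)
  cats <- matrix(sample(c("open", "bushy", "forest", "barrier"), n * n,
                        replace = TRUE, prob = c(0.45, 0.3, 0.2, 0.05)), n, n)
  landuse <- landuse_grid(cats, "dry", 90)
  ext <- c(0, 0, n * 90, n * 90)
  mesh <- generate_mesh(ext, 150, terrain, landuse)
  road <- matrix(c(100, 100, n * 90 - 100, n * 90 - 100), 2, 2, byrow = TRUE)
  roads <- road_network(list(road), sample(c("tarmac", "motorable"), 1))
  mesh <- merge_roads(mesh, roads, terrain)
  weight_edges(mesh, landuse = landuse)
}

# Tiny flat all-open district for closed-form tests.
flat_frictionless_ctx <- function(n = 41, cell = 90, connectivity = 16) {
  fr1 <- friction_table(
    slope = c("0-20" = 1, "20-40" = 1, "40-60" = 1, "60-80" = 1,
              "80-100" = 1, ">100" = 1),
    landuse = list(dry = c(open = 1, bushy = 1, forest = 1),
                   wet = c(open = 1, bushy = 1, forest = 1)))
  tm <- terrain_model(matrix(500, n, n), cell)
  lu <- landuse_grid(matrix("open", n, n), "dry", cell)
  cost_context(tm, lu, friction = fr1, connectivity = connectivity)
}
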