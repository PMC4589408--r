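test_that("terrain generation is deterministic, with exact water fraction", {
  spec <- district_spec(extent_km = 9, n_villages = 12, seed = 5,
                        water_fraction = 0.1)
  a <- make_terrain(spec); b <- make_terrain(spec)
  expect_identical(a$terrain$values, b$terrain$values)
  expect_identical(a$landuse$values, b$landuse$values)
  frac <- mean(a$landuse$values == "barrier")
  expect_lt(abs(frac - 0.1), 0.01)
  # flat spec: all slopes zero
  flat <- make_terrain(district_spec(extent_km = 9, relief_amplitude_m = 0,
                                     water_fraction = 0, seed = 5))
  expect_true(all(slope_grid(flat$terrain) == 0))
})

test_that("settlements conserve population and respond to dispersion", {
  spec <- district_spec(extent_km = 9, n_villages = 10,
                        population_total = 100000, seed = 8)
  tl <- make_terrain(spec)
  st <- make_settlements(spec, tl$terrain, tl$landuse)
  expect_equal(sum(st$pop$values), 100000, tolerance = 1e-6)
  expect_identical(nrow(st$villages), 10L)
  # villages sit on non-barrier cells
  expect_true(all(tl$landuse$values[cbind(st$villages$row,
                                          st$villages$col)] != "barrier"))
  # one village: unimodal (single connected region at half-peak)
  sp1 <- district_spec(extent_km = 9, n_villages = 1, seed = 8)
  t1 <- make_terrain(sp1)
  s1 <- make_settlements(sp1, t1$terrain, t1$landuse)
  peak <- which(s1$pop$values == max(s1$pop$values), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(s1$villages$row[1], s1$villages$col[1]))
  # higher dispersion -> higher spatial entropy
  ent <- function(spec) {
    tl <- make_terrain(spec)
    p <- make_settlements(spec, tl$terrain, tl$landuse)$pop$values
    p <- p[p > 0] / sum(p)
    -sum(p * log(p))
  }
  lo <- ent(district_spec(extent_km = 9, clustering_dispersion_km = 0.4,
                          seed = 21, n_villages = 10))
  hi <- ent(district_spec(extent_km = 9, clustering_dispersion_km = 1.6,
                          seed = 21, n_villages = 10))
  expect_gt(hi, lo)
})

test_that("roads form a connected classed network; facilities at villages", {
  spec <- district_spec(extent_km = 12, n_villages = 20, n_dispensaries = 6,
                        n_health_centres = 2, n_hospitals = 1, seed = 3)
  d <- make_district(spec)
  expect_true(all(d$roads$road_class %in%
                    c("tarmac", "loose_surface", "dry_weather", "motorable",
                      "footpath")))
  # connectivity of the village road graph (union-find over segments)
  seg_ends <- do.call(rbind, lapply(d$roads$segments, function(s)
    rbind(s[1, ], s[nrow(s), ])))
  key <- apply(round(seg_ends, 3), 1, paste, collapse = "_")
  # iterative label propagation over segment endpoints
  lbl <- setNames(seq_along(unique(key)), unique(key))
  for (rep in 1:30) {
    for (i in seq_len(length(d$roads$segments))) {
      a <- key[2 * i - 1]; b <- key[2 * i]
      m <- min(lbl[a], lbl[b]); lbl[a] <- m; lbl[b] <- m
    }
  }
  expect_identical(length(unique(lbl)), 1L)
  # facility structure
  expect_identical(sum(d$facilities$level == "hospital"), 1L)
  expect_identical(nrow(d$facilities), 9L)
  vil_xy <- paste(d$villages$x, d$villages$y)
  expect_true(all(paste(d$facilities$x, d$facilities$y) %in% vil_xy))
  # hospital at the largest village
  big <- d$villages[which.max(d$villages$size_weight), ]
  hosp <- d$facilities[d$facilities$level == "hospital", ]
  expect_equal(c(hosp$x, hosp$y), c(big$x, big$y))
})

test_that("caseload and staffing distributions mirror the stated structure", {
  frac_under100 <- numeric(0)
  shares <- numeric(0)
  staff0 <- integer(0)
  for (seed in 1:20) {
    spec <- district_spec(extent_km = 18, n_villages = 110,
                          n_dispensaries = 61, n_health_centres = 9,
                          n_hospitals = 1,
                          staffing_fractions = c(0.25, 0.5, 0.25),
                          seed = seed)
    tl <- make_terrain(spec)
    st <- make_settlements(spec, tl$terrain, tl$landuse)
    rf <- make_roads_facilities(spec, st$villages)
    fs <- facility_summary(rf$facilities)
    expect_identical(fs$n_first_line, 70L)
    reported <- fs$n_first_line - unname(fs$caseload["missing"])
    frac_under100 <- c(frac_under100, fs$under_100 / reported)
    shares <- c(shares, fs$hospital_share_pct)
    staff0 <- c(staff0, unname(fs$staffing["0"]))
  }
  # ~70-80% of first-line facilities below 100 deliveries across seeds
  expect_true(all(frac_under100 >= 0.6 & frac_under100 <= 0.9))
  # hospitals absorb a 30-70% share
  expect_true(all(shares > 30 & shares < 70))
  # staffing multinomial about 0.25 * 70 = 17.5
  expect_gt(mean(staff0), 17.5 - 5)
  expect_lt(mean(staff0), 17.5 + 5)
})

test_that("district generation is fully deterministic and errors sensibly", {
  spec <- district_spec(extent_km = 9, n_villages = 8, n_dispensaries = 4,
                        n_health_centres = 1, n_hospitals = 1, seed = 99)
  d1 <- make_district(spec); d2 <- make_district(spec)
  expect_identical(d1$pop$values, d2$pop$values)
  expect_identical(d1$facilities, d2$facilities)
  expect_identical(d1$roads$segments, d2$roads$segments)
  bad <- district_spec(extent_km = 9, n_villages = 4, n_dispensaries = 10,
                       seed = 1)
  tl <- make_terrain(bad)
  st <- make_settlements(bad, tl$terrain, tl$landuse)
  expect_error(make_roads_facilities(bad, st$villages), "more facilities")
})
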