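# ---------------------------------------------------------------------------
# Population coverage and facility descriptive statistics --------------------

#' Cumulative population coverage by travel-time bands
#'
#' Zonal statistics of a population grid over a travel-time surface (raster
#' engine) or over per-node minutes (network engine, with each population
#' cell assigned its nearest graph node's time). Returns cumulative
#' percentages at every band boundary plus summary rows at the access
#' thresholds.
#'
#' @param x a `travel_time_surface`, or the numeric per-node minutes from
#'   [shortest_times()] (then `graph` is required).
#' @param pop a [population_grid()] aligned with the surface.
#' @param band_width band width in minutes.
#' @param thresholds access thresholds in minutes (summary rows).
#' @param scenario scenario label.
#' @param graph the `mesh_graph` behind per-node minutes.
#' @param max_alloc_dist furthest a population cell may sit from a graph
#'   node and still be allocated to it (metres); unallocated population is
#'   beyond range.
#' @return A `coverage_table`: data.frame of `bound` (minutes) and
#'   `cum_pct`, with attributes `summary` (named vector: one entry per
#'   threshold plus the beyond-range remainder), `total_population` and
#'   `scenario`.
#' @export
coverage <- function(x, pop, band_width = 20, thresholds = c(60, 120),
                     scenario = "baseline", graph = NULL,
                     max_alloc_dist = NULL) {
  stopifnot(inherits(pop, "population_grid"))
  if (pop$total_population <= 0) stop("total population is zero")
  if (inherits(x, "travel_time_surface")) {
    g <- new_grid(x$minutes, x$cell_size, x$origin, x$crs, "terrain_model")
    pg <- new_grid(pop$values, pop$cell_size, pop$origin, pop$crs,
                   "terrain_model")
    if (!same_geometry(g, pg))
      stop("population grid is not aligned with the travel-time surface")
    minutes <- as.vector(x$minutes)
    weights <- as.vector(pop$values)
  } else {
    if (is.null(graph)) stop("per-node minutes need the mesh graph")
    if (is.null(max_alloc_dist)) max_alloc_dist <- 5 * graph$side
    minutes <- allocate_population_minutes(as.numeric(x), graph, pop,
                                           max_alloc_dist)
    weights <- as.vector(pop$values)
  }
  weights[is.na(weights)] <- 0
  total <- sum(weights)
  bounds <- seq(band_width, max(thresholds), by = band_width)
  cum_pct <- vapply(bounds, function(b)
    100 * sum(weights[which(minutes <= b)]) / total, numeric(1))
  le <- vapply(thresholds, function(b)
    100 * sum(weights[which(minutes <= b)]) / total, numeric(1))
  summary <- c(setNames(le, paste0("le_", thresholds)),
               setNames(100 - le[length(le)],
                        paste0("gt_", thresholds[length(thresholds)])))
  tab <- data.frame(bound = bounds, cum_pct = cum_pct)
  structure(tab, summary = summary, total_population = total,
            scenario = scenario, band_width = band_width,
            thresholds = thresholds,
            class = c("coverage_table", "data.frame"))
}

# Per-population-cell minutes under the network engine: nearest-node
# allocation, beyond-range (Inf) where no node is close enough.
allocate_population_minutes <- function(node_minutes, graph, pop,
                                        max_alloc_dist) {
  nr <- nrow(pop$values); nc <- ncol(pop$values)
  cells <- which(!is.na(pop$values) & pop$values > 0)
  rows <- ((cells - 1L) %% nr) + 1L
  cols <- ((cells - 1L) %/% nr) + 1L
  xy <- cell_xy(pop, rows, cols)
  hit <- cpp_nearest_point(xy$x, xy$y, graph$nodes$x, graph$nodes$y,
                           max_alloc_dist)
  minutes <- rep(Inf, nr * nc)
  ok <- !is.na(hit)
  minutes[cells[ok]] <- node_minutes[hit[ok]]
  minutes
}

#' Write a coverage table as CSV
#'
#' @param tab a `coverage_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(tab, path) {
  s <- attr(tab, "summary")
  out <- rbind(data.frame(row = paste0("band_", tab$bound),
                          pct = round(tab$cum_pct, 1)),
               data.frame(row = names(s), pct = round(unname(s), 1)))
  out$scenario <- attr(tab, "scenario")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.coverage_table <- function(x, ...) {
  cat(sprintf("<coverage_table> scenario '%s', %.0f people\n",
              attr(x, "scenario"), attr(x, "total_population")))
  print.data.frame(transform(as.data.frame(x), cum_pct = round(cum_pct, 1)))
  s <- attr(x, "summary")
  cat(paste(sprintf("%s: %.1f%%", names(s), s), collapse = "  "), "\n")
  invisible(x)
}

#' Staffing and caseload summary of first-line facilities
#'
#' First-line facilities are dispensaries and health centres; hospitals are
#' always excluded from the staffing and caseload classes. Facilities with
#' unreported caseloads count in the missing class and are excluded from
#' the median, range and the under-100 tally.
#'
#' @param ft a [facility_table()].
#' @return A `facility_summary` list: `n_first_line`, `staffing` (counts
#'   for 0 / 1 / >=2 skilled birth attendants), `caseload` (counts for
#'   0-49 / 50-99 / 100-199 / >=200 / missing), `under_100`,
#'   `median_caseload`, `range_caseload`, `hospital_share_pct`.
#' @export
facility_summary <- function(ft) {
  stopifnot(inherits(ft, "facility_table"), nrow(ft) > 0)
  fl <- ft[ft$level != "hospital" & ft$offers_delivery, ]
  staffing <- c("0" = sum(fl$sba_count == 0),
                "1" = sum(fl$sba_count == 1),
                ">=2" = sum(fl$sba_count >= 2))
  d <- fl$deliveries
  caseload <- c("0-49" = sum(!is.na(d) & d <= 49),
                "50-99" = sum(!is.na(d) & d >= 50 & d <= 99),
                "100-199" = sum(!is.na(d) & d >= 100 & d <= 199),
                ">=200" = sum(!is.na(d) & d >= 200),
                "missing" = sum(is.na(d)))
  rep_d <- d[!is.na(d)]
  share <- tryCatch(hospital_share(ft), error = function(e) NA_real_)
  structure(list(
    n_first_line = nrow(fl),
    staffing = staffing,
    caseload = caseload,
    under_100 = sum(rep_d < 100),
    median_caseload = if (length(rep_d)) median(rep_d) else NA_real_,
    range_caseload = if (length(rep_d)) range(rep_d) else c(NA_real_, NA_real_),
    first_line_deliveries = sum(rep_d),
    hospital_share_pct = share),
    class = "facility_summary")
}

#' @export
print.facility_summary <- function(x, ...) {
  cat(sprintf("<facility_summary> %d first-line facilities\n", x$n_first_line))
  cat("  SBA counts      :", paste(names(x$staffing), x$staffing,
                                   sep = "=", collapse = "  "), "\n")
  cat("  caseload classes:", paste(names(x$caseload), x$caseload,
                                   sep = "=", collapse = "  "), "\n")
  cat(sprintf("  caseload median %s (range %s-%s); <100 in %d; hospital share %.1f%%\n",
              format(x$median_caseload), format(x$range_caseload[1]),
              format(x$range_caseload[2]), x$under_100,
              x$hospital_share_pct))
  invisible(x)
}

#' Hospital share of reported institutional deliveries
#'
#' @param ft a [facility_table()].
#' @param digits rounding for the returned percentage (`NULL` = none).
#' @return Percentage of all reported deliveries taking place in
#'   hospitals.
#' @export
hospital_share <- function(ft, digits = NULL) {
  stopifnot(inherits(ft, "facility_table"))
  hosp <- ft$level == "hospital"
  if (!any(hosp & !is.na(ft$deliveries)))
    stop("no hospital with reported deliveries")
  total <- sum(ft$deliveries, na.rm = TRUE)
  if (total == 0) stop("no reported deliveries")
  pct <- 100 * sum(ft$deliveries[hosp], na.rm = TRUE) / total
  if (!is.null(digits)) round(pct, digits) else pct
}
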