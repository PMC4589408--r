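# ---------------------------------------------------------------------------
# Delivery-site reduction scenarios ------------------------------------------
#
# The planning question: can ~40% of delivery sites be closed while keeping
# roughly 80% of the population within two hours' walk? Site selection is
# greedy maximal coverage: hospitals are locked in, then the facility that
# adds the most population within the 2-hour threshold joins the set, with
# a deterministic tie-break on facility id. Greedy maximal coverage is
# within (1 - 1/e) of the optimum at any fixed site count.

#' Per-facility travel-time columns
#'
#' Runs one single-source accumulation per facility and stacks the results
#' into a units x facilities matrix of minutes: rows are raster cells (with
#' `engine = "raster"`) or population cells allocated to mesh nodes
#' (`engine = "network"`). This matrix is the input the greedy planner and
#' `compare()` work from.
#'
#' @param facilities a [facility_table()].
#' @param ctx a [cost_context()] (raster engine) or weighted `mesh_graph`
#'   (network engine).
#' @param pop a [population_grid()] aligned with the engine's geometry.
#' @param engine `"raster"` or `"network"`.
#' @param mode travel mode for the network engine.
#' @return List with `minutes` (matrix, one column per facility id),
#'   `weights` (population per unit) and `facilities`.
#' @export
facility_travel_times <- function(facilities, ctx, pop,
                                  engine = c("raster", "network"),
                                  mode = "pedestrian") {
  engine <- match.arg(engine)
  n_fac <- nrow(facilities)
  if (engine == "raster") {
    cols <- lapply(seq_len(n_fac), function(i)
      as.vector(accumulate(ctx, facilities[i, , drop = FALSE])$minutes))
    weights <- as.vector(pop$values)
  } else {
    cols <- lapply(seq_len(n_fac), function(i) {
      nm <- shortest_times(ctx, facilities[i, , drop = FALSE], mode)
      allocate_population_minutes(as.numeric(nm), ctx, pop, 5 * ctx$side)
    })
    weights <- as.vector(pop$values)
  }
  weights[is.na(weights)] <- 0
  minutes <- do.call(cbind, cols)
  colnames(minutes) <- facilities$id
  list(minutes = minutes, weights = weights, facilities = facilities)
}

#' Greedy delivery-site reduction
#'
#' Starting from the locked set (hospitals), repeatedly adds the facility
#' with the largest gain in population within `threshold` minutes, until
#' either `target_count` facilities are selected or cumulative coverage
#' reaches `min_coverage` percent. Ties break on ascending facility id.
#' Deterministic and seed-free.
#'
#' @param tt result of [facility_travel_times()].
#' @param target_count total number of facilities to keep (locked
#'   included), or `NULL`.
#' @param min_coverage stop once coverage at `threshold` reaches this
#'   percent, or `NULL`. Infeasible targets (above the all-facility
#'   baseline) error, reporting the baseline.
#' @param threshold coverage threshold in minutes used during selection.
#' @param locked facility ids that are always kept (defaults to all
#'   hospitals).
#' @return A `scenario`: `selected` ids in selection order, `locked` ids,
#'   `coverage_pct` at `threshold` after each addition, and the per-unit
#'   minutes of the selected set.
#' @export
reduce_sites <- function(tt, target_count = NULL, min_coverage = NULL,
                         threshold = 120,
                         locked = tt$facilities$id[tt$facilities$level ==
                                                     "hospital"]) {
  ids <- colnames(tt$minutes)
  stopifnot(all(locked %in% ids))
  if (is.null(target_count) && is.null(min_coverage))
    stop("give target_count or min_coverage")
  total <- sum(tt$weights)
  cov_of <- function(min_vec) 100 * sum(tt$weights[which(min_vec <=
                                                           threshold)]) / total
  baseline <- cov_of(apply_pmin(tt$minutes, ids))
  if (!is.null(min_coverage) && min_coverage > baseline + 1e-9)
    stop(sprintf("coverage target %.1f%% is infeasible: baseline with all facilities is %.1f%%",
                 min_coverage, baseline))
  if (is.null(target_count)) target_count <- length(ids)

  selected <- sort(locked)
  best <- if (length(selected)) apply_pmin(tt$minutes, selected) else
    rep(Inf, nrow(tt$minutes))
  cov_path <- if (length(selected)) cov_of(best) else numeric(0)
  remaining <- setdiff(ids, selected)
  while (length(selected) < target_count && length(remaining) > 0) {
    cur_cov <- cov_of(best)
    if (!is.null(min_coverage) && cur_cov >= min_coverage) break
    gains <- vapply(remaining, function(f) {
      sum(tt$weights[which(tt$minutes[, f] <= threshold & best > threshold)])
    }, numeric(1))
    pick <- remaining[order(-gains, remaining)][1]  # tie-break: id asc
    selected <- c(selected, pick)
    best <- pmin(best, tt$minutes[, pick])
    cov_path <- c(cov_path, cov_of(best))
    remaining <- setdiff(remaining, pick)
  }
  structure(list(selected = selected, locked = sort(locked),
                 coverage_pct = cov_path, threshold = threshold,
                 minutes = best, baseline_pct = baseline),
            class = "scenario")
}

apply_pmin <- function(m, cols) {
  out <- m[, cols[1]]
  for (f in cols[-1]) out <- pmin(out, m[, f])
  out
}

#' Coverage table of a scenario
#'
#' @param scn a `scenario` from [reduce_sites()].
#' @param tt the [facility_travel_times()] the scenario was built from.
#' @param pop the population grid (for the total).
#' @param band_width,thresholds banding as in [coverage()].
#' @param label scenario label.
#' @return A `coverage_table` for the scenario's selected set.
#' @export
scenario_coverage <- function(scn, tt, pop, band_width = 20,
                              thresholds = c(60, 120), label = "reduced") {
  weights <- tt$weights
  total <- sum(weights)
  bounds <- seq(band_width, max(thresholds), by = band_width)
  cum_pct <- vapply(bounds, function(b)
    100 * sum(weights[which(scn$minutes <= b)]) / total, numeric(1))
  le <- vapply(thresholds, function(b)
    100 * sum(weights[which(scn$minutes <= b)]) / total, numeric(1))
  summary <- c(setNames(le, paste0("le_", thresholds)),
               setNames(100 - le[length(le)],
                        paste0("gt_", thresholds[length(thresholds)])))
  structure(data.frame(bound = bounds, cum_pct = cum_pct),
            summary = summary, total_population = total, scenario = label,
            band_width = band_width, thresholds = thresholds,
            class = c("coverage_table", "data.frame"))
}

#' Compare two scenarios
#'
#' Per-threshold percentage-point differences (reduced minus baseline) and
#' the lost-access units: cells/nodes within the last threshold at baseline
#' but beyond it in the reduced scenario.
#'
#' @param baseline,reduced `coverage_table`s on the same bands.
#' @param minutes_baseline,minutes_reduced optional per-unit minutes to
#'   derive the lost-access set.
#' @return List with `delta` (named percentage-point differences per band
#'   bound and threshold) and `lost_access` (integer unit indices or
#'   `NULL`).
#' @export
compare_scenarios <- function(baseline, reduced, minutes_baseline = NULL,
                              minutes_reduced = NULL) {
  if (!identical(baseline$bound, reduced$bound) ||
      !identical(attr(baseline, "thresholds"), attr(reduced, "thresholds")))
    stop("scenarios use different bands; cannot compare")
  delta <- c(setNames(reduced$cum_pct - baseline$cum_pct,
                      paste0("band_", baseline$bound)),
             attr(reduced, "summary") - attr(baseline, "summary"))
  lost <- NULL
  if (!is.null(minutes_baseline) && !is.null(minutes_reduced)) {
    thr <- max(attr(baseline, "thresholds"))
    lost <- which(minutes_baseline <= thr & minutes_reduced > thr)
  }
  list(delta = delta, lost_access = lost)
}

#' Write a scenario as CSV
#'
#' One row per facility with selected/locked flags.
#'
#' @param scn a `scenario`.
#' @param facilities the full [facility_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scn, facilities, path) {
  df <- data.frame(id = facilities$id,
                   selected = facilities$id %in% scn$selected,
                   locked = facilities$id %in% scn$locked)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
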