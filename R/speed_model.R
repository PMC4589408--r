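# ---------------------------------------------------------------------------
# Walking-speed rule and friction tables ------------------------------------
#
# The pedestrian speed model is the Naismith-Langmuir rule: a basal pace of
# 4 km/h (15 min per horizontal km), slowed by 0.1 min for every metre
# climbed, sped up by 0.03 min per metre descended on moderate downgrades
# (slope angle between -5 deg and -12 deg), and slowed by 0.03 min per metre
# descended on steep downgrades (beyond -12 deg). The rule is evaluated
# continuously in the signed slope; published per-class speeds serve only
# as a validation oracle for the ascending classes.

#' Naismith-Langmuir speed rule parameters
#'
#' @param basal_kmh basal flat-ground speed, km/h.
#' @param ascent_min_per_m extra minutes per metre climbed.
#' @param descent_bonus_min_per_m minutes saved per metre descended on
#'   moderate downgrades.
#' @param steep_descent_min_per_m extra minutes per metre descended on
#'   steep downgrades.
#' @param bonus_band_deg slope-angle band (degrees, negative = downhill) in
#'   which the descent bonus applies; open at the shallow end, closed at
#'   the steep end.
#' @return A `speed_rule` object.
#' @export
speed_rule <- function(basal_kmh = 4, ascent_min_per_m = 0.1,
                       descent_bonus_min_per_m = 0.03,
                       steep_descent_min_per_m = 0.03,
                       bonus_band_deg = c(-5, -12)) {
  stopifnot(basal_kmh > 0, ascent_min_per_m > 0,
            descent_bonus_min_per_m > 0, steep_descent_min_per_m > 0,
            bonus_band_deg[1] > bonus_band_deg[2])
  structure(list(basal_kmh = basal_kmh,
                 ascent_min_per_m = ascent_min_per_m,
                 descent_bonus_min_per_m = descent_bonus_min_per_m,
                 steep_descent_min_per_m = steep_descent_min_per_m,
                 bonus_band_deg = bonus_band_deg),
            class = "speed_rule")
}

#' Walking speed from signed slope
#'
#' Evaluates the Naismith-Langmuir rule at a signed rise/run slope along
#' the direction of travel and returns the equivalent speed over the
#' horizontal distance, in km/h. Vectorized.
#'
#' @param slope signed rise/run fraction (positive = uphill).
#' @param rule a [speed_rule()].
#' @return Speed in km/h (`60 / minutes-per-horizontal-km`).
#' @export
walking_speed <- function(slope, rule = speed_rule()) {
  stopifnot(all(is.finite(slope)))
  base_min <- 60 / rule$basal_kmh            # minutes per horizontal km
  rise <- slope * 1000                        # metres per horizontal km
  ang <- atan(slope) * 180 / pi
  t <- rep(base_min, length(slope))
  up <- slope > 0
  t[up] <- base_min + rule$ascent_min_per_m * rise[up]
  bonus <- ang < rule$bonus_band_deg[1] & ang >= rule$bonus_band_deg[2]
  t[bonus] <- base_min - rule$descent_bonus_min_per_m * abs(rise[bonus])
  steep <- ang < rule$bonus_band_deg[2]
  t[steep] <- base_min + rule$steep_descent_min_per_m * abs(rise[steep])
  60 / t
}

#' Friction coefficient table
#'
#' Multiplicative friction coefficients applied to on-foot crossing times:
#' one set keyed by absolute slope class (percent), one by land-use
#' category and season. Defaults reproduce the published calibration,
#' including the non-monotone 1.20 coefficient for the 40-60% class.
#'
#' @param slope named numeric vector of slope-class coefficients; classes
#'   are left-closed, right-open (`[0,20) ... [100,Inf)`).
#' @param landuse list with `dry` and `wet` named vectors over
#'   `open`, `bushy`, `forest`.
#' @return A `friction_table` object.
#' @export
friction_table <- function(
    slope = c("0-20" = 0.98, "20-40" = 1.00, "40-60" = 1.20,
              "60-80" = 1.04, "80-100" = 1.06, ">100" = 1.08),
    landuse = list(dry = c(open = 0.95, bushy = 1.00, forest = 1.05),
                   wet = c(open = 1.00, bushy = 1.05, forest = 1.10))) {
  stopifnot(length(slope) == 6, all(slope > 0),
            all(unlist(landuse) > 0),
            all(c("dry", "wet") %in% names(landuse)))
  structure(list(slope = slope, landuse = landuse), class = "friction_table")
}

#' Slope-class friction coefficient
#'
#' @param slope_pct absolute slope in percent (vectorized).
#' @param table a [friction_table()].
#' @return Coefficient per input.
#' @export
slope_class_coeff <- function(slope_pct, table = friction_table()) {
  s <- abs(slope_pct)
  idx <- findInterval(s, c(0, 20, 40, 60, 80, 100))  # left-closed classes
  unname(table$slope[idx])
}

#' Land-use friction coefficient
#'
#' `barrier` cells are impassable and yield `Inf` (no finite crossing
#' time).
#'
#' @param category land-use category (vectorized).
#' @param season `"dry"` or `"wet"`.
#' @param table a [friction_table()].
#' @return Coefficient per input; `Inf` for barriers.
#' @export
landuse_coeff <- function(category, season = "dry", table = friction_table()) {
  co <- table$landuse[[season]]
  out <- unname(co[category])
  out[category == "barrier"] <- Inf
  if (any(is.na(out) & !is.na(category)))
    stop("unknown land-use category: ",
         paste(unique(category[is.na(out)]), collapse = ", "))
  out
}

#' Minutes to cross a distance at a given speed with friction
#'
#' `minutes = (distance/1000) / speed * 60 * slope_coeff * landuse_coeff`.
#' Linear in distance, inversely proportional to speed. An infinite
#' coefficient (barrier) propagates to an infinite time.
#'
#' @param speed_kmh speed in km/h (> 0).
#' @param distance_m distance in metres (> 0).
#' @param slope_coeff,landuse_coeff friction multipliers (> 0, may be Inf).
#' @return Minutes (possibly `Inf`).
#' @export
cell_crossing_time <- function(speed_kmh, distance_m, slope_coeff = 1,
                               landuse_coeff = 1) {
  if (any(speed_kmh <= 0) || any(distance_m <= 0))
    stop("speed and distance must be positive")
  if (any(slope_coeff <= 0) || any(landuse_coeff <= 0))
    stop("friction coefficients must be positive")
  (distance_m / 1000) / speed_kmh * 60 * slope_coeff * landuse_coeff
}

#' Road speed table for motorized travel
#'
#' Vehicular speeds by road class, km/h. The footpath class carries the
#' pedestrian basal speed and is not motorable.
#'
#' @param speeds named numeric vector over the five road classes.
#' @return A `road_speed_table` object.
#' @export
road_speed_table <- function(speeds = c(tarmac = 75, loose_surface = 45,
                                        dry_weather = 40, motorable = 20,
                                        footpath = 4)) {
  stopifnot(all(speeds > 0), all(ROAD_CLASSES %in% names(speeds)))
  structure(list(speeds = speeds), class = "road_speed_table")
}

#' Vehicular speed for a road class
#'
#' @param road_class one of the five road classes (vectorized).
#' @param table a [road_speed_table()].
#' @return Speed in km/h.
#' @export
vehicle_speed <- function(road_class, table = road_speed_table()) {
  if (!all(road_class %in% ROAD_CLASSES))
    stop("unknown road class: ",
         paste(setdiff(road_class, ROAD_CLASSES), collapse = ", "))
  unname(table$speeds[road_class])
}

# Apply config overrides (keys friction_slope_<class>, friction_<season>_<cat>,
# roadspeed_<class>) onto the default tables.
apply_overrides <- function(cfg, friction = friction_table(),
                            roads = road_speed_table()) {
  for (k in names(cfg$overrides)) {
    v <- cfg$overrides[[k]]
    if (grepl("^friction_slope_", k)) {
      cls <- sub("^friction_slope_", "", k)
      if (!cls %in% names(friction$slope)) stop("unknown slope class: ", cls)
      friction$slope[cls] <- v
    } else if (grepl("^friction_(dry|wet)_", k)) {
      parts <- strsplit(sub("^friction_", "", k), "_")[[1]]
      friction$landuse[[parts[1]]][parts[2]] <- v
    } else if (grepl("^roadspeed_", k)) {
      cls <- sub("^roadspeed_", "", k)
      if (!cls %in% ROAD_CLASSES) stop("unknown road class: ", cls)
      roads$speeds[cls] <- v
    } else stop("unrecognized override key: ", k)
  }
  list(friction = friction, roads = roads)
}
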