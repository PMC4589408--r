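# ---------------------------------------------------------------------------
# Synthetic reference facility tables ----------------------------------------
#
# The original per-facility staffing/caseload datasets for the two worked
# examples are spreadsheet supplements that are not redistributable here.
# These constructors build SYNTHETIC stand-in tables whose published
# aggregates are reproduced exactly: facility-level mix, staffing class
# counts, caseload class counts (including the missing class), first-line
# delivery sums, medians and ranges, and hospital delivery totals. The
# individual rows are fabricated; only the aggregates are real. Facility
# coordinates are placeholders on a unit grid and carry no geography.

iringa_first_line_caseloads <- function() {
  low <- c(2, 10, 12, 15, 18, 20, 22, 25, 28, 30, 32, 35, 38, 40, 42, 44,
           45, 46, 47, 48, 49)                                    # 21 in 0-49
  mid <- c(50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 60, 62, 65, 65,
           70, 72, 75, 78, 80, 82, 85, 88, 90, 92, 95, 97, 99)    # 27 in 50-99
  high <- c(100, 105, 110, 112, 115, 118, 120, 125, 130, 135, 140, 145,
            150, 155, 155, 160, 165)                              # 17 in 100-199
  top <- c(210, 230, 277)                                         # 3 >= 200
  vals <- c(low, mid, high, top)
  stopifnot(length(vals) == 68, sum(vals) == 5505,
            median(vals) == 65, min(vals) == 2, max(vals) == 277,
            sum(vals < 100) == 48)
  vals
}

ludewa_first_line_caseloads <- function() {
  low <- c(2:21, 21, 22, 22,
           23, 25, 27, 29, 30, 32, 34, 35, 35, 36, 38, 40, 41, 42, 44,
           45, 46, 47)                                            # 41 in 0-49
  mid <- c(55, 60)                                                # 2 in 50-99
  high <- c(105, 117)                                             # 2 in 100-199
  vals <- c(low, mid, high)
  stopifnot(length(vals) == 45, sum(vals) == 1281,
            median(vals) == 22, min(vals) == 2, max(vals) == 117,
            sum(vals < 100) == 43)
  vals
}

build_reference_table <- function(prefix, n_disp, n_hc, hosp_deliveries,
                                  caseloads, n_missing, staffing_counts,
                                  zero_sba_dispensaries, hosp_sba) {
  n_fl <- n_disp + n_hc
  n_hosp <- length(hosp_deliveries)
  lev <- c(rep("dispensary", n_disp), rep("health_centre", n_hc),
           rep("hospital", n_hosp))
  # staffing: zero-SBA rows first (all dispensaries), then singles, then >=2
  sba_fl <- c(rep(0L, staffing_counts[1]), rep(1L, staffing_counts[2]),
              rep(2L, staffing_counts[3]))
  stopifnot(length(sba_fl) == n_fl, staffing_counts[1] == zero_sba_dispensaries)
  deliveries_fl <- c(caseloads, rep(NA_real_, n_missing))
  stopifnot(length(deliveries_fl) == n_fl)
  n <- n_fl + n_hosp
  facility_table(data.frame(
    id = sprintf("%s%03d", prefix, seq_len(n)),
    name = paste0(prefix, "_synthetic_", seq_len(n)),
    level = lev,
    x = (seq_len(n) - 1) %% 10 * 1000,
    y = (seq_len(n) - 1) %/% 10 * 1000,
    sba_count = c(sba_fl, rep(hosp_sba, n_hosp)),
    deliveries = c(deliveries_fl, hosp_deliveries),
    offers_delivery = TRUE))
}

#' Synthetic stand-in facility tables for the two worked-example districts
#'
#' `district = "iringa"`: 70 first-line facilities (64 dispensaries, 6
#' health centres) plus one hospital; staffing classes 2 / 30 / 38,
#' caseload classes 21 / 27 / 17 / 3 with 2 missing, reported first-line
#' deliveries summing 5505 with median 65 (range 2-277), hospital
#' caseload 2140 (28.0% of 7645).
#'
#' `district = "ludewa"`: 52 first-line facilities (46 dispensaries, 6
#' health centres) plus three hospitals; staffing classes 12 / 29 / 11,
#' caseload classes 41 / 2 / 2 / 0 with 7 missing, reported first-line
#' deliveries summing 1281 with median 22 (range 2-117), hospital
#' caseloads summing 2808 (68.7% of 4089).
#'
#' Rows are synthetic: only these aggregates are faithful. Coordinates are
#' placeholders.
#'
#' @param district `"iringa"` or `"ludewa"`.
#' @return A [facility_table()].
#' @export
reference_facility_table <- function(district = c("iringa", "ludewa")) {
  district <- match.arg(district)
  if (district == "iringa") {
    build_reference_table("IR", n_disp = 64, n_hc = 6,
                          hosp_deliveries = 2140,
                          caseloads = iringa_first_line_caseloads(),
                          n_missing = 2,
                          staffing_counts = c(2, 30, 38),
                          zero_sba_dispensaries = 2, hosp_sba = 25L)
  } else {
    build_reference_table("LU", n_disp = 46, n_hc = 6,
                          hosp_deliveries = c(1500, 800, 508),
                          caseloads = ludewa_first_line_caseloads(),
                          n_missing = 7,
                          staffing_counts = c(12, 29, 11),
                          zero_sba_dispensaries = 12, hosp_sba = 10L)
  }
}
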