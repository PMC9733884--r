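#' Standard indicator definitions
#'
#' Metadata for the eight indicators of the standard indicator set: name,
#' the domain group it belongs to, whether a higher raw value means higher
#' food-insecurity risk, and units. The direction flag drives
#' [orient_for_risk()]: claimant, low-income, no-qualification percentages,
#' mental ill-health score, travel time and store distance all rise with
#' risk; download speed and bus-stop density fall with risk.
#'
#' @return Data frame with columns `name`, `domain`,
#'   `higher_raw_is_higher_risk`, `units`.
#' @export
indicator_definitions <- function() {
  data.frame(
    name = c("claimants_pct", "low_income_pct", "no_quals_pct",
             "mental_health_score", "travel_time_min",
             "download_speed_mbit", "bus_stop_density",
             "store_distance_km"),
    domain = c("benefit", "household", "compositional", "compositional",
               "structural", "structural", "structural", "structural"),
    higher_raw_is_higher_risk = c(TRUE, TRUE, TRUE, TRUE,
                                  TRUE, FALSE, FALSE, TRUE),
    units = c("%", "%", "%", "score", "minutes", "Mbit/s",
              "stops/km2", "km"),
    stringsAsFactors = FALSE)
}

#' Percentage of benefit claimants in an area
#'
#' `100 * claimant_count / population`. Because claimant counts and
#' population denominators come from different sources and reference dates,
#' small areas can produce values above 100; these are returned but flagged
#' with a warning rather than truncated.
#'
#' @param claimant_count Non-negative count(s) of benefit claimants.
#' @param population Positive population denominator(s).
#' @return Numeric percentage(s).
#' @examples
#' percent_claimants(300, 1500)  # 20
#' @export
percent_claimants <- function(claimant_count, population) {
  if (any(!is.finite(population)) || any(population <= 0)) {
    stop("percent_claimants: 'population' must be positive", call. = FALSE)
  }
  if (any(!is.finite(claimant_count)) || any(claimant_count < 0)) {
    stop("percent_claimants: 'claimant_count' must be non-negative",
         call. = FALSE)
  }
  pct <- 100 * claimant_count / population
  if (any(pct > 100)) {
    warning("percent_claimants: ", sum(pct > 100),
            " value(s) above 100% (denominator mismatch)", call. = FALSE)
  }
  pct
}

#' Joint probability of low income and target household type
#'
#' Combines two census marginal proportions -- the proportion of people in
#' low-income households and the proportion in the target household type
#' (living alone or with dependent children) -- as their product. The two
#' tables are published separately with no cross-tabulation, so independence
#' is assumed; the result is an approximation of the joint prevalence.
#'
#' @param p_low_income Proportion(s) in \[0,1\].
#' @param p_target_household Proportion(s) in \[0,1\].
#' @return Joint proportion(s) in \[0,1\]; multiply by 100 for a percentage.
#' @examples
#' joint_low_income_probability(0.3, 0.2)  # 0.06
#' @export
joint_low_income_probability <- function(p_low_income, p_target_household) {
  check01 <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0 | x > 1)) {
      stop("joint_low_income_probability: '", nm,
           "' must lie in [0, 1]", call. = FALSE)
    }
  }
  check01(p_low_income, "p_low_income")
  check01(p_target_household, "p_target_household")
  p_low_income * p_target_household
}

#' Bus-stop density of an area
#'
#' Count of bus-stop points assigned to each area divided by the area's
#' size in square kilometres. Point-to-area assignment is supplied as a
#' mapping (synthetic point sets carry their `area_id`); polygon
#' point-in-polygon tests are out of scope.
#'
#' @param stop_area_ids Character vector: the area each bus stop falls in
#'   (one element per stop).
#' @param area_id Character vector of area identifiers to report on.
#' @param area_km2 Positive areas in square km, aligned with `area_id`.
#' @return Numeric vector of stops per square km, aligned with `area_id`.
#' @examples
#' bus_stop_density(rep("A", 12), "A", 4)  # 3
#' @export
bus_stop_density <- function(stop_area_ids, area_id, area_km2) {
  if (length(area_km2) != length(area_id)) {
    stop("bus_stop_density: 'area_id' and 'area_km2' lengths differ",
         call. = FALSE)
  }
  if (any(!is.finite(area_km2)) || any(area_km2 <= 0)) {
    stop("bus_stop_density: 'area_km2' must be positive", call. = FALSE)
  }
  counts <- table(factor(stop_area_ids, levels = area_id))
  as.numeric(counts) / area_km2
}

#' Euclidean distance to the nearest grocery store
#'
#' Minimum planar Euclidean distance from each area centroid to any store
#' point. Coordinates are planar km; no geodesic correction is applied.
#'
#' @param centroid_x,centroid_y Numeric centroid coordinates (km).
#' @param store_points Data frame with numeric columns `x` and `y`, one row
#'   per store; must be non-empty.
#' @return Numeric vector of nearest-store distances (km).
#' @examples
#' nearest_store_distance(0, 0, data.frame(x = c(3, 6), y = c(4, 8)))  # 5
#' @export
nearest_store_distance <- function(centroid_x, centroid_y, store_points) {
  if (!is.data.frame(store_points) || nrow(store_points) == 0L ||
      !all(c("x", "y") %in% names(store_points))) {
    stop("nearest_store_distance: 'store_points' must be a non-empty ",
         "data frame with columns x and y", call. = FALSE)
  }
  stopifnot(length(centroid_x) == length(centroid_y))
  sx <- store_points$x
  sy <- store_points$y
  vapply(seq_along(centroid_x), function(i) {
    sqrt(min((sx - centroid_x[i])^2 + (sy - centroid_y[i])^2))
  }, numeric(1))
}

#' Derive point-based structural indicators for an indicator table
#'
#' Replaces (or adds) the `bus_stop_density` and `store_distance_km` columns
#' of an indicator table by deriving them from point data: bus stops per
#' square km from the stop-to-area assignment, and nearest-store Euclidean
#' distance from area centroids.
#'
#' @param indicators Indicator table with `area_id`.
#' @param geography Geography table with `area_id`, `area_km2`,
#'   `centroid_x`, `centroid_y`.
#' @param store_points Data frame with columns `x`, `y`.
#' @param bus_stop_points Data frame with columns `x`, `y`, `area_id`.
#' @return The indicator table with derived `bus_stop_density` and
#'   `store_distance_km` columns.
#' @export
derive_point_indicators <- function(indicators, geography, store_points,
                                    bus_stop_points) {
  stopifnot(all(c("area_id", "area_km2", "centroid_x", "centroid_y") %in%
                  names(geography)))
  g <- geography[match(indicators$area_id, geography$area_id), ]
  indicators$bus_stop_density <-
    bus_stop_density(bus_stop_points$area_id, g$area_id, g$area_km2)
  indicators$store_distance_km <-
    nearest_store_distance(g$centroid_x, g$centroid_y, store_points)
  indicators
}
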