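#' Configuration for the synthetic small-area generator
#'
#' Defines the latent-factor model the generator draws from. Small areas
#' (LSOA-like, ~1,500 residents) nest in MSOAs which nest in regions. Two
#' standardised latent factors drive the indicators: a compositional risk
#' factor (population characteristics: benefit claiming, low income, no
#' qualifications, mental ill health) with a region-level random intercept,
#' and a structural accessibility factor (travel time, download speed,
#' bus-stop density, store distance) shifted upward in rural areas.
#' Validation variables (IMD-like deprivation, free school meals %, child
#' obesity %) load on the compositional latent.
#'
#' @param n_regions Number of regions (default 9, the number of English
#'   regions).
#' @param msoas_per_region MSOAs per region.
#' @param lsoas_per_msoa_range Integer `c(min, max)`: LSOAs per MSOA drawn
#'   uniformly from this range.
#' @param rural_proportion Fraction of areas flagged rural, in \[0,1\].
#' @param region_sd Standard deviation of the region-level random intercept
#'   on the compositional latent (default 0.3); residual variance is reduced
#'   so the latent's marginal sd stays 1.
#' @param compositional_loadings Named loadings in \[-1,1\] of the four
#'   compositional indicators on the compositional latent.
#' @param structural_loadings Named loadings in \[-1,1\] of the four
#'   structural indicators on the accessibility latent.
#' @param rural_accessibility_shift Offset added to the accessibility latent
#'   in rural areas (dimensionless, default 1).
#' @param noise_sd Residual standard deviation added to each indicator and
#'   validation variable on the latent scale.
#' @param validation_loadings Named loadings (`imd`, `fsm`, `obesity`) of
#'   the validation variables on the compositional latent.
#' @param urban_intensity_ratio Urban:rural intensity ratio for store and
#'   bus-stop point placement (default 10).
#' @param stores_per_area Expected grocery stores per area (default 0.12).
#' @param seed Integer RNG seed; every draw derives deterministically from
#'   it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_regions = 9,
                             msoas_per_region = 10,
                             lsoas_per_msoa_range = c(3, 7),
                             rural_proportion = 0.2,
                             region_sd = 0.3,
                             compositional_loadings = c(
                               claimants_pct = 0.8,
                               low_income_pct = 0.8,
                               no_quals_pct = 0.8,
                               mental_health_score = 0.8),
                             structural_loadings = c(
                               travel_time_min = 0.8,
                               download_speed_mbit = 0.8,
                               bus_stop_density = 0.8,
                               store_distance_km = 0.8),
                             rural_accessibility_shift = 1,
                             noise_sd = 0.3,
                             validation_loadings = c(
                               imd = 0.9, fsm = 0.75, obesity = 0.65),
                             urban_intensity_ratio = 10,
                             stores_per_area = 0.12,
                             seed = 1L) {
  fail <- function(field, why) {
    stop("synthetic_config: invalid '", field, "': ", why, call. = FALSE)
  }
  # YAML round-trips named vectors as lists; coerce back
  compositional_loadings <- unlist(compositional_loadings)
  structural_loadings <- unlist(structural_loadings)
  validation_loadings <- unlist(validation_loadings)
  lsoas_per_msoa_range <- unlist(lsoas_per_msoa_range)
  if (!is.numeric(n_regions) || n_regions < 1) fail("n_regions", "must be >= 1")
  if (!is.numeric(msoas_per_region) || msoas_per_region < 1) {
    fail("msoas_per_region", "must be >= 1")
  }
  if (length(lsoas_per_msoa_range) != 2L || lsoas_per_msoa_range[1] < 1 ||
      lsoas_per_msoa_range[2] < lsoas_per_msoa_range[1]) {
    fail("lsoas_per_msoa_range", "must be c(min, max) with min >= 1")
  }
  if (rural_proportion < 0 || rural_proportion > 1) {
    fail("rural_proportion", "must lie in [0, 1]")
  }
  if (region_sd < 0 || region_sd > 1) fail("region_sd", "must lie in [0, 1]")
  for (nm in c("compositional_loadings", "structural_loadings",
               "validation_loadings")) {
    v <- get(nm)
    if (is.null(names(v)) || any(abs(v) > 1)) {
      fail(nm, "must be a named vector with loadings in [-1, 1]")
    }
  }
  if (noise_sd < 0) fail("noise_sd", "must be non-negative")
  if (!is.numeric(seed) || length(seed) != 1L) fail("seed", "must be a number")
  structure(list(
    n_regions = as.integer(n_regions),
    msoas_per_region = as.integer(msoas_per_region),
    lsoas_per_msoa_range = as.integer(lsoas_per_msoa_range),
    rural_proportion = rural_proportion,
    region_sd = region_sd,
    compositional_loadings = compositional_loadings,
    structural_loadings = structural_loadings,
    rural_accessibility_shift = rural_accessibility_shift,
    noise_sd = noise_sd,
    validation_loadings = validation_loadings,
    urban_intensity_ratio = urban_intensity_ratio,
    stores_per_area = stores_per_area,
    seed = as.integer(seed)), class = "synthetic_config")
}

# run code under a stage-specific seed, restoring the caller's RNG state
with_stage_seed <- function(config, stage_offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((abs(config$seed) %% 1000000L) * 1000L + stage_offset)
  force(code)
}

#' Generate a nested synthetic geography
#'
#' Builds the small-area skeleton: regions laid out on a planar grid, MSOA
#' centres scattered around their region centre, area centroids scattered
#' tightly around their MSOA centre (so within-MSOA centroids are closer on
#' average than across MSOAs). `ceiling(rural_proportion * N)` areas are
#' flagged rural (seeded assignment); rural areas are drawn larger (area in
#' km2) than urban ones. Populations are around 1,500 residents, the
#' typical LSOA size.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with columns `area_id`, `msoa_id`, `region`,
#'   `urban_rural`, `area_km2`, `centroid_x`, `centroid_y`, `population`.
#' @export
generate_geography <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_stage_seed(config, 1L, {
    nr <- config$n_regions
    grid_cols <- ceiling(sqrt(nr))
    region_centres <- cbind(
      x = 200 * ((seq_len(nr) - 1) %% grid_cols),
      y = 200 * ((seq_len(nr) - 1) %/% grid_cols))
    rows <- list()
    msoa_counter <- 0L
    for (ri in seq_len(nr)) {
      region <- sprintf("region_%02d", ri)
      for (mi in seq_len(config$msoas_per_region)) {
        msoa_counter <- msoa_counter + 1L
        msoa_id <- sprintf("M%04d", msoa_counter)
        mx <- region_centres[ri, "x"] + stats::rnorm(1, 0, 15)
        my <- region_centres[ri, "y"] + stats::rnorm(1, 0, 15)
        n_lsoa <- if (config$lsoas_per_msoa_range[1] ==
                        config$lsoas_per_msoa_range[2]) {
          config$lsoas_per_msoa_range[1]
        } else {
          sample(config$lsoas_per_msoa_range[1]:config$lsoas_per_msoa_range[2],
                 1L)
        }
        rows[[msoa_counter]] <- data.frame(
          msoa_id = msoa_id, region = region,
          centroid_x = mx + stats::rnorm(n_lsoa, 0, 1.5),
          centroid_y = my + stats::rnorm(n_lsoa, 0, 1.5),
          stringsAsFactors = FALSE)
      }
    }
    geo <- do.call(rbind, rows)
    n <- nrow(geo)
    geo$area_id <- sprintf("A%05d", seq_len(n))
    n_rural <- ceiling(config$rural_proportion * n)
    rural_idx <- if (n_rural > 0) sample.int(n, n_rural) else integer(0)
    geo$urban_rural <- "urban"
    geo$urban_rural[rural_idx] <- "rural"
    geo$area_km2 <- ifelse(
      geo$urban_rural == "urban",
      stats::rlnorm(n, meanlog = log(0.6), sdlog = 0.4),
      stats::rlnorm(n, meanlog = log(8), sdlog = 0.5))
    geo$population <- pmax(800L, pmin(3000L,
      as.integer(round(stats::rnorm(n, 1500, 180)))))
    geo[c("area_id", "msoa_id", "region", "urban_rural", "area_km2",
          "centroid_x", "centroid_y", "population")]
  })
}

#' Generate latent risk factors for a geography
#'
#' Draws the two standardised latents per area: the compositional latent
#' `L_comp` as a region-level random intercept (sd `region_sd`) plus an
#' independent residual scaled so the marginal sd is 1, and the structural
#' accessibility latent `L_struct` as a standard normal draw plus
#' `rural_accessibility_shift` for rural areas.
#'
#' @param geography Output of [generate_geography()].
#' @param config The [synthetic_config()] used to build it.
#' @return Data frame with `area_id`, `L_comp`, `L_struct`.
#' @export
generate_latents <- function(geography, config) {
  stopifnot(inherits(config, "synthetic_config"),
            all(c("area_id", "region", "urban_rural") %in% names(geography)))
  with_stage_seed(config, 2L, {
    n <- nrow(geography)
    regions <- unique(geography$region)
    intercepts <- stats::rnorm(length(regions), 0, config$region_sd)
    names(intercepts) <- regions
    resid_sd <- sqrt(max(0, 1 - config$region_sd^2))
    l_comp <- intercepts[geography$region] + stats::rnorm(n, 0, resid_sd)
    l_struct <- stats::rnorm(n) +
      config$rural_accessibility_shift * (geography$urban_rural == "rural")
    data.frame(area_id = geography$area_id,
               L_comp = as.numeric(l_comp),
               L_struct = as.numeric(l_struct),
               stringsAsFactors = FALSE)
  })
}

# monotone links from the latent scale to each indicator's natural scale;
# increasing links for risk-increasing indicators, decreasing otherwise
indicator_links <- function() {
  clip_pct <- function(x) pmin(100, pmax(0, x))
  list(
    claimants_pct = function(z) clip_pct(15 + 8 * z),
    low_income_pct = function(z) clip_pct(10 + 5 * z),
    no_quals_pct = function(z) clip_pct(22 + 9 * z),
    mental_health_score = function(z) z,
    travel_time_min = function(z) 20 * exp(0.4 * z),
    download_speed_mbit = function(z) 45 * exp(-0.5 * z),
    bus_stop_density = function(z) 12 * exp(-0.6 * z),
    store_distance_km = function(z) 1.5 * exp(0.7 * z))
}

#' Generate raw indicator values from the latents
#'
#' Each indicator is `loading * latent + N(0, noise_sd)` pushed through a
#' monotone link to its natural scale: percentages are affine and clipped to
#' \[0,100\] (means kept away from the bounds so clipping is rare), the
#' mental ill-health score stays on the latent scale, and the structural
#' quantities use log-linear links so travel time, download speed, bus-stop
#' density and store distance are positive. Links are increasing for
#' risk-increasing indicators and decreasing for download speed and
#' bus-stop density, where higher raw values mean better access.
#'
#' @param latents Output of [generate_latents()].
#' @param geography Matching geography table.
#' @param config The shared [synthetic_config()].
#' @return Indicator table: `area_id` plus one column per configured
#'   indicator.
#' @export
generate_indicators <- function(latents, geography, config) {
  stopifnot(inherits(config, "synthetic_config"),
            all(latents$area_id == geography$area_id))
  links <- indicator_links()
  loadings <- c(config$compositional_loadings, config$structural_loadings)
  unknown <- setdiff(names(loadings), names(links))
  if (length(unknown)) {
    stop("generate_indicators: unknown indicator name(s) in loadings: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  with_stage_seed(config, 3L, {
    n <- nrow(latents)
    out <- data.frame(area_id = latents$area_id, stringsAsFactors = FALSE)
    for (nm in names(config$compositional_loadings)) {
      z <- config$compositional_loadings[[nm]] * latents$L_comp +
        stats::rnorm(n, 0, config$noise_sd)
      out[[nm]] <- links[[nm]](z)
    }
    for (nm in names(config$structural_loadings)) {
      z <- config$structural_loadings[[nm]] * latents$L_struct +
        stats::rnorm(n, 0, config$noise_sd)
      out[[nm]] <- links[[nm]](z)
    }
    out
  })
}

#' Generate grocery-store and bus-stop point sets
#'
#' Places store points at area centroids chosen with urban areas weighted
#' `urban_intensity_ratio` times more heavily than rural ones (plus planar
#' jitter), and bus stops as a per-area Poisson count with urban intensity
#' `urban_intensity_ratio` times the rural intensity, scattered around the
#' area centroid. Rural areas therefore see longer nearest-store distances
#' and lower stop densities on average.
#'
#' @param geography Output of [generate_geography()].
#' @param config The shared [synthetic_config()].
#' @return List with `store_points` (`point_id`, `x`, `y`) and
#'   `bus_stop_points` (`point_id`, `x`, `y`, `area_id`; the generator
#'   supplies the point-to-area assignment directly).
#' @export
generate_points <- function(geography, config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_stage_seed(config, 4L, {
    n <- nrow(geography)
    urban <- geography$urban_rural == "urban"
    n_stores <- max(1L, round(config$stores_per_area * n))
    w <- ifelse(urban, config$urban_intensity_ratio, 1)
    host <- sample.int(n, n_stores, replace = TRUE, prob = w / sum(w))
    stores <- data.frame(
      point_id = sprintf("S%04d", seq_len(n_stores)),
      x = geography$centroid_x[host] + stats::rnorm(n_stores, 0, 0.3),
      y = geography$centroid_y[host] + stats::rnorm(n_stores, 0, 0.3),
      stringsAsFactors = FALSE)

    # bus stops: expected stops/km2 of 12 urban vs 12/ratio rural
    dens <- ifelse(urban, 12, 12 / config$urban_intensity_ratio)
    counts <- stats::rpois(n, dens * geography$area_km2)
    idx <- rep.int(seq_len(n), counts)
    radius <- sqrt(geography$area_km2[idx] / pi)
    total <- length(idx)
    theta <- stats::runif(total, 0, 2 * pi)
    rad <- radius * sqrt(stats::runif(total))
    stops <- data.frame(
      point_id = sprintf("B%06d", seq_len(total)),
      x = geography$centroid_x[idx] + rad * cos(theta),
      y = geography$centroid_y[idx] + rad * sin(theta),
      area_id = geography$area_id[idx],
      stringsAsFactors = FALSE)
    list(store_points = stores, bus_stop_points = stops)
  })
}

#' Generate validation variables correlated with the compositional latent
#'
#' Produces an IMD-like deprivation score at area level
#' (`loading * L_comp + N(0, noise_sd)`, ranked worst-first) and MSOA-level
#' free-school-meals and child-obesity percentages built from the mean
#' compositional latent of each MSOA's constituent areas plus noise, mapped
#' to percentage scales.
#'
#' @param latents Output of [generate_latents()].
#' @param geography Matching geography table.
#' @param config The shared [synthetic_config()].
#' @return List with `area_validation` (`area_id`, `imd_score`, `imd_rank`;
#'   rank 1 = most deprived) and `msoa_validation` (`msoa_id`, `fsm_pct`,
#'   `obesity_pct`), one row per MSOA.
#' @export
generate_validation_vars <- function(latents, geography, config) {
  stopifnot(inherits(config, "synthetic_config"),
            all(latents$area_id == geography$area_id))
  vl <- config$validation_loadings
  with_stage_seed(config, 5L, {
    n <- nrow(latents)
    imd <- vl[["imd"]] * latents$L_comp + stats::rnorm(n, 0, config$noise_sd)
    area_val <- data.frame(area_id = latents$area_id,
                           imd_score = imd,
                           imd_rank = rank_worst_first(imd),
                           stringsAsFactors = FALSE)
    msoa_ids <- sort(unique(geography$msoa_id))
    m_lat <- tapply(latents$L_comp, geography$msoa_id, mean)[msoa_ids]
    nm <- length(msoa_ids)
    clip_pct <- function(x) pmin(100, pmax(0, x))
    fsm_z <- vl[["fsm"]] * as.numeric(m_lat) +
      stats::rnorm(nm, 0, config$noise_sd)
    obe_z <- vl[["obesity"]] * as.numeric(m_lat) +
      stats::rnorm(nm, 0, config$noise_sd)
    msoa_val <- data.frame(msoa_id = msoa_ids,
                           fsm_pct = clip_pct(14 + 7 * fsm_z),
                           obesity_pct = clip_pct(20 + 5 * obe_z),
                           stringsAsFactors = FALSE)
    list(area_validation = area_val, msoa_validation = msoa_val)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running every generator stage off one configuration:
#' geography, latents, indicators, point sets and validation variables, all
#' deterministic in `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with `geography`, `latents`, `indicators`, `store_points`,
#'   `bus_stop_points`, `area_validation`, `msoa_validation`, and the
#'   `config` echoed back.
#' @export
generate_synthetic_dataset <- function(config = synthetic_config()) {
  geography <- generate_geography(config)
  latents <- generate_latents(geography, config)
  indicators <- generate_indicators(latents, geography, config)
  points <- generate_points(geography, config)
  validation <- generate_validation_vars(latents, geography, config)
  list(geography = geography, latents = latents, indicators = indicators,
       store_points = points$store_points,
       bus_stop_points = points$bus_stop_points,
       area_validation = validation$area_validation,
       msoa_validation = validation$msoa_validation,
       config = config)
}
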