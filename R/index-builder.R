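#' Exponential transformation parameters
#'
#' Parameters of the IMD-style exponential transformation applied to scaled
#' domain scores. The defaults (scaling constant 23, range constant 100)
#' give the canonical transform
#' `X = -23 * ln(1 - s * (1 - exp(-100/23)))`, which maps \[0,1\] onto
#' \[0,100\], is convex, and stretches the high-risk tail so that extreme
#' risk in one domain is not cancelled by low risk in another when domains
#' are added.
#'
#' @param scaling_constant Positive scalar `c`; controls the curvature that
#'   limits cancellation between domains. Default 23.
#' @param range_constant Positive scalar `R`; the upper end of the
#'   transformed range. Default 100.
#' @return A list of class `exp_transform_params`.
#' @export
exp_transform_params <- function(scaling_constant = 23, range_constant = 100) {
  if (!is.numeric(scaling_constant) || length(scaling_constant) != 1L ||
      !is.finite(scaling_constant) || scaling_constant <= 0) {
    stop("exp_transform_params: 'scaling_constant' must be a positive number",
         call. = FALSE)
  }
  if (!is.numeric(range_constant) || length(range_constant) != 1L ||
      !is.finite(range_constant) || range_constant <= 0) {
    stop("exp_transform_params: 'range_constant' must be a positive number",
         call. = FALSE)
  }
  structure(list(scaling_constant = scaling_constant,
                 range_constant = range_constant),
            class = "exp_transform_params")
}

#' Weighted domain score from indicator scores
#'
#' Sums the named Rankit indicator scores per area with the given weights.
#' Equal weights are the default: no evidence base supports emphasising one
#' indicator over another, so each contributes identically to its domain.
#'
#' @param scores Score table (data frame with `area_id` and one score column
#'   per indicator), as from [rankit_transform()].
#' @param indicator_names Character vector naming the columns that make up
#'   the domain.
#' @param weights Non-negative numeric weights, one per indicator; default
#'   equal (1 each).
#' @return Numeric vector of per-area raw domain scores, in row order.
#' @export
domain_score <- function(scores, indicator_names,
                         weights = rep(1, length(indicator_names))) {
  stopifnot(is.data.frame(scores), length(indicator_names) >= 1L)
  unknown <- setdiff(indicator_names, names(scores))
  if (length(unknown)) {
    stop("domain_score: unknown indicator name(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(weights) != length(indicator_names) || any(weights < 0)) {
    stop("domain_score: 'weights' must be non-negative, one per indicator",
         call. = FALSE)
  }
  m <- as.matrix(scores[indicator_names])
  drop(m %*% weights)
}

#' Rank-scale raw domain scores onto the unit interval
#'
#' Ranks areas by raw domain score ascending (most risk = smallest raw
#' score, the orientation produced by the Rankit stage) and maps rank `r`
#' among `n` areas to `(n - r + 0.5) / n`, so the most-at-risk area gets the
#' largest scaled value (just under 1) and the least-at-risk just above 0.
#' Ties share averaged ranks. Values stay strictly inside (0, 1), keeping
#' the exponential transform away from its logarithmic endpoint.
#'
#' @param domain_score_raw Numeric vector of raw domain scores, length >= 2.
#' @return Numeric vector in (0, 1), most-at-risk area largest.
#' @export
scale_to_unit <- function(domain_score_raw) {
  if (!is.numeric(domain_score_raw) || length(domain_score_raw) < 2L) {
    stop("scale_to_unit: need a numeric vector of length >= 2", call. = FALSE)
  }
  if (any(!is.finite(domain_score_raw))) {
    stop("scale_to_unit: non-finite values in input", call. = FALSE)
  }
  n <- length(domain_score_raw)
  r <- rank(domain_score_raw, ties.method = "average")
  (n - r + 0.5) / n
}

#' Exponential transformation of a scaled domain score
#'
#' The IMD-style convex map
#' `X = -c * ln(1 - s * (1 - exp(-R/c)))`
#' with scaling constant `c` and range constant `R`, applied to a scaled
#' domain score `s` in \[0,1\]. `X(0) = 0` and `X(1) = R` exactly; the map is
#' strictly increasing and convex, so high-risk domain values dominate when
#' domains are summed ("cancellation" of a high-risk domain by a low-risk one
#' is reduced).
#'
#' @param domain_scaled Numeric vector with values in \[0,1\].
#' @param params An [exp_transform_params()] object.
#' @return Numeric vector in \[0, `range_constant`\].
#' @examples
#' exponential_transform(c(0, 0.5, 1))  # 0, 15.65, 100
#' @export
exponential_transform <- function(domain_scaled,
                                  params = exp_transform_params()) {
  stopifnot(inherits(params, "exp_transform_params"))
  if (!is.numeric(domain_scaled) || any(!is.finite(domain_scaled))) {
    stop("exponential_transform: input must be finite numeric", call. = FALSE)
  }
  if (any(domain_scaled < 0 | domain_scaled > 1)) {
    stop("exponential_transform: scaled domain scores must lie in [0, 1]",
         call. = FALSE)
  }
  cc <- params$scaling_constant
  rr <- params$range_constant
  -cc * log(1 - domain_scaled * (1 - exp(-rr / cc)))
}

#' Combine exponentially transformed domain scores into a composite
#'
#' Per-area weighted sum of the transformed domain scores. Equal weighting
#' is the default (two-domain indices use 50%/50% in the sense that each
#' domain contributes a weight of one).
#'
#' @param domain_exps Named list of numeric vectors, one per domain, all the
#'   same length and area order.
#' @param domain_weights Non-negative weights, one per domain; default equal.
#' @return Numeric vector of combined composite scores.
#' @export
combine_domains <- function(domain_exps,
                            domain_weights = rep(1, length(domain_exps))) {
  stopifnot(is.list(domain_exps), length(domain_exps) >= 1L)
  lens <- vapply(domain_exps, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("combine_domains: domains cover different area sets (lengths ",
         paste(lens, collapse = ", "), ")", call. = FALSE)
  }
  if (length(domain_weights) != length(domain_exps) || any(domain_weights < 0)) {
    stop("combine_domains: 'domain_weights' must be non-negative, one per domain",
         call. = FALSE)
  }
  out <- numeric(lens[1])
  for (i in seq_along(domain_exps)) {
    out <- out + domain_weights[i] * domain_exps[[i]]
  }
  out
}

#' Competition ranking of composite scores, 1 = most at risk
#'
#' Ranks areas so that rank 1 marks the population most at risk. Ties
#' receive the lowest applicable rank (competition / minimum-rank ties): all
#' members of a tied block share the block's smallest rank and the next
#' distinct value skips by the block size.
#'
#' @param combined_score Numeric vector of composite scores, finite.
#' @param most_at_risk `"high"` when the largest score marks most risk (the
#'   default orientation, where the scaled domain score approaches 1 for the
#'   most-at-risk area) or `"low"` for the opposite orientation. Both give
#'   identical rank sets on mirrored scores.
#' @return Integer vector of ranks, 1 = most at risk.
#' @examples
#' rank_index(c(5, 3, 3, 1))  # 1, 2, 2, 4
#' @export
rank_index <- function(combined_score, most_at_risk = c("high", "low")) {
  most_at_risk <- match.arg(most_at_risk)
  if (!is.numeric(combined_score) || length(combined_score) < 1L) {
    stop("rank_index: need a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(combined_score))) {
    stop("rank_index: non-finite scores", call. = FALSE)
  }
  x <- if (most_at_risk == "high") -combined_score else combined_score
  rank(x, ties.method = "min")
}

#' Assign risk deciles from ranks
#'
#' Decile `d` contains areas whose rank lies in `((d-1) * n/10, d * n/10]`,
#' so decile 1 is the most-at-risk tenth. With minimum-rank ties a tied
#' block spanning a boundary shares its block minimum rank and therefore
#' falls in the earlier (higher-risk) decile.
#'
#' @param ranks Integer vector of ranks (1 = most at risk), n >= 10.
#' @return Integer vector of decile labels in 1..10.
#' @export
assign_deciles <- function(ranks) {
  if (!is.numeric(ranks) || length(ranks) < 10L) {
    stop("assign_deciles: need at least 10 ranked areas", call. = FALSE)
  }
  n <- length(ranks)
  d <- as.integer(ceiling(ranks * 10 / n))
  pmin(pmax(d, 1L), 10L)
}

#' Aggregate transformed domain scores from small areas to MSOAs
#'
#' Sums each domain's exponentially transformed scores over the small areas
#' (LSOAs) of each MSOA, combines the per-MSOA domain sums with the domain
#' weights, and ranks the result with the same competition tie rule
#' (1 = most at risk). Summation -- not averaging -- is used, matching the
#' published aggregation of the underlying methodology.
#'
#' @param domain_exps Named list of per-area transformed domain score
#'   vectors, aligned with `area_id`.
#' @param area_id Character vector of small-area identifiers.
#' @param lookup Geography table with columns `area_id` and `msoa_id`.
#' @param domain_weights Non-negative weights, one per domain; default equal.
#' @param most_at_risk Orientation passed to [rank_index()].
#' @return Data frame with one row per MSOA: `msoa_id`, one `<domain>_exp`
#'   column per domain (the per-MSOA sums), `combined_score`, `rank`, and
#'   `decile` (when at least 10 MSOAs are present).
#' @export
aggregate_to_msoa <- function(domain_exps, area_id, lookup,
                              domain_weights = rep(1, length(domain_exps)),
                              most_at_risk = "high") {
  stopifnot(is.list(domain_exps),
            all(c("area_id", "msoa_id") %in% names(lookup)))
  missing_ids <- setdiff(area_id, lookup$area_id)
  if (length(missing_ids)) {
    stop("aggregate_to_msoa: area(s) missing from lookup: ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) ", ...", call. = FALSE)
  }
  msoa <- lookup$msoa_id[match(area_id, lookup$area_id)]
  msoa_ids <- sort(unique(msoa))
  out <- data.frame(msoa_id = msoa_ids, stringsAsFactors = FALSE)
  sums <- vector("list", length(domain_exps))
  for (i in seq_along(domain_exps)) {
    agg <- tapply(domain_exps[[i]], msoa, sum)
    sums[[i]] <- as.numeric(agg[msoa_ids])
    nm <- names(domain_exps)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("domain", i)
    out[[paste0(nm, "_exp")]] <- sums[[i]]
  }
  out$combined_score <- combine_domains(sums, domain_weights)
  out$rank <- rank_index(out$combined_score, most_at_risk = most_at_risk)
  if (nrow(out) >= 10L) out$decile <- assign_deciles(out$rank)
  out
}

#' Index specifications for the four published index variants
#'
#' Returns the domain structure of the four index variants built from the
#' standard indicator set: the Simple Index (benefit claimants domain +
#' household type domain, equal weight), the Complex Index (Compositional
#' domain of four population-characteristic indicators + Structural domain
#' of four area-access indicators, equal weight), and the two single-domain
#' variants (Compositional only, Structural only).
#'
#' @param which One of `"simple"`, `"complex"`, `"compositional"`,
#'   `"structural"`.
#' @return A list with elements `name` and `domains`; `domains` is a named
#'   list of lists with `indicators` (character) and `weight` (numeric).
#' @export
index_spec <- function(which = c("simple", "complex", "compositional",
                                 "structural")) {
  which <- match.arg(which)
  compositional <- c("claimants_pct", "low_income_pct", "no_quals_pct",
                     "mental_health_score")
  structural <- c("travel_time_min", "download_speed_mbit",
                  "bus_stop_density", "store_distance_km")
  domains <- switch(which,
    simple = list(
      benefit = list(indicators = "claimants_pct", weight = 1),
      household = list(indicators = "low_income_pct", weight = 1)),
    complex = list(
      compositional = list(indicators = compositional, weight = 1),
      structural = list(indicators = structural, weight = 1)),
    compositional = list(
      compositional = list(indicators = compositional, weight = 1)),
    structural = list(
      structural = list(indicators = structural, weight = 1)))
  list(name = which, domains = domains)
}

#' Build a food-insecurity risk index from raw indicators
#'
#' Orchestrates the full construction: orient each indicator for risk,
#' Rankit-score it, sum scores into equal-weight domain scores, rank-scale
#' each domain onto (0,1), apply the exponential transformation, combine the
#' transformed domains (skipped for single-domain specifications), rank with
#' competition ties (1 = most at risk) and assign deciles. All intermediate
#' per-stage columns are returned for audit.
#'
#' @param indicators Indicator table: data frame with `area_id` and one
#'   numeric column per indicator.
#' @param spec Index specification from [index_spec()] (or a list of the
#'   same shape).
#' @param definitions Indicator definitions from [indicator_definitions()];
#'   must cover every indicator the spec names.
#' @param params [exp_transform_params()] for the domain transformation.
#' @param orientation `"risk-high"` (default; most-at-risk area carries the
#'   largest scaled/transformed score, rank 1 = largest composite) or
#'   `"risk-low"` (mirrored scaling, rank 1 = smallest composite). The two
#'   orientations produce identical ranks and deciles.
#' @return A list of class `food_risk_index` with elements
#'   `index` (data frame: `area_id`, `combined_score`, `rank`, `decile`),
#'   `domains` (named list of data frames with `domain_score_raw`,
#'   `domain_rank`, `domain_scaled`, `domain_exp`), `scores` (the Rankit
#'   score table) and `spec_name`.
#' @export
build_index <- function(indicators, spec,
                        definitions = indicator_definitions(),
                        params = exp_transform_params(),
                        orientation = c("risk-high", "risk-low")) {
  orientation <- match.arg(orientation)
  stopifnot(is.data.frame(indicators), "area_id" %in% names(indicators),
            is.list(spec), !is.null(spec$domains))
  wanted <- unique(unlist(lapply(spec$domains, `[[`, "indicators")))
  unknown <- setdiff(wanted, definitions$name)
  if (length(unknown)) {
    stop("build_index: indicator(s) without definitions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(wanted, names(indicators))
  if (length(missing_cols)) {
    stop("build_index: indicator column(s) missing from table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # drop areas with any missing value in a selected indicator (no imputation)
  keep <- stats::complete.cases(indicators[wanted])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("build_index: excluded ", n_dropped,
            " area(s) with missing indicator values")
    indicators <- indicators[keep, , drop = FALSE]
  }
  defs <- definitions[definitions$name %in% wanted, , drop = FALSE]
  scores <- rankit_transform(indicators, defs)

  # The method is computed in the risk-high orientation (most-at-risk area
  # ~1 on the scaled domain, largest transformed score). "risk-low" is the
  # mirrored presentation of the same quantities -- scaled' = 1 - scaled,
  # exp' = R - exp, rank by smallest composite -- so both orientations
  # always produce identical rank sets.
  mirror <- orientation == "risk-low"
  domains <- list()
  domain_exps <- list()
  weights <- numeric(0)
  for (dn in names(spec$domains)) {
    d <- spec$domains[[dn]]
    raw <- domain_score(scores, d$indicators)
    scaled <- scale_to_unit(raw)
    dexp <- exponential_transform(scaled, params)
    if (mirror) {
      scaled <- 1 - scaled
      dexp <- params$range_constant - dexp
    }
    domains[[dn]] <- data.frame(
      area_id = scores$area_id,
      domain_score_raw = raw,
      domain_rank = rank(raw, ties.method = "min"),  # 1 = most at risk
      domain_scaled = scaled,
      domain_exp = dexp,
      stringsAsFactors = FALSE)
    domain_exps[[dn]] <- dexp
    weights <- c(weights, d$weight)
  }
  combined <- if (length(domain_exps) == 1L) {
    domain_exps[[1L]]
  } else {
    combine_domains(domain_exps, weights)
  }
  rk <- rank_index(combined,
                   most_at_risk = if (mirror) "low" else "high")
  idx <- data.frame(area_id = scores$area_id,
                    combined_score = combined,
                    rank = rk,
                    stringsAsFactors = FALSE)
  if (nrow(idx) >= 10L) idx$decile <- assign_deciles(idx$rank)
  structure(list(index = idx, domains = domains, scores = scores,
                 spec_name = spec$name, domain_weights = weights,
                 n_excluded = n_dropped, orientation = orientation),
            class = "food_risk_index")
}

#' @export
print.food_risk_index <- function(x, ...) {
  cat("Food insecurity risk index:", x$spec_name, "\n")
  cat("  areas ranked:", nrow(x$index),
      " domains:", paste(names(x$domains), collapse = ", "), "\n")
  cat("  orientation:", x$orientation, "(rank 1 = most at risk)\n")
  invisible(x)
}
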