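#' Orient raw indicator values so that smaller means higher risk
#'
#' Indicators enter the index on different natural scales: for some a high
#' raw value marks high food-insecurity risk (benefit claimant %), for others
#' a high value marks low risk (download speed, bus-stop density). All
#' indicators are aligned before scoring so that ascending order of the
#' oriented vector corresponds to descending risk -- the most-at-risk area
#' always has the smallest oriented value.
#'
#' @param values Numeric vector of raw indicator values (finite).
#' @param higher_raw_is_higher_risk Logical flag: `TRUE` when a larger raw
#'   value indicates more risk (the vector is negated), `FALSE` when a larger
#'   raw value indicates less risk (returned unchanged).
#' @return Numeric vector of the same length, oriented for risk.
#' @examples
#' orient_for_risk(c(10, 50), TRUE)   # 50% claimants ranks first (most risk)
#' orient_for_risk(c(5, 100), FALSE)  # 5 Mbit/s ranks first
#' @export
orient_for_risk <- function(values, higher_raw_is_higher_risk) {
  stopifnot(is.numeric(values), is.logical(higher_raw_is_higher_risk),
            length(higher_raw_is_higher_risk) == 1L)
  if (any(!is.finite(values))) {
    stop("orient_for_risk: 'values' must be finite", call. = FALSE)
  }
  if (higher_raw_is_higher_risk) -values else values
}

#' Rankit rank-based inverse normal scores
#'
#' Maps a vector to standard-normal scores through its ranks: the value with
#' ascending rank r among n receives `qnorm((r - 0.5) / n)` (the Rankit
#' plotting position). Ties are given the mean of the ranks they span before
#' the quantile map, which preserves the zero-mean antisymmetry of the
#' scores. When the input has been oriented for risk (see
#' [orient_for_risk()]) the most-at-risk area receives the minimum score.
#'
#' @param oriented Numeric vector, length >= 2, finite; typically the output
#'   of [orient_for_risk()].
#' @return Numeric vector of normal scores, same length and order as the
#'   input.
#' @examples
#' rankit_scores(c(3, 1, 2))  # qnorm(c(5, 1, 3) / 6)
#' @export
rankit_scores <- function(oriented) {
  if (!is.numeric(oriented) || length(oriented) < 2L) {
    stop("rankit_scores: need a numeric vector of length >= 2", call. = FALSE)
  }
  if (any(!is.finite(oriented))) {
    stop("rankit_scores: non-finite values in input", call. = FALSE)
  }
  n <- length(oriented)
  r <- rank(oriented, ties.method = "average")
  stats::qnorm((r - 0.5) / n)
}

#' Score an indicator table with the Rankit transformation
#'
#' Applies [orient_for_risk()] then [rankit_scores()] to every indicator
#' column of an area-by-indicator table, using per-indicator risk-direction
#' metadata. The result is a score table on a common standard-normal scale
#' where, for every indicator, the most-at-risk area holds the minimum
#' score.
#'
#' @param indicators Data frame with an `area_id` column and one numeric
#'   column per indicator.
#' @param definitions Data frame of indicator definitions as returned by
#'   [indicator_definitions()], with columns `name` and
#'   `higher_raw_is_higher_risk`. Only indicators listed here are scored.
#' @return Data frame with `area_id` and one Rankit score column per
#'   indicator, same row order as the input.
#' @export
rankit_transform <- function(indicators, definitions) {
  stopifnot(is.data.frame(indicators), "area_id" %in% names(indicators),
            is.data.frame(definitions),
            all(c("name", "higher_raw_is_higher_risk") %in% names(definitions)))
  missing_cols <- setdiff(definitions$name, names(indicators))
  if (length(missing_cols)) {
    stop("rankit_transform: indicators missing from table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(area_id = indicators$area_id,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(definitions))) {
    nm <- definitions$name[i]
    oriented <- orient_for_risk(indicators[[nm]],
                                definitions$higher_raw_is_higher_risk[i])
    out[[nm]] <- rankit_scores(oriented)
  }
  out
}
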