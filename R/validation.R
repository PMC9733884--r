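#' Spearman rank correlation
#'
#' Product-moment correlation of tie-averaged ranks: the standard
#' non-parametric agreement measure between two area rankings.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, finite, each with
#'   non-zero variance.
#' @return Spearman coefficient in \[-1, 1\].
#' @examples
#' spearman_rank_corr(1:3, 3:1)  # -1
#' @export
spearman_rank_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("spearman_rank_corr: need equal-length vectors, n >= 3",
         call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("spearman_rank_corr: non-finite values", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("spearman_rank_corr: zero variance in input", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Chi-square test of association between two decile classifications
#'
#' Pearson chi-square on the 10x10 cross-tabulation of two decile label
#' vectors, expected counts from the marginals, no continuity correction.
#' Decile levels absent from both margins are dropped (with a warning) and
#' the degrees of freedom adjusted; with all ten levels occupied on both
#' sides the test has 81 degrees of freedom.
#'
#' @param dec_x,dec_y Integer decile labels in 1..10, equal length.
#' @return List with `chi2`, `dof`, `p`.
#' @export
decile_chi_square <- function(dec_x, dec_y) {
  if (length(dec_x) != length(dec_y)) {
    stop("decile_chi_square: length mismatch", call. = FALSE)
  }
  if (any(!dec_x %in% 1:10) || any(!dec_y %in% 1:10)) {
    stop("decile_chi_square: labels must lie in 1..10", call. = FALSE)
  }
  fx <- factor(dec_x, levels = 1:10)
  fy <- factor(dec_y, levels = 1:10)
  tab <- table(fx, fy)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("decile_chi_square: empty decile level(s) dropped; ",
            "degrees of freedom adjusted", call. = FALSE)
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic),
       dof = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Intraclass correlation ICC(A,1) with confidence interval
#'
#' Single-rater absolute-agreement intraclass correlation from the two-way
#' ANOVA decomposition of an n x 2 rating table (two-way model, raters
#' fixed, absolute agreement):
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with `k = 2`,
#' where MSR, MSC, MSE are the row (area), column (rater) and error mean
#' squares. The confidence interval uses the McGraw-Wong F-based method
#' with Satterthwaite degrees of freedom. Values are returned unclamped:
#' strong disagreement can push the point estimate below zero.
#'
#' @param x,y Numeric vectors of equal length `n >= 5` (the two "raters",
#'   e.g. two area rankings).
#' @param alpha Two-sided confidence level complement; default 0.05 for a
#'   95% interval.
#' @return List with `icc`, `ci_low`, `ci_high`.
#' @examples
#' icc_agreement(1:10, 1:10)$icc  # 1
#' @export
icc_agreement <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y) || length(x) < 5L) {
    stop("icc_agreement: need equal-length vectors, n >= 5", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("icc_agreement: non-finite values", call. = FALSE)
  }
  n <- length(x)
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  if (ss_total == 0) {
    stop("icc_agreement: zero total variance", call. = FALSE)
  }
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  # McGraw-Wong CI for ICC(A,1)
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci_low = ci_low, ci_high = ci_high)
}

#' Rank areas with 1 = least desirable outcome
#'
#' Helper for validation comparisons: validation criteria (IMD-like
#' deprivation score, free-school-meals %, child obesity %) are ranked so
#' that rank 1 marks the least desirable outcome (highest criterion value).
#'
#' @param values Numeric criterion values; larger = less desirable.
#' @return Tie-averaged ranks with 1 = worst.
#' @export
rank_worst_first <- function(values) {
  rank(-values, ties.method = "average")
}

#' Agreement battery between an index ranking and a validation criterion
#'
#' For each requested stratum (all areas, urban only, rural only) ranks both
#' the index and the criterion within the stratum (1 = least desirable /
#' most at risk), then computes the Spearman rank correlation, the 10x10
#' decile chi-square, and ICC(A,1) on the rank vectors.
#'
#' @param index_scores Data frame with `area_id` (or `msoa_id`) and a
#'   `combined_score` column for the index; larger = more at risk under the
#'   default orientation.
#' @param criterion Data frame with the same id column and a `value` column;
#'   larger = less desirable outcome.
#' @param geography Optional geography table supplying `urban_rural` for the
#'   id column; required for urban/rural strata. For MSOA-level comparisons
#'   an MSOA is urban when the majority of its areas are urban.
#' @param strata Character subset of `c("all", "urban", "rural")`.
#' @param index_name,criterion_name Labels copied into the report.
#' @param id_col Identifier column name shared by the inputs
#'   (default `"area_id"`).
#' @return Data frame, one row per stratum: `index_name`, `criterion_name`,
#'   `stratum`, `n`, `r_s`, `chi2`, `chi2_dof`, `chi2_p`, `icc`,
#'   `icc_ci_low`, `icc_ci_high`.
#' @export
validate_index <- function(index_scores, criterion, geography = NULL,
                           strata = "all", index_name = "index",
                           criterion_name = "criterion",
                           id_col = "area_id") {
  stopifnot(id_col %in% names(index_scores), id_col %in% names(criterion),
            "combined_score" %in% names(index_scores),
            "value" %in% names(criterion))
  merged <- merge(index_scores[c(id_col, "combined_score")],
                  criterion[c(id_col, "value")], by = id_col)
  if (any(c("urban", "rural") %in% strata)) {
    if (is.null(geography)) {
      stop("validate_index: geography needed for urban/rural strata",
           call. = FALSE)
    }
    flag <- urban_rural_flag(geography, merged[[id_col]], id_col)
    merged$urban_rural <- flag
  }
  out <- list()
  for (s in strata) {
    sub <- switch(s,
                  all = merged,
                  urban = merged[merged$urban_rural == "urban", ],
                  rural = merged[merged$urban_rural == "rural", ],
                  stop("validate_index: unknown stratum '", s, "'",
                       call. = FALSE))
    if (nrow(sub) == 0L) {
      warning("validate_index: stratum '", s, "' is empty; skipped",
              call. = FALSE)
      next
    }
    r_idx <- rank_worst_first(sub$combined_score)
    r_crit <- rank_worst_first(sub$value)
    rs <- spearman_rank_corr(r_idx, r_crit)
    chi <- decile_chi_square(assign_deciles(rank(r_idx, ties.method = "min")),
                             assign_deciles(rank(r_crit, ties.method = "min")))
    icc <- icc_agreement(r_idx, r_crit)
    out[[s]] <- data.frame(
      index_name = index_name, criterion_name = criterion_name,
      stratum = s, n = nrow(sub), r_s = rs,
      chi2 = chi$chi2, chi2_dof = chi$dof, chi2_p = chi$p,
      icc = icc$icc, icc_ci_low = icc$ci_low, icc_ci_high = icc$ci_high,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# urban/rural flag for area_id (direct) or msoa_id (majority vote)
urban_rural_flag <- function(geography, ids, id_col) {
  if (id_col == "area_id") {
    geography$urban_rural[match(ids, geography$area_id)]
  } else {
    share <- tapply(geography$urban_rural == "urban", geography$msoa_id, mean)
    ifelse(share[ids] >= 0.5, "urban", "rural")
  }
}

#' Regional and urban/rural composition of the most-at-risk decile
#'
#' Percentage breakdown of the areas in decile 1 (the most-at-risk tenth)
#' by region and by urban/rural classification.
#'
#' @param index Index result data frame with `area_id` and `decile`.
#' @param geography Geography table with `area_id`, `region`, `urban_rural`.
#' @return List with data frames `by_region` (`region`, `n`, `share_pct`)
#'   and `by_urban_rural` (`urban_rural`, `n`, `share_pct`); shares sum to
#'   100 within rounding.
#' @export
top_decile_summary <- function(index, geography) {
  stopifnot(all(c("area_id", "decile") %in% names(index)),
            all(c("area_id", "region", "urban_rural") %in% names(geography)))
  top <- index$area_id[index$decile == 1L]
  g <- geography[match(top, geography$area_id), ]
  by_region <- as.data.frame(table(region = g$region),
                             stringsAsFactors = FALSE)
  names(by_region)[2] <- "n"
  by_region$share_pct <- 100 * by_region$n / length(top)
  by_ur <- as.data.frame(table(urban_rural = g$urban_rural),
                         stringsAsFactors = FALSE)
  names(by_ur)[2] <- "n"
  by_ur$share_pct <- 100 * by_ur$n / length(top)
  list(by_region = by_region, by_urban_rural = by_ur,
       n_top_decile = length(top))
}
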