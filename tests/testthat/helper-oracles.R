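# Independent brute-force oracles. Deliberately avoid the package's code
# paths (and rank()): tie-averaged ranks are computed by counting.

oracle_avg_rank <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

oracle_rankit <- function(x) {
  n <- length(x)
  qnorm((oracle_avg_rank(x) - 0.5) / n)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_avg_rank(x), oracle_avg_rank(y))
}

oracle_chi2 <- function(dx, dy) {
  lx <- sort(unique(dx)); ly <- sort(unique(dy))
  n <- length(dx)
  chi2 <- 0
  for (a in lx) {
    for (b in ly) {
      o <- sum(dx == a & dy == b)
      e <- sum(dx == a) * sum(dy == b) / n
      chi2 <- chi2 + (o - e)^2 / e
    }
  }
  list(chi2 = chi2, dof = (length(lx) - 1) * (length(ly) - 1))
}

# two-way ANOVA mean squares computed from explicit sums of squares
oracle_icc_a1 <- function(x, y) {
  n <- length(x); k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - grand)^2)
  ss_cols <- n * sum((colMeans(m) - grand)^2)
  ss_err <- sum((m - grand)^2) - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# smallest decile d such that rank <= d * n / 10
oracle_decile <- function(ranks) {
  n <- length(ranks)
  vapply(ranks, function(r) {
    for (d in 1:10) if (r <= d * n / 10) return(d)
    10L
  }, integer(1))
}

# small synthetic configurations reused across tests
small_config <- function(seed = 1, ...) {
  synthetic_config(n_regions = 2, msoas_per_region = 5,
                   lsoas_per_msoa_range = c(4, 6), seed = seed, ...)
}

config_n <- function(n_areas, seed = 1, per_msoa = 20, ...) {
  stopifnot(n_areas %% per_msoa == 0)
  n_msoa <- n_areas / per_msoa
  regions <- max(1, min(9, n_msoa))
  while (n_msoa %% regions != 0) regions <- regions - 1
  synthetic_config(n_regions = regions, msoas_per_region = n_msoa / regions,
                   lsoas_per_msoa_range = c(per_msoa, per_msoa),
                   seed = seed, ...)
}
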