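test_that("Spearman correlation handles the canonical cases and oracle", {
  expect_equal(spearman_rank_corr(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(spearman_rank_corr(c(2, 5, 9, 1), c(2, 5, 9, 1)), 1)
  expect_error(spearman_rank_corr(1:2, 1:2), "n >= 3")
  expect_error(spearman_rank_corr(rep(1, 5), 1:5), "zero variance")
  set.seed(41)
  max_diff <- 0
  for (i in 1:500) {
    n <- sample(4:50, 1)
    x <- round(rnorm(n), 1); y <- round(rnorm(n), 1)  # ties likely
    max_diff <- max(max_diff,
                    abs(spearman_rank_corr(x, y) - oracle_spearman(x, y)))
  }
  expect_lte(max_diff, 1e-12)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(42)
  x <- rnorm(100); y <- rnorm(100)
  base <- spearman_rank_corr(x, y)
  expect_equal(spearman_rank_corr(exp(x), y), base, tolerance = 1e-12)
  expect_equal(spearman_rank_corr(x, atan(3 * y + 1)), base,
               tolerance = 1e-12)
})

test_that("decile chi-square matches closed form and brute force", {
  d <- rep(1:10, each = 100)
  res <- decile_chi_square(d, d)
  expect_equal(res$chi2, 9000)  # perfect diagonal, uniform marginals: 9n
  expect_equal(res$dof, 81)
  expect_lt(res$p, 1e-10)
  set.seed(43)
  for (i in 1:20) {
    n <- sample(100:400, 1)
    dx <- sample(1:10, n, replace = TRUE)
    dy <- sample(1:10, n, replace = TRUE)
    got <- decile_chi_square(dx, dy)
    brute <- oracle_chi2(dx, dy)
    expect_equal(got$chi2, brute$chi2, tolerance = 1e-10)
    expect_equal(got$dof, brute$dof)
  }
  expect_error(decile_chi_square(c(1, 11), c(1, 2)), "1..10")
})

test_that("empty decile levels are dropped with adjusted dof", {
  set.seed(40)
  dx <- sample(1:9, 200, replace = TRUE)  # level 10 never occurs
  dy <- sample(1:10, 200, replace = TRUE)
  expect_warning(res <- decile_chi_square(dx, dy), "dropped")
  expect_equal(res$dof, 8 * 9)
})

test_that("decile chi-square is calibrated under the null", {
  set.seed(44)
  rejections <- 0
  for (i in 1:200) {
    dx <- assign_deciles(rank_index(rnorm(1000)))
    dy <- assign_deciles(rank_index(rnorm(1000)))
    if (decile_chi_square(dx, dy)$p < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / 200, 0.01)
  expect_lte(rejections / 200, 0.09)
})

test_that("ICC(A,1) matches the ANOVA oracle and penalises shifts", {
  expect_equal(icc_agreement(1:10, 1:10)$icc, 1)
  set.seed(45)
  max_diff <- 0
  for (i in 1:200) {
    n <- sample(5:60, 1)
    x <- rnorm(n); y <- 0.7 * x + rnorm(n, 0, 0.5)
    max_diff <- max(max_diff,
                    abs(icc_agreement(x, y)$icc - oracle_icc_a1(x, y)))
  }
  expect_lte(max_diff, 1e-10)
  # constant shift: absolute agreement drops below 1, consistency stays 1
  x <- rnorm(200)
  res <- icc_agreement(x, x + 2)
  expect_lt(res$icc, 1)
  expect_equal(cor(x, x + 2), 1)
  expect_lte(res$ci_low, res$icc)
  expect_gte(res$ci_high, res$icc)
  expect_error(icc_agreement(rep(1, 10), rep(1, 10)), "zero total variance")
  expect_error(icc_agreement(1:3, 1:3), "n >= 5")
})

test_that("ICC(A,1) never exceeds 1 and approaches Pearson for matched
           columns at large n", {
  set.seed(46)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_lte(icc_agreement(x, y)$icc, 1)
  }
  # equal means and variances by construction: permutation of the same set
  x <- rnorm(2000); y <- sample(x)
  expect_lt(abs(icc_agreement(x, y)$icc - cor(x, y)), 0.01)
})

test_that("validate_index reports agreement per stratum on synthetic data", {
  cfg <- config_n(5000, seed = 47, validation_loadings = c(
    imd = 0, fsm = 0.75, obesity = 0.65))
  d <- generate_synthetic_dataset(cfg)
  bi <- build_index(d$indicators, index_spec("compositional"))
  rep0 <- validate_index(
    data.frame(area_id = bi$index$area_id,
               combined_score = -bi$index$rank),
    data.frame(area_id = d$area_validation$area_id,
               value = d$area_validation$imd_score),
    geography = d$geography, strata = c("all", "urban", "rural"),
    index_name = "compositional", criterion_name = "imd")
  # zero validation loading: no association
  expect_lte(abs(rep0$r_s[rep0$stratum == "all"]), 0.05)
  # stratum counts partition the overall count
  expect_equal(rep0$n[rep0$stratum == "urban"] +
                 rep0$n[rep0$stratum == "rural"],
               rep0$n[rep0$stratum == "all"])
  expect_true(all(abs(rep0$r_s) <= 1))
  expect_true(all(rep0$chi2 >= 0))
  expect_true(all(rep0$icc_ci_low <= rep0$icc &
                    rep0$icc <= rep0$icc_ci_high))
})

test_that("criterion loaded on the compositional latent prefers the
           Compositional Domain over the Complex Index", {
  cfg <- config_n(2000, seed = 48)
  d <- generate_synthetic_dataset(cfg)
  comp <- build_index(d$indicators, index_spec("compositional"))
  cplx <- build_index(d$indicators, index_spec("complex"))
  imd_rank <- d$area_validation$imd_rank
  rs_comp <- spearman_rank_corr(comp$index$rank, imd_rank)
  rs_cplx <- spearman_rank_corr(cplx$index$rank, imd_rank)
  expect_gt(rs_comp, rs_cplx)
  # structural domain alone should agree much less with a compositional
  # criterion than the compositional domain does
  struct <- build_index(d$indicators, index_spec("structural"))
  expect_gt(rs_comp, spearman_rank_corr(struct$index$rank, imd_rank))
})

test_that("top-decile summary percentages are a valid breakdown", {
  d <- generate_synthetic_dataset(config_n(500, seed = 49, per_msoa = 10))
  bi <- build_index(d$indicators, index_spec("complex"))
  summ <- top_decile_summary(bi$index, d$geography)
  expect_equal(sum(summ$by_region$share_pct), 100, tolerance = 0.01)
  expect_equal(sum(summ$by_urban_rural$share_pct), 100, tolerance = 0.01)
  expect_equal(summ$n_top_decile, sum(bi$index$decile == 1))
  # degenerate case: every top-decile area in one region
  idx <- data.frame(area_id = sprintf("a%02d", 1:20),
                    decile = rep(c(1L, 2L), each = 10))
  geo <- data.frame(area_id = sprintf("a%02d", 1:20),
                    region = rep(c("north", "south"), each = 10),
                    urban_rural = "urban")
  s2 <- top_decile_summary(idx, geo)
  expect_equal(s2$by_region$share_pct[s2$by_region$region == "north"], 100)
})

test_that("a raised region intercept inflates that region's top-decile
           share beyond its population share", {
  cfg <- config_n(2000, seed = 50, region_sd = 0.6)
  d <- generate_synthetic_dataset(cfg)
  bi <- build_index(d$indicators, index_spec("compositional"))
  region_means <- tapply(d$latents$L_comp, d$geography$region, mean)
  hot <- names(which.max(region_means))
  summ <- top_decile_summary(bi$index, d$geography)
  pop_share <- 100 * mean(d$geography$region == hot)
  got <- summ$by_region$share_pct[summ$by_region$region == hot]
  expect_gt(got, pop_share)
})
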