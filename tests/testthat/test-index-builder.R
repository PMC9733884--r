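test_that("domain scores are weighted sums of indicator scores", {
  sc <- data.frame(area_id = c("a", "b"), i1 = c(-1, 1), i2 = c(-1, 0.5))
  expect_equal(domain_score(sc, c("i1", "i2")), c(-2, 1.5))
  expect_equal(domain_score(sc, "i1"), sc$i1)  # single-indicator identity
  expect_error(domain_score(sc, c("i1", "nope")), "nope")
  expect_error(domain_score(sc, c("i1", "i2"), weights = c(-1, 1)),
               "non-negative")
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:40, 1); k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k), n)
    tab <- data.frame(area_id = seq_len(n), m)
    names(tab)[-1] <- paste0("v", 1:k)
    w <- runif(k)
    brute <- apply(m, 1, function(row) sum(row * w))
    expect_equal(domain_score(tab, paste0("v", 1:k), w), brute,
                 tolerance = 1e-12)
  }
})

test_that("unit scaling sends the most-at-risk area towards 1", {
  # most risk = smallest raw domain score
  raw <- c(-3, -1, 0.5, 2)
  expect_equal(scale_to_unit(raw), c(0.875, 0.625, 0.375, 0.125))
  expect_equal(scale_to_unit(rep(7, 6)), rep(0.5, 6))
  set.seed(22)
  x <- rnorm(50)
  s <- scale_to_unit(x)
  expect_true(all((rank(x) <= 25) == (s > 0.5)))
  expect_equal(order(s), order(x, decreasing = TRUE))
  expect_true(all(s > 0 & s < 1))
  expect_error(scale_to_unit(1), "length")
})

test_that("the exponential transform matches its closed form and shape", {
  expect_equal(exponential_transform(0), 0, tolerance = 1e-9)
  expect_equal(exponential_transform(1), 100, tolerance = 1e-9)
  expect_equal(exponential_transform(0.5), 15.65, tolerance = 0.01)
  g <- seq(0, 1, length.out = 1001)
  y <- exponential_transform(g)
  expect_true(all(diff(y) > 0))        # strictly increasing
  expect_true(all(diff(diff(y)) > 0))  # convex
  expect_true(all(y >= 0 & y <= 100))
  expect_error(exponential_transform(1.01), "\\[0, 1\\]")
  # non-default constants keep the endpoint property X(1) = R
  p <- exp_transform_params(scaling_constant = 10, range_constant = 50)
  expect_equal(exponential_transform(1, p), 50, tolerance = 1e-9)
  expect_error(exp_transform_params(scaling_constant = 0), "scaling_constant")
})

test_that("combining domains sums with weights and resists cancellation", {
  expect_equal(combine_domains(list(a = c(100, 1), b = c(100, 2))),
               c(200, 3))
  # degenerate constant domain leaves the other's ordering intact
  x <- c(30, 10, 80)
  comb <- combine_domains(list(a = x, b = rep(0, 3)))
  expect_equal(order(comb), order(x))
  expect_error(combine_domains(list(a = 1:3, b = 1:4)), "different area sets")
  # convexity upstream: extreme risk in one domain beats a balanced tie
  a <- exponential_transform(0.9) + exponential_transform(0.1)
  b <- exponential_transform(0.5) + exponential_transform(0.5)
  expect_gt(a, b)
})

test_that("ranking applies the lowest applicable rank to ties", {
  expect_equal(rank_index(c(5, 3, 3, 1)), c(1, 2, 2, 4))
  set.seed(23)
  x <- rnorm(100)
  expect_equal(sort(rank_index(x)), 1:100)
  # flipped orientation on mirrored scores reproduces identical ranks
  expect_equal(rank_index(-x, most_at_risk = "low"), rank_index(x))
  expect_error(rank_index(c(1, NA)), "non-finite")
})

test_that("deciles partition ranks into near-equal risk tenths", {
  r <- rank_index(rnorm(32844))
  d <- assign_deciles(r)
  expect_true(sum(d == 1) %in% c(3284, 3285))
  expect_equal(sum(d == 1), 3284)
  d100 <- assign_deciles(rank_index(rnorm(100)))
  expect_equal(as.vector(table(d100)), rep(10, 10))
  set.seed(24)
  for (i in 1:20) {
    n <- sample(10:500, 1)
    rk <- rank_index(round(rnorm(n), 1))
    expect_equal(assign_deciles(rk), oracle_decile(rk))
  }
  expect_error(assign_deciles(1:5), "at least 10")
})

test_that("MSOA aggregation sums, conserves mass, and keeps the tie rule", {
  lookup <- data.frame(area_id = c("a1", "a2", "b1"),
                       msoa_id = c("M1", "M1", "M2"))
  agg <- aggregate_to_msoa(list(dom = c(10, 20, 5)),
                           c("a1", "a2", "b1"), lookup)
  expect_equal(agg$dom_exp, c(30, 5))
  expect_equal(agg$rank, c(1L, 2L))
  expect_error(aggregate_to_msoa(list(dom = c(1, 2)), c("a1", "zz"), lookup),
               "zz")
  # single-LSOA MSOAs: MSOA ranking equals LSOA ranking
  solo <- data.frame(area_id = letters[1:6], msoa_id = paste0("M", 1:6))
  v <- c(4, 9, 1, 7, 2, 5)
  agg2 <- aggregate_to_msoa(list(dom = v), letters[1:6], solo)
  expect_equal(agg2$rank[match(paste0("M", 1:6), agg2$msoa_id)],
               rank_index(v))
  # brute-force group-and-sum on random partitions, plus conservation
  set.seed(25)
  for (i in 1:10) {
    n <- sample(20:100, 1)
    ids <- sprintf("a%03d", 1:n)
    lk <- data.frame(area_id = ids,
                     msoa_id = sample(sprintf("M%02d", 1:8), n, replace = TRUE))
    v1 <- runif(n, 0, 100); v2 <- runif(n, 0, 100)
    agg3 <- aggregate_to_msoa(list(d1 = v1, d2 = v2), ids, lk)
    brute <- sapply(agg3$msoa_id, function(m)
      sum(v1[lk$msoa_id == m]) + sum(v2[lk$msoa_id == m]))
    expect_equal(agg3$combined_score, unname(brute), tolerance = 1e-12)
    expect_lt(abs(sum(agg3$combined_score) - (sum(v1) + sum(v2))), 1e-9)
  }
})

test_that("build_index orchestrates the stages into coherent ranks", {
  d <- generate_synthetic_dataset(config_n(500, seed = 31, per_msoa = 10))
  bi <- build_index(d$indicators, index_spec("complex"))
  expect_s3_class(bi, "food_risk_index")
  expect_equal(sort(unique(bi$index$decile)), 1:10)
  expect_true(all(bi$index$combined_score >= 0 &
                    bi$index$combined_score <= 200))
  for (dm in bi$domains) {
    expect_true(all(dm$domain_exp >= 0 & dm$domain_exp <= 100))
    expect_true(all(dm$domain_scaled >= 0 & dm$domain_scaled <= 1))
  }
  # extracting the compositional domain ranks equals building it directly
  solo <- build_index(d$indicators, index_spec("compositional"))
  expect_equal(solo$index$rank,
               rank_index(bi$domains$compositional$domain_exp))
  # row-order invariance
  perm <- sample(nrow(d$indicators))
  bp <- build_index(d$indicators[perm, ], index_spec("complex"))
  expect_equal(bp$index$rank[match(bi$index$area_id, bp$index$area_id)],
               bi$index$rank)
  # both orientations give identical rank sets
  blo <- build_index(d$indicators, index_spec("complex"),
                     orientation = "risk-low")
  expect_equal(blo$index$rank, bi$index$rank)
  expect_error(build_index(d$indicators,
                           list(name = "bad", domains = list(
                             d1 = list(indicators = "ghost", weight = 1)))),
               "ghost")
})

test_that("worsening a risk indicator never makes an area look safer", {
  d <- generate_synthetic_dataset(config_n(500, seed = 32, per_msoa = 10))
  base <- build_index(d$indicators, index_spec("complex"))
  target <- d$indicators$area_id[250]
  worse <- d$indicators
  i <- which(worse$area_id == target)
  worse$claimants_pct[i] <- min(100, worse$claimants_pct[i] + 20)
  after <- build_index(worse, index_spec("complex"))
  expect_lte(after$index$rank[after$index$area_id == target],
             base$index$rank[base$index$area_id == target])
})

test_that("areas with missing indicator values are excluded with a count", {
  d <- generate_synthetic_dataset(small_config(seed = 33))
  d$indicators$no_quals_pct[3] <- NA
  expect_message(bi <- build_index(d$indicators, index_spec("complex")),
                 "excluded 1")
  expect_equal(nrow(bi$index), nrow(d$indicators) - 1)
  expect_false(d$indicators$area_id[3] %in% bi$index$area_id)
})
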