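test_that("perfectly correlated indicators give two score levels, wealthier higher", {
  x <- matrix(c(0, 0, 1, 1,
                0, 0, 1, 1), ncol = 2)
  sc <- wealth_scores(x)
  expect_length(unique(round(sc, 10)), 2L)
  expect_true(all(sc[3:4] > sc[1:2]))
  expect_equal(sc[1], sc[2])
})

test_that("scores match an independent eigen-decomposition oracle", {
  x <- matrix(c(0, 2, 3, 5,
                1, 0, 3, 4), ncol = 2)
  z <- scale(x)
  v <- eigen(stats::cor(x))$vectors[, 1]
  oracle <- as.numeric(z %*% v)
  if (sum(oracle * rowSums(z)) < 0) oracle <- -oracle
  expect_equal(wealth_scores(x), oracle, tolerance = 1e-10)
})

test_that("owning every asset yields the maximal score; none the minimal", {
  s <- generate_survey(generator_config(seed = 5, n_patients = 500,
                                        n_facilities = 50))
  a <- asset_matrix(s)
  a <- rbind(a, 1, 0)
  sc <- wealth_scores(a)
  expect_equal(which.max(sc), nrow(a) - 1L)
  expect_equal(which.min(sc), nrow(a))
})

test_that("constant indicators are dropped with a warning; too few is an error", {
  x <- cbind(c(0, 1, 0, 1), c(1, 1, 1, 1), c(0, 0, 1, 1))
  expect_warning(sc <- wealth_scores(x), "constant indicator")
  expect_length(sc, 4L)
  expect_error(suppressWarnings(wealth_scores(cbind(c(0, 1), c(1, 1)))),
               "fewer than 2 usable")
  x[2, 1] <- NA
  expect_error(wealth_scores(x), "missing asset indicator")
})

test_that("scores are invariant to positive affine rescaling of one indicator", {
  set.seed(9)
  x <- matrix(rbinom(80, 1, 0.5) + rnorm(80, sd = 0.01), ncol = 4)
  x2 <- x; x2[, 2] <- 100 * x2[, 2] + 7
  expect_equal(wealth_scores(x), wealth_scores(x2), tolerance = 1e-8)
  x3 <- x; x3[, 3] <- -2 * x3[, 3] + 1   # sign flip: equal up to overall sign
  expect_equal(abs(stats::cor(wealth_scores(x), wealth_scores(x3))), 1,
               tolerance = 1e-8)
})

test_that("untied unit-weight fractional ranks follow (i - 0.5)/n", {
  expect_equal(fractional_ranks(c(3, 1, 4, 2, 5))[order(c(3, 1, 4, 2, 5))],
               c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_equal(fractional_ranks(10), 0.5)
  expect_error(fractional_ranks(numeric(0)), "empty")
})

test_that("tied scores share the average of the ranks their positions occupy", {
  expect_equal(fractional_ranks(c(1, 1, 2)), c(1 / 3, 1 / 3, 5 / 6))
  expect_equal(fractional_ranks(c(2, 1, 1)), c(5 / 6, 1 / 3, 1 / 3))
  expect_equal(fractional_ranks(rep(7, 4)), rep(0.5, 4))
})

test_that("weighted mean rank is 0.5 to machine precision on random inputs", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(2:60, 1)
    sc <- sample(round(rnorm(n), sample(0:2, 1)))  # induces ties
    w <- rexp(n) + 0.1
    r <- fractional_ranks(sc, w)
    expect_equal(sum(w * r) / sum(w), 0.5, tolerance = 1e-12)
    expect_true(all(r > 0 & r < 1))
    expect_true(all(diff(r[order(sc)]) >= -1e-12))
  }
})

test_that("ranks are invariant under strictly monotone transforms of scores", {
  set.seed(12)
  sc <- rnorm(40)
  expect_equal(fractional_ranks(exp(sc)), fractional_ranks(sc))
  expect_equal(fractional_ranks(sc^3), fractional_ranks(sc))
})

test_that("quintile cut balances group sizes and respects ties", {
  r100 <- fractional_ranks(sample(1:100))
  expect_equal(as.integer(table(assign_quintiles(r100))), rep(20L, 5))
  r7 <- (2 * (1:7) - 1) / 14
  expect_equal(as.integer(table(assign_quintiles(r7))), c(1L, 2L, 1L, 2L, 1L))
  expect_equal(unique(assign_quintiles(fractional_ranks(rep(3, 9)))), 3L)
  expect_error(assign_quintiles(c(0.2, 1.0)), "strictly in")
})

test_that("recovered scores track latent wealth on synthetic households", {
  cfg <- generator_config(seed = 77, n_patients = 2000, n_facilities = 200,
                          n_assets = 20, asset_loadings = rep(1, 20))
  s <- generate_survey(cfg)
  sc <- wealth_scores(s)
  expect_gt(stats::cor(sc, s$truth$latent_wealth, method = "spearman"), 0.8)
})

test_that("ranked_sample bundles consistent ranks and quintiles", {
  rs <- ranked_sample(c(5, 3, 8, 1), scores = c(0.2, -1, 2, -3))
  expect_s3_class(rs, "ranked_sample")
  expect_equal(rs$ranks, fractional_ranks(c(0.2, -1, 2, -3)))
  expect_equal(rs$quintile, assign_quintiles(rs$ranks))
  expect_error(ranked_sample(numeric(0)), "empty")
  expect_error(ranked_sample(1:3), "supply scores or ranks")
})
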