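test_that("closed-form concentration indices are reproduced", {
  # constant outcome: zero covariance
  expect_equal(concentration_index(rep(1, 8), scores = 1:8)$index, 0)
  # single positive case held by the richest: C = (n-1)/n
  expect_equal(concentration_index(c(0, 0, 0, 0, 1), scores = 1:5)$index,
               0.8)
  # y equal to its own midpoint rank: C = (n^2-1)/(3n^2)
  r <- fractional_rank(1:10)
  expect_equal(concentration_index(r, ranks = r)$index, 99 / 300)
})

test_that("index interprets direction and respects its bounds", {
  set.seed(1)
  for (i in 1:20) {
    n <- sample(5:300, 1)
    y <- rbinom(n, 1, 0.3)
    if (sum(y) == 0) y[1] <- 1
    w <- rexp(n) + 0.1
    s <- rnorm(n)
    res <- concentration_index(y, scores = s, weights = w)
    expect_true(res$index >= -1 && res$index <= 1)
    # binary bound |C| <= 1 - mu + 1/n
    expect_lte(abs(res$index), 1 - res$mu + 1 / n + 1e-12)
  }
})

test_that("index is scale invariant and antisymmetric in the ranking", {
  set.seed(2)
  y <- rbinom(50, 1, 0.4); y[1] <- 1
  w <- runif(50, 0.5, 2)
  s <- rnorm(50)
  c1 <- concentration_index(y, scores = s, weights = w)$index
  expect_equal(concentration_index(3.7 * y, scores = s, weights = w)$index,
               c1, tolerance = 1e-12)
  expect_equal(concentration_index(y, scores = -s, weights = w)$index,
               -c1, tolerance = 1e-12)
})

test_that("undefined index and curve raise informative errors", {
  expect_error(concentration_index(rep(0, 5), scores = 1:5), "undefined")
  expect_error(concentration_curve(rep(0, 5), 1:5), "undefined")
})

test_that("concentration curve has the stated geometry", {
  # constant outcome: the diagonal
  cv <- concentration_curve(rep(1, 4), 1:4)
  expect_equal(cv$p, cv$L)
  # all utilisation at the richest record: L = 0 up to p = 0.8
  cv <- concentration_curve(c(0, 0, 0, 0, 1), 1:5)
  expect_equal(cv$L[cv$p == 0.8], 0)
  expect_equal(cv$p[1], 0); expect_equal(cv$L[1], 0)
  expect_equal(cv$p[nrow(cv)], 1); expect_equal(cv$L[nrow(cv)], 1)
  # reversing the ranking mirrors the curve about the diagonal
  y <- c(1, 0, 1, 0, 0, 1); s <- 1:6
  a <- concentration_curve(y, s)
  b <- concentration_curve(y, -s)
  expect_equal(sort(1 - b$L), sort(a$L), tolerance = 1e-12)
})

test_that("twice-area oracle agrees with the covariance form", {
  expect_equal(ci_from_curve(data.frame(p = c(0, 1), L = c(0, 1))), 0)
  cv <- concentration_curve(c(0, 0, 0, 0, 1), 1:5)
  expect_equal(ci_from_curve(cv), 0.8)
  r <- fractional_rank(1:10)
  expect_equal(ci_from_curve(concentration_curve(r, 1:10)), 99 / 300,
               tolerance = 1e-12)
  # property: oracle equivalence over random instances with distinct scores
  set.seed(3)
  for (i in 1:50) {
    n <- sample(3:1000, 1)
    y <- rbinom(n, 1, runif(1, 0.05, 0.95)); if (!sum(y)) y[n] <- 1
    w <- if (i %% 2) rep(1, n) else rexp(n) + 0.05
    s <- sample(seq_len(n))                       # distinct scores
    c_cov <- concentration_index(y, scores = s, weights = w)$index
    c_area <- ci_from_curve(concentration_curve(y, s, w))
    expect_equal(c_cov, c_area, tolerance = 1e-10)
  }
})

test_that("malformed curves are rejected by the oracle", {
  expect_error(ci_from_curve(data.frame(p = c(0, 0.5), L = c(0, 0.4))),
               "anchored")
  expect_error(
    ci_from_curve(data.frame(p = c(0, 0.7, 0.4, 1), L = c(0, 0.2, 0.5, 1))),
    "nondecreasing")
})

test_that("quintile-group ranking collapses ranks within quintiles", {
  set.seed(4)
  y <- rbinom(200, 1, 0.3); y[1] <- 1
  s <- rnorm(200)
  a <- concentration_index(y, scores = s,
                           ranking_basis = "quintile_groups")
  b <- concentration_index(y, scores = s)
  expect_s3_class(a, "concindex")
  # grouped ranking loses within-quintile detail, so the two may differ,
  # but both must carry the same mean and direction of the gradient
  expect_equal(a$mu, b$mu)
})

test_that("grouped indices recompute ranks within each group", {
  tab <- make_survey(40,
                     state = rep(c("A", "B"), each = 20),
                     wealth_score = rep(1:20, 2),
                     full_anc = rep(c(0, 1), 20))
  res <- ci_by_group(tab, "full_anc", "state", min_n = 10)
  expect_named(res, c("A", "B"))
  # identical groups give identical indices
  expect_equal(res$A$index, res$B$index)
  # constant outcome in one group gives C = 0 there
  tab$full_anc[tab$state == "B"] <- 1
  res2 <- ci_by_group(tab, "full_anc", "state", min_n = 10)
  expect_equal(res2$B$index, 0)
  # threshold excludes small groups; all excluded is an error
  expect_message(
    res3 <- ci_by_group(tab[c(1:20, 21), ], "full_anc", "state",
                        min_n = 10),
    "skipping")
  expect_named(res3, "A")
  expect_error(
    suppressMessages(ci_by_group(tab, "full_anc", "state", min_n = 1000)),
    "threshold")
})
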