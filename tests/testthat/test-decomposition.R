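test_that("a perfect-fit single regressor explains the whole index", {
  y <- c(0, 0, 1, 1, 0, 1)
  r <- fractional_rank(c(3, 1, 6, 5, 2, 4))
  res <- wagstaff_decompose(y, matrix(y, dimnames = list(NULL, "x")),
                            ranks = r)
  expect_equal(res$explained, res$total, tolerance = 1e-12)
  expect_equal(res$residual, 0, tolerance = 1e-12)
  pc <- percent_contributions(res)
  expect_equal(unname(pc["x"]), 100, tolerance = 1e-10)
})

test_that("the additive identity is exact for the linear model", {
  set.seed(12)
  for (i in 1:5) {
    n <- 400
    tab <- make_survey(n,
                       wealth_score = rnorm(n),
                       wealth_quintile = sample(1:5, n, TRUE),
                       weight = rexp(n) + 0.2,
                       residence = sample(c("urban", "rural"), n, TRUE),
                       age_group = sample(c("15-24", "25-34", "35-49"), n,
                                          TRUE),
                       birth_order = sample(c("1", "2", "3+"), n, TRUE),
                       education = sample(c("none", "primary", "secondary",
                                            "higher"), n, TRUE),
                       caste = sample(c("SC", "ST", "OBC", "Others"), n,
                                      TRUE),
                       media_exposure = sample(c("no", "yes"), n, TRUE))
    y <- rbinom(n, 1, plogis(-1 + (tab$residence == "urban")))
    if (!sum(y)) y[1] <- 1
    d <- build_design(tab, weights = tab$weight)
    # ties in the score must not break the identity
    score <- if (i %% 2) tab$wealth_score else round(tab$wealth_score, 1)
    r <- fractional_rank(score, tab$weight)
    res <- wagstaff_decompose(y, d, tab$weight, r)
    expect_equal(res$explained + res$residual, res$total,
                 tolerance = 1e-10)
    # and the total matches the outcome's concentration index
    expect_equal(res$total,
                 concentration_index(y, ranks = r,
                                     weights = tab$weight)$index,
                 tolerance = 1e-12)
  }
})

test_that("a wealth-uncorrelated regressor contributes exactly zero", {
  # x is rank-symmetric about 1/2: C_k = 0 by construction
  n <- 8
  r <- fractional_rank(1:n)
  x <- c(1, 0, 0, 1, 1, 0, 0, 1)
  stopifnot(abs(mean(x * r) - mean(x) * mean(r)) < 1e-12)
  y <- rbinom(n, 1, 0.5); y[1] <- 1
  res <- wagstaff_decompose(y, cbind(x = x), ranks = r)
  expect_equal(res$rows$contribution[res$rows$regressor == "x"], 0,
               tolerance = 1e-12)
})

test_that("decomposition is invariant to regressor order and weight scale", {
  set.seed(13)
  n <- 200
  X <- cbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.3),
             c = rbinom(n, 1, 0.7))
  y <- rbinom(n, 1, plogis(-0.5 + X[, "a"] - X[, "b"]))
  if (!sum(y)) y[1] <- 1
  w <- runif(n, 0.5, 2)
  r <- fractional_rank(rnorm(n), w)
  r1 <- wagstaff_decompose(y, X, w, r)
  r2 <- wagstaff_decompose(y, X[, c("c", "a", "b")], w, r)
  m <- match(r1$rows$regressor, r2$rows$regressor)
  expect_equal(r1$rows$contribution, r2$rows$contribution[m],
               tolerance = 1e-12)
  r3 <- wagstaff_decompose(y, X, 5 * w, r)
  expect_equal(r1$rows$contribution, r3$rows$contribution,
               tolerance = 1e-10)
  expect_equal(r1$total, r3$total, tolerance = 1e-12)
})

test_that("logit-AME decomposition closes with residual = total - explained", {
  set.seed(14)
  tab <- generate_population(scenario_preset("nfhs4_like", n = 3000),
                             seed = 21)
  fit <- ci_decomp(sba ~ ., data = tab, model_kind = "logit_ame")
  expect_equal(fit$model_kind, "logit_ame")
  expect_equal(fit$explained + fit$residual, fit$total, tolerance = 1e-12)
  expect_true(all(abs(fit$rows$beta) < 1))
})

test_that("percentage contributions support both denominators", {
  y <- c(0, 0, 1, 1, 0, 1)
  r <- fractional_rank(c(3, 1, 6, 5, 2, 4))
  res <- wagstaff_decompose(y, matrix(y, dimnames = list(NULL, "x")),
                            ranks = r)
  # arithmetic on constructed components
  res$rows$contribution <- c(0.05)
  res$rows <- rbind(res$rows, res$rows)
  res$rows$regressor <- c("x", "z")
  res$total <- 0.2
  res$explained <- 0.1
  expect_equal(as.numeric(percent_contributions(res, "total")), c(25, 25))
  expect_equal(as.numeric(percent_contributions(res, "explained")),
               c(50, 50))
  res$total <- 0
  expect_warning(pc <- percent_contributions(res, "total"), "undefined")
  expect_true(all(is.na(pc)))
})

test_that("formula interface validates its inputs", {
  tab <- generate_population(scenario_preset("nfhs4_like", n = 500),
                             seed = 2)
  expect_error(ci_decomp(nope ~ ., data = tab), "outcome column")
  expect_error(ci_decomp(full_anc ~ education + wealth_score, data = tab),
               "non-covariate")
  fit <- ci_decomp(full_anc ~ education + media_exposure, data = tab)
  expect_true(all(grepl("^(edu_|media_)", fit$rows$regressor)))
  expect_equal(fit$explained + fit$residual, fit$total, tolerance = 1e-10)
})

test_that("model methods expose coefficients, residuals and fitted values", {
  tab <- generate_population(scenario_preset("nfhs3_like", n = 800),
                             seed = 4)
  fit <- ci_decomp(pnc ~ ., data = tab)
  expect_named(coef(fit), fit$rows$regressor)
  expect_equal(length(residuals(fit)), nrow(tab))
  expect_equal(tab$pnc - fitted(fit), unname(residuals(fit)),
               tolerance = 1e-12)
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("identity gap", out)))
})
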