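test_that("design matrix uses the conventional reference categories", {
  tab <- make_survey(2,
                     residence = c("rural", "urban"),
                     age_group = c("15-24", "35-49"),
                     birth_order = c("1", "3+"),
                     education = c("none", "higher"),
                     caste = c("Others", "OBC"),
                     media_exposure = c("no", "yes"))
  d <- build_design(tab)
  # reference record: all dummies zero
  expect_true(all(d$X[1, ] == 0))
  # the second record lights exactly one dummy per variable
  expect_equal(sum(d$X[2, ]), 6)
  expect_equal(d$X[2, c("urban", "age_35_49", "birth_order_3plus",
                        "edu_higher", "caste_OBC", "media_yes")],
               setNames(rep(1, 6), c("urban", "age_35_49",
                                     "birth_order_3plus", "edu_higher",
                                     "caste_OBC", "media_yes")))
  # equal weights: means are simple column averages
  expect_equal(unname(d$means), unname(colMeans(d$X)))
  # within one variable at most one dummy is set per row
  expect_true(all(rowSums(d$X[, c("edu_primary", "edu_secondary",
                                  "edu_higher"), drop = FALSE]) <= 1))
})

test_that("reference-level overrides change the omitted category", {
  tab <- make_survey(4)
  d <- build_design(tab, overrides = list(residence = "urban"))
  expect_true("rural" %in% colnames(d$X))
  expect_false("urban" %in% colnames(d$X))
  expect_error(build_design(tab, overrides = list(residence = "suburb")),
               "invalid reference level")
  expect_error(build_design(make_survey(2, caste = c("XX", "SC"))),
               "outside its domain")
})

test_that("weighted least squares reproduces hand calculations", {
  # y identical to a regressor: perfect fit
  x <- c(0, 0, 1, 1)
  f <- fit_lpm(c(0, 0, 1, 1), matrix(x, dimnames = list(NULL, "x")))
  expect_equal(unname(f$beta), 1)
  expect_equal(f$intercept, 0)
  expect_equal(unname(f$residuals), rep(0, 4))
  # hand least squares on the 2x2 design
  f2 <- fit_lpm(c(0, 1, 1, 1), matrix(x, dimnames = list(NULL, "x")))
  expect_equal(unname(f2$beta), 0.5)
  expect_equal(f2$intercept, 0.5)
  # weighted mean residual is zero
  set.seed(5)
  w <- runif(4, 0.5, 2)
  f3 <- fit_lpm(c(0, 1, 0, 1), matrix(x, dimnames = list(NULL, "x")), w)
  expect_equal(sum(w * f3$residuals) / sum(w), 0, tolerance = 1e-10)
})

test_that("lpm coefficients are invariant to weight rescaling", {
  set.seed(6)
  tab <- make_survey(80,
                     residence = sample(c("urban", "rural"), 80, TRUE),
                     age_group = sample(c("15-24", "25-34", "35-49"), 80,
                                        TRUE),
                     birth_order = sample(c("1", "2", "3+"), 80, TRUE),
                     education = sample(c("none", "primary", "secondary",
                                          "higher"), 80, TRUE),
                     caste = sample(c("SC", "ST", "OBC", "Others"), 80,
                                    TRUE),
                     media_exposure = sample(c("no", "yes"), 80, TRUE))
  y <- rbinom(80, 1, 0.4)
  d <- build_design(tab)
  w <- runif(80, 0.5, 3)
  f1 <- suppressMessages(fit_lpm(y, d$X, w))
  f2 <- suppressMessages(fit_lpm(y, d$X, 7 * w))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-10)
})

test_that("constant columns are dropped and collinearity is an error", {
  X <- cbind(a = c(0, 1, 0, 1, 1), b = rep(0, 5))
  expect_message(f <- fit_lpm(c(0, 1, 1, 0, 1), X), "constant")
  expect_named(f$beta, "a")
  X2 <- cbind(a = c(0, 1, 0, 1), twice_a = c(0, 2, 0, 2))
  expect_error(fit_lpm(c(0, 1, 1, 0), X2), "collinear")
})

test_that("saturated logit AME equals the difference in cell proportions", {
  x <- rep(c(1, 0), each = 10)
  y <- c(rep(1, 6), rep(0, 4), rep(1, 2), rep(0, 8))   # 6/10 vs 2/10
  f <- fit_logit_ame(y, matrix(x, dimnames = list(NULL, "x")))
  expect_equal(unname(f$beta["x"]), 0.4, tolerance = 1e-8)
  expect_equal(f$model_kind, "logit_ame")
  # weighted version: AME matches weighted cell-proportion difference
  w <- runif(20, 0.5, 2)
  fw <- fit_logit_ame(y, matrix(x, dimnames = list(NULL, "x")), w)
  p1 <- sum(w * y * x) / sum(w * x)
  p0 <- sum(w * y * (1 - x)) / sum(w * (1 - x))
  expect_equal(unname(fw$beta["x"]), p1 - p0, tolerance = 1e-8)
})

test_that("logit AME is zero when the outcome is independent of x", {
  # balanced 2x2 with identical outcome rates in both cells
  x <- rep(c(0, 1), each = 10)
  y <- rep(c(1, 1, 0, 0, 0), 4)
  f <- fit_logit_ame(y, matrix(x, dimnames = list(NULL, "x")))
  expect_equal(unname(f$beta["x"]), 0, tolerance = 1e-8)
  expect_true(abs(f$beta["x"]) < 1)
})

test_that("perfect separation falls back to the linear model", {
  x <- c(0, 0, 0, 1, 1, 1)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_warning(f <- fit_logit_ame(y, matrix(x, dimnames = list(NULL, "x"))),
                 "separation")
  expect_equal(f$model_kind, "lpm")
})

test_that("generalised concentration index follows its definition", {
  r <- fractional_rank(1:6)
  expect_equal(generalized_ci(rep(0, 6), r), 0)
  # residuals equal to y itself: GC = mu * C(y)
  y <- c(0, 1, 0, 1, 1, 1)
  ci <- concentration_index(y, ranks = r)
  expect_equal(generalized_ci(y, r), ci$mu * ci$index, tolerance = 1e-12)
  # residuals orthogonalised against the ranks give exactly zero
  set.seed(8)
  e <- rnorm(6)
  rc <- r - mean(r)
  e_orth <- e - sum(e * rc) / sum(rc^2) * rc
  e_orth <- e_orth - mean(e_orth)
  expect_equal(generalized_ci(e_orth, r), 0, tolerance = 1e-12)
})
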