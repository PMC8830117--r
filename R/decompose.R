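#' Wagstaff-type decomposition of a concentration index
#'
#' Decomposes the concentration index of a binary outcome into per-regressor
#' contributions.  For the linear model \eqn{y_i = \alpha + \sum_k \beta_k
#' x_{ki} + \epsilon_i}, the index satisfies
#' \deqn{C = \sum_k (\beta_k \bar x_k / \mu)\, C_k + GC_\epsilon / \mu,}
#' where \eqn{C_k} is the concentration index of regressor \eqn{x_k}
#' (computed with the same fractional ranks and weights as the outcome's
#' index), \eqn{\beta_k \bar x_k/\mu} the elasticity, and
#' \eqn{GC_\epsilon} the generalised concentration index of the residuals.
#' With `model_kind = "lpm"` this identity is exact; with
#' `model_kind = "logit_ame"` the \eqn{\beta_k} are average marginal effects
#' and the residual is defined as `total - explained`.
#'
#' @param y 0/1 outcome vector.
#' @param design `"design_matrix"` from [build_design()] or a numeric dummy
#'   matrix.
#' @param weights positive weights (defaults to the design's weights).
#' @param ranks fractional ranks of the socioeconomic score, from
#'   [fractional_rank()], computed on the same records with the same
#'   weights.
#' @param model_kind `"lpm"` (default; exact identity) or `"logit_ame"`.
#' @return object of class `"wagstaff_decomp"`: list with `rows` (data frame
#'   with columns `regressor`, `beta`, `mean`, `ci`, `elasticity`,
#'   `contribution`, `percent`), `explained`, `residual`, `total`, `mu`,
#'   `model_kind`, `n`, and `fit` (the `"coefficient_set"`).
#' @export
wagstaff_decompose <- function(y, design, weights = NULL, ranks,
                               model_kind = c("lpm", "logit_ame")) {
  model_kind <- match.arg(model_kind)
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (is.null(weights))
    weights <- if (inherits(design, "design_matrix")) design$weights
               else rep(1, length(y))
  if (length(y) != length(ranks) || length(y) != length(weights) ||
      length(y) != nrow(X))
    stop("wagstaff_decompose: y, ranks, weights and design must align")
  mu <- sum(weights * y) / sum(weights)
  if (mu <= 0)
    stop("wagstaff_decompose: outcome mean is not positive; ",
         "the index is undefined")

  fit <- switch(model_kind,
                lpm = fit_lpm(y, X, weights),
                logit_ame = fit_logit_ame(y, X, weights))
  X <- fit$X                                   # after constant-column drops
  w <- weights / sum(weights)
  xbar <- colSums(w * X)
  ck <- vapply(seq_len(ncol(X)), function(j)
    2 / xbar[j] * weighted_cov(X[, j], ranks, weights), numeric(1))
  elas <- fit$beta * xbar / mu
  contrib <- elas * ck
  total <- 2 / mu * weighted_cov(y, ranks, weights)
  explained <- sum(contrib)
  residual <- if (fit$model_kind == "lpm")
    generalized_ci(fit$residuals, ranks, weights) / mu
  else
    total - explained
  rows <- data.frame(
    regressor = colnames(X), beta = unname(fit$beta), mean = unname(xbar),
    ci = ck, elasticity = unname(elas), contribution = unname(contrib),
    percent = if (abs(total) > 0) 100 * unname(contrib) / total else NA_real_,
    row.names = NULL)
  structure(
    list(rows = rows, explained = explained, residual = residual,
         total = total, mu = mu, model_kind = fit$model_kind,
         n = length(y), fit = fit, ranks = ranks, weights = weights),
    class = "wagstaff_decomp")
}

#' Percentage contributions of the decomposition rows
#'
#' @param result `"wagstaff_decomp"` object.
#' @param denominator `"total"` (default) or `"explained"`: which index the
#'   percentages are taken over.
#' @return named numeric vector of percentages; attribute `denominator`
#'   records the choice.  A zero denominator yields `NA`s with a warning.
#' @export
percent_contributions <- function(result,
                                  denominator = c("total", "explained")) {
  stopifnot(inherits(result, "wagstaff_decomp"))
  denominator <- match.arg(denominator)
  den <- switch(denominator, total = result$total,
                explained = result$explained)
  pc <- if (abs(den) > 0) 100 * result$rows$contribution / den else {
    warning("percent_contributions: zero ", denominator,
            " index; percentages undefined")
    rep(NA_real_, nrow(result$rows))
  }
  names(pc) <- result$rows$regressor
  attr(pc, "denominator") <- denominator
  pc
}

#' Fit and decompose the concentration index of an outcome
#'
#' The main estimator: given a formula naming a 0/1 outcome and analysis
#' covariates, it builds the dummy design with the conventional reference
#' categories, computes Lerman-Yitzhaki fractional ranks on the wealth
#' score, fits the outcome model, and returns the full Wagstaff-type
#' decomposition.
#'
#' @param formula e.g. `full_anc ~ residence + age_group + birth_order +
#'   education + caste + media_exposure`, or `full_anc ~ .` for all six
#'   covariates.  RHS terms must be analysis covariates.
#' @param data survey data frame (see [load_survey()] /
#'   [generate_population()]).
#' @param weights sampling weights; defaults to the `weight` column.
#' @param score ranking variable; a column name (default `"wealth_score"`)
#'   or a numeric vector.
#' @param model_kind `"lpm"` or `"logit_ame"`.
#' @param ranking_basis `"continuous_score"` or `"quintile_groups"`.
#' @param reference_levels optional overrides, see [build_design()].
#' @return object of class `c("ci_decomp", "wagstaff_decomp")` with the
#'   fields of [wagstaff_decompose()] plus `call`, `outcome` and
#'   `ranking_basis`.
#' @examples
#' tab <- generate_population(scenario_preset("nfhs4_like", n = 2000),
#'                            seed = 1)
#' fit <- ci_decomp(full_anc ~ ., data = tab)
#' fit
#' coef(fit)
#' @export
ci_decomp <- function(formula, data, weights = NULL, score = "wealth_score",
                      model_kind = c("lpm", "logit_ame"),
                      ranking_basis = c("continuous_score",
                                        "quintile_groups"),
                      reference_levels = NULL) {
  model_kind <- match.arg(model_kind)
  ranking_basis <- match.arg(ranking_basis)
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  outcome <- all.vars(formula[[2L]])
  if (!outcome %in% names(data))
    stop("ci_decomp: outcome column not found: ", outcome)
  rhs_vars <- all.vars(formula[[3L]])
  if (identical(rhs_vars, ".")) {
    vars <- names(.covariate_domains)
  } else {
    bad <- setdiff(rhs_vars, names(.covariate_domains))
    if (length(bad))
      stop("ci_decomp: non-covariate term(s) in formula: ",
           paste(bad, collapse = ", "))
    vars <- rhs_vars
  }
  if (is.null(weights)) {
    weights <- if ("weight" %in% names(data)) data$weight
               else rep(1, nrow(data))
  }
  svec <- if (is.character(score)) {
    if (!score %in% names(data))
      stop("ci_decomp: score column not found: ", score)
    data[[score]]
  } else score
  rank_base <- if (ranking_basis == "quintile_groups")
    weighted_quintiles(svec, weights) else svec
  ranks <- fractional_rank(rank_base, weights)
  design <- build_design(data, overrides = reference_levels,
                         weights = weights, variables = vars)
  out <- wagstaff_decompose(data[[outcome]], design, weights, ranks,
                            model_kind)
  out$call <- match.call()
  out$outcome <- outcome
  out$ranking_basis <- ranking_basis
  class(out) <- c("ci_decomp", class(out))
  out
}

#' @export
print.wagstaff_decomp <- function(x, digits = 3, ...) {
  cat("Wagstaff-type decomposition of the concentration index\n")
  if (!is.null(x$outcome))
    cat("  outcome:", x$outcome, " (model:", x$model_kind,
        ", ranking:", if (is.null(x$ranking_basis)) "precomputed"
                      else x$ranking_basis, ")\n")
  else
    cat("  model:", x$model_kind, "\n")
  tab <- x$rows
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("  Explained CI %+ .*f   Residual %+ .*f   Total CI %+ .*f\n",
              digits, x$explained, digits, x$residual, digits, x$total))
  invisible(x)
}

#' @export
summary.wagstaff_decomp <- function(object, ...) {
  s <- object
  s$rows <- s$rows[order(-abs(s$rows$contribution)), ]
  s$identity_gap <- s$total - (s$explained + s$residual)
  class(s) <- c("summary.wagstaff_decomp", class(object))
  s
}

#' @export
print.summary.wagstaff_decomp <- function(x, digits = 3, ...) {
  NextMethod()
  cat(sprintf("  mu = %.4f, n = %d, identity gap = %.2e\n",
              x$mu, x$n, x$identity_gap))
  invisible(x)
}

#' @export
coef.wagstaff_decomp <- function(object, ...) {
  stats::setNames(object$rows$beta, object$rows$regressor)
}

#' @export
residuals.wagstaff_decomp <- function(object, ...) object$fit$residuals

#' @export
fitted.wagstaff_decomp <- function(object, ...) object$fit$fitted

#' @export
plot.wagstaff_decomp <- function(x, denominator = "total", ...) {
  pc <- percent_contributions(x, denominator)
  op <- graphics::par(mar = c(5, 9, 3, 1)); on.exit(graphics::par(op))
  graphics::barplot(rev(pc), horiz = TRUE, las = 1,
                    xlab = sprintf("%% contribution (of %s CI)", denominator),
                    main = if (!is.null(x$outcome))
                      paste("Decomposition:", x$outcome)
                    else "Decomposition", ...)
  invisible(x)
}
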