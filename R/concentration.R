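#' Weighted population covariance
#'
#' Population (divide-by-sum-of-weights, not n-1) form, so the Wagstaff
#' decomposition identity holds exactly.
#' @noRd
weighted_cov <- function(x, y, w) {
  w <- w / sum(w)
  sum(w * (x - sum(w * x)) * (y - sum(w * y)))
}

#' Concentration index of a health variable
#'
#' Computes the concentration index \eqn{C = (2/\mu)\,cov_w(y, R)}, where
#' \eqn{R} is the weighted fractional rank in the distribution of a
#' socioeconomic score and \eqn{\mu} the weighted mean of the outcome.
#' Positive values indicate pro-rich concentration (the outcome accumulates
#' among the better-off), negative values pro-poor; \eqn{C} lies in
#' \eqn{[-1, 1]}, and for a binary outcome \eqn{|C| \le 1 - \mu + 1/n}.
#'
#' Exactly one of `scores` and `ranks` must be supplied.  With `scores` and
#' `ranking_basis = "quintile_groups"` the score is first collapsed to
#' weighted quintiles, each quintile sharing its tied midpoint rank; the
#' default `"continuous_score"` ranks on the score directly.
#'
#' @param y numeric outcome vector (0/1 or nonnegative).
#' @param scores ranking variable (e.g. continuous wealth score).
#' @param ranks precomputed fractional ranks (overrides `scores`).
#' @param weights positive sampling weights.
#' @param ranking_basis `"continuous_score"` or `"quintile_groups"`.
#' @return An object of class `"concindex"`: list with elements `index`,
#'   `mu`, `n`, `curve` (data frame of cumulative population share `p` and
#'   cumulative outcome share `L`), and `ranking_basis`.
#' @examples
#' # single positive case held by the richest of five: C = (n-1)/n = 0.8
#' concentration_index(c(0, 0, 0, 0, 1), scores = 1:5)$index
#' @seealso [ci_from_curve()] for the independent twice-area computation,
#'   [ci_by_group()] for per-stratum indices.
#' @export
concentration_index <- function(y, scores = NULL, ranks = NULL,
                                weights = rep(1, length(y)),
                                ranking_basis = c("continuous_score",
                                                  "quintile_groups")) {
  ranking_basis <- match.arg(ranking_basis)
  if (length(weights) == 1L) weights <- rep(weights, length(y))
  if (is.null(ranks)) {
    if (is.null(scores))
      stop("concentration_index: supply either 'scores' or 'ranks'")
    base <- if (ranking_basis == "quintile_groups")
      weighted_quintiles(scores, weights) else scores
    ranks <- fractional_rank(base, weights)
  }
  stopifnot(length(y) == length(ranks), length(y) == length(weights))
  if (any(weights <= 0)) stop("concentration_index: weights must be positive")
  mu <- sum(weights * y) / sum(weights)
  if (mu <= 0)
    stop("concentration_index: weighted mean of the outcome is not positive; ",
         "the index is undefined")
  idx <- 2 / mu * weighted_cov(y, ranks, weights)
  curve <- if (!is.null(scores))
    concentration_curve(y, scores, weights)
  else
    concentration_curve(y, ranks, weights)
  structure(
    list(index = idx, mu = mu, n = length(y), curve = curve,
         ranking_basis = if (is.null(scores)) "precomputed_ranks"
                         else ranking_basis),
    class = "concindex")
}

#' @export
print.concindex <- function(x, digits = 4, ...) {
  cat("Concentration index\n")
  cat(sprintf("  C = %.*f  (mu = %.*f, n = %d, ranking: %s)\n",
              digits, x$index, digits, x$mu, x$n, x$ranking_basis))
  dir <- if (abs(x$index) < 1e-12) "no socioeconomic gradient"
         else if (x$index > 0) "pro-rich (concentrated among the better-off)"
         else "pro-poor (concentrated among the worse-off)"
  cat("  interpretation:", dir, "\n")
  invisible(x)
}

#' @export
plot.concindex <- function(x, ...) {
  plot(x$curve$p, x$curve$L, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "cumulative population share (poorest to richest)",
       ylab = "cumulative outcome share",
       main = sprintf("Concentration curve (C = %.3f)", x$index), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Concentration curve coordinates
#'
#' Records are sorted by the ranking score (poorest to richest); the curve
#' plots cumulative weighted outcome share against cumulative weighted
#' population share.  Tied scores are merged into a single point.  The curve
#' is anchored at (0, 0) and ends at (1, 1); a curve below the diagonal
#' indicates pro-rich concentration.
#'
#' @inheritParams concentration_index
#' @return data frame with columns `p` (population share) and `L` (outcome
#'   share), first row (0, 0), last row (1, 1).
#' @export
concentration_curve <- function(y, scores, weights = rep(1, length(y))) {
  if (length(weights) == 1L) weights <- rep(weights, length(y))
  stopifnot(length(y) == length(scores), length(y) == length(weights))
  tot_y <- sum(weights * y)
  if (tot_y <= 0)
    stop("concentration_curve: weighted outcome total is not positive; ",
         "the curve is undefined")
  ord <- order(scores)
  w <- weights[ord] / sum(weights)
  wy <- (weights * y)[ord] / tot_y
  ss <- scores[ord]
  ties <- ss[-1L] == ss[-length(ss)]
  if (any(ties)) {
    block <- cumsum(c(TRUE, !ties))
    w <- as.numeric(tapply(w, block, sum))
    wy <- as.numeric(tapply(wy, block, sum))
  }
  p <- cumsum(w); L <- cumsum(wy)
  p[length(p)] <- 1; L[length(L)] <- 1      # guard rounding at the endpoint
  data.frame(p = c(0, p), L = c(0, L))
}

#' Concentration index from curve coordinates (twice-area oracle)
#'
#' Integrates twice the area between the diagonal and a piecewise-linear
#' concentration curve by exact trapezoids:
#' \eqn{C = 2\int_0^1 (p - L(p))\,dp = 1 - 2\int L\,dp}.  Serves as an
#' independent check on the covariance form in [concentration_index()]; the
#' two agree to numerical precision for distinct scores.
#'
#' @param curve data frame with columns `p` and `L` as returned by
#'   [concentration_curve()]; must be anchored at (0,0) and (1,1) with both
#'   coordinates nondecreasing.
#' @return the scalar index.
#' @export
ci_from_curve <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("p", "L") %in% names(curve)))
  p <- curve$p; L <- curve$L
  eps <- 1e-12
  if (abs(p[1]) > eps || abs(L[1]) > eps ||
      abs(p[length(p)] - 1) > eps || abs(L[length(L)] - 1) > eps)
    stop("ci_from_curve: curve must be anchored at (0,0) and (1,1)")
  if (any(diff(p) < -eps) || any(diff(L) < -eps))
    stop("ci_from_curve: curve coordinates must be nondecreasing")
  area_L <- sum(diff(p) * (L[-1] + L[-length(L)]) / 2)
  1 - 2 * area_L
}

#' Concentration indices by group (e.g. state-wise)
#'
#' Recomputes fractional ranks within each group, so each stratum's index
#' reflects its own wealth ranking.  Groups whose record count falls below
#' `min_n` are skipped with a message (small strata yield unstable indices,
#' the convention for state-level survey estimates).
#'
#' @param table survey data frame (see [load_survey()]).
#' @param outcome name of a 0/1 indicator column.
#' @param group name of a categorical grouping column.
#' @param score_col,weight_col ranking score and weight columns.
#' @param min_n minimum records per group (default 250).
#' @param ranking_basis passed to [concentration_index()].
#' @return named list of `"concindex"` objects, one per retained group.
#' @export
ci_by_group <- function(table, outcome, group,
                        score_col = "wealth_score", weight_col = "weight",
                        min_n = 250, ranking_basis = "continuous_score") {
  stopifnot(is.data.frame(table))
  for (col in c(outcome, group, score_col, weight_col))
    if (!col %in% names(table))
      stop("ci_by_group: column not found: ", col)
  levs <- unique(as.character(table[[group]]))
  out <- list()
  for (g in levs) {
    sub <- table[as.character(table[[group]]) == g, , drop = FALSE]
    if (nrow(sub) < min_n) {
      message(sprintf("ci_by_group: skipping group '%s' (n = %d < %d)",
                      g, nrow(sub), min_n))
      next
    }
    out[[g]] <- concentration_index(
      sub[[outcome]], scores = sub[[score_col]], weights = sub[[weight_col]],
      ranking_basis = ranking_basis)
  }
  if (!length(out))
    stop("ci_by_group: no group meets the minimum size threshold (min_n = ",
         min_n, ")")
  out
}
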