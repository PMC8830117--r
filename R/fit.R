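#' Drop constant columns, check rank, return kept column names
#' @noRd
.prune_design <- function(X, weights) {
  keep <- apply(X, 2, function(col) stats::var(col) > 0)
  if (any(!keep))
    message("dropping constant design column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  X <- X[, keep, drop = FALSE]
  qrX <- qr(sqrt(weights) * cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    bad <- setdiff(colnames(X),
                   colnames(X)[qrX$pivot[seq_len(qrX$rank)] - 1L])
    stop("estimation error: collinear design column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Weighted linear probability model
#'
#' Weighted least squares of a 0/1 outcome on the dummy design.  The linear
#' probability model (LPM) is the default engine for the decomposition
#' because it makes the contribution identity exact.  Constant columns are
#' dropped with a message; remaining collinearity is an error naming the
#' offending columns.  Coefficients are invariant to rescaling all weights
#' by a positive constant, and the weighted mean residual is 0.
#'
#' @param y 0/1 outcome vector.
#' @param design `"design_matrix"` from [build_design()], or a plain numeric
#'   matrix of regressors.
#' @param weights positive weights (defaults to the design's weights).
#' @return object of class `"coefficient_set"`: list with `model_kind`
#'   (`"lpm"`), `intercept`, `beta` (named), `fitted`, `residuals`.
#' @export
fit_lpm <- function(y, design, weights = NULL) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (is.null(weights))
    weights <- if (inherits(design, "design_matrix")) design$weights
               else rep(1, length(y))
  stopifnot(length(y) == nrow(X), length(weights) == nrow(X),
            all(weights > 0))
  X <- .prune_design(X, weights)
  fit <- stats::lm.wfit(cbind(`(Intercept)` = 1, X), y, w = weights)
  beta <- fit$coefficients[-1L]
  fitted <- drop(cbind(1, X) %*% fit$coefficients)
  structure(
    list(model_kind = "lpm", intercept = unname(fit$coefficients[1L]),
         beta = beta, fitted = fitted, residuals = y - fitted,
         X = X, weights = weights),
    class = "coefficient_set")
}

#' Weighted logit with finite-difference average marginal effects
#'
#' Fits a weighted maximum-likelihood logistic regression, then computes for
#' each dummy regressor the average marginal effect (AME): the mean over
#' records of the discrete difference in predicted probability when that
#' dummy is switched 0 to 1, holding all other regressors at their observed
#' values.  On a saturated single-dummy design the AME equals the difference
#' in weighted cell proportions.  Perfect separation triggers a warning and
#' a fall-back to [fit_lpm()].
#'
#' @inheritParams fit_lpm
#' @param maxit maximum IRLS iterations.
#' @return object of class `"coefficient_set"` with `model_kind`
#'   `"logit_ame"`; `beta` holds the AMEs, `coefficients_logit` the
#'   log-odds coefficients.
#' @export
fit_logit_ame <- function(y, design, weights = NULL, maxit = 100) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (is.null(weights))
    weights <- if (inherits(design, "design_matrix")) design$weights
               else rep(1, length(y))
  stopifnot(length(y) == nrow(X), length(weights) == nrow(X),
            all(weights > 0))
  X <- .prune_design(X, weights)
  dat <- data.frame(.y = y, X, check.names = FALSE)
  form <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`",
                                                        colnames(X)),
                                                collapse = " + ")))
  # quasibinomial: identical point estimates, accepts non-integer weights
  fit <- suppressWarnings(stats::glm(form, data = dat,
                                     family = stats::quasibinomial(),
                                     weights = weights,
                                     control = list(maxit = maxit)))
  if (!fit$converged)
    stop("estimation error: logit did not converge in ", maxit,
         " iterations")
  eps <- 1e-8
  if (any(fit$fitted.values < eps | fit$fitted.values > 1 - eps) &&
      max(abs(stats::coef(fit)[-1L]), na.rm = TRUE) > 15) {
    warning("possible perfect separation in logit; falling back to the ",
            "linear probability model")
    return(fit_lpm(y, X, weights))
  }
  cf <- stats::coef(fit)
  w <- weights / sum(weights)
  ame <- vapply(colnames(X), function(k) {
    X1 <- X; X1[, k] <- 1
    X0 <- X; X0[, k] <- 0
    p1 <- stats::plogis(drop(cbind(1, X1) %*% cf))
    p0 <- stats::plogis(drop(cbind(1, X0) %*% cf))
    sum(w * (p1 - p0))
  }, numeric(1))
  fitted <- fit$fitted.values
  structure(
    list(model_kind = "logit_ame", intercept = unname(cf[1L]),
         beta = ame, coefficients_logit = cf,
         fitted = fitted, residuals = y - fitted,
         X = X, weights = weights),
    class = "coefficient_set")
}

#' Generalised concentration index
#'
#' The unscaled index \eqn{2\,cov_w(\epsilon, R)}: twice the weighted
#' population covariance between a variable (typically regression residuals)
#' and the fractional rank.  Division by the outcome mean happens in the
#' decomposition, where the residual term is \eqn{GC_\epsilon/\mu}.
#'
#' @param residuals numeric vector.
#' @param ranks fractional ranks from [fractional_rank()].
#' @param weights positive weights.
#' @return scalar generalised concentration index.
#' @export
generalized_ci <- function(residuals, ranks,
                           weights = rep(1, length(residuals))) {
  if (length(weights) == 1L) weights <- rep(weights, length(residuals))
  stopifnot(length(residuals) == length(ranks),
            length(residuals) == length(weights))
  2 * weighted_cov(residuals, ranks, weights)
}
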