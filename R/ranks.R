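#' Weighted fractional ranks (Lerman-Yitzhaki midpoints)
#'
#' Ranks each record in the weighted distribution of a socioeconomic score.
#' With weights normalised to sum to one and records sorted by score, record
#' \eqn{i} receives \eqn{R_i = \sum_{j<i} w_j + w_i/2}, the midpoint of its
#' weight interval in the cumulative distribution.  Tied scores share the
#' weighted midpoint of their tied block, so the result is invariant to the
#' ordering of records within a tie.  The weighted mean of the returned ranks
#' is exactly 1/2.
#'
#' @param scores numeric vector; the ranking variable (e.g. a wealth score).
#' @param weights positive numeric vector of sampling weights, recycled to
#'   `length(scores)` if scalar.
#' @return numeric vector of ranks in `(0, 1)`, in the original record order.
#' @examples
#' fractional_rank(c(10, 20, 30, 40))            # 0.125 0.375 0.625 0.875
#' fractional_rank(c(1, 2, 3), c(1, 1, 2))       # 0.125 0.375 0.750
#' @export
fractional_rank <- function(scores, weights = rep(1, length(scores))) {
  if (length(weights) == 1L) weights <- rep(weights, length(scores))
  stopifnot(length(scores) == length(weights), length(scores) >= 1L)
  if (anyNA(scores) || anyNA(weights))
    stop("fractional_rank: scores and weights must not contain NA")
  if (any(weights <= 0))
    stop("fractional_rank: weights must be strictly positive")
  w <- weights / sum(weights)
  ord <- order(scores)
  ws <- w[ord]
  cum <- cumsum(ws)
  mid <- cum - ws / 2
  # tied blocks share the weighted midpoint of the whole block
  ss <- scores[ord]
  ties <- ss[-1L] == ss[-length(ss)]
  if (any(ties)) {
    block <- cumsum(c(TRUE, !ties))
    lo <- c(0, cum)[match(unique(block), block)]        # cum weight before block
    bw <- tapply(ws, block, sum)
    mid <- (lo + bw / 2)[block]
  }
  r <- numeric(length(scores))
  r[ord] <- mid
  r
}

#' Weighted quintiles of a score
#'
#' Splits records into five groups each holding as close to 20% of the total
#' weight as the tie structure allows, monotone in the score.  A tied block is
#' never split across quintiles.  With fewer than five distinct scores the
#' split is degenerate and a warning is issued; all-identical scores land in
#' quintile 1.
#'
#' @inheritParams fractional_rank
#' @return integer vector of quintile labels 1..5 (1 = poorest).
#' @examples
#' weighted_quintiles(1:10)                     # 1 1 2 2 3 3 4 4 5 5
#' weighted_quintiles(1:5, rep(2, 5))           # 1 2 3 4 5
#' @export
weighted_quintiles <- function(scores, weights = rep(1, length(scores))) {
  if (length(weights) == 1L) weights <- rep(weights, length(scores))
  stopifnot(length(scores) == length(weights), length(scores) >= 1L)
  if (any(weights <= 0))
    stop("weighted_quintiles: weights must be strictly positive")
  if (length(unique(scores)) < 5L)
    warning("weighted_quintiles: fewer than 5 distinct scores; ",
            "quintile split is degenerate")
  w <- weights / sum(weights)
  ord <- order(scores)
  ws <- w[ord]
  cum <- cumsum(ws)
  start <- cum - ws                                    # cum weight before record
  ss <- scores[ord]
  ties <- ss[-1L] == ss[-length(ss)]
  if (any(ties)) {                                     # block start for ties
    block <- cumsum(c(TRUE, !ties))
    lo <- c(0, cum)[match(unique(block), block)]
    start <- lo[block]
  }
  q <- pmin(5L, as.integer(floor(start * 5)) + 1L)
  out <- integer(length(scores))
  out[ord] <- q
  out
}
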