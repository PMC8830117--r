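#' Maternal-care indicator recodes
#'
#' Derive the three binary utilisation indicators from raw survey fields,
#' using the standard DHS-style definitions for the last birth:
#' \describe{
#'   \item{full ANC}{four or more antenatal visits, at least one tetanus
#'     injection, and 100+ IFA tablets/syrup days.}
#'   \item{SBA}{delivery in a medical institution, or at home attended by a
#'     skilled provider (doctor/nurse/LHV/ANM).}
#'   \item{PNC}{maternal check-up at a facility/doctor within 48 hours of
#'     delivery.}
#' }
#' All recodes are vectorised, deterministic and return 0/1 integers.
#'
#' @param anc_visits,tt_injections,ifa_count nonnegative integer vectors.
#' @return integer vector of 0/1 indicators.
#' @examples
#' recode_full_anc(4, 1, 100)   # 1: meets all three criteria exactly
#' recode_full_anc(3, 2, 150)   # 0: too few visits
#' @name recodes
NULL

#' @rdname recodes
#' @export
recode_full_anc <- function(anc_visits, tt_injections, ifa_count) {
  if (any(anc_visits < 0) || any(tt_injections < 0) || any(ifa_count < 0))
    stop("recode_full_anc: counts must be nonnegative")
  as.integer(anc_visits >= 4 & tt_injections >= 1 & ifa_count >= 100)
}

#' @rdname recodes
#' @param institutional_delivery,skilled_attendant_at_home logical vectors.
#' @export
recode_sba <- function(institutional_delivery, skilled_attendant_at_home) {
  if (anyNA(institutional_delivery) || anyNA(skilled_attendant_at_home))
    stop("recode_sba: delivery flags must be defined")
  as.integer(institutional_delivery | skilled_attendant_at_home)
}

#' @rdname recodes
#' @param pnc_within_48h logical vector.
#' @export
recode_pnc <- function(pnc_within_48h) {
  if (anyNA(pnc_within_48h)) stop("recode_pnc: flag must be defined")
  as.integer(pnc_within_48h)
}

#' Poor / non-poor dichotomy from wealth quintiles
#'
#' Quintiles 1-2 (poorest, poorer) are "poor"; 3-5 (middle, richer, richest)
#' are "non-poor".
#'
#' @param wealth_quintile integer vector with values in 1..5.
#' @return factor with levels `c("poor", "non-poor")`.
#' @export
dichotomize_wealth <- function(wealth_quintile) {
  if (any(!wealth_quintile %in% 1:5))
    stop("dichotomize_wealth: quintile must be in 1..5")
  factor(ifelse(wealth_quintile <= 2, "poor", "non-poor"),
         levels = c("poor", "non-poor"))
}

#' Weighted utilisation percentage
#'
#' @param indicator 0/1 vector.
#' @param weights positive weights of the same length.
#' @return percentage `100 * sum(w * y) / sum(w)`.
#' @export
weighted_proportion <- function(indicator, weights = rep(1, length(indicator))) {
  if (length(weights) == 1L) weights <- rep(weights, length(indicator))
  if (!length(indicator)) stop("weighted_proportion: empty input")
  stopifnot(length(indicator) == length(weights))
  if (any(weights <= 0)) stop("weighted_proportion: weights must be positive")
  100 * sum(weights * indicator) / sum(weights)
}
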