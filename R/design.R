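#' Dummy-coded design matrix for the decomposition
#'
#' Expands the six analysis covariates into 0/1 dummies with the
#' conventional reference categories: rural residence, age 15-24, first
#' birth, no education, "Others" caste, no media exposure.  The resulting
#' columns are (in table order): urban; age 25-34, 35-49; birth order 2, 3+;
#' primary/secondary/higher education; SC, ST, OBC; media exposure yes.
#' Weighted column means are recorded for the elasticity computation.
#'
#' @param table survey data frame with valid covariate columns.
#' @param overrides optional named list `variable -> reference level` to
#'   change the omitted category of any covariate.
#' @param weights weights used for the column means (defaults to the table's
#'   `weight` column, equal weights if absent).
#' @param variables which covariates to include (default all six).
#' @return object of class `"design_matrix"`: list with `X` (numeric dummy
#'   matrix, no intercept), `reference_levels`, `means` (weighted), and
#'   `weights`.
#' @export
build_design <- function(table, overrides = NULL, weights = NULL,
                         variables = names(.covariate_domains)) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  variables <- match.arg(variables, names(.covariate_domains),
                         several.ok = TRUE)
  if (is.null(weights))
    weights <- if ("weight" %in% names(table)) table$weight
               else rep(1, nrow(table))
  stopifnot(length(weights) == nrow(table), all(weights > 0))

  refs <- list(residence = "rural", age_group = "15-24", birth_order = "1",
               education = "none", caste = "Others", media_exposure = "no")
  for (v in names(overrides)) {
    if (!v %in% names(.covariate_domains))
      stop("build_design: unknown variable in overrides: ", v)
    if (!overrides[[v]] %in% .covariate_domains[[v]])
      stop("build_design: invalid reference level for ", v, ": ",
           overrides[[v]])
    refs[[v]] <- overrides[[v]]
  }

  cols <- list()
  for (v in variables) {
    vals <- as.character(table[[v]])
    dom <- .covariate_domains[[v]]
    if (any(!vals %in% dom))
      stop("build_design: ", v, " contains level(s) outside its domain: ",
           paste(unique(vals[!vals %in% dom]), collapse = ", "))
    for (lev in setdiff(dom, refs[[v]]))
      cols[[dummy_name(v, lev)]] <- as.numeric(vals == lev)
  }
  X <- do.call(cbind, cols)
  w <- weights / sum(weights)
  structure(
    list(X = X, reference_levels = refs[variables],
         means = colSums(w * X), weights = weights),
    class = "design_matrix")
}

#' Human-readable dummy column names
#' @noRd
dummy_name <- function(variable, level) {
  pretty <- c(residence = "", age_group = "age_", birth_order = "birth_order_",
              education = "edu_", caste = "caste_", media_exposure = "media_")
  lev <- gsub("\\+", "plus", gsub("-", "_", level))
  paste0(pretty[[variable]], lev)
}
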