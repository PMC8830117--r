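#' @noRd
.covariate_domains <- list(
  residence      = c("urban", "rural"),
  age_group      = c("15-24", "25-34", "35-49"),
  birth_order    = c("1", "2", "3+"),
  education      = c("none", "primary", "secondary", "higher"),
  caste          = c("SC", "ST", "OBC", "Others"),
  media_exposure = c("no", "yes")
)

#' @noRd
.canonical_columns <- c(
  "woman_id", "state", "weight", "wealth_score", "wealth_quintile",
  "residence", "age_group", "birth_order", "education", "caste",
  "media_exposure", "anc_visits", "tt_injections", "ifa_count",
  "institutional_delivery", "skilled_attendant_at_home", "pnc_within_48h",
  "months_since_last_birth")

#' Columns required complete for analysis (listwise deletion applies here)
#' @noRd
.analysis_columns <- setdiff(.canonical_columns, "woman_id")

#' Validate a survey table against the data model
#'
#' Checks every row against the domain invariants: positive weight, quintile
#' in 1..5, categorical fields within their stated domains, nonnegative
#' counts, logical delivery/PNC flags.  Returns the table with offending rows
#' dropped; per-row diagnostics are emitted as a warning.
#'
#' @param df data frame with the canonical columns.
#' @return validated data frame (attribute `n_rejected` records the drops).
#' @export
validate_survey <- function(df) {
  missing_cols <- setdiff(.canonical_columns, names(df))
  if (length(missing_cols))
    stop("survey schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))

  # listwise deletion over analysis columns, with a per-column report
  na_counts <- vapply(.analysis_columns, function(cl) sum(is.na(df[[cl]])),
                      integer(1))
  if (any(na_counts > 0)) {
    keep <- stats::complete.cases(df[, .analysis_columns])
    message("listwise deletion: dropped ", sum(!keep), " row(s); ",
            "missing by column: ",
            paste(sprintf("%s=%d", names(na_counts)[na_counts > 0],
                          na_counts[na_counts > 0]), collapse = ", "))
    df <- df[keep, , drop = FALSE]
  }

  bad <- rep(FALSE, nrow(df))
  note <- character(nrow(df))
  flag <- function(cond, why) {
    note[cond & !bad] <<- why
    bad <<- bad | cond
  }
  flag(df$weight <= 0, "nonpositive weight")
  flag(!df$wealth_quintile %in% 1:5, "wealth_quintile outside 1..5")
  for (v in names(.covariate_domains))
    flag(!as.character(df[[v]]) %in% .covariate_domains[[v]],
         paste0(v, " outside domain"))
  flag(df$anc_visits < 0 | df$tt_injections < 0 | df$ifa_count < 0 |
         df$months_since_last_birth < 0, "negative count field")
  for (fl in c("institutional_delivery", "skilled_attendant_at_home",
               "pnc_within_48h"))
    flag(is.na(as.logical(df[[fl]])), paste0("non-boolean ", fl))

  if (any(bad)) {
    warning("rejected ", sum(bad), " row(s): ",
            paste(utils::head(sprintf("row %d (%s)", which(bad),
                                      note[bad]), 10), collapse = "; "),
            if (sum(bad) > 10) " ..." else "")
    df <- df[!bad, , drop = FALSE]
  }
  if (!nrow(df)) stop("survey data error: no valid rows remain")
  for (fl in c("institutional_delivery", "skilled_attendant_at_home",
               "pnc_within_48h"))
    df[[fl]] <- as.logical(df[[fl]])
  attr(df, "n_rejected") <- sum(bad)
  df
}

#' Load woman-level survey microdata from CSV
#'
#' Reads a UTF-8 CSV with a header row, optionally renames source columns to
#' the canonical names through a dictionary, validates every row against the
#' data model ([validate_survey()]), applies listwise deletion over the
#' analysis columns (counts logged), and attaches the derived indicator
#' columns `full_anc`, `sba`, `pnc` and the `poverty` dichotomy.
#'
#' @param path CSV file path.
#' @param dictionary optional column map: named character vector or list
#'   (canonical name -> source column name), or the path to a YAML file with
#'   the same mapping.
#' @param religion optional value; if the file has a `religion` column the
#'   table is restricted to rows matching this value (the pipeline itself is
#'   population-agnostic).
#' @return validated data frame (a `SurveyTable`); attribute `provenance`
#'   holds the file path.
#' @export
load_survey <- function(path, dictionary = NULL, religion = NULL) {
  if (!file.exists(path)) stop("load_survey: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.character(dictionary) && length(dictionary) == 1L &&
      file.exists(dictionary))
    dictionary <- yaml::read_yaml(dictionary)
  if (!is.null(dictionary)) {
    dictionary <- unlist(dictionary)
    missing_src <- setdiff(unname(dictionary), names(df))
    if (length(missing_src))
      stop("survey schema error: dictionary names absent from file: ",
           paste(missing_src, collapse = ", "))
    names(df)[match(unname(dictionary), names(df))] <- names(dictionary)
  }
  if (!is.null(religion) && "religion" %in% names(df))
    df <- df[df$religion == religion, , drop = FALSE]
  df <- validate_survey(df)
  df <- derive_indicators(df)
  attr(df, "provenance") <- path
  df
}

#' Attach derived indicator columns to a validated table
#' @param df validated survey data frame.
#' @return the table with `full_anc`, `sba`, `pnc` (0/1) and `poverty`
#'   (poor / non-poor factor) columns.
#' @export
derive_indicators <- function(df) {
  df$full_anc <- recode_full_anc(df$anc_visits, df$tt_injections,
                                 df$ifa_count)
  df$sba <- recode_sba(df$institutional_delivery,
                       df$skilled_attendant_at_home)
  df$pnc <- recode_pnc(df$pnc_within_48h)
  df$poverty <- dichotomize_wealth(df$wealth_quintile)
  df
}

#' Restrict to births within the eligibility window
#'
#' Keeps records whose last birth occurred strictly less than `window_months`
#' months before the survey (half-open window, the DHS convention for
#' "births in the five years preceding the survey").  Record order is
#' preserved; the result may be empty.
#'
#' @param table survey data frame.
#' @param window_months window length in months (default 60).
#' @return filtered data frame.
#' @export
filter_eligible <- function(table, window_months = 60) {
  stopifnot("months_since_last_birth" %in% names(table))
  table[table$months_since_last_birth < window_months, , drop = FALSE]
}

#' Poor vs non-poor utilisation gap table
#'
#' For each outcome and each level of each stratifier, the weighted
#' utilisation percentage among poor (quintiles 1-2) and non-poor (3-5)
#' women, with unweighted cell counts.  A "Total" row per outcome summarises
#' the whole table.  An empty poor or non-poor cell yields `NA` (never 0,
#' which would be indistinguishable from genuine zero utilisation) and a
#' message.
#'
#' @param table survey data frame with derived indicators (see
#'   [derive_indicators()]).
#' @param outcomes character vector of indicator column names.
#' @param stratifiers character vector of covariate column names (may be
#'   empty for the Total rows only).
#' @return data frame with columns `stratifier`, `level`, `outcome`,
#'   `poor_pct`, `nonpoor_pct`, `n_poor`, `n_nonpoor`.
#' @export
gap_table <- function(table, outcomes = c("full_anc", "sba", "pnc"),
                      stratifiers = character(0)) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  for (col in c(outcomes, stratifiers, "wealth_quintile", "weight"))
    if (!col %in% names(table)) stop("gap_table: column not found: ", col)
  poor <- dichotomize_wealth(table$wealth_quintile) == "poor"
  cell <- function(rows, y) {
    if (!any(rows)) {
      message("gap_table: empty cell; reporting NA")
      return(NA_real_)
    }
    weighted_proportion(table[[y]][rows], table$weight[rows])
  }
  rows <- list()
  for (y in outcomes) {
    for (s in stratifiers) {
      for (lev in unique(as.character(table[[s]]))) {
        in_lev <- as.character(table[[s]]) == lev
        rows[[length(rows) + 1L]] <- data.frame(
          stratifier = s, level = lev, outcome = y,
          poor_pct = cell(in_lev & poor, y),
          nonpoor_pct = cell(in_lev & !poor, y),
          n_poor = sum(in_lev & poor), n_nonpoor = sum(in_lev & !poor))
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      stratifier = "Total", level = "Total", outcome = y,
      poor_pct = cell(poor, y), nonpoor_pct = cell(!poor, y),
      n_poor = sum(poor), n_nonpoor = sum(!poor))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
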