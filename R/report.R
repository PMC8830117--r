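#' Pipeline run configuration
#'
#' Collects every toggle of the full analysis in one validated object.
#' Either `input` (a CSV path, read through [load_survey()]) or `scenario`
#' (a preset name or `"scenario_config"`, passed to
#' [generate_population()]) must be given.
#'
#' @param input CSV path, or `NULL` when using a scenario.
#' @param scenario preset name (`"nfhs3_like"` / `"nfhs4_like"`) or a
#'   `"scenario_config"` object, or `NULL`.
#' @param n sample size when `scenario` is a preset name.
#' @param outcomes indicator columns to analyse.
#' @param stratifiers covariates for the gap table.
#' @param ranking_basis,model_kind,percent_denominator analysis toggles,
#'   see [concentration_index()], [wagstaff_decompose()],
#'   [percent_contributions()].
#' @param group column for grouped indices (default `"state"`).
#' @param min_group_n minimum records per group (default 250).
#' @param window_months eligibility window (default 60).
#' @param dictionary optional column dictionary for [load_survey()].
#' @param seed integer seed used for scenario generation.
#' @return object of class `"run_config"`.
#' @export
run_config <- function(input = NULL, scenario = NULL, n = 20000,
                       outcomes = c("full_anc", "sba", "pnc"),
                       stratifiers = names(.covariate_domains),
                       ranking_basis = c("continuous_score",
                                         "quintile_groups"),
                       model_kind = c("lpm", "logit_ame"),
                       percent_denominator = c("total", "explained"),
                       group = "state", min_group_n = 250,
                       window_months = 60, dictionary = NULL, seed = 1) {
  ranking_basis <- match.arg(ranking_basis)
  model_kind <- match.arg(model_kind)
  percent_denominator <- match.arg(percent_denominator)
  if (is.null(input) && is.null(scenario))
    stop("run config error: supply 'input' or 'scenario'")
  allowed <- c("full_anc", "sba", "pnc")
  if (any(!outcomes %in% allowed))
    stop("run config error: unknown outcome(s): ",
         paste(setdiff(outcomes, allowed), collapse = ", "))
  structure(list(input = input, scenario = scenario, n = n,
                 outcomes = outcomes, stratifiers = stratifiers,
                 ranking_basis = ranking_basis, model_kind = model_kind,
                 percent_denominator = percent_denominator, group = group,
                 min_group_n = min_group_n, window_months = window_months,
                 dictionary = dictionary, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return `"run_config"` object.
#' @export
read_run_config <- function(path) {
  # keep YAML-1.1 boolean-like keys ("n", "y", ...) as literal strings
  keep <- function(x) x
  cfg <- yaml::yaml.load_file(path,
                              handlers = list(`bool#no` = keep,
                                              `bool#yes` = keep))
  do.call(run_config, cfg)
}

#' Run the full inequality analysis
#'
#' Executes the stage chain: load or generate the table, restrict to the
#' eligibility window, derive indicators, build the poor/non-poor gap
#' table, compute the national concentration index per outcome (both
#' ranking bases; both are reported when they differ by more than 0.005),
#' grouped indices, and the Wagstaff-type decomposition per outcome.
#' Identical `(input, config)` yields an identical bundle.
#'
#' @param config `"run_config"` object.
#' @return object of class `"report_bundle"`: list with `table`,
#'   `gap_table`, `ci` (per-outcome `"concindex"`), `ci_alt` (alternative
#'   ranking basis where it differs), `ci_by_group`, `decomposition`
#'   (per-outcome `"ci_decomp"`), `percent` and `metadata`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "load"
  res <- tryCatch({
    tab <- if (!is.null(config$scenario)) {
      sc <- if (inherits(config$scenario, "scenario_config"))
        config$scenario
      else scenario_preset(config$scenario, n = config$n)
      generate_population(sc, seed = config$seed)
    } else {
      load_survey(config$input, dictionary = config$dictionary)
    }
    n_loaded <- nrow(tab)

    stage <- "filter_eligible"
    tab <- filter_eligible(tab, config$window_months)
    if (!nrow(tab)) stop("no eligible records after the window filter")
    n_eligible <- nrow(tab)

    stage <- "gap_table"
    gaps <- gap_table(tab, config$outcomes, config$stratifiers)

    stage <- "concentration_index"
    ci <- list(); ci_alt <- list()
    other <- setdiff(c("continuous_score", "quintile_groups"),
                     config$ranking_basis)
    for (y in config$outcomes) {
      ci[[y]] <- concentration_index(tab[[y]], scores = tab$wealth_score,
                                     weights = tab$weight,
                                     ranking_basis = config$ranking_basis)
      alt <- concentration_index(tab[[y]], scores = tab$wealth_score,
                                 weights = tab$weight,
                                 ranking_basis = other)
      if (abs(alt$index - ci[[y]]$index) > 0.005) ci_alt[[y]] <- alt
    }

    stage <- "ci_by_group"
    by_group <- lapply(config$outcomes, function(y)
      tryCatch(
        ci_by_group(tab, y, config$group, min_n = config$min_group_n,
                    ranking_basis = config$ranking_basis),
        error = function(e) {
          warning("grouped indices unavailable for ", y, ": ",
                  conditionMessage(e), call. = FALSE)
          list()
        }))
    names(by_group) <- config$outcomes

    stage <- "decomposition"
    dec <- lapply(config$outcomes, function(y)
      ci_decomp(stats::as.formula(paste(y, "~ .")), data = tab,
                model_kind = config$model_kind,
                ranking_basis = config$ranking_basis))
    names(dec) <- config$outcomes
    pct <- lapply(dec, percent_contributions,
                  denominator = config$percent_denominator)

    cfg_echo <- unclass(config)
    cfg_echo$scenario <- if (inherits(config$scenario, "scenario_config"))
      config$scenario$name else config$scenario
    meta <- list(
      package_version = as.character(utils::packageVersion("concindex")),
      config = cfg_echo,
      row_counts = list(loaded = n_loaded, eligible = n_eligible),
      ranking_basis = config$ranking_basis,
      model_kind = config$model_kind,
      percent_denominator = config$percent_denominator)
    message(sprintf("run_analysis: %d loaded, %d eligible", n_loaded,
                    n_eligible))
    structure(list(table = tab, gap_table = gaps, ci = ci, ci_alt = ci_alt,
                   ci_by_group = by_group, decomposition = dec,
                   percent = pct, metadata = meta),
              class = "report_bundle")
  }, error = function(e)
    stop("run_analysis [stage: ", stage, "]: ", conditionMessage(e),
         call. = FALSE))
  res
}

#' Write all report artifacts of a bundle
#'
#' Emits `gap_table.csv`, `ci_by_state.csv`, `curves.csv`, one
#' `decomposition_<outcome>.csv` each (with Explained / Total / Residual
#' summary rows), `percent_contributions.csv` and `run_metadata.json`.
#' Before writing, every decomposition is asserted to satisfy the
#' additivity identity (explained + residual = total) to 1e-8.  Numbers are
#' serialised at full precision.
#'
#' @param bundle `"report_bundle"` from [run_analysis()].
#' @param outdir output directory (created if absent).
#' @return data frame manifest (`file`, `md5`), invisibly.
#' @export
write_tables <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  if (file.access(outdir, 2) != 0)
    stop("write_tables: directory not writable: ", outdir)

  for (y in names(bundle$decomposition)) {
    d <- bundle$decomposition[[y]]
    if (abs(d$total - (d$explained + d$residual)) > 1e-8)
      stop("write_tables: additivity identity violated for ", y)
  }

  paths <- character(0)
  wr <- function(df, file) {
    p <- file.path(outdir, file)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(bundle$gap_table, "gap_table.csv")

  st <- do.call(rbind, lapply(names(bundle$ci_by_group), function(y) {
    g <- bundle$ci_by_group[[y]]
    if (!length(g)) return(NULL)
    data.frame(group = names(g), outcome = y,
               n = vapply(g, function(r) r$n, numeric(1)),
               mu = vapply(g, function(r) r$mu, numeric(1)),
               C = vapply(g, function(r) r$index, numeric(1)),
               ranking_basis = vapply(g, function(r) r$ranking_basis,
                                      character(1)))
  }))
  if (is.null(st))
    st <- data.frame(group = character(0), outcome = character(0),
                     n = numeric(0), mu = numeric(0), C = numeric(0),
                     ranking_basis = character(0))
  wr(st, "ci_by_state.csv")

  cv <- do.call(rbind, lapply(names(bundle$ci), function(y)
    cbind(outcome = y, bundle$ci[[y]]$curve)))
  wr(cv, "curves.csv")

  for (y in names(bundle$decomposition)) {
    d <- bundle$decomposition[[y]]
    summary_rows <- data.frame(
      regressor = c("Explained CI", "Total CI", "Residual"),
      beta = NA_real_, mean = NA_real_, ci = NA_real_,
      elasticity = NA_real_,
      contribution = c(d$explained, d$total, d$residual),
      percent = NA_real_)
    wr(rbind(d$rows, summary_rows),
       sprintf("decomposition_%s.csv", y))
  }

  pc <- do.call(rbind, lapply(names(bundle$percent), function(y)
    data.frame(outcome = y, regressor = names(bundle$percent[[y]]),
               percent = as.numeric(bundle$percent[[y]]),
               denominator = attr(bundle$percent[[y]], "denominator"))))
  wr(pc, "percent_contributions.csv")

  meta_path <- file.path(outdir, "run_metadata.json")
  jsonlite::write_json(bundle$metadata, meta_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  paths <- c(paths, meta_path)

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  invisible(manifest)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Report bundle:", x$metadata$row_counts$eligible, "eligible records",
      sprintf("(of %d loaded)\n", x$metadata$row_counts$loaded))
  for (y in names(x$ci))
    cat(sprintf("  %-9s mu = %.3f  C = %+.3f  explained = %+.3f  residual = %+.3f\n",
                y, x$ci[[y]]$mu, x$ci[[y]]$index,
                x$decomposition[[y]]$explained,
                x$decomposition[[y]]$residual))
  invisible(x)
}
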