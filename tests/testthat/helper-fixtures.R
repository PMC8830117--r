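# Build a small, valid canonical survey table in code; any column can be
# overridden by name.  Defaults describe n women with increasing wealth.
make_survey <- function(n = 6, ...) {
  df <- data.frame(
    woman_id = sprintf("W%03d", seq_len(n)),
    state = rep_len(c("UP", "WB"), n),
    weight = rep(1, n),
    wealth_score = seq_len(n),
    wealth_quintile = as.integer(ceiling(5 * seq_len(n) / n)),
    residence = rep_len(c("rural", "urban"), n),
    age_group = rep_len(c("15-24", "25-34", "35-49"), n),
    birth_order = rep_len(c("1", "2", "3+"), n),
    education = rep_len(c("none", "primary", "secondary", "higher"), n),
    caste = rep_len(c("SC", "ST", "OBC", "Others"), n),
    media_exposure = rep_len(c("no", "yes"), n),
    anc_visits = rep_len(c(0L, 4L), n),
    tt_injections = rep_len(c(0L, 2L), n),
    ifa_count = rep_len(c(0L, 120L), n),
    institutional_delivery = rep_len(c(FALSE, TRUE), n),
    skilled_attendant_at_home = rep(FALSE, n),
    pnc_within_48h = rep_len(c(FALSE, TRUE), n),
    months_since_last_birth = rep_len(c(10L, 30L), n),
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

write_survey_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}
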