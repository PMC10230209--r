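# End-to-end orchestration: run the validation and linkage steps from
# file or data-frame input and write machine-readable reports.

validation_report_list <- function(fit) {
  ct <- fit$crosstab
  list(
    algorithm = fit$spec$algorithm,
    hash_fields = fit$spec$fields,
    salted = nzchar(fit$spec$salt),
    convention = fit$convention,
    ci_method = fit$ci_method,
    conf_level = fit$conf_level,
    counts = as.list(fit$counts),
    crosstab = list(a = ct$a, b = ct$b, c = ct$c, d = ct$d, n = ct$n),
    sensitivity = unname(fit$estimates[["sensitivity"]]),
    specificity = unname(fit$estimates[["specificity"]]),
    sensitivity_ci = as.list(fit$ci["sensitivity", ]),
    specificity_ci = as.list(fit$ci["specificity", ]),
    chi_square = fit$chi2$statistic,
    p_value = fit$chi2$p_value,
    auc = fit$auc,
    formatted = list(
      sensitivity = fmt_pct(fit$estimates[["sensitivity"]]),
      specificity = fmt_pct(fit$estimates[["specificity"]]),
      chi_square = fmt_chi2(fit$chi2$statistic),
      p = fmt_p(fit$chi2$p_value),
      auc = fmt_pct(fit$auc)
    )
  )
}

#' Run the step-1 validation end to end and write its reports
#'
#' Reads a roster (CSV path or data frame), runs
#' [validate_roster()], and — when `output_dir` is given — writes
#' `report.json` (the full accuracy report), `crosstab.csv` and
#' `exclusions.csv`, logging per-stage record counts.
#'
#' @param input CSV path or data frame.
#' @param output_dir Directory for report files; created if needed.
#'   `NULL` (default) writes nothing.
#' @param quiet Suppress the per-stage count messages.
#' @param ... Passed to [validate_roster()] (column mapping, pattern,
#'   `strict`, `spec`, `convention`, `conf_level`, `ci_method`).
#' @return The `"uid_validation"` object, invisibly.
#' @export
run_validation <- function(input, output_dir = NULL, quiet = FALSE, ...) {
  fit <- validate_roster(input, ...)
  if (!quiet) {
    message("records in: ", fit$counts[["n_input"]],
            "; clean: ", fit$counts[["n_clean"]],
            "; excluded: ", fit$counts[["n_excluded"]])
    message("gold primaries: ", fit$counts[["gold_primaries"]],
            "; hash primaries: ", fit$counts[["hash_primaries"]])
  }
  if (anyNA(fit$estimates) && !quiet) {
    message("warning: accuracy statistics undefined (empty margin)")
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(validation_report_list(fit),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ct <- fit$crosstab
    utils::write.csv(
      data.frame(cell = c("a", "b", "c", "d"),
                 gold = c("primary", "duplicate", "primary", "duplicate"),
                 hash = c("primary", "primary", "duplicate", "duplicate"),
                 count = c(ct$a, ct$b, ct$c, ct$d)),
      file.path(output_dir, "crosstab.csv"), row.names = FALSE)
    utils::write.csv(fit$cleaning$exclusions,
                     file.path(output_dir, "exclusions.csv"),
                     row.names = FALSE)
  }
  invisible(fit)
}

#' Run the step-2 linkage end to end and write its report
#'
#' Validates (cleans and hashes) both rosters, links them one-to-one on
#' the anonymous identifier, and — when `output_dir` is given — writes
#' `linkage.json`.
#'
#' @param left,right CSV paths or data frames.
#' @param output_dir Directory for the report file, or `NULL`.
#' @param strict,keep_uids Passed to [link_rosters()].
#' @param quiet Suppress count messages.
#' @param ... Passed to [validate_roster()] for both sides.
#' @return The `"uid_linkage"` object, invisibly.
#' @export
run_linkage <- function(left, right, output_dir = NULL, strict = FALSE,
                        keep_uids = FALSE, quiet = FALSE, ...) {
  fl <- validate_roster(left, ...)
  fr <- validate_roster(right, ...)
  lk <- link_rosters(fl, fr, convention = fl$convention,
                     strict = strict, keep_uids = keep_uids)
  if (!quiet) {
    message("left: ", fl$counts[["n_clean"]], " clean records, ",
            lk$left_primaries, " distinct uids")
    message("right: ", fr$counts[["n_clean"]], " clean records, ",
            lk$right_primaries, " distinct uids")
    message("matched: ", lk$matched)
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- list(matched = lk$matched, left_only = lk$left_only,
                right_only = lk$right_only,
                left_primaries = lk$left_primaries,
                right_primaries = lk$right_primaries,
                left_collapsed = lk$left_collapsed,
                right_collapsed = lk$right_collapsed,
                convention = lk$convention)
    if (keep_uids) out$matched_uids <- lk$matched_uids
    jsonlite::write_json(out, file.path(output_dir, "linkage.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(lk)
}
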