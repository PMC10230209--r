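# The main validation entry point: clean -> hash -> flag -> cross-tabulate
# -> accuracy statistics, returned as a classed object with methods.

#' Validate the hash identifier against the gold-standard key
#'
#' Runs the full step-1 procedure on a roster: cleans the key fields,
#' assigns SHA-256 unique identifiers, flags primary/duplicate cases under
#' both the gold-standard key (service number alone) and the hash
#' identifier, cross-tabulates the two labelings, and computes
#' sensitivity, specificity, exact binomial confidence intervals, the
#' uncorrected Pearson chi-square and the single-threshold ROC AUC.
#'
#' Because the hash input contains the gold key, the hash grouping
#' partitions each gold group into one or more subgroups; a gold-primary
#' record is therefore always hash-primary, cell `c` of the
#' cross-tabulation is zero and sensitivity is structurally 100%.
#' Specificity falls below 100% exactly when distinct individuals share a
#' service number but differ in gender — the collisions the two-field
#' identifier resolves.
#'
#' @param x Roster data frame or CSV path (see [clean_roster()]).
#' @param gender_col,service_col,pattern,strict Passed to [clean_roster()].
#' @param spec A [hash_spec()]; its fields must include `service_col`'s
#'   clean name (`"service_number"`) for the refinement guarantee.
#' @param convention Primary-case convention, `"first"` or `"last"`; the
#'   cross-tabulated counts are identical under either.
#' @param conf_level Confidence level for the binomial intervals.
#' @param ci_method `"clopper-pearson"` (default) or `"wilson"`.
#' @return Object of class `"uid_validation"`: list with `crosstab`
#'   (a `"crosstab2x2"`), `estimates` (sensitivity, specificity),
#'   `ci` (2x2 matrix of bounds), `chi2`, `auc`, `counts` (records in,
#'   cleaned, excluded, gold/hash primaries), `cleaning` (the
#'   `"roster_clean"` audit), `records` (hashed records), and the
#'   configuration used.
#' @examples
#' sim <- simulate_roster(roster_config(n_persons = 60, n_records = 90,
#'                                      collision_pairs = 3, seed = 1))
#' fit <- validate_roster(sim$roster)
#' fit
#' coef(fit)
#' confint(fit)
#' @export
validate_roster <- function(x, gender_col = "gender",
                            service_col = "service_number",
                            pattern = sn_patterns[["any"]], strict = FALSE,
                            spec = hash_spec(),
                            convention = c("first", "last"),
                            conf_level = 0.95,
                            ci_method = c("clopper-pearson", "wilson")) {
  convention <- match.arg(convention)
  ci_method <- match.arg(ci_method)
  cleaning <- clean_roster(x, gender_col = gender_col,
                           service_col = service_col,
                           pattern = pattern, strict = strict)
  hashed <- hash_roster(cleaning, spec = spec)
  gold <- flag_primaries(hashed$service_number, convention)
  hash <- flag_primaries(hashed$uid, convention)
  ct <- cross_tabulate(gold, hash)
  est <- sensitivity_specificity(ct)
  ci <- rbind(
    sensitivity = if (is.na(est[["sensitivity"]])) c(lower = NA_real_, upper = NA_real_)
                  else binom_ci(ct$a, ct$a + ct$c, conf_level, ci_method),
    specificity = if (is.na(est[["specificity"]])) c(lower = NA_real_, upper = NA_real_)
                  else binom_ci(ct$d, ct$b + ct$d, conf_level, ci_method)
  )
  chi2 <- pearson_chi2(ct)
  auc <- if (anyNA(est)) NA_real_ else binary_roc_auc(est[["sensitivity"]], est[["specificity"]])
  out <- list(
    crosstab = ct,
    estimates = est,
    ci = ci,
    chi2 = chi2,
    auc = auc,
    counts = c(n_input = cleaning$n_input,
               n_clean = nrow(cleaning$clean),
               n_excluded = nrow(cleaning$exclusions),
               gold_primaries = ct$a + ct$c,
               hash_primaries = ct$a + ct$b),
    cleaning = cleaning,
    records = hashed,
    spec = spec,
    convention = convention,
    conf_level = conf_level,
    ci_method = ci_method
  )
  class(out) <- "uid_validation"
  out
}

# round-half-up at d decimals (the print convention of the source tables;
# base round() ties to even)
round_half_up <- function(x, d = 0L) {
  s <- sign(x)
  s * floor(abs(x) * 10^d + 0.5) / 10^d
}

fmt_pct <- function(p, d = 1L) {
  if (is.na(p)) return("undefined")
  v <- round_half_up(100 * p, d)
  if (v == round(v)) sprintf("%d%%", as.integer(round(v))) else
    sprintf(paste0("%.", d, "f%%"), v)
}

fmt_chi2 <- function(x) if (is.na(x)) "undefined" else sprintf("%.3f", round_half_up(x, 3L))

fmt_p <- function(p) {
  if (is.na(p)) "undefined"
  else if (p < 0.001) "p < 0.001"
  else sprintf("p = %.3f", p)
}

#' @export
print.uid_validation <- function(x, ...) {
  ct <- x$crosstab
  cat("Hash-identifier validation against gold-standard key\n")
  cat("  records: ", x$counts[["n_input"]], " in, ",
      x$counts[["n_clean"]], " clean (",
      x$counts[["n_excluded"]], " excluded)\n", sep = "")
  cat("  primaries: ", x$counts[["gold_primaries"]], " gold, ",
      x$counts[["hash_primaries"]], " hash (", x$convention,
      "-occurrence convention)\n", sep = "")
  cat("  sensitivity ", fmt_pct(x$estimates[["sensitivity"]]),
      " (", round(100 * x$conf_level), "% CI ",
      fmt_pct(x$ci["sensitivity", "lower"]), "-",
      fmt_pct(x$ci["sensitivity", "upper"]), ")\n", sep = "")
  cat("  specificity ", fmt_pct(x$estimates[["specificity"]]),
      " (", round(100 * x$conf_level), "% CI ",
      fmt_pct(x$ci["specificity", "lower"]), "-",
      fmt_pct(x$ci["specificity", "upper"]), ")\n", sep = "")
  cat("  chi-square ", fmt_chi2(x$chi2$statistic), ", ",
      fmt_p(x$chi2$p_value), "\n", sep = "")
  cat("  AUC [(sens + spec)/2] ", fmt_pct(x$auc), "\n", sep = "")
  invisible(x)
}

#' @export
summary.uid_validation <- function(object, ...) {
  print(object)
  cat("\nCross-tabulation (", object$spec$algorithm, " identifier vs gold key):\n",
      sep = "")
  print(object$crosstab)
  if (nrow(object$cleaning$exclusions) > 0L) {
    cat("\nExclusion reasons:\n")
    print(table(object$cleaning$exclusions$reason))
  }
  invisible(object)
}

#' @export
coef.uid_validation <- function(object, ...) object$estimates

#' @export
confint.uid_validation <- function(object, parm, level, ...) object$ci

#' Plot the single-threshold ROC curve of a validation
#'
#' Draws the polyline (0,0) -> (1 - specificity, sensitivity) -> (1,1)
#' with the chance diagonal and the AUC in the legend.
#'
#' @param x A `"uid_validation"`.
#' @param ... Passed to [plot()].
#' @export
plot.uid_validation <- function(x, ...) {
  sens <- x$estimates[["sensitivity"]]
  spec <- x$estimates[["specificity"]]
  if (is.na(sens) || is.na(spec)) stop("statistics undefined; nothing to plot", call. = FALSE)
  plot(c(0, 1 - spec, 1), c(0, sens, 1), type = "l", lwd = 2,
       xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "sensitivity",
       main = "ROC of hash identifier vs gold standard", ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = (sens + spec)/2 = %s", fmt_pct(x$auc, 2L)))
  invisible(x)
}
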