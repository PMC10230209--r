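# Step-1 validation: cross-tabulation of gold-standard vs hash
# primary/duplicate status and the derived accuracy statistics.

#' Construct a 2x2 primary/duplicate cross-tabulation
#'
#' Cells follow the diagnostic-accuracy layout with the gold-standard
#' primary case as the positive class:
#' \describe{
#'   \item{a}{gold-primary and hash-primary (true positive)}
#'   \item{b}{gold-duplicate and hash-primary (false positive)}
#'   \item{c}{gold-primary and hash-duplicate (false negative)}
#'   \item{d}{gold-duplicate and hash-duplicate (true negative)}
#' }
#' When the hash input fields contain the gold key field, the hash
#' grouping refines (splits, never merges) the gold grouping, so cell `c`
#' is structurally zero and sensitivity is structurally 100%.
#'
#' @param gold_status,hash_status Character vectors of
#'   `"primary"`/`"duplicate"` from [flag_primaries()], covering the same
#'   records in the same order; or pass counts directly via `a`,`b`,`c`,`d`.
#' @param a,b,c,d Cell counts, as an alternative to label vectors.
#' @return Object of class `"crosstab2x2"`: list with `a`,`b`,`c`,`d`,`n`.
#' @examples
#' cross_tabulate(a = 2296, b = 10, c = 0, d = 316)
#' cross_tabulate(c("primary", "primary", "duplicate"),
#'                c("primary", "primary", "duplicate"))
#' @export
cross_tabulate <- function(gold_status = NULL, hash_status = NULL,
                           a = NULL, b = NULL, c = NULL, d = NULL) {
  if (is.null(gold_status)) {
    stopifnot(!is.null(a), !is.null(b), !is.null(c), !is.null(d))
    cells <- as.numeric(c(a, b, c, d))
    if (any(cells < 0) || anyNA(cells)) stop("cell counts must be >= 0", call. = FALSE)
    out <- list(a = cells[1L], b = cells[2L], c = cells[3L], d = cells[4L])
  } else {
    if (length(gold_status) != length(hash_status)) {
      stop("gold and hash label vectors must cover the same records", call. = FALSE)
    }
    ok <- c("primary", "duplicate")
    stopifnot(all(gold_status %in% ok), all(hash_status %in% ok))
    gp <- gold_status == "primary"
    hp <- hash_status == "primary"
    out <- list(a = sum(gp & hp), b = sum(!gp & hp),
                c = sum(gp & !hp), d = sum(!gp & !hp))
  }
  out$n <- out$a + out$b + out$c + out$d
  class(out) <- "crosstab2x2"
  out
}

#' @export
print.crosstab2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$a + x$b, x$c, x$d, x$c + x$d,
                x$a + x$c, x$b + x$d, x$n),
              nrow = 3, byrow = TRUE,
              dimnames = list(
                c("hash primary", "hash duplicate", "total"),
                c("gold primary", "gold duplicate", "total")))
  print(m)
  invisible(x)
}

#' Sensitivity and specificity from a 2x2 cross-tabulation
#'
#' Sensitivity `a/(a+c)` is the proportion of gold-standard primary
#' (unique) records the hash identifier also classifies primary;
#' specificity `d/(b+d)` is the proportion of gold-standard duplicates it
#' also classifies duplicate. An empty margin yields `NA`, flagged rather
#' than silently zero. No rounding: formatting happens only at report
#' rendering.
#'
#' @param ct A `"crosstab2x2"`.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @examples
#' sensitivity_specificity(cross_tabulate(a = 2296, b = 10, c = 0, d = 316))
#' @export
sensitivity_specificity <- function(ct) {
  stopifnot(inherits(ct, "crosstab2x2"))
  sens <- if (ct$a + ct$c > 0) ct$a / (ct$a + ct$c) else NA_real_
  spec <- if (ct$b + ct$d > 0) ct$d / (ct$b + ct$d) else NA_real_
  c(sensitivity = sens, specificity = spec)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Inverts the binomial tails: the lower bound solves
#' `P(X >= x | p) = alpha/2` and the upper bound `P(X <= x | p) = alpha/2`,
#' computed through the beta-quantile closed form. Boundaries follow the
#' closed forms `x = n => (alpha/2)^(1/n), 1)` and `x = 0 => (0,
#' 1 - (alpha/2)^(1/n))`. A Wilson score interval is available for
#' comparison; the exact interval is the default because it reproduces
#' published bounds that Wilson does not.
#'
#' @param x Number of successes, `0 <= x <= n`.
#' @param n Number of trials, `> 0` (`n = 0` returns `NA` bounds).
#' @param conf_level Confidence level, default 0.95.
#' @param method `"clopper-pearson"` (default) or `"wilson"`.
#' @return Named numeric vector `c(lower, upper)` of proportions.
#' @examples
#' binom_ci(2296, 2296)   # lower bound 0.998 to 3 dp
#' binom_ci(316, 326)     # (0.944, 0.985) to 3 dp
#' @export
binom_ci <- function(x, n, conf_level = 0.95,
                     method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  stopifnot(length(x) == 1L, length(n) == 1L, conf_level > 0, conf_level < 1)
  if (n == 0L) return(c(lower = NA_real_, upper = NA_real_))
  stopifnot(x >= 0, x <= n)
  alpha <- 1 - conf_level
  if (method == "clopper-pearson") {
    lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
    upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    p <- x / n
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lower <- max(0, centre - half)
    upper <- min(1, centre + half)
  }
  c(lower = lower, upper = upper)
}

#' Pearson chi-square for a 2x2 cross-tabulation
#'
#' The uncorrected statistic
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with the p-value from the
#' chi-square distribution on 1 degree of freedom. No Yates continuity
#' correction. Any zero margin leaves the statistic undefined (`NA`).
#'
#' @param ct A `"crosstab2x2"`.
#' @return List with `statistic`, `p_value`, `df = 1`.
#' @examples
#' pearson_chi2(cross_tabulate(a = 2296, b = 10, c = 0, d = 316))$statistic
#' @export
pearson_chi2 <- function(ct) {
  stopifnot(inherits(ct, "crosstab2x2"))
  margins <- c(ct$a + ct$b, ct$c + ct$d, ct$a + ct$c, ct$b + ct$d)
  if (ct$n == 0 || any(margins == 0)) {
    return(list(statistic = NA_real_, p_value = NA_real_, df = 1L))
  }
  stat <- ct$n * (ct$a * ct$d - ct$b * ct$c)^2 / prod(margins)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       df = 1L)
}

#' Area under the single-threshold ROC curve
#'
#' A single-threshold binary classifier traces the ROC polyline (0,0) ->
#' (1 - specificity, sensitivity) -> (1,1); its trapezoidal area is
#' algebraically `(sensitivity + specificity) / 2`, which is what this
#' returns and how reports label it.
#'
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @return AUC in `[0, 1]`.
#' @examples
#' binary_roc_auc(1, 0.969)
#' @export
binary_roc_auc <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  (sensitivity + specificity) / 2
}
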