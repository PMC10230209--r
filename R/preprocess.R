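# Data preparation: gender recoding, service-number canonicalization, and
# listwise deletion of records missing either key field, with an audit trail.

#' Named service-number validation presets
#'
#' Anchored regular expressions applied to the canonicalized (uppercased,
#' whitespace-stripped) service number. The `"any"` preset accepts any
#' non-empty run of letters and digits and is the package default; the real
#' per-service formats are not public, so the stricter presets are
#' plausible shapes, not authoritative ones.
#'
#' @format Named character vector of anchored regular expressions.
#' @export
sn_patterns <- c(
  any                  = "^[A-Z0-9]+$",
  two_letter_six_digit = "^[A-Z]{2}[0-9]{6}$",
  eight_digit          = "^[0-9]{8}$"
)

#' Normalize free-text gender to the codes M / F
#'
#' Trims surrounding whitespace and case-folds, then maps `M`/`MALE` to
#' `"M"` and `F`/`FEMALE` to `"F"`. Anything else is flagged invalid;
#' absent or blank input is flagged missing. Never errors: failures are
#' returned as `NA` codes with a parallel reason vector in the
#' `"reason"` attribute (`NA` where normalization succeeded).
#'
#' @param x Character vector (or anything coercible); `NA` allowed.
#' @return Character vector of `"M"`/`"F"`/`NA` with attribute `"reason"`
#'   containing `NA`, `"missing_gender"` or `"invalid_gender"` per element.
#' @examples
#' normalize_gender(c("M", " female ", "unknown", NA))
#' @export
normalize_gender <- function(x) {
  x <- as.character(x)
  folded <- toupper(trimws(x))
  code <- rep(NA_character_, length(x))
  reason <- rep(NA_character_, length(x))
  missing <- is.na(x) | folded == ""
  reason[missing] <- "missing_gender"
  male <- !missing & folded %in% c("M", "MALE")
  female <- !missing & folded %in% c("F", "FEMALE")
  code[male] <- "M"
  code[female] <- "F"
  invalid <- !missing & !male & !female
  reason[invalid] <- "invalid_gender"
  structure(code, reason = reason)
}

#' Canonicalize and validate service numbers
#'
#' Trims, uppercases and removes all internal whitespace, then validates
#' the result against an anchored pattern. Pattern mismatches are flagged,
#' not dropped here: [clean_roster()] decides (via `strict`) whether a
#' flagged record is excluded or only warned about.
#'
#' @param x Character vector of raw service numbers; `NA` allowed.
#' @param pattern Anchored regular expression the canonical value must
#'   match. See [sn_patterns] for presets. A malformed pattern errors
#'   immediately.
#' @return Character vector of canonical values (`NA` where missing) with
#'   attribute `"reason"` containing `NA`, `"missing_service_number"` or
#'   `"invalid_service_number_format"` per element. Invalid-format entries
#'   keep their canonicalized value so non-strict cleaning can retain them.
#' @examples
#' normalize_service_number(" ab 123456 ", sn_patterns[["two_letter_six_digit"]])
#' @export
normalize_service_number <- function(x, pattern = sn_patterns[["any"]]) {
  check_pattern(pattern)
  x <- as.character(x)
  canon <- toupper(gsub("[[:space:]]+", "", trimws(x)))
  reason <- rep(NA_character_, length(x))
  missing <- is.na(x) | canon == ""
  canon[missing] <- NA_character_
  reason[missing] <- "missing_service_number"
  ok <- !missing & grepl(pattern, canon)
  reason[!missing & !ok] <- "invalid_service_number_format"
  structure(canon, reason = reason)
}

check_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern)) {
    stop("`pattern` must be a single regular expression string", call. = FALSE)
  }
  tryCatch(suppressWarnings(grepl(pattern, "")), error = function(e) {
    stop("malformed service-number pattern: ", conditionMessage(e), call. = FALSE)
  })
  invisible(pattern)
}

#' Clean a roster: normalize key fields and delete records missing either
#'
#' Applies [normalize_gender()] and [normalize_service_number()] to every
#' row and excludes records per the preparation rules: a record missing
#' either key field is always deleted; a record whose fields are present
#' but unrecognized (gender outside M/F, service number failing the format
#' pattern) is deleted only when `strict = TRUE`, otherwise retained with a
#' warning count. Each excluded record carries exactly one reason — the
#' first failing rule, gender checked before service number — so the audit
#' trail partitions the input: `nrow(clean) + nrow(exclusions) == nrow(x)`.
#' Surviving records keep their input order, which downstream
#' primary-case flagging relies on.
#'
#' @param x Data frame, one row per service contact, or a path to a CSV
#'   file with a header row.
#' @param gender_col,service_col Names of the gender and service-number
#'   columns in `x`.
#' @param pattern Anchored service-number pattern; see [sn_patterns].
#' @param strict If `TRUE`, invalid (as opposed to missing) values also
#'   exclude the record; default `FALSE` retains them after
#'   canonicalization.
#' @return An object of class `"roster_clean"`: a list with `clean`
#'   (data frame: `record_index`, `gender`, `service_number`),
#'   `exclusions` (data frame: `record_index`, `reason`), `n_input`,
#'   `pattern`, `strict`. `record_index` is the 1-based input row number.
#' @examples
#' x <- data.frame(gender = c("M", "female", NA, "M"),
#'                 service_number = c("AB123456", " cd 654321", "EF111111", ""))
#' clean_roster(x)
#' @export
clean_roster <- function(x, gender_col = "gender", service_col = "service_number",
                         pattern = sn_patterns[["any"]], strict = FALSE) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x))
  for (col in c(gender_col, service_col)) {
    if (!col %in% names(x)) {
      stop("column '", col, "' not found in roster", call. = FALSE)
    }
  }
  n <- nrow(x)
  g <- normalize_gender(x[[gender_col]])
  s <- normalize_service_number(x[[service_col]], pattern)
  g_reason <- attr(g, "reason")
  s_reason <- attr(s, "reason")

  # first-failing-rule wins: gender before service number
  reason <- rep(NA_character_, n)
  take <- function(r) !is.na(r) & is.na(reason)
  sel <- take(ifelse(g_reason == "missing_gender", g_reason, NA)); reason[sel] <- "missing_gender"
  sel <- take(ifelse(s_reason == "missing_service_number", s_reason, NA)); reason[sel] <- "missing_service_number"
  if (strict) {
    sel <- take(ifelse(g_reason == "invalid_gender", g_reason, NA)); reason[sel] <- "invalid_gender"
    sel <- take(ifelse(s_reason == "invalid_service_number_format", s_reason, NA))
    reason[sel] <- "invalid_service_number_format"
  } else {
    n_warn <- sum(is.na(reason) &
                    (!is.na(g_reason) | !is.na(s_reason)), na.rm = TRUE)
    if (n_warn > 0L) {
      warning(n_warn, " record(s) with invalid key values retained; ",
              "set strict = TRUE to exclude them", call. = FALSE)
    }
  }

  keep <- is.na(reason)
  out <- list(
    clean = data.frame(
      record_index = seq_len(n)[keep],
      gender = as.character(g)[keep],
      service_number = as.character(s)[keep],
      stringsAsFactors = FALSE
    ),
    exclusions = data.frame(
      record_index = seq_len(n)[!keep],
      reason = reason[!keep],
      stringsAsFactors = FALSE
    ),
    n_input = n,
    pattern = pattern,
    strict = strict
  )
  class(out) <- "roster_clean"
  out
}

#' @export
print.roster_clean <- function(x, ...) {
  cat("Cleaned roster: ", nrow(x$clean), " of ", x$n_input,
      " records retained\n", sep = "")
  if (nrow(x$exclusions) > 0L) {
    tab <- table(x$exclusions$reason)
    cat("Exclusions:\n")
    for (r in names(tab)) cat("  ", r, ": ", tab[[r]], "\n", sep = "")
  } else {
    cat("Exclusions: none\n")
  }
  invisible(x)
}
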