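# Primary/duplicate case flagging under a key.

#' Flag primary and duplicate cases under a key
#'
#' The first record (in input order) holding each key value is the
#' primary case; every later holder is a duplicate. The `"last"`
#' convention is symmetric (the final holder is primary). The number of
#' primaries always equals the number of distinct key values, whichever
#' convention is used, so cross-tabulated counts downstream are
#' convention-invariant.
#'
#' @param keys Vector of key values (gold-standard service numbers or
#'   hash uids), in record order.
#' @param convention `"first"` (default) or `"last"`.
#' @return Character vector of `"primary"`/`"duplicate"`, same length as
#'   `keys`.
#' @examples
#' flag_primaries(c("X", "X", "Y"))
#' flag_primaries(c("X", "X", "Y"), convention = "last")
#' @export
flag_primaries <- function(keys, convention = c("first", "last")) {
  convention <- match.arg(convention)
  if (length(keys) == 0L) return(character(0L))
  if (anyNA(keys)) stop("keys must not contain missing values", call. = FALSE)
  dup <- duplicated(keys, fromLast = identical(convention, "last"))
  ifelse(dup, "duplicate", "primary")
}

#' Record and distinct-key counts for a roster key
#'
#' @param keys Vector of key values.
#' @return Named integer vector `c(n_records, n_distinct_keys)`;
#'   `n_distinct_keys` equals the primary-case count from
#'   [flag_primaries()].
#' @examples
#' group_counts(c("X", "X", "Y"))
#' @export
group_counts <- function(keys) {
  c(n_records = length(keys),
    n_distinct_keys = length(unique(keys)))
}
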