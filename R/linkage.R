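# Step-2 linkage: one-to-one matching of deduplicated rosters on the
# anonymous identifier.

#' One-to-one linkage of two hashed rosters
#'
#' Each side is first reduced to one record per uid (the primary-case
#' convention of [flag_primaries()]); the match count is the size of the
#' uid-set intersection. Duplicates therefore never inflate the match
#' count: repeating a record on either side changes nothing. With
#' `strict = TRUE` the reduction is skipped and duplicate uids on either
#' side are an error, mimicking a hard one-to-one merge.
#'
#' @param left,right Data frames with a `uid` column (from
#'   [hash_roster()]), or `"uid_validation"` objects.
#' @param convention Primary-case convention used to collapse duplicates.
#' @param strict Error on duplicate uids instead of collapsing them.
#' @param keep_uids Include the matched uid list in the result.
#' @return Object of class `"uid_linkage"`: list with `matched`,
#'   `left_only`, `right_only`, per-side primary and collapsed-duplicate
#'   counts, and (optionally) `matched_uids`.
#' @examples
#' a <- data.frame(uid = c("u1", "u1", "u2"))
#' b <- data.frame(uid = c("u2", "u3"))
#' link_rosters(a, b)
#' @export
link_rosters <- function(left, right, convention = c("first", "last"),
                         strict = FALSE, keep_uids = FALSE) {
  convention <- match.arg(convention)
  uid_of <- function(x, side) {
    if (inherits(x, "uid_validation")) x <- x$records
    stopifnot(is.data.frame(x))
    if (!"uid" %in% names(x)) {
      stop(side, " roster has no 'uid' column; run hash_roster() first",
           call. = FALSE)
    }
    x$uid
  }
  lu <- uid_of(left, "left")
  ru <- uid_of(right, "right")
  if (strict && (anyDuplicated(lu) || anyDuplicated(ru))) {
    stop("duplicate uids present under strict one-to-one linkage; ",
         "deduplicate first or set strict = FALSE", call. = FALSE)
  }
  lp <- lu[flag_primaries(lu, convention) == "primary"]
  rp <- ru[flag_primaries(ru, convention) == "primary"]
  shared <- intersect(lp, rp)
  out <- list(
    matched = length(shared),
    left_only = length(lp) - length(shared),
    right_only = length(rp) - length(shared),
    left_primaries = length(lp),
    right_primaries = length(rp),
    left_collapsed = length(lu) - length(lp),
    right_collapsed = length(ru) - length(rp),
    convention = convention
  )
  if (keep_uids) out$matched_uids <- shared
  class(out) <- "uid_linkage"
  out
}

#' @export
print.uid_linkage <- function(x, ...) {
  cat("One-to-one linkage on anonymous identifier\n")
  cat("  left:  ", x$left_primaries, " distinct uids (",
      x$left_collapsed, " duplicate records collapsed)\n", sep = "")
  cat("  right: ", x$right_primaries, " distinct uids (",
      x$right_collapsed, " duplicate records collapsed)\n", sep = "")
  cat("  matched: ", x$matched, "  left-only: ", x$left_only,
      "  right-only: ", x$right_only, "\n", sep = "")
  invisible(x)
}
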