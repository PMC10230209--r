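# Anonymous unique identifiers: canonical hash input construction and
# SHA-256 digests over the configured key fields.

#' Specify how the anonymous identifier is built
#'
#' The identifier is the SHA-256 digest of a delimiter-joined canonical
#' string: the salt (when non-empty), then each key field value in
#' `fields` order. Delimiter-joining rather than bare concatenation keeps
#' inputs like ("M", "1A") and ("M1", "A") distinct. The salt is a secret
#' prefix: unsalted digests of a small identifier space can be reversed by
#' enumeration, so real deployments must set one; the default is empty so
#' worked examples are reproducible.
#'
#' @param fields Ordered, duplicate-free character vector of clean-record
#'   field names to hash. Default `c("gender", "service_number")`.
#' @param delimiter Single separator string; must not occur inside any
#'   field value (checked at hash time).
#' @param salt Optional secret string, default `""` (unsalted).
#' @return Object of class `"hash_spec"`.
#' @examples
#' hash_spec()
#' hash_spec(salt = "s3cret")
#' @export
hash_spec <- function(fields = c("gender", "service_number"),
                      delimiter = "|", salt = "") {
  stopifnot(is.character(fields), length(fields) >= 1L, !anyNA(fields))
  if (anyDuplicated(fields)) stop("`fields` must be duplicate-free", call. = FALSE)
  stopifnot(is.character(delimiter), length(delimiter) == 1L, nchar(delimiter) >= 1L)
  stopifnot(is.character(salt), length(salt) == 1L, !is.na(salt))
  structure(
    list(fields = fields, delimiter = delimiter, salt = salt,
         algorithm = "sha256"),
    class = "hash_spec"
  )
}

#' @export
print.hash_spec <- function(x, ...) {
  cat("Hash spec: ", x$algorithm, " over [",
      paste(x$fields, collapse = ", "), "] joined by '", x$delimiter, "'",
      if (nzchar(x$salt)) ", salted" else ", unsalted", "\n", sep = "")
  invisible(x)
}

#' Build canonical hash-input strings for clean records
#'
#' Joins the salt (when non-empty) and the configured field values with
#' the spec delimiter. Errors, naming the offending `record_index`, if the
#' delimiter occurs inside any field value: such a value would make the
#' concatenation ambiguous.
#'
#' @param records Data frame of clean records containing every column in
#'   `spec$fields` (and `record_index`, used only in error messages).
#' @param spec A [hash_spec()].
#' @return Character vector of canonical strings, one per row.
#' @examples
#' recs <- data.frame(gender = "M", service_number = "AB123456")
#' make_hash_input(recs, hash_spec())
#' @export
make_hash_input <- function(records, spec = hash_spec()) {
  stopifnot(is.data.frame(records), inherits(spec, "hash_spec"))
  missing_cols <- setdiff(spec$fields, names(records))
  if (length(missing_cols)) {
    stop("records lack hash field(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cols <- lapply(spec$fields, function(f) as.character(records[[f]]))
  for (i in seq_along(cols)) {
    bad <- which(grepl(spec$delimiter, cols[[i]], fixed = TRUE))
    if (length(bad)) {
      idx <- if ("record_index" %in% names(records)) {
        records$record_index[bad[1L]]
      } else bad[1L]
      stop("delimiter '", spec$delimiter, "' found inside field '",
           spec$fields[i], "' at record_index ", idx, call. = FALSE)
    }
    if (anyNA(cols[[i]])) {
      stop("missing value in hash field '", spec$fields[i],
           "'; clean the roster first", call. = FALSE)
    }
  }
  if (nzchar(spec$salt)) cols <- c(list(rep(spec$salt, nrow(records))), cols)
  do.call(paste, c(cols, sep = spec$delimiter))
}

#' SHA-256 digest of strings, as lowercase hexadecimal
#'
#' Each element is encoded as UTF-8 bytes and digested with SHA-256; the
#' 256-bit digest is rendered as 64 lowercase hex characters. Matches the
#' FIPS 180-4 reference vectors.
#'
#' @param x Character vector.
#' @return Character vector of 64-character lowercase hex digests.
#' @examples
#' sha256_hex("abc")
#' @export
sha256_hex <- function(x) {
  vapply(enc2utf8(as.character(x)),
         function(s) digest::digest(s, algo = "sha256", serialize = FALSE),
         character(1L), USE.NAMES = FALSE)
}

#' Assign the anonymous unique identifier to every clean record
#'
#' Order-preserving: returns the input records with a `uid` column, the
#' SHA-256 digest of the canonical (salt, gender, service number) string.
#' Identical field values (under the same salt) always produce identical
#' uids, on any platform and in any input order. With
#' `drop_identifiers = TRUE` the personal key columns are removed after
#' hashing, so downstream output carries only the anonymous identifier.
#'
#' @param x A `"roster_clean"` object from [clean_roster()], or a data
#'   frame of clean records.
#' @param spec A [hash_spec()].
#' @param drop_identifiers Drop the hashed personal columns from the
#'   output? Default `FALSE` (kept, for validation against the gold
#'   standard key).
#' @return Data frame of hashed records with a `uid` column.
#' @examples
#' x <- data.frame(gender = c("M", "F"), service_number = c("AB123456", "AB123456"))
#' hash_roster(x)$uid
#' @export
hash_roster <- function(x, spec = hash_spec(), drop_identifiers = FALSE) {
  records <- if (inherits(x, "roster_clean")) x$clean else x
  stopifnot(is.data.frame(records))
  records$uid <- sha256_hex(make_hash_input(records, spec))
  if (drop_identifiers) {
    records <- records[, setdiff(names(records), spec$fields), drop = FALSE]
  }
  records
}
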