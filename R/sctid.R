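# SNOMED-style concept identifiers: 6-18 decimal digits, no leading zero,
# terminated by a Verhoeff check digit computed over the preceding digits.
# The partition digits are deliberately not interpreted: identifiers are
# opaque tokens beyond length and checksum.

# Verhoeff dihedral-group tables (D5): d = group operation, p = permutation
# applied by digit position, inv = group inverses.
.verhoeff_d <- matrix(as.integer(c(
  0, 1, 2, 3, 4, 5, 6, 7, 8, 9,
  1, 2, 3, 4, 0, 6, 7, 8, 9, 5,
  2, 3, 4, 0, 1, 7, 8, 9, 5, 6,
  3, 4, 0, 1, 2, 8, 9, 5, 6, 7,
  4, 0, 1, 2, 3, 9, 5, 6, 7, 8,
  5, 9, 8, 7, 6, 0, 4, 3, 2, 1,
  6, 5, 9, 8, 7, 1, 0, 4, 3, 2,
  7, 6, 5, 9, 8, 2, 1, 0, 4, 3,
  8, 7, 6, 5, 9, 3, 2, 1, 0, 4,
  9, 8, 7, 6, 5, 4, 3, 2, 1, 0)), nrow = 10, byrow = TRUE)

.verhoeff_p <- matrix(as.integer(c(
  0, 1, 2, 3, 4, 5, 6, 7, 8, 9,
  1, 5, 7, 6, 2, 8, 3, 0, 9, 4,
  5, 8, 0, 3, 7, 9, 6, 1, 4, 2,
  8, 9, 1, 6, 0, 4, 3, 5, 2, 7,
  9, 4, 5, 3, 1, 2, 6, 8, 7, 0,
  4, 2, 8, 6, 5, 7, 3, 9, 0, 1,
  2, 7, 9, 3, 8, 0, 6, 4, 1, 5,
  7, 0, 4, 6, 9, 1, 3, 2, 5, 8)), nrow = 8, byrow = TRUE)

.verhoeff_inv <- as.integer(c(0, 4, 3, 2, 1, 5, 6, 7, 8, 9))

.verhoeff_checksum <- function(digits) {
  # digits: integer vector, most significant first, checksum position 0 is
  # the rightmost digit
  c <- 0L
  pos <- 0L
  for (dg in rev(digits)) {
    c <- .verhoeff_d[c + 1L, .verhoeff_p[(pos %% 8L) + 1L, dg + 1L] + 1L]
    pos <- pos + 1L
  }
  c
}

#' Compute the Verhoeff check digit for a digit string
#'
#' Returns the single digit that, appended to `body`, yields a string whose
#' Verhoeff checksum is zero. Used when minting synthetic identifiers.
#'
#' @param body A string of decimal digits (the identifier without its final
#'   check digit).
#' @return A single integer in 0-9.
#' @examples
#' verhoeff_check_digit("4516900") # 1, completing 45169001
#' @export
verhoeff_check_digit <- function(body) {
  stopifnot(is.character(body), length(body) == 1L)
  if (!stri_detect_regex(body, "^[0-9]+$")) {
    abort("`body` must contain only decimal digits.", class = "fdg_malformed_id")
  }
  digits <- as.integer(stri_sub(body, seq_len(stri_length(body)), length = 1L))
  # shift left one position (check digit occupies position 0)
  c <- 0L
  pos <- 1L
  for (dg in rev(digits)) {
    c <- .verhoeff_d[c + 1L, .verhoeff_p[(pos %% 8L) + 1L, dg + 1L] + 1L]
    pos <- pos + 1L
  }
  .verhoeff_inv[c + 1L]
}

#' Validate a SNOMED-style concept identifier
#'
#' A valid identifier is a string of 6 to 18 decimal digits with no leading
#' zero whose final digit is a correct Verhoeff check digit over the
#' preceding digits. Malformed input of any kind returns `FALSE` rather than
#' raising an error.
#'
#' @param candidate Character vector of candidate identifiers.
#' @return Logical vector, `TRUE` where the candidate is a valid identifier.
#' @examples
#' validate_sctid("45169001")            # TRUE  (Without (attribute))
#' validate_sctid(c("123", "45169002"))  # FALSE, FALSE
#' @export
validate_sctid <- function(candidate) {
  if (length(candidate) == 0L) return(logical(0))
  vapply(as.character(candidate), function(x) {
    if (is.na(x)) return(FALSE)
    if (!stri_detect_regex(x, "^[1-9][0-9]{5,17}$")) return(FALSE)
    digits <- as.integer(stri_sub(x, seq_len(stri_length(x)), length = 1L))
    .verhoeff_checksum(digits) == 0L
  }, logical(1), USE.NAMES = FALSE)
}

#' Mint a valid synthetic identifier from a digit body
#'
#' Appends the Verhoeff check digit to `body`, producing an identifier that
#' passes [validate_sctid()].
#'
#' @param body Digit string (5-17 digits, no leading zero).
#' @return A valid identifier string.
#' @export
make_sctid <- function(body) {
  stopifnot(is.character(body), length(body) == 1L)
  if (!stri_detect_regex(body, "^[1-9][0-9]{4,16}$")) {
    abort("`body` must be 5-17 digits with no leading zero.",
          class = "fdg_malformed_id")
  }
  paste0(body, verhoeff_check_digit(body))
}
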