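#' Encode a vegetation transition code (iTr)
#'
#' A transition from origin class \code{class_from} to destination class
#' \code{class_to} is encoded by concatenating the two class codes as digits:
#' (1, 9) -> 19, (2, 3) -> 23, (1, 10) -> 110. Only transitions from a lower
#' to a higher code are encoded; the reverse direction equals the encoded one
#' with the sign of the difference flipped.
#'
#' @param class_from,class_to integer class codes with
#'   \code{class_from < class_to}.
#' @return integer transition code.
#' @examples
#' encodeTransition(1, 9)   # 19
#' encodeTransition(1, 10)  # 110
#' @export
encodeTransition <- function(class_from, class_to) {
  class_from <- as.integer(class_from)
  class_to <- as.integer(class_to)
  if (any(is.na(class_from)) || any(is.na(class_to)))
    stop("class codes must be integers")
  if (any(class_from < 1L) || any(class_to < 1L))
    stop("class codes must be positive")
  if (any(class_from >= class_to))
    stop("transitions from a larger code to a smaller one are not encoded; ",
         "swap the classes and flip the sign of the difference")
  if (any(class_from > 9L) || any(class_to > 10L))
    stop("class codes above 10 (origin above 9) cannot be encoded")
  as.integer(class_from * ifelse(class_to >= 10L, 100L, 10L) + class_to)
}

#' Decode a vegetation transition code (iTr)
#'
#' Inverse of [encodeTransition()]. Three-digit codes are unambiguous: they
#' always denote a transition into class 10.
#'
#' @param code integer transition code.
#' @return integer matrix with columns \code{class_from}, \code{class_to}.
#' @examples
#' decodeTransition(110)  # 1 -> 10
#' @export
decodeTransition <- function(code) {
  code <- as.integer(code)
  if (any(is.na(code))) stop("transition codes must be integers")
  from <- ifelse(code >= 100L, code %/% 100L, code %/% 10L)
  to <- ifelse(code >= 100L, code %% 100L, code %% 10L)
  bad <- code < 12L | (code >= 100L & to != 10L) | from >= to | from < 1L
  if (any(bad))
    stop("malformed transition code(s): ", paste(code[bad], collapse = ", "))
  cbind(class_from = as.integer(from), class_to = as.integer(to))
}

#' All transition codes of a scheme
#'
#' Every ordered pair of vegetated classes (lower code to higher code):
#' (10^2-10)/2 = 45 codes for IGBPdet, (4^2-4)/2 = 6 for IGBPgen.
#'
#' @param scheme a [ClassScheme-class] (or scheme name).
#' @return integer vector of iTr codes, sorted by (class_from, class_to).
#' @export
schemeTransitions <- function(scheme) {
  if (is.character(scheme)) scheme <- getScheme(scheme)
  veg <- sort(vegetatedClasses(scheme))
  pairs <- which(upper.tri(diag(length(veg))), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  encodeTransition(veg[pairs[, 1L]], veg[pairs[, 2L]])
}
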