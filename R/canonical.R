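#' Canonical JSON serialization
#'
#' Deterministic JSON encoding used wherever bytes are hashed: object keys
#' are sorted lexicographically (C locale), no insignificant whitespace is
#' emitted, and doubles are rendered with the shortest decimal string that
#' round-trips to the same IEEE-754 value. Logically equal structures
#' therefore always serialize to identical bytes, independent of the key
#' order they were built with.
#'
#' Supported values: NULL, logical, numeric, character (scalars and
#' unnamed vectors/lists as arrays), and named lists as objects. NA is not
#' representable and raises an error, as befits an audit record.
#'
#' @param x an R value.
#' @return A length-1 character string of JSON.
#' @examples
#' canonical_json(list(b = 1, a = list(2, "x")))
#' @export
canonical_json <- function(x) {
  paste0(canon_value(x), collapse = "")
}

canon_value <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nm <- names(x)
    if (is.null(nm) || all(nm == "")) {
      return(paste0("[", paste(vapply(x, canon_value, character(1)),
                               collapse = ","), "]"))
    }
    if (anyDuplicated(nm) || any(nm == "")) {
      stop("canonical_json: object keys must be unique and non-empty")
    }
    ord <- order_c(nm)
    parts <- vapply(ord, function(i) {
      paste0(canon_string(nm[i]), ":", canon_value(x[[i]]))
    }, character(1))
    return(paste0("{", paste(parts, collapse = ","), "}"))
  }
  if (length(x) != 1L) {
    return(paste0("[", paste(vapply(seq_along(x), function(i) canon_value(x[i]),
                                    character(1)), collapse = ","), "]"))
  }
  if (is.na(x)) stop("canonical_json: NA is not representable")
  if (is.logical(x)) return(if (x) "true" else "false")
  if (is.numeric(x)) return(shortest_double(as.numeric(x)))
  if (is.character(x)) return(canon_string(x))
  if (is.factor(x)) return(canon_string(as.character(x)))
  stop("canonical_json: unsupported type: ", class(x)[1])
}

order_c <- function(nm) {
  # byte-wise (C locale) ordering, independent of the session locale
  order(vapply(nm, function(s) {
    paste(sprintf("%03d", utf8ToInt(enc2utf8(s))), collapse = "")
  }, character(1)), nm)
}

canon_string <- function(s) {
  s <- enc2utf8(s)
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  # remaining control characters (NUL cannot occur in an R string)
  for (cc in 1:31) {
    ch <- intToUtf8(cc)
    if (cc %in% c(9L, 10L, 13L)) next
    if (grepl(ch, s, fixed = TRUE, useBytes = TRUE)) {
      s <- gsub(ch, sprintf("\\u%04x", cc), s, fixed = TRUE)
    }
  }
  paste0("\"", s, "\"")
}

#' Shortest round-trip decimal representation of a double
#'
#' Smallest number of significant digits (1..17) whose decimal string
#' parses back to the identical IEEE-754 double. Integral values render
#' without exponent or trailing ".0".
#'
#' @param x a single finite numeric value.
#' @return A character scalar.
#' @keywords internal
shortest_double <- function(x) {
  if (!is.finite(x)) stop("shortest_double: non-finite value")
  if (x == 0) return("0") # normalize negative zero
  if (x == floor(x) && abs(x) < 1e15) {
    return(sprintf("%.0f", x))
  }
  for (d in 1:17) {
    s <- formatC(x, digits = d, format = "g", mode = "double")
    if (as.numeric(s) == x) return(s)
  }
  sprintf("%.17g", x)
}
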