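#' SHA-256 digest of a string or raw vector
#'
#' Hash primitive behind model version fingerprints and the AFPR
#' inference-log hash chain. Character input is hashed as its UTF-8 byte
#' representation.
#'
#' @param x character scalar or raw vector.
#' @return 64-character lowercase hex digest.
#' @examples
#' sha256_hex("abc")
#' @export
sha256_hex <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- charToRaw(enc2utf8(x))
  }
  stopifnot(is.raw(x))
  .sha256_raw(x)
}

#' @useDynLib fairaudit, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL
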