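# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == round(x)
}

#' Compose a C(Xa:A) karyotype label
#'
#' A karyotype is written `C(x:a)` where `x` is the number of active X
#' chromosomes and `a` the autosome ploidy in multiples of 22; the normal
#' somatic karyotype is `C(1:2)`.
#'
#' @param xa_count Integer number of active X chromosomes (>= 0).
#' @param n_A Integer autosome ploidy (>= 1).
#' @return Character label, or `NA_character_` if either input is `NA`.
#' @export
#' @examples
#' cxa_label(2, 3)
cxa_label <- function(xa_count, n_A) {
  out <- rep(NA_character_, length(xa_count))
  ok <- !is.na(xa_count) & !is.na(n_A)
  if (any(ok & (xa_count < 0 | n_A < 1))) {
    stopf("cxa_label: xa_count must be >= 0 and n_A >= 1")
  }
  out[ok] <- sprintf("C(%d:%d)", as.integer(xa_count[ok]), as.integer(n_A[ok]))
  out
}

#' Parse a C(Xa:A) label into its components
#'
#' @param label Character vector of labels such as `"C(2:3)"`.
#' @return A `data.frame` with integer columns `xa_count` and `n_A`.
#' @export
parse_cxa_label <- function(label) {
  m <- regmatches(label, regexec("^C\\((\\d+):(\\d+)\\)$", label))
  bad <- !is.na(label) & vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stopf("malformed C(Xa:A) label: %s", paste(label[bad], collapse = ", "))
  }
  xa <- vapply(m, function(p) if (length(p) == 3L) as.integer(p[2L]) else NA_integer_, 1L)
  na <- vapply(m, function(p) if (length(p) == 3L) as.integer(p[3L]) else NA_integer_, 1L)
  data.frame(xa_count = xa, n_A = na)
}
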