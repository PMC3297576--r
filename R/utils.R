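`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Percentage rounded to the nearest integer
#'
#' Reporting helper shared by all summary tables: percentages are rounded to
#' the nearest integer, matching the reporting style of the study design this
#' pipeline emulates (e.g. 3068/19621 genes modified -> 16).
#'
#' @param n Numerator (count).
#' @param total Denominator (count); `NA` is returned when `total` is 0.
#' @return Integer percentage, or `NA` if `total == 0`.
#' @export
#' @examples
#' percent_of(25, 41) # 61
percent_of <- function(n, total) {
  if (length(total) != 1L || is.na(total) || total == 0) return(NA_integer_)
  as.integer(round(100 * n / total))
}
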