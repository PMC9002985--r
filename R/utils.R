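#' Round half away from zero
#'
#' Print-style rounding used in the descriptive and effect reports: exact
#' halves move away from zero (2.5 -> 3, -2.5 -> -3), unlike [base::round()]'s
#' round-half-even. Internal estimates are never rounded; this is applied only
#' when formatting report tables.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_away(c(2.5, -2.5, 12.04), 1)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

drop_log <- function(reason, n) {
  if (n > 0) inform(sprintf("DROPPED %d rows: %s", n, reason))
  invisible(n)
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(ifelse(is.na(x), NA, x != 0))
  if (is.character(x)) {
    out <- rep(NA, length(x))
    out[x %in% c("1", "true", "TRUE", "yes")] <- TRUE
    out[x %in% c("0", "false", "FALSE", "no")] <- FALSE
    return(out)
  }
  abort("cannot interpret column as a 0/1 flag")
}

check_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}
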