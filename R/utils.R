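#' Round half away from zero
#'
#' Decimal rounding with ties going up (away from zero), the convention used
#' for reported identity percentages. Base \code{round()} rounds half to even,
#' which turns e.g. 50.05 into 50.0 rather than 50.1.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Stops with the caller's message, no call in the condition
abort <- function(...) stop(..., call. = FALSE)

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    abort(what, " must be a single character string")
  s <- toupper(seq)
  if (grepl("[^ACGT]", s))
    abort(what, " contains non-ACGT characters: ",
          paste(unique(strsplit(gsub("[ACGT]", "", s), "")[[1]]), collapse = ", "))
  s
}
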