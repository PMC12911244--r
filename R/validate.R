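# internal argument checks; every user-facing error names the offending field

assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("'", name, "' must be a single non-missing number", call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name) {
  assert_scalar_num(x, name)
  if (x < 0 || abs(x - round(x)) > 1e-8)
    stop("'", name, "' must be a non-negative integer", call. = FALSE)
  invisible(x)
}

assert_prob_open <- function(x, name) {
  assert_scalar_num(x, name)
  if (x <= 0 || x >= 1)
    stop("'", name, "' must lie strictly between 0 and 1", call. = FALSE)
  invisible(x)
}

assert_prob_closed <- function(x, name) {
  assert_scalar_num(x, name)
  if (x < 0 || x > 1)
    stop("'", name, "' must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

assert_d <- function(d) {
  assert_scalar_num(d, "d")
  if (d < 0 || d > 1)
    stop("'d' must lie in [0, 1]", call. = FALSE)
  invisible(d)
}
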