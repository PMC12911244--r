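#' Beta prior or posterior for an arm's response rate
#'
#' A `Beta(alpha, beta)` distribution describing the response rate of one
#' treatment arm.  `alpha` counts pseudo-responders and `beta`
#' pseudo-non-responders, so `alpha + beta` is the prior effective sample
#' size and `alpha / (alpha + beta)` the prior mean response rate.
#'
#' @param alpha Positive shape parameter (pseudo-responders).
#' @param beta Positive shape parameter (pseudo-non-responders).
#' @return An object of class `beta_params`.
#' @examples
#' beta_params(1, 1)          # vague prior
#' beta_params(3, 7)          # 10 pseudo-patients at a 30% response rate
#' @export
beta_params <- function(alpha, beta) {
  assert_scalar_num(alpha, "alpha")
  assert_scalar_num(beta, "beta")
  if (alpha <= 0 || beta <= 0)
    stop("'alpha' and 'beta' must be strictly positive", call. = FALSE)
  if (!is.finite(alpha) || !is.finite(beta))
    stop("'alpha' and 'beta' must be finite", call. = FALSE)
  structure(list(alpha = alpha, beta = beta), class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf("Beta(%g, %g)  [mean %.3f, effective sample size %g]\n",
              x$alpha, x$beta, x$alpha / (x$alpha + x$beta),
              x$alpha + x$beta))
  invisible(x)
}

#' Observed trial outcome for one arm
#'
#' @param n Number of patients treated (non-negative integer).
#' @param successes Number of responders (integer, `0 <= successes <= n`).
#' @return An object of class `arm_outcome`.
#' @examples
#' arm_outcome(40, 22)
#' @export
arm_outcome <- function(n, successes) {
  assert_count(n, "n")
  assert_count(successes, "successes")
  if (successes > n)
    stop("'successes' must not exceed 'n' (got ", successes, " > ", n, ")",
         call. = FALSE)
  structure(list(n = as.integer(n), successes = as.integer(successes)),
            class = "arm_outcome")
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("%d responders / %d patients\n", x$successes, x$n))
  invisible(x)
}

#' Decision constants shared by the selection criteria
#'
#' @param d Clinically meaningful difference in response rates, in `[0, 1)`.
#'   Differences larger than `d` count as a correct selection of the better
#'   arm; differences within `[-d, d]` are ambiguous.
#' @param rho Weight in `[0, 1]` given to the ambiguous zone in
#'   `lambda* = PCorr* + rho * PAmb*`.  `rho = 0.5` treats an ambiguous
#'   trial as a fair coin toss between arms; `rho = 1` yields a
#'   non-inferiority-style rule; `rho = 0` ignores ambiguity.
#' @param theta Decision threshold in `(0, 1)`: arm A is selected outright
#'   when `lambda* > theta`.
#' @return An object of class `design_params`.
#' @examples
#' design_params(d = 0.10, rho = 0.5, theta = 0.90)
#' @export
design_params <- function(d, rho = 0.5, theta = 0.90) {
  assert_scalar_num(d, "d")
  assert_scalar_num(rho, "rho")
  assert_scalar_num(theta, "theta")
  if (d < 0 || d >= 1)
    stop("'d' must lie in [0, 1)", call. = FALSE)
  if (rho < 0 || rho > 1)
    stop("'rho' must lie in [0, 1]", call. = FALSE)
  if (theta <= 0 || theta >= 1)
    stop("'theta' must lie in (0, 1)", call. = FALSE)
  structure(list(d = d, rho = rho, theta = theta), class = "design_params")
}

#' Conjugate Beta-binomial posterior update
#'
#' With prior `pi ~ Beta(alpha, beta)` and `S` responders among `n`
#' patients, the posterior is `Beta(alpha + S, beta + n - S)`.
#'
#' @param prior A [beta_params] prior.
#' @param outcome An [arm_outcome] with the observed counts.
#' @return The posterior as a [beta_params] object.
#' @examples
#' beta_update(beta_params(1, 1), arm_outcome(40, 22))  # Beta(23, 19)
#' @export
beta_update <- function(prior, outcome) {
  prior <- as_beta_params(prior)
  if (!inherits(outcome, "arm_outcome"))
    outcome <- arm_outcome(outcome$n, outcome$successes)
  beta_params(prior$alpha + outcome$successes,
              prior$beta + outcome$n - outcome$successes)
}

# coerce (alpha, beta) pairs given as plain vectors/lists
as_beta_params <- function(x) {
  if (inherits(x, "beta_params")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(beta_params(x[1], x[2]))
  if (is.list(x) && !is.null(x$alpha)) return(beta_params(x$alpha, x$beta))
  stop("cannot interpret object as Beta parameters", call. = FALSE)
}
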