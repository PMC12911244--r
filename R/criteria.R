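# Posterior selection criteria for two independent Beta posteriors.
#
# With pi_A ~ Beta(a1, b1) and pi_B ~ Beta(a2, b2) independent,
#   PCorr* = Pr(pi_A - pi_B > d)
#          = int_0^{1-d} [1 - F(x + d; a1, b1)] f(x; a2, b2) dx
#   PAmb*  = Pr(-d <= pi_A - pi_B <= d)
#          = Pr(pi_A - pi_B >= -d) - Pr(pi_A - pi_B > d),
# where F and f are the Beta cdf/pdf.  The cdf argument is clamped to
# [0, 1]; the density is zero outside [0, 1] so the value is unchanged.

# Pr(pi_A - pi_B > shift) by adaptive quadrature; shift may be negative,
# in which case the event boundary is inclusive/exclusive irrelevant
# (continuous distribution).  The integrand has a kink where the clamped
# cdf argument hits the support boundary, so the integral is split there:
# for x < -shift the survival factor is identically 1 and that piece
# reduces to a Beta cdf difference; beyond 1 - shift it vanishes.
beta_diff_exceeds <- function(post_a, post_b, shift) {
  a1 <- post_a$alpha; b1 <- post_a$beta
  a2 <- post_b$alpha; b2 <- post_b$beta
  if (shift >= 1) return(0)
  # effective support of the pi_B posterior
  lo <- max(0, qbeta(1e-15, a2, b2))
  hi <- min(1, qbeta(1e-15, a2, b2, lower.tail = FALSE), 1 - shift)
  if (hi <= lo) return(0)
  head_mass <- 0
  if (shift < 0 && -shift > lo) {
    cut <- min(-shift, hi)
    head_mass <- pbeta(cut, a2, b2) - pbeta(lo, a2, b2)
    lo <- cut
  }
  if (hi <= lo) return(min(max(head_mass, 0), 1))
  f <- function(x) {
    pbeta(pmin(pmax(x + shift, 0), 1), a1, b1, lower.tail = FALSE) *
      dbeta(x, a2, b2)
  }
  res <- integrate(f, lo, hi, rel.tol = 1e-11, abs.tol = 1e-12,
                   subdivisions = 500L, stop.on.error = FALSE)
  if (res$message != "OK" && res$abs.error > 1e-8)
    stop(sprintf(
      "quadrature did not converge (achieved absolute error %.3g): %s",
      res$abs.error, res$message), call. = FALSE)
  min(max(head_mass + res$value, 0), 1)
}

#' Posterior probability of correct selection
#'
#' `Pr(pi_A - pi_B > d)` under independent Beta posteriors for the two
#' arms: the posterior probability that the nominated better arm A beats
#' arm B by more than the clinically meaningful difference `d`.
#'
#' @param post_a,post_b [beta_params] posteriors for arms A and B.
#' @param d Clinically meaningful difference, in `[0, 1]` (`d = 1` makes
#'   the event impossible and returns 0).
#' @return A probability.
#' @examples
#' prob_correct(beta_params(23, 19), beta_params(17, 25), d = 0.10)
#' @export
prob_correct <- function(post_a, post_b, d) {
  post_a <- as_beta_params(post_a); post_b <- as_beta_params(post_b)
  assert_d(d)
  beta_diff_exceeds(post_a, post_b, d)
}

#' Posterior probability of an ambiguous outcome
#'
#' `Pr(-d <= pi_A - pi_B <= d)` under independent Beta posteriors: the
#' posterior probability that the two response rates are within the
#' clinically meaningful difference of each other, so that secondary
#' factors (toxicity, cost, convenience) would drive the selection.
#' Computed as the difference of two tail integrals,
#' `Pr(pi_A - pi_B >= -d) - Pr(pi_A - pi_B > d)`.
#'
#' @inheritParams prob_correct
#' @return A probability (exactly 0 when `d = 0`).
#' @examples
#' prob_ambiguous(beta_params(23, 19), beta_params(17, 25), d = 0.10)
#' @export
prob_ambiguous <- function(post_a, post_b, d) {
  post_a <- as_beta_params(post_a); post_b <- as_beta_params(post_b)
  assert_d(d)
  if (d == 0) return(0)
  upper <- beta_diff_exceeds(post_a, post_b, d)
  lower <- beta_diff_exceeds(post_a, post_b, -d)
  min(max(lower - upper, 0), 1)
}

#' The combined selection criterion lambda*
#'
#' Computes all three posterior criteria for a pair of arm posteriors:
#' the probability of correct selection `PCorr*`, the probability of an
#' ambiguous outcome `PAmb*`, and `lambda* = PCorr* + rho * PAmb*`.
#'
#' @param post_a,post_b [beta_params] posteriors for arms A and B.
#' @param params A [design_params] object carrying `d`, `rho` and `theta`.
#' @return An object of class `posterior_criteria` with elements
#'   `p_correct`, `p_ambiguous`, `lambda_star`, `d`, `rho`, `theta` and
#'   `decision` (see [decide]).
#' @examples
#' post_a <- beta_update(beta_params(1, 1), arm_outcome(40, 22))
#' post_b <- beta_update(beta_params(1, 1), arm_outcome(40, 16))
#' lambda_star(post_a, post_b, design_params(d = 0.10, rho = 0.5))
#' @export
lambda_star <- function(post_a, post_b, params) {
  post_a <- as_beta_params(post_a); post_b <- as_beta_params(post_b)
  stopifnot(inherits(params, "design_params"))
  p_corr <- prob_correct(post_a, post_b, params$d)
  p_amb <- prob_ambiguous(post_a, post_b, params$d)
  lam <- min(max(p_corr + params$rho * p_amb, 0), 1)
  out <- structure(
    list(p_correct = p_corr, p_ambiguous = p_amb, lambda_star = lam,
         d = params$d, rho = params$rho, theta = params$theta,
         decision = NA_character_),
    class = "posterior_criteria")
  out$decision <- decide(out, params$theta)
  out
}

#' Threshold decision rule
#'
#' Arm A is selected outright when `lambda* > theta` (strict); otherwise
#' the choice between arms falls to secondary factors.
#'
#' @param criteria A `posterior_criteria` object (from [lambda_star]) or a
#'   single numeric `lambda*` value.
#' @param theta Decision threshold in `(0, 1)`.
#' @return `"SELECT_A"` or `"CONSIDER_OTHER_FACTORS"`.
#' @examples
#' decide(0.95, theta = 0.90)
#' decide(0.90, theta = 0.90)   # boundary is not enough
#' @export
decide <- function(criteria, theta = 0.90) {
  assert_prob_open(theta, "theta")
  lam <- if (inherits(criteria, "posterior_criteria"))
    criteria$lambda_star else assert_prob_closed(criteria, "criteria")
  if (lam > theta) "SELECT_A" else "CONSIDER_OTHER_FACTORS"
}

#' @export
print.posterior_criteria <- function(x, digits = 2, ...) {
  cat("Posterior selection criteria (d =", format(x$d),
      ", rho =", format(x$rho), ")\n")
  cat(sprintf("  PCorr*  = %.*f\n", digits, x$p_correct))
  cat(sprintf("  PAmb*   = %.*f\n", digits, x$p_ambiguous))
  cat(sprintf("  lambda* = %.*f\n", digits, x$lambda_star))
  cat("  decision (theta =", format(x$theta), "):", x$decision, "\n")
  invisible(x)
}
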