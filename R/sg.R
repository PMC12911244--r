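# Sargent-Goldberg frequentist selection design (two arms), computed by
# exact binomial enumeration.
#
# With x_A ~ Binomial(n, pi_A), x_B ~ Binomial(n, pi_B) independent,
#   PCorr = Pr(phat_A - phat_B > d)      (strict)
#   PAmb  = Pr(|phat_A - phat_B| <= d)   (inclusive)
#   lambda = PCorr + rho * PAmb.
# The rate difference is compared in integer arithmetic: x_A - x_B
# against d * n, with d * n snapped to the nearest integer when it is
# within 1e-9 of one, so the boundary at, e.g., d * n = 4 is classified
# exactly.  The (strict, inclusive) convention reproduces the design's
# reference value lambda = 0.81 at rates 0.55 vs 0.40, d = 0.10, n = 40.

#' Sargent-Goldberg scenario
#'
#' @param pi_a,pi_b True response rates in `(0, 1)`; arm A is the better
#'   arm (`pi_a > pi_b`).
#' @param d Clinically meaningful difference in observed rates, `[0, 1)`.
#' @param rho Ambiguity weight in `[0, 1]` (the classical two-arm design
#'   uses 1/2).
#' @param n Patients per group.
#' @return An object of class `sg_scenario`.
#' @examples
#' sg_scenario(0.55, 0.40, d = 0.10, rho = 0.5, n = 40)
#' @export
sg_scenario <- function(pi_a, pi_b, d, rho = 0.5, n) {
  assert_prob_open(pi_a, "pi_a")
  assert_prob_open(pi_b, "pi_b")
  if (pi_a <= pi_b)
    stop("'pi_a' must exceed 'pi_b' (arm A is the better arm)",
         call. = FALSE)
  assert_scalar_num(d, "d")
  if (d < 0 || d > 1) stop("'d' must lie in [0, 1]", call. = FALSE)
  assert_prob_closed(rho, "rho")
  assert_count(n, "n")
  if (n < 1L) stop("'n' must be at least 1", call. = FALSE)
  structure(list(pi_a = pi_a, pi_b = pi_b, d = d, rho = rho,
                 n = as.integer(n)),
            class = "sg_scenario")
}

# count-difference threshold with exact boundary handling
sg_threshold <- function(d, n) {
  thr <- d * n
  if (abs(thr - round(thr)) < 1e-9) round(thr) else thr
}

#' Exact selection probabilities of the Sargent-Goldberg design
#'
#' Enumerates all `(n + 1)^2` outcome pairs and sums the joint binomial
#' probabilities of a correct selection (`phat_A - phat_B > d`, strict),
#' an ambiguous outcome (`|phat_A - phat_B| <= d`, inclusive) and a wrong
#' selection (the complement).
#'
#' @param scenario An [sg_scenario].
#' @return A list with `p_correct`, `p_ambiguous` and `p_wrong` summing
#'   to 1 exactly.
#' @examples
#' sg_probabilities(sg_scenario(0.55, 0.40, d = 0.10, rho = 0.5, n = 40))
#' @export
sg_probabilities <- function(scenario) {
  stopifnot(inherits(scenario, "sg_scenario"))
  n <- scenario$n
  x <- 0:n
  joint <- outer(dbinom(x, n, scenario$pi_a), dbinom(x, n, scenario$pi_b))
  diff <- outer(x, x, "-")
  thr <- sg_threshold(scenario$d, n)
  p_correct <- sum(joint[diff > thr])
  p_ambiguous <- sum(joint[abs(diff) <= thr])
  list(p_correct = p_correct, p_ambiguous = p_ambiguous,
       p_wrong = sum(joint[-diff > thr]))
}

#' The Sargent-Goldberg selection criterion
#'
#' `lambda = PCorr + rho * PAmb` from the exact enumeration in
#' [sg_probabilities].
#'
#' @param scenario An [sg_scenario].
#' @return The `lambda` value.
#' @examples
#' sg_lambda(sg_scenario(0.55, 0.40, d = 0.10, rho = 0.5, n = 40))  # ~0.81
#' @export
sg_lambda <- function(scenario) {
  p <- sg_probabilities(scenario)
  p$p_correct + scenario$rho * p$p_ambiguous
}

#' Frequentist required sample size
#'
#' Scans per-group sizes and returns the smallest `n` with
#' `lambda >= lambda_threshold` holding at `n` and at every larger
#' candidate up to `n_max_search` (the same stabilisation as the
#' deterministic Bayesian search; attainment of the threshold counts,
#' hence the non-strict inequality).
#'
#' When `d > 0`, candidate sizes are restricted to those where `d * n`
#' is a whole count, so the observed-rate difference boundary is exactly
#' attainable: at other sizes the inclusive/exclusive boundary is
#' asymmetric and `lambda` drops each time `d * n` passes an integer,
#' which would make the "smallest n" ill-posed.  This convention
#' reproduces the design's published size of 40 per group at
#' `d = 0.10`, threshold 0.80.  If no such candidate exists in the
#' search range, all integers are scanned.
#'
#' @param pi_a,pi_b True response rates (`pi_a > pi_b`).
#' @param d Clinically meaningful difference.
#' @param rho Ambiguity weight.
#' @param lambda_threshold Required `lambda`, in `(0, 1)`.
#' @param n_min_search,n_max_search Per-group search range.
#' @return A `sample_size_result` (method label `SG`).
#' @examples
#' \donttest{
#' sg_sample_size(0.55, 0.40, d = 0.10, rho = 0.5,
#'                lambda_threshold = 0.80, n_max_search = 100)  # 40
#' }
#' @export
sg_sample_size <- function(pi_a, pi_b, d, rho = 0.5, lambda_threshold,
                           n_min_search = 2L, n_max_search = 1000L) {
  assert_prob_open(lambda_threshold, "lambda_threshold")
  assert_count(n_min_search, "n_min_search")
  assert_count(n_max_search, "n_max_search")
  if (n_min_search < 1L || n_min_search > n_max_search)
    stop("'n_min_search' must lie in [1, n_max_search]", call. = FALSE)
  ns <- seq.int(n_min_search, n_max_search)
  if (d > 0) {
    whole <- abs(d * ns - round(d * ns)) < 1e-9
    if (any(whole)) ns <- ns[whole]
  }
  crit <- vapply(ns, function(n)
    sg_lambda(sg_scenario(pi_a, pi_b, d, rho, n)), numeric(1))
  trace <- data.frame(n = ns, criterion = crit)
  below <- which(crit < lambda_threshold)
  if (length(below) == 0L) {
    new_ss_result(ns[1L], TRUE, trace, "SG", lambda_threshold)
  } else if (max(below) == length(ns)) {
    new_ss_result(NA, FALSE, trace, "SG", lambda_threshold)
  } else {
    new_ss_result(ns[max(below) + 1L], TRUE, trace, "SG", lambda_threshold)
  }
}
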