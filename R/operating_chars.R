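# Operating characteristics of the selection rule.
#
# Under assumed true response rates the trial counts are binomial; each
# simulated (or enumerated) trial yields a lambda*, and
#   xi = Pr(lambda* > theta)      (correct outright selection of arm A)
#   nu = 1 - xi                   (decision deferred to secondary factors)
# are estimated by seeded Monte Carlo or computed exactly on the
# (n + 1) x (n + 1) outcome grid.  Both backends share the memoised
# lambda* grid, so they evaluate one and the same criterion.

#' Operating-characteristics scenario
#'
#' @param true_pi_a,true_pi_b True response rates in `(0, 1)` used to
#'   generate trial data.
#' @param prior_a,prior_b [beta_params] priors used in the analysis
#'   (default vague `Beta(1, 1)`).
#' @param n_per_arm Patients per arm.
#' @param d Clinically meaningful difference in `[0, 1)`.
#' @param rho Ambiguity weight in `[0, 1]`.
#' @param theta Decision threshold (default 0.90).
#' @param k Monte Carlo replicates (default 100000).
#' @param seed RNG seed for the Monte Carlo backend.
#' @return An object of class `oc_scenario`.
#' @examples
#' oc_scenario(0.30, 0.15, n_per_arm = 39, d = 0.05, rho = 0.5)
#' @export
oc_scenario <- function(true_pi_a, true_pi_b,
                        prior_a = beta_params(1, 1),
                        prior_b = beta_params(1, 1),
                        n_per_arm, d, rho, theta = 0.90,
                        k = 100000L, seed = 1L) {
  assert_prob_open(true_pi_a, "true_pi_a")
  assert_prob_open(true_pi_b, "true_pi_b")
  assert_count(n_per_arm, "n_per_arm")
  if (n_per_arm < 1L) stop("'n_per_arm' must be at least 1", call. = FALSE)
  assert_scalar_num(d, "d")
  if (d < 0 || d >= 1) stop("'d' must lie in [0, 1)", call. = FALSE)
  assert_prob_closed(rho, "rho")
  assert_prob_open(theta, "theta")
  assert_count(k, "k")
  if (k < 1L) stop("'k' must be at least 1", call. = FALSE)
  assert_scalar_num(seed, "seed")
  structure(
    list(true_pi_a = true_pi_a, true_pi_b = true_pi_b,
         prior_a = as_beta_params(prior_a), prior_b = as_beta_params(prior_b),
         n_per_arm = as.integer(n_per_arm), d = d, rho = rho, theta = theta,
         k = as.integer(k), seed = as.integer(seed)),
    class = "oc_scenario")
}

new_oc_result <- function(xi, mc_se, k_used, backend, scenario) {
  structure(
    list(xi = xi, nu = 1 - xi, mc_se = mc_se, k_used = as.integer(k_used),
         backend = backend, scenario = scenario),
    class = "oc_result")
}

#' @export
print.oc_result <- function(x, ...) {
  s <- x$scenario
  cat(sprintf(
    "Operating characteristics (%s backend, n = %d per arm)\n",
    x$backend, s$n_per_arm))
  cat(sprintf("  true rates %.2f vs %.2f, d = %g, rho = %g, theta = %g\n",
              s$true_pi_a, s$true_pi_b, s$d, s$rho, s$theta))
  cat(sprintf("  xi = %.1f%%   nu = %.1f%%", 100 * x$xi, 100 * x$nu))
  if (x$backend == "MC")
    cat(sprintf("   (MC se %.2f points, k = %d)", 100 * x$mc_se, x$k_used))
  cat("\n")
  invisible(x)
}

# scenario -> lambda* grid over the full outcome space
oc_lambda_grid <- function(scenario) {
  lambda_star_grid(scenario$n_per_arm, scenario$prior_a, scenario$prior_b,
                   scenario$d, scenario$rho)
}

#' Simulate operating characteristics
#'
#' Draws `k` replicate trials `S_A ~ Binomial(n, true_pi_a)`,
#' `S_B ~ Binomial(n, true_pi_b)`, computes `lambda*` for each via the
#' memoised count grid, and estimates
#' `xi = Pr(lambda* > theta)` as the replicate fraction exceeding the
#' threshold.  Reproducible given the scenario seed; the caller's RNG
#' state is restored afterwards.
#'
#' @param scenario An [oc_scenario].
#' @return An `oc_result` with `xi`, `nu = 1 - xi`,
#'   `mc_se = sqrt(xi (1 - xi) / k)`, `k_used` and `backend = "MC"`.
#' @examples
#' \donttest{
#' sc <- oc_scenario(0.30, 0.15, n_per_arm = 39, d = 0.05, rho = 0.5,
#'                   k = 10000, seed = 7)
#' oc_simulate(sc)
#' }
#' @export
oc_simulate <- function(scenario) {
  stopifnot(inherits(scenario, "oc_scenario"))
  n <- scenario$n_per_arm
  G <- oc_lambda_grid(scenario)
  hit <- G > scenario$theta
  xi <- with_local_seed(scenario$seed, {
    sa <- rbinom(scenario$k, n, scenario$true_pi_a)
    sb <- rbinom(scenario$k, n, scenario$true_pi_b)
    mean(hit[cbind(sa + 1L, sb + 1L)])
  })
  new_oc_result(xi, sqrt(xi * (1 - xi) / scenario$k), scenario$k, "MC",
                scenario)
}

#' Exact operating characteristics by enumeration
#'
#' Computes `xi = sum Bin(S_A) Bin(S_B) 1(lambda*(S_A, S_B) > theta)`
#' over the full `(n + 1)^2` outcome grid — the exact expectation that
#' [oc_simulate] estimates.  Deterministic; `mc_se` is 0.
#'
#' @param scenario An [oc_scenario] (`k` and `seed` are ignored).
#' @return An `oc_result` with `backend = "EXACT"`; `k_used` records the
#'   number of outcome pairs enumerated.
#' @examples
#' \donttest{
#' sc <- oc_scenario(0.30, 0.15, n_per_arm = 39, d = 0.05, rho = 0.5)
#' oc_exact(sc)   # xi ~ 0.544
#' }
#' @export
oc_exact <- function(scenario) {
  stopifnot(inherits(scenario, "oc_scenario"))
  n <- scenario$n_per_arm
  x <- 0:n
  pa <- dbinom(x, n, scenario$true_pi_a)
  pb <- dbinom(x, n, scenario$true_pi_b)
  G <- oc_lambda_grid(scenario)
  xi <- sum(outer(pa, pb) * (G > scenario$theta))
  new_oc_result(min(max(xi, 0), 1), 0, (n + 1L)^2, "EXACT", scenario)
}

#' Evaluate a grid of operating-characteristics scenarios
#'
#' Runs each scenario through the chosen backend and returns a tidy
#' table, one row per scenario.  A scenario that fails validation or
#' computation is recorded in the `error` column and the grid continues.
#'
#' @param scenarios A list of [oc_scenario] objects (names, if any,
#'   become scenario ids).
#' @param backend `"exact"` (deterministic) or `"mc"`.
#' @return A data.frame with columns `scenario_id`, `true_pi_a`,
#'   `true_pi_b`, `alpha_a`, `beta_a`, `alpha_b`, `beta_b`, `n`,
#'   `xi_pct`, `nu_pct`, `mc_se`, `backend`, `error`.
#' @export
oc_grid <- function(scenarios, backend = c("exact", "mc")) {
  backend <- match.arg(backend)
  if (!is.list(scenarios) || length(scenarios) == 0L)
    stop("'scenarios' must be a non-empty list of oc_scenario objects",
         call. = FALSE)
  if (inherits(scenarios, "oc_scenario")) scenarios <- list(scenarios)
  ids <- names(scenarios)
  if (is.null(ids)) ids <- as.character(seq_along(scenarios))
  rows <- lapply(seq_along(scenarios), function(i) {
    sc <- scenarios[[i]]
    res <- tryCatch({
      if (!inherits(sc, "oc_scenario"))
        stop("element ", i, " is not an oc_scenario")
      if (backend == "exact") oc_exact(sc) else oc_simulate(sc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(scenario_id = ids[i], true_pi_a = NA_real_,
                 true_pi_b = NA_real_, alpha_a = NA_real_, beta_a = NA_real_,
                 alpha_b = NA_real_, beta_b = NA_real_, n = NA_integer_,
                 xi_pct = NA_real_, nu_pct = NA_real_, mc_se = NA_real_,
                 backend = toupper(backend), error = conditionMessage(res))
    } else {
      s <- res$scenario
      data.frame(scenario_id = ids[i], true_pi_a = s$true_pi_a,
                 true_pi_b = s$true_pi_b, alpha_a = s$prior_a$alpha,
                 beta_a = s$prior_a$beta, alpha_b = s$prior_b$alpha,
                 beta_b = s$prior_b$beta, n = s$n_per_arm,
                 xi_pct = 100 * res$xi, nu_pct = 100 * res$nu,
                 mc_se = res$mc_se, backend = res$backend,
                 error = NA_character_)
    }
  })
  do.call(rbind, rows)
}
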