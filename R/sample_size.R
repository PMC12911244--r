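# Sample-size determination for the Bayesian selection design.
#
# Two algorithms share the request object below.  The deterministic
# method plugs the expected responder counts x_i = round(n * pi_i) into
# the posterior and asks for the smallest n from which lambda* stays
# above gamma* (the criterion is a sawtooth in n because of the rounding,
# so a plain first crossing would return spuriously small n at peaks).
# The simulation-based method instead treats the counts as
# Binomial(n, pi_i) draws and thresholds the mean of lambda* over that
# sampling distribution; the resulting curve is smooth and a first
# crossing suffices.  An exact enumeration backend computes the same
# expectation without Monte Carlo error.

#' Expected responder count
#'
#' The hypothesised number of responders among `n` patients at response
#' rate `pi_tilde`, rounded to an integer.  Rounding follows R's
#' round-half-to-even convention (so `expected_responders(30, 0.25)` is 8);
#' this is the convention under which the deterministic search reproduces
#' the design's reference sample-size tables.
#'
#' @param n Patients per group.
#' @param pi_tilde Anticipated response rate in `[0, 1]`.
#' @return A non-negative integer count.
#' @examples
#' expected_responders(30, 0.25)  # 8
#' expected_responders(40, 0.55)  # 22
#' @export
expected_responders <- function(n, pi_tilde) {
  assert_count(n, "n")
  assert_prob_closed(pi_tilde, "pi_tilde")
  # kill representation noise (e.g. 0.15 * 70 = 10.499999...) before rounding
  as.integer(round(round(n * pi_tilde, 9)))
}

#' Sample-size determination request
#'
#' Bundles the design inputs shared by [find_nmin_deterministic] and
#' [find_nmin_simulated].  Arm A is the anticipated better treatment, so
#' `pi_tilde_a > pi_tilde_b` is required.  Equal allocation
#' (`n_A = n_B = n`) is assumed at the design stage.
#'
#' @param pi_tilde_a,pi_tilde_b Anticipated response rates in `(0, 1)`.
#' @param prior_a,prior_b [beta_params] priors (default vague
#'   `Beta(1, 1)`).
#' @param d Clinically meaningful difference in `[0, 1)`.
#' @param rho Ambiguity weight in `[0, 1]`.
#' @param gamma_star Design-stage threshold in `(0, 1)` that the
#'   criterion must exceed.
#' @param n_min_search,n_max_search Per-group search range (defaults 2
#'   and 1000).
#' @param m Monte Carlo replicates per candidate `n` for [lambda_bar_mc].
#' @param seed Root seed; per-candidate substreams are derived from
#'   `(seed, n)` so traces do not depend on the search range.
#' @return An object of class `ss_request`.
#' @examples
#' ss_request(0.30, 0.15, d = 0.05, rho = 0.5, gamma_star = 0.90)
#' @export
ss_request <- function(pi_tilde_a, pi_tilde_b,
                       prior_a = beta_params(1, 1),
                       prior_b = beta_params(1, 1),
                       d, rho, gamma_star,
                       n_min_search = 2L, n_max_search = 1000L,
                       m = 10000L, seed = 1L) {
  assert_prob_open(pi_tilde_a, "pi_tilde_a")
  assert_prob_open(pi_tilde_b, "pi_tilde_b")
  if (pi_tilde_a <= pi_tilde_b)
    stop("'pi_tilde_a' must exceed 'pi_tilde_b' (arm A is the better arm)",
         call. = FALSE)
  assert_scalar_num(d, "d")
  if (d < 0 || d >= 1) stop("'d' must lie in [0, 1)", call. = FALSE)
  assert_prob_closed(rho, "rho")
  assert_prob_open(gamma_star, "gamma_star")
  assert_count(n_min_search, "n_min_search")
  assert_count(n_max_search, "n_max_search")
  if (n_min_search < 1L || n_min_search > n_max_search)
    stop("'n_min_search' must lie in [1, n_max_search]", call. = FALSE)
  assert_count(m, "m")
  if (m < 1L) stop("'m' must be at least 1", call. = FALSE)
  assert_scalar_num(seed, "seed")
  structure(
    list(pi_tilde_a = pi_tilde_a, pi_tilde_b = pi_tilde_b,
         prior_a = as_beta_params(prior_a), prior_b = as_beta_params(prior_b),
         d = d, rho = rho, gamma_star = gamma_star,
         n_min_search = as.integer(n_min_search),
         n_max_search = as.integer(n_max_search),
         m = as.integer(m), seed = as.integer(seed)),
    class = "ss_request")
}

new_ss_result <- function(n_min, found, trace, method, gamma_star) {
  structure(
    list(n_min = if (found) as.integer(n_min) else NA_integer_,
         found = found, trace = trace, method = method,
         gamma_star = gamma_star),
    class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat("Per-group sample size (", x$method, " method, threshold ",
      format(x$gamma_star), ")\n", sep = "")
  if (x$found) {
    shown <- if (x$n_min < 10) "<10" else as.character(x$n_min)
    cat("  n_min =", shown, "per group\n")
  } else {
    cat("  NOT FOUND within the search range (max criterion ",
        sprintf("%.4f", max(x$trace$criterion)), ")\n", sep = "")
  }
  cat("  candidates examined:", nrow(x$trace), "\n")
  invisible(x)
}

#' Deterministic criterion at a candidate sample size
#'
#' Plugs the expected responder counts at `n` patients per group into the
#' conjugate update and returns the resulting `lambda*`.
#'
#' @param request An [ss_request].
#' @param n Candidate per-group sample size.
#' @return The `lambda*` value.
#' @examples
#' req <- ss_request(0.55, 0.40, d = 0.10, rho = 0.5, gamma_star = 0.80)
#' lambda_at_n(req, 40)   # ~0.82
#' @export
lambda_at_n <- function(request, n) {
  stopifnot(inherits(request, "ss_request"))
  assert_count(n, "n")
  if (n < 1L) stop("'n' must be at least 1", call. = FALSE)
  xa <- expected_responders(n, request$pi_tilde_a)
  xb <- expected_responders(n, request$pi_tilde_b)
  post_a <- beta_update(request$prior_a, arm_outcome(n, xa))
  post_b <- beta_update(request$prior_b, arm_outcome(n, xb))
  p_corr <- prob_correct(post_a, post_b, request$d)
  if (request$rho == 0 || request$d == 0) return(p_corr)
  p_corr + request$rho * prob_ambiguous(post_a, post_b, request$d)
}

#' Deterministic sample-size search
#'
#' Scans per-group sizes over the search range and returns the smallest
#' `n` such that `lambda* > gamma_star` holds at `n` *and at every larger
#' candidate* up to `n_max_search`.  The stabilisation guards against the
#' sawtooth the integer rounding of expected counts induces: a first
#' crossing would pick a transient peak.
#'
#' @param request An [ss_request].
#' @return A `sample_size_result` with the minimal `n` (or a `NOT_FOUND`
#'   sentinel, `n_min = NA` and `found = FALSE`) and the full
#'   `(n, lambda*)` trace.
#' @examples
#' \donttest{
#' req <- ss_request(0.30, 0.15, d = 0.05, rho = 0.5, gamma_star = 0.90,
#'                   n_max_search = 150)
#' find_nmin_deterministic(req)   # 39 per group
#' }
#' @export
find_nmin_deterministic <- function(request) {
  stopifnot(inherits(request, "ss_request"))
  ns <- seq.int(request$n_min_search, request$n_max_search)
  crit <- vapply(ns, function(n) lambda_at_n(request, n), numeric(1))
  trace <- data.frame(n = ns, criterion = crit)
  below <- which(crit <= request$gamma_star)
  if (length(below) == 0L) {
    new_ss_result(ns[1L], TRUE, trace, "DETERMINISTIC", request$gamma_star)
  } else if (max(below) == length(ns)) {
    new_ss_result(NA, FALSE, trace, "DETERMINISTIC", request$gamma_star)
  } else {
    new_ss_result(ns[max(below) + 1L], TRUE, trace, "DETERMINISTIC",
                  request$gamma_star)
  }
}

# deterministic substream seed for candidate n (kept below 2^31)
substream_seed <- function(seed, n) {
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(n)) %% 2147483647)
}

# run code under a local RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# lambda* looked up on the memoised grid for sampled count pairs
grid_lookup <- function(request, n, xa, xb) {
  ua <- sort(unique(xa)); ub <- sort(unique(xb))
  G <- lambda_star_grid(n, request$prior_a, request$prior_b,
                        request$d, request$rho, xa = ua, xb = ub)
  G[cbind(match(xa, ua), match(xb, ub))]
}

#' Monte Carlo mean criterion at a candidate sample size
#'
#' Draws `m` responder-count pairs `x_A ~ Binomial(n, pi_tilde_a)`,
#' `x_B ~ Binomial(n, pi_tilde_b)`, computes `lambda*` for each posterior
#' pair (via the memoised count grid), and returns the mean and its
#' Monte Carlo standard error.  Reproducible given `(seed, n, m)`; the
#' caller's RNG state is left untouched.
#'
#' @param request An [ss_request] (fields `m` and `seed` are used).
#' @param n Candidate per-group sample size.
#' @return Named numeric vector `c(mean, mc_se)`.
#' @export
lambda_bar_mc <- function(request, n) {
  stopifnot(inherits(request, "ss_request"))
  assert_count(n, "n")
  m <- request$m
  lam <- with_local_seed(substream_seed(request$seed, n), {
    xa <- rbinom(m, n, request$pi_tilde_a)
    xb <- rbinom(m, n, request$pi_tilde_b)
    grid_lookup(request, n, xa, xb)
  })
  c(mean = mean(lam), mc_se = if (m > 1L) sd(lam) / sqrt(m) else NA_real_)
}

#' Exact mean criterion at a candidate sample size
#'
#' The expectation that [lambda_bar_mc] estimates, computed by full
#' enumeration of the binomial outcome grid:
#' `E[lambda*] = sum_xa sum_xb Bin(xa; n, pi_a) Bin(xb; n, pi_b)
#' lambda*(xa, xb)`.  Count pairs with joint probability below 1e-13 per
#' margin are dropped (total neglected mass < 1e-10).
#'
#' @param request An [ss_request].  The anticipated rates may be 0 or 1
#'   here (degenerate single-outcome distributions are enumerable).
#' @param n Candidate per-group sample size.
#' @return The exact expected `lambda*`.
#' @export
lambda_bar_exact <- function(request, n) {
  stopifnot(inherits(request, "ss_request"))
  assert_count(n, "n")
  x <- 0:n
  pa <- dbinom(x, n, request$pi_tilde_a)
  pb <- dbinom(x, n, request$pi_tilde_b)
  ka <- which(pa > 1e-13); kb <- which(pb > 1e-13)
  G <- lambda_star_grid(n, request$prior_a, request$prior_b,
                        request$d, request$rho,
                        xa = x[ka], xb = x[kb])
  sum(outer(pa[ka], pb[kb]) * G)
}

#' Simulation-based sample-size search
#'
#' Scans per-group sizes upward and returns the smallest `n` whose mean
#' criterion `lambda-bar*` (Monte Carlo with `m` replicates, or the exact
#' enumeration when `method = "exact"`) strictly exceeds `gamma_star`.
#' Averaging over the binomial sampling of the counts smooths out the
#' rounding sawtooth, so a plain first crossing is used — a deliberate
#' asymmetry with [find_nmin_deterministic].
#'
#' @param request An [ss_request].
#' @param method `"mc"` (default) or `"exact"`.
#' @return A `sample_size_result` (method label `SIMULATED` or `EXACT`)
#'   with the `(n, lambda-bar*)` trace over the candidates examined.
#' @examples
#' \donttest{
#' req <- ss_request(0.30, 0.15, d = 0.05, rho = 0.5, gamma_star = 0.90,
#'                   n_max_search = 100)
#' find_nmin_simulated(req, method = "exact")
#' }
#' @export
find_nmin_simulated <- function(request, method = c("mc", "exact")) {
  stopifnot(inherits(request, "ss_request"))
  method <- match.arg(method)
  label <- if (method == "exact") "EXACT" else "SIMULATED"
  ns <- integer(0); crit <- numeric(0)
  for (n in seq.int(request$n_min_search, request$n_max_search)) {
    val <- if (method == "exact") lambda_bar_exact(request, n)
           else unname(lambda_bar_mc(request, n)["mean"])
    ns <- c(ns, n); crit <- c(crit, val)
    if (val > request$gamma_star) {
      return(new_ss_result(n, TRUE, data.frame(n = ns, criterion = crit),
                           label, request$gamma_star))
    }
  }
  new_ss_result(NA, FALSE, data.frame(n = ns, criterion = crit),
                label, request$gamma_star)
}

#' Export a sample-size search trace as CSV
#'
#' Writes the `(n, criterion)` pairs behind a search — the data from
#' which the criterion-versus-sample-size curves are drawn — with columns
#' `n`, `criterion`, `method`, `gamma_star`.
#'
#' @param result A `sample_size_result`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(result, path) {
  stopifnot(inherits(result, "sample_size_result"))
  df <- result$trace
  df$method <- result$method
  df$gamma_star <- result$gamma_star
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
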