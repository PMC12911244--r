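# Brute-force sampling oracle for Pr(pi_A - pi_B > d), independent of the
# quadrature path it checks.
mc_exceed_prob <- function(post_a, post_b, d, n_draws = 1e6, seed = 42) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  da <- rbeta(n_draws, post_a$alpha, post_a$beta)
  db <- rbeta(n_draws, post_b$alpha, post_b$beta)
  p <- mean(da - db > d)
  list(est = p, se = sqrt(max(p * (1 - p), 1e-12) / n_draws))
}

# Pr(-d <= pi_A - pi_B <= d) by the same sampling route
mc_between_prob <- function(post_a, post_b, d, n_draws = 1e6, seed = 42) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  da <- rbeta(n_draws, post_a$alpha, post_a$beta)
  db <- rbeta(n_draws, post_b$alpha, post_b$beta)
  p <- mean(abs(da - db) <= d)
  list(est = p, se = sqrt(max(p * (1 - p), 1e-12) / n_draws))
}

# random posterior/difference configurations for property sweeps
random_configs <- function(n_cfg, seed) {
  set.seed(seed)
  lapply(seq_len(n_cfg), function(i) {
    list(post_a = beta_params(runif(1, 0.5, 40), runif(1, 0.5, 40)),
         post_b = beta_params(runif(1, 0.5, 40), runif(1, 0.5, 40)),
         d = runif(1, 0, 0.4))
  })
}

case_study_request <- function(rho = 0.5, gamma_star = 0.80) {
  ss_request(0.55, 0.40, d = 0.10, rho = rho, gamma_star = gamma_star,
             n_max_search = 100)
}
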