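test_that("conjugate Beta updating adds counts and rejects invalid outcomes", {
  expect_equal(beta_update(beta_params(1, 1), arm_outcome(10, 5)),
               beta_params(6, 6))
  expect_equal(beta_update(beta_params(1, 1), arm_outcome(40, 22)),
               beta_params(23, 19))
  # no data leaves the prior unchanged
  expect_equal(beta_update(beta_params(2, 8), arm_outcome(0, 0)),
               beta_params(2, 8))
  expect_error(arm_outcome(10, 11), "successes")
  expect_error(arm_outcome(-1, 0), "non-negative")
  expect_error(beta_params(0, 1), "positive")
})

test_that("prob_correct handles symmetric and degenerate differences", {
  flat <- beta_params(1, 1)
  expect_equal(prob_correct(flat, flat, 0), 0.5, tolerance = 1e-9)
  expect_equal(prob_correct(beta_params(5, 3), beta_params(2, 9), 1), 0)
  # continuous difference: d = 0 ambiguity is a null event
  expect_equal(prob_ambiguous(beta_params(3, 4), beta_params(2, 5), 0), 0)
  # d near 1 captures essentially the whole support
  expect_equal(prob_ambiguous(beta_params(4, 4), beta_params(4, 4), 0.999999),
               1, tolerance = 1e-5)
})

test_that("quadrature matches the million-draw sampling oracle", {
  post_a <- beta_params(23, 19)
  post_b <- beta_params(17, 25)
  oc <- mc_exceed_prob(post_a, post_b, 0.10)
  expect_lt(abs(prob_correct(post_a, post_b, 0.10) - oc$est), 3 * oc$se)
  oa <- mc_between_prob(post_a, post_b, 0.10)
  expect_lt(abs(prob_ambiguous(post_a, post_b, 0.10) - oa$est), 3 * oa$se)
})

test_that("the three selection events partition the posterior support", {
  for (cfg in random_configs(8, seed = 101)) {
    total <- prob_correct(cfg$post_a, cfg$post_b, cfg$d) +
      prob_ambiguous(cfg$post_a, cfg$post_b, cfg$d) +
      prob_correct(cfg$post_b, cfg$post_a, cfg$d)
    expect_equal(total, 1, tolerance = 1e-6)
    # arm swap leaves the ambiguity probability unchanged
    expect_equal(prob_ambiguous(cfg$post_a, cfg$post_b, cfg$d),
                 prob_ambiguous(cfg$post_b, cfg$post_a, cfg$d),
                 tolerance = 1e-8)
  }
})

test_that("criteria are monotone in d and in rho", {
  post_a <- beta_params(9, 21)
  post_b <- beta_params(5, 25)
  ds <- c(0, 0.02, 0.05, 0.1, 0.2, 0.4)
  pc <- vapply(ds, function(d) prob_correct(post_a, post_b, d), numeric(1))
  pa <- vapply(ds, function(d) prob_ambiguous(post_a, post_b, d), numeric(1))
  expect_true(all(diff(pc) <= 1e-10))
  expect_true(all(diff(pa) >= -1e-10))
  rhos <- seq(0, 1, by = 0.25)
  lams <- vapply(rhos, function(r)
    lambda_star(post_a, post_b, design_params(0.1, r))$lambda_star,
    numeric(1))
  expect_true(all(diff(lams) > 0))  # strict: PAmb* > 0 here
})

test_that("lambda* combines the criteria and honours rho endpoints", {
  post_a <- beta_params(23, 19)
  post_b <- beta_params(17, 25)
  c0 <- lambda_star(post_a, post_b, design_params(0.10, 0))
  expect_identical(c0$lambda_star, c0$p_correct)
  # case study: vague priors updated with expected counts 22/40 vs 16/40
  c5 <- lambda_star(post_a, post_b, design_params(0.10, 0.5))
  expect_equal(round(c5$lambda_star, 2), 0.82)
  expect_equal(c5$lambda_star, c5$p_correct + 0.5 * c5$p_ambiguous)
  # rho = 1 collapses to Pr(pi_A - pi_B >= -d); the difference is
  # continuous so the strict-inequality oracle measures the same event
  c1 <- lambda_star(post_a, post_b, design_params(0.10, 1))
  oc <- mc_exceed_prob(post_a, post_b, -0.10, seed = 9)
  expect_lt(abs(c1$lambda_star - oc$est), 3 * oc$se)
})

test_that("the threshold decision is strict", {
  expect_identical(decide(0.95, 0.90), "SELECT_A")
  expect_identical(decide(0.90, 0.90), "CONSIDER_OTHER_FACTORS")
  post_a <- beta_params(23, 19); post_b <- beta_params(17, 25)
  crit <- lambda_star(post_a, post_b, design_params(0.10, 0.5, 0.90))
  expect_identical(crit$decision, "CONSIDER_OTHER_FACTORS")
})

test_that("the vectorised count grid agrees with the scalar quadrature", {
  set.seed(3)
  G <- lambda_star_grid(25, beta_params(2, 8), beta_params(1, 9),
                        d = 0.07, rho = 0.4)
  for (i in sample(0:25, 5)) {
    j <- sample(0:25, 1)
    post_a <- beta_params(2 + i, 8 + 25 - i)
    post_b <- beta_params(1 + j, 9 + 25 - j)
    ref <- prob_correct(post_a, post_b, 0.07) +
      0.4 * prob_ambiguous(post_a, post_b, 0.07)
    expect_equal(G[as.character(i), as.character(j)], ref,
                 tolerance = 1e-9)
  }
})
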