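test_that("the GP covariance has the closed form and its limits", {
  ages <- c(0, 3, 10)
  K <- gp_cov(ages, amplitude = 2, lengthscale = 5, jitter = 0)
  expect_equal(K[1, 1], 4)
  expect_equal(K[1, 2], 4 * exp(-9 / 50))
  expect_equal(K, t(K))

  # flat-function limit: a huge length-scale correlates everything
  Kflat <- gp_cov(ages, 1, 1e6, jitter = 0)
  expect_true(all(abs(Kflat - 1) < 1e-9))

  # zero amplitude leaves only the jitter diagonal
  K0 <- gp_cov(ages, 0, 5, jitter = 1e-3)
  expect_equal(K0, diag(1e-3, 3))

  expect_error(gp_cov(c(1, 1, 2), 1, 1), "distinct")
})

test_that("the GP covariance is positive semi-definite on random grids", {
  set.seed(13)
  for (rep in 1:10) {
    ages <- sort(sample(0:60, 15))
    K <- gp_cov(ages, amplitude = runif(1, 0.1, 3),
                lengthscale = runif(1, 0.5, 30), jitter = 0)
    expect_gt(min(eigen(K, symmetric = TRUE,
                        only.values = TRUE)$values), -1e-8)
  }
})

test_that("stage log-likelihood matches hand and brute-force sums", {
  ages <- c(p1 = 3, p2 = 10, p3 = 20)
  # one paper, n = 3, x2 = 3, all effects zero, phi2 = 0: 3 log(1/2)
  res1 <- tibble::tibble(paper_id = "p1", n_results = 3L,
                         n_data_usable = 3L, n_analysis_clear = 3L,
                         n_results_agree = 3L)
  hp <- hier_params(phi = c(0, 20, 20), psi = c(0, 0, 0))
  ll <- stages_loglik(hp, res1, ages)
  # stages 3-4 have p ~ 1 so contribute ~0
  expect_equal(ll, 3 * log(0.5), tolerance = 1e-6)

  # x2 = 0 empties the later stages entirely
  res0 <- tibble::tibble(paper_id = "p1", n_results = 2L,
                         n_data_usable = 0L, n_analysis_clear = 0L,
                         n_results_agree = 0L)
  hp0 <- hier_params(phi = c(0.3, -5, 4), psi = c(0, 0, 0))
  expect_equal(stages_loglik(hp0, res0, ages),
               dbinom(0, 2, plogis(0.3), log = TRUE))

  # random instances against an independently coded per-stage sum
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(1:6, 3, replace = TRUE)
    x2 <- rbinom(3, n, 0.7); x3 <- rbinom(3, x2, 0.8)
    x4 <- rbinom(3, x3, 0.9)
    res <- tibble::tibble(paper_id = names(ages), n_results = n,
                          n_data_usable = x2, n_analysis_clear = x3,
                          n_results_agree = x4)
    beta <- matrix(rnorm(9, 0, 0.5), 3,
                   dimnames = list(NULL, names(ages)))
    phi <- rnorm(3); psi <- c(0.5, 0.5, 0.5)
    hp <- hier_params(phi = phi, psi = psi, beta = beta)
    # oracle: loop over stages and papers with dbinom directly
    oracle <- 0
    xs <- cbind(x2, x3, x4); ds <- cbind(n, x2, x3)
    for (s in 1:3) for (i in 1:3) {
      if (ds[i, s] > 0) {
        oracle <- oracle + dbinom(xs[i, s], ds[i, s],
                                  plogis(phi[s] + beta[s, i]), log = TRUE)
      }
    }
    expect_equal(stages_loglik(hp, res, ages), unname(oracle))
  }
})

test_that("nesting violations are rejected before evaluation", {
  res <- tibble::tibble(paper_id = "p1", n_results = 3L,
                        n_data_usable = 1L, n_analysis_clear = 2L,
                        n_results_agree = 0L)
  hp <- hier_params(phi = c(0, 0, 0), psi = c(0, 0, 0))
  expect_error(stages_loglik(hp, res, c(p1 = 3)), "nesting")
})

test_that("the logit-normal marginal matches quadrature symmetry and MC", {
  # phi = 0: exactly 1/2 by symmetry for any psi
  expect_equal(logit_normal_mean(0, 0), 0.5)
  expect_lt(abs(logit_normal_mean(0, 2.7) - 0.5), 1e-9)

  # phi = 1, psi = 2: brute-force Monte-Carlo oracle
  set.seed(23)
  z <- rnorm(1e6)
  mc <- mean(plogis(1 + 2 * z))
  se <- sd(plogis(1 + 2 * z)) / 1000
  expect_lt(abs(logit_normal_mean(1, 2) - mc), 3 * se)
})

test_that("marginalisation contracts toward one half", {
  for (phi in c(-2, -0.5, 0.7, 1.5, 3)) {
    for (psi in c(0.3, 1, 2, 4)) {
      m <- logit_normal_mean(phi, psi)
      expect_true(m > min(plogis(phi), 0.5) && m < max(plogis(phi), 0.5))
    }
  }
})

test_that("single-paper results are rejected as unidentifiable", {
  res <- tibble::tibble(paper_id = "p1", n_results = 3L,
                        n_data_usable = 2L, n_analysis_clear = 2L,
                        n_results_agree = 1L)
  expect_error(fit_stages(res, c(p1 = 4)), "at least 2")
})

test_that("a small hierarchical fit recovers sensible marginals", {
  sim <- simulate_audit(sim_config(n_papers = 600, results_subsample = 60),
                        audit_truth(p2 = 0.8, p3 = 0.9, p4 = 0.9,
                                    psi = 1),
                        seed = 29)
  fit <- fit_stages_quiet(sim$data, control = test_control(seed = 30),
                          year_effect = "none")
  m2 <- marginal_stage_prob(fit, 2)
  expect_true(m2$lower < 0.8 && 0.8 < m2$upper)
  # sample-average and population-average marginals broadly agree
  m2s <- marginal_stage_prob(fit, 2, method = "sample")
  expect_lt(abs(m2$estimate - m2s$estimate), 0.1)
  # draws multiply into a combined rate bounded by each stage
  d2 <- marginal_stage_prob(fit, 2, draws = TRUE)
  d3 <- marginal_stage_prob(fit, 3, draws = TRUE)
  d4 <- marginal_stage_prob(fit, 4, draws = TRUE)
  pr <- combined_rate(1, d2, d3, d4)
  expect_true(all(pr <= pmin(d2, d3, d4) + 1e-12))
})

test_that("a paper-effect scale of zero shrinks psi toward zero", {
  # informative design: many papers with the maximum number of results,
  # mid-range success probabilities
  cfg <- sim_config(n_papers = 700, results_subsample = 80,
                    results_probs = c(0, 0, 0, 0, 0, 1))
  shrunk <- logical(4)
  for (r in 1:4) {
    sim <- simulate_audit(
      cfg, audit_truth(p2 = 0.7, p3 = 0.8, p4 = 0.8, psi = 0),
      seed = 40 + r)
    fit <- fit_stages_quiet(sim$data,
                            control = test_control(seed = 50 + r,
                                                   iter = 400,
                                                   warmup = 300),
                            year_effect = "none")
    psi2 <- reproaudit:::draw_vector(fit$draws, "psi[usable]")
    shrunk[r] <- hpdi(psi2, 0.89)[["upper"]] < 1
  }
  expect_gte(sum(shrunk), 3)
})

test_that("the unconditional-denominator sensitivity variant runs", {
  sim <- simulate_audit(sim_config(n_papers = 300, results_subsample = 30),
                        seed = 59)
  fit <- fit_stages_quiet(sim$data,
                          control = test_control(seed = 60, iter = 300,
                                                 warmup = 200),
                          year_effect = "none", denominator = "total")
  expect_equal(fit$denominator, "total")
  expect_s3_class(marginal_stage_prob(fit, 3), "tbl_df")
})
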