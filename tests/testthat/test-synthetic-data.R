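test_that("identical seeds reproduce the dataset; different seeds differ", {
  a <- simulate_audit(seed = 7)
  b <- simulate_audit(seed = 7)
  c <- simulate_audit(seed = 8)
  expect_equal(a$data$papers, b$data$papers)
  expect_equal(a$data$results, b$data$results)
  expect_equal(a$latents$beta, b$latents$beta)
  expect_false(identical(a$data$papers, c$data$papers))
})

test_that("recovered fraction matches the geometric-series closed form", {
  # lambda = 0: no decay, fraction ~ alpha
  cfg <- sim_config(n_papers = 10000, year_range = c(1999, 2019),
                    age_geom_prob = 1e-9, results_subsample = 40)
  truth0 <- audit_truth(stage1 = stage1_params(alpha = 0.8, lambda = 0))
  sim0 <- simulate_audit(cfg, truth0, seed = 11)
  expect_lt(abs(mean(sim0$data$papers$recovered) - 0.8),
            3 * sqrt(0.8 * 0.2 / 10000))

  # alpha 0.8, lambda 0.12, ages uniform on 0..20:
  # mean = 0.8 * (1/21) * sum_k exp(-0.12 k), a finite geometric series
  cfg2 <- sim_config(n_papers = 50000, year_range = c(1999, 2019),
                     age_geom_prob = 1e-9, results_subsample = 40)
  truth2 <- audit_truth(stage1 = stage1_params(alpha = 0.8, lambda = 0.12))
  sim2 <- simulate_audit(cfg2, truth2, seed = 12)
  r <- exp(-0.12)
  expected <- 0.8 * (1 - r^21) / (21 * (1 - r))
  expect_equal(expected, 0.8 * mean(exp(-0.12 * (0:20))))  # series oracle
  expect_lt(abs(mean(sim2$data$papers$recovered) - expected),
            3 * sqrt(expected * (1 - expected) / 50000))
})

test_that("simulated stage counts are nested by construction", {
  for (s in 1:5) {
    sim <- simulate_audit(seed = 100 + s)
    r <- sim$data$results
    expect_true(all(r$n_results_agree <= r$n_analysis_clear))
    expect_true(all(r$n_analysis_clear <= r$n_data_usable))
    expect_true(all(r$n_data_usable <= r$n_results))
    expect_true(all(r$paper_id %in%
                      sim$data$papers$paper_id[sim$data$papers$recovered == 1]))
  }
})

test_that("results-per-paper distribution has the designed median and range", {
  sim <- simulate_audit(sim_config(n_papers = 2000, results_subsample = 400),
                        seed = 5)
  n <- sim$data$results$n_results
  expect_equal(median(n), 3)
  expect_true(all(n >= 1 & n <= 6))
})

test_that("with no paper or year effects the pooled stage-2 fraction is plogis(phi)", {
  truth <- audit_truth(p2 = 0.75, p3 = 0.9, p4 = 0.9, psi = 0)
  expect_equal(unname(truth$hier$phi["usable"]), qlogis(0.75))
  cfg <- sim_config(n_papers = 4000, results_subsample = 800)
  sim <- simulate_audit(cfg, truth, seed = 21)
  r <- sim$data$results
  frac <- sum(r$n_data_usable) / sum(r$n_results)
  n_tot <- sum(r$n_results)
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / n_tot))
})

test_that("recovery declines with age when lambda is positive", {
  sim <- simulate_audit(sim_config(n_papers = 20000), seed = 31)
  p <- sim$data$papers
  young <- mean(p$recovered[p$age < 5])
  old <- mean(p$recovered[p$age > 20])
  expect_gt(young, old)
})

test_that("an infeasible subsample size is a clear error", {
  cfg <- sim_config(n_papers = 50, results_subsample = 45)
  truth <- audit_truth(stage1 = stage1_params(alpha = 0.2, lambda = 0.3))
  expect_error(simulate_audit(cfg, truth, seed = 2), "recovered papers")
})

test_that("type probabilities must be a simplex", {
  expect_error(sim_config(type_probs = c(0.5, 0.5, 0.1, 0.1)), "sum to 1")
  expect_error(sim_config(results_subsample = 1000, n_papers = 500),
               "exceed")
})

test_that("large paper effects produce bimodal per-paper success rates", {
  cfg <- sim_config(n_papers = 5000, results_subsample = 500,
                    results_probs = c(0, 0, 0, 0, 0, 1))  # 6 results each
  base <- audit_truth(p2 = 0.7, p3 = 0.9, p4 = 0.9, psi = 0)
  wide <- audit_truth(p2 = 0.7, p3 = 0.9, p4 = 0.9, psi = 3)
  f0 <- simulate_audit(cfg, base, seed = 41)$data$results
  f3 <- simulate_audit(cfg, wide, seed = 41)$data$results
  # bimodality: mass of per-paper fractions at the extremes
  extreme <- function(r) mean(r$n_data_usable %in% c(0, r$n_results))
  expect_gt(extreme(f3), extreme(f0) + 0.2)
})

test_that("a one-replicate adequacy run yields a one-replicate table", {
  adequacy <- adequacy_simulation(
    sim_config(n_papers = 300, results_subsample = 20),
    n_replicates = 1, control = test_control(seed = 3, iter = 300,
                                             warmup = 200), seed = 9)
  expect_equal(nrow(adequacy), 3)
  expect_setequal(adequacy$stage, 2:4)
  expect_true(all(c("covered", "width", "phi_covered", "converged") %in%
                    names(adequacy)))
  cov <- coverage_summary(adequacy)
  expect_equal(nrow(cov), 3)
})

test_that("more results per paper tighten the stage-2 interval", {
  cfg1 <- sim_config(n_papers = 400, results_subsample = 40,
                     results_probs = c(1, 0, 0, 0, 0, 0))
  cfg6 <- sim_config(n_papers = 400, results_subsample = 40,
                     results_probs = c(0, 0, 0, 0, 0, 1))
  a1 <- adequacy_simulation(cfg1, n_replicates = 3,
                            control = test_control(iter = 400,
                                                   warmup = 300), seed = 4)
  a6 <- adequacy_simulation(cfg6, n_replicates = 3,
                            control = test_control(iter = 400,
                                                   warmup = 300), seed = 4)
  w1 <- mean(a1$width[a1$stage == 2])
  w6 <- mean(a6$width[a6$stage == 2])
  expect_gt(w1, w6)
})
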