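test_that("recovery log-likelihood matches hand-computed Bernoulli terms", {
  p1 <- tibble::tibble(study_type = "human_experimental", age = 0,
                       recovered = 1L)
  params <- stage1_params(alpha = 0.5, lambda = 0.7)
  expect_equal(stage1_loglik(params, p1), log(0.5))

  p2 <- tibble::tibble(study_type = rep("human_experimental", 2), age = 0,
                       recovered = c(1L, 0L))
  params0 <- stage1_params(alpha = 0.5, lambda = 0)
  expect_equal(stage1_loglik(params0, p2), 2 * log(0.5))

  # age shifts the success term by -lambda * v
  p3 <- tibble::tibble(study_type = "nonhuman_observational", age = 10,
                       recovered = 1L)
  expect_equal(stage1_loglik(stage1_params(0.8, 0.12), p3),
               log(0.8) - 1.2)
})

test_that("boundary and impossible configurations are handled explicitly", {
  expect_error(stage1_params(alpha = 1, lambda = 0.1), "inside")
  expect_error(stage1_params(alpha = 0.5, lambda = -0.1), "non-negative")
  # success with numerically zero probability: log-scale evaluation keeps
  # the term finite (and hugely negative) rather than crashing
  p <- tibble::tibble(study_type = "human_experimental", age = 10000,
                      recovered = 1L)
  ll <- stage1_loglik(stage1_params(0.5, 0.5), p)
  expect_true(is.finite(ll) && ll < -4000)
})

test_that("half-life is the closed form log(2)/lambda", {
  expect_equal(half_life(log(2)), 1.0)
  expect_equal(round(half_life(0.1216), 2), 5.70)
  expect_error(half_life(0), "undefined")
  expect_error(half_life(-1), "undefined")
})

test_that("the half-life identity holds across a lambda and age grid", {
  for (lam in c(0.01, 0.1, 0.5, 2)) {
    t_half <- half_life(lam)
    for (v in c(0, 1, 7.5, 40)) {
      p <- function(t) 0.9 * exp(-lam * t)
      expect_lt(abs(p(v + t_half) - p(v) / 2), 1e-12)
    }
  }
})

test_that("predictions from a degenerate posterior follow the decay curve", {
  fit <- fake_stage1_fit(alpha = 0.6, lambda = 0.1)
  at0 <- predict_recovery(fit, 0, "human_experimental")
  expect_equal(at0$estimate, 0.6)
  expect_equal(at0$lower, 0.6)
  at_half <- predict_recovery(fit, log(2) / 0.1, "human_experimental")
  expect_equal(at_half$estimate, 0.3)
  # marginal prediction with identical types equals the per-type one
  expect_equal(predict_recovery(fit, 5, "marginal")$estimate,
               predict_recovery(fit, 5, "human_experimental")$estimate)
})

test_that("posterior-mean prediction decreases with age on a fitted model", {
  sim <- simulate_audit(sim_config(n_papers = 400), seed = 61)
  fit <- fit_stage1_quiet(sim$data, control = test_control(seed = 62))
  curve <- predict_recovery(fit, 0:40, "marginal")
  expect_true(all(diff(curve$estimate) < 0))
  expect_true(all(curve$estimate > 0 & curve$estimate < 1))
  expect_true(all(curve$lower <= curve$estimate &
                    curve$estimate <= curve$upper))
})

test_that("an all-failure dataset drives alpha low without crashing", {
  papers <- tibble::tibble(study_type = "human_experimental",
                           age = rep(0, 80), recovered = 0L)
  fit <- fit_stage1_quiet(papers, control = test_control(seed = 8))
  a <- mean(reproaudit:::draw_vector(fit$draws,
                                     "alpha[human_experimental]"))
  expect_lt(a, 0.15)  # posterior mass near the prior's lower range
})

test_that("types absent from the data are dropped with a warning", {
  papers <- dplyr::filter(tiny_papers(),
                          study_type == "human_experimental") |>
    dplyr::mutate(age = 2019 - pub_year,
                  recovered = as.integer(recovery_category %in%
                                           c("online", "received")))
  w <- testthat::capture_warnings(
    fit <- fit_stage1(papers, control = test_control(seed = 3, iter = 200,
                                                     warmup = 100)))
  expect_true(any(grepl("absent", w)))
  expect_equal(fit$types, "human_experimental")
})

test_that("the logistic robustness link recovers slope signs", {
  # strong decay: fitted slope should be negative
  cfg <- sim_config(n_papers = 500)
  sim <- simulate_audit(cfg, audit_truth(
    stage1 = stage1_params(0.9, 0.15)), seed = 71)
  flog <- fit_stage1_quiet(sim$data, control = test_control(seed = 72),
                           link = "logistic")
  b <- reproaudit:::draw_block(flog$draws, "^b\\[")
  expect_true(all(colMeans(b) < 0))

  # flat truth: slope interval covers zero
  flat <- simulate_audit(
    sim_config(n_papers = 500, year_range = c(1999, 2019),
               age_geom_prob = 1e-9),
    audit_truth(stage1 = stage1_params(0.5, 0)), seed = 73)
  fflat <- fit_stage1_quiet(flat$data, control = test_control(seed = 74),
                            link = "logistic")
  b1 <- reproaudit:::draw_vector(fflat$draws, "b[human_experimental]")
  iv <- hpdi(b1, 0.89)
  expect_true(iv[["lower"]] <= 0 && 0 <= iv[["upper"]])
  expect_error(half_life_table(fflat), "logistic")
})

test_that("link comparison yields two finite scores and a preferred model", {
  sim <- simulate_audit(sim_config(n_papers = 300), seed = 81)
  ctrl <- test_control(seed = 82, iter = 400, warmup = 300)
  fe <- fit_stage1_quiet(sim$data, control = ctrl)
  fl <- fit_stage1_quiet(sim$data, control = ctrl, link = "logistic")
  cmp <- compare_links(fe, fl)
  expect_equal(nrow(cmp), 2)
  expect_true(all(is.finite(cmp$waic)))
  expect_equal(sum(cmp$preferred), 1)
})

test_that("stage-1 prior predictive spans the unit interval sensibly", {
  pp <- prior_predictive("stage1", n_sims = 4000, seed = 91)
  at10 <- pp$implied$p[pp$implied$age == 10]
  expect_lt(mean(at10 > 0.9), 0.10)
  expect_lt(mean(at10 < 1e-4), 0.55)
  # prior median half-life between 1 and 3 years (lambda ~ Exp(2):
  # median half-life = log(2)/qexp(0.5, 2) = 2 exactly)
  expect_equal(log(2) / qexp(0.5, 2), 2)
  hl <- half_life(pmax(pp$params$lambda, 1e-12))
  expect_gt(median(hl), 1); expect_lt(median(hl), 3)
})
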