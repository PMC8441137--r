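#' Configuration of a synthetic audit
#'
#' Describes the design of a simulated literature audit. Defaults mirror a
#' published audit of the social-learning literature: 560 papers published
#' 1955-2018 (ages counted from a 2019 reference year), four study types
#' with a mix respecting the printed sample margins, a 40-paper
#' reproduction subsample drawn without replacement among recovered
#' papers, and 1-6 identified results per subsampled paper with median 3.
#' The age mix is a truncated geometric favouring recent years.
#'
#' @param n_papers Number of audited papers.
#' @param reference_year Year ages are counted from.
#' @param year_range Inclusive publication-year range.
#' @param age_geom_prob Success probability of the truncated-geometric age
#'   distribution (larger = younger literature). The default is solved so
#'   that, under the default truth, the marginal recovery probability
#'   matches the audited 29.8%.
#' @param type_probs Length-4 probabilities over [study_types()], summing
#'   to 1.
#' @param results_subsample Number of recovered papers selected for
#'   reproduction.
#' @param results_probs Probabilities of 1-6 identified results per
#'   subsampled paper.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_papers = 560, reference_year = 2019,
                       year_range = c(1955, 2018),
                       age_geom_prob = 0.046,
                       type_probs = c(162, 33, 284, 81) / 560,
                       results_subsample = 40,
                       results_probs = c(0.20, 0.25, 0.30, 0.10, 0.10,
                                         0.05)) {
  stopifnot(n_papers >= 1, length(year_range) == 2,
            year_range[1] <= year_range[2],
            year_range[2] <= reference_year,
            age_geom_prob > 0, age_geom_prob < 1,
            length(type_probs) == 4, all(type_probs >= 0),
            length(results_probs) == 6, all(results_probs >= 0))
  if (abs(sum(type_probs) - 1) > 1e-12) {
    stop("type_probs must sum to 1 (within 1e-12)", call. = FALSE)
  }
  if (results_subsample > n_papers) {
    stop("results_subsample cannot exceed n_papers", call. = FALSE)
  }
  structure(list(n_papers = as.integer(n_papers),
                 reference_year = as.integer(reference_year),
                 year_range = as.integer(year_range),
                 age_geom_prob = age_geom_prob,
                 type_probs = stats::setNames(type_probs, study_types()),
                 results_subsample = as.integer(results_subsample),
                 results_probs = results_probs / sum(results_probs)),
            class = "sim_config")
}

#' Generative truth for a synthetic audit
#'
#' Bundles the stage-1 decay parameters and the hierarchical stage 2-4
#' parameters used to simulate audits. Defaults encode the audited
#' literature's published estimates: per-type decay rates are
#' `log(2) / half-life` with half-lives 9.6, 6.1, 6.5 and 4.5 years;
#' recovery at publication is 0.93 for every type (solved so recent-year
#' and sample-marginal recovery match the published 68%-success year and
#' 29.8% margin); stage intercepts are solved so the marginal stage
#' probabilities equal `p2`, `p3`, `p4` given the paper-effect scale
#' `psi`.
#'
#' @param stage1 A [stage1_params()] object.
#' @param p2,p3,p4 Target marginal probabilities of the three later stages.
#' @param psi Paper-effect standard deviation(s), recycled to length 3.
#' @param phi Optional length-3 stage intercepts on the logit scale,
#'   bypassing the marginal calibration (the implied marginals are then
#'   computed from `phi` and `psi` instead).
#' @param eta,rho GP year-effect amplitude and length-scale per stage
#'   (amplitude 0 disables year effects, matching the audited finding of
#'   little to no age effect past stage 1).
#' @return An `audit_truth` list with elements `stage1` and `hier`.
#' @export
audit_truth <- function(stage1 = stage1_params(
                          alpha = 0.93,
                          lambda = log(2) / c(9.6, 6.1, 6.5, 4.5)),
                        p2 = 0.87, p3 = 0.97, p4 = 0.96,
                        psi = 1.5, eta = rep(0, 3), rho = rep(10, 3),
                        phi = NULL) {
  stopifnot(inherits(stage1, "stage1_params"),
            all(c(p2, p3, p4) > 0), all(c(p2, p3, p4) < 1))
  psi <- vctrs_recycle(psi, 3, "psi")
  if (is.null(phi)) {
    phi <- purrr::map2_dbl(c(p2, p3, p4), psi, solve_phi_for_marginal)
    marginals <- c(usable = p2, clear = p3, agree = p4)
  } else {
    phi <- vctrs_recycle(phi, 3, "phi")
    marginals <- stats::setNames(logit_normal_mean(phi, psi),
                                 stage_names())
  }
  structure(list(stage1 = stage1,
                 hier = hier_params(phi = phi, psi = psi, eta = eta,
                                    rho = rho),
                 marginals = marginals),
            class = "audit_truth")
}

# invert the logit-normal mean: find phi with E[plogis(phi + psi Z)] = p
solve_phi_for_marginal <- function(p, psi) {
  if (psi == 0) return(stats::qlogis(p))
  stats::uniroot(function(phi) logit_normal_mean(phi, psi) - p,
                 interval = c(-30, 30), tol = 1e-12)$root
}

#' Simulate a synthetic audit
#'
#' Draws a complete audit dataset from the staged generative model:
#' publication ages from the truncated-geometric mix, study types from the
#' type mix, stage-1 recovery as `Bernoulli(alpha_Y exp(-lambda_Y age))`,
#' a without-replacement reproduction subsample among recovered papers,
#' and conditional stage counts
#' `x2 ~ Bin(n, p2), x3 ~ Bin(x2, p3), x4 ~ Bin(x3, p4)` with
#' `logit(p_s) = phi_s + beta_s,paper + gamma_s,age`. Recovery categories
#' are assigned consistently with the recovered flag (online vs received,
#' and lost / no response / no request among failures, at the audited
#' sample's proportions). The latent paper and year effects are returned
#' separately so parameter-recovery studies can score them; real audits
#' never observe them.
#'
#' @param config A [sim_config()].
#' @param truth An [audit_truth()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A list with `data` (an [audit_data()] object) and `latents`
#'   (tibbles `beta` and `gamma`, plus the truth used).
#' @export
simulate_audit <- function(config = sim_config(), truth = audit_truth(),
                           seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "audit_truth"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_papers
  ages_support <- (config$reference_year - config$year_range[2]):
    (config$reference_year - config$year_range[1])
  aw <- stats::dgeom(ages_support - min(ages_support),
                     config$age_geom_prob)
  age <- sample(ages_support, n, replace = TRUE, prob = aw / sum(aw))
  type <- sample(study_types(), n, replace = TRUE,
                 prob = config$type_probs)
  p1 <- truth$stage1$alpha[type] * exp(-truth$stage1$lambda[type] * age)
  recovered <- stats::rbinom(n, 1, p1)

  # category mix consistent with the audited margins
  cat_rec <- c(online = 62, received = 105)
  cat_fail <- c(lost = 210, no_response = 158, no_request = 25)
  category <- character(n)
  category[recovered == 1] <- sample(names(cat_rec), sum(recovered),
                                     replace = TRUE,
                                     prob = cat_rec / sum(cat_rec))
  category[recovered == 0] <- sample(names(cat_fail), sum(!recovered),
                                     replace = TRUE,
                                     prob = cat_fail / sum(cat_fail))
  papers <- tibble::tibble(
    paper_id = sprintf("paper_%04d", seq_len(n)),
    pub_year = config$reference_year - age,
    study_type = type,
    recovery_category = category)

  n_rec <- sum(recovered)
  if (n_rec < config$results_subsample) {
    stop("only ", n_rec, " recovered papers but results_subsample = ",
         config$results_subsample, "; increase n_papers or recovery ",
         "probability in the truth", call. = FALSE)
  }
  sub <- sample(papers$paper_id[recovered == 1], config$results_subsample)
  sub <- sub[order(match(sub, papers$paper_id))]
  nres <- sample(1:6, length(sub), replace = TRUE,
                 prob = config$results_probs)

  h <- truth$hier
  beta <- matrix(stats::rnorm(3 * length(sub), 0, h$psi), nrow = 3)
  colnames(beta) <- sub
  sub_age <- age[match(sub, papers$paper_id)]
  grid <- sort(unique(sub_age))
  gamma <- matrix(0, 3, length(grid))
  colnames(gamma) <- grid
  for (s in 1:3) {
    if (h$eta[s] > 0) {
      K <- gp_cov(grid, h$eta[s], h$rho[s], jitter = 1e-9)
      gamma[s, ] <- drop(chol(K) %*% stats::rnorm(length(grid)))
    }
  }
  ai <- match(sub_age, grid)
  pr <- function(s) stats::plogis(h$phi[s] + beta[s, ] + gamma[s, ai])
  x2 <- stats::rbinom(length(sub), nres, pr(1))
  x3 <- stats::rbinom(length(sub), x2, pr(2))
  x4 <- stats::rbinom(length(sub), x3, pr(3))
  results <- tibble::tibble(paper_id = sub, n_results = nres,
                            n_data_usable = x2, n_analysis_clear = x3,
                            n_results_agree = x4)

  latents <- list(
    beta = tibble::tibble(paper_id = rep(sub, each = 3),
                          stage = rep(stage_names(), length(sub)),
                          beta = as.vector(beta)),
    gamma = tibble::tibble(age = rep(grid, each = 3),
                           stage = rep(stage_names(), length(grid)),
                           gamma = as.vector(gamma)),
    truth = truth)
  list(data = audit_data(papers, results,
                         reference_year = config$reference_year),
       latents = latents)
}

#' Sample-size adequacy simulation
#'
#' Repeatedly simulates reproduction subsamples of the configured size,
#' fits the stage 2-4 models, and records whether each stage's 89%
#' interval for the marginal probability covers the generative truth,
#' along with interval widths and convergence. Used to confirm that the
#' audit's subsample size gives adequate power to recover the stage
#' parameters.
#'
#' @param config A [sim_config()].
#' @param truth An [audit_truth()].
#' @param n_replicates Number of simulated audits.
#' @param control [mcmc_control()] for the replicate fits (a compact
#'   default keeps the study fast).
#' @param year_effect Passed to [fit_stages()].
#' @param mass Interval mass to score.
#' @param seed Integer seed for the whole study.
#' @return A tibble with one row per replicate x stage: `replicate`,
#'   `stage`, `truth`, `estimate`, `lower`, `upper`, `covered`, `width`,
#'   `converged`, plus the analogous `phi_truth`, `phi_estimate`,
#'   `phi_covered` for the stage intercepts on the logit scale.
#' @export
adequacy_simulation <- function(config = sim_config(),
                                truth = audit_truth(),
                                n_replicates = 20,
                                control = quick_control(),
                                year_effect = "none", mass = 0.89,
                                seed = 1) {
  stopifnot(n_replicates >= 1)
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    sim <- simulate_audit(config, truth, seed = seed + 7919L * r)
    ctrl <- control
    ctrl$seed <- seed + 104729L * r
    fit <- suppressWarnings(
      fit_stages(sim$data, control = ctrl, year_effect = year_effect))
    purrr::map_dfr(2:4, function(s) {
      tr <- truth$marginals[s - 1]
      est <- marginal_stage_prob(fit, s, mass = mass)
      phi_tr <- truth$hier$phi[s - 1]
      phi_d <- draw_vector(fit$draws,
                           paste0("phi[", stage_names()[s - 1], "]"))
      phi_iv <- hpdi(phi_d, mass)
      tibble::tibble(replicate = r, stage = s, truth = unname(tr),
                     estimate = est$estimate, lower = est$lower,
                     upper = est$upper,
                     covered = tr >= est$lower & tr <= est$upper,
                     width = est$upper - est$lower,
                     converged = !any_flagged(fit$diagnostics),
                     phi_truth = unname(phi_tr),
                     phi_estimate = mean(phi_d),
                     phi_covered = phi_tr >= phi_iv[["lower"]] &
                       phi_tr <= phi_iv[["upper"]])
    })
  })
}

#' Coverage summary of an adequacy simulation
#'
#' @param adequacy Output of [adequacy_simulation()].
#' @return A tibble per stage with empirical coverage and mean interval
#'   width.
#' @export
coverage_summary <- function(adequacy) {
  adequacy |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(n = dplyr::n(), coverage = mean(.data$covered),
                     mean_width = mean(.data$width),
                     prop_converged = mean(.data$converged))
}
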