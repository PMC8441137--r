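# Small hand-written audit fixtures and degenerate fit objects used across
# the test files. Everything is built in code at test time.

tiny_papers <- function() {
  tibble::tibble(
    paper_id = paste0("p", 1:5),
    pub_year = c(2018, 2010, 2000, 1995, 2015),
    study_type = c("human_experimental", "human_observational",
                   "nonhuman_experimental", "nonhuman_observational",
                   "human_experimental"),
    recovery_category = c("online", "online", "received", "no_response",
                          "no_response"))
}

tiny_results <- function() {
  tibble::tibble(paper_id = c("p1", "p3"),
                 n_results = c(3L, 4L),
                 n_data_usable = c(3L, 2L),
                 n_analysis_clear = c(2L, 2L),
                 n_results_agree = c(2L, 1L))
}

tiny_audit <- function() audit_data(tiny_papers(), tiny_results())

# papers table encoding the audited sample's printed margins:
# 560 papers, 62 online, 105 received, 315 informative responses
margins_papers <- function() {
  counts <- c(online = 62, received = 105, lost = 210, no_response = 158,
              no_request = 25)
  tibble::tibble(
    paper_id = sprintf("m%03d", seq_len(sum(counts))),
    pub_year = 2000L,
    study_type = "human_experimental",
    recovery_category = rep(names(counts), counts))
}

# a stage1_fit whose "posterior" is a handful of known draws, for testing
# the prediction and half-life transforms without running a sampler
fake_stage1_fit <- function(alpha, lambda, types = study_types(),
                            data = NULL, n_draws = NULL) {
  stopifnot(length(alpha) == length(lambda))
  if (is.null(n_draws)) n_draws <- max(length(alpha), 10)
  alpha <- rep_len(alpha, n_draws)
  lambda <- rep_len(lambda, n_draws)
  if (is.null(data)) {
    data <- tibble::tibble(study_type = rep(types, 2),
                           age = rep(c(1, 10), each = length(types)),
                           recovered = 1L)
  }
  rows <- purrr::map_dfr(types, function(tp) {
    tibble::tibble(
      chain = 1L, iteration = rep(seq_len(n_draws), 2),
      parameter = rep(c(paste0("alpha[", tp, "]"),
                        paste0("lambda[", tp, "]")), each = n_draws),
      value = c(alpha, lambda))
  })
  draws <- as_repro_draws(rows, model = "stage1_exponential")
  structure(list(draws = draws, diagnostics = NULL, data = data,
                 link = "exponential", priors = stage1_priors(),
                 control = mcmc_control(chains = 1, iter = n_draws),
                 types = types, fix_alpha = NULL),
            class = "stage1_fit")
}

# a stages_fit with fixed phi/psi draws and no year effect
fake_stages_fit <- function(phi, psi, ages = c(1, 10), n_draws = 10) {
  sn <- c("usable", "clear", "agree")
  results <- tibble::tibble(paper_id = c("p1", "p2"),
                            n_results = c(3L, 3L),
                            n_data_usable = c(3L, 3L),
                            n_analysis_clear = c(3L, 3L),
                            n_results_agree = c(3L, 3L))
  rows <- purrr::map_dfr(1:3, function(s) {
    dplyr::bind_rows(
      tibble::tibble(chain = 1L, iteration = seq_len(n_draws),
                     parameter = paste0("phi[", sn[s], "]"),
                     value = rep(phi[s], n_draws)),
      tibble::tibble(chain = 1L, iteration = seq_len(n_draws),
                     parameter = paste0("psi[", sn[s], "]"),
                     value = rep(psi[s], n_draws)),
      purrr::map_dfr(c("p1", "p2"), function(p)
        tibble::tibble(chain = 1L, iteration = seq_len(n_draws),
                       parameter = paste0("beta[", sn[s], ",", p, "]"),
                       value = 0)))
  })
  draws <- as_repro_draws(rows, model = "stages")
  structure(list(draws = draws, diagnostics = NULL, results = results,
                 ages = stats::setNames(ages, c("p1", "p2")),
                 age_grid = sort(unique(ages)),
                 priors = stages_priors(),
                 control = mcmc_control(chains = 1, iter = n_draws),
                 year_effect = "none", denominator = "conditional"),
            class = "stages_fit")
}

# sampler settings compact enough for simulation studies in the tests
test_control <- function(seed = NULL, chains = 2, iter = 600,
                         warmup = 400, adapt = 300) {
  mcmc_control(chains = chains, iter = iter, warmup = warmup,
               adapt = adapt, seed = seed)
}

# quiet wrapper: short-chain fits legitimately warn about diagnostics
fit_stage1_quiet <- function(...) suppressWarnings(fit_stage1(...))
fit_stages_quiet <- function(...) suppressWarnings(fit_stages(...))
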