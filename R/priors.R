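#' Priors for the stage-1 recovery models
#'
#' Regularising priors for the exponential-decay recovery model (and its
#' logistic-link robustness variant), validated by [prior_predictive()]:
#' recovery-at-publication `alpha ~ Beta(2, 2)` keeps mass away from 0 and
#' 1; decay rate `lambda ~ Exponential(2)` implies a prior median half-life
#' of about 1.4 years with a heavy right tail; the logistic link uses
#' `a ~ Normal(0, 1.5)` and age slope `b ~ Normal(0, 0.5)`.
#'
#' @param alpha_shape1,alpha_shape2 Beta shape parameters for `alpha`.
#' @param lambda_rate Exponential rate for `lambda` (per year).
#' @param a_mean,a_sd,b_mean,b_sd Normal priors for the logistic link.
#' @return An object of class `stage1_priors`.
#' @export
stage1_priors <- function(alpha_shape1 = 2, alpha_shape2 = 2,
                          lambda_rate = 2, a_mean = 0, a_sd = 1.5,
                          b_mean = 0, b_sd = 0.5) {
  stopifnot(alpha_shape1 > 0, alpha_shape2 > 0, lambda_rate > 0,
            a_sd > 0, b_sd > 0)
  structure(list(alpha_shape1 = alpha_shape1, alpha_shape2 = alpha_shape2,
                 lambda_rate = lambda_rate, a_mean = a_mean, a_sd = a_sd,
                 b_mean = b_mean, b_sd = b_sd),
            class = "stage1_priors")
}

#' Priors for the hierarchical stage 2-4 models
#'
#' Stage intercepts `phi_s ~ Normal(phi_mean, phi_sd)` on the logit scale
#' (the default scale 2.5 lets stages be near-certain, as audit stages
#' often are, while still regularising; prior-predictively the implied
#' stage probability keeps under 5% of its mass beyond 0.99);
#' paper-effect scale `psi_s ~ Exponential(psi_rate)`; Gaussian-process
#' year-effect amplitude `eta_s ~ Exponential(eta_rate)` and length-scale
#' `rho_s ~ LogNormal(rho_meanlog, rho_sdlog)` (default centred on a
#' decade, so the year effect is smooth over decade scales).
#'
#' @param phi_mean,phi_sd Normal prior for the stage intercepts.
#' @param psi_rate Exponential rate for the paper-effect scale.
#' @param eta_rate Exponential rate for the GP amplitude.
#' @param rho_meanlog,rho_sdlog Log-normal prior for the GP length-scale in
#'   years.
#' @return An object of class `stages_priors`.
#' @export
stages_priors <- function(phi_mean = 0, phi_sd = 2.5, psi_rate = 1,
                          eta_rate = 1, rho_meanlog = log(10),
                          rho_sdlog = 0.5) {
  stopifnot(phi_sd > 0, psi_rate > 0, eta_rate > 0, rho_sdlog > 0)
  structure(list(phi_mean = phi_mean, phi_sd = phi_sd, psi_rate = psi_rate,
                 eta_rate = eta_rate, rho_meanlog = rho_meanlog,
                 rho_sdlog = rho_sdlog),
            class = "stages_priors")
}

#' Prior-predictive simulation
#'
#' Draws parameters from the priors and propagates them to observable
#' scales, to check that the priors imply plausible data before any fitting:
#' for the stage-1 models the implied recovery probability across a grid of
#' publication ages, for the stage 2-4 models the implied marginal stage
#' probability (paper effects integrated out).
#'
#' @param model One of `"stage1"`, `"stage1_logistic"`, `"stages"`.
#' @param priors A [stage1_priors()] or [stages_priors()] object matching
#'   `model` (defaults used when `NULL`).
#' @param n_sims Number of prior draws.
#' @param ages Integer grid of publication ages for the stage-1 curves.
#' @param seed Optional seed.
#' @return A list of class `prior_predictive` with tibbles `params`
#'   (one row per simulation) and `implied` (implied probabilities).
#' @export
prior_predictive <- function(model = c("stage1", "stage1_logistic",
                                       "stages"),
                             priors = NULL, n_sims = 1000, ages = 0:40,
                             seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (model %in% c("stage1", "stage1_logistic")) {
    if (is.null(priors)) priors <- stage1_priors()
    stopifnot(inherits(priors, "stage1_priors"))
    if (model == "stage1") {
      params <- tibble::tibble(
        sim = seq_len(n_sims),
        alpha = stats::rbeta(n_sims, priors$alpha_shape1,
                             priors$alpha_shape2),
        lambda = stats::rexp(n_sims, priors$lambda_rate))
      implied <- tidyr::crossing(params, age = ages) |>
        dplyr::mutate(p = .data$alpha * exp(-.data$lambda * .data$age)) |>
        dplyr::select("sim", "age", "p")
    } else {
      params <- tibble::tibble(
        sim = seq_len(n_sims),
        a = stats::rnorm(n_sims, priors$a_mean, priors$a_sd),
        b = stats::rnorm(n_sims, priors$b_mean, priors$b_sd))
      implied <- tidyr::crossing(params, age = ages) |>
        dplyr::mutate(p = stats::plogis(.data$a + .data$b * .data$age)) |>
        dplyr::select("sim", "age", "p")
    }
  } else {
    if (is.null(priors)) priors <- stages_priors()
    stopifnot(inherits(priors, "stages_priors"))
    params <- tibble::tibble(
      sim = seq_len(n_sims),
      phi = stats::rnorm(n_sims, priors$phi_mean, priors$phi_sd),
      psi = stats::rexp(n_sims, priors$psi_rate))
    implied <- dplyr::mutate(params,
                             p = logit_normal_mean(.data$phi, .data$psi)) |>
      dplyr::select("sim", "p")
  }
  structure(list(model = model, params = params, implied = implied),
            class = "prior_predictive")
}

#' @export
print.prior_predictive <- function(x, ...) {
  cat("<prior_predictive> model:", x$model, "-", nrow(x$params),
      "prior draws\n")
  q <- stats::quantile(x$implied$p, c(0.05, 0.5, 0.95))
  cat("implied probability quantiles (5/50/95%):",
      paste(signif(q, 3), collapse = " / "), "\n")
  invisible(x)
}
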