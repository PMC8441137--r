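stage_names <- function() c("usable", "clear", "agree")

#' Parameters of the hierarchical stage 2-4 models
#'
#' For each of the three conditional stages s (data usability, analytical
#' clarity, results consistency), the per-paper success probability is
#' `plogis(phi[s] + beta[s, paper] + gamma[s, age])` with paper effects
#' `beta ~ Normal(0, psi[s])` and a Gaussian-process prior over the
#' age-specific effects `gamma` (squared-exponential kernel with marginal
#' standard deviation `eta[s]` and length-scale `rho[s]` in years).
#'
#' @param phi Length-3 numeric, stage intercepts on the logit scale.
#' @param psi Length-3 non-negative, paper-effect standard deviations.
#' @param beta Optional 3 x n_papers matrix of paper effects (rows =
#'   stages; column names = paper ids).
#' @param gamma Optional 3 x n_ages matrix of age effects.
#' @param ages Ages (columns of `gamma`).
#' @param eta,rho Length-3 GP amplitude (>= 0) and length-scale (> 0).
#' @return A `hier_params` list.
#' @export
hier_params <- function(phi, psi, beta = NULL, gamma = NULL, ages = NULL,
                        eta = rep(0, 3), rho = rep(10, 3)) {
  phi <- vctrs_recycle(phi, 3, "phi")
  psi <- vctrs_recycle(psi, 3, "psi")
  eta <- vctrs_recycle(eta, 3, "eta")
  rho <- vctrs_recycle(rho, 3, "rho")
  if (any(psi < 0) || any(eta < 0)) {
    stop("psi and eta must be non-negative", call. = FALSE)
  }
  if (any(rho <= 0)) stop("rho must be positive", call. = FALSE)
  if (!is.null(beta) && (!is.matrix(beta) || nrow(beta) != 3)) {
    stop("beta must be a 3 x n_papers matrix", call. = FALSE)
  }
  if (!is.null(gamma)) {
    if (!is.matrix(gamma) || nrow(gamma) != 3) {
      stop("gamma must be a 3 x n_ages matrix", call. = FALSE)
    }
    if (is.null(ages) || length(ages) != ncol(gamma)) {
      stop("ages must accompany gamma, one per column", call. = FALSE)
    }
  }
  structure(list(phi = stats::setNames(phi, stage_names()),
                 psi = stats::setNames(psi, stage_names()),
                 beta = beta, gamma = gamma, ages = ages,
                 eta = stats::setNames(eta, stage_names()),
                 rho = stats::setNames(rho, stage_names())),
            class = "hier_params")
}

#' Squared-exponential Gaussian-process covariance
#'
#' `K[i, j] = amplitude^2 * exp(-(v_i - v_j)^2 / (2 * lengthscale^2))`
#' plus `jitter` on the diagonal, over a grid of distinct ages.
#'
#' @param ages Distinct numeric ages.
#' @param amplitude Marginal standard deviation (>= 0).
#' @param lengthscale Smoothness in years (> 0).
#' @param jitter Non-negative diagonal stabiliser.
#' @return A symmetric positive semi-definite matrix.
#' @export
gp_cov <- function(ages, amplitude, lengthscale, jitter = 1e-8) {
  if (anyDuplicated(ages)) {
    stop("ages must be distinct (collapse duplicates upstream)",
         call. = FALSE)
  }
  stopifnot(amplitude >= 0, lengthscale > 0, jitter >= 0)
  d <- outer(ages, ages, "-")
  amplitude^2 * exp(-d^2 / (2 * lengthscale^2)) +
    jitter * diag(length(ages))
}

#' Log-likelihood of the conditional stage models
#'
#' Sum over papers of the three conditional binomial terms:
#' `x2 ~ Binomial(n, p2)`, `x3 ~ Binomial(x2, p3)`,
#' `x4 ~ Binomial(x3, p4)`, each success probability
#' `plogis(phi_s + beta_s,i + gamma_s,age(i))`. Later-stage terms vanish
#' when their denominator is zero. Nesting of the counts is validated
#' before evaluation.
#'
#' @param params A [hier_params()] object with `beta` (and `gamma` when any
#'   `eta > 0`) supplied; missing paper/age effects are treated as zero.
#' @param results Results tibble (columns `paper_id`, `n_results`,
#'   `n_data_usable`, `n_analysis_clear`, `n_results_agree`).
#' @param ages Named vector mapping `paper_id` to age.
#' @return Scalar log-likelihood.
#' @export
stages_loglik <- function(params, results, ages) {
  stopifnot(inherits(params, "hier_params"))
  results <- check_columns(results, c("paper_id", "n_results",
                                      "n_data_usable", "n_analysis_clear",
                                      "n_results_agree"), "results")
  mono <- with(results, n_results_agree <= n_analysis_clear &
                 n_analysis_clear <= n_data_usable &
                 n_data_usable <= n_results & n_results_agree >= 0)
  if (any(!mono)) {
    stop("stage counts violate monotone nesting for paper '",
         results$paper_id[!mono][1], "'", call. = FALSE)
  }
  if (!all(results$paper_id %in% names(ages))) {
    stop("ages missing for some result papers", call. = FALSE)
  }
  a <- ages[results$paper_id]
  eff <- function(s) {
    b <- if (!is.null(params$beta)) params$beta[s, results$paper_id] else 0
    g <- if (!is.null(params$gamma)) {
      params$gamma[s, match(a, params$ages)]
    } else 0
    params$phi[s] + b + g
  }
  x <- cbind(results$n_data_usable, results$n_analysis_clear,
             results$n_results_agree)
  size <- cbind(results$n_results, results$n_data_usable,
                results$n_analysis_clear)
  ll <- 0
  for (s in 1:3) {
    p <- stats::plogis(eff(s))
    keep <- size[, s] > 0
    ll <- ll + sum(stats::dbinom(x[keep, s], size[keep, s], p[keep],
                                 log = TRUE))
  }
  ll
}

#' Fit the hierarchical stage 2-4 models
#'
#' Fits the three conditional binomial models jointly by MCMC, with
#' independent intercepts, paper-effect scales and (optionally) GP year
#' effects per stage. Draws are reported on the natural scale with
#' parameters named `phi[usable]`, `psi[clear]`, `beta[agree,<paper>]`,
#' `gamma[usable,<age>]`, `eta[...]`, `rho[...]`.
#'
#' @param results Results tibble or an `audit_data` object (in which case
#'   ages are taken from its papers table).
#' @param ages Named `paper_id -> age` vector (ignored when `results` is an
#'   `audit_data`).
#' @param priors A [stages_priors()] object.
#' @param control An [mcmc_control()] object.
#' @param year_effect `"gp"` for the Gaussian-process age smoother,
#'   `"none"` to omit age effects.
#' @param denominator `"conditional"` (each stage among survivors of the
#'   previous, the primary model) or `"total"` (every stage out of
#'   `n_results`, a sensitivity variant).
#' @param jitter Diagonal stabiliser for the GP covariance.
#' @return A `stages_fit` object.
#' @export
fit_stages <- function(results, ages = NULL, priors = stages_priors(),
                       control = mcmc_control(),
                       year_effect = c("gp", "none"),
                       denominator = c("conditional", "total"),
                       jitter = 1e-6) {
  year_effect <- match.arg(year_effect)
  denominator <- match.arg(denominator)
  if (inherits(results, "audit_data")) {
    ages <- paper_ages(results)
    results <- results$results
  }
  results <- check_columns(results, c("paper_id", "n_results",
                                      "n_data_usable", "n_analysis_clear",
                                      "n_results_agree"), "results")
  stopifnot(inherits(priors, "stages_priors"),
            inherits(control, "mcmc_control"))
  if (nrow(results) < 2) {
    stop("at least 2 papers are required (paper effects are ",
         "unidentifiable from a single paper)", call. = FALSE)
  }
  if (is.null(ages) || !all(results$paper_id %in% names(ages))) {
    stop("ages must be supplied for every result paper", call. = FALSE)
  }
  v <- unname(ages[results$paper_id])
  grid <- sort(unique(v))
  ai <- match(v, grid)

  np <- nrow(results)
  x2 <- results$n_data_usable
  x3 <- results$n_analysis_clear
  x4 <- results$n_results_agree
  d2 <- results$n_results
  d3 <- if (denominator == "conditional") x2 else results$n_results
  d4 <- if (denominator == "conditional") x3 else results$n_results
  idx3 <- which(d3 > 0); idx4 <- which(d4 > 0)

  # Non-centred parameterisation throughout: beta = psi * z and
  # gamma = eta * L(rho) z with standard-normal z. The centred form leaves
  # the scale parameters frozen when the data inform the effects weakly;
  # non-centring restores mixing. The GP length-scale is sampled on a
  # quantile grid of its log-normal prior so the Cholesky factors of the
  # correlation matrices can be precomputed once and passed as data.
  gp_lines <- if (year_effect == "gp") paste0(
    "  ridx[s] ~ dcat(pg)\n",
    "  rho[s] <- rho_grid[ridx[s]]\n",
    "  for (j in 1:M) { zg[j,s] ~ dnorm(0, 1) }\n",
    "  g[1:M,s] <- eta[s] * (Lmat[1:M,1:M,ridx[s]] %*% zg[1:M,s])\n",
    "  eta[s] ~ dexp(eta_rate)\n")
  else ""

  model <- paste0(
    "model {\n",
    "for (i in 1:Np) {\n",
    "  x2[i] ~ dbin(p2[i], d2[i])\n",
    "  logit(p2[i]) <- phi[1] + beta[1,i]", gterm(year_effect, 1), "\n",
    "  logit(p3[i]) <- phi[2] + beta[2,i]", gterm(year_effect, 2), "\n",
    "  logit(p4[i]) <- phi[3] + beta[3,i]", gterm(year_effect, 3), "\n",
    "  for (s in 1:3) {\n",
    "    zb[s,i] ~ dnorm(0, 1)\n",
    "    beta[s,i] <- psi[s] * zb[s,i]\n",
    "  }\n",
    "}\n",
    if (length(idx3)) "for (i3 in 1:N3) { x3[idx3[i3]] ~ dbin(p3[idx3[i3]], d3[idx3[i3]]) }\n" else "",
    if (length(idx4)) "for (i4 in 1:N4) { x4[idx4[i4]] ~ dbin(p4[idx4[i4]], d4[idx4[i4]]) }\n" else "",
    "for (s in 1:3) {\n",
    "  phi[s] ~ dnorm(phi_mean, 1 / (phi_sd * phi_sd))\n",
    "  psi[s] ~ dexp(psi_rate)\n",
    gp_lines,
    "}\n",
    "}\n")

  dat <- list(Np = np, x2 = x2, d2 = d2, d3 = d3, d4 = d4,
              phi_mean = priors$phi_mean, phi_sd = priors$phi_sd,
              psi_rate = priors$psi_rate)
  if (length(idx3)) { dat$idx3 <- idx3; dat$N3 <- length(idx3); dat$x3 <- x3 }
  if (length(idx4)) { dat$idx4 <- idx4; dat$N4 <- length(idx4); dat$x4 <- x4 }
  monitors <- c("phi", "psi", "beta")
  if (year_effect == "gp") {
    ngrid <- 25
    rho_grid <- stats::qlnorm((seq_len(ngrid) - 0.5) / ngrid,
                              priors$rho_meanlog, priors$rho_sdlog)
    lmat <- vapply(rho_grid, function(r) {
      t(chol(gp_cov(grid, 1, r, jitter = jitter)))
    }, matrix(0, length(grid), length(grid)))
    dat$M <- length(grid); dat$ai <- ai
    dat$rho_grid <- rho_grid; dat$pg <- rep(1 / ngrid, ngrid)
    dat$Lmat <- lmat
    dat$eta_rate <- priors$eta_rate
    monitors <- c(monitors, "g", "eta", "rho")
  }

  draws <- run_jags(model, dat, monitors, control, model_label = "stages")
  draws$parameter <- rename_stage_params(draws$parameter,
                                         results$paper_id, grid)
  attr(draws, "model") <- "stages"
  diagnostics <- diagnose(draws)
  fit <- structure(
    list(draws = draws, diagnostics = diagnostics, results = results,
         ages = stats::setNames(v, results$paper_id), age_grid = grid,
         priors = priors, control = control, year_effect = year_effect,
         denominator = denominator),
    class = "stages_fit")
  if (any_flagged(diagnostics)) {
    warning("stage 2-4 fit has flagged parameters (see $diagnostics); ",
            "treat results as non-converged", call. = FALSE)
  }
  fit
}

gterm <- function(year_effect, s) {
  if (year_effect == "gp") paste0(" + g[ai[i],", s, "]") else ""
}

rename_stage_params <- function(params, paper_ids, grid) {
  sn <- stage_names()
  out <- params
  # phi[1] -> phi[usable]; psi, eta, rho likewise
  for (nm in c("phi", "psi", "eta", "rho")) {
    pat <- paste0("^", nm, "\\[(\\d+)\\]$")
    hit <- grepl(pat, params)
    idx <- as.integer(sub(pat, "\\1", params[hit]))
    out[hit] <- paste0(nm, "[", sn[idx], "]")
  }
  # beta[s,i] -> beta[stage,paper]
  pat <- "^beta\\[(\\d+),(\\d+)\\]$"
  hit <- grepl(pat, params)
  s <- as.integer(sub(pat, "\\1", params[hit]))
  i <- as.integer(sub(pat, "\\2", params[hit]))
  out[hit] <- paste0("beta[", sn[s], ",", paper_ids[i], "]")
  # g[j,s] -> gamma[stage,age]
  pat <- "^g\\[(\\d+),(\\d+)\\]$"
  hit <- grepl(pat, params)
  j <- as.integer(sub(pat, "\\1", params[hit]))
  s <- as.integer(sub(pat, "\\2", params[hit]))
  out[hit] <- paste0("gamma[", sn[s], ",", grid[j], "]")
  out
}

# cached Gauss-Hermite rule
gh_env <- new.env(parent = emptyenv())
gh_rule <- function(n = 127) {
  key <- as.character(n)
  if (is.null(gh_env[[key]])) {
    gh_env[[key]] <- statmod::gauss.quad(n, kind = "hermite")
  }
  gh_env[[key]]
}

#' Mean of a logit-normal distribution
#'
#' `E[plogis(mu + sigma * Z)]` for standard-normal `Z`, by Gauss-Hermite
#' quadrature (127 nodes; absolute error below 1e-6 for `sigma <= 4`).
#' Vectorised over `mu` and `sigma`.
#'
#' @param mu Location(s) on the logit scale.
#' @param sigma Standard deviation(s), non-negative.
#' @return Numeric vector of means in (0, 1).
#' @export
logit_normal_mean <- function(mu, sigma) {
  stopifnot(all(sigma >= 0))
  gq <- gh_rule()
  k <- length(mu)
  sigma <- rep_len(sigma, k)
  # outer: k x nodes
  z <- outer(sigma * sqrt(2), gq$nodes)
  out <- drop(stats::plogis(mu + z) %*% gq$weights) / sqrt(pi)
  pmin(pmax(out, 0), 1)  # quadrature round-off can overshoot by ~1e-16
}

#' Marginal stage probability
#'
#' The population-level probability of passing one reproduction stage:
#' for each posterior draw, the paper effect is integrated out over
#' `Normal(0, psi_s)` (Gauss-Hermite quadrature) and the year effect is
#' averaged over an age distribution. The default `"population"` method
#' describes a new paper from the population; `"sample"` averages the
#' fitted papers' own effects instead.
#'
#' @param fit A `stages_fit`.
#' @param stage Stage number 2, 3 or 4 (data usability, analytical
#'   clarity, results consistency).
#' @param age_weights Optional named vector of weights over the fitted age
#'   grid; defaults to the empirical age distribution of the fitted papers.
#' @param method `"population"` or `"sample"`.
#' @param mass Interval mass.
#' @param draws If `TRUE` return the per-draw probabilities.
#' @return A one-row tibble `stage`, `estimate`, `lower`, `upper` (or a
#'   draws vector).
#' @export
marginal_stage_prob <- function(fit, stage, age_weights = NULL,
                                method = c("population", "sample"),
                                mass = 0.89, draws = FALSE) {
  stopifnot(inherits(fit, "stages_fit"), stage %in% 2:4)
  method <- match.arg(method)
  d <- stage_prob_draws(fit, stage, age_weights, method)
  if (draws) return(d)
  iv <- hpdi(d, mass)
  tibble::tibble(stage = stage, estimate = mean(d), lower = iv[["lower"]],
                 upper = iv[["upper"]])
}

stage_prob_draws <- function(fit, stage, age_weights = NULL,
                             method = "population") {
  sn <- stage_names()[stage - 1]
  phi <- draw_vector(fit$draws, paste0("phi[", sn, "]"))
  gmat <- gamma_draw_matrix(fit, sn)   # draws x ages (zero when no GP)
  w <- age_weight_vector(fit, age_weights)
  if (method == "population") {
    psi <- draw_vector(fit$draws, paste0("psi[", sn, "]"))
    p <- vapply(seq_along(fit$age_grid), function(j) {
      logit_normal_mean(phi + gmat[, j], psi)
    }, numeric(length(phi)))
    drop(p %*% w)
  } else {
    bmat <- draw_block(fit$draws, paste0("^beta\\[", sn, ","))
    ai <- match(fit$ages, fit$age_grid)
    p <- stats::plogis(phi + bmat + gmat[, ai, drop = FALSE])
    rowMeans(p)
  }
}

gamma_draw_matrix <- function(fit, sn) {
  nd <- length(draw_vector(fit$draws, paste0("phi[", sn, "]")))
  if (fit$year_effect == "none") {
    return(matrix(0, nd, length(fit$age_grid)))
  }
  vapply(fit$age_grid, function(a) {
    draw_vector(fit$draws, paste0("gamma[", sn, ",", a, "]"))
  }, numeric(nd))
}

age_weight_vector <- function(fit, age_weights) {
  if (is.null(age_weights)) {
    w <- as.numeric(table(factor(fit$ages, fit$age_grid)))
  } else {
    w <- rep(0, length(fit$age_grid))
    idx <- match(as.numeric(names(age_weights)), fit$age_grid)
    if (anyNA(idx)) stop("age_weights must be named by fitted ages",
                         call. = FALSE)
    w[idx] <- age_weights
  }
  w / sum(w)
}

#' @export
print.stages_fit <- function(x, ...) {
  cat("<stages_fit> ", nrow(x$results), " papers, ",
      sum(x$results$n_results), " results; year effect: ", x$year_effect,
      "; denominators: ", x$denominator, "\n", sep = "")
  if (any_flagged(x$diagnostics)) {
    cat("WARNING:", sum(x$diagnostics$flagged),
        "parameters flagged by diagnostics\n")
  }
  keep <- grepl("^(phi|psi|eta|rho)\\[", draw_params(x$draws))
  print(dplyr::filter(tidy.stages_fit(x),
                      .data$term %in% draw_params(x$draws)[keep]))
  invisible(x)
}

#' @method tidy stages_fit
#' @export
tidy.stages_fit <- function(x, mass = 0.89, ...) {
  summarise_draws_tbl(x$draws, x$diagnostics, mass)
}

#' @method glance stages_fit
#' @export
glance.stages_fit <- function(x, ...) {
  tibble::tibble(n_papers = nrow(x$results),
                 n_results = sum(x$results$n_results),
                 year_effect = x$year_effect,
                 denominator = x$denominator,
                 chains = x$control$chains,
                 draws = length(draw_vector(x$draws, "phi[usable]")),
                 max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
                 min_ess = min(x$diagnostics$ess),
                 converged = !any_flagged(x$diagnostics))
}
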