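#' Parameters of the exponential-decay recovery model
#'
#' Per study type: `alpha`, the probability that a paper's data can be
#' recovered at the moment of publication, and `lambda`, the yearly decay
#' rate, so that the recovery probability at age `v` is
#' `alpha * exp(-lambda * v)`.
#'
#' @param alpha Numeric vector of recovery probabilities at age 0, strictly
#'   inside (0, 1); recycled to and named by [study_types()].
#' @param lambda Numeric vector of non-negative decay rates per year.
#' @return A `stage1_params` list.
#' @export
stage1_params <- function(alpha, lambda) {
  types <- study_types()
  alpha <- vctrs_recycle(alpha, length(types), "alpha")
  lambda <- vctrs_recycle(lambda, length(types), "lambda")
  if (any(alpha <= 0 | alpha >= 1)) {
    stop("alpha must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(lambda < 0)) stop("lambda must be non-negative", call. = FALSE)
  structure(list(alpha = stats::setNames(alpha, types),
                 lambda = stats::setNames(lambda, types)),
            class = "stage1_params")
}

vctrs_recycle <- function(x, n, what) {
  if (length(x) == 1) x <- rep(x, n)
  if (length(x) != n) {
    stop("`", what, "` must have length 1 or ", n, call. = FALSE)
  }
  as.double(x)
}

#' Log-likelihood of the recovery model
#'
#' Bernoulli log-likelihood of the recovery outcomes under
#' `p_i = alpha[type_i] * exp(-lambda[type_i] * age_i)`. Outcomes that are
#' impossible under the parameters (probability numerically 0 with a
#' success, or 1 with a failure) give `-Inf` rather than an error.
#'
#' @param params A [stage1_params()] object.
#' @param papers Papers tibble (from an `audit_data` object) with columns
#'   `study_type`, `age`, `recovered`.
#' @return Scalar log-likelihood.
#' @export
stage1_loglik <- function(params, papers) {
  stopifnot(inherits(params, "stage1_params"))
  papers <- check_columns(papers, c("study_type", "age", "recovered"),
                          "papers")
  if (any(papers$age < 0)) stop("ages must be non-negative", call. = FALSE)
  a <- params$alpha[papers$study_type]
  l <- params$lambda[papers$study_type]
  if (anyNA(a)) stop("unknown study_type in papers", call. = FALSE)
  logp <- log(a) - l * papers$age
  p <- exp(logp)
  x <- papers$recovered
  ll <- ifelse(x == 1, logp, log1p(-p))
  if (any(!is.finite(ll))) return(-Inf)
  sum(ll)
}

#' Fit the stage-1 data-recovery model
#'
#' Fits the exponential-decay recovery model (or the logistic-link
#' robustness variant) by MCMC, one `alpha`/`lambda` (or intercept/slope)
#' pair per study type present in the data. Study types absent from the
#' data are dropped with a warning. A convergence report
#' ([diagnose()]) is attached; flagged parameters mark the fit as
#' non-converged but are never silently discarded.
#'
#' @param papers Papers tibble, or an `audit_data` object.
#' @param priors A [stage1_priors()] object.
#' @param control An [mcmc_control()] object.
#' @param link `"exponential"` (decay model) or `"logistic"`.
#' @param fix_alpha Optional named numeric vector fixing `alpha` for some or
#'   all study types (exponential link only), used e.g. to reduce the model
#'   to the one-parameter decay problem.
#' @return A `stage1_fit` object with elements `draws` (a `repro_draws`
#'   tibble with parameters like `alpha[human_experimental]`),
#'   `diagnostics`, `data`, `link`, `priors`, `control`, `types`.
#' @export
fit_stage1 <- function(papers, priors = stage1_priors(),
                       control = mcmc_control(), link = c("exponential",
                                                          "logistic"),
                       fix_alpha = NULL) {
  link <- match.arg(link)
  if (inherits(papers, "audit_data")) papers <- papers$papers
  papers <- check_columns(papers, c("study_type", "age", "recovered"),
                          "papers")
  stopifnot(inherits(priors, "stage1_priors"),
            inherits(control, "mcmc_control"))
  types <- study_types()[study_types() %in% unique(papers$study_type)]
  if (!length(types)) stop("no known study types in data", call. = FALSE)
  dropped <- setdiff(study_types(), types)
  if (length(dropped)) {
    warning("study type(s) absent from data, dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  ty <- match(papers$study_type, types)
  dat <- list(x = papers$recovered, v = papers$age, ty = ty,
              N = nrow(papers), K = length(types))

  if (link == "exponential") {
    alpha_line <- "alpha[k] ~ dbeta(a1, a2)"
    if (!is.null(fix_alpha)) {
      fixed <- rep(NA_real_, length(types))
      names(fixed) <- types
      fixed[names(fix_alpha)] <- fix_alpha
      if (all(!is.na(fixed))) {
        alpha_line <- ""
        dat$alpha <- unname(fixed)
      } else {
        stop("fix_alpha must cover every study type present in the data",
             call. = FALSE)
      }
    }
    model <- paste0(
      "model {\n",
      "  for (i in 1:N) {\n",
      "    x[i] ~ dbern(alpha[ty[i]] * exp(-lam[ty[i]] * v[i]))\n",
      "  }\n",
      "  for (k in 1:K) {\n",
      "    ", alpha_line, "\n",
      "    lam[k] ~ dexp(lr)\n",
      "  }\n",
      "}\n")
    dat$lr <- priors$lambda_rate
    if (is.null(dat$alpha)) {
      dat$a1 <- priors$alpha_shape1; dat$a2 <- priors$alpha_shape2
    }
    monitors <- c(if (is.null(dat$alpha)) "alpha", "lam")
  } else {
    model <- paste0(
      "model {\n",
      "  for (i in 1:N) {\n",
      "    x[i] ~ dbern(p[i])\n",
      "    logit(p[i]) <- a[ty[i]] + b[ty[i]] * v[i]\n",
      "  }\n",
      "  for (k in 1:K) {\n",
      "    a[k] ~ dnorm(am, 1 / (asd * asd))\n",
      "    b[k] ~ dnorm(bm, 1 / (bsd * bsd))\n",
      "  }\n",
      "}\n")
    dat$am <- priors$a_mean; dat$asd <- priors$a_sd
    dat$bm <- priors$b_mean; dat$bsd <- priors$b_sd
    monitors <- c("a", "b")
  }

  draws <- run_jags(model, dat, monitors, control,
                    model_label = paste0("stage1_", link))
  draws$parameter <- rename_indexed(draws$parameter,
                                    c(alpha = "alpha", lam = "lambda",
                                      a = "a", b = "b"), types)
  attr(draws, "model") <- paste0("stage1_", link)
  diagnostics <- diagnose(draws)
  fit <- structure(
    list(draws = draws, diagnostics = diagnostics, data = papers,
         link = link, priors = priors, control = control, types = types,
         fix_alpha = fix_alpha),
    class = "stage1_fit")
  if (any_flagged(diagnostics)) {
    warning("stage-1 fit has flagged parameters (see $diagnostics); ",
            "treat results as non-converged", call. = FALSE)
  }
  fit
}

# turn JAGS names like "lam[2]" into "lambda[human_observational]";
# single-type models monitor scalars, which JAGS names without an index
rename_indexed <- function(params, map, types) {
  base <- sub("\\[.*", "", params)
  idx <- suppressWarnings(as.integer(sub(".*\\[(\\d+)\\].*", "\\1", params)))
  idx[is.na(idx) & base %in% names(map)] <- 1L
  out <- params
  has <- base %in% names(map) & !is.na(idx)
  out[has] <- paste0(map[base[has]], "[", types[idx[has]], "]")
  out
}

#' Data half-life
#'
#' The time over which the expected probability of recovering a paper's
#' data halves under the exponential-decay model: `log(2) / lambda`. Only
#' defined for strictly positive decay rates (the logistic-link model has
#' no constant half-life).
#'
#' @param lambda Decay rate(s) per year, strictly positive.
#' @return Half-life in years, same length as `lambda`.
#' @export
half_life <- function(lambda) {
  if (any(lambda <= 0)) {
    stop("half-life is undefined for lambda <= 0 (no constant half-life)",
         call. = FALSE)
  }
  log(2) / lambda
}

#' Predicted probability of data recovery
#'
#' Evaluates the posterior predicted recovery probability at given
#' publication ages, per study type or marginalised over the fitted
#' sample's study-type mix. Point estimate is the posterior mean; the
#' interval is the narrowest 89% interval ([hpdi()]).
#'
#' @param fit A `stage1_fit`.
#' @param ages Non-negative ages (years since publication).
#' @param study_type A type from [study_types()], or `"marginal"` to
#'   average over the sample's type mix.
#' @param mass Interval probability mass.
#' @return A tibble with columns `age`, `study_type`, `estimate`, `lower`,
#'   `upper`.
#' @export
predict_recovery <- function(fit, ages, study_type = "marginal",
                             mass = 0.89) {
  stopifnot(inherits(fit, "stage1_fit"), all(ages >= 0))
  purrr::map_dfr(ages, function(a) {
    d <- recovery_draws(fit, a, study_type)
    iv <- hpdi(d, mass)
    tibble::tibble(age = a, study_type = study_type, estimate = mean(d),
                   lower = iv[["lower"]], upper = iv[["upper"]])
  })
}

# posterior draws of p(recovery) at one age, for a type or the sample's mix
recovery_draws <- function(fit, age, study_type = "marginal") {
  if (study_type == "marginal") {
    wts <- table(factor(fit$data$study_type, fit$types))
    wts <- as.numeric(wts) / sum(wts)
    ps <- vapply(fit$types, function(tp) recovery_draws_type(fit, age, tp),
                 numeric(n_total_draws(fit)))
    as.vector(ps %*% wts)
  } else {
    recovery_draws_type(fit, age, study_type)
  }
}

recovery_draws_type <- function(fit, age, type) {
  if (!type %in% fit$types) {
    stop("study type '", type, "' was not in the fitted data",
         call. = FALSE)
  }
  if (fit$link == "exponential") {
    a <- alpha_draws(fit, type)
    l <- draw_vector(fit$draws, paste0("lambda[", type, "]"))
    a * exp(-l * age)
  } else {
    a <- draw_vector(fit$draws, paste0("a[", type, "]"))
    b <- draw_vector(fit$draws, paste0("b[", type, "]"))
    stats::plogis(a + b * age)
  }
}

alpha_draws <- function(fit, type) {
  if (!is.null(fit$fix_alpha)) {
    rep(fit$fix_alpha[[type]], n_total_draws(fit))
  } else {
    draw_vector(fit$draws, paste0("alpha[", type, "]"))
  }
}

n_total_draws <- function(fit) {
  p1 <- draw_params(fit$draws)[1]
  sum(fit$draws$parameter == p1)
}

#' Recovery probability pooled over the audited sample
#'
#' The marginal probability that a paper drawn from the audited sample has
#' recoverable data: the decay curve averaged draw-wise over the empirical
#' (age, study type) pairs of the fitted papers.
#'
#' @inheritParams predict_recovery
#' @param draws If `TRUE` return the vector of posterior draws instead of
#'   the summary tibble.
#' @return A one-row tibble `estimate`, `lower`, `upper` (or a numeric
#'   vector of draws).
#' @export
pooled_recovery <- function(fit, mass = 0.89, draws = FALSE) {
  stopifnot(inherits(fit, "stage1_fit"))
  dat <- dplyr::count(fit$data, .data$study_type, .data$age)
  ps <- matrix(0, n_total_draws(fit), nrow(dat))
  for (i in seq_len(nrow(dat))) {
    ps[, i] <- recovery_draws_type(fit, dat$age[i], dat$study_type[i])
  }
  d <- as.vector(ps %*% (dat$n / sum(dat$n)))
  if (draws) return(d)
  iv <- hpdi(d, mass)
  tibble::tibble(estimate = mean(d), lower = iv[["lower"]],
                 upper = iv[["upper"]])
}

#' Compare the exponential and logistic recovery links
#'
#' Computes WAIC (widely applicable information criterion) for the
#' exponential-decay fit and the logistic-link robustness fit on their
#' common data, and labels the preferred (lower-WAIC) model.
#'
#' @param fit_exp,fit_log `stage1_fit` objects for the two links, fitted to
#'   the same papers.
#' @return A tibble with one row per model: `model`, `elpd`, `p_waic`,
#'   `waic`, `se_waic`, `preferred`.
#' @export
compare_links <- function(fit_exp, fit_log) {
  stopifnot(inherits(fit_exp, "stage1_fit"),
            inherits(fit_log, "stage1_fit"))
  if (nrow(fit_exp$data) != nrow(fit_log$data)) {
    stop("fits must be on the same data", call. = FALSE)
  }
  w <- dplyr::bind_rows(waic_stage1(fit_exp), waic_stage1(fit_log))
  w$preferred <- w$waic == min(w$waic)
  w
}

# pointwise log-likelihood matrix (draws x papers) -> WAIC
waic_stage1 <- function(fit) {
  papers <- fit$data
  nd <- n_total_draws(fit)
  ll <- matrix(0, nd, nrow(papers))
  for (tp in fit$types) {
    rows <- which(papers$study_type == tp)
    for (i in rows) {
      p <- recovery_draws_type(fit, papers$age[i], tp)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      ll[, i] <- stats::dbinom(papers$recovered[i], 1, p, log = TRUE)
    }
  }
  lppd_i <- apply(ll, 2, function(v) matrixStats_logmeanexp(v))
  p_i <- apply(ll, 2, stats::var)
  waic_i <- -2 * (lppd_i - p_i)
  tibble::tibble(model = paste0("stage1_", fit$link),
                 elpd = sum(lppd_i - p_i), p_waic = sum(p_i),
                 waic = sum(waic_i),
                 se_waic = sqrt(length(waic_i) * stats::var(waic_i)))
}

matrixStats_logmeanexp <- function(v) {
  m <- max(v)
  m + log(mean(exp(v - m)))
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat("<stage1_fit> link:", x$link, "-", nrow(x$data), "papers,",
      length(x$types), "study types\n")
  cat("chains:", x$control$chains, " draws/chain:", x$control$iter, "\n")
  if (any_flagged(x$diagnostics)) {
    cat("WARNING:", sum(x$diagnostics$flagged),
        "parameters flagged by diagnostics\n")
  }
  print(tidy.stage1_fit(x))
  invisible(x)
}

#' @method tidy stage1_fit
#' @export
tidy.stage1_fit <- function(x, mass = 0.89, ...) {
  summarise_draws_tbl(x$draws, x$diagnostics, mass)
}

#' @method glance stage1_fit
#' @export
glance.stage1_fit <- function(x, ...) {
  tibble::tibble(link = x$link, nobs = nrow(x$data),
                 n_types = length(x$types),
                 chains = x$control$chains,
                 draws = n_total_draws(x),
                 max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
                 min_ess = min(x$diagnostics$ess),
                 converged = !any_flagged(x$diagnostics))
}

summarise_draws_tbl <- function(draws, diagnostics, mass = 0.89) {
  purrr::map_dfr(draw_params(draws), function(p) {
    v <- draw_vector(draws, p)
    iv <- hpdi(v, mass)
    tibble::tibble(term = p, estimate = mean(v),
                   std.error = stats::sd(v),
                   conf.low = iv[["lower"]], conf.high = iv[["upper"]])
  }) |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(diagnostics),
                    term = "parameter", "rhat", "ess"),
      by = "term")
}
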