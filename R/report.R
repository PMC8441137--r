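#' Combined reproducibility rate
#'
#' The probability that a result of a randomly chosen paper reproduces:
#' the product of the four stage probabilities, each conditional on passing
#' all previous stages. Scalars give a scalar; equal-length draw vectors
#' are multiplied draw-wise to propagate posterior uncertainty (scalars
#' recycle against vectors).
#'
#' @param p1,p2,p3,p4 Stage probabilities in \[0, 1\], scalars or draw
#'   vectors of a common length.
#' @return Scalar or draw vector of the combined rate.
#' @export
combined_rate <- function(p1, p2, p3, p4) {
  ps <- list(p1, p2, p3, p4)
  lens <- lengths(ps)
  if (length(unique(lens[lens > 1])) > 1) {
    stop("draw vectors must have equal length (got ",
         paste(lens, collapse = ", "), ")", call. = FALSE)
  }
  if (any(vapply(ps, function(p) any(p < 0 | p > 1), logical(1)))) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  p1 * p2 * p3 * p4
}

#' Per-type and pooled data half-lives
#'
#' Applies [half_life()] draw-wise to each study type's decay rate, and
#' computes a pooled half-life per draw as the time at which the
#' type-mixture recovery curve (weighted by the fitted sample's type mix)
#' falls to half its age-0 value. Only defined for the exponential link.
#'
#' @param fit A `stage1_fit` with `link = "exponential"`.
#' @param mass Interval mass.
#' @return A tibble with columns `study_type` (types plus `"pooled"`),
#'   `estimate`, `lower`, `upper` in years.
#' @export
half_life_table <- function(fit, mass = 0.89) {
  stopifnot(inherits(fit, "stage1_fit"))
  if (fit$link != "exponential") {
    stop("half-lives require the exponential link (the logistic model ",
         "has no constant half-life)", call. = FALSE)
  }
  rows <- purrr::map_dfr(fit$types, function(tp) {
    hl <- half_life(draw_vector(fit$draws, paste0("lambda[", tp, "]")))
    iv <- hpdi(hl, mass)
    tibble::tibble(study_type = tp, estimate = mean(hl),
                   lower = iv[["lower"]], upper = iv[["upper"]])
  })
  pooled <- pooled_half_life_draws(fit)
  iv <- hpdi(pooled, mass)
  dplyr::bind_rows(rows,
                   tibble::tibble(study_type = "pooled",
                                  estimate = mean(pooled),
                                  lower = iv[["lower"]],
                                  upper = iv[["upper"]]))
}

# per draw: solve mix(t) = mix(0) / 2 for the sample-weighted mixture curve
pooled_half_life_draws <- function(fit) {
  wts <- table(factor(fit$data$study_type, fit$types))
  wts <- as.numeric(wts) / sum(wts)
  am <- vapply(fit$types, function(tp) alpha_draws(fit, tp),
               numeric(n_total_draws(fit)))
  lm_ <- vapply(fit$types, function(tp)
    draw_vector(fit$draws, paste0("lambda[", tp, "]")),
    numeric(n_total_draws(fit)))
  vapply(seq_len(nrow(am)), function(d) {
    c0 <- sum(wts * am[d, ])
    f <- function(t) sum(wts * am[d, ] * exp(-lm_[d, ] * t)) - c0 / 2
    if (all(lm_[d, ] <= 0)) return(Inf)
    stats::uniroot(f, c(1e-6, 1e4))$root
  }, numeric(1))
}

#' Overall success rate by publication year
#'
#' Combines the stage-1 decay posterior and the stage 2-4 posterior into
#' the probability that a result of a paper published in a given year
#' reproduces: the type-marginal recovery probability at the matching age,
#' times the three conditional stage probabilities evaluated at the same
#' age (paper effects integrated out), multiplied draw-wise and summarised
#' with the narrowest interval.
#'
#' @param stage1_fit A `stage1_fit`.
#' @param stages_fit A `stages_fit`.
#' @param years Calendar year(s) to evaluate.
#' @param reference_year Year ages are counted from.
#' @param mass Interval mass.
#' @return A tibble `year`, `age`, `estimate`, `lower`, `upper`.
#' @export
success_by_year <- function(stage1_fit, stages_fit, years, reference_year,
                            mass = 0.89) {
  stopifnot(inherits(stage1_fit, "stage1_fit"),
            inherits(stages_fit, "stages_fit"))
  if (any(years > reference_year)) {
    stop("years must not exceed the reference year", call. = FALSE)
  }
  fitted_years <- reference_year - range(stage1_fit$data$age)
  if (any(years < min(fitted_years)) || any(years > max(fitted_years))) {
    warning("some years fall outside the fitted publication range (",
            min(fitted_years), "-", max(fitted_years),
            "); predictions are extrapolations", call. = FALSE)
  }
  purrr::map_dfr(years, function(y) {
    age <- reference_year - y
    d <- success_draws_at_age(stage1_fit, stages_fit, age)
    iv <- hpdi(d, mass)
    tibble::tibble(year = y, age = age, estimate = mean(d),
                   lower = iv[["lower"]], upper = iv[["upper"]])
  })
}

success_draws_at_age <- function(stage1_fit, stages_fit, age) {
  p1 <- recovery_draws(stage1_fit, age, "marginal")
  # stage draws at the matching year effect: weight entirely on this age
  # (or the nearest fitted age when the GP grid does not contain it)
  grid <- stages_fit$age_grid
  nearest <- grid[which.min(abs(grid - age))]
  w <- stats::setNames(1, nearest)
  p234 <- lapply(2:4, function(s)
    marginal_stage_prob(stages_fit, s, age_weights = w, draws = TRUE))
  n <- min(length(p1), lengths(p234))
  combined_rate(p1[seq_len(n)], p234[[1]][seq_len(n)],
                p234[[2]][seq_len(n)], p234[[3]][seq_len(n)])
}

#' Summary report of a full audit analysis
#'
#' Combines the two fitted models into the audit's headline quantities:
#' the four stage probabilities (stage 1 pooled over the sample's ages
#' and types; stages 2-4 marginal over paper effects and the sample's
#' ages), the combined reproducibility rate `p_r` computed draw-wise, the
#' half-life table, and the overall success rate by publication year.
#'
#' @param stage1_fit A `stage1_fit`.
#' @param stages_fit A `stages_fit` (or `NULL` for a stage-1-only report).
#' @param reference_year Year ages are counted from.
#' @param years Years for the by-year decomposition (default: the fitted
#'   range, most recent 25 years at most).
#' @param mass Interval mass.
#' @return An `audit_report` object: list of tibbles `stage_probs`,
#'   `half_lives`, `by_year`, a `converged` flag and metadata.
#' @export
audit_report <- function(stage1_fit, stages_fit = NULL, reference_year,
                         years = NULL, mass = 0.89) {
  stopifnot(inherits(stage1_fit, "stage1_fit"))
  p1 <- pooled_recovery(stage1_fit, draws = TRUE)
  summarise_p <- function(d, label) {
    iv <- hpdi(d, mass)
    tibble::tibble(quantity = label, estimate = mean(d),
                   lower = iv[["lower"]], upper = iv[["upper"]])
  }
  stage_probs <- summarise_p(p1, "p1_recovery")
  by_year <- NULL
  flagged <- any_flagged(stage1_fit$diagnostics)
  if (!is.null(stages_fit)) {
    stopifnot(inherits(stages_fit, "stages_fit"))
    p234 <- lapply(2:4, function(s)
      marginal_stage_prob(stages_fit, s, draws = TRUE))
    n <- min(length(p1), lengths(p234))
    pr <- combined_rate(p1[seq_len(n)], p234[[1]][seq_len(n)],
                        p234[[2]][seq_len(n)], p234[[3]][seq_len(n)])
    stage_probs <- dplyr::bind_rows(
      stage_probs,
      summarise_p(p234[[1]], "p2_usability"),
      summarise_p(p234[[2]], "p3_clarity"),
      summarise_p(p234[[3]], "p4_agreement"),
      summarise_p(pr, "p_r_combined"))
    if (is.null(years)) {
      yr_max <- reference_year - min(stage1_fit$data$age)
      years <- seq(max(reference_year - max(stage1_fit$data$age),
                       yr_max - 24), yr_max)
    }
    by_year <- success_by_year(stage1_fit, stages_fit, years,
                               reference_year, mass = mass)
    flagged <- flagged || any_flagged(stages_fit$diagnostics)
  }
  structure(
    list(stage_probs = stage_probs,
         half_lives = if (stage1_fit$link == "exponential")
           half_life_table(stage1_fit, mass = mass) else NULL,
         by_year = by_year,
         reference_year = reference_year,
         mass = mass,
         converged = !flagged,
         stage1_fit = stage1_fit, stages_fit = stages_fit),
    class = "audit_report")
}

#' @export
print.audit_report <- function(x, force = FALSE, ...) {
  if (!x$converged && !force) {
    cat("<audit_report> NOT CONVERGED: diagnostics flagged parameters.\n")
    cat("Inspect $stage1_fit$diagnostics / $stages_fit$diagnostics;\n")
    cat("print(report, force = TRUE) to display summaries anyway.\n")
    return(invisible(x))
  }
  cat("Reproducibility audit report (", round(100 * x$mass),
      "% narrowest intervals)\n", sep = "")
  sp <- x$stage_probs
  for (i in seq_len(nrow(sp))) {
    cat(sprintf("  %-14s %.2f (%.2f-%.2f)\n", sp$quantity[i],
                sp$estimate[i], sp$lower[i], sp$upper[i]))
  }
  if (!is.null(x$half_lives)) {
    cat("Data half-life (years):\n")
    hl <- x$half_lives
    for (i in seq_len(nrow(hl))) {
      cat(sprintf("  %-24s %.1f (%.1f-%.1f)\n", hl$study_type[i],
                  hl$estimate[i], hl$lower[i], hl$upper[i]))
    }
  }
  if (!is.null(x$by_year)) {
    recent <- utils::tail(x$by_year, 1)
    cat(sprintf("Overall success in %d: %.2f (%.2f-%.2f)\n", recent$year,
                recent$estimate, recent$lower, recent$upper))
  }
  invisible(x)
}

#' @method tidy audit_report
#' @export
tidy.audit_report <- function(x, ...) {
  out <- dplyr::bind_rows(
    dplyr::rename(x$stage_probs, term = "quantity"),
    dplyr::transmute(x$half_lives,
                     term = paste0("half_life_", .data$study_type),
                     estimate = .data$estimate, lower = .data$lower,
                     upper = .data$upper))
  if (!is.null(x$by_year)) {
    out <- dplyr::bind_rows(
      out,
      dplyr::transmute(x$by_year, term = paste0("p_r_", .data$year),
                       estimate = .data$estimate, lower = .data$lower,
                       upper = .data$upper))
  }
  out
}

#' Run the full audit pipeline
#'
#' One-call orchestration: read (or simulate) the audit tables, fit the
#' stage-1 decay model, fit the stage 2-4 hierarchical models, run
#' diagnostics, and assemble the [audit_report()]. With an output
#' directory, the input tables, posterior draws (flat CSV), diagnostics
#' and a machine-readable `summary.json` (with the seed and configuration
#' echoed) are written out.
#'
#' @param config A list, or path to a YAML file, with (all optional)
#'   entries: `papers`/`results` (input CSV paths), `reference_year`,
#'   `simulate` (a list of [sim_config()] arguments used when no input
#'   paths are given), `seed`, `chains`, `iter`, `warmup`, `adapt`,
#'   `year_effect`, `out_dir`.
#' @return An `audit_report`; its `converged` field is `FALSE` when any
#'   diagnostic flagged (summaries then refuse to print without
#'   `force = TRUE`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  reference_year <- config$reference_year %||% 2019L
  control <- mcmc_control(chains = config$chains %||% 4,
                          iter = config$iter %||% 2500,
                          warmup = config$warmup %||% 2500,
                          adapt = config$adapt %||% 1000,
                          seed = seed)
  if (!is.null(config$papers)) {
    message("reading audit tables")
    ds <- read_audit(config$papers, config$results,
                     reference_year = reference_year)
  } else {
    message("simulating a synthetic audit")
    sc <- do.call(sim_config, config$simulate %||% list())
    reference_year <- sc$reference_year
    ds <- simulate_audit(sc, audit_truth(), seed = seed)$data
  }
  message("fitting stage 1 (data recovery, exponential decay)")
  f1 <- fit_stage1(ds, control = control)
  f234 <- NULL
  if (nrow(ds$results) >= 2) {
    message("fitting stages 2-4 (usability, clarity, agreement)")
    f234 <- fit_stages(ds, control = control,
                       year_effect = config$year_effect %||% "gp")
  } else {
    message("no (or too few) results rows: stage-1-only report")
  }
  message("assembling report")
  rep <- audit_report(f1, f234, reference_year = reference_year)

  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_audit(ds, file.path(out_dir, "papers.csv"),
                file.path(out_dir, "results.csv"))
    write_draws(f1$draws, file.path(out_dir, "post_stage1.csv"))
    readr::write_csv(tibble::as_tibble(f1$diagnostics),
                     file.path(out_dir, "diagnostics_stage1.csv"),
                     progress = FALSE)
    if (!is.null(f234)) {
      write_draws(f234$draws, file.path(out_dir, "post_stages.csv"))
      readr::write_csv(tibble::as_tibble(f234$diagnostics),
                       file.path(out_dir, "diagnostics_stages.csv"),
                       progress = FALSE)
    }
    summary <- list(seed = seed, reference_year = reference_year,
                    control = unclass(control),
                    converged = rep$converged,
                    stage_probs = rep$stage_probs,
                    half_lives = rep$half_lives,
                    by_year = rep$by_year)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  rep
}

`%||%` <- function(a, b) if (is.null(a)) b else a
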