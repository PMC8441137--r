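#' Rank-normalised split-chain R-hat
#'
#' Convergence diagnostic computed as the maximum of the bulk and the
#' tail-folded rank-normalised split potential-scale-reduction statistic:
#' chains are split in half, all draws are replaced by normal scores of
#' their pooled ranks, and the classic between/within variance ratio is
#' computed on the scores (and again on scores of the absolute deviations
#' from the median, which is sensitive to tail non-mixing). Values near 1
#' indicate mixed chains; the package flags parameters above 1.01.
#'
#' @param x Draws for one parameter: a matrix (iterations x chains) or a
#'   list of equal-length numeric vectors, with at least 2 chains of at
#'   least 4 draws.
#' @return A scalar; `NA_real_` for constant draws (not applicable).
#' @export
rhat <- function(x) {
  m <- chains_matrix(x)
  if (ncol(m) < 2) stop("rhat needs at least 2 chains", call. = FALSE)
  if (nrow(m) < 4) stop("rhat needs at least 4 draws per chain",
                        call. = FALSE)
  if (max(m) - min(m) < .Machine$double.eps * 100) return(NA_real_)
  bulk <- rhat_basic(z_scale(split_chains(m)))
  folded <- rhat_basic(z_scale(split_chains(abs(m - stats::median(m)))))
  max(bulk, folded)
}

#' Effective sample size
#'
#' Autocorrelation-adjusted number of draws, computed on rank-normalised
#' split chains with the initial-monotone-sequence truncation of the summed
#' autocorrelations. Approximately the total draw count for independent
#' draws, and much smaller for sticky chains; capped at the total number of
#' draws (antithetic chains can otherwise exceed it).
#'
#' @inheritParams rhat
#' @return A non-negative scalar; 0 for constant draws.
#' @export
ess <- function(x) {
  m <- chains_matrix(x)
  if (nrow(m) < 4) stop("ess needs at least 4 draws per chain",
                        call. = FALSE)
  if (max(m) - min(m) < .Machine$double.eps * 100) return(0)
  z <- z_scale(split_chains(m))
  n <- nrow(z); k <- ncol(z)
  acov <- vapply(seq_len(k), function(j) {
    a <- stats::acf(z[, j], lag.max = n - 1, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  }, numeric(n))
  mean_acov <- rowMeans(acov)
  w <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- w * (n - 1) / n
  if (k > 1) var_plus <- var_plus + stats::var(colMeans(z))
  rho <- 1 - (w - mean_acov) / var_plus
  # Geyer pairs: truncate at first negative pair, enforce monotonicity
  max_pairs <- floor(n / 2) - 1
  tau <- 0; prev <- Inf
  for (p in 0:max_pairs) {
    pair <- rho[2 * p + 1] + if (2 * p + 2 <= n) rho[2 * p + 2] else 0
    if (p > 0 && pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + pair
    prev <- pair
  }
  tau <- max(2 * tau - 1, 1 / log10(n * k + 1))
  min(n * k / tau, nrow(m) * ncol(m))
}

chains_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    len <- lengths(x)
    if (length(unique(len)) != 1) {
      stop("all chains must have the same length", call. = FALSE)
    }
    x <- vapply(x, as.numeric, numeric(len[1]))
  }
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (!is.matrix(x)) stop("draws must be a matrix or list of vectors",
                          call. = FALSE)
  x
}

split_chains <- function(m) {
  n <- nrow(m)
  h <- floor(n / 2)
  m <- m[(n - 2 * h + 1):n, , drop = FALSE]  # drop first draw if odd
  cbind(m[1:h, , drop = FALSE], m[(h + 1):(2 * h), , drop = FALSE])
}

z_scale <- function(m) {
  r <- rank(as.vector(m), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(m), ncol = ncol(m))
}

rhat_basic <- function(m) {
  n <- nrow(m); k <- ncol(m)
  w <- mean(apply(m, 2, stats::var))
  b_over_n <- stats::var(colMeans(m))
  sqrt((n - 1) / n + b_over_n / w)
}

#' Highest-posterior-density interval
#'
#' The narrowest contiguous interval containing the requested probability
#' mass: among all windows of `ceiling(mass * N)` consecutive sorted draws,
#' the one with minimal width (ties broken toward the lower interval).
#'
#' @param x Numeric vector of draws.
#' @param mass Probability mass, default 0.89.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(x, mass = 0.89) {
  if (!length(x)) stop("empty draws", call. = FALSE)
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)", call. = FALSE)
  n <- length(x)
  if (n * mass < 1) stop("too few draws for requested mass", call. = FALSE)
  sx <- sort(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(lower = sx[1], upper = sx[n]))
  starts <- seq_len(n - k + 1)
  widths <- sx[starts + k - 1] - sx[starts]
  i <- which.min(widths)  # which.min takes the first minimum: lower window
  c(lower = sx[i], upper = sx[i + k - 1])
}

#' Convergence report for a set of posterior draws
#'
#' Computes [rhat()] and [ess()] for every parameter and flags those
#' exceeding the thresholds (or with non-applicable diagnostics). Purely a
#' function of the draws: identical input gives an identical report.
#'
#' @param draws A `repro_draws` tibble.
#' @param rhat_threshold Flag parameters with R-hat above this (default
#'   1.01).
#' @param ess_threshold Flag parameters with fewer effective draws than
#'   this (default 400).
#' @return A `repro_diagnostics` tibble with columns `parameter`, `rhat`,
#'   `ess`, `flagged`.
#' @export
diagnose <- function(draws, rhat_threshold = 1.01, ess_threshold = 400) {
  stopifnot(inherits(draws, "repro_draws"))
  n_chains <- length(unique(draws$chain))
  pars <- draw_params(draws)
  out <- purrr::map_dfr(pars, function(p) {
    m <- draw_matrix(draws, p)
    r <- if (n_chains >= 2) rhat(m) else NA_real_
    tibble::tibble(parameter = p, rhat = r, ess = ess(m))
  })
  out <- dplyr::mutate(
    out,
    flagged = is.na(.data$rhat) | .data$rhat > rhat_threshold |
      .data$ess < ess_threshold)
  if (n_chains < 2) {
    warning("fewer than 2 chains: R-hat is not defined; parameters flagged",
            call. = FALSE)
    out$flagged <- TRUE
  }
  structure(out, class = c("repro_diagnostics", class(out)),
            rhat_threshold = rhat_threshold, ess_threshold = ess_threshold)
}

#' @rdname diagnose
#' @param report A `repro_diagnostics` object.
#' @export
any_flagged <- function(report) {
  stopifnot(inherits(report, "repro_diagnostics"))
  any(report$flagged)
}

#' @export
print.repro_diagnostics <- function(x, ...) {
  cat("MCMC diagnostics (", nrow(x), " parameters): ",
      sum(x$flagged), " flagged (R-hat > ",
      attr(x, "rhat_threshold"), " or ESS < ", attr(x, "ess_threshold"),
      ")\n", sep = "")
  worst <- dplyr::arrange(tibble::as_tibble(x), dplyr::desc(.data$rhat))
  print(utils::head(worst, 5))
  invisible(x)
}
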