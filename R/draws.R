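#' MCMC sampler settings
#'
#' Settings for the JAGS backend used by [fit_stage1()] and [fit_stages()].
#' The reporting default follows common practice for published audits:
#' 4 chains of 2500 retained draws each (10 000 summarised draws), after
#' adaptation and warm-up.
#'
#' @param chains Number of chains (>= 2 required for split R-hat).
#' @param iter Retained (post-warmup) iterations per chain.
#' @param warmup Warm-up iterations per chain, discarded.
#' @param adapt Adaptation steps for the sampler.
#' @param thin Thinning interval.
#' @param seed Integer seed; chain RNGs are derived deterministically from
#'   it so a fit is reproducible end-to-end.
#' @return An object of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, iter = 2500, warmup = 2500,
                         adapt = 1000, thin = 1, seed = NULL) {
  stopifnot(chains >= 1, iter >= 1, warmup >= 0, adapt >= 0, thin >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), adapt = as.integer(adapt),
                 thin = as.integer(thin),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "mcmc_control")
}

# Compact settings for simulation studies and examples.
quick_control <- function(chains = 2, iter = 750, warmup = 400, adapt = 300,
                          seed = NULL) {
  mcmc_control(chains = chains, iter = iter, warmup = warmup, adapt = adapt,
               seed = seed)
}

# deterministic per-chain JAGS RNG initialisation from one integer seed
jags_inits <- function(control) {
  seed <- if (is.null(control$seed)) sample.int(.Machine$integer.max, 1)
          else control$seed
  lapply(seq_len(control$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed + 104729L * ch) %% 2147483647L)
  })
}

# Run a JAGS model and return draws in the long layout.
run_jags <- function(model_string, data, monitors, control, model_label) {
  inits <- jags_inits(control)
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = control$chains,
                          n.adapt = control$adapt, quiet = TRUE)
  if (control$warmup > 0) {
    stats::update(jm, n.iter = control$warmup, progress.bar = "none")
  }
  samp <- rjags::coda.samples(jm, variable.names = monitors,
                              n.iter = control$iter * control$thin,
                              thin = control$thin, progress.bar = "none")
  as_repro_draws(samp, model = model_label, control = control)
}

#' Posterior draws in a tidy long layout
#'
#' Converts sampler output (a `coda::mcmc.list` or a data frame already in
#' long form) into the package's draw container: a tibble with columns
#' `chain`, `iteration`, `parameter`, `value` and class `repro_draws`.
#' All chains must have the same number of iterations.
#'
#' @param x Sampler output.
#' @param model Model label stored with the draws.
#' @param control Optional [mcmc_control()] stored with the draws.
#' @return A `repro_draws` tibble.
#' @export
as_repro_draws <- function(x, model = "model", control = NULL) {
  if (inherits(x, "mcmc.list")) {
    out <- purrr::imap_dfr(x, function(ch, i) {
      m <- as.matrix(ch)
      tibble::tibble(chain = as.integer(i),
                     iteration = rep(seq_len(nrow(m)), ncol(m)),
                     parameter = rep(colnames(m), each = nrow(m)),
                     value = as.vector(m))
    })
  } else if (is.data.frame(x)) {
    out <- check_columns(x, c("chain", "iteration", "parameter", "value"),
                         "draws")
    out <- dplyr::mutate(out, chain = as.integer(.data$chain),
                         iteration = as.integer(.data$iteration),
                         parameter = as.character(.data$parameter),
                         value = as.double(.data$value))
  } else {
    stop("cannot convert object of class ", class(x)[1], " to repro_draws",
         call. = FALSE)
  }
  per <- dplyr::count(out, .data$chain, .data$parameter)
  if (length(unique(per$n)) > 1) {
    stop("all chains must contain the same number of iterations per ",
         "parameter", call. = FALSE)
  }
  structure(out, class = c("repro_draws", class(tibble::tibble())),
            model = model, control = control)
}

# parameter -> matrix(iterations x chains)
draw_matrix <- function(draws, parameter) {
  d <- draws[draws$parameter == parameter, , drop = FALSE]
  if (!nrow(d)) stop("no draws for parameter '", parameter, "'",
                     call. = FALSE)
  chains <- sort(unique(d$chain))
  vapply(chains, function(ch) d$value[d$chain == ch],
         numeric(sum(d$chain == chains[1])))
}

# pooled vector of draws for one parameter (chains concatenated, in chain
# then iteration order, so element i of two parameters belongs to the same
# posterior draw)
draw_vector <- function(draws, parameter) {
  d <- draws[draws$parameter == parameter, , drop = FALSE]
  if (!nrow(d)) stop("no draws for parameter '", parameter, "'",
                     call. = FALSE)
  d <- d[order(d$chain, d$iteration), ]
  d$value
}

draw_params <- function(draws) unique(draws$parameter)

# draws (chains pooled, aligned) for all parameters matching a regex, as a
# matrix with one column per parameter
draw_block <- function(draws, pattern) {
  pars <- grep(pattern, draw_params(draws), value = TRUE)
  if (!length(pars)) stop("no parameters match '", pattern, "'",
                          call. = FALSE)
  vapply(pars, function(p) draw_vector(draws, p),
         numeric(sum(draws$parameter == pars[1])))
}

#' Write or read posterior draws as a delimited table
#'
#' The on-disk layout is one row per (chain, iteration, parameter) with the
#' drawn value, a flat CSV that round-trips through [read_draws()].
#'
#' @param draws A `repro_draws` tibble.
#' @param path Output path.
#' @return `draws` invisibly (write) or a `repro_draws` tibble (read).
#' @export
write_draws <- function(draws, path) {
  readr::write_csv(tibble::as_tibble(draws), path, progress = FALSE)
  invisible(draws)
}

#' @rdname write_draws
#' @param model Model label to attach on read.
#' @export
read_draws <- function(path, model = "model") {
  as_repro_draws(readr::read_csv(path, show_col_types = FALSE,
                                 progress = FALSE), model = model)
}
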