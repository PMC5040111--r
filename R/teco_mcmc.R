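# Bayesian inversion of the six-pool carbon model by random-walk
# Metropolis-Hastings: uniform priors within bounds, Gaussian observation
# likelihood per data stream (heterotrophic respiration, aboveground
# biomass).

#' Log posterior of carbon-model parameters
#'
#' Uniform log prior within the parameter bounds (-Inf outside) plus a
#' Gaussian log likelihood of the residuals per observation stream with
#' stream-specific error standard deviations. A zero observation sd is
#' floored at 1e-8 to keep the density proper.
#'
#' @param params a [teco_parameters()] object, or a named/plain numeric vector
#'   of the seven parameters in canonical order.
#' @param drivers driver data frame (see [simulate_teco()]).
#' @param obs observation set: list with `rh` and `agb` data frames (`day`,
#'   `value`) and noise sds `sd_rh`, `sd_agb`, as produced by
#'   [generate_teco_dataset()].
#' @param initial,tref,alloc,resp_frac forward-model configuration.
#' @param bounds bounds matrix used for the uniform prior when `params` is a
#'   plain vector.
#' @return log posterior density (up to a constant); `-Inf` signals an
#'   out-of-bounds proposal.
#' @export
log_posterior <- function(params, drivers, obs,
                          initial = default_initial_state(), tref = 10,
                          alloc = c(foliage = 0.45, root = 0.55),
                          resp_frac = 0.55,
                          bounds = default_teco_bounds()) {
  if (inherits(params, "teco_parameters")) {
    v <- params$values
    bounds <- params$bounds
  } else {
    v <- as.numeric(params)
    if (length(v) != 7) stop("expected 7 parameters")
    names(v) <- TECO_PARAM_NAMES
  }
  if (is.null(obs$rh) && is.null(obs$agb)) stop("observation set is empty")
  if (any(v < bounds[, 1] | v > bounds[, 2])) return(-Inf)
  traj <- simulate_teco(params_from_vector(v, bounds), drivers,
                        initial = initial, tref = tref, alloc = alloc,
                        resp_frac = resp_frac)
  ll <- 0
  if (!is.null(obs$rh) && nrow(obs$rh) > 0) {
    sd_rh <- max(obs$sd_rh, 1e-8)
    idx <- match(obs$rh$day, drivers$day)
    ll <- ll + sum(dnorm(obs$rh$value - traj$rh[idx], sd = sd_rh, log = TRUE))
  }
  if (!is.null(obs$agb) && nrow(obs$agb) > 0) {
    sd_agb <- max(obs$sd_agb, 1e-8)
    idx <- match(obs$agb$day, drivers$day)
    ll <- ll + sum(dnorm(obs$agb$value - traj$agb[idx], sd = sd_agb,
                         log = TRUE))
  }
  ll
}

# Generic random-walk Metropolis-Hastings sampler in a bounded box.
# Independent Gaussian steps per coordinate; out-of-bounds proposals are
# rejected (uniform prior truncation). When `adapt` is TRUE the proposal is
# tuned during burn-in only (then frozen, so the post-burn-in chain is a
# valid fixed-kernel MH chain): every `adapt_interval` steps the
# per-coordinate scales are refreshed from the sample standard deviations of
# the recent window (diagonal adaptive Metropolis, 2.4/sqrt(d) factor) and a
# global factor nudges the realized acceptance toward `target_acceptance`.
mh_sample <- function(log_post_fn, init, lower, upper, scales, n_steps,
                      burn_in, seed = 1L, adapt = TRUE, adapt_interval = 200L,
                      target_acceptance = 0.3) {
  d <- length(init)
  stopifnot(length(lower) == d, length(upper) == d, length(scales) == d,
            n_steps > burn_in)
  with_seed(seed, {
    samples <- matrix(NA_real_, nrow = n_steps, ncol = d)
    log_posts <- numeric(n_steps)
    cur <- init
    cur_lp <- log_post_fn(cur)
    if (!is.finite(cur_lp)) stop("initial point has zero posterior density")
    accepted <- 0L
    window_acc <- 0L
    global_factor <- 1
    for (i in seq_len(n_steps)) {
      prop <- cur + rnorm(d) * scales
      if (all(prop >= lower & prop <= upper)) {
        prop_lp <- log_post_fn(prop)
        if (is.finite(prop_lp) && log(runif(1)) < prop_lp - cur_lp) {
          cur <- prop
          cur_lp <- prop_lp
          accepted <- accepted + 1L
          window_acc <- window_acc + 1L
        }
      }
      samples[i, ] <- cur
      log_posts[i] <- cur_lp
      if (adapt && i <= burn_in && i %% adapt_interval == 0L) {
        rate <- window_acc / adapt_interval
        global_factor <- global_factor * exp(rate - target_acceptance)
        win <- samples[seq(i - adapt_interval + 1L, i), , drop = FALSE]
        sdw <- apply(win, 2, sd)
        use <- is.finite(sdw) & sdw > 0
        scales[use] <- 2.4 / sqrt(d) * sdw[use] * global_factor
        scales[!use] <- scales[!use] * exp(rate - target_acceptance)
        window_acc <- 0L
      }
    }
    list(samples = samples, log_posteriors = log_posts,
         acceptance_rate = accepted / n_steps, accepted = accepted,
         scales = scales)
  })
}

#' MCMC configuration for the carbon-model inversion
#'
#' @param n_steps total chain length.
#' @param burn_in steps discarded as burn-in; must be < `n_steps`.
#' @param proposal_scales named vector of per-parameter random-walk step sizes;
#'   default 2% of each bound width.
#' @param bounds 7 x 2 bounds matrix.
#' @param init starting point; default the arithmetic midpoint for `q10` and
#'   the geometric midpoint for the exit rates.
#' @param adapt tune the step scale during burn-in toward
#'   `target_acceptance` (frozen afterwards).
#' @param adapt_interval,target_acceptance adaptation controls.
#' @param seed integer seed.
#' @return An `mh_config` list.
#' @export
mh_config <- function(n_steps = 20000, burn_in = 5000,
                      proposal_scales = NULL, bounds = default_teco_bounds(),
                      init = NULL, adapt = TRUE, adapt_interval = 200L,
                      target_acceptance = 0.3, seed = 1L) {
  if (!is_count(n_steps) || !is_count(burn_in) || burn_in >= n_steps) {
    stop("need integer n_steps > burn_in >= 1")
  }
  if (is.null(proposal_scales)) {
    proposal_scales <- 0.02 * (bounds[, 2] - bounds[, 1])
  }
  if (is.null(init)) {
    init <- c(mean(bounds["q10", ]), sqrt(bounds[-1, 1] * bounds[-1, 2]))
    names(init) <- TECO_PARAM_NAMES
  }
  structure(
    list(n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
         proposal_scales = proposal_scales, bounds = bounds, init = init,
         adapt = adapt, adapt_interval = as.integer(adapt_interval),
         target_acceptance = target_acceptance, seed = as.integer(seed)),
    class = "mh_config"
  )
}

#' Invert the carbon model by Metropolis-Hastings MCMC
#'
#' Random-walk proposals; a proposal is accepted with probability
#' `min(1, exp(delta log posterior))`, and proposals outside the prior bounds
#' are rejected. With no observations (`obs = NULL`) the chain samples the
#' uniform prior, which is useful for prior-recovery checks. Chains are
#' reproducible under the config seed.
#'
#' @param drivers driver data frame (see [simulate_teco()]).
#' @param obs observation set as in [log_posterior()], or `NULL` for a
#'   flat likelihood.
#' @param config an [mh_config()].
#' @param initial,tref,alloc,resp_frac forward-model configuration.
#' @return A `teco_mcmc` object: `samples` (n_steps x 7 matrix),
#'   `log_posteriors`, `acceptance_rate`, `burn_in`, `seed`, `bounds`.
#' @export
run_mh_chain <- function(drivers, obs = NULL, config = mh_config(),
                         initial = default_initial_state(), tref = 10,
                         alloc = c(foliage = 0.45, root = 0.55),
                         resp_frac = 0.55) {
  stopifnot(inherits(config, "mh_config"))
  bounds <- config$bounds
  lp_fn <- if (is.null(obs)) {
    function(v) 0
  } else {
    function(v) log_posterior(v, drivers, obs, initial = initial, tref = tref,
                              alloc = alloc, resp_frac = resp_frac,
                              bounds = bounds)
  }
  res <- mh_sample(lp_fn, init = config$init, lower = bounds[, 1],
                   upper = bounds[, 2], scales = config$proposal_scales,
                   n_steps = config$n_steps, burn_in = config$burn_in,
                   seed = config$seed, adapt = config$adapt,
                   adapt_interval = config$adapt_interval,
                   target_acceptance = config$target_acceptance)
  if (res$accepted == 0L) {
    warning("no proposal was accepted over the whole chain; ",
            "proposal scales are pathological")
  }
  colnames(res$samples) <- TECO_PARAM_NAMES
  structure(
    list(samples = res$samples, log_posteriors = res$log_posteriors,
         acceptance_rate = res$acceptance_rate, burn_in = config$burn_in,
         seed = config$seed, bounds = bounds),
    class = "teco_mcmc"
  )
}

#' @export
print.teco_mcmc <- function(x, ...) {
  cat(sprintf("teco_mcmc: %d steps (burn-in %d), acceptance %.2f\n",
              nrow(x$samples), x$burn_in, x$acceptance_rate))
  invisible(x)
}

#' Posterior summary of one parameter
#'
#' The mode is the midpoint of the highest-density bin of an equal-width
#' histogram over the post-burn-in samples; the credible interval is the
#' central `prob` quantile interval.
#'
#' @param result a `teco_mcmc` from [run_mh_chain()].
#' @param parameter parameter name (default `"q10"`).
#' @param bins histogram bin count for the mode.
#' @param prob credible-interval mass (default 0.95).
#' @return list with `mode`, `mean`, `ci` (length-2 vector), `n_samples`.
#' @export
summarize_posterior <- function(result, parameter = "q10", bins = 30,
                                prob = 0.95) {
  stopifnot(inherits(result, "teco_mcmc"))
  if (!parameter %in% colnames(result$samples)) {
    stop("unknown parameter '", parameter, "'")
  }
  x <- result$samples[-seq_len(result$burn_in), parameter]
  if (length(x) < 100) stop("fewer than 100 post-burn-in samples")
  if (max(x) == min(x)) {
    return(list(mode = x[1], mean = x[1], ci = c(x[1], x[1]),
                n_samples = length(x)))
  }
  breaks <- seq(min(x), max(x), length.out = bins + 1)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = bins)
  top <- which.max(counts)
  mode <- (breaks[top] + breaks[top + 1]) / 2
  alpha <- (1 - prob) / 2
  list(mode = mode, mean = mean(x),
       ci = unname(quantile(x, c(alpha, 1 - alpha))),
       n_samples = length(x))
}
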