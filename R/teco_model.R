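# Six-pool terrestrial carbon model with Q10-scaled heterotrophic
# respiration: parameters, temperature scalar, forward simulation.

TECO_PARAM_NAMES <- c("q10", "k_foliage", "k_root", "k_litter", "k_fast",
                      "k_slow", "k_passive")
TECO_POOL_NAMES <- c("foliage", "root", "litter", "fast", "slow", "passive")

#' Default parameter bounds for the carbon-model inversion
#'
#' Q10 is bounded to \[1.5, 5\] (site-level regression estimates of the
#' temperature sensitivity of heterotrophic respiration). Each exit rate is
#' bounded two orders of magnitude around a literature-scale turnover time
#' (foliage/litter about a year, fine roots about 3 years, fast SOM about
#' 5 years, slow SOM about 50, passive SOM about 500).
#'
#' @return 7 x 2 matrix with rownames the parameter names and columns
#'   `lower`, `upper`.
#' @export
default_teco_bounds <- function() {
  k_def <- c(k_foliage = 2.7e-3, k_root = 9.1e-4, k_litter = 2.7e-3,
             k_fast = 5.5e-4, k_slow = 5.5e-5, k_passive = 5.5e-6)
  b <- rbind(q10 = c(1.5, 5),
             cbind(k_def / 10, k_def * 10))
  dimnames(b) <- list(TECO_PARAM_NAMES, c("lower", "upper"))
  b
}

#' Parameters of the six-pool carbon model
#'
#' The seven inverted parameters: the Q10 of heterotrophic respiration and the
#' exit rates (day^-1) of the foliage, fine root, litter, fast SOM, slow SOM
#' and passive SOM pools.
#'
#' @param q10 temperature sensitivity of heterotrophic respiration; must lie
#'   within its bounds (default \[1.5, 5\]).
#' @param k_foliage,k_root,k_litter,k_fast,k_slow,k_passive positive exit
#'   rates in day^-1.
#' @param bounds 7 x 2 bounds matrix as from [default_teco_bounds()].
#' @return A `teco_parameters` object.
#' @export
teco_parameters <- function(q10 = 2.5, k_foliage = 2.7e-3, k_root = 9.1e-4,
                            k_litter = 2.7e-3, k_fast = 5.5e-4,
                            k_slow = 5.5e-5, k_passive = 5.5e-6,
                            bounds = default_teco_bounds()) {
  values <- c(q10 = q10, k_foliage = k_foliage, k_root = k_root,
              k_litter = k_litter, k_fast = k_fast, k_slow = k_slow,
              k_passive = k_passive)
  if (any(!is.finite(values))) stop("non-finite parameter value")
  if (any(values[-1] <= 0)) stop("exit rates must be positive")
  if (!all(rownames(bounds) == TECO_PARAM_NAMES)) {
    stop("`bounds` must have rows ", paste(TECO_PARAM_NAMES, collapse = ", "))
  }
  out_of <- values < bounds[, 1] | values > bounds[, 2]
  if (any(out_of)) {
    stop("parameter(s) outside bounds: ",
         paste(names(values)[out_of], collapse = ", "))
  }
  structure(list(values = values, bounds = bounds), class = "teco_parameters")
}

#' @export
print.teco_parameters <- function(x, ...) {
  cat("teco_parameters:\n")
  print(signif(x$values, 4))
  invisible(x)
}

params_from_vector <- function(v, bounds) {
  names(v) <- TECO_PARAM_NAMES
  structure(list(values = v, bounds = bounds), class = "teco_parameters")
}

#' Default initial carbon pools
#'
#' Grassland-scale pool sizes in g C m-2 used by the synthetic dataset
#' generator and as the known initial state of the inversion.
#'
#' @return named numeric vector over the six pools.
#' @export
default_initial_state <- function() {
  c(foliage = 150, root = 300, litter = 200, fast = 300, slow = 2000,
    passive = 5000)
}

#' Q10 temperature scalar
#'
#' The multiplicative factor `q10^((temp - temp_ref)/10)` applied to litter
#' and SOM decomposition fluxes: a Q10 of 2 doubles the rate for every 10 degC
#' above the reference temperature.
#'
#' @param q10 positive temperature sensitivity.
#' @param temp temperature (degC); vectorized.
#' @param temp_ref reference temperature (degC).
#' @return positive scalar(s).
#' @export
temperature_scalar <- function(q10, temp, temp_ref = 10) {
  if (any(q10 <= 0)) stop("`q10` must be positive")
  q10^((temp - temp_ref) / 10)
}

#' Forward simulation of the six-pool carbon model
#'
#' Daily explicit update. Carbon input is allocated to the foliage and fine
#' root pools; donor-controlled first-order transfers run foliage -> litter,
#' root -> litter, litter -> (fast SOM + CO2), fast -> (slow + CO2),
#' slow -> (passive + CO2), passive -> CO2. Litter and SOM fluxes are
#' multiplied by [temperature_scalar()]; `resp_frac` of each such donor flux
#' is respired (the terminal passive flux entirely), the remainder is
#' transferred. Heterotrophic respiration is the sum of respired fractions and
#' aboveground biomass is the foliage pool, so carbon is conserved exactly:
#' total input minus total respiration equals the storage change.
#'
#' Forward-Euler stability is config-checked: the largest temperature-scaled
#' rate must satisfy `k * xi <= 1`.
#'
#' @param params a [teco_parameters()] object.
#' @param drivers data frame with columns `day`, `temp` (degC) and `c_input`
#'   (g C m-2 day-1) covering the simulation horizon.
#' @param initial named vector of initial pools (g C m-2).
#' @param tref reference temperature of the Q10 scalar (degC).
#' @param alloc allocation fractions of input to `foliage` and `root`; must
#'   sum to 1.
#' @param resp_frac respired fraction of each temperature-scaled donor flux.
#' @return A `teco_trajectory`: list with `pools` (days x 6 matrix), `rh`
#'   (daily heterotrophic respiration), `agb` (daily foliage pool), `days`,
#'   and the inputs needed for bookkeeping (`initial`, `drivers`).
#' @export
simulate_teco <- function(params, drivers, initial = default_initial_state(),
                          tref = 10, alloc = c(foliage = 0.45, root = 0.55),
                          resp_frac = 0.55) {
  stopifnot(inherits(params, "teco_parameters"))
  if (!is.data.frame(drivers) ||
      !all(c("day", "temp", "c_input") %in% names(drivers))) {
    stop("`drivers` must have columns day, temp, c_input")
  }
  if (abs(sum(alloc) - 1) > 1e-12) stop("allocation fractions must sum to 1")
  if (resp_frac < 0 || resp_frac > 1) stop("`resp_frac` must be in [0, 1]")
  if (any(drivers$c_input < 0)) stop("negative carbon input")
  if (!all(TECO_POOL_NAMES %in% names(initial))) {
    stop("`initial` must name pools ", paste(TECO_POOL_NAMES, collapse = ", "))
  }
  initial <- initial[TECO_POOL_NAMES]
  if (any(initial < 0)) stop("initial pools must be nonnegative")
  v <- params$values
  xi_max <- max(temperature_scalar(v["q10"], drivers$temp, tref))
  if (max(v[-1] * c(1, 1, xi_max, xi_max, xi_max, xi_max)[1:6]) > 1) {
    stop("unstable daily step: an exit rate times the maximum temperature ",
         "scalar exceeds 1")
  }
  sim <- .teco_forward_cpp(unname(initial), unname(v[-1]), v[["q10"]], tref,
                           drivers$temp, drivers$c_input,
                           alloc[["foliage"]], alloc[["root"]], resp_frac)
  colnames(sim$pools) <- TECO_POOL_NAMES
  structure(
    list(pools = sim$pools, rh = as.numeric(sim$rh), agb = as.numeric(sim$agb),
         days = drivers$day, initial = initial, drivers = drivers),
    class = "teco_trajectory"
  )
}

#' @export
print.teco_trajectory <- function(x, ...) {
  cat(sprintf("teco_trajectory: %d days, final total C = %.1f g C m-2\n",
              length(x$days), sum(x$pools[nrow(x$pools), ])))
  invisible(x)
}

#' Carbon-balance residual of a trajectory
#'
#' `sum(input) - sum(rh) - (final storage - initial storage)`; zero up to
#' floating-point rounding for every valid simulation.
#'
#' @param traj a `teco_trajectory`.
#' @return the residual in g C m-2.
#' @export
carbon_balance_residual <- function(traj) {
  stopifnot(inherits(traj, "teco_trajectory"))
  storage0 <- sum(traj$initial)
  storage1 <- sum(traj$pools[nrow(traj$pools), ])
  sum(traj$drivers$c_input) - sum(traj$rh) - (storage1 - storage0)
}
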