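# Synthetic-data module: generators for every input the pipeline consumes,
# with known ground truth. All generators are pure functions of their spec and
# seed; the caller's RNG state is never touched.

#' Effect specification for one synthetic variable
#'
#' Encodes the ground truth of a factorial response: a baseline level, percent
#' warming and clipping main effects, and a percent interaction injected only
#' into the combined (CW) cell, so that the observed combined effect deviates
#' from additivity by exactly `interaction_pct` in expectation. Block and
#' residual variation are multiplicative, mean-one lognormal (keeps
#' concentrations/signals positive and makes percent effects scale-free).
#'
#' @param baseline expected value in the untreated (UU) cell; must be nonzero
#'   when any percent effect is nonzero.
#' @param warming_pct,clipping_pct percent main effects of warming and
#'   clipping relative to baseline.
#' @param interaction_pct percent deviation of the combined (CW) cell from
#'   additivity: the CW expectation is
#'   `baseline * (1 + (warming_pct + clipping_pct + interaction_pct)/100)`.
#' @param block_sd,noise_sd standard deviations (on the log scale) of the
#'   multiplicative block effect and the per-observation noise; 0 disables.
#' @param seed integer seed for this variable's private RNG stream.
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(baseline, warming_pct = 0, clipping_pct = 0,
                        interaction_pct = 0, block_sd = 0, noise_sd = 0,
                        seed = 1L) {
  stopifnot_scalar_number(baseline, "baseline")
  stopifnot_scalar_number(warming_pct, "warming_pct")
  stopifnot_scalar_number(clipping_pct, "clipping_pct")
  stopifnot_scalar_number(interaction_pct, "interaction_pct")
  stopifnot_scalar_number(block_sd, "block_sd", lower = 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (baseline == 0 &&
      any(c(warming_pct, clipping_pct, interaction_pct) != 0)) {
    stop("zero `baseline` with a nonzero percent effect: relative effect undefined")
  }
  structure(
    list(baseline = baseline, warming_pct = warming_pct,
         clipping_pct = clipping_pct, interaction_pct = interaction_pct,
         block_sd = block_sd, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "effect_spec"
  )
}

# mean-one multiplicative lognormal factors
lognormal_mult <- function(n, sdlog) {
  if (sdlog == 0) rep(1, n) else exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Generate a synthetic paired-factorial property table
#'
#' One row per block x treatment cell. Conditional on the block's
#' multiplicative effect, the cell expectation is
#' `baseline * block_mult * (1 + (w*warmed + c*clipped + g*warmed*clipped)/100)`
#' with `(w, c, g)` from the variable's [effect_spec()]. Because every percent
#' effect is relative to the same block's UU cell, [compute_effects()] on a
#' noiseless table returns `W = w`, `C = c`, `OE - PE = g` to machine
#' precision regardless of `block_sd`.
#'
#' @param design a [factorial_design()].
#' @param specs a named list of [effect_spec()] objects (names become variable
#'   columns), or a single `effect_spec` (variable named `"value"`).
#' @return A property table: data frame with columns
#'   `block`, `warmed`, `clipped`, then one column per variable.
#' @examples
#' tab <- generate_factorial_properties(
#'   factorial_design(6),
#'   list(temperature = effect_spec(14, warming_pct = 8.1, seed = 42))
#' )
#' compute_effects(tab, "temperature")
#' @export
generate_factorial_properties <- function(design, specs) {
  stopifnot(inherits(design, "factorial_design"))
  if (inherits(specs, "effect_spec")) specs <- list(value = specs)
  if (!is.list(specs) || length(specs) == 0 || is.null(names(specs)) ||
      any(names(specs) == "")) {
    stop("`specs` must be a named list of effect_spec objects")
  }
  tab <- design$table
  out <- tab[, c("block", "warmed", "clipped")]
  for (v in names(specs)) {
    sp <- specs[[v]]
    if (!inherits(sp, "effect_spec")) stop("spec for '", v, "' is not an effect_spec")
    eff <- 1 + (sp$warming_pct * tab$warmed + sp$clipping_pct * tab$clipped +
                  sp$interaction_pct * tab$warmed * tab$clipped) / 100
    out[[v]] <- with_seed(sp$seed, {
      block_mult <- lognormal_mult(design$n_blocks, sp$block_sd)
      noise_mult <- lognormal_mult(nrow(tab), sp$noise_sd)
      sp$baseline * block_mult[tab$block] * eff * noise_mult
    })
  }
  out
}

#' Fixture specification for a synthetic functional gene array
#'
#' Describes a GeoChip-style probe-level fixture: `n_genes` genes with
#' `probes_per_gene` designed probes each, laid out on `n_subgrids` subgrids,
#' hybridized once per sample (block x treatment) and technical replicate.
#' Probe signals are lognormal around a gene-level mean scaled by the
#' per-category treatment fold change in `differential_spec`; QC-flagged spots
#' and low signal-to-noise spots are injected at the stated rates.
#'
#' @param n_genes,probes_per_gene,n_subgrids positive integers.
#' @param category_map character vector of functional category labels, either
#'   length `n_genes` (gene i gets label i) or shorter and recycled. Must be
#'   nonempty.
#' @param differential_spec named list: category -> named numeric vector of
#'   multiplicative fold changes per treatment (e.g.
#'   `list(C_deg = c(CU = 2))`); treatments absent from the vector get fold 1.
#' @param flag_rate,low_snr_rate probabilities in \[0, 1\] of a spot being
#'   flagged (flag 1 or 3) or rendered low-SNR (SNR < 2).
#' @param signal_scale median gene-level signal intensity.
#' @param n_tech_reps technical replicates (slides) per sample.
#' @param probe_sd lognormal sigma of probe-level measurement noise.
#' @param background_mean,background_sd background level and its standard
#'   deviation, shared by all spots.
#' @param seed integer seed.
#' @return An `array_fixture_spec` object.
#' @export
array_fixture_spec <- function(n_genes, probes_per_gene, n_subgrids = 4,
                               category_map = "uncategorized",
                               differential_spec = list(),
                               flag_rate = 0, low_snr_rate = 0,
                               signal_scale = 1000, n_tech_reps = 1,
                               probe_sd = 0.25,
                               background_mean = 50, background_sd = 10,
                               seed = 1L) {
  if (!is_count(n_genes)) stop("`n_genes` must be a positive integer")
  if (!is_count(probes_per_gene)) stop("`probes_per_gene` must be a positive integer (>= 1)")
  if (!is_count(n_subgrids)) stop("`n_subgrids` must be a positive integer")
  if (!is_count(n_tech_reps)) stop("`n_tech_reps` must be a positive integer")
  if (!is.character(category_map) || length(category_map) == 0) {
    stop("`category_map` must be a nonempty character vector")
  }
  stopifnot_scalar_number(flag_rate, "flag_rate", 0, 1)
  stopifnot_scalar_number(low_snr_rate, "low_snr_rate", 0, 1)
  stopifnot_scalar_number(signal_scale, "signal_scale", lower = .Machine$double.eps)
  stopifnot_scalar_number(probe_sd, "probe_sd", lower = 0)
  stopifnot_scalar_number(background_mean, "background_mean", lower = 0)
  stopifnot_scalar_number(background_sd, "background_sd",
                          lower = .Machine$double.eps)
  if (!is.list(differential_spec)) stop("`differential_spec` must be a list")
  for (cat in names(differential_spec)) {
    fc <- differential_spec[[cat]]
    if (!is.numeric(fc) || is.null(names(fc)) || any(fc <= 0)) {
      stop("differential_spec entries must be named positive numeric vectors")
    }
    bad <- setdiff(names(fc), c("UU", "UW", "CU", "CW"))
    if (length(bad)) stop("unknown treatment in differential_spec: ", bad[1])
  }
  structure(
    list(n_genes = as.integer(n_genes),
         probes_per_gene = as.integer(probes_per_gene),
         n_subgrids = as.integer(n_subgrids),
         category_map = category_map,
         differential_spec = differential_spec,
         flag_rate = flag_rate, low_snr_rate = low_snr_rate,
         signal_scale = signal_scale, n_tech_reps = as.integer(n_tech_reps),
         probe_sd = probe_sd,
         background_mean = background_mean, background_sd = background_sd,
         seed = as.integer(seed)),
    class = "array_fixture_spec"
  )
}

#' Generate a synthetic probe-level array fixture
#'
#' Emulates the raw probe table of a functional gene array experiment. Each
#' record is one spot on one slide (one hybridization = one sample x technical
#' replicate). The clean-signal floor is `background_mean + 2*background_sd`,
#' so with `flag_rate = 0` and `low_snr_rate = 0` every record passes
#' [qc_filter_probes()] (the no-QC identity used in testing).
#'
#' @param spec an [array_fixture_spec()].
#' @param design a [factorial_design()].
#' @return A probe record data frame with the canonical columns
#'   `slide_id sample_id subgrid probe_id gene_id category signal background
#'   background_sd flag`, with
#'   `n_genes * probes_per_gene * n_blocks * 4 * n_tech_reps` rows.
#' @export
generate_geochip_fixture <- function(spec, design) {
  stopifnot(inherits(spec, "array_fixture_spec"),
            inherits(design, "factorial_design"))
  genes <- sprintf("g%03d", seq_len(spec$n_genes))
  category <- rep_len(spec$category_map, spec$n_genes)
  n_probes <- spec$n_genes * spec$probes_per_gene
  probe_gene_idx <- rep(seq_len(spec$n_genes), each = spec$probes_per_gene)
  probe_ids <- sprintf("%s_p%02d", genes[probe_gene_idx],
                       sequence(rep(spec$probes_per_gene, spec$n_genes)))
  subgrid <- ((seq_len(n_probes) - 1L) %% spec$n_subgrids) + 1L

  samples <- design$table
  fold_for <- function(cat, trt) {
    fc <- spec$differential_spec[[cat]]
    if (is.null(fc) || is.na(fc[trt])) 1 else unname(fc[trt])
  }

  with_seed(spec$seed, {
    gene_mean <- spec$signal_scale * exp(rnorm(spec$n_genes, 0, 0.5))
    probe_affinity <- exp(rnorm(n_probes, 0, 0.2))
    recs <- vector("list", nrow(samples) * spec$n_tech_reps)
    k <- 0L
    for (s in seq_len(nrow(samples))) {
      trt <- samples$treatment[s]
      fold <- vapply(category, fold_for, numeric(1), trt = trt)
      for (r in seq_len(spec$n_tech_reps)) {
        mu <- gene_mean[probe_gene_idx] * probe_affinity *
          fold[probe_gene_idx]
        signal <- mu * exp(rnorm(n_probes, 0, spec$probe_sd)) +
          spec$background_mean
        # clean spots always clear the SNR >= 2 bar
        signal <- pmax(signal, spec$background_mean + 2 * spec$background_sd)
        flag <- integer(n_probes)
        if (spec$flag_rate > 0) {
          hit <- runif(n_probes) < spec$flag_rate
          flag[hit] <- sample(c(1L, 3L), sum(hit), replace = TRUE)
        }
        if (spec$low_snr_rate > 0) {
          low <- runif(n_probes) < spec$low_snr_rate
          signal[low] <- spec$background_mean +
            runif(sum(low), 0, 1.9) * spec$background_sd
        }
        k <- k + 1L
        recs[[k]] <- data.frame(
          slide_id = sprintf("%s_r%d", samples$sample_id[s], r),
          sample_id = samples$sample_id[s],
          subgrid = subgrid,
          probe_id = probe_ids,
          gene_id = genes[probe_gene_idx],
          category = category[probe_gene_idx],
          signal = signal,
          background = spec$background_mean,
          background_sd = spec$background_sd,
          flag = flag,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}

#' Designed probe counts of a fixture
#'
#' @param spec an [array_fixture_spec()].
#' @return data frame `gene_id`, `designed_probes` (the per-gene designed
#'   probe number used by [filter_genes_and_probes()]).
#' @export
designed_probe_counts <- function(spec) {
  stopifnot(inherits(spec, "array_fixture_spec"))
  data.frame(gene_id = sprintf("g%03d", seq_len(spec$n_genes)),
             designed_probes = spec$probes_per_gene,
             stringsAsFactors = FALSE)
}

#' Dataset specification for the soil-carbon model inversion
#'
#' Describes a synthetic driver + observation set for the six-pool carbon
#' model: a seasonal sinusoidal soil-temperature series (site mean 16.3 degC),
#' a seasonal nonnegative daily carbon input series, and observations equal to
#' the forward model run at `true_params` plus independent Gaussian noise
#' (daily heterotrophic respiration; aboveground biomass every
#' `agb_interval` days). With both noise standard deviations 0 the
#' observations reproduce the forward simulation exactly.
#'
#' @param true_params a [teco_parameters()] object: the ground truth.
#' @param n_days length of the daily simulation; default three years.
#' @param temp_mean,temp_amp,temp_noise_sd mean (degC), seasonal amplitude and
#'   day-to-day noise sd of soil temperature.
#' @param c_input_mean,c_input_amp mean and seasonal amplitude of daily carbon
#'   input (g C m-2 day-1); the series is truncated at zero.
#' @param obs_noise_sd_rh,obs_noise_sd_agb Gaussian observation noise sd for
#'   heterotrophic respiration (g C m-2 day-1) and aboveground biomass
#'   (g C m-2). Must be nonnegative.
#' @param agb_interval days between biomass observations.
#' @param initial named initial pool vector (see [default_initial_state()]).
#' @param tref,alloc,resp_frac forward-model structural constants, see
#'   [simulate_teco()].
#' @param seed integer seed.
#' @return A `teco_dataset_spec` object.
#' @export
teco_dataset_spec <- function(true_params = teco_parameters(),
                              n_days = 3 * 365,
                              temp_mean = 16.3, temp_amp = 10,
                              temp_noise_sd = 1,
                              c_input_mean = 1.5, c_input_amp = 1,
                              obs_noise_sd_rh = 0.05, obs_noise_sd_agb = 5,
                              agb_interval = 30,
                              initial = default_initial_state(),
                              tref = 10,
                              alloc = c(foliage = 0.45, root = 0.55),
                              resp_frac = 0.55,
                              seed = 1L) {
  stopifnot(inherits(true_params, "teco_parameters"))
  if (!is_count(n_days)) stop("`n_days` must be a positive integer")
  if (!is_count(agb_interval)) stop("`agb_interval` must be a positive integer")
  stopifnot_scalar_number(obs_noise_sd_rh, "obs_noise_sd_rh", lower = 0)
  stopifnot_scalar_number(obs_noise_sd_agb, "obs_noise_sd_agb", lower = 0)
  stopifnot_scalar_number(temp_noise_sd, "temp_noise_sd", lower = 0)
  structure(
    list(true_params = true_params, n_days = as.integer(n_days),
         temp_mean = temp_mean, temp_amp = temp_amp,
         temp_noise_sd = temp_noise_sd,
         c_input_mean = c_input_mean, c_input_amp = c_input_amp,
         obs_noise_sd_rh = obs_noise_sd_rh,
         obs_noise_sd_agb = obs_noise_sd_agb,
         agb_interval = as.integer(agb_interval),
         initial = initial, tref = tref, alloc = alloc,
         resp_frac = resp_frac, seed = as.integer(seed)),
    class = "teco_dataset_spec"
  )
}

#' Generate synthetic drivers and observations for the carbon-model inversion
#'
#' @param spec a [teco_dataset_spec()].
#' @return list with `drivers` (data frame `day`, `temp`, `c_input`), `obs`
#'   (an observation set: list with `rh` and `agb` data frames of `day`,
#'   `value` plus `sd_rh`, `sd_agb`), `truth` (the generating parameters),
#'   `initial`, and the structural constants `tref`, `alloc`, `resp_frac`.
#' @export
generate_teco_dataset <- function(spec) {
  stopifnot(inherits(spec, "teco_dataset_spec"))
  days <- seq_len(spec$n_days)
  out <- with_seed(spec$seed, {
    temp <- spec$temp_mean +
      spec$temp_amp * sin(2 * pi * (days - 120) / 365) +
      rnorm(spec$n_days, 0, spec$temp_noise_sd)
    c_input <- pmax(0, spec$c_input_mean +
                      spec$c_input_amp * sin(2 * pi * (days - 120) / 365))
    drivers <- data.frame(day = days, temp = temp, c_input = c_input)
    sim <- simulate_teco(spec$true_params, drivers, initial = spec$initial,
                         tref = spec$tref, alloc = spec$alloc,
                         resp_frac = spec$resp_frac)
    agb_days <- seq(spec$agb_interval, spec$n_days, by = spec$agb_interval)
    rh_obs <- sim$rh + rnorm(spec$n_days, 0, spec$obs_noise_sd_rh)
    agb_obs <- sim$agb[agb_days] + rnorm(length(agb_days), 0,
                                         spec$obs_noise_sd_agb)
    list(
      drivers = drivers,
      obs = list(rh = data.frame(day = days, value = rh_obs),
                 agb = data.frame(day = agb_days, value = agb_obs),
                 sd_rh = spec$obs_noise_sd_rh,
                 sd_agb = spec$obs_noise_sd_agb),
      truth = spec$true_params,
      initial = spec$initial,
      tref = spec$tref, alloc = spec$alloc, resp_frac = spec$resp_frac
    )
  })
  # Degenerate noise sds would make the Gaussian likelihood singular;
  # downstream inversion replaces 0 by a small positive sd when needed.
  out
}
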