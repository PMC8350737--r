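# Synthetic ground-truth generators: batch fermentation time courses driven
# by the dual-substrate uptake model with a prescribed logistic biomass
# curve, and toy linear pathways for exercising the thermodynamic and
# enzyme-cost optimizers.

#' Specification of a synthetic batch fermentation
#'
#' Defaults emulate the modeled experiment: initial glucose/xylose of
#' 443/245 mM, a 65 h batch, and transporter constants at the fitted values
#' with stand-in inhibition constants (`Ki_xyl` = 200 mM,
#' `Ki_glc` = 600 mM; the glucose constant chosen much larger, reflecting
#' its weak inhibitory role). Biomass follows a prescribed logistic curve
#' rather than emerging from the simulation, so transporter fitting is
#' decoupled from growth modeling. Measurement noise is multiplicative:
#' `value * (1 + cv * e)`, `e ~ N(0,1)`, clamped at zero, emulating
#' concentration-proportional HPLC error.
#'
#' @param true_params [transporter_kinetics()] ground truth.
#' @param initial_glc,initial_xyl initial sugar concentrations, mM.
#' @param initial_biomass inoculum, gDCW L^-1 (default: OD 0.84 converted
#'   with the default factor, see [od_to_biomass()]).
#' @param growth_rate logistic specific growth rate, h^-1.
#' @param carrying_capacity logistic plateau, gDCW L^-1.
#' @param t_end batch length, h.
#' @param n_samples number of equally spaced samples (>= 4).
#' @param noise_cv coefficient of variation of measurement noise (< 0.5).
#' @param seed integer seed.
#' @return list of class `synthetic_batch_spec`.
#' @export
synthetic_batch_spec <- function(true_params = transporter_kinetics(
                                   29.30, 40.21, 600, 3.18, 80.96, 200),
                                 initial_glc = 443, initial_xyl = 245,
                                 initial_biomass = od_to_biomass(0.84),
                                 growth_rate = 0.20,
                                 carrying_capacity = 2.5,
                                 t_end = 65, n_samples = 27L,
                                 noise_cv = 0.02, seed = 1L) {
  spec <- list(true_params = true_params, initial_glc = initial_glc,
               initial_xyl = initial_xyl, initial_biomass = initial_biomass,
               growth_rate = growth_rate,
               carrying_capacity = carrying_capacity,
               t_end = t_end, n_samples = as.integer(n_samples),
               noise_cv = noise_cv, seed = as.integer(seed))
  stopifnot(inherits(true_params, "transporter_kinetics"))
  nonneg <- c("initial_glc", "initial_xyl", "initial_biomass", "growth_rate",
              "carrying_capacity", "t_end")
  if (any(unlist(spec[nonneg]) < 0)) {
    stop_zf("all concentrations and rates must be >= 0", "zf_bad_spec")
  }
  if (spec$n_samples < 4) stop_zf("n_samples must be >= 4", "zf_bad_spec")
  if (spec$noise_cv < 0 || spec$noise_cv >= 0.5) {
    stop_zf("noise_cv must be in [0, 0.5)", "zf_bad_spec")
  }
  class(spec) <- "synthetic_batch_spec"
  spec
}

#' Logistic biomass curve of a synthetic batch
#'
#' `X(t) = K X0 e^(mu t) / (K + X0 (e^(mu t) - 1))`; reduces to constant
#' `X0` when `mu = 0` or `X0 = 0`.
#'
#' @param spec a [synthetic_batch_spec()].
#' @return function of time (h) returning gDCW L^-1.
#' @export
logistic_biomass <- function(spec) {
  X0 <- spec$initial_biomass; K <- spec$carrying_capacity
  mu <- spec$growth_rate
  function(t) {
    if (X0 == 0 || mu == 0 || K == 0) return(rep(X0, length(t)))
    e <- exp(mu * t)
    K * X0 * e / (K + X0 * (e - 1))
  }
}

#' Generate a synthetic fermentation time course
#'
#' Integrates the dual-substrate uptake ODEs against the prescribed logistic
#' biomass curve of `spec`, samples `n_samples` equally spaced times in
#' `[0, t_end]`, and applies multiplicative Gaussian measurement noise to the
#' sugar and biomass channels. Both the noisy and noiseless channels are
#' returned.
#'
#' @param spec a [synthetic_batch_spec()].
#' @return list of class `synthetic_course`: `$course` (noisy
#'   [fermentation_course()]), `$truth` (noiseless), `$spec`.
#' @export
generate_fermentation <- function(spec) {
  stopifnot(inherits(spec, "synthetic_batch_spec"))
  bio <- logistic_biomass(spec)
  t_grid <- seq(0, spec$t_end, length.out = spec$n_samples)
  # the sugar ODEs are driven by the biomass curve linearly interpolated
  # between the sampled timepoints - exactly the curve any downstream
  # analysis of the emitted table can reconstruct, mirroring how measured
  # biomass is treated as interpolated data
  bio_interp <- stats::approxfun(t_grid, bio(t_grid), rule = 2)
  truth <- simulate_uptake(spec$true_params, spec$initial_glc,
                           spec$initial_xyl, bio_interp, t_grid)
  if (anyNA(truth)) {
    stop_zf("non-finite ODE solution; check true_params", "zf_bad_spec")
  }
  noisy <- truth
  if (spec$noise_cv > 0) {
    noisy[c("glc_mM", "xyl_mM", "biomass_gdcw_L")] <- with_seed(spec$seed, {
      lapply(truth[c("glc_mM", "xyl_mM", "biomass_gdcw_L")], function(v) {
        pmax(v * (1 + spec$noise_cv * stats::rnorm(length(v))), 0)
      })
    })
  }
  structure(list(course = fermentation_course(noisy),
                 truth = truth, spec = spec),
            class = "synthetic_course")
}

#' Specification of a toy linear pathway
#'
#' A chain `A0 -> A1 -> ... -> An` of uni-uni reactions with standard Gibbs
#' energies, Michaelis constants, turnover numbers and molecular weights
#' sampled from the given ranges (log-uniform for `km`/`kcat`, uniform
#' otherwise).
#'
#' @param n_reactions chain length (>= 1).
#' @param dg0_range interval for standard Gibbs energies, kJ mol^-1.
#' @param km_range interval for Michaelis constants, mM.
#' @param kcat_range interval for turnover numbers, s^-1.
#' @param mw_range interval for enzyme molecular weights, g mol^-1.
#' @param seed integer seed.
#' @return list of class `toy_pathway_spec`.
#' @export
toy_pathway_spec <- function(n_reactions = 3L, dg0_range = c(-15, 5),
                             km_range = c(0.05, 5), kcat_range = c(10, 200),
                             mw_range = c(2e4, 1e5), seed = 1L) {
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2]
  if (n_reactions < 1) stop_zf("n_reactions must be >= 1", "zf_bad_spec")
  if (!all(vapply(list(dg0_range, km_range, kcat_range, mw_range), rng_ok,
                  logical(1)))) {
    stop_zf("all ranges must be ordered intervals", "zf_bad_spec")
  }
  structure(list(n_reactions = as.integer(n_reactions),
                 dg0_range = dg0_range, km_range = km_range,
                 kcat_range = kcat_range, mw_range = mw_range,
                 seed = as.integer(seed)),
            class = "toy_pathway_spec")
}

#' Generate a toy linear pathway with sampled parameters
#'
#' @param spec a [toy_pathway_spec()].
#' @return a [pathway_model()]: chain `A0 -> ... -> An` of reversible
#'   uni-uni reactions `r1..rn` with unit relative flux; `A0` pinned at
#'   1 mM, the remaining metabolites free within the default bounds.
#' @export
generate_toy_pathway <- function(spec) {
  stopifnot(inherits(spec, "toy_pathway_spec"))
  n <- spec$n_reactions
  runif_log <- function(k, r) exp(stats::runif(k, log(r[1]), log(r[2])))
  draws <- with_seed(spec$seed, list(
    dg0 = stats::runif(n, spec$dg0_range[1], spec$dg0_range[2]),
    km_s = runif_log(n, spec$km_range),
    km_p = runif_log(n, spec$km_range),
    kcat = runif_log(n, spec$kcat_range),
    mw = stats::runif(n, spec$mw_range[1], spec$mw_range[2])
  ))
  mets <- paste0("A", 0:n)
  rxns <- lapply(seq_len(n), function(j) {
    st <- stats::setNames(c(-1, 1), c(mets[j], mets[j + 1]))
    km <- stats::setNames(c(draws$km_s[j], draws$km_p[j]),
                          c(mets[j], mets[j + 1]))
    thermo_reaction(id = paste0("r", j), stoich = st,
                    dg0_prime = draws$dg0[j], reversible = TRUE,
                    kinetics = enzyme_kinetics(kcat_fwd = draws$kcat[j],
                                               km = km, mw = draws$mw[j]))
  })
  pathway_model(reactions = rxns,
                rel_flux = stats::setNames(rep(1, n), paste0("r", seq_len(n))),
                fixed_conc = c(A0 = 1),
                boundary = c(mets[1], mets[n + 1]))
}
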