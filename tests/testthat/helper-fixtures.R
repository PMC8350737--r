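# Shared fixtures and independent oracles used across the test files.

RT298 <- 8.314e-3 * 298.15

# the six transporter constants reported for the strain (Ki values are the
# package's synthetic-data defaults; the study never printed them)
tk_fitted <- function() transporter_kinetics(29.30, 40.21, 600, 3.18, 80.96, 200)

synthetic_params_path <- function() {
  system.file("extdata", "params_synthetic.tsv", package = "zymoflux",
              mustWork = TRUE)
}

glucose_pathway_param <- function(...) {
  merge_parameters(glucose_bdo_pathway(...),
                   load_parameter_table(synthetic_params_path()))
}

xylose_pathway_param <- function(...) {
  merge_parameters(xylose_bdo_pathway(...),
                   load_parameter_table(synthetic_params_path()))
}

# independent fine-step RK4 integrator for the dual-substrate uptake ODEs,
# written directly from the rate law (oracle for simulate_uptake and the
# synthetic generator; shares no code with the package's integration paths)
oracle_integrate_uptake <- function(p, g0, x0, biofun, t_end, h = 0.005) {
  rate <- function(g, x) {
    g <- max(g, 0); x <- max(x, 0)
    c(-p$vmax_glc * g / (p$km_glc * (1 + x / p$ki_xyl) + g),
      -p$vmax_xyl * x / (p$km_xyl * (1 + g / p$ki_glc) + x))
  }
  f <- function(t, y) rate(y[1], y[2]) * biofun(t)
  n <- ceiling(t_end / h)
  y <- c(g0, x0)
  t <- 0
  for (i in seq_len(n)) {
    hh <- min(h, t_end - t)
    k1 <- f(t, y); k2 <- f(t + hh / 2, y + hh / 2 * k1)
    k3 <- f(t + hh / 2, y + hh / 2 * k2); k4 <- f(t + hh, y + hh * k3)
    y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + hh
    if (t >= t_end) break
  }
  y
}

# brute-force maximin oracle for chain pathways A0 -> ... -> An with A0
# pinned: exhaustive search over a log-concentration grid, evaluated by
# dynamic programming over the chain (each reaction couples only adjacent
# metabolites, so the grid maximin factorizes exactly)
oracle_chain_mdf <- function(pathway, n_grid = 400) {
  rxns <- pathway$reactions
  n <- length(rxns)
  lb <- log(pathway$conc_lb / 1000)
  ub <- log(pathway$conc_ub / 1000)
  grid <- seq(lb, ub, length.out = n_grid)
  x_pin <- log(pathway$fixed_conc[["A0"]] / 1000)
  dg0 <- vapply(rxns, `[[`, numeric(1), "dg0_prime")
  # F[j] = best achievable min over reactions 1..j as function of x_j
  f_prev <- -(dg0[1] + RT298 * (grid - x_pin))     # reaction 1: A0 -> A1
  for (j in seq_len(n)[-1]) {
    # reaction j: A_{j-1} (value v) -> A_j (grid)
    best <- numeric(n_grid)
    for (i in seq_len(n_grid)) {
      neg_dg <- -(dg0[j] + RT298 * (grid[i] - grid))
      best[i] <- max(pmin(f_prev, neg_dg))
    }
    f_prev <- best
  }
  max(f_prev)
}

# independent enzyme-demand formula (common modular rate law), written
# straight from the factorization E = MW v / (kcat eta_rev eta_sat)
oracle_demand <- function(mw, kcat, flux, dg, stoich, km_mM, conc_M,
                          irreversible = FALSE) {
  eta_rev <- if (irreversible) 1 else 1 - exp(dg / RT298)
  km_M <- km_mM / 1000
  subs <- names(stoich)[stoich < 0]
  prods <- if (irreversible) character(0) else names(stoich)[stoich > 0]
  subs <- intersect(subs, names(km_M)); prods <- intersect(prods, names(km_M))
  num <- prod((conc_M[subs] / km_M[subs])^abs(stoich[subs]))
  den <- prod((1 + conc_M[subs] / km_M[subs])^abs(stoich[subs])) +
    prod((1 + conc_M[prods] / km_M[prods])^abs(stoich[prods])) - 1
  mw * flux / (kcat * eta_rev * (num / den))
}

# minimal batch-trajectory stand-in for productivity bookkeeping tests
fake_trajectory <- function(time_h, bdo_mM) {
  structure(list(states = data.frame(time_h = time_h, bdo_mM = bdo_mM)),
            class = "batch_trajectory")
}

# carbon bookkeeping for the shipped core network
core_carbon <- c(glc = 6, xyl = 5, bdo = 4, actn = 4, glyc = 3, co2 = 1,
                 etoh = 2, acald = 2)

# carbon content of biomass implied by the shipped biomass reaction,
# mmol C per gDCW, recomputed from the precursor drains
biomass_carbon_mmol <- function() {
  prec <- c(g6p = 6, r5p = 5, e4p = 4, g3p = 3, pg3 = 3, pep = 3, pyr = 3)
  bm <- zymoflux:::.BIOMASS_STOICH
  sum(-bm[names(prec)] * prec)
}
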