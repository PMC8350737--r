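# Dynamic flux balance analysis in the static optimization approach:
# kinetic exchange bounds from the extracellular state, a lexicographic FBA
# solve per step, and integration of the extracellular mass balances with
# fluxes frozen over the step. Dissolved oxygen is stiff (its Michaelis
# constant is three orders of magnitude below the mM scale of the other
# species), so within each step it follows the exact solution of its linear
# ODE instead of an explicit Euler update.

#' Oxygen gas-liquid transfer parameters
#'
#' @param kla volumetric mass-transfer coefficient, h^-1 (default 30, the
#'   modeled value at 300 rpm).
#' @param o2_sat saturation (gas-phase equilibrium) dissolved oxygen, mM
#'   (default 0.21).
#' @return list of class `gas_transfer`.
#' @export
gas_transfer <- function(kla = 30, o2_sat = 0.21) {
  if (kla < 0 || o2_sat <= 0) {
    stop_zf("kla must be >= 0 and o2_sat > 0", "zf_bad_gas")
  }
  structure(list(kla = kla, o2_sat = o2_sat), class = "gas_transfer")
}

#' Uptake kinetic limits for oxygen and fermentation products
#'
#' Michaelis-Menten caps on oxygen, acetoin and 2,3-BDO uptake. Defaults:
#' oxygen Vmax 15 mmol gDCW^-1 h^-1 with Km 1.24e-3 mM (1.24 uM);
#' acetoin and 2,3-BDO re-uptake Vmax 10 mmol gDCW^-1 h^-1 with Km 5 mM.
#'
#' @param vmax_o2,km_o2 oxygen uptake parameters (mmol gDCW^-1 h^-1, mM).
#' @param vmax_actn,km_actn,vmax_bdo,km_bdo product re-uptake parameters.
#' @return list of class `uptake_limits`.
#' @export
uptake_limits <- function(vmax_o2 = 15, km_o2 = 1.24e-3,
                          vmax_actn = 10, km_actn = 5,
                          vmax_bdo = 10, km_bdo = 5) {
  p <- c(vmax_o2 = vmax_o2, km_o2 = km_o2, vmax_actn = vmax_actn,
         km_actn = km_actn, vmax_bdo = vmax_bdo, km_bdo = km_bdo)
  if (any(p <= 0)) stop_zf("all uptake limits must be positive", "zf_bad_limits")
  structure(as.list(p), class = "uptake_limits")
}

#' Extracellular state of a batch
#'
#' @param glc,xyl,o2,actn,bdo,glyc concentrations, mM.
#' @param biomass gDCW L^-1.
#' @param time h.
#' @return list of class `extracellular_state`.
#' @export
extracellular_state <- function(glc = 443, xyl = 245, o2 = 0.21,
                                actn = 0, bdo = 0, glyc = 0,
                                biomass = od_to_biomass(0.84), time = 0) {
  s <- list(glc = glc, xyl = xyl, o2 = o2, actn = actn, bdo = bdo,
            glyc = glyc, biomass = biomass, time = time)
  if (any(unlist(s) < 0)) {
    stop_zf("state variables must be non-negative", "zf_bad_state")
  }
  structure(s, class = "extracellular_state")
}

#' Convert optical density to dry-cell-weight concentration
#'
#' @param od600 optical density at 600 nm.
#' @param factor gDCW L^-1 per OD unit (default 0.33; strain-specific and
#'   configurable, see the methods vignette).
#' @return gDCW L^-1.
#' @export
od_to_biomass <- function(od600, factor = 0.33) {
  if (any(od600 < 0)) stop_zf("od600 must be >= 0", "zf_bad_state")
  od600 * factor
}

#' Kinetic exchange bounds from the extracellular state
#'
#' Uptake lower bounds are set to minus the kinetic rates: sugars by the
#' competitive-inhibition model, oxygen/acetoin/2,3-BDO by plain
#' Michaelis-Menten. Products may be secreted freely (unbounded above);
#' acetoin and 2,3-BDO may be re-consumed up to their kinetic caps.
#'
#' @param state an [extracellular_state()].
#' @param tk [transporter_kinetics()].
#' @param ul [uptake_limits()].
#' @param reuptake allow acetoin/2,3-BDO re-consumption (default TRUE).
#' @return named list of `c(lb, ub)` pairs keyed by species
#'   (`glc`, `xyl`, `o2`, `actn`, `bdo`, `glyc`).
#' @export
exchange_bounds <- function(state, tk, ul, reuptake = TRUE) {
  mm <- function(vmax, km, s) vmax * s / (km + s)
  v <- uptake_rates(state$glc, state$xyl, tk)
  big <- 1000
  list(
    glc = c(-v$v_glc, 0),
    xyl = c(-v$v_xyl, 0),
    o2 = c(-mm(ul$vmax_o2, ul$km_o2, state$o2), 0),
    actn = c(if (reuptake) -mm(ul$vmax_actn, ul$km_actn, state$actn) else 0, big),
    bdo = c(if (reuptake) -mm(ul$vmax_bdo, ul$km_bdo, state$bdo) else 0, big),
    glyc = c(0, big)
  )
}

#' Plain FBA solve
#'
#' @param net a [core_network()].
#' @param objective reaction id.
#' @param maximize logical.
#' @param lb,ub optional bound overrides (named, full vectors).
#' @return list `flux` (named vector), `objval`, `feasible`.
#' @export
solve_fba <- function(net, objective = net$biomass_reaction,
                      maximize = TRUE, lb = net$lb, ub = net$ub) {
  n <- length(net$reactions)
  obj <- stats::setNames(numeric(n), net$reactions)
  obj[objective] <- 1
  sol <- lp_solve(obj, Aeq = net$S, beq = rep(0, nrow(net$S)),
                  lb = lb[net$reactions], ub = ub[net$reactions],
                  maximize = maximize)
  flux <- stats::setNames(sol$x, net$reactions)
  list(flux = flux, objval = sol$objval, feasible = sol$feasible)
}

#' Lexicographic FBA
#'
#' Sequentially optimizes: (1) max biomass, (2) max 2,3-BDO export, (3) max
#' acetoin export, (4) max glycerol export, (5) min glucose uptake, (6) min
#' xylose uptake, (7) min oxygen uptake — fixing each optimum (within 1e-6
#' relative) before the next. Stages (5)-(7) are maximizations of the
#' (negative) exchange fluxes. An infeasible primary stage returns the
#' zero-flux vector with `feasible = FALSE`.
#'
#' @param net a [core_network()].
#' @param bounds named list of `c(lb, ub)` exchange overrides as produced
#'   by [exchange_bounds()].
#' @return list `flux`, `growth`, `feasible`.
#' @export
solve_lex_fba <- function(net, bounds = list()) {
  lb <- net$lb; ub <- net$ub
  for (sp in names(bounds)) {
    id <- net$exchange_ids[[sp]]
    if (is.null(id)) next
    lb[id] <- bounds[[sp]][1]
    ub[id] <- bounds[[sp]][2]
  }
  stages <- c(net$biomass_reaction,
              net$exchange_ids$bdo, net$exchange_ids$actn,
              net$exchange_ids$glyc, net$exchange_ids$glc,
              net$exchange_ids$xyl, net$exchange_ids$o2)
  flux <- NULL
  for (k in seq_along(stages)) {
    sol <- solve_fba(net, objective = stages[k], maximize = TRUE,
                     lb = lb, ub = ub)
    if (!sol$feasible) {
      if (k == 1) {
        return(list(flux = stats::setNames(numeric(length(net$reactions)),
                                           net$reactions),
                    growth = 0, feasible = FALSE))
      }
      break  # keep the last feasible stage's vertex
    }
    flux <- sol$flux
    v <- sol$objval
    tol <- 1e-6 * max(1, abs(v))
    lb[stages[k]] <- max(lb[stages[k]], v - tol)
  }
  list(flux = flux, growth = flux[[net$biomass_reaction]], feasible = TRUE)
}

#' Simulate batch growth by dynamic FBA (static optimization approach)
#'
#' Loops over time steps of width `dt`: kinetic exchange bounds are derived
#' from the current state, a lexicographic FBA is solved, and the
#' extracellular balances are integrated with fluxes frozen. Biomass grows
#' exponentially within the step at the solved rate; sugar/product updates
#' use the step-averaged biomass; dissolved oxygen follows the exact
#' within-step solution of `d[o2]/dt = -v_o2 X + kla (o2* - [o2])`.
#' Concentrations are clamped at zero. Infeasible steps advance the state
#' with zero biological flux (abiotic oxygen transfer still applies) and
#' are flagged in the diagnostics.
#'
#' @param net a [core_network()].
#' @param tk [transporter_kinetics()].
#' @param ul [uptake_limits()].
#' @param gas [gas_transfer()].
#' @param init initial [extracellular_state()].
#' @param t_end batch length, h (default 65).
#' @param dt step, h (default 0.1).
#' @param reuptake allow acetoin/2,3-BDO re-consumption.
#' @return object of class `batch_trajectory`: `states` (data frame of the
#'   extracellular state over time), `fluxes` (steps x reactions matrix),
#'   `growth_rate` (h^-1 per step), `diagnostics` (per-step feasibility).
#' @export
simulate_batch <- function(net, tk, ul = uptake_limits(),
                           gas = gas_transfer(), init = extracellular_state(),
                           t_end = 65, dt = 0.1, reuptake = TRUE) {
  if (dt <= 0 || t_end < dt) stop_zf("need dt > 0 and t_end >= dt", "zf_bad_grid")
  n_steps <- ceiling(t_end / dt - 1e-9)
  times <- seq(0, by = dt, length.out = n_steps + 1)
  times[n_steps + 1] <- min(times[n_steps + 1], t_end)
  st <- init
  states <- matrix(NA_real_, n_steps + 1, 8,
                   dimnames = list(NULL, c("time_h", "glc_mM", "xyl_mM",
                                           "o2_mM", "actn_mM", "bdo_mM",
                                           "glyc_mM", "biomass_gdcw_L")))
  fluxes <- matrix(NA_real_, n_steps, length(net$reactions),
                   dimnames = list(NULL, net$reactions))
  mu <- numeric(n_steps)
  feas <- logical(n_steps)
  as_row <- function(s) c(s$time, s$glc, s$xyl, s$o2, s$actn, s$bdo,
                          s$glyc, s$biomass)
  states[1, ] <- as_row(st)
  ex <- net$exchange_ids
  for (k in seq_len(n_steps)) {
    h <- times[k + 1] - times[k]
    bnds <- exchange_bounds(st, tk, ul, reuptake = reuptake)
    sol <- solve_lex_fba(net, bnds)
    v <- sol$flux
    feas[k] <- sol$feasible
    fluxes[k, ] <- v
    g <- if (sol$feasible) sol$growth else 0
    mu[k] <- g
    X0 <- st$biomass
    X1 <- X0 * exp(g * h)
    # step-averaged biomass for the frozen-flux mass balances
    Xbar <- if (abs(g) > 1e-12) X0 * (exp(g * h) - 1) / (g * h) else X0
    upd <- function(cur, sp) max(0, cur + v[[ex[[sp]]]] * Xbar * h)
    st$glc <- upd(st$glc, "glc")
    st$xyl <- upd(st$xyl, "xyl")
    st$actn <- upd(st$actn, "actn")
    st$bdo <- upd(st$bdo, "bdo")
    st$glyc <- upd(st$glyc, "glyc")
    # oxygen: exact within-step solution of the linear ODE
    vo2 <- v[[ex$o2]]  # <= 0 (uptake)
    if (gas$kla > 0) {
      a <- gas$kla * gas$o2_sat + vo2 * Xbar
      o2_inf <- a / gas$kla
      st$o2 <- max(0, o2_inf + (st$o2 - o2_inf) * exp(-gas$kla * h))
    } else {
      st$o2 <- max(0, st$o2 + vo2 * Xbar * h)
    }
    st$biomass <- X1
    st$time <- times[k + 1]
    states[k + 1, ] <- as_row(st)
  }
  structure(list(states = as.data.frame(states), fluxes = fluxes,
                 growth_rate = mu, diagnostics = data.frame(
                   time_h = times[-length(times)], feasible = feas)),
            class = "batch_trajectory")
}

#' @export
print.batch_trajectory <- function(x, ...) {
  fin <- x$states[nrow(x$states), ]
  cat(sprintf("Batch trajectory: %d steps over %.1f h; final BDO %.1f mM, biomass %.2f gDCW/L\n",
              nrow(x$fluxes), fin$time_h, fin$bdo_mM, fin$biomass_gdcw_L))
  invisible(x)
}

#' Write a batch trajectory as TSV
#' @param traj a `batch_trajectory`.
#' @param path output file.
#' @export
write_trajectory_tsv <- function(traj, path) {
  df <- traj$states
  df$mu_per_h <- c(traj$growth_rate, NA)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the per-step solved flux vectors as CSV
#'
#' One row per time step (`time_h` first column), one column per reaction,
#' fluxes in mmol gDCW^-1 h^-1.
#'
#' @param traj a `batch_trajectory`.
#' @param path output file.
#' @export
write_flux_csv <- function(traj, path) {
  df <- data.frame(time_h = traj$diagnostics$time_h, traj$fluxes,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
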