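# Enzyme protein cost: minimal total enzyme mass per unit pathway flux,
# g (mol s^-1)^-1, under a common modular rate law with Haldane-consistent
# reverse rates. The demand of one reaction factorizes as
#   E = MW * v / (kcat_fwd * eta_rev * eta_sat)
# with eta_rev = 1 - exp(dG'/RT) (1 for irreversible steps) and eta_sat the
# common-modular saturation term. The total cost is minimized over free log
# concentrations by sequential quadratic programming with multiple starts.

.ECM_EPS_DG <- 1e-3  # strict forward feasibility: dG' <= -1e-3 kJ/mol

#' Haldane-consistent reverse turnover number
#'
#' `K_eq = exp(-dG0'/RT)`;
#' `kcat_rev = kcat_fwd * prod_P Km^|nu| / (K_eq * prod_S Km^|nu|)` with the
#' Michaelis constants converted to molar.
#'
#' @param kin an [enzyme_kinetics()] with `irreversible = FALSE`.
#' @param dg0_prime standard Gibbs energy, kJ mol^-1.
#' @param stoich signed stoichiometry of the reaction.
#' @param temperature K.
#' @return s^-1.
#' @export
haldane_kcat_rev <- function(kin, dg0_prime, stoich, temperature = 298.15) {
  if (kin$irreversible) {
    stop_zf("reverse rate undefined for an irreversible reaction",
            "zf_irreversible")
  }
  miss <- setdiff(names(stoich), names(kin$km))
  if (length(miss)) {
    stop_zf(paste("missing Km for:", paste(miss, collapse = ", ")),
            "zf_missing_km")
  }
  keq <- exp(-dg0_prime / rt_kj(temperature))
  km_M <- kin$km / 1000
  subs <- names(stoich)[stoich < 0]
  prods <- names(stoich)[stoich > 0]
  kin$kcat_fwd * prod(km_M[prods]^abs(stoich[prods])) /
    (keq * prod(km_M[subs]^abs(stoich[subs])))
}

# thermodynamic and saturation efficiencies of one reaction at ln_conc.
# Species absent from the Km map do not enter the saturation term; for
# irreversible reactions the product terms are dropped entirely.
reaction_efficiencies <- function(rxn, ln_conc, temperature) {
  kin <- rxn$kinetics
  dg <- reaction_dg(rxn, ln_conc, temperature)
  irr <- kin$irreversible || !rxn$reversible
  eta_rev <- if (irr) 1 else 1 - exp(dg / rt_kj(temperature))
  km_M <- kin$km / 1000
  sat_names <- intersect(names(rxn$stoich), names(km_M))
  subs <- sat_names[rxn$stoich[sat_names] < 0]
  prods <- if (irr) character(0) else sat_names[rxn$stoich[sat_names] > 0]
  conc <- exp(ln_conc)
  s_ratio <- conc[subs] / km_M[subs]
  p_ratio <- conc[prods] / km_M[prods]
  nu_s <- abs(rxn$stoich[subs])
  nu_p <- abs(rxn$stoich[prods])
  num <- prod(s_ratio^nu_s)
  den <- prod((1 + s_ratio)^nu_s) + prod((1 + p_ratio)^nu_p) - 1
  list(dg = dg, eta_rev = eta_rev, eta_sat = num / den)
}

#' Enzyme demand of one reaction at given concentrations
#'
#' `demand = MW * v / (kcat_fwd * eta_rev * eta_sat)` in g, for a flux `v`
#' in mol s^-1. Reversible reactions must be thermodynamically feasible
#' (`dG' < 0`) at the supplied concentrations.
#'
#' @param rxn a [thermo_reaction()] carrying [enzyme_kinetics()].
#' @param ln_conc named log concentrations, ln(M).
#' @param flux reaction flux, mol s^-1 (> 0).
#' @param temperature K.
#' @return g of enzyme.
#' @export
enzyme_demand <- function(rxn, ln_conc, flux, temperature = 298.15) {
  if (is.null(rxn$kinetics)) {
    stop_zf(sprintf("reaction %s carries no kinetics", rxn$id),
            "zf_missing_kinetics")
  }
  if (flux <= 0) stop_zf("flux must be > 0", "zf_bad_flux")
  eff <- reaction_efficiencies(rxn, ln_conc, temperature)
  if (!(rxn$kinetics$irreversible || !rxn$reversible) && eff$dg >= 0) {
    stop_zf(sprintf("reaction %s thermodynamically infeasible (dG' = %.3g >= 0)",
                    rxn$id, eff$dg), "zf_infeasible")
  }
  rxn$kinetics$mw * flux / (rxn$kinetics$kcat_fwd * eff$eta_rev * eff$eta_sat)
}

# total pathway cost (and per-enzyme breakdown) at a full ln-conc vector
pathway_cost_at <- function(pathway, ln_conc) {
  per <- vapply(pathway$reactions, function(r) {
    enzyme_demand(r, ln_conc, flux = pathway$rel_flux[[r$id]],
                  temperature = pathway$temperature)
  }, numeric(1))
  list(per_enzyme = per, total = sum(per))
}

#' Minimize total enzyme cost of a pathway
#'
#' Minimizes the summed enzyme demand per unit pathway flux (1 mol
#' 2,3-BDO s^-1; each reaction carries `rel_flux` mol s^-1) over the free
#' log concentrations, within the same bounds and pins as the MDF problem
#' and subject to `dG'_j <= -1e-3 kJ mol^-1` for every reversible reaction.
#' The MDF-optimal concentration vector seeds the first start (it is
#' feasible whenever the pathway MDF is positive); the remaining starts are
#' feasibility-filtered jitters of it. Deterministic given `seed`.
#'
#' @param pathway a [pathway_model()] whose reactions all carry kinetics
#'   and `dg0_prime`.
#' @param n_starts number of optimizer starts (default 10).
#' @param seed integer seed for the jittered starts.
#' @param mdf_sol optionally, a precomputed [optimize_mdf()] solution.
#' @param x0 optional named warm-start vector (ln M) tried as an extra
#'   start (used by [timecourse_cost()]).
#' @return object of class `ecm_solution`: `total_cost`, `per_enzyme_cost`,
#'   `per_enzyme_share`, `ln_conc`, `dg_prime`, `converged`.
#' @export
minimize_pathway_cost <- function(pathway, n_starts = 10L, seed = 1L,
                                  mdf_sol = NULL, x0 = NULL) {
  for (r in pathway$reactions) {
    if (is.null(r$kinetics)) {
      stop_zf(sprintf("reaction %s carries no kinetics", r$id),
              "zf_missing_kinetics")
    }
  }
  mdf_sol <- mdf_sol %||% optimize_mdf(pathway)
  if (mdf_sol$mdf <= 0) {
    tight <- names(which.max(mdf_sol$dg_prime))
    stop_zf(sprintf("pathway MDF <= 0; no feasible interior (bottleneck: %s)",
                    tight), "zf_infeasible")
  }
  lay <- conc_layout(pathway)
  nf <- length(lay$free)
  rev_ids <- names(Filter(function(r) r$reversible && !r$kinetics$irreversible,
                          pathway$reactions))

  full_x <- function(xf) {
    x <- c(stats::setNames(xf, lay$free), lay$x_pin)
    x[lay$mets]
  }
  fn <- function(xf) {
    x <- full_x(xf)
    tot <- 0
    for (r in pathway$reactions) {
      eff <- reaction_efficiencies(r, x, pathway$temperature)
      if (!(r$kinetics$irreversible || !r$reversible) && eff$dg >= 0) {
        return(1e12)  # outside the constrained region (line-search guard)
      }
      tot <- tot + r$kinetics$mw * pathway$rel_flux[[r$id]] /
        (r$kinetics$kcat_fwd * eff$eta_rev * eff$eta_sat)
    }
    tot
  }
  # feasibility constraints hin(x) <= 0: dg_j + eps <= 0
  hin <- function(xf) {
    x <- full_x(xf)
    vapply(rev_ids, function(id) {
      reaction_dg(pathway$reactions[[id]], x, pathway$temperature) +
        .ECM_EPS_DG
    }, numeric(1))
  }
  feasible <- function(xf) length(rev_ids) == 0 || all(hin(xf) < 0)

  x_mdf <- mdf_sol$ln_conc[lay$free]
  starts <- list(x_mdf)
  if (!is.null(x0)) {
    x0f <- pmin(pmax(x0[lay$free], lay$lb), lay$ub)
    if (feasible(x0f)) starts <- c(starts, list(x0f))
  }
  jit <- with_seed(seed, replicate(max(0L, n_starts - length(starts)), {
    cand <- x_mdf + stats::rnorm(nf, sd = 1.0)
    pmin(pmax(cand, lay$lb), lay$ub)
  }, simplify = FALSE))
  starts <- c(starts, Filter(feasible, jit))

  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      nloptr::slsqp(unname(st), fn = fn,
                    lower = rep(lay$lb, nf), upper = rep(lay$ub, nf),
                    hin = if (length(rev_ids)) hin else NULL,
                    control = list(xtol_rel = 1e-9, maxeval = 2000),
                    deprecatedBehavior = FALSE),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$value)) next
    if (!feasible(opt$par)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    stop_zf("enzyme-cost optimization failed from every start", "zf_ecm_failure")
  }
  # never worse than the cost at the MDF optimum itself
  if (fn(x_mdf) < best$value) best <- list(par = unname(x_mdf), value = fn(x_mdf))
  x <- full_x(best$par)
  cost <- pathway_cost_at(pathway, x)
  dg <- vapply(pathway$reactions, reaction_dg, numeric(1),
               ln_conc = x, temperature = pathway$temperature)
  structure(list(total_cost = cost$total,
                 per_enzyme_cost = cost$per_enzyme,
                 per_enzyme_share = cost$per_enzyme / cost$total,
                 ln_conc = x, dg_prime = dg, converged = TRUE),
            class = "ecm_solution")
}

#' @export
print.ecm_solution <- function(x, ...) {
  top <- names(which.max(x$per_enzyme_cost))
  cat(sprintf("Enzyme cost: total %.4g g/(mol/s); largest share %s (%.0f%%)\n",
              x$total_cost, top, 100 * x$per_enzyme_share[[top]]))
  invisible(x)
}

#' Enzyme cost along a fermentation substrate series
#'
#' Re-solves the cost minimization at each timepoint with pinned substrate
#' concentrations taken from the series (clipped at `floor_mM`), warm-
#' starting each solve from the previous optimum. Timepoints where the
#' pathway is thermodynamically infeasible are reported with `NA` cost and
#' `feasible = FALSE`, never dropped.
#'
#' @param pathway a [pathway_model()] with kinetics on every reaction.
#' @param substrate_series data frame with `time_h` plus one column per
#'   pinned metabolite (mM).
#' @param n_starts optimizer starts per timepoint (warm start plus MDF
#'   start are always included).
#' @param seed integer seed.
#' @param floor_mM substrate clipping floor, mM.
#' @return data frame `time_h`, `total_cost`, `feasible`, plus one
#'   `cost_<id>` column per reaction.
#' @export
timecourse_cost <- function(pathway, substrate_series, n_starts = 2L,
                            seed = 1L, floor_mM = 1e-3) {
  pins <- intersect(names(substrate_series), names(pathway$fixed_conc))
  if (!length(pins)) {
    stop_zf("substrate_series has no column matching a pinned metabolite",
            "zf_bad_series")
  }
  n <- nrow(substrate_series)
  ids <- names(pathway$reactions)
  per <- matrix(NA_real_, n, length(ids),
                dimnames = list(NULL, paste0("cost_", ids)))
  total <- rep(NA_real_, n)
  ok <- rep(FALSE, n)
  prev_x <- NULL
  for (i in seq_len(n)) {
    pw <- pathway
    pw$fixed_conc[pins] <- pmax(as.numeric(substrate_series[i, pins]),
                                floor_mM)
    sol <- tryCatch(
      minimize_pathway_cost(pw, n_starts = n_starts, seed = seed,
                            x0 = prev_x),
      error = function(e) NULL
    )
    if (!is.null(sol)) {
      total[i] <- sol$total_cost
      per[i, ] <- sol$per_enzyme_cost[ids]
      ok[i] <- TRUE
      prev_x <- sol$ln_conc
    }
  }
  out <- data.frame(time_h = substrate_series$time_h, total_cost = total,
                    feasible = ok)
  cbind(out, per)
}
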