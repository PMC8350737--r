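# Pathway representation: ordered enzyme reactions with stoichiometry,
# standard Gibbs energies, kinetics, and a relative flux per unit pathway
# flux (mol per mol 2,3-BDO). Water and protons are excluded from
# stoichiometries by convention (absorbed into the transformed standard
# Gibbs energies).

#' Enzyme kinetic parameters for one reaction
#'
#' @param kcat_fwd forward turnover number, s^-1.
#' @param km named vector of Michaelis constants, mM (names are metabolite
#'   ids; species without an entry are treated as non-saturating, e.g. CO2).
#' @param mw enzyme molecular weight, g mol^-1.
#' @param irreversible logical; irreversible reactions have no reverse rate
#'   and their products do not enter the saturation term.
#' @return list of class `enzyme_kinetics`.
#' @export
enzyme_kinetics <- function(kcat_fwd, km, mw, irreversible = FALSE) {
  if (!is.finite(kcat_fwd) || kcat_fwd <= 0) {
    stop_zf("kcat_fwd must be > 0", "zf_bad_kinetics")
  }
  if (length(km) && (is.null(names(km)) || any(km <= 0))) {
    stop_zf("km must be a named vector of positive mM values", "zf_bad_kinetics")
  }
  if (!is.finite(mw) || mw <= 0) stop_zf("mw must be > 0", "zf_bad_kinetics")
  structure(list(kcat_fwd = kcat_fwd, km = km, mw = mw,
                 irreversible = isTRUE(irreversible)),
            class = "enzyme_kinetics")
}

#' A single pathway reaction with thermodynamic (and optional kinetic) data
#'
#' @param id enzyme abbreviation (e.g. `glf`, `glk`, `g6pdh`, ...).
#' @param stoich named numeric vector: signed stoichiometric coefficients,
#'   substrates negative.
#' @param dg0_prime transformed standard Gibbs energy, kJ mol^-1 (may be
#'   `NA` until a parameter table is merged).
#' @param reversible logical.
#' @param kinetics optional [enzyme_kinetics()].
#' @return list of class `thermo_reaction`.
#' @export
thermo_reaction <- function(id, stoich, dg0_prime = NA_real_,
                            reversible = TRUE, kinetics = NULL) {
  if (!length(stoich) || is.null(names(stoich)) || any(names(stoich) == "")) {
    stop_zf("stoich must be a non-empty named vector", "zf_bad_reaction")
  }
  structure(list(id = id, stoich = stoich, dg0_prime = dg0_prime,
                 reversible = isTRUE(reversible), kinetics = kinetics),
            class = "thermo_reaction")
}

#' Ordered pathway model
#'
#' Bundles an ordered list of reactions with the relative flux each carries
#' per unit pathway flux (mol per mol 2,3-BDO), pinned metabolite
#' concentrations (extracellular sugars), concentration bounds for the free
#' metabolites, and the temperature used for thermodynamic calculations.
#'
#' The steady-state invariant is enforced at construction: for every
#' intermediate (any metabolite not listed in `boundary`),
#' `sum_j rel_flux_j * stoich_ij = 0`.
#'
#' @param reactions list of [thermo_reaction()] in pathway order.
#' @param rel_flux named positive vector, one entry per reaction id.
#' @param fixed_conc named vector of pinned concentrations, mM.
#' @param conc_lb,conc_ub concentration bounds for free metabolites, mM
#'   (defaults 1e-3 mM = 1 uM, and 10 mM).
#' @param boundary character vector of boundary species exempt from the
#'   steady-state balance (substrates, products, cofactors).
#' @param temperature K (default 298.15, the standard-state convention of
#'   the Gibbs energy source).
#' @return list of class `pathway_model`.
#' @export
pathway_model <- function(reactions, rel_flux, fixed_conc = numeric(),
                          conc_lb = .CONC_LB_MM, conc_ub = .CONC_UB_MM,
                          boundary = character(), temperature = 298.15) {
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop_zf("duplicate reaction ids", "zf_bad_pathway")
  if (!setequal(names(rel_flux), ids)) {
    stop_zf("rel_flux must name every reaction exactly once", "zf_bad_pathway")
  }
  if (any(rel_flux <= 0)) stop_zf("every rel_flux must be > 0", "zf_bad_pathway")
  rel_flux <- rel_flux[ids]
  names(reactions) <- ids
  pw <- structure(list(reactions = reactions, rel_flux = rel_flux,
                       fixed_conc = fixed_conc, conc_lb = conc_lb,
                       conc_ub = conc_ub, boundary = boundary,
                       temperature = temperature),
                  class = "pathway_model")
  bal <- net_balance(pw)
  inter <- setdiff(names(bal), boundary)
  bad <- inter[abs(bal[inter]) > 1e-9]
  if (length(bad)) {
    stop_zf(paste("steady-state violation at intermediate(s):",
                  paste(bad, collapse = ", ")), "zf_steady_state")
  }
  pw
}

#' All metabolites appearing in a pathway
#' @param pathway a [pathway_model()].
#' @return character vector in order of first appearance.
#' @export
pathway_metabolites <- function(pathway) {
  unique(unlist(lapply(pathway$reactions, function(r) names(r$stoich))))
}

#' Flux-weighted net stoichiometry over all metabolites
#' @noRd
net_balance <- function(pathway) {
  mets <- pathway_metabolites(pathway)
  bal <- stats::setNames(numeric(length(mets)), mets)
  for (r in pathway$reactions) {
    bal[names(r$stoich)] <- bal[names(r$stoich)] +
      pathway$rel_flux[[r$id]] * r$stoich
  }
  bal
}

#' Net stoichiometric yields per mol 2,3-BDO
#'
#' Flux-weighted net stoichiometry of the boundary species, i.e.
#' `sum_j rel_flux_j * stoich_ij` for substrates, products and cofactors.
#' If a `bdo` entry is present the yields are normalized so the
#' 2,3-BDO coefficient equals +1.
#'
#' @param pathway a [pathway_model()] (steady state is validated at
#'   construction).
#' @return named numeric vector of yields, mol per mol 2,3-BDO; empty
#'   pathway gives an empty vector.
#' @export
net_yields <- function(pathway) {
  if (!length(pathway$reactions)) return(stats::setNames(numeric(0), character(0)))
  bal <- net_balance(pathway)
  y <- bal[intersect(names(bal), pathway$boundary)]
  if ("bdo" %in% names(y) && abs(y[["bdo"]]) > 1e-12) {
    y <- y / y[["bdo"]]
  }
  y
}

#' Per-pathway carbon balance check
#'
#' Given carbon counts for the boundary species, verifies that substrate
#' carbon equals product carbon.
#'
#' @param pathway a [pathway_model()].
#' @param carbon named vector of carbon atom counts per metabolite.
#' @return the signed carbon imbalance (mol C per mol BDO); 0 when balanced.
#' @export
carbon_balance <- function(pathway, carbon) {
  y <- net_yields(pathway)
  common <- intersect(names(y), names(carbon))
  sum(y[common] * carbon[common])
}

# ---------------------------------------------------------------------------
# shipped pathways: glucose -> 2,3-BDO via the Entner-Doudoroff route, and
# xylose -> 2,3-BDO via the pentose phosphate rearrangement feeding ED and
# lower glycolysis. Thermodynamic and kinetic fields are NA until a
# parameter table is merged (see merge_parameters()).

.BOUNDARY_METS <- c("glc_ext", "xyl_ext", "bdo", "co2",
                    "atp", "adp", "nad", "nadh", "nadp", "nadph", "pi")

#' Carbon atom counts of the species tracked in the shipped pathways
#' @export
carbon_counts <- function() {
  c(glc_ext = 6, xyl_ext = 5, glc = 6, xyl = 5, xlu = 5,
    g6p = 6, f6p = 6, pgl6 = 6, pg6 = 6, kdpg = 6,
    x5p = 5, ru5p = 5, r5p = 5, s7p = 7, e4p = 4,
    g3p = 3, dpg13 = 3, pg3 = 3, pg2 = 3, pep = 3, pyr = 3,
    alac = 5, actn = 4, bdo = 4, co2 = 1)
}

glucose_reactions <- function() {
  s <- function(...) {
    v <- c(...)
    stats::setNames(as.numeric(v), names(v))
  }
  list(
    thermo_reaction("glf", s(glc_ext = -1, glc = 1), dg0_prime = 0,
                    reversible = FALSE),
    thermo_reaction("glk", s(glc = -1, atp = -1, g6p = 1, adp = 1)),
    thermo_reaction("g6pdh", s(g6p = -1, nadp = -1, pgl6 = 1, nadph = 1)),
    thermo_reaction("pgl", s(pgl6 = -1, pg6 = 1)),
    thermo_reaction("edd", s(pg6 = -1, kdpg = 1)),
    thermo_reaction("eda", s(kdpg = -1, pyr = 1, g3p = 1)),
    thermo_reaction("gapdh", s(g3p = -1, nad = -1, pi = -1,
                               dpg13 = 1, nadh = 1)),
    thermo_reaction("pgk", s(dpg13 = -1, adp = -1, pg3 = 1, atp = 1)),
    thermo_reaction("pgm", s(pg3 = -1, pg2 = 1)),
    thermo_reaction("eno", s(pg2 = -1, pep = 1)),
    thermo_reaction("pyk", s(pep = -1, adp = -1, pyr = 1, atp = 1)),
    thermo_reaction("als", s(pyr = -2, alac = 1, co2 = 1),
                    reversible = FALSE),
    thermo_reaction("aldc", s(alac = -1, actn = 1, co2 = 1),
                    reversible = FALSE),
    thermo_reaction("bdh", s(actn = -1, nadh = -1, bdo = 1, nad = 1))
  )
}

xylose_reactions <- function() {
  s <- function(...) {
    v <- c(...)
    stats::setNames(as.numeric(v), names(v))
  }
  c(list(
    thermo_reaction("glf", s(xyl_ext = -1, xyl = 1), dg0_prime = 0,
                    reversible = FALSE),
    thermo_reaction("xyl", s(xyl = -1, xlu = 1)),
    thermo_reaction("xk", s(xlu = -1, atp = -1, x5p = 1, adp = 1)),
    thermo_reaction("rpe", s(x5p = -1, ru5p = 1)),
    thermo_reaction("rpi", s(ru5p = -1, r5p = 1)),
    thermo_reaction("tkt1", s(x5p = -1, r5p = -1, s7p = 1, g3p = 1)),
    thermo_reaction("tal", s(s7p = -1, g3p = -1, f6p = 1, e4p = 1)),
    thermo_reaction("tkt2", s(x5p = -1, e4p = -1, f6p = 1, g3p = 1)),
    thermo_reaction("pgi", s(f6p = -1, g6p = 1))
  ), glucose_reactions()[-(1:2)])
}

#' Shipped glucose -> 2,3-BDO pathway
#'
#' Fourteen reactions (glf, glk, g6pdh, pgl, edd, eda, gapdh, pgk, pgm, eno,
#' pyk, als, aldc, bdh), each carrying unit relative flux per mol 2,3-BDO.
#' Sugar transport (glf) is irreversible with zero standard Gibbs energy;
#' the two decarboxylations (als, aldc) are treated irreversible by default.
#' Standard Gibbs energies and enzyme kinetics other than glf are `NA`
#' until merged from a parameter table ([merge_parameters()]).
#'
#' @param glc_ext_mM pinned extracellular glucose concentration, mM.
#' @param temperature K.
#' @return a [pathway_model()].
#' @export
glucose_bdo_pathway <- function(glc_ext_mM = 443, temperature = 298.15) {
  rxns <- glucose_reactions()
  ids <- vapply(rxns, `[[`, character(1), "id")
  pathway_model(rxns,
                rel_flux = stats::setNames(rep(1, length(rxns)), ids),
                fixed_conc = c(glc_ext = glc_ext_mM),
                boundary = .BOUNDARY_METS,
                temperature = temperature)
}

#' Shipped xylose -> 2,3-BDO pathway
#'
#' Xylose enters through glf, is isomerized and phosphorylated to
#' xylulose-5-P, rearranged in the pentose phosphate pathway and fed through
#' the Entner-Doudoroff route and lower glycolysis. The relative flux split
#' per mol 2,3-BDO (1.2 through glf/xyl/xk, 0.4 through rpe/rpi/tkt1/tal/
#' tkt2, 0.8 through pgi and the ED reactions, 1.2 through lower glycolysis,
#' 1 through als/aldc/bdh) is the unique split satisfying carbon balance
#' (1.2 x C5 = C4 + 2 x C1).
#'
#' @param xyl_ext_mM pinned extracellular xylose concentration, mM.
#' @param temperature K.
#' @return a [pathway_model()].
#' @export
xylose_bdo_pathway <- function(xyl_ext_mM = 245, temperature = 298.15) {
  rxns <- xylose_reactions()
  rel <- c(glf = 1.2, xyl = 1.2, xk = 1.2,
           rpe = 0.4, rpi = 0.4, tkt1 = 0.4, tal = 0.4, tkt2 = 0.4,
           pgi = 0.8, g6pdh = 0.8, pgl = 0.8, edd = 0.8, eda = 0.8,
           gapdh = 1.2, pgk = 1.2, pgm = 1.2, eno = 1.2, pyk = 1.2,
           als = 1, aldc = 1, bdh = 1)
  pathway_model(rxns, rel_flux = rel,
                fixed_conc = c(xyl_ext = xyl_ext_mM),
                boundary = .BOUNDARY_METS,
                temperature = temperature)
}

#' @export
print.pathway_model <- function(x, ...) {
  cat(sprintf("Pathway model: %d reactions, %d metabolites (%d pinned)\n",
              length(x$reactions), length(pathway_metabolites(x)),
              length(x$fixed_conc)))
  cat("  order:", paste(names(x$reactions), collapse = " -> "), "\n")
  invisible(x)
}
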