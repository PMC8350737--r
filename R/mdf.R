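# Pathway thermodynamics: reaction Gibbs energies at given log
# concentrations, and the max-min driving force (MDF) linear program over
# log metabolite concentrations.
#
# Concentrations are handled in molar inside this file (standard state 1 M);
# pathway-level pins and bounds arrive in mM and are converted here.

#' Gibbs energy of one reaction at given concentrations
#'
#' `dG' = dG0' + RT * sum_i nu_i * ln(c_i)` with concentrations in molar
#' (standard state 1 M) and `R = 8.314e-3 kJ mol^-1 K^-1`.
#'
#' @param rxn a [thermo_reaction()] with finite `dg0_prime`.
#' @param ln_conc named vector of log concentrations, ln(M).
#' @param temperature K.
#' @return kJ mol^-1.
#' @export
reaction_dg <- function(rxn, ln_conc, temperature = 298.15) {
  miss <- setdiff(names(rxn$stoich), names(ln_conc))
  if (length(miss)) {
    stop_zf(paste0("no concentration for metabolite(s): ",
                   paste(miss, collapse = ", "), " (reaction ", rxn$id, ")"),
            "zf_missing_metabolite")
  }
  if (is.na(rxn$dg0_prime)) {
    stop_zf(sprintf("reaction %s has no standard Gibbs energy", rxn$id),
            "zf_missing_dg0")
  }
  rxn$dg0_prime + rt_kj(temperature) *
    sum(rxn$stoich * ln_conc[names(rxn$stoich)])
}

# stoichiometric matrix (metabolites x reactions) of a pathway
pathway_smat <- function(pathway) {
  mets <- pathway_metabolites(pathway)
  S <- matrix(0, length(mets), length(pathway$reactions),
              dimnames = list(mets, names(pathway$reactions)))
  for (r in pathway$reactions) S[names(r$stoich), r$id] <- r$stoich
  S
}

# log-concentration layout shared by the MDF LP and the cost NLP:
# pins in ln M, free-metabolite bounds in ln M
conc_layout <- function(pathway) {
  mets <- pathway_metabolites(pathway)
  pinned <- intersect(names(pathway$fixed_conc), mets)
  if (length(pinned) < length(pathway$fixed_conc)) {
    extra <- setdiff(names(pathway$fixed_conc), mets)
    stop_zf(paste("fixed_conc names absent from pathway:",
                  paste(extra, collapse = ", ")), "zf_bad_pathway")
  }
  list(mets = mets, pinned = pinned, free = setdiff(mets, pinned),
       x_pin = log(pathway$fixed_conc[pinned] / 1000),
       lb = log(pathway$conc_lb / 1000), ub = log(pathway$conc_ub / 1000))
}

#' Max-min driving force optimization
#'
#' Maximizes `B` subject to `-(dG0'_j + RT * S_j' x) >= B` for every
#' reaction, `ln(lb) <= x <= ln(ub)` for free metabolites and `x` pinned at
#' the fixed concentrations, where `x` is the vector of log molar
#' concentrations. After the optimal `B` is found, a secondary LP minimizes
#' the total pathway Gibbs energy at fixed `B`, so the reported
#' concentration vector (and the cumulative profile) is well defined among
#' the maximin optima.
#'
#' @param pathway a [pathway_model()] whose reactions all carry `dg0_prime`.
#' @param extra_eq optional list `list(A, b)` of additional equality
#'   constraints `A x = b` on the full log-concentration vector (used by
#'   [cofactor_ratio_scan()]).
#' @return object of class `mdf_solution`: `mdf` (kJ mol^-1), `ln_conc`
#'   (named, ln M), `dg_prime` (named, kJ mol^-1), `cumulative_dg` (ordered
#'   partial sums), `total_dg`.
#' @export
optimize_mdf <- function(pathway, extra_eq = NULL) {
  lay <- conc_layout(pathway)
  S <- pathway_smat(pathway)
  RT <- rt_kj(pathway$temperature)
  dg0 <- vapply(pathway$reactions, `[[`, numeric(1), "dg0_prime")
  if (anyNA(dg0)) {
    stop_zf(paste("missing dg0_prime for:",
                  paste(names(dg0)[is.na(dg0)], collapse = ", ")),
            "zf_missing_dg0")
  }
  nf <- length(lay$free)
  nr <- ncol(S)
  # variables: x_free (nf), B (1)
  Sf <- t(S[lay$free, , drop = FALSE])         # nr x nf
  pin_term <- if (length(lay$pinned)) {
    as.numeric(t(S[lay$pinned, , drop = FALSE]) %*% lay$x_pin)
  } else rep(0, nr)
  # RT*Sf x + B <= -(dg0 + RT*pin_term)
  A <- cbind(RT * Sf, 1)
  b <- -(dg0 + RT * pin_term)
  Aeq <- beq <- NULL
  if (!is.null(extra_eq)) {
    Af <- extra_eq$A[, lay$free, drop = FALSE]
    bshift <- if (length(lay$pinned)) {
      as.numeric(extra_eq$A[, lay$pinned, drop = FALSE] %*% lay$x_pin)
    } else 0
    Aeq <- cbind(Af, 0)
    beq <- extra_eq$b - bshift
  }
  lb <- c(rep(lay$lb, nf), -1e3)
  ub <- c(rep(lay$ub, nf), 1e3)
  sol <- lp_solve(c(rep(0, nf), 1), A = A, b = b, Aeq = Aeq, beq = beq,
                  lb = lb, ub = ub, maximize = TRUE)
  if (!sol$feasible) {
    stop_zf("MDF LP infeasible (contradictory pins or constraints)",
            "zf_infeasible")
  }
  B <- sol$objval
  # secondary LP: fix B, minimize total dG' = const + RT * colSums over rxns
  obj2 <- as.numeric(RT * colSums(Sf))         # coefficient per free met
  A2 <- rbind(A, c(rep(0, nf), -1))
  b2 <- c(b, -(B - 1e-9))                      # B >= B* (within tolerance)
  sol2 <- lp_solve(c(obj2, 0), A = A2, b = b2, Aeq = Aeq, beq = beq,
                   lb = lb, ub = ub, maximize = FALSE)
  if (sol2$feasible) sol <- sol2
  x_free <- stats::setNames(sol$x[seq_len(nf)], lay$free)
  ln_conc <- c(x_free, lay$x_pin)[lay$mets]
  names(ln_conc) <- lay$mets
  dg <- vapply(pathway$reactions, reaction_dg, numeric(1),
               ln_conc = ln_conc, temperature = pathway$temperature)
  structure(list(mdf = B, ln_conc = ln_conc, dg_prime = dg,
                 cumulative_dg = cumsum(dg), total_dg = sum(dg)),
            class = "mdf_solution")
}

#' @export
print.mdf_solution <- function(x, ...) {
  cat(sprintf("MDF = %.3f kJ/mol; total pathway dG' = %.1f kJ/mol\n",
              x$mdf, x$total_dg))
  invisible(x)
}

#' Cumulative Gibbs energy profile along the pathway
#'
#' Ordered partial sums of the per-reaction Gibbs energies, either from an
#' [optimize_mdf()] solution or from any named `dg` vector (e.g. the
#' 1 mM reference profile of [reference_dg()]).
#'
#' @param sol an `mdf_solution`, or a named numeric vector of per-reaction
#'   Gibbs energies.
#' @param order reaction ids in pathway order (default: the order stored in
#'   the solution/vector).
#' @return named numeric vector of partial sums, kJ mol^-1.
#' @export
cumulative_profile <- function(sol, order = NULL) {
  dg <- if (inherits(sol, "mdf_solution")) sol$dg_prime else sol
  order <- order %||% names(dg)
  unknown <- setdiff(order, names(dg))
  if (length(unknown)) {
    stop_zf(paste("unknown reaction id(s):", paste(unknown, collapse = ", ")),
            "zf_unknown_id")
  }
  if (!setequal(order, names(dg))) {
    stop_zf("order must cover all reactions exactly once", "zf_unknown_id")
  }
  cumsum(dg[order])
}

#' Per-reaction Gibbs energies at a uniform reference concentration
#'
#' Evaluates every reaction's Gibbs energy with all metabolites (including
#' pinned ones) at a common concentration, the reference used for
#' bottleneck identification and the standard profile (default 1 mM).
#'
#' @param pathway a [pathway_model()].
#' @param conc_mM reference concentration, mM.
#' @return named numeric vector, kJ mol^-1.
#' @export
reference_dg <- function(pathway, conc_mM = 1) {
  mets <- pathway_metabolites(pathway)
  ln_conc <- stats::setNames(rep(log(conc_mM / 1000), length(mets)), mets)
  vapply(pathway$reactions, reaction_dg, numeric(1),
         ln_conc = ln_conc, temperature = pathway$temperature)
}

#' Thermodynamic bottleneck reactions
#'
#' Reactions whose Gibbs energy is positive with every metabolite at the
#' 1 mM reference concentration, reported in pathway order.
#'
#' @param pathway a [pathway_model()].
#' @param conc_mM reference concentration, mM.
#' @return character vector of reaction ids.
#' @export
bottleneck_report <- function(pathway, conc_mM = 1) {
  dg <- reference_dg(pathway, conc_mM)
  names(dg)[dg > 0]
}

#' MDF along a fermentation substrate series
#'
#' Re-solves the MDF at each timepoint with the pinned substrate
#' concentration(s) set to the corresponding series values (clipped below at
#' `floor_mM` to keep logarithms finite near depletion).
#'
#' @param pathway a [pathway_model()] with at least one pinned metabolite.
#' @param substrate_series data frame with `time_h` plus one column per
#'   pinned metabolite (mM), e.g. `glc_ext`.
#' @param floor_mM clip concentrations below this value, mM.
#' @return data frame `time_h`, `mdf`, `total_dg`, plus one `dg_<id>` column
#'   per reaction; the per-timepoint solutions in `attr(, "solutions")`.
#' @export
timecourse_mdf <- function(pathway, substrate_series, floor_mM = 1e-3) {
  pins <- intersect(names(substrate_series), names(pathway$fixed_conc))
  if (!length(pins)) {
    stop_zf("substrate_series has no column matching a pinned metabolite",
            "zf_bad_series")
  }
  sols <- vector("list", nrow(substrate_series))
  for (i in seq_len(nrow(substrate_series))) {
    pw <- pathway
    pw$fixed_conc[pins] <- pmax(as.numeric(substrate_series[i, pins]),
                                floor_mM)
    sols[[i]] <- optimize_mdf(pw)
  }
  dgm <- t(vapply(sols, `[[`, numeric(length(pathway$reactions)), "dg_prime"))
  colnames(dgm) <- paste0("dg_", names(pathway$reactions))
  out <- data.frame(time_h = substrate_series$time_h,
                    mdf = vapply(sols, `[[`, numeric(1), "mdf"),
                    total_dg = vapply(sols, `[[`, numeric(1), "total_dg"))
  out <- cbind(out, dgm)
  attr(out, "solutions") <- sols
  out
}

#' Total driving force under pinned cofactor ratios
#'
#' For each requested ratio `r`, re-optimizes the MDF with the additional
#' constraint `ln c_num - ln c_den = ln r` and reports the optimized total
#' pathway Gibbs energy (and the MDF) at that ratio.
#'
#' @param pathway a [pathway_model()] containing both cofactors.
#' @param numerator,denominator metabolite ids, e.g. `"atp"`, `"adp"`.
#' @param ratios positive ratios to scan.
#' @return data frame `ratio`, `mdf`, `total_dg`, `feasible`.
#' @export
cofactor_ratio_scan <- function(pathway, numerator, denominator, ratios) {
  mets <- pathway_metabolites(pathway)
  if (!all(c(numerator, denominator) %in% mets)) {
    stop_zf(sprintf("cofactor(s) %s/%s not present in the pathway",
                    numerator, denominator), "zf_missing_metabolite")
  }
  out <- data.frame(ratio = ratios, mdf = NA_real_, total_dg = NA_real_,
                    feasible = FALSE)
  A <- matrix(0, 1, length(mets), dimnames = list(NULL, mets))
  A[1, numerator] <- 1
  A[1, denominator] <- -1
  for (i in seq_along(ratios)) {
    sol <- tryCatch(
      optimize_mdf(pathway, extra_eq = list(A = A, b = log(ratios[i]))),
      error = function(e) NULL
    )
    if (!is.null(sol)) {
      out$mdf[i] <- sol$mdf
      out$total_dg[i] <- sol$total_dg
      out$feasible[i] <- TRUE
    }
  }
  out
}
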