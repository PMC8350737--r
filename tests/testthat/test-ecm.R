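# Enzyme protein cost: Haldane consistency, the common-modular demand
# formula, and the pathway cost optimizer.

test_that("Haldane reverse rate matches closed forms and refuses irreversible steps", {
  kin <- enzyme_kinetics(kcat_fwd = 10, km = c(S = 1, P = 1), mw = 5e4)
  st <- c(S = -1, P = 1)
  # dg0 = 0 and symmetric Km: kcat_rev = kcat_fwd
  expect_equal(haldane_kcat_rev(kin, 0, st), 10)
  # Keq = 10, Km ratio 1: kcat_rev = kcat_fwd / 10
  expect_equal(haldane_kcat_rev(kin, -RT298 * log(10), st), 1,
               tolerance = 1e-12)
  # asymmetric Km enters through the Km products
  kin2 <- enzyme_kinetics(10, c(S = 1, P = 5), 5e4)
  expect_equal(haldane_kcat_rev(kin2, 0, st), 50)
  kin_irr <- enzyme_kinetics(10, c(S = 1), 5e4, irreversible = TRUE)
  expect_error(haldane_kcat_rev(kin_irr, 0, st), class = "zf_irreversible")
  expect_error(haldane_kcat_rev(kin, 0, c(S = -1, X = 1)),
               class = "zf_missing_km")
})

test_that("enzyme demand matches its closed-form limits", {
  mk <- function(dg0, irr, km = c(A = 1, B = 1)) {
    thermo_reaction("r", c(A = -1, B = 1), dg0_prime = dg0,
                    reversible = !irr,
                    kinetics = enzyme_kinetics(50, km, 1e5, irreversible = irr))
  }
  # irreversible, saturating substrate: demand -> MW * v / kcat
  r <- mk(0, TRUE)
  expect_equal(enzyme_demand(r, c(A = log(1), B = log(1e-6)), 1),
               1e5 / 50, tolerance = 2e-3)
  # irreversible at s = Km: eta_sat = 1/2
  expect_equal(enzyme_demand(r, c(A = log(1e-3), B = log(1e-6)), 1),
               2 * 1e5 / 50, tolerance = 1e-9)
  # reversible at dG = -RT ln 2: eta_rev = 1/2, demand doubles relative to
  # the far-from-equilibrium case at the same saturation
  rrev <- mk(0, FALSE)
  xa <- log(1e-3)
  xb <- xa - log(2)  # B/A = 1/2 -> dG = -RT ln 2
  d_near <- enzyme_demand(rrev, c(A = xa, B = xb), 1)
  eff <- zymoflux:::reaction_efficiencies(rrev, c(A = xa, B = xb), 298.15)
  expect_equal(eff$eta_rev, 0.5, tolerance = 1e-12)
  expect_equal(d_near, 1e5 / (50 * 0.5 * eff$eta_sat), tolerance = 1e-9)
  # infeasible direction refused
  expect_error(enzyme_demand(rrev, c(A = log(1e-4), B = log(1e-3)), 1),
               class = "zf_infeasible")
})

test_that("demand never violates the MW*v/kcat lower bound (1000 random states)", {
  set.seed(42)
  for (i in 1:1000) {
    km <- stats::setNames(10^stats::runif(2, -2, 1), c("A", "B"))
    kcat <- 10^stats::runif(1, 0, 3)
    mw <- 10^stats::runif(1, 4, 5.5)
    irr <- stats::runif(1) < 0.5
    dg0 <- stats::runif(1, -30, 10)
    r <- thermo_reaction("r", c(A = -1, B = 1), dg0, reversible = !irr,
                         kinetics = enzyme_kinetics(kcat, km, mw,
                                                    irreversible = irr))
    x <- stats::setNames(stats::runif(2, log(1e-6), log(1e-2)), c("A", "B"))
    flux <- 10^stats::runif(1, -1, 1)
    d <- tryCatch(enzyme_demand(r, x, flux), error = function(e) NULL)
    if (is.null(d)) next  # thermodynamically infeasible draw
    expect_gte(d, mw * flux / kcat - 1e-9)
    eff <- zymoflux:::reaction_efficiencies(r, x, 298.15)
    expect_true(eff$eta_rev > 0 && eff$eta_rev <= 1)
    expect_true(eff$eta_sat > 0 && eff$eta_sat <= 1)
  }
})

test_that("single irreversible step: optimum pushes the substrate to its upper bound", {
  r <- thermo_reaction("r", c(A = -1, B = 1), dg0_prime = -20,
                       reversible = FALSE,
                       kinetics = enzyme_kinetics(50, c(A = 1), 1e5,
                                                  irreversible = TRUE))
  pw <- pathway_model(list(r), c(r = 1), boundary = c("A", "B"))
  sol <- minimize_pathway_cost(pw, n_starts = 3, seed = 1)
  expect_equal(sol$ln_conc[["A"]], log(1e-2), tolerance = 1e-5)
  s_ub <- 1e-2 / (1 / 1000)
  eta <- (s_ub / 1) / (1 + s_ub / 1) * (1 / 1)  # km 1 mM in M units
  expect_equal(sol$total_cost, 1e5 / (50 * (10 / 11)), tolerance = 1e-3)
})

test_that("optimizer matches a dense 2-D grid on seeded 2-reaction toys", {
  for (seed in c(4, 8)) {
    pw <- generate_toy_pathway(toy_pathway_spec(n_reactions = 2, seed = seed))
    sol <- minimize_pathway_cost(pw, n_starts = 4, seed = 1)
    # independent grid evaluation of the demand sum over (A1, A2)
    grid <- seq(log(1e-6), log(1e-2), length.out = 120)
    x0 <- log(1e-3)
    best <- Inf
    for (x1 in grid) {
      for (x2 in grid) {
        tot <- 0
        for (j in 1:2) {
          r <- pw$reactions[[j]]
          xs <- c(x0, x1, x2)[j]
          xp <- c(x0, x1, x2)[j + 1]
          dg <- r$dg0_prime + RT298 * (xp - xs)
          if (dg >= -1e-3) { tot <- Inf; break }
          st <- stats::setNames(c(-1, 1), names(r$stoich)[order(r$stoich)])
          conc <- stats::setNames(exp(c(xs, xp)), names(st))
          tot <- tot + oracle_demand(r$kinetics$mw, r$kinetics$kcat_fwd, 1,
                                     dg, st, r$kinetics$km, conc)
        }
        if (tot < best) best <- tot
      }
    }
    expect_lt(abs(sol$total_cost - best) / best, 0.01)
  }
})

test_that("pathway cost bookkeeping: shares sum to one, feasibility enforced, MDF seed never beaten", {
  pw <- generate_toy_pathway(toy_pathway_spec(n_reactions = 3, seed = 6))
  mdf <- optimize_mdf(pw)
  sol <- minimize_pathway_cost(pw, n_starts = 3, seed = 2, mdf_sol = mdf)
  expect_equal(sum(sol$per_enzyme_share), 1)
  expect_equal(sum(sol$per_enzyme_cost), sol$total_cost)
  expect_true(all(sol$per_enzyme_cost > 0))
  expect_true(all(sol$dg_prime < 0))
  expect_lte(sol$total_cost,
             zymoflux:::pathway_cost_at(pw, mdf$ln_conc)$total + 1e-6)
  # flux-unit invariance: costs are per unit pathway flux
  pw2 <- pw
  expect_equal(minimize_pathway_cost(pw2, n_starts = 2, seed = 2)$total_cost,
               sol$total_cost, tolerance = 1e-4)
})

test_that("infeasible pathways are refused with the bottleneck named", {
  r <- thermo_reaction("blocked", c(A = -1, B = 1), dg0_prime = 60,
                       kinetics = enzyme_kinetics(50, c(A = 1, B = 1), 1e5))
  pw <- pathway_model(list(r), c(blocked = 1), boundary = c("A", "B"))
  expect_error(minimize_pathway_cost(pw), "blocked", class = "zf_infeasible")
})

test_that("time-course cost: flat under constant substrate, rising as it depletes, glf scaling", {
  pw <- generate_toy_pathway(toy_pathway_spec(n_reactions = 2, seed = 3))
  const <- data.frame(time_h = 0:2, A0 = rep(1, 3))
  tc <- timecourse_cost(pw, const, seed = 1)
  expect_true(all(tc$feasible))
  expect_lt(max(abs(diff(tc$total_cost))) / tc$total_cost[1], 1e-3)
  dec <- data.frame(time_h = 0:3, A0 = c(5, 1, 0.2, 0.05))
  td <- timecourse_cost(pw, dec, seed = 1)
  expect_true(all(diff(td$total_cost) > 0))
  # far below Km, halving the pinned substrate about doubles the first
  # enzyme's cost (Michaelis-Menten first-order limit)
  g <- glucose_pathway_param()
  lowA <- timecourse_cost(g, data.frame(time_h = 0:1, glc_ext = c(0.2, 0.1)),
                          seed = 1)
  expect_equal(lowA$cost_glf[2] / lowA$cost_glf[1], 2, tolerance = 0.05)
})
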