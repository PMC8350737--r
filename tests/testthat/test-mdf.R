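# Reaction Gibbs energies and the max-min driving force optimization.

test_that("reaction Gibbs energy matches closed forms", {
  r <- thermo_reaction("r", c(A = -1, B = 1), dg0_prime = 0)
  # standard state: all 1 M
  expect_equal(reaction_dg(r, c(A = 0, B = 0)), 0)
  # concentration ratio 10 at dg0 = 0
  expect_equal(reaction_dg(r, c(A = log(0.01), B = log(0.1))),
               RT298 * log(10), tolerance = 1e-12)
  # doubling all concentrations of a balanced uni-uni reaction changes nothing
  x <- c(A = log(0.003), B = log(0.02))
  expect_equal(reaction_dg(r, x + log(2)), reaction_dg(r, x))
  expect_error(reaction_dg(r, c(A = 0)), "B",
               class = "zf_missing_metabolite")
})

test_that("MDF closed forms: single reaction and two-reaction chain", {
  r1 <- thermo_reaction("r1", c(A = -1, B = 1), dg0_prime = 0)
  pw1 <- pathway_model(list(r1), c(r1 = 1), boundary = c("A", "B"))
  sol1 <- optimize_mdf(pw1)
  expect_equal(sol1$mdf, RT298 * log(1e4), tolerance = 1e-6)
  r2 <- thermo_reaction("r2", c(B = -1, C = 1), dg0_prime = 0)
  pw2 <- pathway_model(list(r1, r2), c(r1 = 1, r2 = 1),
                       boundary = c("A", "C"))
  sol2 <- optimize_mdf(pw2)
  expect_equal(sol2$mdf, RT298 * log(1e4) / 2, tolerance = 1e-6)
  # optimal interior concentration sits at the geometric mean of the bounds
  expect_equal(sol2$ln_conc[["B"]], log(1e-4), tolerance = 1e-4)
})

test_that("LP optimum matches the brute-force grid oracle on seeded toys", {
  for (seed in 1:20) {
    pw <- generate_toy_pathway(toy_pathway_spec(n_reactions = 3, seed = seed))
    lp <- optimize_mdf(pw)$mdf
    grid <- oracle_chain_mdf(pw)
    expect_lt(abs(lp - grid), 0.1)
    expect_gte(lp, grid - 1e-9)  # the grid optimum is a feasible point
  }
})

test_that("solutions satisfy the maximin structure: a tight reaction, bounds, pins", {
  pw <- generate_toy_pathway(toy_pathway_spec(n_reactions = 4, seed = 5))
  sol <- optimize_mdf(pw)
  expect_equal(min(-sol$dg_prime), sol$mdf, tolerance = 1e-6)
  expect_true(all(-sol$dg_prime >= sol$mdf - 1e-6))
  free <- setdiff(names(sol$ln_conc), "A0")
  expect_true(all(sol$ln_conc[free] >= log(pw$conc_lb / 1000) - 1e-9))
  expect_true(all(sol$ln_conc[free] <= log(pw$conc_ub / 1000) + 1e-9))
  expect_equal(sol$ln_conc[["A0"]], log(1e-3))
})

test_that("tightening the upper concentration bound never increases the MDF", {
  pw <- generate_toy_pathway(toy_pathway_spec(n_reactions = 3, seed = 9))
  mdfs <- vapply(c(10, 5, 1, 0.1), function(ub) {
    pw$conc_ub <- ub
    optimize_mdf(pw)$mdf
  }, numeric(1))
  expect_true(all(diff(mdfs) <= 1e-9))
})

test_that("cumulative profile sums per-reaction energies in pathway order", {
  pw <- generate_toy_pathway(toy_pathway_spec(n_reactions = 3, seed = 2))
  sol <- optimize_mdf(pw)
  prof <- cumulative_profile(sol)
  expect_equal(unname(prof[3]), sum(sol$dg_prime))
  expect_equal(unname(prof[1]), unname(sol$dg_prime[1]))
  # final total is permutation invariant
  prof2 <- cumulative_profile(sol, order = c("r2", "r3", "r1"))
  expect_equal(unname(prof2[3]), unname(prof[3]))
  expect_error(cumulative_profile(sol, order = c("r1", "r2", "nope")),
               class = "zf_unknown_id")
  # reference (1 mM) profile for a single reaction is just dG0 for uni-uni
  r <- thermo_reaction("solo", c(A = -1, B = 1), dg0_prime = -3)
  pw1 <- pathway_model(list(r), c(solo = 1), boundary = c("A", "B"))
  expect_equal(unname(cumulative_profile(reference_dg(pw1))), -3)
})

test_that("bottleneck report flags positive reference-state energies in order", {
  mk <- function(dg) {
    rs <- list(thermo_reaction("a", c(A = -1, B = 1), dg[1]),
               thermo_reaction("b", c(B = -1, C = 1), dg[2]),
               thermo_reaction("c", c(C = -1, D = 1), dg[3]))
    pathway_model(rs, c(a = 1, b = 1, c = 1), boundary = c("A", "D"))
  }
  expect_equal(bottleneck_report(mk(c(-10, -10, -10))), character(0))
  expect_equal(bottleneck_report(mk(c(-1, 0.001, -1))), "b")
  expect_equal(bottleneck_report(mk(c(2, -1, 3))), c("a", "c"))
})

test_that("synthetic-parameter pathways reproduce the expected bottleneck structure", {
  g <- glucose_pathway_param()
  x <- xylose_pathway_param()
  expect_equal(bottleneck_report(g), c("g6pdh", "gapdh", "pgm"))
  expect_setequal(setdiff(bottleneck_report(x), bottleneck_report(g)),
                  c("xyl", "rpe"))
  # both remain thermodynamically feasible overall
  expect_gt(optimize_mdf(g)$mdf, 0)
  expect_gt(optimize_mdf(x)$mdf, 0)
})

test_that("time-course MDF: constant series flat, weakening with substrate depletion", {
  pw <- generate_toy_pathway(toy_pathway_spec(n_reactions = 2, seed = 3))
  const <- data.frame(time_h = 0:3, A0 = rep(2, 4))
  tm <- timecourse_mdf(pw, const)
  expect_equal(diff(tm$mdf), rep(0, 3), tolerance = 1e-6)
  dec <- data.frame(time_h = 0:4, A0 = c(8, 4, 2, 0.5, 1e-7))
  td <- timecourse_mdf(pw, dec)
  expect_true(all(diff(td$total_dg) >= -1e-6))  # driving force weakens
  expect_true(all(is.finite(td$mdf)))           # floor keeps logs finite
})

test_that("cofactor ratio pinning shifts the driving force with the stoichiometric sign", {
  # net ATP-producing chain (A + adp -> B + atp): a lower ATP/ADP ratio
  # pulls the phosphorylation forward, so the total Gibbs energy becomes
  # more negative as the ratio drops - the behavior reported for the
  # sugar-to-BDO pathways, which produce net ATP
  r1 <- thermo_reaction("k1", c(A = -1, adp = -1, B = 1, atp = 1), -5)
  r2 <- thermo_reaction("k2", c(B = -1, C = 1), -5)
  pw <- pathway_model(list(r1, r2), c(k1 = 1, k2 = 1),
                      boundary = c("A", "C", "atp", "adp"))
  sc <- cofactor_ratio_scan(pw, "atp", "adp", c(100, 1, 0.01))
  expect_true(all(sc$feasible))
  expect_true(all(diff(sc$total_dg) < 0))
  # an ATP-consuming chain shows the mirror-image response
  c1 <- thermo_reaction("c1", c(A = -1, atp = -1, B = 1, adp = 1), -5)
  pwc <- pathway_model(list(c1), c(c1 = 1),
                       boundary = c("A", "B", "atp", "adp"))
  scc <- cofactor_ratio_scan(pwc, "atp", "adp", c(100, 1, 0.01))
  expect_true(all(diff(scc$total_dg) > 0))
  # the parameterized glucose route is a net producer: same sign as the toy
  sg <- cofactor_ratio_scan(glucose_pathway_param(), "atp", "adp",
                            c(10, 1, 0.1))
  expect_true(all(diff(sg$total_dg) < 0))
  expect_error(cofactor_ratio_scan(pw, "nadh", "nad", 1),
               class = "zf_missing_metabolite")
})
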