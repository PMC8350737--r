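# Core network construction, exchange bounds, and lexicographic FBA.

test_that("shipped core network is well-formed with the decarboxylase knocked out", {
  net <- zm_core_network()
  expect_s3_class(net, "core_network")
  expect_true(all(c("EX_glc", "EX_xyl", "EX_o2", "EX_bdo") %in% net$reactions))
  expect_equal(net$lb[["pdc"]], 0)
  expect_equal(net$ub[["pdc"]], 0)
  expect_equal(net$lb[[net$ngam_id]], 0)
  # maximal flux through the knocked-out reaction is zero
  lb <- net$lb; lb["EX_glc"] <- -20
  s <- solve_fba(net, "pdc", TRUE, lb, net$ub)
  expect_lt(abs(s$objval), 1e-8)
})

test_that("forced glucose-to-BDO conversion carries 1 ATP per BDO, consistent with the pathway model", {
  net <- zm_core_network()
  lb <- net$lb; ub <- net$ub
  # feed exactly 1 glucose, demand 1 BDO, no growth; oxygen stays open so
  # the pathway's NADPH by-product can be re-oxidized (respiration is
  # ATP-uncoupled, so it cannot inflate the ATP count)
  lb["EX_glc"] <- -1; ub["EX_glc"] <- -1
  lb["EX_xyl"] <- 0; ub["EX_xyl"] <- 0
  lb["EX_bdo"] <- 1
  ub["biomass"] <- 0
  sol <- solve_fba(net, "ngam", TRUE, lb, ub)
  expect_true(sol$feasible)
  # all spare ATP is drained through maintenance: net 1 ATP per glucose,
  # matching the pathway-level stoichiometric yield
  expect_equal(sol$objval, 1, tolerance = 1e-6)
  expect_equal(max(abs(net$S %*% sol$flux)), 0, tolerance = 1e-8)
})

test_that("kinetic exchange bounds reproduce their half-saturation values", {
  tk <- tk_fitted()
  ul <- uptake_limits()
  # all concentrations zero: no uptake anywhere
  b0 <- exchange_bounds(extracellular_state(glc = 0, xyl = 0, o2 = 0,
                                            actn = 0, bdo = 0), tk, ul)
  expect_equal(unname(vapply(b0, `[`, numeric(1), 1)), rep(0, 6))
  # oxygen at its Km: bound = Vmax/2 = 7.5
  b1 <- exchange_bounds(extracellular_state(o2 = ul$km_o2), tk, ul)
  expect_equal(b1$o2[1], -7.5)
  # BDO at 5 mM (its Km): reuptake bound = 5
  b2 <- exchange_bounds(extracellular_state(bdo = 5), tk, ul)
  expect_equal(b2$bdo[1], -5)
  # reuptake switched off
  b3 <- exchange_bounds(extracellular_state(bdo = 5, actn = 5), tk, ul,
                        reuptake = FALSE)
  expect_equal(b3$bdo[1], 0)
  expect_equal(b3$actn[1], 0)
})

test_that("lexicographic FBA honors its stage contracts", {
  net <- zm_core_network()
  tk <- tk_fitted()
  ul <- uptake_limits()
  # zero state: zero growth and products
  z <- solve_lex_fba(net, exchange_bounds(
    extracellular_state(glc = 0, xyl = 0, o2 = 0, actn = 0, bdo = 0),
    tk, ul))
  expect_equal(unname(z$growth), 0, tolerance = 1e-9)
  expect_equal(unname(z$flux[["EX_bdo"]]), 0, tolerance = 1e-8)
  # stage 1 equals plain max-biomass FBA
  bnds <- exchange_bounds(extracellular_state(), tk, ul)
  lex <- solve_lex_fba(net, bnds)
  lb <- net$lb; ub <- net$ub
  for (sp in names(bnds)) {
    id <- net$exchange_ids[[sp]]
    lb[id] <- bnds[[sp]][1]; ub[id] <- bnds[[sp]][2]
  }
  plain <- solve_fba(net, net$biomass_reaction, TRUE, lb, ub)
  expect_equal(unname(lex$growth), plain$objval, tolerance = 1e-4)
  # every solved vector is a steady state within bounds
  expect_lt(max(abs(net$S %*% lex$flux)), 1e-8)
  expect_true(all(lex$flux >= lb[net$reactions] - 1e-6 &
                    lex$flux <= ub[net$reactions] + 1e-6))
})

test_that("a tabular model file round-trips through build_core_network", {
  net <- zm_core_network()
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  eqs <- vapply(net$reactions, function(id) {
    st <- net$S[, id]
    zymoflux:::format_equation(st[st != 0])
  }, character(1))
  utils::write.table(
    data.frame(id = net$reactions, equation = eqs,
               lb = net$lb, ub = net$ub),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  back <- build_core_network(path)
  expect_setequal(back$reactions, net$reactions)
  expect_equal(back$lb[net$reactions], net$lb)
  # same optimum as the in-memory network
  tk <- tk_fitted()
  b <- exchange_bounds(extracellular_state(), tk, uptake_limits())
  expect_equal(unname(solve_lex_fba(back, b)$growth),
               unname(solve_lex_fba(net, b)$growth), tolerance = 1e-6)
})

test_that("the SBML reader extracts stoichiometry and FBC bounds", {
  path <- tempfile(fileext = ".xml")
  on.exit(unlink(path))
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2">
 <model id="toy">
  <listOfParameters>
   <parameter id="lb_m10" value="-10" constant="true"/>
   <parameter id="ub_20" value="20" constant="true"/>
  </listOfParameters>
  <listOfReactions>
   <reaction id="r1" reversible="true" fbc:lowerFluxBound="lb_m10" fbc:upperFluxBound="ub_20">
    <listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>
   </reaction>
   <reaction id="r2" reversible="false">
    <listOfReactants><speciesReference species="B" stoichiometry="1"/></listOfReactants>
   </reaction>
  </listOfReactions>
 </model>
</sbml>', path)
  parsed <- zymoflux:::read_sbml_network(path)
  expect_equal(parsed$S["A", "r1"], -1)
  expect_equal(parsed$S["B", "r1"], 2)
  expect_equal(parsed$S["B", "r2"], -1)
  expect_equal(parsed$lb[["r1"]], -10)
  expect_equal(parsed$ub[["r1"]], 20)
  expect_equal(parsed$lb[["r2"]], 0)    # irreversible default
  expect_equal(parsed$ub[["r2"]], 1000)
})

test_that("OD conversion is the plain product", {
  expect_equal(od_to_biomass(0), 0)
  expect_equal(od_to_biomass(0.84), 0.84 * 0.33)
  expect_equal(od_to_biomass(2.5, factor = 1), 2.5)
  expect_error(od_to_biomass(-1), class = "zf_bad_state")
})
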