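# Dual-substrate uptake kinetics: rate law identities, simulation
# contracts, goodness-of-fit bookkeeping, rate surfaces.

test_that("uptake rate law satisfies its closed-form identities", {
  tk <- tk_fitted()
  expect_equal(uptake_rates(0, 123, tk)$v_glc, 0)
  expect_equal(uptake_rates(321, 0, tk)$v_xyl, 0)
  # half saturation with no inhibitor
  expect_equal(uptake_rates(tk$km_glc, 0, tk)$v_glc, tk$vmax_glc / 2)
  expect_equal(uptake_rates(0, tk$km_xyl, tk)$v_xyl, tk$vmax_xyl / 2)
  # substrate at Km and inhibitor at Ki: denominator Km*2 + Km
  expect_equal(uptake_rates(tk$km_glc, tk$ki_xyl, tk)$v_glc, tk$vmax_glc / 3)
  expect_error(uptake_rates(-1, 0, tk), class = "zf_negative_conc")
})

test_that("rates are degree-0 homogeneous in ([s], Km, Ki) and recover plain MM as Ki grows", {
  tk <- tk_fitted()
  for (f in c(0.1, 3, 42)) {
    scaled <- transporter_kinetics(tk$vmax_glc, f * tk$km_glc, f * tk$ki_glc,
                                   tk$vmax_xyl, f * tk$km_xyl, f * tk$ki_xyl)
    v0 <- uptake_rates(100, 80, tk)
    v1 <- uptake_rates(f * 100, f * 80, scaled)
    expect_equal(v1$v_glc, v0$v_glc, tolerance = 1e-12)
    expect_equal(v1$v_xyl, v0$v_xyl, tolerance = 1e-12)
  }
  nolim <- transporter_kinetics(tk$vmax_glc, tk$km_glc, 1e12,
                                tk$vmax_xyl, tk$km_xyl, 1e12)
  v <- uptake_rates(100, 200, nolim)
  expect_equal(v$v_glc, tk$vmax_glc * 100 / (tk$km_glc + 100),
               tolerance = 1e-9)
  expect_equal(v$v_xyl, tk$vmax_xyl * 200 / (tk$km_xyl + 200),
               tolerance = 1e-9)
})

test_that("uptake simulation respects conservation, the first-order limit and zero-biomass identity", {
  tk <- tk_fitted()
  # biomass 0: sugars constant
  sim0 <- simulate_uptake(tk, 100, 50, function(t) 0, seq(0, 10, 1))
  expect_equal(sim0$glc_mM, rep(100, 11))
  expect_equal(sim0$xyl_mM, rep(50, 11))
  # first-order analytic limit: glc << Km, xyl = 0, constant biomass
  p <- transporter_kinetics(10, 100, 1e6, 1, 100, 1e6)
  tg <- seq(0, 2, 0.25)
  sim <- simulate_uptake(p, 100 / 20, 0, function(t) 0.5, tg)
  expect_equal(sim$glc_mM, 5 * exp(-10 * 0.5 * tg / 100), tolerance = 0.01)
  # conservation: depletion equals the integral of v * X (augmented state)
  bio <- function(t) 0.4 + 0.05 * t
  dense <- seq(0, 30, length.out = 601)
  simd <- simulate_uptake(tk, 200, 150, bio, dense)
  v <- uptake_rates(simd$glc_mM, simd$xyl_mM, tk)
  upt <- v$v_glc * simd$biomass_gdcw_L
  trapz <- sum((upt[-1] + upt[-length(upt)]) / 2 * diff(dense))
  expect_equal(200 - simd$glc_mM[length(dense)], trapz, tolerance = 1e-3)
  # against the independent fine-step oracle
  fin <- oracle_integrate_uptake(tk, 200, 150, bio, 30)
  expect_equal(simd$glc_mM[length(dense)], fin[1], tolerance = 1e-4)
  expect_equal(simd$xyl_mM[length(dense)], fin[2], tolerance = 1e-4)
  # monotone non-increasing trajectories
  expect_true(all(diff(simd$glc_mM) <= 1e-9))
  expect_true(all(diff(simd$xyl_mM) <= 1e-9))
})

test_that("pooled R-squared matches hand computations and flags zero variance", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), c(2, 2, 2)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  # pooling: each channel centered at its own mean
  expect_equal(r_squared(list(c(1, 2, 3), c(10, 20, 30)),
                         list(c(1, 2, 4), c(10, 20, 30))),
               1 - 1 / (2 + 200))
  expect_warning(out <- r_squared(c(5, 5, 5), c(5, 5, 4)), "variance")
  expect_true(is.na(out))
})

test_that("uptake surface reduces to the rate law and is monotone along both axes", {
  tk <- tk_fitted()
  s1 <- uptake_surface(tk, 50, 20)
  expect_equal(s1$v_glc[1, 1], uptake_rates(50, 20, tk)$v_glc)
  gg <- seq(0, 300, length.out = 50)
  xx <- seq(0, 300, length.out = 50)
  s <- uptake_surface(tk, gg, xx)
  expect_true(all(apply(s$v_glc, 2, function(col) all(diff(col) >= -1e-12))))
  expect_true(all(apply(s$v_glc, 1, function(row) all(diff(row) <= 1e-12))))
  # row at xyl = 0 is the plain Michaelis-Menten curve
  expect_equal(s$v_glc[, 1], tk$vmax_glc * gg / (tk$km_glc + gg),
               ignore_attr = TRUE)
})

test_that("specific rates from a course match hand computation and mark zero biomass", {
  t <- seq(0, 10, 0.5)
  course <- data.frame(time_h = t, glc_mM = 100 - 2 * t,
                       xyl_mM = rep(30, length(t)),
                       biomass_gdcw_L = rep(0.5, length(t)))
  r <- specific_rates_from_course(course)
  expect_equal(r$v_glc, rep(4, length(t)))
  expect_equal(r$v_xyl, rep(0, length(t)))
  course$biomass_gdcw_L[3] <- 0
  expect_true(is.na(specific_rates_from_course(course)$v_glc[3]))
})

test_that("rates recomputed from a simulated course agree with the rate law", {
  tk <- tk_fitted()
  bio <- function(t) 0.8
  tg <- seq(0, 20, 0.2)
  sim <- simulate_uptake(tk, 300, 200, bio, tg)
  rates <- specific_rates_from_course(sim)
  direct <- uptake_rates(sim$glc_mM, sim$xyl_mM, tk)
  mid <- 5:90  # interior points, central differences
  expect_equal(rates$v_glc[mid], direct$v_glc[mid], tolerance = 0.02)
  expect_equal(rates$v_xyl[mid], direct$v_xyl[mid], tolerance = 0.02)
})

test_that("time-course TSV round-trips", {
  tk <- tk_fitted()
  sim <- simulate_uptake(tk, 100, 50, function(t) 0.3, seq(0, 5, 0.5))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_course_tsv(sim, path)
  back <- read_course_tsv(path)
  expect_equal(back$glc_mM, sim$glc_mM, tolerance = 1e-9)
  expect_s3_class(back, "fermentation_course")
})
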