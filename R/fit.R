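# Least-squares estimation of the six transporter constants from a measured
# batch time course, following the approach of fitting simulated to measured
# sugar concentrations with biomass linearly interpolated between data points.

#' Fit transporter kinetics to a fermentation time course
#'
#' Estimates `Vmax`, `Km` and `Ki` for both sugars by minimizing the pooled
#' sum of squared residuals between the measured glucose/xylose
#' concentrations and an ODE simulation of the uptake model
#' ([simulate_uptake()]), with the biomass curve obtained by linear
#' interpolation of the measured biomass. Residuals of the two sugars are
#' pooled unweighted in mM^2.
#'
#' All parameters are optimized in log-space (Levenberg-Marquardt via
#' [minpack.lm::nls.lm()]); the weakly identified inhibition constants are
#' bounded to `[1, 1e4]` mM. Besides the user-supplied initial guess, the
#' optimizer is restarted from `n_restarts` log-uniform random guesses; the
#' best converged solution is returned. Deterministic for a given `seed`.
#'
#' @param course a [fermentation_course()] with `glc_mM`, `xyl_mM`,
#'   `biomass_gdcw_L` columns.
#' @param initial_guess optional [transporter_kinetics()] starting point.
#' @param n_restarts number of random restarts (default 20).
#' @param seed integer seed controlling the restart draws.
#' @param ki_bounds bounds for both inhibition constants, mM.
#' @return object of class `fit_result`: list with `params`
#'   ([transporter_kinetics()]), `r_squared` (pooled over both sugars),
#'   `residual_ss` (mM^2), `converged`, `n_restarts_used`, and the per-start
#'   objective values in `restart_ss`.
#' @export
fit_transporter <- function(course, initial_guess = NULL, n_restarts = 20L,
                            seed = 1L, ki_bounds = c(1, 1e4)) {
  course <- fermentation_course(as.data.frame(course))
  t_obs <- course$time_h
  obs <- rbind(course$glc_mM, course$xyl_mM)
  bio_fun <- stats::approxfun(t_obs, course$biomass_gdcw_L, rule = 2)
  g0 <- course$glc_mM[1]; x0 <- course$xyl_mM[1]

  resid_fun <- function(theta) {
    p <- theta_to_params(theta)
    sim <- tryCatch(rk4_uptake(p, g0, x0, bio_fun, t_obs),
                    error = function(e) NULL)
    if (is.null(sim) || anyNA(sim)) return(rep(1e4, 2 * length(t_obs)))
    c(sim[, 1] - course$glc_mM, sim[, 2] - course$xyl_mM)
  }

  # optimize log-parameters; order matches transporter_kinetics()
  lower <- log(c(1e-3, 1e-2, ki_bounds[1], 1e-3, 1e-2, ki_bounds[1]))
  upper <- log(c(1e3, 1e4, ki_bounds[2], 1e3, 1e4, ki_bounds[2]))

  starts <- list()
  if (!is.null(initial_guess)) {
    stopifnot(inherits(initial_guess, "transporter_kinetics"))
    starts[[1]] <- pmin(pmax(log(unlist(initial_guess)), lower), upper)
  } else {
    # data-driven start: peak specific rates approximate Vmax, half the
    # initial concentrations approximate Km, Ki starts mid-bounds
    rates <- tryCatch(specific_rates_from_course(course),
                      error = function(e) NULL)
    vg <- max(1e-2, rates$v_glc, na.rm = TRUE)
    vx <- max(1e-2, rates$v_xyl, na.rm = TRUE)
    km_guess <- function(s0) max(1, min(s0 / 2, 50))
    # the inhibition constants are the weakly identified directions: start
    # once per Ki regime (strong, moderate, negligible inhibition) so the
    # deterministic starts straddle both valleys of the likelihood
    starts <- lapply(c(50, 200, 2000), function(ki0) {
      pmin(pmax(log(c(vg, km_guess(g0), ki0, vx, km_guess(x0), ki0)),
                lower), upper)
    })
  }
  # random restarts draw log-uniformly over physiologically plausible
  # magnitudes (narrower than the optimization bounds, which exist to keep
  # the search sane, not to encode priors)
  r_lo <- log(c(0.5, 5, 10, 0.05, 5, 10))
  r_hi <- log(c(100, 500, 5e3, 50, 500, 5e3))
  extra <- with_seed(seed, replicate(n_restarts, {
    stats::runif(6, r_lo, r_hi)
  }, simplify = FALSE))
  starts <- c(starts, extra)

  best <- NULL
  restart_ss <- rep(NA_real_, length(starts))
  for (k in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[k]], lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 150, ftol = 1e-12, ptol = 1e-10,
                           # finite-difference steps sized to clear the
                           # integration error floor
                           epsfcn = 1e-6)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    restart_ss[k] <- ss
    conv <- fit$info %in% 1:4
    if (is.null(best) || ss < best$ss - 1e-12) {
      best <- list(par = fit$par, ss = ss, conv = conv)
    }
  }
  if (is.null(best)) {
    stop_zf("all optimizer restarts failed", "zf_fit_failure")
  }

  # polish: re-run from the incumbent with a finer finite-difference step;
  # the (Km, Ki) directions are nearly collinear and the first pass can
  # stall part-way down the valley
  for (ef in c(1e-9)) {
    pol <- tryCatch(
      minpack.lm::nls.lm(par = best$par, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-14, ptol = 1e-12,
                           epsfcn = ef)),
      error = function(e) NULL
    )
    if (!is.null(pol)) {
      ss <- sum(pol$fvec^2)
      if (ss < best$ss) best <- list(par = pol$par, ss = ss,
                                     conv = pol$info %in% 1:4 || best$conv)
    }
  }

  params <- theta_to_params(best$par)
  sim <- simulate_uptake(params, g0, x0, bio_fun, t_obs)
  r2 <- suppressWarnings(r_squared(
    list(course$glc_mM, course$xyl_mM),
    list(sim$glc_mM, sim$xyl_mM)
  ))
  structure(list(params = params, r_squared = r2, residual_ss = best$ss,
                 converged = best$conv,
                 n_restarts_used = length(starts) - 1L,
                 restart_ss = restart_ss),
            class = "fit_result")
}

theta_to_params <- function(theta) {
  e <- exp(theta)
  transporter_kinetics(e[1], e[2], e[3], e[4], e[5], e[6])
}

# fixed-step classical RK4 integration of the two-sugar uptake ODEs on the
# observation grid (nsub substeps per interval). Used inside the fit: the
# solution is a smooth deterministic function of the parameters, which
# adaptive integrators are not, so finite-difference Jacobians stay clean.
rk4_uptake <- function(p, g0, x0, biofun, t_grid, nsub = 6L) {
  n <- length(t_grid)
  out <- matrix(0, n, 2)
  y <- c(g0, x0)
  out[1, ] <- y
  f <- function(t, y) {
    s <- pmax(y, 0)
    v <- uptake_rates(s[1], s[2], p)
    X <- biofun(t)
    c(-v$v_glc * X, -v$v_xyl * X)
  }
  for (i in 2:n) {
    h <- (t_grid[i] - t_grid[i - 1]) / nsub
    t <- t_grid[i - 1]
    for (k in seq_len(nsub)) {
      k1 <- f(t, y)
      k2 <- f(t + h / 2, y + h / 2 * k1)
      k3 <- f(t + h / 2, y + h / 2 * k2)
      k4 <- f(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i, ] <- y
  }
  pmax(out, 0)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Transporter fit: R^2 = %.4f, SS = %.4g mM^2, converged = %s\n",
              x$r_squared, x$residual_ss, x$converged))
  print(x$params)
  invisible(x)
}

#' Serialize a fit result to JSON (units embedded)
#'
#' @param fit a `fit_result`.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    params = fit$params[],
    units = list(vmax = "mmol gDCW-1 h-1", km = "mM", ki = "mM"),
    r_squared = fit$r_squared,
    residual_ss_mM2 = fit$residual_ss,
    converged = fit$converged,
    n_restarts_used = fit$n_restarts_used
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fit result written by [write_fit_json()]
#' @param path JSON file.
#' @return a [transporter_kinetics()] object.
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(transporter_kinetics, as.list(unlist(obj$params)))
}
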