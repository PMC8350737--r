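# Dual-substrate transporter kinetics: Michaelis-Menten uptake of glucose and
# xylose through the shared glf facilitator, with mutual competitive
# inhibition. Rates in mmol gDCW^-1 h^-1, concentrations in mM.

#' Transporter kinetic parameter set
#'
#' The six constants of the dual-substrate competitive-inhibition uptake model:
#' for each sugar a maximum specific uptake rate `vmax` (mmol gDCW^-1 h^-1),
#' a Michaelis constant `km` (mM) and an inhibition constant `ki` (mM)
#' describing how strongly that sugar inhibits uptake of the other.
#'
#' @param vmax_glc,vmax_xyl maximum uptake rates, mmol gDCW^-1 h^-1.
#' @param km_glc,km_xyl Michaelis constants, mM.
#' @param ki_glc,ki_xyl inhibition constants, mM: `ki_glc` is the constant
#'   with which glucose inhibits xylose uptake, `ki_xyl` the converse.
#' @return object of class `transporter_kinetics`.
#' @examples
#' transporter_kinetics(29.30, 40.21, 600, 3.18, 80.96, 200)
#' @export
transporter_kinetics <- function(vmax_glc, km_glc, ki_glc,
                                 vmax_xyl, km_xyl, ki_xyl) {
  p <- c(vmax_glc = vmax_glc, km_glc = km_glc, ki_glc = ki_glc,
         vmax_xyl = vmax_xyl, km_xyl = km_xyl, ki_xyl = ki_xyl)
  if (!all(is.finite(p)) || any(p <= 0)) {
    stop_zf("all six transporter parameters must be strictly positive and finite",
            "zf_bad_kinetics")
  }
  structure(as.list(p), class = "transporter_kinetics")
}

#' @export
print.transporter_kinetics <- function(x, ...) {
  cat("Transporter kinetics (glf)\n")
  cat(sprintf("  glucose: Vmax %.4g mmol/gDCW/h, Km %.4g mM, Ki %.4g mM\n",
              x$vmax_glc, x$km_glc, x$ki_glc))
  cat(sprintf("  xylose : Vmax %.4g mmol/gDCW/h, Km %.4g mM, Ki %.4g mM\n",
              x$vmax_xyl, x$km_xyl, x$ki_xyl))
  invisible(x)
}

#' Specific uptake rates of glucose and xylose
#'
#' Competitive-inhibition Michaelis-Menten rates through the shared
#' transporter:
#' `v_glc = Vmax_glc * [glc] / (Km_glc * (1 + [xyl]/Ki_xyl) + [glc])` and
#' symmetrically for xylose with `Ki_glc`. Vectorized over concentrations.
#'
#' @param glc,xyl extracellular concentrations, mM (non-negative; recycled).
#' @param params a [transporter_kinetics()] object.
#' @return list with numeric vectors `v_glc` and `v_xyl`
#'   (mmol gDCW^-1 h^-1).
#' @export
uptake_rates <- function(glc, xyl, params) {
  stopifnot(inherits(params, "transporter_kinetics"))
  if (any(!is.finite(glc)) || any(!is.finite(xyl)) ||
      any(glc < 0) || any(xyl < 0)) {
    stop_zf("substrate concentrations must be finite and non-negative",
            "zf_negative_conc")
  }
  v_glc <- params$vmax_glc * glc /
    (params$km_glc * (1 + xyl / params$ki_xyl) + glc)
  v_xyl <- params$vmax_xyl * xyl /
    (params$km_xyl * (1 + glc / params$ki_glc) + xyl)
  list(v_glc = v_glc, v_xyl = v_xyl)
}

#' Construct/validate a fermentation time course
#'
#' A data frame with strictly increasing `time_h`, sugar concentrations
#' `glc_mM` and `xyl_mM`, biomass `biomass_gdcw_L`, and optionally
#' `actn_mM`, `bdo_mM`, `glyc_mM`, `o2_mM`.
#'
#' @param df data frame with at least `time_h`, `glc_mM`, `xyl_mM`,
#'   `biomass_gdcw_L`.
#' @return the validated data frame, classed `fermentation_course`.
#' @export
fermentation_course <- function(df) {
  need <- c("time_h", "glc_mM", "xyl_mM", "biomass_gdcw_L")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_zf(paste("missing time-course columns:", paste(miss, collapse = ", ")),
            "zf_bad_course")
  }
  if (nrow(df) < 2) stop_zf("a time course needs at least 2 rows", "zf_bad_course")
  if (anyNA(df$time_h) || any(diff(df$time_h) <= 0)) {
    stop_zf("time_h must be complete and strictly increasing", "zf_bad_course")
  }
  num <- intersect(c(need, "actn_mM", "bdo_mM", "glyc_mM", "o2_mM"), names(df))
  if (any(vapply(df[num], function(v) any(v < -1e-9, na.rm = TRUE), logical(1)))) {
    stop_zf("concentrations in a time course must be non-negative", "zf_bad_course")
  }
  class(df) <- unique(c("fermentation_course", class(df)))
  df
}

#' Read / write the TSV time-course dialect
#'
#' Tab-separated files with unit-bearing column headers
#' (`time_h`, `glc_mM`, `xyl_mM`, `biomass_gdcw_L`, ...).
#'
#' @param path file path.
#' @return `read_course_tsv` returns a [fermentation_course()].
#' @export
read_course_tsv <- function(path) {
  fermentation_course(utils::read.delim(path, sep = "\t", check.names = FALSE))
}

#' @param course a [fermentation_course()].
#' @rdname read_course_tsv
#' @export
write_course_tsv <- function(course, path) {
  utils::write.table(course, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate substrate depletion against a prescribed biomass curve
#'
#' Integrates `d[glc]/dt = -v_glc * X(t)`, `d[xyl]/dt = -v_xyl * X(t)` with
#' the competitive-inhibition uptake rates and a biomass concentration given
#' as a function of time (typically a linear interpolant of measured data).
#' Concentrations are clamped at zero.
#'
#' @param params [transporter_kinetics()].
#' @param initial_glc,initial_xyl initial concentrations, mM.
#' @param biomass_curve function of time (h) returning biomass in gDCW L^-1.
#' @param t_grid increasing time grid (h) at which to report the solution.
#' @param rtol,atol integrator tolerances passed to [deSolve::ode()].
#' @return a [fermentation_course()] with the simulated sugars and the
#'   biomass curve evaluated on `t_grid`.
#' @export
simulate_uptake <- function(params, initial_glc, initial_xyl, biomass_curve,
                            t_grid, rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(params, "transporter_kinetics"),
            is.function(biomass_curve))
  if (any(diff(t_grid) <= 0)) {
    stop_zf("t_grid must be strictly increasing", "zf_bad_grid")
  }
  if (initial_glc < 0 || initial_xyl < 0) {
    stop_zf("initial concentrations must be non-negative", "zf_negative_conc")
  }
  deriv <- function(t, y, parms) {
    s <- pmax(y, 0)
    v <- uptake_rates(s[1], s[2], params)
    X <- biomass_curve(t)
    list(c(-v$v_glc * X, -v$v_xyl * X))
  }
  out <- deSolve::ode(y = c(glc = initial_glc, xyl = initial_xyl),
                      times = t_grid, func = deriv, parms = NULL,
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0 || anyNA(out)) {
    last_t <- max(out[stats::complete.cases(out), "time"], -Inf)
    stop_zf(sprintf("ODE integration failed; last valid time %.3g h", last_t),
            "zf_integration_failure")
  }
  fermentation_course(data.frame(
    time_h = out[, "time"],
    glc_mM = pmax(out[, "glc"], 0),
    xyl_mM = pmax(out[, "xyl"], 0),
    biomass_gdcw_L = vapply(out[, "time"], biomass_curve, numeric(1))
  ))
}

#' Pooled coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`. When `observed`/`predicted` are lists of
#' equal-length numeric vectors (one per measurement channel), residual and
#' total sums of squares are pooled across channels, each channel centered
#' at its own mean.
#'
#' @param observed,predicted numeric vectors, or lists of numeric vectors.
#' @return R-squared, or `NA_real_` (with a warning) when the observations
#'   carry zero total variance.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
r_squared <- function(observed, predicted) {
  if (!is.list(observed)) observed <- list(observed)
  if (!is.list(predicted)) predicted <- list(predicted)
  stopifnot(length(observed) == length(predicted))
  ss_res <- ss_tot <- 0
  for (k in seq_along(observed)) {
    o <- observed[[k]]; p <- predicted[[k]]
    if (length(o) != length(p) || length(o) < 2) {
      stop_zf("channels must have equal lengths >= 2", "zf_bad_r2_input")
    }
    ss_res <- ss_res + sum((o - p)^2)
    ss_tot <- ss_tot + sum((o - mean(o))^2)
  }
  if (ss_tot <= 0) {
    warning("zero total variance in observations; R^2 undefined")
    return(NA_real_)
  }
  1 - ss_res / ss_tot
}

#' Uptake-rate surfaces over concentration grids
#'
#' Evaluates [uptake_rates()] on the outer product of a glucose and a xylose
#' concentration grid, as used for rate contour plots.
#'
#' @param params [transporter_kinetics()].
#' @param glc_grid,xyl_grid non-negative concentration grids, mM.
#' @return list of two matrices `v_glc`, `v_xyl` with
#'   `dim = c(length(glc_grid), length(xyl_grid))`; element `[i, j]` is the
#'   rate at `(glc_grid[i], xyl_grid[j])`.
#' @export
uptake_surface <- function(params, glc_grid, xyl_grid) {
  if (any(glc_grid < 0) || any(xyl_grid < 0)) {
    stop_zf("grids must be non-negative", "zf_negative_conc")
  }
  g <- matrix(glc_grid, nrow = length(glc_grid), ncol = length(xyl_grid))
  x <- matrix(xyl_grid, nrow = length(glc_grid), ncol = length(xyl_grid),
              byrow = TRUE)
  v <- uptake_rates(as.numeric(g), as.numeric(x), params)
  dn <- list(glc = as.character(glc_grid), xyl = as.character(xyl_grid))
  list(v_glc = matrix(v$v_glc, length(glc_grid), dimnames = dn),
       v_xyl = matrix(v$v_xyl, length(glc_grid), dimnames = dn))
}

#' Specific uptake rates from a (fitted) time course
#'
#' First derivative of the sugar concentration curves by central finite
#' differences (one-sided at the ends), negated and divided by the biomass
#' concentration. Intended for smooth model-fitted curves rather than raw
#' noisy data; points with zero biomass are reported as `NA`.
#'
#' @param course a [fermentation_course()] with at least 3 rows.
#' @return data frame `time_h`, `v_glc`, `v_xyl` (mmol gDCW^-1 h^-1).
#' @export
specific_rates_from_course <- function(course) {
  course <- fermentation_course(as.data.frame(course))
  if (nrow(course) < 3) stop_zf("need >= 3 time points", "zf_bad_course")
  t <- course$time_h
  dconc <- function(y) {
    n <- length(y)
    d <- numeric(n)
    d[1] <- (y[2] - y[1]) / (t[2] - t[1])
    d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
    if (n > 2) {
      i <- 2:(n - 1)
      d[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
    }
    d
  }
  X <- course$biomass_gdcw_L
  ok <- X > 0
  v_glc <- ifelse(ok, -dconc(course$glc_mM) / X, NA_real_)
  v_xyl <- ifelse(ok, -dconc(course$xyl_mM) / X, NA_real_)
  data.frame(time_h = t, v_glc = v_glc, v_xyl = v_xyl)
}
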