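#' Affine map between simulated lactate and assay signal
#'
#' The plate reader reports a dimensionless normalized signal, not a lactate
#' concentration; an affine map `signal = a * Lac_ex + b` (a > 0) links the
#' two. [fit_affine_map()] estimates it by ordinary least squares of the
#' observed curve on the simulated extracellular lactate, interpolated
#' linearly to the curve's time points. If the unconstrained slope is
#' nonpositive, the smallest positive allowed slope is returned with a
#' degeneracy flag.
#'
#' @param traj an `eca_trajectory` whose grid covers the curve's times.
#' @param curve an [eca_norm_curve()].
#' @param a_min smallest admissible positive slope.
#' @return List with `a`, `b`, `rss` and `degenerate` flag.
#' @export
fit_affine_map <- function(traj, curve, a_min = 1e-12) {
  stopifnot(inherits(traj, "eca_trajectory"), inherits(curve, "eca_norm_curve"))
  lac <- stats::approx(traj$times, traj$states[, "Lac_ex"],
                       xout = curve$times, rule = 1)$y
  if (anyNA(lac)) stop("curve times fall outside the trajectory grid", call. = FALSE)
  y <- curve$value
  sxx <- sum((lac - mean(lac))^2)
  if (sxx == 0) stop("degenerate regressor: simulated Lac_ex is constant", call. = FALSE)
  a <- sum((lac - mean(lac)) * (y - mean(y))) / sxx
  degenerate <- FALSE
  if (a <= 0) {
    a <- a_min
    degenerate <- TRUE
  }
  b <- mean(y) - a * mean(lac)
  list(a = a, b = b, rss = sum((y - (a * lac + b))^2), degenerate = degenerate)
}

#' Define a calibration problem
#'
#' Bundles the target curves (each with the modulator dose it was recorded
#' under), the base parameter set, the free-parameter subset with its bounds,
#' and the multistart configuration. The default free set is exactly the set
#' of parameters that differs between the published cell-line fits
#' (`k_in`, `Capacity_G`, `Capacity_M`, `kr_3`, `i2`); everything else stays
#' frozen at the base values. Default bounds span a factor of 10 either side
#' of each base value.
#'
#' @param curves list of entries, each `list(curve = <eca_norm_curve>,
#'   dose = <eca_dose>)`; a bare `eca_norm_curve` is taken at dose (0, 0).
#' @param base an [eca_params()] object supplying all fixed values.
#' @param free character vector of free parameter names (may be empty).
#' @param bounds optional named list of `c(lower, upper)` per free parameter.
#' @param multistart number of optimization starts (>= 1).
#' @param seed integer seed controlling the start draws; mandatory.
#' @return An object of class `eca_calib_problem`.
#' @export
calibration_problem <- function(curves, base,
                                free = c("k_in", "Capacity_G", "Capacity_M",
                                         "kr_3", "i2"),
                                bounds = NULL, multistart = 10L, seed) {
  validate_params(base)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (inherits(curves, "eca_norm_curve")) curves <- list(curves)
  curves <- lapply(curves, function(e) {
    if (inherits(e, "eca_norm_curve")) e <- list(curve = e, dose = eca_dose())
    stopifnot(inherits(e$curve, "eca_norm_curve"), inherits(e$dose, "eca_dose"))
    e
  })
  bad <- setdiff(free, param_names())
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (is.null(bounds)) {
    bounds <- lapply(stats::setNames(free, free), function(nm) {
      v <- base[[nm]]
      if (v <= 0) stop("cannot derive default bounds for zero-valued `", nm, "`",
                       call. = FALSE)
      c(v / 10, v * 10)
    })
  }
  for (nm in free) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2L || any(!is.finite(b)) || b[1] <= 0 ||
        b[2] <= b[1]) {
      stop("bounds for `", nm, "` must be finite, positive and increasing",
           call. = FALSE)
    }
  }
  structure(list(curves = curves, base = base, free = free,
                 bounds = bounds[free], multistart = as.integer(multistart),
                 seed = as.integer(seed)),
            class = "eca_calib_problem")
}

theta_to_params <- function(problem, theta) {
  args <- problem$base[param_names()]
  for (nm in problem$free) args[[nm]] <- unname(theta[[nm]])
  do.call(eca_params, args)
}

#' Calibration objective
#'
#' Sum over target curves of the residual sum of squares between the observed
#' normalized signal and the best affine image of the simulated extracellular
#' lactate under that curve's dose. The affine map is profiled out by inner
#' ordinary least squares, leaving a scalar objective over the free kinetic
#' parameters. A failed simulation contributes a large finite penalty so the
#' optimizer can retreat.
#'
#' @param problem an [calibration_problem()].
#' @param theta named numeric vector of free-parameter values, within bounds.
#' @return Nonnegative scalar objective value.
#' @export
calib_objective <- function(problem, theta) {
  params <- tryCatch(theta_to_params(problem, theta), error = function(e) NULL)
  if (is.null(params)) return(1e12)
  total <- 0
  for (entry in problem$curves) {
    ct <- entry$curve$times
    pts <- if (ct[1] > 0) c(0, ct) else ct
    traj <- tryCatch(
      simulate_eca(params, entry$dose, eca_grid(points = pts)),
      error = function(e) NULL)
    if (is.null(traj)) return(1e12)
    am <- tryCatch(fit_affine_map(traj, entry$curve), error = function(e) NULL)
    if (is.null(am)) return(1e12)
    total <- total + am$rss
  }
  total
}

#' Fit the model to normalized assay curves
#'
#' Bounded local least squares from multiple starting points: starts are
#' drawn log-uniformly within the bounds using the problem's seed (the first
#' start is the base parameter set itself), each start is refined by
#' L-BFGS-B on log10-transformed parameters, and the best converged start is
#' returned. Identical problems and seeds give identical results.
#'
#' @param problem an [calibration_problem()].
#' @return An object of class `eca_calib_result`: `params` (fitted
#'   [eca_params()]), `affine_maps` (one per curve), `rss`, `theta`,
#'   `starts` (per-start data.frame of objectives and convergence codes),
#'   `seed`, `bounds`.
#' @export
fit_calibration <- function(problem) {
  stopifnot(inherits(problem, "eca_calib_problem"))
  free <- problem$free
  finish <- function(params, theta, starts) {
    maps <- lapply(problem$curves, function(entry) {
      ct <- entry$curve$times
      pts <- if (ct[1] > 0) c(0, ct) else ct
      traj <- simulate_eca(params, entry$dose, eca_grid(points = pts))
      fit_affine_map(traj, entry$curve)
    })
    structure(list(params = params, affine_maps = maps,
                   rss = sum(vapply(maps, `[[`, numeric(1), "rss")),
                   theta = theta, starts = starts,
                   seed = problem$seed, bounds = problem$bounds),
              class = "eca_calib_result")
  }
  if (!length(free)) {
    return(finish(problem$base, numeric(0),
                  data.frame(start = integer(0), objective = numeric(0),
                             convergence = integer(0))))
  }
  lo <- log10(vapply(problem$bounds, `[`, numeric(1), 1L))
  hi <- log10(vapply(problem$bounds, `[`, numeric(1), 2L))
  base_theta <- log10(vapply(free, function(nm) problem$base[[nm]], numeric(1)))
  base_theta <- pmin(pmax(base_theta, lo), hi)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(problem$seed)
  n_free <- length(free)
  starts_mat <- rbind(base_theta,
                      if (problem$multistart > 1L) {
                        matrix(stats::runif((problem$multistart - 1L) * n_free,
                                            rep(lo, each = problem$multistart - 1L),
                                            rep(hi, each = problem$multistart - 1L)),
                               ncol = n_free)
                      })
  colnames(starts_mat) <- free

  obj_log <- function(lt) {
    calib_objective(problem, stats::setNames(10^lt, free))
  }
  results <- vector("list", nrow(starts_mat))
  for (k in seq_len(nrow(starts_mat))) {
    results[[k]] <- tryCatch(
      stats::optim(starts_mat[k, ], obj_log, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) list(par = starts_mat[k, ], value = Inf,
                               convergence = 99L))
  }
  objs <- vapply(results, `[[`, numeric(1), "value")
  if (all(!is.finite(objs))) {
    stop("calibration failed: no start converged (objectives: ",
         paste(signif(objs, 3), collapse = ", "), ")", call. = FALSE)
  }
  starts_df <- data.frame(start = seq_along(results), objective = objs,
                          convergence = vapply(results, function(r)
                            as.integer(r$convergence), integer(1)))
  best <- results[[which.min(objs)]]
  theta <- stats::setNames(10^best$par, free)
  finish(theta_to_params(problem, theta), theta, starts_df)
}

#' @export
print.eca_calib_result <- function(x, ...) {
  cat(sprintf("<eca_calib_result> RSS %.6g over %d curve(s); %d start(s)\n",
              x$rss, length(x$affine_maps), nrow(x$starts)))
  if (length(x$theta)) {
    cat("fitted:\n"); print(x$theta)
  }
  invisible(x)
}

#' Serialize a calibration result to JSON
#'
#' Writes fitted parameters, per-curve affine maps, the residual sum of
#' squares, the seed, the bounds and the per-start table.
#'
#' @param result an `eca_calib_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(result, path) {
  stopifnot(inherits(result, "eca_calib_result"))
  payload <- list(
    fitted_parameters = result$params[param_names()],
    affine_maps = lapply(result$affine_maps, function(m)
      m[c("a", "b", "rss", "degenerate")]),
    rss = result$rss,
    seed = result$seed,
    bounds = result$bounds,
    starts = result$starts)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
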