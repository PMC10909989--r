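#' Output time grid
#'
#' The default grid mirrors the plate reader's kinetic acquisition: 400
#' cycles at 0.35 min per cycle, i.e. samples at 0, 0.35, ..., 139.65 min.
#'
#' @param t_start start time (min, >= 0).
#' @param cycles number of samples.
#' @param dt spacing between samples (min).
#' @param points explicit strictly increasing time vector; overrides the
#'   other arguments when given.
#' @return An object of class `eca_grid` holding the ordered time points.
#' @export
eca_grid <- function(t_start = 0, cycles = 400, dt = 0.35, points = NULL) {
  if (is.null(points)) {
    points <- t_start + dt * (seq_len(cycles) - 1)
  }
  points <- as.numeric(points)
  if (length(points) < 2L || any(!is.finite(points)) ||
      any(diff(points) <= 0) || points[1] < 0) {
    stop("time grid must be >= 2 finite, strictly increasing times with t_start >= 0",
         call. = FALSE)
  }
  structure(list(points = points,
                 t_start = points[1],
                 t_end = points[length(points)]),
            class = "eca_grid")
}

#' Simulate the model
#'
#' Integrates the seven-reaction system from the assay's initial condition
#' (all species zero except extracellular glucose at `glu_ex0`) over the
#' output grid with a stiff-capable adaptive solver. The capacity factors
#' create fast transients near t = 0, hence the tight default tolerances.
#' After integration the trajectory is checked for total-mass conservation
#' and for negativity beyond a small numerical tolerance.
#'
#' @param params an [eca_params()] object.
#' @param dose an [eca_dose()] object; `eca_dose(0, 0)` is the unmodulated
#'   control and yields exactly the unmodulated rate laws.
#' @param grid an [eca_grid()].
#' @param rtol,atol relative / absolute solver tolerances. `atol = NULL`
#'   defaults to `1e-10 * glu_ex0` (with floor 1e-12 when glucose is zero).
#' @return An object of class `eca_trajectory`: list with `times`, `states`
#'   (n_times x 8 matrix, um, frozen species order), `params`, `dose`, and
#'   `diagnostics` (solver steps, tolerances, success flag, max conservation
#'   error).
#' @export
simulate_eca <- function(params, dose = eca_dose(), grid = eca_grid(),
                         rtol = 1e-8, atol = NULL) {
  validate_params(params)
  if (!inherits(grid, "eca_grid")) stop("`grid` must be an eca_grid", call. = FALSE)
  if (is.null(atol)) atol <- max(1e-10 * params$glu_ex0, 1e-12)
  y0 <- initial_state(params)
  p <- params
  deriv <- function(t, y, parms) {
    f2 <- max(0, 1 + dose$oligo * p$i2 - dose$dg2 * p$i1)
    r1 <- p$k_in * y[1] * (p$Capacity_G - y[2])
    r2 <- p$kf_1 * y[2] * f2 - p$kr_1 * y[3]
    r3 <- p$kf_2 * y[3] - p$kr_2 * y[4]
    r4 <- p$kf_3 * y[4] - p$kr_3 * y[5]
    r5 <- p$kf_4 * y[3] * (p$Capacity_M - y[6]) - p$kr_4 * y[6]
    r6 <- p$kf_5 * y[6] * (1 - dose$oligo * p$i2)
    r7 <- p$kf_6 * y[6]
    list(c(-r1, r1 - r2, r2 - r3 - r5, r3 - r4, r4, r5 - r6 - r7, r6, r7))
  }
  sol <- deSolve::lsoda(y = y0, times = grid$points, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = 50000)
  diag_attr <- attributes(sol)
  ok <- is.null(diag_attr$istate) || diag_attr$istate[1] >= 0
  states <- unname(sol[, -1, drop = FALSE])
  colnames(states) <- species_names()
  if (!ok || nrow(states) < length(grid$points) || anyNA(states)) {
    stop("ODE integration failed: ",
         paste(utils::capture.output(deSolve::diagnostics(sol)), collapse = " "),
         call. = FALSE)
  }
  totals <- rowSums(states)
  cons_err <- if (params$glu_ex0 > 0) {
    max(abs(totals - params$glu_ex0)) / params$glu_ex0
  } else {
    max(abs(totals))
  }
  eps_neg <- 1e-6 * max(params$glu_ex0, 1)
  if (min(states) < -eps_neg) {
    stop(sprintf("trajectory breaches nonnegativity tolerance (min %g)",
                 min(states)), call. = FALSE)
  }
  structure(list(times = grid$points,
                 states = states,
                 params = params,
                 dose = dose,
                 diagnostics = list(rtol = rtol, atol = atol,
                                    success = TRUE,
                                    n_steps = unname(diag_attr$istate[3]),
                                    conservation_error = cons_err)),
            class = "eca_trajectory")
}

#' @export
print.eca_trajectory <- function(x, ...) {
  cat(sprintf("<eca_trajectory> %d points, %.2f-%.2f min, dose (oligo %g, 2DG %g)\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              x$dose$oligo, x$dose$dg2))
  invisible(x)
}

#' Trajectory summary metrics
#'
#' Quantifies the two-phase response: the extracellular lactate peak (global
#' maximum on the grid, earliest index on ties) marks the handover from the
#' glycolytic production phase to the consumption phase; glucose exhaustion is
#' the first time extracellular glucose falls below 1% of its initial value
#' (`Inf` if never; a run started with no glucose is exhausted at t_start).
#'
#' @param traj an `eca_trajectory` from [simulate_eca()].
#' @return List with `lac_ex_peak`, `lac_ex_peak_time`,
#'   `glucose_exhaustion_time` (min), and terminal `OxPP`, `CellComponents`
#'   and `Lac_ex` values (um).
#' @export
summarize_eca <- function(traj) {
  if (!inherits(traj, "eca_trajectory") || nrow(traj$states) == 0L) {
    stop("`traj` must be a non-empty eca_trajectory", call. = FALSE)
  }
  lac <- traj$states[, "Lac_ex"]
  i_peak <- which.max(lac)  # earliest index on ties
  glu0 <- traj$params$glu_ex0
  if (glu0 <= 0) {
    t_exh <- traj$times[1]
  } else {
    below <- which(traj$states[, "Glu_ex"] < 0.01 * glu0)
    t_exh <- if (length(below)) traj$times[below[1]] else Inf
  }
  n <- nrow(traj$states)
  list(lac_ex_peak = unname(lac[i_peak]),
       lac_ex_peak_time = traj$times[i_peak],
       glucose_exhaustion_time = t_exh,
       terminal_oxpp = unname(traj$states[n, "OxPP"]),
       terminal_cellcomponents = unname(traj$states[n, "CellComponents"]),
       terminal_lac_ex = unname(traj$states[n, "Lac_ex"]))
}

#' Write / read a trajectory as CSV
#'
#' Columns: `time_min` then the eight species in the frozen order. Numbers
#' are written with 17 significant digits so the round trip is lossless.
#'
#' @param traj an `eca_trajectory`.
#' @param path file path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a data.frame.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time_min = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_min", species_names())
  if (!identical(names(df), need)) {
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}
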