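#' Plate-reader kinetic curve
#'
#' One well's kinetic ECA series: times in minutes and raw signal in relative
#' fluorescence units (RFU), with condition metadata and a flag marking
#' cell-free control wells.
#'
#' @param times strictly increasing time vector (min).
#' @param rfu finite signal vector, same length as `times`.
#' @param cell_line cell-line label.
#' @param condition one of `"control"`, `"oligo"`, `"dg2"`.
#' @param replicate replicate identifier.
#' @param is_cell_free logical: is this a cell-free control well?
#' @param well optional well label.
#' @return An object of class `eca_curve`.
#' @export
eca_curve <- function(times, rfu, cell_line = "unknown",
                      condition = c("control", "oligo", "dg2"),
                      replicate = 1L, is_cell_free = FALSE, well = NA_character_) {
  condition <- match.arg(condition)
  times <- as.numeric(times); rfu <- as.numeric(rfu)
  if (length(times) != length(rfu)) stop("times and rfu lengths differ", call. = FALSE)
  if (length(times) < 2L || any(diff(times) <= 0) || any(!is.finite(times))) {
    stop("times must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(rfu))) stop("rfu must be finite", call. = FALSE)
  structure(list(times = times, rfu = rfu, cell_line = cell_line,
                 condition = condition, replicate = replicate,
                 is_cell_free = isTRUE(is_cell_free), well = well),
            class = "eca_curve")
}

#' Normalized kinetic curve
#'
#' A dimensionless ECA curve after cell-free-control normalization, carrying
#' provenance (source wells and normalization method tag).
#'
#' @param times time vector (min).
#' @param value normalized signal.
#' @param provenance list recording source curve ids and the method tag.
#' @return An object of class `eca_norm_curve`.
#' @export
eca_norm_curve <- function(times, value, provenance = list()) {
  if (length(times) != length(value)) stop("length mismatch", call. = FALSE)
  structure(list(times = as.numeric(times), value = as.numeric(value),
                 provenance = provenance),
            class = "eca_norm_curve")
}

#' Normalize a sample well by its cell-free control
#'
#' The pointwise ratio sample/control. Any multiplicative sensor or
#' instrument drift common to both wells cancels exactly, which is the
#' purpose of running cell-free controls on the same plate. A subtractive
#' method (`method = "subtract"`) is provided as an alternative but division
#' is the default because the assay's drift is multiplicative in character.
#'
#' @param sample an [eca_curve()] from a cell-containing well.
#' @param cell_free an [eca_curve()] with `is_cell_free = TRUE`; for the
#'   division method its signal must be positive everywhere.
#' @param method `"divide"` (default) or `"subtract"`.
#' @return An [eca_norm_curve()] on the shared grid.
#' @export
normalize_by_cell_free <- function(sample, cell_free, method = c("divide", "subtract")) {
  method <- match.arg(method)
  stopifnot(inherits(sample, "eca_curve"), inherits(cell_free, "eca_curve"))
  if (!cell_free$is_cell_free) stop("`cell_free` is not flagged cell-free", call. = FALSE)
  if (!isTRUE(all.equal(sample$times, cell_free$times))) {
    stop("sample and control time grids differ", call. = FALSE)
  }
  if (method == "divide" && any(cell_free$rfu <= 0)) {
    stop("cell-free control has nonpositive signal; cannot divide", call. = FALSE)
  }
  v <- if (method == "divide") sample$rfu / cell_free$rfu else sample$rfu - cell_free$rfu
  eca_norm_curve(sample$times, v,
                 provenance = list(sample_well = sample$well,
                                   control_well = cell_free$well,
                                   cell_line = sample$cell_line,
                                   condition = sample$condition,
                                   method = method))
}

#' Average replicate curves pointwise
#'
#' @param curves list of [eca_norm_curve()] objects on a common grid.
#' @return The pointwise arithmetic mean as an [eca_norm_curve()].
#' @export
average_replicates <- function(curves) {
  if (!length(curves)) stop("need at least one curve", call. = FALSE)
  t0 <- curves[[1]]$times
  for (c in curves) {
    if (!isTRUE(all.equal(c$times, t0))) stop("curves are on mixed time grids", call. = FALSE)
  }
  vals <- rowMeans(vapply(curves, `[[`, numeric(length(t0)), "value"))
  eca_norm_curve(t0, vals,
                 provenance = list(n_replicates = length(curves),
                                   method = curves[[1]]$provenance$method))
}

#' Extracellular acidification rate (ECAR) series
#'
#' The local slope of the normalized signal versus time, estimated by an
#' ordinary-least-squares fit over a centered sliding window (default 7
#' samples, about 2.45 min on the instrument grid) — more robust to
#' point-to-point noise than a two-point difference. Edge windows are
#' truncated one-sided so the output sits on the input grid.
#'
#' @param curve an [eca_norm_curve()].
#' @param window window width in samples (odd, >= 3).
#' @return Numeric ECAR series (signal units per min), same length as the grid.
#' @export
ecar <- function(curve, window = 7L) {
  stopifnot(inherits(curve, "eca_norm_curve"))
  n <- length(curve$times)
  window <- as.integer(window)
  if (window < 3L || window > n) {
    stop("window must be >= 3 samples and fit inside the curve", call. = FALSE)
  }
  half <- window %/% 2L
  out <- numeric(n)
  t <- curve$times; y <- curve$value
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    tw <- t[lo:hi]; yw <- y[lo:hi]
    tc <- tw - mean(tw)
    out[i] <- sum(tc * yw) / sum(tc * tc)
  }
  out
}

#' Two-phase metrics of a normalized curve
#'
#' The assay response rises while glucose lasts (phase 1, < 70 min) and falls
#' once exported lactate is re-imported and consumed (phase 2, > 90 min).
#' The peak time is the argmax of a 5-point centered moving average of the
#' signal (earliest time on ties); the phase ECAR values are means of the
#' [ecar()] series over [0, 70) min and (90 min, end].
#'
#' @param curve an [eca_norm_curve()] spanning at least 90 min.
#' @param window ECAR window passed to [ecar()].
#' @return List with `peak_time` (min), `phase1_mean_ecar`, `phase2_mean_ecar`.
#' @export
phase_metrics <- function(curve, window = 7L) {
  stopifnot(inherits(curve, "eca_norm_curve"))
  t <- curve$times
  if (t[length(t)] - t[1] < 90) stop("curve must span at least 90 min", call. = FALSE)
  # centered 5-point moving average, windows truncated at the edges
  n <- length(curve$value)
  cs <- cumsum(c(0, curve$value))
  lo <- pmax(seq_len(n) - 2L, 1L)
  hi <- pmin(seq_len(n) + 2L, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  i_peak <- which.max(sm)
  rate <- ecar(curve, window)
  list(peak_time = t[i_peak],
       phase1_mean_ecar = mean(rate[t >= 0 & t < 70]),
       phase2_mean_ecar = mean(rate[t > 90]))
}

#' Read / write kinetic plate data as long-format CSV
#'
#' The interchange dialect for plate-reader kinetic data: one row per well
#' per time point with columns `well`, `cell_line`, `condition`, `replicate`,
#' `is_cell_free`, `time_min`, `rfu` (UTF-8, header required, times in
#' minutes as decimals).
#'
#' @param curves list of [eca_curve()] objects.
#' @param path file path.
#' @return `write_kinetic_csv()` returns `path` invisibly;
#'   `read_kinetic_csv()` returns a list of [eca_curve()] objects, one per
#'   well, in file order.
#' @export
write_kinetic_csv <- function(curves, path) {
  rows <- lapply(curves, function(c) {
    data.frame(well = c$well, cell_line = c$cell_line, condition = c$condition,
               replicate = c$replicate, is_cell_free = c$is_cell_free,
               time_min = c$times, rfu = c$rfu)
  })
  df <- do.call(rbind, rows)
  df$time_min <- format(df$time_min, digits = 17, scientific = FALSE, trim = TRUE)
  df$rfu <- format(df$rfu, digits = 17, scientific = FALSE, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kinetic_csv
#' @export
read_kinetic_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("well", "cell_line", "condition", "replicate", "is_cell_free",
            "time_min", "rfu")
  if (!all(need %in% names(df))) {
    stop("kinetic CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  wells <- unique(df$well)
  lapply(wells, function(w) {
    d <- df[df$well == w, ]
    eca_curve(times = d$time_min, rfu = d$rfu,
              cell_line = d$cell_line[1], condition = d$condition[1],
              replicate = d$replicate[1],
              is_cell_free = as.logical(d$is_cell_free[1]), well = w)
  })
}
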