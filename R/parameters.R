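#' Model parameter set
#'
#' Construct the full parameter set of the seven-reaction glucose catabolism
#' model: the glucose-uptake rate constant, six forward and four reverse
#' mass-action rate constants, the two drug-sensitivity rates, the two
#' capacity boundary quantities and the initial extracellular glucose.
#'
#' Concentrations are carried in micromolar (\eqn{\mu}m) and time in minutes;
#' rate constants are kept numerically as model units without dimensional
#' analysis of the composite capacity terms. Compartment volumes (media, cell,
#' mitochondria) are fixed at 1 and do not enter the rate equations.
#'
#' @param k_in glucose-uptake rate constant (min^-1 conc^-1).
#' @param kf_1,kf_2,kf_3,kf_4,kf_5,kf_6 forward rate constants (min^-1).
#' @param kr_1,kr_2,kr_3,kr_4 reverse rate constants (min^-1).
#' @param i1 2-deoxyglucose inhibition rate (per dose unit).
#' @param i2 oligomycin stimulation/inhibition rate (per dose unit); one
#'   shared parameter acting at both the glucose-to-pyruvate step
#'   (stimulation) and the TCA-to-OxPP step (inhibition).
#' @param Capacity_G glycolysis capacity (conc units): throttles glucose entry
#'   into the cell through the factor (Capacity_G - Glu).
#' @param Capacity_M mitochondrial capacity (conc units): throttles pyruvate
#'   entry into the mitochondrion through (Capacity_M - TCA).
#' @param glu_ex0 initial extracellular glucose (\eqn{\mu}m).
#'
#' @return An object of class `eca_params`: a named list of the 17 scalars
#'   plus the fixed unit compartment volumes.
#' @seealso [eca_preset()] for the published cell-line parameterisations.
#' @export
eca_params <- function(k_in = 0.00012,
                       kf_1 = 1, kr_1 = 0.01,
                       kf_2 = 1, kr_2 = 0.1,
                       kf_3 = 1, kr_3 = 0.1,
                       kf_4 = 0.1, kr_4 = 1,
                       kf_5 = 1, kf_6 = 1,
                       i1 = 0.1, i2 = 0.1,
                       Capacity_G = 500, Capacity_M = 50,
                       glu_ex0 = 20000) {
  p <- list(k_in = k_in,
            kf_1 = kf_1, kr_1 = kr_1,
            kf_2 = kf_2, kr_2 = kr_2,
            kf_3 = kf_3, kr_3 = kr_3,
            kf_4 = kf_4, kr_4 = kr_4,
            kf_5 = kf_5, kf_6 = kf_6,
            i1 = i1, i2 = i2,
            Capacity_G = Capacity_G, Capacity_M = Capacity_M,
            glu_ex0 = glu_ex0,
            compartment_volumes = c(media = 1, cell = 1, mitochondria = 1))
  class(p) <- "eca_params"
  validate_params(p)
  p
}

#' @export
print.eca_params <- function(x, ...) {
  cat("<eca_params>\n")
  num <- unlist(x[setdiff(names(x), "compartment_volumes")])
  print(num)
  invisible(x)
}

# Names of the scalar parameters a one-at-a-time sweep may scale.
param_names <- function() {
  c("k_in", "kf_1", "kr_1", "kf_2", "kr_2", "kf_3", "kr_3",
    "kf_4", "kr_4", "kf_5", "kf_6", "i1", "i2",
    "Capacity_G", "Capacity_M", "glu_ex0")
}

validate_params <- function(p) {
  if (!inherits(p, "eca_params")) stop("not an `eca_params` object", call. = FALSE)
  for (nm in param_names()) {
    v <- p[[nm]]
    if (is.null(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("invalid parameter: `%s` must be a finite scalar", nm),
           call. = FALSE)
    }
    if (v < 0) {
      stop(sprintf("invalid parameter: `%s` is negative (%g)", nm, v),
           call. = FALSE)
    }
  }
  if (!all(p$compartment_volumes == 1)) {
    stop("invalid parameter: compartment volumes must all equal 1", call. = FALSE)
  }
  invisible(p)
}

#' Published cell-line parameterisations
#'
#' Optimised parameter sets for the three cell lines studied with the kinetic
#' glycolysis assay. `"A549"` (human lung carcinoma) is the reference set;
#' `"LLCMK2"` (rhesus monkey kidney) differs only in the uptake constant
#' (`k_in` = 1e-4) and lactate re-import rate (`kr_3` = 0.2); `"HepG2"`
#' (human hepatoma) lowers `k_in` to 1e-4, the glycolytic capacity to 350,
#' the mitochondrial capacity to 40 and the oligomycin sensitivity `i2` to
#' 0.01. All share an initial extracellular glucose of 20 000 um.
#'
#' @param cell_line one of `"A549"`, `"LLCMK2"`, `"HepG2"`.
#' @return An [eca_params()] object.
#' @export
eca_preset <- function(cell_line) {
  valid <- c("A549", "LLCMK2", "HepG2")
  if (length(cell_line) != 1L || !cell_line %in% valid) {
    stop(sprintf("unknown cell line %s; valid names: %s",
                 deparse(cell_line), paste(valid, collapse = ", ")),
         call. = FALSE)
  }
  switch(cell_line,
         A549   = eca_params(),
         LLCMK2 = eca_params(k_in = 0.0001, kr_3 = 0.2),
         HepG2  = eca_params(k_in = 0.0001, Capacity_G = 350,
                             Capacity_M = 40, i2 = 0.01))
}

#' Modulator dose pair
#'
#' Dimensionless oligomycin and 2-deoxyglucose concentrations in model units.
#' The published sweeps span 0-10 units; the mapping from wet-lab doses
#' (2 uM oligomycin, 100 mM 2DG) to model units is not defined, so doses are
#' always interpreted in model units.
#'
#' @param oligo oligomycin dose (model units, >= 0).
#' @param dg2 2-deoxyglucose dose (model units, >= 0).
#' @return An object of class `eca_dose`.
#' @export
eca_dose <- function(oligo = 0, dg2 = 0) {
  if (length(oligo) != 1L || length(dg2) != 1L ||
      !is.finite(oligo) || !is.finite(dg2) || oligo < 0 || dg2 < 0) {
    stop("doses must be finite nonnegative scalars", call. = FALSE)
  }
  structure(list(oligo = oligo, dg2 = dg2), class = "eca_dose")
}

#' @export
print.eca_dose <- function(x, ...) {
  cat(sprintf("<eca_dose> oligo = %g, 2DG = %g (model units)\n", x$oligo, x$dg2))
  invisible(x)
}

# TOML key used for the initial glucose (table naming), vs the field name.
toml_key_map <- function() {
  keys <- param_names()
  keys[keys == "glu_ex0"] <- "Glu_ex"
  stats::setNames(keys, param_names())
}

#' Read / write parameter sets as flat TOML
#'
#' Parameter sets serialize to a flat `key = value` TOML document whose keys
#' match the published table names (`k_in`, `kf_1`, ..., `i2`, `Capacity_G`,
#' `Capacity_M`, `Glu_ex`). Only the flat scalar dialect is supported:
#' comments (`#`), blank lines and `key = number` pairs.
#'
#' @param params an [eca_params()] object.
#' @param path file path.
#' @return `write_params_toml()` returns `path` invisibly;
#'   `read_params_toml()` returns an [eca_params()] object.
#' @export
write_params_toml <- function(params, path) {
  validate_params(params)
  km <- toml_key_map()
  lines <- vapply(param_names(), function(nm) {
    sprintf("%s = %s", km[[nm]], format(params[[nm]], digits = 17))
  }, character(1))
  writeLines(c("# ecaflux parameter set", lines), path)
  invisible(path)
}

#' @rdname write_params_toml
#' @export
read_params_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.+)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) {
    stop("cannot parse TOML line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, character(1), 3L)))
  if (anyNA(vals)) {
    stop("non-numeric value for key(s): ", paste(keys[is.na(vals)], collapse = ", "),
         call. = FALSE)
  }
  km <- toml_key_map()
  args <- list()
  for (nm in param_names()) {
    key <- km[[nm]]
    if (!key %in% keys) stop("missing key in parameter file: ", key, call. = FALSE)
    args[[nm]] <- vals[[match(key, keys)]]
  }
  do.call(eca_params, args)
}
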