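#' Dynamic species of the model
#'
#' The eight dynamic species, in the frozen order used by every state vector,
#' trajectory column block and serialization in the package: extracellular
#' glucose, intracellular glucose, pyruvate, intracellular lactate,
#' extracellular lactate, the lumped TCA pool, the oxidative-phosphorylation
#' sink and the cell-components (biomass) sink. The two capacities are not
#' state: they are constant boundary quantities.
#'
#' @return Character vector of the 8 species names.
#' @export
species_names <- function() {
  c("Glu_ex", "Glu", "Pyr", "Lac", "Lac_ex", "TCA", "OxPP", "CellComponents")
}

#' Initial state vector
#'
#' All species start at zero except extracellular glucose, which starts at
#' `glu_ex0` — the assay adds a single glucose bolus to starved cells.
#'
#' @param params an [eca_params()] object.
#' @return Named numeric vector of length 8 in the frozen species order.
#' @export
initial_state <- function(params) {
  validate_params(params)
  s <- stats::setNames(numeric(8), species_names())
  s["Glu_ex"] <- params$glu_ex0
  s
}

as_state <- function(state) {
  if (length(state) != 8L) stop("state must have 8 entries", call. = FALSE)
  if (!all(is.finite(state))) stop("non-finite state vector", call. = FALSE)
  stats::setNames(as.numeric(state), species_names())
}

#' Stoichiometry matrix
#'
#' The 8 species x 7 reactions stoichiometry matrix. Every reaction is a 1:1
#' mass transfer, so each column contains one -1, one +1 and zeros, and sums
#' to zero over the dynamic species — the structural basis of total-mass
#' conservation along trajectories.
#'
#' @return An 8 x 7 integer matrix with dimnames (species, R1..R7).
#' @export
stoichiometry_matrix <- function() {
  sp <- species_names()
  S <- matrix(0L, nrow = 8, ncol = 7,
              dimnames = list(sp, paste0("R", 1:7)))
  S["Glu_ex", "R1"] <- -1L; S["Glu", "R1"] <- 1L
  S["Glu", "R2"] <- -1L; S["Pyr", "R2"] <- 1L
  S["Pyr", "R3"] <- -1L; S["Lac", "R3"] <- 1L
  S["Lac", "R4"] <- -1L; S["Lac_ex", "R4"] <- 1L
  S["Pyr", "R5"] <- -1L; S["TCA", "R5"] <- 1L
  S["TCA", "R6"] <- -1L; S["OxPP", "R6"] <- 1L
  S["TCA", "R7"] <- -1L; S["CellComponents", "R7"] <- 1L
  S
}

#' Assemble the reaction network
#'
#' Builds the seven-reaction network: capacity-limited glucose uptake (R1),
#' reversible glucose-to-pyruvate conversion carrying both drug modulations
#' (R2), reversible pyruvate-lactate interconversion (R3), reversible lactate
#' export (R4), capacity-limited reversible pyruvate entry into the TCA pool
#' (R5), and the two irreversible mitochondrial drains into OxPP (R6, carries
#' the oligomycin inhibition) and CellComponents (R7). Reactions 2-5 are
#' reversible.
#'
#' @param params an [eca_params()] object; validated on entry.
#' @return An object of class `eca_network` with elements `reactions` (list
#'   of 7, each with `id`, `reactant`, `product`, `reversible` and a `rate`
#'   closure over state and dose) and `stoichiometry`.
#' @export
build_network <- function(params) {
  validate_params(params)
  p <- params
  mk <- function(id, reactant, product, reversible, rate) {
    list(id = id, reactant = reactant, product = product,
         reversible = reversible, rate = rate)
  }
  reactions <- list(
    mk("R1", "Glu_ex", "Glu", FALSE, function(s, d) {
      p$k_in * s[["Glu_ex"]] * (p$Capacity_G - s[["Glu"]])
    }),
    mk("R2", "Glu", "Pyr", TRUE, function(s, d) {
      f <- max(0, 1 + d$oligo * p$i2 - d$dg2 * p$i1)
      p$kf_1 * s[["Glu"]] * f - p$kr_1 * s[["Pyr"]]
    }),
    mk("R3", "Pyr", "Lac", TRUE, function(s, d) {
      p$kf_2 * s[["Pyr"]] - p$kr_2 * s[["Lac"]]
    }),
    mk("R4", "Lac", "Lac_ex", TRUE, function(s, d) {
      p$kf_3 * s[["Lac"]] - p$kr_3 * s[["Lac_ex"]]
    }),
    mk("R5", "Pyr", "TCA", TRUE, function(s, d) {
      p$kf_4 * s[["Pyr"]] * (p$Capacity_M - s[["TCA"]]) - p$kr_4 * s[["TCA"]]
    }),
    mk("R6", "TCA", "OxPP", FALSE, function(s, d) {
      p$kf_5 * s[["TCA"]] * (1 - d$oligo * p$i2)
    }),
    mk("R7", "TCA", "CellComponents", FALSE, function(s, d) {
      p$kf_6 * s[["TCA"]]
    })
  )
  structure(list(reactions = reactions,
                 stoichiometry = stoichiometry_matrix(),
                 params = params),
            class = "eca_network")
}

#' @export
print.eca_network <- function(x, ...) {
  cat(sprintf("<eca_network> %d reactions (%d reversible)\n",
              length(x$reactions),
              sum(vapply(x$reactions, `[[`, logical(1), "reversible"))))
  for (r in x$reactions) {
    cat(sprintf("  %s: %s %s %s\n", r$id, r$reactant,
                if (r$reversible) "<->" else "->", r$product))
  }
  invisible(x)
}

#' Net reaction fluxes
#'
#' Evaluates the net (forward minus reverse) rate of each of the seven
#' reactions at a state. The drug-modulation factor on the glucose-to-pyruvate
#' forward rate, \eqn{f = 1 + oligo \cdot i2 - dg2 \cdot i1}, is clamped at
#' zero from below: beyond the published 0-10 dose range the printed law would
#' drive the forward flux negative (a reversed enzyme), while inside that
#' range with the published sensitivities the clamp is inactive. The factor
#' applies only to the forward term, never to the reverse `kr_1 * Pyr` term.
#'
#' @param state numeric state vector of length 8 (frozen species order).
#' @param params an [eca_params()] object.
#' @param dose an [eca_dose()] object.
#' @return Named numeric vector of 7 net fluxes (um/min), names R1..R7.
#' @export
reaction_fluxes <- function(state, params, dose = eca_dose()) {
  s <- as_state(state)
  validate_params(params)
  p <- params
  f2 <- max(0, 1 + dose$oligo * p$i2 - dose$dg2 * p$i1)
  c(R1 = p$k_in * s[["Glu_ex"]] * (p$Capacity_G - s[["Glu"]]),
    R2 = p$kf_1 * s[["Glu"]] * f2 - p$kr_1 * s[["Pyr"]],
    R3 = p$kf_2 * s[["Pyr"]] - p$kr_2 * s[["Lac"]],
    R4 = p$kf_3 * s[["Lac"]] - p$kr_3 * s[["Lac_ex"]],
    R5 = p$kf_4 * s[["Pyr"]] * (p$Capacity_M - s[["TCA"]]) - p$kr_4 * s[["TCA"]],
    R6 = p$kf_5 * s[["TCA"]] * (1 - dose$oligo * p$i2),
    R7 = p$kf_6 * s[["TCA"]])
}

#' ODE right-hand side
#'
#' Time-autonomous derivative of the state: the stoichiometry matrix applied
#' to the net reaction fluxes. Component form: d(Glu_ex) = -R1; d(Glu) = R1 -
#' R2; d(Pyr) = R2 - R3 - R5; d(Lac) = R3 - R4; d(Lac_ex) = R4; d(TCA) = R5 -
#' R6 - R7; d(OxPP) = R6; d(CellComponents) = R7. The entries always sum to
#' zero, so total mass is conserved.
#'
#' @param t time (minutes); unused, the system is autonomous.
#' @inheritParams reaction_fluxes
#' @return Named numeric derivative vector of length 8 (um/min).
#' @export
eca_rhs <- function(t, state, params, dose = eca_dose()) {
  v <- reaction_fluxes(state, params, dose)
  drop(stoichiometry_matrix() %*% v)
}
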