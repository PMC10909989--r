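# Fixed-step explicit-Euler integrator written directly from the printed
# rate equations, independent of the package's stoichiometry-matrix /
# adaptive-solver path. Serves as the brute-force oracle for solver checks.
#
# `p` is a plain list with fields k_in, kf_1..kf_6, kr_1..kr_4, i1, i2,
# Capacity_G, Capacity_M, glu_ex0. Records every `record_every` steps when
# requested (row = time then the 8 species in the frozen order).
euler_oracle <- function(p, oligo = 0, dg2 = 0, t_end = 139.65, dt = 1e-3,
                         record_every = NA) {
  glu_ex <- p$glu_ex0; glu <- 0; pyr <- 0; lac <- 0; lac_ex <- 0
  tca <- 0; oxpp <- 0; cc <- 0
  n <- round(t_end / dt)
  f2 <- max(0, 1 + oligo * p$i2 - dg2 * p$i1)
  rec <- NULL
  ri <- 1L
  if (!is.na(record_every)) {
    rec <- matrix(NA_real_, nrow = floor(n / record_every) + 1L, ncol = 9L)
    rec[1L, ] <- c(0, glu_ex, glu, pyr, lac, lac_ex, tca, oxpp, cc)
  }
  for (i in seq_len(n)) {
    r1 <- p$k_in * glu_ex * (p$Capacity_G - glu)
    r2 <- p$kf_1 * glu * f2 - p$kr_1 * pyr
    r3 <- p$kf_2 * pyr - p$kr_2 * lac
    r4 <- p$kf_3 * lac - p$kr_3 * lac_ex
    r5 <- p$kf_4 * pyr * (p$Capacity_M - tca) - p$kr_4 * tca
    r6 <- p$kf_5 * tca * (1 - oligo * p$i2)
    r7 <- p$kf_6 * tca
    glu_ex <- glu_ex - dt * r1
    glu <- glu + dt * (r1 - r2)
    pyr <- pyr + dt * (r2 - r3 - r5)
    lac <- lac + dt * (r3 - r4)
    lac_ex <- lac_ex + dt * r4
    tca <- tca + dt * (r5 - r6 - r7)
    oxpp <- oxpp + dt * r6
    cc <- cc + dt * r7
    if (!is.na(record_every) && i %% record_every == 0L) {
      ri <- ri + 1L
      rec[ri, ] <- c(i * dt, glu_ex, glu, pyr, lac, lac_ex, tca, oxpp, cc)
    }
  }
  final <- c(Glu_ex = glu_ex, Glu = glu, Pyr = pyr, Lac = lac,
             Lac_ex = lac_ex, TCA = tca, OxPP = oxpp, CellComponents = cc)
  list(final = final, record = rec)
}

# Parameter list for the oracle taken from an eca_params object (field copy
# only; the oracle never calls package rate-law code).
oracle_params <- function(params) {
  params[c("k_in", "kf_1", "kr_1", "kf_2", "kr_2", "kf_3", "kr_3",
           "kf_4", "kr_4", "kf_5", "kf_6", "i1", "i2",
           "Capacity_G", "Capacity_M", "glu_ex0")]
}
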