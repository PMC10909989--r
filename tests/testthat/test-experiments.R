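# Sweeps share the instrument grid; simulations are cheap enough to run the
# full 400-point horizon everywhere.

test_that("a one-at-a-time sweep runs exactly 11 simulations on a symmetric factor grid", {
  sw <- oat_sweep(eca_preset("A549"), "k_in")
  expect_length(sw$trajectories, 11L)
  expect_length(sw$metrics, 11L)
  expect_equal(sw$factors, seq(0.5, 1.5, by = 0.1))
  expect_equal(sw$factors + rev(sw$factors), rep(2, 11))  # symmetric about 1
  expect_error(oat_sweep(eca_preset("A549"), "k_out"), "unknown parameter")
})

test_that("a zero step size collapses every run onto the baseline", {
  sw <- oat_sweep(eca_preset("A549"), "kf_2", step = 0,
                  grid = eca_grid(cycles = 50))
  base <- sw$trajectories[[6]]$states
  for (tr in sw$trajectories) expect_identical(tr$states, base)
})

test_that("the glucose-pyruvate reverse rate has negligible influence at +/-10%", {
  sw <- oat_sweep(eca_preset("A549"), "kr_1")
  peaks <- vapply(sw$metrics, `[[`, numeric(1), "lac_ex_peak")
  base <- peaks[sw$factors == 1]
  ten_pct <- abs(sw$factors - 1) <= 0.1 + 1e-12
  expect_lt(max(abs(peaks[ten_pct] - base)) / base, 0.001)
})

test_that("the two mitochondrial drain rates are interchangeable in their effect", {
  sw5 <- oat_sweep(eca_preset("A549"), "kf_5")
  sw6 <- oat_sweep(eca_preset("A549"), "kf_6")
  rep_ <- sensitivity_report(list(sw5, sw6))
  expect_lt(abs(rep_$max_rel_dpeak[1] - rep_$max_rel_dpeak[2]), 1e-9)
  peaks5 <- vapply(sw5$metrics, `[[`, numeric(1), "lac_ex_peak")
  peaks6 <- vapply(sw6$metrics, `[[`, numeric(1), "lac_ex_peak")
  expect_equal(peaks5, peaks6, tolerance = 1e-9)
})

test_that("sensitivity ranking places capacities above inert reverse rates", {
  sw_kr1 <- oat_sweep(eca_preset("A549"), "kr_1")
  sw_cg <- oat_sweep(eca_preset("A549"), "Capacity_G")
  rep_ <- sensitivity_report(list(sw_kr1, sw_cg))
  expect_identical(rep_$parameter[1], "Capacity_G")
  expect_gt(rep_$max_rel_dpeak[1], rep_$max_rel_dpeak[2])
  expect_error(sensitivity_report(list()), "at least one")
})

test_that("directional effects match the one-at-a-time narratives", {
  p <- eca_preset("A549")
  up_vs_down <- function(name, field = "lac_ex_peak") {
    sw <- oat_sweep(p, name)
    vals <- vapply(sw$metrics, `[[`, numeric(1), field)
    vals[11] - vals[1]  # factor 1.5 minus factor 0.5
  }
  # more supplied glucose -> higher terminal lactate plateau
  expect_gt(up_vs_down("glu_ex0", "terminal_lac_ex"), 0)
  # larger mitochondrial capacity -> lower lactate peak
  expect_lt(up_vs_down("Capacity_M"), 0)
  # forward glycolytic steps raise the peak; their reverse rates lower it
  expect_gt(up_vs_down("kf_2"), 0)
  expect_gt(up_vs_down("kf_3"), 0)
  expect_lt(up_vs_down("kr_2"), 0)
  expect_lt(up_vs_down("kr_3"), 0)
  # faster pyruvate entry into mitochondria lowers the peak; kr_4 matters
  # much less than its forward counterpart (the flux mostly accumulates in
  # the irreversible mitochondrial sinks)
  expect_lt(up_vs_down("kf_4"), 0)
  ten_pct_effect <- function(name) {
    sw <- oat_sweep(p, name)
    peaks <- vapply(sw$metrics, `[[`, numeric(1), "lac_ex_peak")
    max(abs(peaks[5:7] - peaks[6])) / peaks[6]
  }
  expect_lt(ten_pct_effect("kr_4"), ten_pct_effect("kf_4"))
  expect_lt(ten_pct_effect("kr_4"), 0.005)
})

test_that("increasing glycolytic capacity accelerates phase-1 glucose consumption", {
  p <- eca_preset("A549")
  sw <- oat_sweep(p, "Capacity_G")
  # glucose remaining at 35 min (mid phase 1), per capacity factor
  i35 <- which.min(abs(sw$trajectories[[1]]$times - 35))
  glu35 <- vapply(sw$trajectories, function(tr) tr$states[i35, "Glu_ex"],
                  numeric(1))
  expect_true(all(diff(glu35) < 0))
})

test_that("oligomycin raises and 2DG lowers the lactate peak monotonically", {
  p <- eca_preset("A549")
  sw_o <- dose_sweep(p, "oligo")
  peaks_o <- vapply(sw_o$metrics, `[[`, numeric(1), "lac_ex_peak")
  expect_true(all(diff(peaks_o) >= 0))
  sw_d <- dose_sweep(p, "dg2")
  peaks_d <- vapply(sw_d$metrics, `[[`, numeric(1), "lac_ex_peak")
  expect_true(all(diff(peaks_d) <= 0))
  # strong inhibition starves the mitochondrial sinks too; at low doses the
  # 140-min endpoint OxPP is nearly flat (the slower flux still arrives
  # within the horizon), so the drop is asserted from mid-range doses up
  oxpp_d <- vapply(sw_d$metrics, `[[`, numeric(1), "terminal_oxpp")
  expect_true(all(diff(oxpp_d[sw_d$doses >= 5]) <= 0))
  expect_lt(oxpp_d[length(oxpp_d)], 0.5 * oxpp_d[1])
  # dose zero is bit-identical to the control simulation
  control <- simulate_eca(p)
  expect_identical(sw_o$trajectories[[1]]$states, control$states)
  expect_identical(sw_d$trajectories[[1]]$states, control$states)
  expect_error(dose_sweep(p, "oligo", doses = c(-1, 0)), "nonnegative")
})

test_that("every sweep run conserves total mass", {
  sw <- dose_sweep(eca_preset("LLCMK2"), "oligo", doses = c(0, 5, 10))
  for (tr in sw$trajectories) {
    expect_lt(tr$diagnostics$conservation_error, 1e-6)
  }
})

test_that("sweep results export as tidy CSV", {
  sw <- oat_sweep(eca_preset("A549"), "kr_1", grid = eca_grid(cycles = 50))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(sw, path)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("parameter", "factor", "metric", "value"))
  expect_equal(nrow(df), 11L * 6L)
})
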