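# Thinner grid than the instrument's 400 cycles keeps the optimizer fast;
# the latent kinetics are fully resolved at 1.4-min spacing.
fit_grid <- eca_grid(cycles = 100, dt = 1.4)

test_that("affine map recovers exact affine images of simulated lactate", {
  tr <- simulate_eca(eca_preset("A549"), grid = fit_grid)
  lac <- tr$states[, "Lac_ex"]
  exact <- eca_norm_curve(tr$times, 2 * lac + 5)
  am <- fit_affine_map(tr, exact)
  expect_equal(am$a, 2, tolerance = 1e-10)
  expect_equal(am$b, 5, tolerance = 1e-8)
  expect_lt(am$rss, 1e-12 * sum(exact$value^2))
  expect_false(am$degenerate)

  ident <- fit_affine_map(tr, eca_norm_curve(tr$times, lac))
  expect_equal(ident$a, 1, tolerance = 1e-10)
  expect_equal(ident$b, 0, tolerance = 1e-8)

  # anti-correlated signal: slope pinned at the smallest positive bound
  neg <- fit_affine_map(tr, eca_norm_curve(tr$times, -lac))
  expect_true(neg$degenerate)
  expect_gt(neg$a, 0)
})

test_that("a constant regressor is rejected as degenerate", {
  tr <- simulate_eca(eca_params(glu_ex0 = 0), grid = eca_grid(cycles = 20))
  curve <- eca_norm_curve(tr$times, rnorm(20))
  expect_error(fit_affine_map(tr, curve), "degenerate")
})

test_that("generator round-trip recovers the virtual sensor's affine map", {
  cfg <- generator_config(doses = list(control = eca_dose()), sigma = 0,
                          drift_slope = 0, a = 0.004, b = 10, seed = 3,
                          grid = fit_grid)
  ds <- generate_eca_dataset(cfg)
  tr <- simulate_eca(eca_preset("A549"), grid = fit_grid)
  # the raw drift-free well carries the sensor map itself
  raw <- Filter(function(c) !c$is_cell_free, ds$curves)[[1]]
  am <- fit_affine_map(tr, eca_norm_curve(raw$times, raw$rfu))
  expect_equal(am$a, 0.004, tolerance = 1e-6)
  expect_equal(am$b, 10, tolerance = 1e-6)
  # cell-free normalization rescales the map by the sensor offset: (a/b, 1)
  norm <- preprocess_plate(ds)$control
  am2 <- fit_affine_map(tr, norm)
  expect_equal(am2$a, 0.004 / 10, tolerance = 1e-6)
  expect_equal(am2$b, 1, tolerance = 1e-6)
})

test_that("the profiled objective vanishes at the generating truth and grows away from it", {
  cfg <- generator_config(cell_line = "LLCMK2", doses = list(control = eca_dose()),
                          sigma = 0, seed = 4, grid = fit_grid)
  curve <- preprocess_plate(generate_eca_dataset(cfg))$control
  prob <- calibration_problem(list(list(curve = curve, dose = eca_dose())),
                              base = eca_preset("LLCMK2"), free = "kr_3",
                              seed = 1)
  at_truth <- calib_objective(prob, c(kr_3 = 0.2))
  expect_lt(at_truth, 1e-10)
  expect_gte(at_truth, 0)
  perturbed <- calib_objective(prob, c(kr_3 = 0.3))
  expect_gt(perturbed, at_truth)
})

test_that("an empty free set returns the base parameters with affine maps only", {
  cfg <- generator_config(doses = list(control = eca_dose()), sigma = 0,
                          seed = 6, grid = fit_grid)
  curve <- preprocess_plate(generate_eca_dataset(cfg))$control
  prob <- calibration_problem(list(list(curve = curve, dose = eca_dose())),
                              base = eca_preset("A549"), free = character(0),
                              seed = 1)
  res <- fit_calibration(prob)
  for (nm in param_names()) {
    expect_identical(res$params[[nm]], eca_preset("A549")[[nm]], info = nm)
  }
  expect_length(res$affine_maps, 1L)
  expect_length(res$theta, 0L)
})

test_that("a single free rate is recovered exactly from noiseless data", {
  truth <- eca_params(kr_3 = 0.2)  # reference set with elevated lactate re-import
  bundle <- generate_recovery_bundle("A549", "kr_3", sigma = 0, seed = 11,
                                     params = truth, grid = fit_grid,
                                     drift_slope = 0)
  curve <- preprocess_plate(bundle$dataset)$control
  prob <- calibration_problem(list(list(curve = curve, dose = eca_dose())),
                              base = eca_preset("A549"), free = "kr_3",
                              multistart = 3L, seed = 21)
  res <- fit_calibration(prob)
  expect_equal(unname(res$theta["kr_3"]), bundle$truth$kr_3, tolerance = 0.01)
  expect_true(all(res$theta >= vapply(res$bounds, `[`, numeric(1), 1L)))
  expect_true(all(res$theta <= vapply(res$bounds, `[`, numeric(1), 2L)))
})

test_that("calibration is deterministic given the seed", {
  cfg <- generator_config(doses = list(control = eca_dose()), sigma = 0.01,
                          seed = 8, grid = fit_grid)
  curve <- preprocess_plate(generate_eca_dataset(cfg))$control
  mk <- function() {
    prob <- calibration_problem(list(list(curve = curve, dose = eca_dose())),
                                base = eca_preset("A549"), free = "Capacity_G",
                                multistart = 2L, seed = 31)
    fit_calibration(prob)
  }
  r1 <- mk(); r2 <- mk()
  expect_identical(r1$theta, r2$theta)
  expect_identical(r1$starts, r2$starts)
})

test_that("problem construction validates free names, bounds and seed", {
  curve <- eca_norm_curve(c(0, 1, 2), c(0, 1, 2))
  expect_error(calibration_problem(list(curve), eca_preset("A549"),
                                   free = "k_out", seed = 1), "k_out")
  expect_error(calibration_problem(list(curve), eca_preset("A549"),
                                   free = "kr_3",
                                   bounds = list(kr_3 = c(1, 0.1)), seed = 1),
               "bounds")
  expect_error(calibration_problem(list(curve), eca_preset("A549")),
               "seed")
})

test_that("calibration results serialize to JSON", {
  cfg <- generator_config(doses = list(control = eca_dose()), sigma = 0,
                          seed = 9, grid = fit_grid)
  curve <- preprocess_plate(generate_eca_dataset(cfg))$control
  prob <- calibration_problem(list(list(curve = curve, dose = eca_dose())),
                              base = eca_preset("A549"), free = character(0),
                              seed = 2)
  res <- fit_calibration(prob)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(res, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$fitted_parameters$k_in, 0.00012)
  expect_equal(back$seed, 2)
})
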