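test_that("landmarks of an analytic profile match the generator", {
  m <- potential_model(g_bulk = -4, g_surface_min = -10)
  p <- symmetrize(model_profile(m, bin_width = 0.005))
  lm <- extract_landmarks(p)
  expect_equal(lm$dg_gs, -10, tolerance = 1e-3)
  expect_equal(lm$dg_hydr, -4, tolerance = 1e-2)
  expect_equal(lm$dg_sl, 6, tolerance = 1.1e-2)
  expect_lt(abs(lm$z_min - m$z_interface), 0.35)
  # additive identity to machine precision
  expect_lt(abs(lm$dg_gs + lm$dg_sl - lm$dg_hydr), 1e-12)
})

test_that("landmarks demand a referenced profile and occupied regions", {
  z <- seq(-3.475, 3.475, by = 0.05)
  raw <- interfep:::new_fep_profile(z, z^2, temperature = 300)
  expect_error(extract_landmarks(raw), "referenced")
  p <- set_reference(raw, c(3.0, 3.5))
  g_hole <- p$g
  g_hole[abs(p$z) <= 0.7] <- NA
  p_hole <- interfep:::new_fep_profile(p$z, g_hole, temperature = 300,
                                       reference = "vacuum-plateau")
  expect_error(extract_landmarks(p_hole), "bulk")
})

test_that("minimum ties resolve to the smaller |z|", {
  z <- seq(-2.975, 2.975, by = 0.05)
  g <- rep(0, length(z))
  g[abs(z - 1.025) < 1e-9] <- -5
  g[abs(z - 2.025) < 1e-9] <- -5
  p <- interfep:::new_fep_profile(z, g, temperature = 300,
                                  reference = "vacuum-plateau")
  lm <- extract_landmarks(p, vacuum_region = c(2.5, 3),
                          interface_region = c(0.8, 2.6),
                          bulk_region = c(0, 0.7))
  expect_equal(lm$z_min, 1.025)
})

test_that("deeper wells and deeper bulk strictly increase the enhancements", {
  gs_levels <- c(-8, -10, -12)
  es <- vapply(gs_levels, function(gmin) {
    p <- symmetrize(model_profile(potential_model(-4, gmin)))
    summarize_species(p, "x")$enhancement_surface
  }, numeric(1))
  expect_true(all(diff(es) > 0))
  eb <- vapply(c(-2, -4, -6), function(gb) {
    p <- symmetrize(model_profile(potential_model(gb, -10)))
    summarize_species(p, "x")$enhancement_bulk
  }, numeric(1))
  expect_true(all(diff(eb) > 0))
})

test_that("species summary composes landmarks, enhancements, class and Henry", {
  m <- potential_model(g_bulk = 3.98, g_surface_min = -3.94)
  p <- symmetrize(model_profile(m))
  row <- summarize_species(p, "O3", henry = henry_constant(1e-4))
  expect_equal(row$hydro_class, "hydrophobic")
  expect_lt(row$enhancement_bulk, 1)
  expect_gt(row$enhancement_surface, 1)
  expect_equal(row$dg_hydr_expt, 3.46, tolerance = 0.005)
  # missing Henry constant leaves the experimental column absent, no error
  row2 <- summarize_species(p, "O3")
  expect_true(is.na(row2$dg_hydr_expt))
  # errors carry the species name
  bad <- interfep:::new_fep_profile(p$z, rep(NA_real_, nrow(p)),
                                    temperature = 300,
                                    reference = "vacuum-plateau")
  expect_error(summarize_species(bad, "O3"), "O3")
})
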