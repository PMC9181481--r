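test_that("sampling is reproducible given the seed", {
  m <- potential_model(-4, -10)
  cfg <- sampler_config(n_steps = 5000, stride = 5, seed = 3)
  s1 <- sample_window(m, 1.2, 2000, cfg)
  s2 <- sample_window(m, 1.2, 2000, cfg)
  expect_identical(s1, s2)
  s3 <- sample_window(m, 1.2, 2000, cfg, seed = 4)
  expect_false(identical(s1, s3))
  # per-window counter seeding is order independent
  ws <- window_scheme(3, 1, 2, -1.5, 1.5)
  w_all <- sample_windows(m, ws, 2000, cfg)
  expect_identical(w_all$samples[[4]],
                   sample_window(m, ws$center[4], 2000, cfg,
                                 seed = cfg$seed + 4))
})

test_that("zero steps yield empty samples and fail analysis", {
  m <- potential_model(-4, -10)
  cfg <- sampler_config(n_steps = 0, seed = 1)
  s <- sample_window(m, 0, 2000, cfg)
  expect_length(s, 0)
  w <- make_windows(list(s), centers = 0)
  expect_error(build_histograms(w), "no samples")
})

test_that("harmonic-bias sample variance matches RT/k on a flat surface", {
  mf <- potential_model(0, 0)
  cfg <- sampler_config(dt = 2.5e-5, n_steps = 400000, stride = 20, seed = 11)
  s <- sample_window(mf, 0, 2000, cfg)
  expect_equal(var(s), RT300 / 2000, tolerance = 0.05)
  expect_lt(abs(mean(s)), 3 * sqrt(RT300 / 2000 / length(s) * 10))
})

test_that("long chains sample the Boltzmann density of the biased surface", {
  # shallow surface, broad weak restraint, fast diffusion: one chain
  # relaxes thousands of times and visits the whole slab
  m <- potential_model(g_bulk = -1, g_surface_min = -2.5)
  k <- 5
  cfg <- sampler_config(dt = 2.5e-5, diffusion = 5, n_steps = 6e6,
                        stride = 100, seed = 5)
  s <- sample_window(m, 0, force_constant = k, cfg = cfg)
  edges <- seq(-3.5, 3.5, by = 0.25)
  cnt <- hist(s[abs(s) < 3.5], breaks = edges, plot = FALSE)$counts
  occupied <- cnt > 20 # rare tail bins carry no information either way
  g_emp <- -RT300 * log(cnt / sum(cnt))
  g_emp <- g_emp - mean(g_emp[occupied])
  mids <- edges[-1] - 0.125
  # bin-averaged Boltzmann weight of the biased potential on the grid
  g_true <- vapply(seq_along(mids), function(b) {
    zz <- seq(edges[b], edges[b + 1], length.out = 21)
    u <- pmf_value(m, zz) + 0.5 * k * zz^2
    -RT300 * log(mean(exp(-u / RT300)))
  }, numeric(1))
  g_true <- g_true - mean(g_true[occupied])
  se <- block_boot_g(s[abs(s) < 3.5], edges, n_blocks = 40, seed = 2)
  expect_true(all(abs(g_emp - g_true)[occupied] <= 3 * se[occupied] + 1e-9))
})

test_that("mirrored windows sample mirrored distributions", {
  m <- potential_model(-4, -10)
  cfg0 <- sampler_config(dt = 2.5e-5, n_steps = 400000, stride = 200)
  rejections <- 0L
  for (seed in 1:5) {
    sp <- sample_window(m, 1.6, 2000, cfg0, seed = seed)
    sm <- sample_window(m, -1.6, 2000, cfg0, seed = seed + 1000)
    p <- suppressWarnings(stats::ks.test(sp, -sm)$p.value)
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})

test_that("unstable settings are rejected and divergence is reported", {
  m <- potential_model(-4, -10)
  expect_error(sample_window(m, 0, 2000, sampler_config(dt = 0.01, seed = 1)),
               "unstable sampler settings")
  # passes the displacement guard but the harmonic update oscillates out
  m_wide <- potential_model(-4, -10, z_interface = 2, w_interface = 1,
                            w_switch = 0.2, z_max = 4)
  cfg <- sampler_config(dt = 0.6, diffusion = 0.01, n_steps = 10000,
                        stride = 10, seed = 1)
  expect_error(sample_window(m_wide, 0, 2000, cfg), "instability")
  ws <- window_scheme(2, 1, 1, -1, 1)
  expect_error(sample_windows(m_wide, ws, 2000, cfg), "z0")
})
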