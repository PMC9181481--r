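test_that("bootstrap rejects too few resamples", {
  w <- make_windows(list(rnorm(100)), centers = 0)
  expect_error(bootstrap_profile(w, n_boot = 5), "at least 20")
})

test_that("a single window gives degenerate resamples and zero se", {
  set.seed(31)
  w <- make_windows(list(rnorm(2000, 0, 0.2)), centers = 0,
                    force_constants = 1e-9)
  p <- bootstrap_profile(w, bin_width = 0.1, z_range = c(-1, 1),
                         n_boot = 20, seed = 1,
                         reference_region = c(0, 1))
  expect_true(all(p$se[is.finite(p$se)] < 1e-12))
})

test_that("bootstrap is reproducible and respects the seed", {
  set.seed(32)
  centers <- seq(-0.8, 0.8, by = 0.2)
  samples <- lapply(centers, function(c0) rnorm(800, c0, sqrt(RT300 / 100)))
  w <- make_windows(samples, centers = centers, force_constants = 100)
  p1 <- bootstrap_profile(w, 0.05, c(-1, 1), n_boot = 25, seed = 9,
                          reference_region = c(0.8, 1))
  p2 <- bootstrap_profile(w, 0.05, c(-1, 1), n_boot = 25, seed = 9,
                          reference_region = c(0.8, 1))
  expect_identical(p1$se, p2$se)
  p3 <- bootstrap_profile(w, 0.05, c(-1, 1), n_boot = 25, seed = 10,
                          reference_region = c(0.8, 1))
  expect_false(identical(p1$se, p3$se))
})

test_that("more data never inflates the average bootstrap error", {
  # stochastic monotonicity check over independent seeds
  centers <- seq(-0.8, 0.8, by = 0.2)
  wins <- 0L
  for (seed in 1:3) {
    set.seed(seed)
    small <- lapply(centers, function(c0)
      rnorm(300, c0, sqrt(RT300 / 100)))
    big <- lapply(seq_along(centers), function(i)
      c(small[[i]], rnorm(1200, centers[i], sqrt(RT300 / 100))))
    se_small <- bootstrap_profile(make_windows(small, centers, 100), 0.05,
                                  c(-1, 1), n_boot = 30, seed = 100,
                                  reference_region = c(0.8, 1))$se
    se_big <- bootstrap_profile(make_windows(big, centers, 100), 0.05,
                                c(-1, 1), n_boot = 30, seed = 100,
                                reference_region = c(0.8, 1))$se
    if (mean(se_big, na.rm = TRUE) <= mean(se_small, na.rm = TRUE)) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 2L)
})
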