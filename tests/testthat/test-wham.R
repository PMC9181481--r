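test_that("a single unbiased window collapses to -RT log(histogram)", {
  set.seed(21)
  s <- rnorm(5000, 0, 0.8)
  w <- make_windows(list(s), centers = 0, force_constants = 1e-12)
  h <- build_histograms(w, 0.2, c(-3, 3))
  p <- wham_solve(h, temperature = 300, tol = 1e-12)
  cnt <- as.vector(h$counts)
  expected <- -RT300 * log(cnt / sum(cnt))
  occ <- cnt > 0
  diff <- p$g[occ] - expected[occ]
  expect_lt(max(abs(diff - mean(diff))), 1e-10)
})

test_that("duplicated windows leave the estimate unchanged", {
  set.seed(22)
  s <- rnorm(2000, 0.5, 0.05)
  w1 <- make_windows(list(s), centers = 0.5)
  w2 <- make_windows(list(s, s), centers = c(0.5, 0.5))
  h1 <- build_histograms(w1, 0.02, c(0, 1))
  h2 <- build_histograms(w2, 0.02, c(0, 1))
  p1 <- wham_solve(h1, tol = 1e-10)
  p2 <- wham_solve(h2, tol = 1e-10)
  occ <- is.finite(p1$g)
  d <- p1$g[occ] - p2$g[occ]
  expect_lt(max(abs(d - mean(d))), 1e-8)
})

test_that("solver matches a naive double-loop fixed point on small instances", {
  set.seed(23)
  cases <- list(
    list(centers = 0.5, k = 800, n = 400),
    list(centers = c(0.3, 0.7), k = c(250, 250), n = c(300, 300)),
    list(centers = c(0.25, 0.5, 0.75), k = c(350, 250, 350),
         n = c(250, 250, 250))
  )
  for (cs in cases) {
    samples <- lapply(seq_along(cs$centers), function(i) {
      rnorm(cs$n[i], cs$centers[i], sqrt(RT300 / cs$k[i]))
    })
    w <- make_windows(samples, centers = cs$centers,
                      force_constants = cs$k)
    h <- build_histograms(w, 0.05, c(0, 1))
    p <- wham_solve(h, tol = 1e-13)
    g_oracle <- naive_wham(h$counts, h$mids, cs$centers,
                           rep(cs$k, length.out = length(cs$centers)),
                           tol = 1e-13)
    occ <- is.finite(p$g)
    d <- p$g[occ] - g_oracle[occ]
    expect_lt(max(abs(d - mean(d))), 1e-8)
  }
})

test_that("the implied probability is normalized over occupied bins", {
  set.seed(24)
  samples <- lapply(seq(-1, 1, by = 0.25), function(c0) {
    rnorm(1000, c0, sqrt(RT300 / 100))
  })
  w <- make_windows(samples, centers = seq(-1, 1, by = 0.25),
                    force_constants = 100)
  h <- build_histograms(w, 0.05, c(-1.5, 1.5))
  p <- wham_solve(h)
  occ <- is.finite(p$g)
  expect_lt(abs(sum(exp(-p$g[occ] / RT300)) - 1), 1e-10)
})

test_that("non-convergence and disconnected windows raise errors", {
  set.seed(25)
  samples <- list(rnorm(500, -1, 0.04), rnorm(500, 1, 0.04))
  w <- make_windows(samples, centers = c(-1, 1))
  h <- build_histograms(w, 0.05, c(-1.5, 1.5))
  expect_error(suppressWarnings(wham_solve(h)), "disconnected")
  samples2 <- list(rnorm(500, -0.05, 0.05), rnorm(500, 0.05, 0.05))
  w2 <- make_windows(samples2, centers = c(-0.05, 0.05))
  h2 <- build_histograms(w2, 0.05, c(-0.5, 0.5))
  expect_error(wham_solve(h2, max_iter = 1), "did not converge")
})
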