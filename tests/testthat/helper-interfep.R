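# Shared fixtures and independent oracles for the test suite.

RT300 <- 8.314462618e-3 * 300

# A fast, deliberately naive WHAM fixed-point iteration written as plain
# double loops -- the independent oracle for wham_solve().  No matrix
# algebra, no shared code with the implementation.
naive_wham <- function(counts, mids, centers, force_constants,
                       temperature = 300, tol = 1e-12, max_iter = 2e5) {
  rt <- 8.314462618e-3 * temperature
  n_bins <- nrow(counts)
  n_win <- ncol(counts)
  h <- rowSums(counts)
  n_i <- colSums(counts)
  f <- numeric(n_win)
  for (iter in seq_len(max_iter)) {
    p <- numeric(n_bins)
    for (b in seq_len(n_bins)) {
      denom <- 0
      for (i in seq_len(n_win)) {
        u <- 0.5 * force_constants[i] * (mids[b] - centers[i])^2
        denom <- denom + n_i[i] * exp((f[i] - u) / rt)
      }
      p[b] <- if (denom > 0) h[b] / denom else 0
    }
    f_new <- numeric(n_win)
    for (i in seq_len(n_win)) {
      z <- 0
      for (b in seq_len(n_bins)) {
        u <- 0.5 * force_constants[i] * (mids[b] - centers[i])^2
        z <- z + p[b] * exp(-u / rt)
      }
      f_new[i] <- -rt * log(z)
    }
    f_new <- f_new - f_new[1]
    if (max(abs(f_new - f)) < tol) {
      f <- f_new
      break
    }
    f <- f_new
  }
  p <- p / sum(p)
  ifelse(h > 0, -rt * log(p), NA_real_)
}

# Build a window tibble directly from sample vectors (no sampler).
make_windows <- function(samples, centers, force_constants = 2000) {
  tibble::tibble(window = seq_along(samples), center = centers,
                 force_constant = rep(force_constants,
                                      length.out = length(samples)),
                 seed = NA_integer_, samples = samples,
                 n_equilibration = 0L)
}

# Block-bootstrap standard error of -RT log(density) per histogram bin,
# for a single correlated trajectory.
block_boot_g <- function(samples, edges, n_blocks = 40, n_boot = 200,
                         temperature = 300, seed = 1) {
  rt <- 8.314462618e-3 * temperature
  blocks <- split(samples, cut(seq_along(samples), n_blocks, labels = FALSE))
  set.seed(seed)
  nb <- length(edges) - 1L
  g <- matrix(NA_real_, nb, n_boot)
  for (b in seq_len(n_boot)) {
    s <- unlist(blocks[sample.int(n_blocks, n_blocks, replace = TRUE)],
                use.names = FALSE)
    cnt <- hist(s, breaks = edges, plot = FALSE)$counts
    gb <- -rt * log(cnt / sum(cnt))
    gb[!is.finite(gb)] <- NA
    g[, b] <- gb - mean(gb, na.rm = TRUE)
  }
  apply(g, 1, stats::sd, na.rm = TRUE)
}

# Analytic profile tibble sampled from a potential_model on a symmetric
# grid, referenced to the vacuum plateau.
model_profile <- function(model, bin_width = 0.05, z_half = 3.5,
                          temperature = 300) {
  z <- seq(-z_half + bin_width / 2, z_half - bin_width / 2, by = bin_width)
  p <- interfep:::new_fep_profile(z, pmf_value(model, z),
                                  temperature = temperature,
                                  bin_width = bin_width)
  set_reference(p, c(3.0, z_half))
}
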