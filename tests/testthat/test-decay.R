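# TCSPC generator and Poisson maximum-likelihood decay fitting.

test_that("decay histogram constructor enforces its invariants", {
  h <- decay_histogram(c(5L, 3L, 1L), bin_width_ns = 0.5)
  expect_equal(length(h$bin_edges_ns), 4L)
  expect_error(decay_histogram(c(-1, 2), bin_width_ns = 0.5))
  expect_error(decay_histogram(c(1, 2), bin_edges_ns = c(0, 1, 1.5)),
               "constant")
  expect_error(decay_histogram(c(1.5, 2), bin_width_ns = 1), "integers")
})

test_that("simulated arrival times have the closed-form mixture mean", {
  # window 50 ns keeps truncation bias of a 3 ns decay below 2e-7 ns
  h <- simulate_decay_histogram(data.frame(tau_ns = 3, amplitude = 1), 1e6,
                                bin_width_ns = 50 / 4096, seed = 7)
  mids <- (h$bin_edges_ns[-1] + h$bin_edges_ns[-4097]) / 2
  expect_equal(sum(mids * h$counts) / sum(h$counts), 3.0, tolerance = 0.01 / 3)

  # mixture mean = sum(a tau^2) / sum(a tau)
  h2 <- simulate_decay_histogram(data.frame(tau_ns = c(1, 3),
                                            amplitude = c(0.5, 0.5)), 1e6,
                                 bin_width_ns = 50 / 4096, seed = 8)
  mean2 <- sum(mids * h2$counts) / sum(h2$counts)
  expect_equal(mean2, 2.5, tolerance = 0.01 / 2.5)

  # identical seed, identical counts; different seed differs
  h3 <- simulate_decay_histogram(data.frame(tau_ns = c(1, 3),
                                            amplitude = c(0.5, 0.5)), 1e6,
                                 bin_width_ns = 50 / 4096, seed = 8)
  expect_identical(h2$counts, h3$counts)
  h4 <- simulate_decay_histogram(data.frame(tau_ns = c(1, 3),
                                            amplitude = c(0.5, 0.5)), 1e6,
                                 bin_width_ns = 50 / 4096, seed = 9)
  expect_false(identical(h2$counts, h4$counts))

  # photons beyond the window are dropped and reported
  h5 <- simulate_decay_histogram(data.frame(tau_ns = 6.8, amplitude = 1), 1e5,
                                 bin_width_ns = 25 / 4096, seed = 10)
  expect_equal(sum(h5$counts) + attr(h5, "n_truncated"), 1e5)
  expect_gt(attr(h5, "n_truncated"), 0)
})

test_that("free fit recovers a single exponential", {
  h <- simulate_decay_histogram(data.frame(tau_ns = 1.8, amplitude = 1), 1e6,
                                seed = 3)
  fit <- fit_decay_free(h, n_components = 1)
  expect_equal(fit$components$tau_ns, 1.8, tolerance = 0.02 / 1.8)
  expect_gt(fit$chi2_reduced, 0.8)
  expect_lt(fit$chi2_reduced, 1.2)
  expect_equal(unname(sum(fit$fractions_pct)), 100, tolerance = 1e-6)
})

test_that("free fit recovers a two-exponential mixture", {
  h <- simulate_decay_histogram(data.frame(tau_ns = c(1.8, 6.8),
                                           amplitude = c(0.5, 0.5)), 1e6,
                                seed = 4)
  fit <- fit_decay_free(h, n_components = 2)
  expect_equal(fit$components$tau_ns, c(1.8, 6.8), tolerance = 0.05)
  expect_equal(unname(fit$fractions_pct), c(50, 50), tolerance = 2 / 50)
  matched <- match_components_to_library(fit)
  expect_equal(matched$components$name,
               c("parallel_dimer", "antiparallel_dimer"))
})

test_that("free fit rejects degenerate inputs", {
  empty <- decay_histogram(rep(0L, 256), bin_width_ns = 0.1)
  expect_error(fit_decay_free(empty, 1), "empty")
  sparse <- decay_histogram(c(1L, rep(0L, 255)), bin_width_ns = 0.1)
  expect_error(fit_decay_free(sparse, 2), "fewer photons")
})

test_that("free-fit bias shrinks with the photon budget", {
  tau_at <- function(n, seed) {
    h <- simulate_decay_histogram(data.frame(tau_ns = 3, amplitude = 1), n,
                                  seed = seed)
    fit_decay_free(h, 1)$components$tau_ns
  }
  err_lo <- abs(mean(vapply(1:5, function(s) tau_at(1e4, s), numeric(1))) - 3)
  err_hi <- abs(mean(vapply(1:5, function(s) tau_at(1e6, s), numeric(1))) - 3)
  expect_lt(err_hi, err_lo)
  expect_lt(err_hi, 0.01)
})

test_that("library-constrained fit separates the organization forms", {
  # pure antiparallel dimer: its fraction pegs at ~100
  h <- simulate_decay_histogram(data.frame(tau_ns = 6.8, amplitude = 1), 1e6,
                                seed = 5)
  fit <- fit_decay_fixed(h)
  expect_equal(unname(fit$fractions_pct["antiparallel_dimer"]), 100,
               tolerance = 1 / 100)
  expect_lt(max(fit$fractions_pct[c("tetramer", "parallel_dimer")]), 1)
  expect_equal(unname(sum(fit$fractions_pct)), 100, tolerance = 1e-6)

  # sterol-type three-component mixture at a fixed seed
  fr <- c(39.6, 27.3, 33.1)
  h2 <- simulate_decay_histogram(data.frame(tau_ns = c(0.35, 1.8, 6.8),
                                            amplitude = fr), 1e6, seed = 6)
  fit2 <- fit_decay_fixed(h2)
  expect_equal(unname(fit2$fractions_pct), fr, tolerance = 1.5 / 30)
  expect_gt(fit2$chi2_reduced, 0.8)
  expect_lt(fit2$chi2_reduced, 1.2)
  expect_true(all(fit2$fractions_se_pct > 0))

  expect_error(fit_decay_fixed(h2, subset = "hexamer"), "unknown")
  tiny <- decay_histogram(c(2L, 1L, 0L, 0L), bin_width_ns = 0.1)
  expect_error(fit_decay_fixed(tiny), "fewer photons")
})

test_that("amplitude-averaged lifetime is the amplitude-weighted mean", {
  expect_equal(amplitude_averaged_lifetime(
    data.frame(tau_ns = 3, amplitude = 1)), 3)
  expect_equal(amplitude_averaged_lifetime(
    data.frame(tau_ns = c(1, 3), amplitude = c(0.5, 0.5))), 2)
  # sterol-column fractions over the library lifetimes
  expect_equal(amplitude_averaged_lifetime(
    data.frame(tau_ns = c(0.35, 1.8, 6.8),
               amplitude = c(39.6, 27.3, 33.1))), 2.881, tolerance = 1e-3)
  expect_error(amplitude_averaged_lifetime(
    data.frame(tau_ns = c(1, 3), amplitude = c(0, 0))), "zero")
})
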