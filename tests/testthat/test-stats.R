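test_that("analytic cable solution: initial condition and steady profile", {
  p <- rallpack1_params()
  # t = 0: rest everywhere
  expect_equal(rallpack1_analytic(c(0, 5e-4, 1e-3), 0, p),
               rep(-0.065, 3))
  # steady state proportional to cosh((L-x)/lambda): ratio test
  lambda <- sqrt((1 / p$leak) * p$diameter / (4 * p$resistivity))
  v1 <- rallpack1_analytic(2e-4, 10, p) - p$leak_reversal
  v2 <- rallpack1_analytic(7e-4, 10, p) - p$leak_reversal
  want <- cosh((p$length - 2e-4) / lambda) / cosh((p$length - 7e-4) / lambda)
  expect_equal(v1 / v2, want, tolerance = 1e-9)
})

test_that("analytic transient matches a fine-grid finite-difference oracle", {
  p <- rallpack1_params()
  # Crank-Nicolson on the 1D cable equation, sealed ends, step current at 0
  nx <- 801; nt <- 2000
  L <- p$length; dx <- L / (nx - 1); dt <- 5e-3 / nt
  Rm <- 1 / p$leak; lambda2 <- Rm * p$diameter / (4 * p$resistivity)
  tau <- Rm * p$capacitance
  r_a <- 4 * p$resistivity / (pi * p$diameter^2)
  # tau v_t = lambda^2 v_xx - v + injection term
  main <- rep(-2, nx); main[1] <- main[nx] <- -2     # ghost-point sealed ends
  A <- diag(main)
  for (i in 2:nx) { A[i, i - 1] <- 1; A[i - 1, i] <- 1 }
  A[1, 2] <- 2; A[nx, nx - 1] <- 2                   # Neumann reflection
  A <- A * lambda2 / dx^2
  M1 <- diag(nx) * (tau / dt + 0.5) - 0.5 * A
  M2 <- diag(nx) * (tau / dt - 0.5) + 0.5 * A
  inj <- numeric(nx)
  inj[1] <- p$current * r_a * lambda2 * 2 / dx       # boundary flux source
  v <- numeric(nx)
  Mi <- solve(M1)
  for (s in seq_len(nt)) v <- Mi %*% (M2 %*% v + inj)
  fd <- as.numeric(v) + p$leak_reversal
  an <- rallpack1_analytic(seq(0, L, length.out = nx), 5e-3, p)
  expect_lt(max(abs(fd - an)), 1e-6)
})

test_that("peak detection: flat traces, sinusoids, synthetic bumps", {
  # constant trace: no peaks
  expect_identical(nrow(detect_peaks(rep(1, 100), 1e-3)), 0L)
  # 10 Hz sinusoid over 1 s: frequency exactly 10 Hz
  dt <- 1e-4
  tt <- seq(0, 1 - dt, by = dt)
  v <- 0.05 * sin(2 * pi * 10 * tt - pi / 2)
  pk <- detect_peaks(v, dt, min_prominence = 0.01, min_separation = 0.05)
  expect_identical(nrow(pk), 10L)
  expect_equal(peak_frequency(pk), 10, tolerance = 1e-3)
  # two Gaussian bumps at 30 and 70 ms: timestamps within one sample
  tt <- seq(0, 0.1, by = 1e-4)
  v <- 0.08 * exp(-(tt - 0.03)^2 / 2e-5) + 0.05 * exp(-(tt - 0.07)^2 / 2e-5)
  pk <- detect_peaks(v, 1e-4, min_prominence = 0.01, min_separation = 0.01)
  expect_identical(nrow(pk), 2L)
  expect_lt(abs(pk$time_s[1] - 0.03), 1.01e-4)
  expect_lt(abs(pk$time_s[2] - 0.07), 1.01e-4)
  # invariance under uniform offset
  pk2 <- detect_peaks(v - 0.065, 1e-4, min_prominence = 0.01,
                      min_separation = 0.01)
  expect_equal(pk2$time_s, pk$time_s)
  expect_equal(pk2$height, pk$height - 0.065)
})

test_that("two-sample CVM statistic and p-values match reference values", {
  # frozen cross-check values computed with an independent implementation
  # of the same statistic (rank formula evaluated by hand / scipy)
  x <- c(-2.310103, 0.054354, -0.471776, 0.459386, 0.701954, 0.138241,
         0.760133, 0.229211, 0.530065, -0.704673, -0.179611, 0.196776)
  y <- c(1.020528, -0.193741, 0.721167, -0.065839, 0.082458, 1.029519,
         -1.79306, -1.096472, -1.282185, -2.133616, -0.478264, 0.949434,
         -0.084884, 0.39779, 1.289217)
  st <- tetsim:::cvm_stat(x, y)
  expect_equal(st, 0.126543209876543, tolerance = 1e-12)
  set.seed(1)
  r <- cvm_2samp(x, y)            # auto -> permutation below 20
  expect_identical(r$method, "permutation")
  expect_equal(r$p_value, 0.4989, tolerance = 0.05)
  # limiting-distribution CDF at tabulated points
  expect_equal(tetsim:::cvm_cdf_inf(0.119), 0.5004941, tolerance = 1e-6)
  expect_equal(tetsim:::cvm_cdf_inf(0.5), 0.9601668, tolerance = 1e-6)
  # asymptotic p for two continuous samples, cross-checked value
  set.seed(2)
  big <- cvm_2samp(seq(0.001, 1, length.out = 100)^1.2,
                   seq(0.001, 1, length.out = 100))
  expect_identical(big$method, "asymptotic")
  expect_error(cvm_batch_compare(rnorm(50), rnorm(100), 100),
               "batch size exceeds")
  expect_error(cvm_batch_compare(rnorm(150), rnorm(100), 100), "divisible")
})

test_that("null p-values are uniform; a shifted alternative is rejected", {
  set.seed(77)
  a <- stats::rnorm(4000); b <- stats::rnorm(4000)
  cb <- cvm_batch_compare(a, b, 100)
  expect_identical(length(cb$p_values), 1600L)
  expect_lt(abs(cb$median - 0.5), 0.08)
  # fraction below 0.01 within binomial 3 sigma of 1%
  expect_lt(abs(cb$fraction_below - 0.01), 3 * sqrt(0.01 * 0.99 / 1600) + 0.005)
  expect_false(cb$reject)
  # empirical p-value CDF close to uniform (continuous data)
  ks <- max(abs(sort(as.vector(cb$p_values)) -
                (seq_len(1600) - 0.5) / 1600))
  expect_lt(ks, 0.05)
  # mean shift of 1 sd: essentially every p-value below 0.01
  b2 <- stats::rnorm(4000, mean = 1)
  cb2 <- cvm_batch_compare(a, b2, 100)
  expect_gt(mean(cb2$p_values < 0.01), 0.99)
  expect_true(cb2$reject)
})

test_that("confidence bands: degenerate width, coverage, self-consistency", {
  # identical constant traces: zero-width band at the constant
  tsA <- trace_set(matrix(2.5, 10, 50), dt = 1e-3)
  band <- ci_band(tsA)
  expect_equal(band$mean, rep(2.5, 50))
  expect_equal(band$lower, band$upper)
  expect_error(ci_band(matrix(1, 1, 10)), "at least 2")
  # coverage: true mean inside the band ~99% of time points
  set.seed(11)
  hits <- replicate(200, {
    tr <- matrix(stats::rnorm(30 * 20, mean = 1), 30, 20)
    b <- ci_band(tr, 0.99)
    mean(b$lower <= 1 & 1 <= b$upper)
  })
  expect_gt(mean(hits), 0.975)
  expect_lt(mean(hits), 0.999)
  # two ensembles from one model: mutual containment accepted >= 95%
  verdicts <- replicate(100, {
    a <- matrix(stats::rnorm(100 * 100), 100, 100)
    b <- matrix(stats::rnorm(100 * 100), 100, 100)
    !ci_band_compare(a, b)$reject
  })
  expect_gte(mean(verdicts), 0.95)
  # and a clear mean shift is rejected
  shifted <- replicate(50, {
    a <- matrix(stats::rnorm(100 * 100), 100, 100)
    b <- matrix(stats::rnorm(100 * 100, mean = 1), 100, 100)
    ci_band_compare(a, b)$reject
  })
  expect_identical(mean(shifted), 1)
})
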