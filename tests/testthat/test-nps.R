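# Helper: power_map built directly from a value matrix (for geometry tests).
fake_power_map <- function(values, pixel_size = 0.429) {
  n <- nrow(values)
  structure(list(values = values,
                 fx = (seq_len(n) - 1 - floor(n / 2)) / (n * pixel_size),
                 fy = (seq_len(n) - 1 - floor(n / 2)) / (n * pixel_size),
                 pixel_size = pixel_size, n_rep_used = 5),
            class = "power_map")
}

test_that("identical repetitions give an all-zero power map", {
  img <- matrix(rnorm(32 * 32), 32, 32)
  arr <- array(rep(img, 3), dim = c(32, 32, 1, 3))
  ens <- noise_ensemble(arr, 0.5)
  m <- ensemble_power_map(ens, 1)
  expect_equal(max(abs(m$values)), 0)
})

test_that("white-noise power maps match the flat closed form", {
  sigma <- 10
  delta <- 0.429
  ens <- make_white_ensemble(n = 64, n_slice = 40, n_rep = 5, sigma = sigma,
                             pixel_size = delta, base = 30, seed = 8)
  m <- mean_power_map(ens)
  target <- white_nps_oracle(sigma, delta)
  expect_lt(abs(mean(m$values) / target - 1), 0.02)
  # flat across the plane: quadrant means agree within 5%
  q <- c(mean(m$values[1:32, 1:32]), mean(m$values[33:64, 1:32]),
         mean(m$values[1:32, 33:64]), mean(m$values[33:64, 33:64]))
  expect_true(all(abs(q / target - 1) < 0.05))
})

test_that("kernel-filtered noise recovers the transfer-function spectrum", {
  # circular convolution with a separable 3-tap kernel via FFT
  n <- 64
  delta <- 0.429
  sigma <- 8
  h <- c(0.5, 0.25, rep(0, n - 3), 0.25)
  H <- Re(fft(h))                       # real symmetric kernel
  n_slice <- 60
  n_rep <- 4
  withr::with_seed(21, {
    arr <- array(0, dim = c(n, n, n_slice, n_rep))
    for (s in seq_len(n_slice)) for (r in seq_len(n_rep)) {
      w <- matrix(rnorm(n * n, sd = sigma), n, n)
      # circular convolution with the separable kernel h (x) h
      arr[, , s, r] <- Re(fft(fft(w) * outer(H, H), inverse = TRUE)) / n^2
    }
  })
  ens <- noise_ensemble(arr, delta)
  m <- mean_power_map(ens)
  Hs <- H[c(seq(n / 2 + 1, n), seq_len(n / 2))]   # shifted to DC-centre
  expected <- sigma^2 * delta^2 * outer(Hs^2, Hs^2)
  keep <- expected > 0.05 * max(expected)          # avoid near-zero bins
  rel <- m$values[keep] / expected[keep] - 1
  expect_lt(abs(mean(rel)), 0.05)
})

test_that("directional sampling respects rotational symmetry on isotropic maps", {
  m <- fake_power_map(matrix(3.3, 64, 64))
  c10 <- directional_spectrum(m, 10)
  c90 <- directional_spectrum(m, 90)
  shared <- seq_len(min(nrow(c10), nrow(c90)))
  expect_lt(max(abs(c10$power[shared] / c90$power[shared] - 1)), 0.01)
})

test_that("an off-axis peak appears only in its own direction", {
  n <- 128
  delta <- 0.429
  vals <- matrix(0, n, n)
  df <- 1 / (n * delta)
  ctr <- floor(n / 2) + 1
  r_bin <- round(0.6 / df)
  i <- ctr + round(r_bin * cos(30 * pi / 180))
  j <- ctr + round(r_bin * sin(30 * pi / 180))
  vals[i, j] <- 100
  m <- fake_power_map(vals, delta)
  c30 <- directional_spectrum(m, 30)
  c120 <- directional_spectrum(m, 120)
  expect_gt(max(c30$power), 1)                    # peak present
  expect_lt(max(c120$power), 0.01 * max(c30$power))
})

test_that("diagonal directions reach beyond the axis Nyquist frequency", {
  m <- fake_power_map(matrix(1, 512, 512), 0.429)
  c45 <- directional_spectrum(m, 45)
  c90 <- directional_spectrum(m, 90)
  expect_gt(max(c45$power), 0)
  expect_gt(max(c45$frequency), 1.3084)           # diagonal exceeds upper band edge
  expect_lt(max(c90$frequency), 1 / (2 * 0.429) + 1e-9)
  expect_lt(max(c45$frequency), sqrt(2) / (2 * 0.429) + 1e-9)
  expect_error(directional_spectrum(m, 0), "angle")
  expect_error(directional_spectrum(m, 181), "angle")
})

test_that("angular averaging is idempotent and tracks line-length support", {
  m <- fake_power_map(matrix(2, 64, 64))
  curves <- directional_spectra(m)
  avg <- angular_average(curves)
  nyq <- 1 / (2 * 0.429)
  s_low <- avg$support_count[which.min(abs(avg$frequency - 0.5 * nyq))]
  s_high <- avg$support_count[which.min(abs(avg$frequency - 1.2 * nyq))]
  expect_identical(s_low, 18L)
  expect_lt(s_high, 18L)
  # 18 copies of one curve average to that curve
  one <- curves[[9]]
  same <- angular_average(rep(list(one), 18))
  expect_equal(same$power, one$power)
  expect_error(angular_average(list()), "no curves")
})

test_that("white-noise angular mean is flat below the axis Nyquist", {
  ens <- make_white_ensemble(n = 64, n_slice = 100, n_rep = 5, sigma = 10,
                             pixel_size = 0.429, seed = 31)
  cv <- ensemble_nps(ens)
  nyq <- 1 / (2 * 0.429)
  band <- cv$frequency > 0.1 & cv$frequency < nyq * (62 / 64)
  expect_lt(max(abs(cv$power[band] / white_nps_oracle(10, 0.429) - 1)), 0.03)
})

test_that("cohort averaging is an unweighted mean over slices", {
  a <- nps_curve(c(0, 0.1, 0.2), c(1, 1, 1), kind = "angular_mean")
  b <- nps_curve(c(0, 0.1, 0.2), c(3, 3, 3), kind = "angular_mean")
  expect_equal(cohort_nps(list(a))$power, a$power)
  expect_equal(cohort_nps(list(a, a, a))$power, a$power)
  expect_equal(cohort_nps(list(a, b))$power, rep(2, 3))
  bad <- nps_curve(c(0, 0.15, 0.3), c(1, 1, 1), kind = "angular_mean")
  expect_error(cohort_nps(list(a, bad)), "grid")
})

test_that("NPS estimates scale quadratically with noise magnitude", {
  ph <- make_head_phantom(phantom_spec(matrix_size = 64, n_slice = 4))
  pr <- default_method_profiles()$FBP
  ens <- synthesize_ensemble(ph, pr, n_rep = 5, seed = 17)
  scaled <- ens
  base <- array(ph, dim = dim(ens$images))
  scaled$images <- base + 3 * (ens$images - base)
  m1 <- ensemble_power_map(ens, 2)
  m3 <- ensemble_power_map(scaled, 2)
  expect_equal(m3$values, 9 * m1$values, tolerance = 1e-10)
})

test_that("the n/(n-1) factor removes the repetition-count bias", {
  t5 <- make_white_ensemble(n = 64, n_slice = 30, n_rep = 5, sigma = 10, seed = 3)
  t50 <- make_white_ensemble(n = 64, n_slice = 3, n_rep = 50, sigma = 10, seed = 4)
  m5 <- mean(mean_power_map(t5)$values)
  m50 <- mean(mean_power_map(t50)$values)
  expect_lt(abs(m5 / m50 - 1), 0.05)    # no systematic n_rep dependence
})

test_that("degenerate ensembles are rejected", {
  expect_error(noise_ensemble(array(0, dim = c(8, 8, 1, 1)), 0.4), "n_rep")
  ens <- make_white_ensemble(n = 16, n_slice = 2, n_rep = 2, seed = 1)
  expect_error(ensemble_power_map(ens, 5), "slice_index")
})
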