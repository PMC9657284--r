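# a windows table covering [0, n*T) in strides of T, all complete
plain_windows <- function(T0, n) {
  tibble::tibble(stride_index = seq_len(n), start_s = (seq_len(n) - 1) * T0,
                 end_s = seq_len(n) * T0, complete = TRUE)
}

test_that("double integration recovers a closed-form sinusoid", {
  A <- 40; f <- 2.5; om <- 2 * pi * f; fs <- 200; T0 <- 1 / f
  tt <- seq(0, 4 * T0 + 2 / fs, by = 1 / fs)
  accel <- tibble::tibble(time_s = tt, head_mps2 = -A * om^2 * sin(om * tt) / 1000)
  win <- plain_windows(T0, 4)
  disp <- integrate_displacement(accel, win)
  idx <- which(tt >= win$start_s[2] & tt < win$end_s[2])
  truth <- A * sin(om * tt[idx])
  expect_lt(sqrt(mean((disp$head_mm[idx] - (truth - mean(truth)))^2)), 0.01 * 2 * A)
  expect_equal(max(disp$head_mm[idx]) - min(disp$head_mm[idx]), 2 * A, tolerance = 0.01)
})

test_that("zero acceleration integrates to zero displacement", {
  fs <- 200
  tt <- seq(0, 2, by = 1 / fs)
  accel <- tibble::tibble(time_s = tt, head_mps2 = rep(0, length(tt)))
  disp <- integrate_displacement(accel, plain_windows(1, 2))
  expect_equal(max(abs(disp$head_mm), na.rm = TRUE), 0, tolerance = 1e-9)
})

test_that("trapezoidal+anchored integration matches a spectral oracle", {
  # band-limited random acceleration, periodic over the window
  fs <- 200; T0 <- 1; n <- round(T0 * fs)
  tt <- seq(0, 2 * T0 + 2 / fs, by = 1 / fs)
  withr::with_seed(11, {
    z_true <- numeric(length(tt))
    acc <- numeric(length(tt))
    for (k in 1:4) {
      amp <- rnorm(1, 0, 10 / k); ph <- runif(1, 0, 2 * pi); om <- 2 * pi * k / T0
      z_true <- z_true + amp * cos(om * tt + ph)
      acc <- acc - amp * om^2 * cos(om * tt + ph)
    }
  })
  accel <- tibble::tibble(time_s = tt, head_mps2 = acc / 1000)
  disp <- integrate_displacement(accel, plain_windows(T0, 2))
  idx <- which(tt >= T0 & tt < 2 * T0)
  # independent spectral double integration: divide FFT by (i*omega)^2
  aw <- acc[idx]
  N <- length(aw)
  om_k <- 2 * pi * ifelse(seq_len(N) - 1 <= N / 2, seq_len(N) - 1, seq_len(N) - 1 - N) * fs / N
  Z <- fft(aw)
  Z[om_k != 0] <- Z[om_k != 0] / (1i * om_k[om_k != 0])^2
  Z[om_k == 0] <- 0
  z_spec <- Re(fft(Z, inverse = TRUE)) / N
  z_spec <- z_spec - mean(z_spec)
  rms_sig <- sqrt(mean(z_spec^2))
  expect_lt(sqrt(mean((disp$head_mm[idx] - z_spec)^2)), 0.01 * rms_sig)
})

test_that("normalization yields fixed-length strides regardless of duration", {
  tpl <- make_template("trot", "warmblood", list(n_strides = 3))
  tr <- simulate_trial(tpl)
  win <- pair_strides(tr$events)
  # 0.78 s at 200 Hz = 156 raw samples -> 101 normalized points
  norm <- segment_and_normalize(tr$truth_disp, win, tr$events)
  lens <- dplyr::count(norm, stride_index, segment)
  expect_true(all(lens$n == 101))
  # different stride durations, same vector length
  win2 <- tibble::tibble(stride_index = 1:2, start_s = c(0, 0.78),
                         end_s = c(0.78, 2.34), complete = TRUE)
  norm2 <- segment_and_normalize(tr$truth_disp, win2, n_points = 101)
  expect_true(all(dplyr::count(norm2, stride_index, segment)$n == 101))
  # per-stride zero mean
  mu <- dplyr::summarise(dplyr::group_by(norm, stride_index, segment),
                         m = mean(disp_mm), .groups = "drop")
  expect_true(all(abs(mu$m) < 1e-9))
  # stance metadata carried in normalized units
  st <- attr(norm, "stance_pct")
  expect_true(all(c("limb", "on_pct", "off_pct") %in% names(st)))
})

test_that("normalization is exact on linear ramps", {
  tt <- seq(0, 2.02, by = 0.005)
  disp <- tibble::tibble(time_s = tt, head_mm = 3 + 2 * tt)
  win <- tibble::tibble(stride_index = 1L, start_s = 0.5, end_s = 1.5, complete = TRUE)
  norm <- segment_and_normalize(disp, win)
  grid <- seq(0, 100, length.out = 101)
  expected <- (3 + 2 * (0.5 + grid / 100))
  expect_equal(norm$disp_mm, expected - mean(expected), tolerance = 1e-9)
})

test_that("normalization preserves extremum timing within half a percent", {
  tpl <- make_template("trot", "warmblood", list(n_strides = 3))
  tr <- simulate_trial(tpl)
  win <- pair_strides(tr$events)
  norm <- segment_and_normalize(tr$truth_disp, win)
  for (seg in c("head", "pelvis")) {
    wp <- hoofbeat:::segment_waveform(tpl, seg)
    s2 <- norm[norm$stride_index == 2 & norm$segment == seg, ]
    got <- s2$phase_pct[which.min(s2$disp_mm)]
    # the two minima sit 50 % apart and are equally deep; compare modulo 50
    expect_lt(abs(wrap_signed(got - 100 * wp$m, 50)), 0.5 + 1e-9)
  }
})

test_that("windows past the end of the trace are dropped with a message", {
  tt <- seq(0, 1, by = 0.005)
  accel <- tibble::tibble(time_s = tt, head_mps2 = sin(4 * pi * tt))
  win <- tibble::tibble(stride_index = 1:2, start_s = c(0, 0.5),
                        end_s = c(0.5, 1.6), complete = TRUE)
  expect_message(disp <- integrate_displacement(accel, win), "past the end")
  expect_true(all(is.na(disp$head_mm[tt > 0.55])))
  expect_false(anyNA(disp$head_mm[tt > 0.05 & tt < 0.45]))
})
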