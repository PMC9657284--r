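test_that("footfalls realize the template dissociations exactly", {
  tpl <- make_template("walk", "warmblood", list(n_strides = 3))
  tr <- simulate_trial(tpl)
  ev <- tr$events
  T0 <- tpl$stride_duration_s
  on_of <- function(l) ev$on_s[ev$limb == l & ev$on_s >= 0]
  # lateral-sequence walk at quarter-stride spacing
  expect_equal(on_of("LF")[1], 0.25 * T0, tolerance = 1e-9)
  expect_equal(on_of("RH")[1], 0.50 * T0, tolerance = 1e-9)
  expect_equal(on_of("RF")[1], 0.75 * T0, tolerance = 1e-9)

  # trot: LF placed by the lateral, RF by the diagonal dissociation
  tpt <- make_template("trot", "warmblood", list(n_strides = 3))
  evt <- simulate_trial(tpt)$events
  lf <- evt$on_s[evt$limb == "LF" & evt$on_s >= 0][1]
  rf <- evt$on_s[evt$limb == "RF"]
  expect_equal(lf / 0.78 * 100, 47, tolerance = 1e-9)
  expect_equal(min(abs(rf - 0)) / 0.78 * 100, 2.6, tolerance = 1e-9)
})

test_that("a degenerate trot with zero dissociation lands diagonals together", {
  tpl <- make_template("trot", "warmblood",
                       list(diagonal_dissociation_pct = 0,
                            lateral_dissociation_pct = 50, n_strides = 3))
  ev <- simulate_trial(tpl)$events
  lh <- ev$on_s[ev$limb == "LH" & ev$on_s >= 0][1]
  rf <- ev$on_s[ev$limb == "RF"]
  expect_equal(min(abs(rf - lh)), 0, tolerance = 1e-12)
})

test_that("simulation is bit-identical under a fixed seed", {
  tpl <- make_template("trot", "iberian",
                       list(n_strides = 3, noise_sd_mm = 2), jitter = TRUE, seed = 42)
  a <- simulate_trial(tpl)
  b <- simulate_trial(tpl)
  expect_identical(a$disp, b$disp)
  expect_identical(a$events, b$events)
  expect_identical(a$accel, b$accel)
  tpl2 <- make_template("trot", "iberian",
                        list(n_strides = 3, noise_sd_mm = 2), jitter = TRUE, seed = 43)
  expect_false(isTRUE(all.equal(simulate_trial(tpl2)$disp, a$disp)))
})

test_that("noiseless symmetric waveforms repeat exactly every half stride", {
  for (gait in c("trot", "pace")) {
    tpl <- make_template(gait, "icelandic_ridden", list(n_strides = 2, fs_hz = 200))
    tr <- simulate_trial(tpl)
    half <- round(tpl$stride_duration_s / 2 * tpl$fs_hz)
    for (col in c("head_mm", "withers_mm", "pelvis_mm")) {
      z <- tr$truth_disp[[col]]
      n <- round(tpl$stride_duration_s * tpl$fs_hz)
      expect_equal(z[seq_len(n - half)], z[seq_len(n - half) + half], tolerance = 1e-9)
    }
  }
})

test_that("emitted acceleration is the second derivative of the ground truth", {
  tpl <- make_template("trot", "warmblood", list(n_strides = 4))
  tr <- simulate_trial(tpl)
  h <- 1 / tpl$fs_hz
  for (seg in c("head", "withers", "pelvis")) {
    z <- tr$truth_disp[[paste0(seg, "_mm")]]
    a <- tr$accel[[paste0(seg, "_mps2")]] * 1000
    i <- 100:500  # interior of one stride (no boundary kinks)
    num <- (z[i + 1] - 2 * z[i] + z[i - 1]) / h^2
    expect_equal(num, a[i], tolerance = 1e-3)
  }
})

test_that("double integration of the emitted acceleration recovers the truth", {
  for (gait in c("walk", "trot")) {
    tpl <- make_template(gait, "warmblood", list(n_strides = 4))
    tr <- simulate_trial(tpl)
    win <- pair_strides(tr$events)
    disp <- integrate_displacement(tr$accel, win)
    for (seg in c("head", "withers", "pelvis")) {
      col <- paste0(seg, "_mm")
      for (k in 2:3) {
        idx <- which(disp$time_s >= win$start_s[k] & disp$time_s < win$end_s[k])
        est <- disp[[col]][idx]
        tru <- tr$truth_disp[[col]][idx]
        tru <- tru - mean(tru)
        rms <- sqrt(mean((est - tru)^2))
        expect_lt(rms, 0.02 * tpl$romz_mm[[seg]])
      }
    }
  }
})

test_that("asymmetry injection is exact, local and reversible at zero", {
  tr <- simulate_trial(make_template("trot", "warmblood", list(n_strides = 4)))
  same <- inject_asymmetry(tr, c(HDmin = 0, PDmax = 0))
  expect_equal(same$truth_disp, tr$truth_disp, tolerance = 1e-12)

  up <- inject_asymmetry(tr, c(HDmin = 12))
  an <- suppressMessages(analyze_trial(up, displacement = "truth"))
  expect_equal(median(an$strides$HDmin), 12, tolerance = 1)
  expect_equal(median(an$strides$HDmax), 0, tolerance = 1)
  expect_equal(median(an$strides$PDmin), 0, tolerance = 1)

  expect_error(inject_asymmetry(tr, c(XDmin = 5)), "unknown asymmetry")
})

test_that("template-level asymmetry propagates through the full pipeline", {
  tpl <- make_template("trot", "warmblood",
                       list(n_strides = 4, asymmetry_mm = c(HDmin = 12, PDmin = 5)))
  an <- suppressMessages(analyze_trial(simulate_trial(tpl)))
  expect_equal(median(an$strides$HDmin), 12, tolerance = 1)
  expect_equal(median(an$strides$PDmin), 5, tolerance = 1)
  expect_equal(median(an$strides$HDmax), 0, tolerance = 1)
})
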