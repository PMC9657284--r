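test_that("ideal evenly spaced walk gives the textbook dissociations", {
  ev <- ideal_walk_events(stride_s = 1.1, n_strides = 4)
  win <- pair_strides(ev)
  tv <- temporal_variables(ev, win, "walk")
  # brute force from the four contact phases 0/25/50/75:
  #   diagonals LH-RF: 75-0-100 -> -25; RH-LF: 25-50 -> -25
  #   lateral  LH-LF: +25;        RH-RF: 75-50 -> +25
  expect_equal(tv$diagonal_dissociation_pct, rep(-25, 4))
  expect_equal(tv$lateral_dissociation_pct, rep(25, 4))
  expect_equal(tv$suspension_pct, rep(0, 4))
  # evenly spaced walk: lateral minus diagonal dissociation is half a stride
  expect_equal(tv$lateral_dissociation_pct - tv$diagonal_dissociation_pct, rep(50, 4))
})

test_that("duty factors reproduce the printed reference medians", {
  cases <- list(
    list(stride = 0.78, st_fl = 0.38, st_hl = 0.31, df_fl = 0.49, df_hl = 0.39,
         phases = c(LH = 0, RH = 0.5, LF = 0.47, RF = 0.974), gait = "trot"),
    list(stride = 1.2, st_fl = 0.77, st_hl = 0.71, df_fl = 0.64, df_hl = 0.59,
         phases = c(LH = 0, LF = 0.27, RH = 0.5, RF = 0.77), gait = "walk"),
    list(stride = 0.42, st_fl = 0.15, st_hl = 0.17, df_fl = 0.36, df_hl = 0.40,
         phases = c(LH = 0, LF = 0.097, RH = 0.5, RF = 0.597), gait = "pace"))
  for (cs in cases) {
    ev <- regular_events(cs$stride, 3, cs$phases, cs$st_fl, cs$st_hl)
    tv <- temporal_variables(ev, pair_strides(ev), cs$gait)
    expect_lt(abs(tv$duty_factor_fl[2] - cs$df_fl), 0.01 + 1e-9)
    expect_lt(abs(tv$duty_factor_hl[2] - cs$df_hl), 0.01 + 1e-9)
    # identity holds to machine precision
    expect_equal(tv$duty_factor_fl * tv$stride_duration_s, tv$stance_duration_fl_s,
                 tolerance = 1e-12)
    expect_equal(tv$stance_duration_fl_s + tv$swing_duration_fl_s, tv$stride_duration_s,
                 tolerance = 1e-12)
  }
})

test_that("suspension of a synchronous pace follows from the gap arithmetic", {
  # lateral pairs land and lift together: stance 0.15, half-stride 0.21
  ev <- regular_events(0.42, 3, c(LH = 0, LF = 0, RH = 0.5, RF = 0.5), 0.15, 0.15)
  tv <- temporal_variables(ev, pair_strides(ev), "pace")
  expect_equal(tv$suspension_pct[2], 2 * (0.21 - 0.15) / 0.42 * 100, tolerance = 1e-9)
})

test_that("suspension is zero for all simulated walks and toelts", {
  for (cond in c("iberian", "icelandic_inhand", "icelandic_ridden", "warmblood")) {
    an <- cached_analysis("walk", cond)
    expect_equal(an$strides$suspension_pct, rep(0, nrow(an$strides)))
  }
  an <- cached_analysis("tolt", "icelandic_ridden")
  expect_equal(an$strides$suspension_pct, rep(0, nrow(an$strides)))
})

test_that("extremum location agrees with dense brute force on random smooth strides", {
  fs <- 200; T0 <- 0.8
  tt <- seq(0, 3 * T0, by = 1 / fs)
  ev <- regular_events(T0, 3, c(LH = 0, RH = 0.5, LF = 0.45, RF = 0.95),
                       0.35 * T0, 0.3 * T0)
  win <- pair_strides(ev)
  withr::with_seed(21, {
    for (rep in 1:25) {
      a2 <- runif(1, 5, 20); p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
      a1 <- runif(1, 0, 0.25) * a2
      f <- function(t) a1 * cos(2 * pi * t / T0 + p1) + a2 * cos(4 * pi * t / T0 + p2)
      disp <- tibble::tibble(time_s = tt, head_mm = f(tt))
      ex <- find_extrema(disp, win[2, ], ev)
      # dense oracle over the window
      td <- seq(win$start_s[2], win$end_s[2], by = 1 / (50 * fs))
      expect_lt(abs(min(ex$min_mm) - min(f(td))), 0.05)
      expect_lt(abs(max(ex$max_mm) - max(f(td))), 0.05)
      expect_lt(min(abs(ex$min_time_s - td[which.min(f(td))])), 1 / fs)
      expect_lt(min(abs(ex$max_time_s - td[which.max(f(td))])), 1 / fs)
    }
  })
})

test_that("a sinusoid bottoming at midstance reads 50 percent of stance", {
  fs <- 200; T0 <- 0.8
  tt <- seq(0, 3 * T0, by = 1 / fs)
  stance <- 0.4 * T0
  ev <- regular_events(T0, 3, c(LH = 0, RH = 0.5, LF = 0, RF = 0.5), stance, stance)
  win <- pair_strides(ev)
  # minima exactly at midstance of LF (phase 0.2) and RF (0.7)
  disp <- tibble::tibble(time_s = tt, head_mm = -cos(4 * pi * (tt / T0 - 0.2)) * 30)
  ex <- find_extrema(disp, win, ev)
  expect_equal(ex$min_pct_stance[ex$stride_index == 2], c(50, 50), tolerance = 0.05)
})

test_that("flat traces are flagged rather than silently measured", {
  tt <- seq(0, 2.4, by = 0.005)
  ev <- regular_events(0.8, 3, c(LH = 0, RH = 0.5, LF = 0.45, RF = 0.95), 0.3, 0.25)
  win <- pair_strides(ev)
  disp <- tibble::tibble(time_s = tt, head_mm = rep(1, length(tt)))
  w <- testthat::capture_warnings(ex <- find_extrema(disp, win, ev))
  expect_match(w, "flat|strict", all = TRUE)
  expect_gt(length(w), 0)
  expect_equal(nrow(ex), 0)
})

test_that("symmetry indices vanish for symmetric strides and ignore offsets", {
  an <- cached_analysis("trot", "warmblood")
  s <- an$strides
  for (v in c("HDmin", "HDmax", "WDmin", "WDmax", "PDmin", "PDmax")) {
    expect_equal(s[[v]], rep(0, nrow(s)), tolerance = 0.02)
  }
  # adding a constant to a trace changes no index and no ROMz
  tr <- simulate_trial(make_template("trot", "warmblood", list(n_strides = 4)))
  shifted <- tr
  shifted$disp$head_mm <- shifted$disp$head_mm + 500
  a1 <- suppressMessages(analyze_trial(tr, displacement = "truth"))
  a2 <- suppressMessages(analyze_trial(shifted, displacement = "truth"))
  expect_equal(a2$strides$HDmin, a1$strides$HDmin, tolerance = 1e-9)
  expect_equal(a2$strides$romz_head, a1$strides$romz_head, tolerance = 1e-9)
})

test_that("exactly two minima and two maxima are reported per segment-stride", {
  an <- cached_analysis("tolt", "icelandic_ridden")
  counts <- dplyr::count(an$extrema, stride_index, segment)
  expect_true(all(counts$n == 2))
  expect_true(all(an$extrema$min_mm < an$extrema$max_mm))
})

test_that("the inclusion filter applies strict thresholds with named reasons", {
  # boundary values are included; only strictly exceeding values exclude
  at <- c(HDmin = 16, HDmax = 16, PDmin = 8, PDmax = 8)
  expect_equal(inclusion_filter(at)$decision, "include")
  combos <- expand.grid(HDmin = c(16, 16.1), HDmax = c(16, 16.1),
                        PDmin = c(8, 8.1), PDmax = c(8, 8.1))
  for (i in seq_len(nrow(combos))) {
    ind <- unlist(combos[i, ])
    res <- inclusion_filter(ind)
    over <- names(ind)[ind > c(16, 16, 8, 8)]
    expect_equal(res$decision, if (length(over) > 0) "exclude" else "include")
    expect_setequal(res$reasons, over)
  }
  # sign is irrelevant; thresholds act on absolute values
  expect_equal(inclusion_filter(c(HDmin = 0, HDmax = 0, PDmin = -8.5, PDmax = 0)),
               list(decision = "exclude", reasons = "PDmin"))
  expect_setequal(inclusion_filter(c(HDmin = 20, HDmax = 3, PDmin = 9, PDmax = 1))$reasons,
                  c("HDmin", "PDmin"))
  expect_equal(inclusion_filter(c(HDmin = 1, HDmax = NA, PDmin = 1, PDmax = 1))$decision,
               "indeterminate")
})
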