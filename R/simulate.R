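# Synthetic gait generator.
#
# Displacement model per axial segment: a phase-modulated cosine with two
# oscillations per stride,
#
#   z(phi) = -(R/2) * cos(psi(phi) - psi0),  psi(phi) = u + beta*sin(u + gamma),
#   u = 4*pi*phi,  phi = within-stride fraction,
#
# which is the minimal smooth half-stride-periodic waveform that places one
# minimum and one maximum per half stride at arbitrary prescribed phases
# (|beta| < 1 guarantees exactly two of each per stride) and reaches
# max - min = R exactly. The published reference data prescribe extremum
# timing and range, not waveform shape, so the family is chosen for
# smoothness (twice differentiable, analytic second derivative) and minimal
# parameters. Movement asymmetry is a multiplicative stride-frequency
# envelope anchored at the left-referenced extrema, solved exactly for the
# requested HDmin/HDmax/PDmin/PDmax.

# Solve the waveform parameters for one segment.
segment_waveform <- function(template, segment) {
  phases <- contact_phases(template)
  T0 <- template$stride_duration_s
  if (segment %in% c("head", "withers")) {
    ref_on <- phases[["LF"]]
    stance_frac <- template$stance_duration_fl_s / T0
    ref_limb <- "LF"
  } else {
    ref_on <- phases[["LH"]]
    stance_frac <- template$stance_duration_hl_s / T0
    ref_limb <- "LH"
  }
  ph <- template$extremum_phase[[segment]]
  m <- (ref_on + ph[["min"]] / 100 * stance_frac) %% 1
  x <- (ref_on + ph[["max"]] / 100 * stance_frac) %% 1
  d <- (x - m) %% 0.5
  if (d < 0.02 || d > 0.48) {
    stop(sprintf("extremum phases for %s place the minimum and maximum %.1f%% of a stride apart; the two-extrema-per-half-stride waveform needs a separation in (1, 24)%% mod 50", segment, 100 * d), call. = FALSE)
  }
  beta <- (pi - 4 * pi * d) / (2 * sin(2 * pi * d))
  um <- 4 * pi * m
  ux <- um + 4 * pi * d
  gamma <- -(um + ux) / 2
  psi0 <- um + beta * sin(um + gamma)
  list(segment = segment, m = m, x = x, beta = beta, gamma = gamma, psi0 = psi0,
       R = template$romz_mm[[segment]], ref_limb = ref_limb,
       ref_on = ref_on, stance_frac = stance_frac)
}

# Envelope coefficients (a1, a2) such that multiplying the symmetric
# waveform by g(phi) = 1 + a1*cos(2*pi*(phi-m)) + a2*cos(2*pi*(phi-x))
# changes the left-minus-right minimum difference by delta_min and the
# maximum difference by delta_max. vsum/wsum are the current sums of the two
# minima / two maxima values (-R and +R for the symmetric waveform).
envelope_coef <- function(delta_min, delta_max, vsum, wsum, m, x) {
  cc <- cos(2 * pi * (m - x))
  A <- rbind(c(vsum, vsum * cc),
             c(wsum * cc, wsum))
  as.numeric(solve(A, c(delta_min, delta_max)))
}

# Evaluate waveform displacement (mm) and its exact second derivative
# (mm/s^2) at within-stride fractions phi, for stride duration Ti and
# amplitude Ri (vectors aligned with phi). env = c(a1, a2) or NULL.
eval_segment <- function(wp, phi, Ti, Ri, env = NULL) {
  u <- 4 * pi * phi
  su <- sin(u + wp$gamma)
  cu <- cos(u + wp$gamma)
  psi <- u + wp$beta * su - wp$psi0
  dpsi <- (4 * pi / Ti) * (1 + wp$beta * cu)
  d2psi <- -(4 * pi / Ti)^2 * wp$beta * su
  cosw <- cos(psi)
  sinw <- sin(psi)
  z <- -(Ri / 2) * cosw
  dz <- (Ri / 2) * sinw * dpsi
  a <- (Ri / 2) * (cosw * dpsi^2 + sinw * d2psi)
  if (!is.null(env) && any(env != 0)) {
    w <- 2 * pi
    g <- 1 + env[1] * cos(w * (phi - wp$m)) + env[2] * cos(w * (phi - wp$x))
    dg <- -(w / Ti) * (env[1] * sin(w * (phi - wp$m)) + env[2] * sin(w * (phi - wp$x)))
    d2g <- -(w / Ti)^2 * (env[1] * cos(w * (phi - wp$m)) + env[2] * cos(w * (phi - wp$x)))
    a <- a * g + 2 * dz * dg + z * d2g
    z <- z * g
  }
  list(z = z, a = a)
}

.seg_delta_names <- list(head = c("HDmin", "HDmax"),
                         withers = c("WDmin", "WDmax"),
                         pelvis = c("PDmin", "PDmax"))

#' Simulate one trial of a gaiting horse
#'
#' Generates, for a single horse and gait, the per-limb hoof-on/off event
#' series, the vertical acceleration of the three axial sensors (head,
#' withers, pelvis), the ground-truth vertical displacement the acceleration
#' is the exact second derivative of, and a stylized distal-limb signal per
#' limb (near zero in stance, oscillatory in swing) for the surrogate event
#' detector. Footfalls realize the template's stride duration, stance
#' durations and dissociations exactly before optional jitter; displacement
#' extrema fall at the template's extremum phases; asymmetry deltas displace
#' alternate extrema by the requested millimetres. All randomness (noise,
#' jitter) is driven by `template$seed`.
#'
#' @param template a [make_template()] object.
#' @return an object of class `gait_trial`: a list with elements `template`,
#'   `events` (tibble: limb, on_s, off_s), `accel` (tibble: time_s,
#'   head_mps2, withers_mps2, pelvis_mps2), `truth_disp` (tibble: time_s,
#'   head_mm, withers_mm, pelvis_mm; noise-free ground truth), `disp`
#'   (ground truth plus measurement noise, if any), `limb_signals` (tibble:
#'   time_s, LF, RF, LH, RH), `truth_extrema` (tibble of true extremum
#'   times/values per stride, segment and side) and `stride_starts_s`.
#' @examples
#' trial <- simulate_trial(make_template("trot", "warmblood", list(n_strides = 4)))
#' trial$events
#' @export
simulate_trial <- function(template) {
  template <- validate_gait_template(template)
  with_seed_if(template$seed, simulate_trial_impl(template))
}

simulate_trial_impl <- function(template) {
  T0 <- template$stride_duration_s
  n <- template$n_strides
  fs <- template$fs_hz
  jit <- template$jitter
  segs <- c("head", "withers", "pelvis")

  Ti <- rep(T0, n)
  if (jit$stride_sd_s > 0) Ti <- pmax(Ti + stats::rnorm(n, 0, jit$stride_sd_s), 0.5 * T0)
  starts <- c(0, cumsum(Ti))

  phases <- contact_phases(template)
  stance <- c(LH = template$stance_duration_hl_s, RH = template$stance_duration_hl_s,
              LF = template$stance_duration_fl_s, RF = template$stance_duration_fl_s)
  ev <- lapply(c("LH", "RH", "LF", "RF"), function(limb) {
    on <- starts[seq_len(n)] + phases[[limb]] * Ti
    if (limb == "LH") on <- c(on, starts[n + 1])  # closing contact of the last stride
    # a stance begun before the recording still covers early samples
    pre <- (phases[[limb]] - 1) * Ti[1]
    if (pre + stance[[limb]] > 0) on <- c(pre, on)
    if (jit$event_sd_s > 0) on <- on + stats::rnorm(length(on), 0, jit$event_sd_s)
    off <- on + stance[[limb]]
    if (jit$event_sd_s > 0) off <- off + stats::rnorm(length(off), 0, jit$event_sd_s)
    tibble::tibble(limb = limb, on_s = on, off_s = off)
  })
  events <- dplyr::arrange(dplyr::bind_rows(ev), .data$limb, .data$on_s)

  end <- starts[n + 1]
  tt <- seq(0, end + 2 / fs, by = 1 / fs)
  si <- pmin(pmax(findInterval(tt, starts), 1L), n)
  phi <- (tt - starts[si]) / Ti[si]

  wps <- lapply(segs, segment_waveform, template = template)
  names(wps) <- segs

  amp <- matrix(rep(template$romz_mm[segs], each = n), nrow = n,
                dimnames = list(NULL, segs))
  if (jit$amp_frac > 0) {
    amp <- amp * pmax(1 + matrix(stats::rnorm(n * 3, 0, jit$amp_frac), n, 3), 0.2)
  }

  disp <- tibble::tibble(time_s = tt)
  accel <- tibble::tibble(time_s = tt)
  truth_rows <- list()
  for (seg in segs) {
    wp <- wps[[seg]]
    dn <- .seg_delta_names[[seg]]
    deltas <- c(template$asymmetry_mm[dn[1]], template$asymmetry_mm[dn[2]])
    deltas[is.na(deltas)] <- 0
    env <- NULL
    if (any(deltas != 0)) {
      env <- envelope_coef(deltas[1], deltas[2], -wp$R, wp$R, wp$m, wp$x)
    }
    out <- eval_segment(wp, phi, Ti[si], amp[cbind(si, match(seg, segs))], env)
    disp[[paste0(seg, "_mm")]] <- out$z
    accel[[paste0(seg, "_mps2")]] <- out$a / 1000

    # true extremum catalogue, one row per stride x side x kind
    for (i in seq_len(n)) {
      for (side in c("left", "right")) {
        off <- if (side == "left") 0 else 0.5
        for (kind in c("min", "max")) {
          p <- ((if (kind == "min") wp$m else wp$x) + off) %% 1
          t_ext <- starts[i] + p * Ti[i]
          v <- eval_segment(wp, p, Ti[i], amp[i, seg], env)$z
          truth_rows[[length(truth_rows) + 1]] <-
            tibble::tibble(stride_index = i, segment = seg, side = side,
                           kind = kind, time_s = t_ext, value_mm = v)
        }
      }
    }
  }
  truth_extrema <- dplyr::bind_rows(truth_rows)

  noisy <- disp
  if (template$noise_sd_mm > 0) {
    for (seg in segs) {
      noisy[[paste0(seg, "_mm")]] <- disp[[paste0(seg, "_mm")]] +
        stats::rnorm(length(tt), 0, template$noise_sd_mm)
      accel[[paste0(seg, "_mps2")]] <- accel[[paste0(seg, "_mps2")]] +
        stats::rnorm(length(tt), 0, template$noise_sd_mm * (4 * pi / T0)^2 / 1000)
    }
  }

  sig <- tibble::tibble(time_s = tt)
  for (limb in c("LF", "RF", "LH", "RH")) {
    e <- events[events$limb == limb, ]
    sig[[limb]] <- limb_swing_signal(tt, e$on_s, e$off_s, T0 - stance[[limb]])
  }

  structure(list(template = template,
                 events = events,
                 accel = accel,
                 truth_disp = disp,
                 disp = noisy,
                 limb_signals = sig,
                 truth_extrema = truth_extrema,
                 stride_starts_s = starts),
            class = "gait_trial")
}

# Stylized metapodial signal: zero during stance, a two-cycle cosine burst
# during swing. The burst starts and ends at full amplitude so that the
# stance/swing boundary is sharp at the sampling grid.
limb_swing_signal <- function(tt, on, off, nominal_swing_s) {
  o <- order(on)
  on <- on[o]; off <- off[o]
  b <- as.vector(rbind(on, off))  # interleaved boundaries, sorted
  k <- findInterval(tt, b)
  in_stance <- k %% 2 == 1
  sig <- numeric(length(tt))
  sw <- !in_stance
  if (any(sw)) {
    prev_off <- ifelse(k[sw] >= 2, b[pmax(k[sw], 2)], on[1] - nominal_swing_s)
    # duration to the next contact when known, nominal otherwise
    next_on <- ifelse(k[sw] + 1 <= length(b), b[pmin(k[sw] + 1, length(b))], NA_real_)
    dur <- ifelse(is.na(next_on), nominal_swing_s, next_on - prev_off)
    prog <- (tt[sw] - prev_off) / dur
    sig[sw] <- cos(2 * pi * 2 * prog)
  }
  sig
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> %s / %s: %d strides at %g Hz (%.2f s)\n",
              x$template$gait, x$template$condition, x$template$n_strides,
              x$template$fs_hz, max(x$accel$time_s)))
  invisible(x)
}

#' Inject movement asymmetry into a simulated trial
#'
#' Displaces alternate minima and/or maxima of the head, withers or pelvis
#' displacement by the requested signed millimetres, leaving extremum
#' locations at their original times. The injected value is exactly what the
#' symmetry indices of [symmetry_indices()] recover (left-referenced minus
#' right-referenced extremum value). Both the ground-truth and the noisy
#' displacement traces are modified; the acceleration traces are left
#' untouched (asymmetry set at template level propagates to acceleration
#' too — use `asymmetry_mm` in [make_template()] for that).
#'
#' @param trial a `gait_trial`.
#' @param deltas named numeric vector; names among `HDmin`, `HDmax`,
#'   `WDmin`, `WDmax`, `PDmin`, `PDmax`; values in mm.
#' @return the modified `gait_trial`.
#' @examples
#' trial <- simulate_trial(make_template("trot", "warmblood", list(n_strides = 4)))
#' lame <- inject_asymmetry(trial, c(HDmin = 20))
#' @export
inject_asymmetry <- function(trial, deltas) {
  stopifnot(inherits(trial, "gait_trial"))
  valid <- unlist(.seg_delta_names, use.names = FALSE)
  bad <- setdiff(names(deltas), valid)
  if (length(bad) > 0 || is.null(names(deltas))) {
    stop(sprintf("unknown asymmetry indices: %s (valid: %s)",
                 paste(bad, collapse = ", "), paste(valid, collapse = ", ")),
         call. = FALSE)
  }
  segs_touched <- names(.seg_delta_names)[vapply(.seg_delta_names, function(dn)
    any(dn %in% names(deltas) & abs(deltas[intersect(dn, names(deltas))]) > 0), logical(1))]
  tex <- trial$truth_extrema
  starts <- trial$stride_starts_s
  n <- trial$template$n_strides
  for (seg in segs_touched) {
    dn <- .seg_delta_names[[seg]]
    dmin <- if (dn[1] %in% names(deltas)) deltas[[dn[1]]] else 0
    dmax <- if (dn[2] %in% names(deltas)) deltas[[dn[2]]] else 0
    ex <- tex[tex$segment == seg, ]
    vsum <- sum(ex$value_mm[ex$kind == "min"]) / n
    wsum <- sum(ex$value_mm[ex$kind == "max"]) / n
    mL <- ex[ex$kind == "min" & ex$side == "left", ]
    xL <- ex[ex$kind == "max" & ex$side == "left", ]
    col <- paste0(seg, "_mm")
    for (tr in c("truth_disp", "disp")) {
      tt <- trial[[tr]]$time_s
      si <- pmin(pmax(findInterval(tt, starts), 1L), n)
      Ti <- diff(starts)[si]
      phi <- (tt - starts[si]) / Ti
      m_i <- (mL$time_s[si] - starts[si]) / Ti  # left-min phase of that stride
      x_i <- (xL$time_s[si] - starts[si]) / Ti
      env <- envelope_coef(dmin, dmax, vsum, wsum, mean(m_i), mean(x_i))
      g <- 1 + env[1] * cos(2 * pi * (phi - m_i)) + env[2] * cos(2 * pi * (phi - x_i))
      trial[[tr]][[col]] <- trial[[tr]][[col]] * g
    }
    # update the truth catalogue values
    env <- envelope_coef(dmin, dmax, vsum, wsum,
                         mean((mL$time_s - starts[mL$stride_index]) / diff(starts)[mL$stride_index]),
                         mean((xL$time_s - starts[xL$stride_index]) / diff(starts)[xL$stride_index]))
    idx <- which(tex$segment == seg)
    for (i in idx) {
      Ti_i <- diff(starts)[tex$stride_index[i]]
      p <- (tex$time_s[i] - starts[tex$stride_index[i]]) / Ti_i
      pm <- (mL$time_s[match(tex$stride_index[i], mL$stride_index)] -
               starts[tex$stride_index[i]]) / Ti_i
      px <- (xL$time_s[match(tex$stride_index[i], xL$stride_index)] -
               starts[tex$stride_index[i]]) / Ti_i
      g <- 1 + env[1] * cos(2 * pi * (p - pm)) + env[2] * cos(2 * pi * (p - px))
      tex$value_mm[i] <- tex$value_mm[i] * g
    }
  }
  trial$truth_extrema <- tex
  trial
}
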