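#' Simulate the noise-free indentation response of one subject
#'
#' Forward model of the motor-driven cyclic indentation test. The indenter
#' trajectory has two phases:
#' \enumerate{
#'   \item a seating/preload phase (duration `protocol$preload_duration`)
#'     during which the coupling force rises towards the preload ceiling and
#'     releases while the tissue is still at its initial thickness (tissue
#'     deformation under the sub-0.5 N preload is neglected; the initial
#'     thickness is defined as the preload-state thickness);
#'   \item `n_cycles` triangular loading cycles to a peak indentation of
#'     `indent_fraction * h0`.
#' }
#' The elastic force is the thin-layer punch relation evaluated with the
#' subject's J-shaped secant law,
#' \deqn{P_e = \frac{2 a \, \kappa(\nu, a/h)}{1 - \nu^2} E(w/h_0)\, w,}
#' with `h` the instantaneous thickness `h0 - w` (switchable to `h0`). A
#' standard-linear-solid viscous term with time constant `relax_time` and
#' relative weight `relax_strength` is added by exponential convolution of
#' the elastic force rate; total force is clamped at zero (the indenter
#' cannot pull).
#'
#' @param truth a [tissue_ground_truth()].
#' @param protocol a [loading_protocol()].
#' @param geom an [indenter_geometry()].
#' @param sim_rate trajectory sampling rate, Hz.
#' @param h_convention `"instantaneous"` (kappa evaluated at `h0 - w`) or
#'   `"initial"` (kappa fixed at `h0`).
#' @return a data frame of class `indentation_trajectory` with columns
#'   `time_s`, `w_mm`, `force_N`, `thickness_mm`, plus attributes `h0_mm`,
#'   `noise_scale` and `protocol`.
#' @export
simulate_indentation <- function(truth, protocol = loading_protocol(),
                                 geom = indenter_geometry(),
                                 sim_rate = 100,
                                 h_convention = c("instantaneous", "initial")) {
  h_convention <- match.arg(h_convention)
  if (protocol$indent_fraction >= 1)
    stop("'indent_fraction' must be < 1", call. = FALSE)
  if (truth$relax_time < 0) stop("'relax_time' must be >= 0", call. = FALSE)

  h0 <- truth$h0
  w_max <- protocol$indent_fraction * h0
  t_pre <- protocol$preload_duration
  t_cyc <- protocol$n_cycles * protocol$cycle_period
  dt <- 1 / sim_rate
  time <- seq(0, t_pre + t_cyc, by = dt)

  ## indentation depth: 0 during preload, then triangular cycles
  w <- numeric(length(time))
  in_cyc <- time >= t_pre
  phase <- (time[in_cyc] - t_pre) %% protocol$cycle_period
  half <- protocol$cycle_period / 2
  w[in_cyc] <- w_max * ifelse(phase <= half, phase / half,
                              2 - phase / half)
  w[length(w)] <- 0  # trajectory ends unloaded

  ## elastic force through the layer-corrected punch relation
  Efun <- secant_modulus(truth)
  h_for_kappa <- if (h_convention == "instantaneous") h0 - w else
    rep(h0, length(w))
  kap <- hayes_kappa(geom$a / h_for_kappa, geom$nu)
  E_kpa <- Efun(w / h0)
  Pe <- 2 * (geom$a * 1e-3) * kap * (E_kpa * 1000) * (w * 1e-3) /
    (1 - geom$nu^2)

  ## standard-linear-solid viscous component: exponential convolution of the
  ## elastic force rate, exact for piecewise-linear Pe(t)
  Pv <- numeric(length(Pe))
  if (truth$relax_time > 0 && truth$relax_strength > 0) {
    tau <- truth$relax_time
    decay <- exp(-dt / tau)
    gain <- truth$relax_strength * (tau / dt) * (1 - decay)
    for (i in 2:length(Pe))
      Pv[i] <- Pv[i - 1] * decay + gain * (Pe[i] - Pe[i - 1])
  }

  ## seating force during the preload phase: ramp to just below the preload
  ## ceiling, then release before the cycles start; for very soft subjects
  ## the operator seats at a fraction of the expected cyclic peak instead
  Ps <- numeric(length(time))
  if (t_pre > 0) {
    peak <- max(Pe + Pv)
    target <- if (peak > 0)
      min(0.9 * protocol$preload_max, max(0.12, 0.3 * peak))
    else 0.9 * protocol$preload_max
    t_up <- 0.8 * t_pre
    pre_i <- which(time < t_pre)
    tp <- time[pre_i]
    Ps[pre_i] <- ifelse(tp <= t_up, target * tp / t_up,
                        target * pmax(0, 1 - (tp - t_up) / (t_pre - t_up)))
  }

  force <- pmax(Pe + Pv + Ps, 0)
  out <- data.frame(time_s = time, w_mm = w, force_N = force,
                    thickness_mm = h0 - w)
  structure(out, class = c("indentation_trajectory", "data.frame"),
            h0_mm = h0, noise_scale = truth$noise_scale,
            protocol = protocol, geom = geom)
}

#' Render a trajectory into synthetic acquisition channels
#'
#' Produces the two raw channels an acquisition system would record: an
#' M-mode frame series (one RF line per frame; two Gaussian-modulated echo
#' pulses at the transducer-skin interface `z1` and the tissue-bone
#' interface `z1 + thickness`) sampled at `frame_rate`, and the force
#' channel resampled at `force_rate`. Additive white noise is applied at
#' `echo_snr` dB relative to the first-echo peak amplitude, scaled by the
#' subject's `noise_scale`; `echo_snr = Inf` renders both channels
#' noise-free.
#'
#' @param trajectory an `indentation_trajectory` from
#'   [simulate_indentation()].
#' @param config an [acquisition_config()].
#' @return an object of class `indentation_recording`: list with elements
#'   `frames` (`times`, `depth_mm`, `amplitude` matrix of n_depth x
#'   n_frames), `force` (`times`, `force_N`), `protocol`, `config` and the
#'   logical flag `overlap_flagged`.
#' @export
render_recording <- function(trajectory, config = acquisition_config()) {
  h0 <- attr(trajectory, "h0_mm")
  noise_scale <- attr(trajectory, "noise_scale") %||% 1
  duration <- max(trajectory$time_s)

  n_frames <- floor(duration * config$frame_rate)
  frame_t <- (seq_len(n_frames) - 1) / config$frame_rate
  n_force <- floor(duration * config$force_rate)
  force_t <- (seq_len(n_force) - 1) / config$force_rate

  thick <- stats::approx(trajectory$time_s, trajectory$thickness_mm,
                         xout = frame_t)$y
  force <- stats::approx(trajectory$time_s, trajectory$force_N,
                         xout = force_t)$y
  ## load-cell saturation
  force <- pmin(force, config$load_cell_max)

  dz <- depth_step_mm(config)
  sz <- pulse_sigma_mm(config)
  res <- pulse_resolution_mm(config)
  overlap <- any(thick < res)
  if (overlap)
    warning(sprintf(
      "echo overlap: thickness fell below the pulse resolution (%.2f mm); interfaces will not be resolvable", res),
      call. = FALSE)

  z1 <- config$z1_mm
  depth <- seq(0, z1 + max(thick) * 1.3 + 2, by = dz)
  ## spatial carrier: f0 in time maps to period c/(2 f0) in depth
  period_mm <- config$sound_speed / (2 * config$carrier_mhz * 1e6) * 1e3

  pulse <- function(center) {
    d <- outer(depth, center, "-")
    exp(-d^2 / (2 * sz^2)) * cos(2 * pi * d / period_mm)
  }
  amp <- pulse(rep(z1, n_frames)) + 0.8 * pulse(z1 + thick)

  noisy <- is.finite(config$echo_snr) && noise_scale > 0
  if (noisy) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(config$seed)
    sd_e <- 10^(-config$echo_snr / 20) * noise_scale
    amp <- amp + stats::rnorm(length(amp), sd = sd_e)
    force <- force + stats::rnorm(n_force,
                                  sd = config$force_noise_sd * noise_scale)
  }

  structure(list(frames = list(times = frame_t, depth_mm = depth,
                               amplitude = amp),
                 force = list(times = force_t, force_N = force),
                 protocol = attr(trajectory, "protocol"),
                 config = config, overlap_flagged = overlap),
            class = "indentation_recording")
}

#' @export
print.indentation_recording <- function(x, ...) {
  cat(sprintf(
    "M-mode indentation recording: %d frames at %.1f Hz, %d force samples at %.0f Hz\n",
    length(x$frames$times), x$config$frame_rate,
    length(x$force$times), x$config$force_rate))
  invisible(x)
}

#' Build a force-deformation curve directly from a trajectory
#'
#' Bypasses echo rendering and interface tracking: the deformation channel is
#' taken from the trajectory itself, sampled at the frame rate. This is the
#' fast analysis path used for large calibration runs, and the reference
#' against which the echo-tracked path is validated.
#'
#' @param trajectory an `indentation_trajectory`.
#' @param frame_rate sampling rate of the resulting curve, Hz.
#' @return a `force_deformation_curve` (see [synchronize()]).
#' @export
curve_from_trajectory <- function(trajectory, frame_rate = 22.5) {
  h0 <- attr(trajectory, "h0_mm")
  duration <- max(trajectory$time_s)
  t <- (seq_len(floor(duration * frame_rate)) - 1) / frame_rate
  w <- stats::approx(trajectory$time_s, trajectory$w_mm, xout = t)$y
  P <- stats::approx(trajectory$time_s, trajectory$force_N, xout = t)$y
  new_curve(t, w, P, h0)
}
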