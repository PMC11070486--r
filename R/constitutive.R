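#' Latent constitutive ground truth for one simulated subject
#'
#' The simulator's per-subject truth: geometry, a J-shaped secant modulus law
#' and a mild viscous component. The secant modulus at engineering strain
#' \eqn{\varepsilon = w / h_0} is
#' \deqn{E(\varepsilon) = E_0 \exp(\gamma \varepsilon)}
#' with toe modulus \eqn{E_0} (`toe_modulus`, kPa) and dimensionless
#' stiffening rate \eqn{\gamma} (`stiffening_rate`); \eqn{\gamma = 0} is
#' linear elastic. When `regional_anchors` is supplied (moduli pinned at
#' named strain levels, as produced by applying region-specific treatment
#' effects), the log-modulus is piecewise-linearly interpolated through the
#' anchors and linearly extrapolated outside them.
#'
#' @param subject_id opaque label.
#' @param group treatment magnitude label in mmHg (e.g. -105, -125, -145).
#' @param h0 initial soft-tissue thickness under preload, mm (> 0).
#' @param toe_modulus small-strain secant modulus, kPa (> 0).
#' @param stiffening_rate dimensionless exponent of the J-shaped law (>= 0).
#' @param relax_time viscous time constant of the standard-linear-solid
#'   relaxation kernel, s (>= 0; 0 disables the viscous term).
#' @param relax_strength dimensionless relative weight of the viscous force
#'   term (>= 0).
#' @param noise_scale multiplier applied to all measurement noise for this
#'   subject (>= 0; 0 renders noise-free).
#' @param regional_anchors optional named numeric vector of secant moduli
#'   (kPa) at fixed strains; names are the strains (e.g. `"0.05"`).
#' @return an object of class `tissue_truth`.
#' @export
tissue_ground_truth <- function(subject_id, group = NA, h0,
                                toe_modulus, stiffening_rate = 0,
                                relax_time = 0, relax_strength = 0.1,
                                noise_scale = 1, regional_anchors = NULL) {
  stopifnot_scalar(h0, "h0", positive = TRUE)
  stopifnot_scalar(toe_modulus, "toe_modulus", positive = TRUE)
  stopifnot_scalar(stiffening_rate, "stiffening_rate")
  if (stiffening_rate < 0) stop("'stiffening_rate' must be >= 0", call. = FALSE)
  if (relax_time < 0) stop("'relax_time' must be >= 0", call. = FALSE)
  if (relax_strength < 0) stop("'relax_strength' must be >= 0", call. = FALSE)
  if (!is.null(regional_anchors)) {
    if (is.null(names(regional_anchors)) || any(regional_anchors <= 0))
      stop("'regional_anchors' must be a named vector of positive moduli",
           call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), group = group,
                 h0 = h0, toe_modulus = toe_modulus,
                 stiffening_rate = stiffening_rate,
                 relax_time = relax_time, relax_strength = relax_strength,
                 noise_scale = noise_scale,
                 regional_anchors = regional_anchors),
            class = "tissue_truth")
}

#' Secant modulus law of a ground-truth subject
#'
#' @param truth a [tissue_ground_truth()].
#' @return a function of strain returning the secant modulus in kPa.
#' @export
secant_modulus <- function(truth) {
  if (is.null(truth$regional_anchors)) {
    E0 <- truth$toe_modulus
    g <- truth$stiffening_rate
    function(eps) E0 * exp(g * eps)
  } else {
    xs <- as.numeric(names(truth$regional_anchors))
    ys <- log(unname(truth$regional_anchors))
    o <- order(xs); xs <- xs[o]; ys <- ys[o]
    if (length(xs) < 2) {
      E0 <- truth$regional_anchors[[1]]
      return(function(eps) rep_len(E0, length(eps)))
    }
    function(eps) {
      ## linear interpolation in log-modulus, end-slope extrapolation
      lo <- ys[1] + (eps - xs[1]) * (ys[2] - ys[1]) / (xs[2] - xs[1])
      n <- length(xs)
      hi <- ys[n] + (eps - xs[n]) * (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1])
      mid <- stats::approx(xs, ys, xout = pmin(pmax(eps, xs[1]), xs[n]))$y
      out <- ifelse(eps < xs[1], lo, ifelse(eps > xs[n], hi, mid))
      exp(out)
    }
  }
}

#' True regional moduli of a ground-truth subject
#'
#' Evaluates the subject's secant law at the toe/heel/linear target strains,
#' the quantities the analysis pipeline is asked to recover.
#'
#' @param truth a [tissue_ground_truth()].
#' @param strains target strain levels, defaults to 5/10/15% of `h0`.
#' @return named numeric vector `c(E1=, E2=, E3=)` in kPa.
#' @export
truth_regional_moduli <- function(truth, strains = c(0.05, 0.10, 0.15)) {
  E <- secant_modulus(truth)(strains)
  stats::setNames(E, paste0("E", seq_along(strains)))
}

#' Cyclic indentation loading protocol
#'
#' Defaults follow the clinical measurement protocol: preload below 0.5 N to
#' establish coupling and define the initial thickness, indentation to 20% of
#' the initial soft-tissue thickness, five triangular loading cycles of about
#' 8 s each within a 40 s test, with advisory compliance windows of 2-4 mm
#' ramp travel per 4 s and 400-600 gram-force peak response.
#'
#' @param preload_max preload force ceiling, N.
#' @param indent_fraction target indentation as a fraction of initial
#'   thickness, in (0, 1).
#' @param n_cycles number of loading cycles.
#' @param cycle_period duration of one cycle, s.
#' @param total_duration nominal cyclic-phase duration, s.
#' @param preload_duration duration of the seating/preload phase preceding
#'   the cycles, s (0 disables the phase).
#' @param ramp_bound advisory ramp-travel window, mm per 4 s.
#' @param force_bound advisory peak-force window, gram-force.
#' @return an object of class `loading_protocol`.
#' @export
loading_protocol <- function(preload_max = 0.5, indent_fraction = 0.20,
                             n_cycles = 5, cycle_period = 8,
                             total_duration = 40, preload_duration = 4,
                             ramp_bound = c(2, 4), force_bound = c(400, 600)) {
  if (indent_fraction <= 0 || indent_fraction >= 1)
    stop("'indent_fraction' must lie in (0, 1)", call. = FALSE)
  if (n_cycles < 1) stop("'n_cycles' must be >= 1", call. = FALSE)
  if (n_cycles * cycle_period > total_duration + 1e-6)
    stop("n_cycles * cycle_period exceeds total_duration", call. = FALSE)
  if (preload_duration < 0)
    stop("'preload_duration' must be >= 0", call. = FALSE)
  structure(list(preload_max = preload_max,
                 indent_fraction = indent_fraction,
                 n_cycles = n_cycles, cycle_period = cycle_period,
                 total_duration = total_duration,
                 preload_duration = preload_duration,
                 ramp_bound = ramp_bound, force_bound = force_bound),
            class = "loading_protocol")
}

#' Acquisition configuration for rendered recordings
#'
#' @param frame_rate M-mode frame rate, Hz (default 22.5).
#' @param force_rate force channel sampling rate, Hz (default 100).
#' @param rf_sampling RF depth sampling rate, MHz (default 40).
#' @param sound_speed assumed speed of sound, m/s (default 1540).
#' @param carrier_mhz pulse carrier (centre) frequency, MHz (default 12,
#'   matching the probe).
#' @param pulse_sigma Gaussian pulse envelope sigma, microseconds.
#' @param echo_snr echo signal-to-noise ratio in dB relative to the first
#'   interface peak; `Inf` renders noise-free.
#' @param force_noise_sd force sensor noise standard deviation, N.
#' @param load_cell_max load cell range, N; rendered force saturates here.
#' @param z1_mm depth of the transducer-skin interface echo, mm.
#' @param seed integer seed for the rendering noise stream.
#' @return an object of class `acquisition_config`.
#' @export
acquisition_config <- function(frame_rate = 22.5, force_rate = 100,
                               rf_sampling = 40, sound_speed = 1540,
                               carrier_mhz = 12, pulse_sigma = 0.1,
                               echo_snr = Inf, force_noise_sd = 0.005,
                               load_cell_max = 49, z1_mm = 10, seed = 1L) {
  for (nm in c("frame_rate", "force_rate", "rf_sampling"))
    stopifnot_scalar(get(nm), nm, positive = TRUE)
  structure(list(frame_rate = frame_rate, force_rate = force_rate,
                 rf_sampling = rf_sampling, sound_speed = sound_speed,
                 carrier_mhz = carrier_mhz, pulse_sigma = pulse_sigma,
                 echo_snr = echo_snr, force_noise_sd = force_noise_sd,
                 load_cell_max = load_cell_max,
                 z1_mm = z1_mm, seed = as.integer(seed)),
            class = "acquisition_config")
}

## Depth sample spacing in mm: one RF sample corresponds to c / (2 fs) of
## round-trip depth.
depth_step_mm <- function(config) {
  config$sound_speed / (2 * config$rf_sampling * 1e6) * 1e3
}

## Gaussian envelope sigma expressed in depth, mm.
pulse_sigma_mm <- function(config) {
  config$sound_speed * config$pulse_sigma * 1e-6 / 2 * 1e3
}

## Axial pulse resolution used for peak separation and overlap flagging, mm.
pulse_resolution_mm <- function(config) 4 * pulse_sigma_mm(config)
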