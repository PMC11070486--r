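#' Select the analysis cycles of a force-deformation curve
#'
#' Cyclic indentation tests of soft tissue conventionally discard the first
#' cycle as preconditioning and analyse the remainder. A single-cycle curve
#' is used verbatim with a warning.
#'
#' @param curve a `force_deformation_curve`.
#' @param drop_first drop the first labelled cycle (default TRUE).
#' @return integer vector of cycle labels to analyse.
#' @export
cycle_policy <- function(curve, drop_first = TRUE) {
  cycles <- sort(unique(curve$cycle[!is.na(curve$cycle)]))
  if (length(cycles) == 0)
    stop("curve has no labelled loading cycles", call. = FALSE)
  if (length(cycles) == 1) {
    warning("single-cycle curve: using it verbatim (no preconditioning cycle to discard)",
            call. = FALSE)
    return(cycles)
  }
  if (drop_first) cycles[-1] else cycles
}

#' Toe/heel/linear regional moduli from a force-deformation curve
#'
#' Segments the J-shaped response at the three target strain levels
#' (defaults 5%, 10% and 15% of the initial thickness: toe, heel and linear
#' regions). For each target strain, the effective Young's modulus is the
#' average of [effective_modulus()] over loading-phase samples whose strain
#' `w/h0` lies within `delta` of the target, computed per analysis cycle and
#' then averaged across cycles.
#'
#' @param curve a `force_deformation_curve` reaching at least the largest
#'   target strain.
#' @param geom an [indenter_geometry()].
#' @param strains target strain levels.
#' @param delta half-width of the strain averaging window.
#' @param h_convention thickness used inside the kappa correction:
#'   `"instantaneous"` (`h0 - w`, default) or `"initial"` (`h0`).
#' @param cycles cycle labels to analyse; defaults to [cycle_policy()].
#' @return an object of class `modulus_triplet`: list with `E1`, `E2`, `E3`
#'   (kPa), `strains`, `h0_mm` and the per-cycle values.
#' @export
regional_moduli <- function(curve, geom = indenter_geometry(),
                            strains = c(0.05, 0.10, 0.15), delta = 0.01,
                            h_convention = c("instantaneous", "initial"),
                            cycles = NULL) {
  h_convention <- match.arg(h_convention)
  h0 <- attr(curve, "h0_mm")
  if (is.null(h0) || h0 <= 0) stop("curve lacks a positive h0", call. = FALSE)
  eps <- curve$w_mm / h0
  if (max(eps, na.rm = TRUE) < max(strains) - delta)
    stop(sprintf(
      "insufficient strain: curve reaches %.1f%% but the largest target region needs %.1f%%",
      100 * max(eps, na.rm = TRUE), 100 * (max(strains) - delta)),
      call. = FALSE)
  if (is.null(cycles)) cycles <- cycle_policy(curve)

  per_cycle <- matrix(NA_real_, nrow = length(cycles),
                      ncol = length(strains),
                      dimnames = list(paste0("cycle", cycles),
                                      paste0("E", seq_along(strains))))
  for (ci in seq_along(cycles)) {
    seg <- which(curve$cycle == cycles[ci])
    if (!length(seg)) next
    loading <- seg[seq_len(which.max(curve$w_mm[seg]))]
    for (si in seq_along(strains)) {
      win <- loading[abs(eps[loading] - strains[si]) <= delta &
                       curve$w_mm[loading] > 0]
      if (!length(win)) next
      h <- if (h_convention == "instantaneous")
        h0 - curve$w_mm[win] else rep(h0, length(win))
      per_cycle[ci, si] <- mean(effective_modulus(
        curve$force_N[win], curve$w_mm[win], h, geom))
    }
  }
  E <- colMeans(per_cycle, na.rm = TRUE)
  if (any(!is.finite(E)))
    stop("empty strain window: no loading-phase samples near a target strain",
         call. = FALSE)
  structure(list(E1 = E[[1]], E2 = E[[2]], E3 = E[[3]],
                 strains = strains, h0_mm = h0, per_cycle = per_cycle),
            class = "modulus_triplet")
}

#' @export
print.modulus_triplet <- function(x, ...) {
  cat(sprintf(
    "Regional moduli (h0 = %.2f mm): E1 = %.1f, E2 = %.1f, E3 = %.1f kPa\n",
    x$h0_mm, x$E1, x$E2, x$E3))
  invisible(x)
}

#' Analyse a rendered recording into thickness and regional moduli
#'
#' Runs the echo-processing chain (interface detection, thickness series,
#' preload thickness, synchronization) followed by the regional modulus
#' segmentation.
#'
#' @param recording an `indentation_recording`.
#' @param geom an [indenter_geometry()].
#' @param contact_threshold contact force for the preload window, N.
#' @param ... passed to [regional_moduli()].
#' @return list with elements `h0_mm`, `triplet`, `curve`, `interfaces`.
#' @export
analyze_recording <- function(recording, geom = indenter_geometry(),
                              contact_threshold = 0.1, ...) {
  ifc <- detect_interfaces(recording)
  ser <- thickness_series(ifc)
  h0 <- initial_thickness(ser, recording$force$times,
                          recording$force$force_N,
                          contact_threshold = contact_threshold,
                          preload_max = recording$protocol$preload_max %||% 0.5)
  curve <- synchronize(ser, recording$force$times, recording$force$force_N,
                       h0 = h0)
  trip <- regional_moduli(curve, geom = geom, ...)
  list(h0_mm = h0, triplet = trip, curve = curve, interfaces = ifc)
}

#' Simulate and analyse one ground-truth subject
#'
#' Convenience wrapper joining the forward simulator to the analysis chain.
#' `mode = "full"` renders M-mode frames and recovers thickness by echo
#' tracking; `mode = "fast"` reads the deformation channel directly off the
#' trajectory (no acquisition emulation), for large calibration runs.
#'
#' @param truth a [tissue_ground_truth()].
#' @param protocol a [loading_protocol()].
#' @param config an [acquisition_config()] (used in full mode).
#' @param geom an [indenter_geometry()].
#' @param mode `"full"` or `"fast"`.
#' @param sim_rate forward-simulation rate, Hz.
#' @param ... passed to [regional_moduli()].
#' @return list with `h0_mm` and `triplet`.
#' @export
analyze_subject <- function(truth, protocol = loading_protocol(),
                            config = acquisition_config(),
                            geom = indenter_geometry(),
                            mode = c("full", "fast"), sim_rate = 100, ...) {
  mode <- match.arg(mode)
  traj <- simulate_indentation(truth, protocol, geom, sim_rate = sim_rate)
  if (mode == "full") {
    rec <- render_recording(traj, config)
    res <- analyze_recording(rec, geom = geom, ...)
    list(h0_mm = res$h0_mm, triplet = res$triplet)
  } else {
    curve <- curve_from_trajectory(traj, frame_rate = config$frame_rate)
    trip <- regional_moduli(curve, geom = geom, ...)
    list(h0_mm = attr(traj, "h0_mm"), triplet = trip)
  }
}
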