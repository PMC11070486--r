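## Echo processing: recover interface depths, thickness and deformation from
## M-mode frames and synchronize them with the force channel.

## Envelope of each frame (columns) as the magnitude of the analytic signal.
frame_envelope <- function(amp) {
  n <- nrow(amp)
  H <- numeric(n)
  if (n %% 2 == 0) {
    H[c(1, n / 2 + 1)] <- 1
    H[2:(n / 2)] <- 2
  } else {
    H[1] <- 1
    H[2:((n + 1) / 2)] <- 2
  }
  A <- stats::mvfft(amp) * H
  Mod(stats::mvfft(A, inverse = TRUE)) / n
}

## Sub-sample peak refinement: parabolic fit on the log-envelope (exact for
## a Gaussian envelope).
refine_peak <- function(env, idx, dz) {
  n <- length(env)
  if (idx <= 1 || idx >= n) return(0)
  l <- log(pmax(env[(idx - 1):(idx + 1)], .Machine$double.xmin))
  den <- l[1] - 2 * l[2] + l[3]
  if (!is.finite(den) || den >= 0) return(0)
  delta <- 0.5 * (l[1] - l[3]) / den
  if (abs(delta) > 1) 0 else delta * dz
}

#' Detect the two echo interfaces in every frame
#'
#' For each M-mode frame, locates the two largest envelope peaks separated
#' by at least the axial pulse resolution. The shallower peak is the
#' transducer-skin interface (`z1`), the deeper one the tissue-bone
#' interface (`z2`). Peak depths are refined to sub-sample precision by a
#' parabolic fit on the log-envelope. Frames in which a second resolvable
#' peak cannot be found (amplitude below `min_ratio` of the primary peak)
#' are marked rejected rather than interpolated.
#'
#' @param recording an `indentation_recording`.
#' @param min_ratio minimum secondary/primary envelope peak amplitude for a
#'   frame to be accepted.
#' @param max_reject_frac maximum tolerated fraction of rejected frames
#'   before the whole recording is rejected with an error.
#' @return a data frame of class `echo_interfaces` with columns `time_s`,
#'   `z1_mm`, `z2_mm`, `confidence`, `accepted`.
#' @export
detect_interfaces <- function(recording, min_ratio = 0.25,
                              max_reject_frac = 0.20) {
  fr <- recording$frames
  if (length(fr$times) < 1) stop("recording has no frames", call. = FALSE)
  dzv <- diff(fr$depth_mm)
  if (max(abs(dzv - dzv[1])) > 1e-9)
    stop("depth axis must be uniform", call. = FALSE)
  dz <- dzv[1]
  sep <- max(1L, ceiling(pulse_resolution_mm(recording$config) / dz))

  env <- frame_envelope(recording$frames$amplitude)
  n_frames <- ncol(env)
  z1 <- z2 <- conf <- rep(NA_real_, n_frames)
  accepted <- logical(n_frames)
  for (k in seq_len(n_frames)) {
    e <- env[, k]
    i1 <- which.max(e)
    a1 <- e[i1]
    if (!is.finite(a1) || a1 <= 0) next
    masked <- e
    masked[max(1, i1 - sep):min(length(e), i1 + sep)] <- -Inf
    i2 <- which.max(masked)
    a2 <- masked[i2]
    if (!is.finite(a2) || a2 < min_ratio * a1) next
    p1 <- fr$depth_mm[i1] + refine_peak(e, i1, dz)
    p2 <- fr$depth_mm[i2] + refine_peak(e, i2, dz)
    z1[k] <- min(p1, p2)
    z2[k] <- max(p1, p2)
    conf[k] <- min(a1, a2) / max(a1, a2)
    accepted[k] <- TRUE
  }
  if (mean(!accepted) > max_reject_frac)
    stop(sprintf(
      "recording rejected: %.0f%% of frames lack two resolvable echo peaks (tolerance %.0f%%)",
      100 * mean(!accepted), 100 * max_reject_frac), call. = FALSE)
  structure(data.frame(time_s = fr$times, z1_mm = z1, z2_mm = z2,
                       confidence = conf, accepted = accepted),
            class = c("echo_interfaces", "data.frame"),
            config = recording$config)
}

#' Tissue thickness series from detected interfaces
#'
#' Thickness is the depth separation of the two echoes, `z2 - z1`, per
#' accepted frame. Rejected frames are excluded, never interpolated.
#'
#' @param interfaces an `echo_interfaces` data frame.
#' @return a data frame of class `thickness_series` with columns `time_s`,
#'   `thickness_mm`.
#' @export
thickness_series <- function(interfaces) {
  keep <- interfaces$accepted
  if (!any(keep)) stop("all frames rejected", call. = FALSE)
  th <- interfaces$z2_mm[keep] - interfaces$z1_mm[keep]
  if (any(th <= 0))
    stop("invariant breach: z2 <= z1 in an accepted frame", call. = FALSE)
  structure(data.frame(time_s = interfaces$time_s[keep], thickness_mm = th),
            class = c("thickness_series", "data.frame"),
            config = attr(interfaces, "config"))
}

#' Initial (preload) tissue thickness
#'
#' The initial thickness `h0` is the mean thickness over the preload
#' window: after contact (force at or above `contact_threshold`) and before
#' the force first reaches the preload ceiling `preload_max`.
#'
#' @param series a `thickness_series`.
#' @param force_times,force_N the force channel.
#' @param contact_threshold contact detection force, N.
#' @param preload_max preload ceiling, N.
#' @return `h0` in mm.
#' @export
initial_thickness <- function(series, force_times, force_N,
                              contact_threshold = 0.1, preload_max = 0.5) {
  f <- stats::approx(force_times, force_N, xout = series$time_s,
                     rule = 1)$y
  ## first contiguous contact episode: the preload application itself, not
  ## the sub-0.5 N portion of the first loading ramp
  idx <- which(f >= contact_threshold & !is.na(f))
  if (length(idx)) {
    run1 <- idx[cumsum(c(1L, diff(idx) != 1L)) == 1L]
    in_window <- run1[f[run1] < preload_max]
  } else in_window <- integer(0)
  if (!length(in_window))
    stop("no preload window: no samples with force in [contact_threshold, preload_max) before loading",
         call. = FALSE)
  mean(series$thickness_mm[in_window])
}

new_curve <- function(time_s, w_mm, force_N, h0) {
  if (any(!is.finite(force_N)))
    stop("force values must be finite", call. = FALSE)
  ## negative excursions are sensor noise around true contact forces >= 0
  w_mm <- pmax(w_mm, 0)
  force_N <- pmax(force_N, 0)
  cyc <- label_cycles(force_N, w_mm)
  structure(data.frame(time_s = time_s, w_mm = w_mm, force_N = force_N,
                       cycle = cyc),
            class = c("force_deformation_curve", "data.frame"),
            h0_mm = h0)
}

## Cycle segmentation: contiguous runs above a small force floor are split
## at force minima (the force channel is the faster, cleaner channel); a
## run qualifies as a loading-cycle core when its deformation reaches at
## least half the global peak, which excludes the seating/preload episode
## regardless of how soft the subject is. Below-floor shoulder samples
## (the low-strain start and end of each cycle, where a strongly J-shaped
## subject transmits almost no force) are attached to the nearest core;
## unqualified above-floor runs stay unlabelled.
label_cycles <- function(force, w = NULL) {
  mx <- max(force, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) return(rep(NA_integer_, length(force)))
  lo <- 0.02 * mx
  active <- force > lo & !is.na(force)
  r <- rle(active)
  lab <- rep(NA_integer_, length(force))
  blocked <- logical(length(force))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  w_mx <- if (!is.null(w)) suppressWarnings(max(w, na.rm = TRUE)) else -Inf
  use_w <- is.finite(w_mx) && w_mx > 0
  core <- list()
  k <- 0L
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    seg <- starts[j]:ends[j]
    qual <- if (use_w) max(w[seg]) >= 0.5 * w_mx
            else max(force[seg]) >= 0.5 * mx
    if (qual) {
      k <- k + 1L
      lab[seg] <- k
      core[[k]] <- range(seg)
    } else blocked[seg] <- TRUE
  }
  if (k == 0L) return(lab)
  un <- which(is.na(lab) & !blocked)
  if (length(un)) {
    dist <- vapply(core, function(rg)
      pmax(rg[1] - un, un - rg[2], 0L), integer(length(un)))
    dist <- matrix(dist, nrow = length(un))
    lab[un] <- max.col(-dist, ties.method = "first")
  }
  lab
}

#' Synchronize thickness and force channels into a force-deformation curve
#'
#' The force channel (fast, 100 Hz) is linearly interpolated onto the frame
#' times of the thickness series (slow, 22.5 Hz); deformation is
#' `w = h0 - thickness`. Loading cycles are labelled from the force channel
#' by segmenting at force minima; sub-preload segments are left unlabelled.
#'
#' @param series a `thickness_series`.
#' @param force_times,force_N the force channel.
#' @param h0 initial thickness in mm; computed by [initial_thickness()] when
#'   `NULL`.
#' @param ... passed to [initial_thickness()].
#' @return a data frame of class `force_deformation_curve` with columns
#'   `time_s`, `w_mm`, `force_N`, `cycle`, and attribute `h0_mm`.
#' @export
synchronize <- function(series, force_times, force_N, h0 = NULL, ...) {
  if (is.unsorted(series$time_s, strictly = TRUE) ||
      is.unsorted(force_times, strictly = TRUE))
    stop("time stamps must be strictly increasing", call. = FALSE)
  if (is.null(h0))
    h0 <- initial_thickness(series, force_times, force_N, ...)
  keep <- series$time_s >= min(force_times) & series$time_s <= max(force_times)
  t <- series$time_s[keep]
  f <- stats::approx(force_times, force_N, xout = t)$y
  new_curve(t, h0 - series$thickness_mm[keep], f, h0)
}
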