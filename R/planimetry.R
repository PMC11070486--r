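#' Scar area by reference-object planimetry
#'
#' Converts a pixel count of the segmented scar region into physical area
#' using a reference object of known area (conventionally a 20 mm^2 tape
#' placed beside the scar) segmented in the same image:
#' `area = scar_pixels * ref_area / ref_pixels`.
#'
#' @param scar_pixels pixel count of the scar region (>= 0).
#' @param ref_pixels pixel count of the reference object (> 0).
#' @param ref_area physical area of the reference object, mm^2 (> 0).
#' @return scar area in mm^2.
#' @export
#' @examples
#' scar_area_from_reference(1500, 200, 20)  # 150 mm^2
scar_area_from_reference <- function(scar_pixels, ref_pixels, ref_area = 20) {
  if (any(ref_pixels <= 0)) stop("'ref_pixels' must be > 0", call. = FALSE)
  if (any(ref_area <= 0)) stop("'ref_area' must be > 0", call. = FALSE)
  if (any(scar_pixels < 0)) stop("'scar_pixels' must be >= 0", call. = FALSE)
  scar_pixels * ref_area / ref_pixels
}

#' Check a measured curve against the protocol compliance windows
#'
#' Advisory check of the clinical acquisition windows: ramp travel of
#' 2-4 mm per 4 s and peak response force of 400-600 gram-force
#' (3.92-5.88 N). Out-of-window runs are flagged, never rejected.
#'
#' @param protocol a [loading_protocol()] carrying the windows.
#' @param curve a `force_deformation_curve`.
#' @return list with `ramp_mm_per_4s`, `peak_gram_force`, logical flags
#'   `ramp_ok`, `force_ok`, and `compliant`.
#' @export
validate_protocol <- function(protocol, curve) {
  if (!nrow(curve)) stop("empty curve", call. = FALSE)
  cycles <- sort(unique(curve$cycle[!is.na(curve$cycle)]))
  ramp <- NA_real_
  if (length(cycles)) {
    rates <- vapply(cycles, function(cy) {
      seg <- which(curve$cycle == cy)
      up <- seg[seq_len(which.max(curve$w_mm[seg]))]
      if (length(up) < 2) return(NA_real_)
      dt <- curve$time_s[up[length(up)]] - curve$time_s[up[1]]
      if (dt <= 0) return(NA_real_)
      (max(curve$w_mm[up]) - min(curve$w_mm[up])) / dt * 4
    }, 0)
    ramp <- mean(rates, na.rm = TRUE)
  }
  peak_gf <- max(curve$force_N, na.rm = TRUE) / GRAM_FORCE_N
  ramp_ok <- !is.na(ramp) && ramp >= protocol$ramp_bound[1] &&
    ramp <= protocol$ramp_bound[2]
  force_ok <- peak_gf >= protocol$force_bound[1] &&
    peak_gf <= protocol$force_bound[2]
  list(ramp_mm_per_4s = ramp, peak_gram_force = peak_gf,
       ramp_ok = ramp_ok, force_ok = force_ok,
       compliant = ramp_ok && force_ok)
}
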