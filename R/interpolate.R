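#' Interpolate a joint-angle series
#'
#' Piecewise-linear interpolation per angle over its defined samples, used to
#' animate in-between frames and to bridge undefined gaps left by missing
#' joints. Defined samples are preserved exactly; interior `NA` runs are
#' bridged linearly and flagged; samples outside an angle's first/last
#' defined timestamps stay `NA`.
#'
#' @param angles a `joint_angles` object.
#' @param target_rate output frame rate in Hz (default: the input rate, i.e.
#'   gap bridging only).
#' @param factor alternatively, an integer upsampling factor.
#' @return A `joint_angles` object at the target rate; the logical matrix of
#'   bridged/interpolated entries is attached as attribute
#'   `"interpolated"`.
#' @export
interpolate_angles <- function(angles, target_rate = NULL, factor = NULL) {
  if (!inherits(angles, "joint_angles"))
    .stopf("angles must be a joint_angles object")
  a <- angles$angles
  if (nrow(a) < 2L) .stopf("interpolation needs at least two frames")
  if (!is.null(factor)) {
    if (factor < 1) .stopf("factor must be >= 1")
    target_rate <- angles$frame_rate * factor
  }
  if (is.null(target_rate)) target_rate <- angles$frame_rate
  t0 <- a$timestamp[1L]; t1 <- a$timestamp[nrow(a)]
  tt <- seq(t0, t1, by = 1 / target_rate)
  # keep the exact endpoint
  if (abs(tt[length(tt)] - t1) > 1e-12) tt <- c(tt, t1)
  out <- matrix(NA_real_, length(tt), length(.ANGLE_NAMES),
                dimnames = list(NULL, .ANGLE_NAMES))
  interp_flag <- matrix(FALSE, length(tt), length(.ANGLE_NAMES),
                        dimnames = list(NULL, .ANGLE_NAMES))
  for (nm in .ANGLE_NAMES) {
    y <- a[[nm]]
    def <- !is.na(y)
    if (sum(def) == 0L)
      .stopf("angle '%s' has no defined samples; cannot interpolate", nm)
    if (sum(def) == 1L) {
      k <- which.min(abs(tt - a$timestamp[def]))
      out[k, nm] <- y[def]
      next
    }
    yi <- stats::approx(a$timestamp[def], y[def], xout = tt,
                        method = "linear", rule = 1)$y
    out[, nm] <- yi
    # exact preservation of defined input samples landing on output stamps
    hit <- match(round(a$timestamp[def], 12), round(tt, 12))
    ok <- !is.na(hit)
    out[hit[ok], nm] <- y[def][ok]
    interp_flag[, nm] <- !is.na(yi)
    interp_flag[hit[ok], nm] <- FALSE
  }
  adf <- data.frame(frame = seq_along(tt) - 1L, timestamp = tt, out)
  res <- structure(list(angles = adf, frame_rate = target_rate,
                        global_up = angles$global_up),
                   class = "joint_angles")
  attr(res, "interpolated") <- interp_flag
  res
}
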