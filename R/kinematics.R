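#' @title Vector-geometry helpers for angle extraction
#' @description
#' The anatomical joint angles are resolved from skeleton coordinates through
#' three primitive operations: projecting a vector onto a plane, measuring the
#' unsigned angle between two vectors, and testing whether a vector lies in
#' the convex cone spanned by two others (the betweenness test that decides
#' the sign of an angle). These primitives are exported because the whole
#' extraction geometry is built out of them.
#' @name kinematics-helpers
NULL

#' Project a vector onto a plane
#'
#' Removes from `v` its component along the plane normal, returning the
#' in-plane part. The result is perpendicular to `normal`, and `v - result`
#' is parallel to `normal`.
#'
#' @param v numeric 3-vector.
#' @param normal plane normal (need not be unit length, but its norm must
#'   exceed `tol`).
#' @param tol singularity tolerance on the normal's norm (meters).
#' @return The projected 3-vector.
#' @rdname kinematics-helpers
#' @export
project_onto_plane <- function(v, normal, tol = 1e-8) {
  if (!.is_pos3(v) || !is.numeric(normal) || length(normal) != 3L)
    .stopf("v and normal must be numeric 3-vectors")
  nhat <- .vunit(normal, tol)
  if (is.null(nhat)) .stopf("plane normal is numerically zero (norm < %g)", tol)
  v - sum(v * nhat) * nhat
}

#' Unsigned angle between two vectors, in degrees
#'
#' Computed as `atan2(|u x v|, u . v)`, which is exact for exactly collinear
#' inputs (0 or 180 degrees) and equivalent to the arccos of the clamped
#' normalized dot product everywhere else.
#'
#' @param u,v numeric 3-vectors, both nonzero.
#' @param tol singularity tolerance on the input norms.
#' @return Angle in `[0, 180]` degrees.
#' @rdname kinematics-helpers
#' @export
angle_between <- function(u, v, tol = 1e-8) {
  if (!is.numeric(u) || length(u) != 3L || !is.numeric(v) || length(v) != 3L)
    .stopf("u and v must be numeric 3-vectors")
  if (.vnorm(u) < tol || .vnorm(v) < tol)
    .stopf("angle between vectors is undefined for a (near-)zero vector")
  atan2(.vnorm(.vcross(u, v)), sum(u * v)) * .DEG
}

#' Test whether a vector lies between two others
#'
#' `v` lies between `a` and `b` when it belongs to the closed convex cone they
#' span, i.e. `angle(a,v) + angle(v,b) = angle(a,b)` up to tolerance. All
#' three vectors must be coplanar; a non-coplanar input beyond tolerance is a
#' domain error.
#'
#' @param v,a,b numeric 3-vectors, nonzero and coplanar.
#' @param tol angular tolerance in degrees for the cone test, and relative
#'   tolerance for the coplanarity check.
#' @return Logical scalar.
#' @rdname kinematics-helpers
#' @export
lies_between <- function(v, a, b, tol = 1e-6) {
  n <- .vcross(a, b)
  nn <- .vnorm(n)
  if (nn > 1e-12 * .vnorm(a) * .vnorm(b)) {
    # well-defined plane: v must lie in it
    if (abs(sum(v * n)) > tol * .vnorm(v) * nn)
      .stopf("lies_between: vectors are not coplanar within tolerance")
  }
  abs(angle_between(a, v) + angle_between(v, b) - angle_between(a, b)) <= tol
}

# internal closed-cone sign test without the coplanarity guard (inputs are
# constructed in-plane); TRUE means the extracted angle is made negative.
.neg_side <- function(x, marker, ref, tol = 1e-6) {
  s1 <- abs(angle_between(marker, x) + angle_between(x, ref) -
              angle_between(marker, ref)) <= tol
  if (s1) return(TRUE)
  abs(angle_between(marker, x) + angle_between(x, -ref) -
        angle_between(marker, -ref)) <= tol
}

.wrap180 <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a <= -180, a + 360, a)
}

# ---- anatomical reference frames ------------------------------------------

.pos <- function(frame, id) frame$positions[id + 1L, ]
.obs <- function(frame, ids) !any(frame$missing[ids + 1L])

# side-specific joint ids
.arm_ids <- function(side) {
  if (side == "right") c(shoulder = 2L, elbow = 3L, wrist = 4L)
  else c(shoulder = 5L, elbow = 6L, wrist = 7L)
}
.leg_ids <- function(side) {
  if (side == "right") c(hip = 8L, knee = 9L, ankle = 10L)
  else c(hip = 11L, knee = 12L, ankle = 13L)
}

# Upper-body references for one side: unit lateral axis (pointing away from
# the body on that side; for the right side this is the Left-to-Right
# Shoulder direction), unit Chest-to-Pelvis, and the side's forward-facing
# direction lat x down. NULL when a needed joint is missing or degenerate.
.upper_refs <- function(frame, side, tol = 1e-8) {
  if (!.obs(frame, c(1L, 2L, 5L, 8L, 11L))) return(NULL)
  pelvis <- (.pos(frame, 8L) + .pos(frame, 11L)) / 2
  chest <- .pos(frame, 1L)
  l2r <- .pos(frame, 2L) - .pos(frame, 5L)
  lat <- .vunit(if (side == "right") l2r else -l2r, tol)
  down <- .vunit(pelvis - chest, tol)
  if (is.null(lat) || is.null(down)) return(NULL)
  fwd <- .vunit(.vcross(lat, down), tol)
  if (is.null(fwd)) return(NULL)  # shoulder line parallel to torso axis
  list(lat = lat, down = down, fwd = fwd, pelvis = pelvis, chest = chest)
}

# Lower-body references: unit lateral hip axis per side, global down, and the
# lower-body forward-facing direction (Right-to-Left Hip x Global Up for the
# right side, mirrored for the left).
.lower_refs <- function(frame, side, global_up = c(0, -1, 0), tol = 1e-8) {
  if (!.obs(frame, c(8L, 11L))) return(NULL)
  l2r <- .pos(frame, 8L) - .pos(frame, 11L)
  lat <- .vunit(if (side == "right") l2r else -l2r, tol)
  down <- .vunit(-global_up, tol)
  if (is.null(lat) || is.null(down)) return(NULL)
  fwd <- .vunit(.vcross(lat, down), tol)
  if (is.null(fwd)) return(NULL)  # hip line parallel to global up
  list(lat = lat, down = down, fwd = fwd)
}

# Signed in-plane angle of `seg` measured in the plane perpendicular to
# `fwd`, from the (possibly oblique) in-plane reference `lat`, negative on
# the closed `down` side: the abduction/adduction-style construction shared
# by the shoulder and hip y-angles.
.y_angle <- function(seg, refs, tol = 1e-8) {
  yproj <- seg - sum(seg * refs$fwd) * refs$fwd
  if (.vnorm(yproj) < tol) return(NA_real_)
  m <- angle_between(yproj, refs$lat)
  if (.neg_side(yproj, refs$down, refs$lat)) -m else m
}

# z-angle: plane perpendicular to `down`, reference = projected lateral axis,
# negative on the closed forward side.
.z_angle <- function(seg, refs, tol = 1e-8) {
  zproj <- seg - sum(seg * refs$down) * refs$down
  latp <- refs$lat - sum(refs$lat * refs$down) * refs$down
  if (.vnorm(zproj) < tol || .vnorm(latp) < tol) return(NA_real_)
  m <- angle_between(zproj, latp)
  if (.neg_side(zproj, refs$fwd, latp)) -m else m
}

# Twist (x) angle about the limb axis `d` (unit, proximal->distal): the
# distal segment `seg2` is projected onto the plane perpendicular to `d` and
# measured against the projected reference direction `refdir`, negative on
# the closed side of the cross-product marker cross(ref_projected, -d) (the
# shoulder's Cross-Elbow) or cross(-d, ref_projected) (the hip's Cross-Knee),
# selected by `marker_order`.
.x_angle <- function(seg2, d, refdir, marker_order = c("ref_first", "d_first"),
                     tol = 1e-8) {
  marker_order <- match.arg(marker_order)
  u <- refdir - sum(refdir * d) * d
  un <- .vunit(u, tol)
  if (is.null(un)) return(NA_real_)   # limb parallel to the reference
  xproj <- seg2 - sum(seg2 * d) * d
  if (.vnorm(xproj) < tol) return(NA_real_)  # straight elbow/knee: no twist
  w <- if (marker_order == "ref_first") .vcross(un, -d) else .vcross(-d, un)
  m <- angle_between(xproj, un)
  if (.neg_side(xproj, w, un)) -m else m
}

# ---- per-frame angle operations -------------------------------------------

#' Shoulder joint angles
#'
#' Resolves the three Euler-style rotations of one shoulder from skeleton
#' coordinates. The x-angle is the circumduction/twist about the upper-arm
#' axis, revealed by the forearm: the elbow-to-wrist vector is projected onto
#' the plane normal to the shoulder-to-elbow vector and measured against the
#' projected forward-facing direction, with the sign decided by the
#' betweenness test against the Cross-Elbow reference. The y-angle
#' (abduction/adduction) measures the shoulder-to-elbow vector in the plane
#' normal to the forward-facing vector against the lateral shoulder axis;
#' the z-angle (flexion/extension) measures it in the plane normal to the
#' chest-to-pelvis vector. The forward-facing vector is the cross product of
#' the left-to-right shoulder vector and the chest-to-pelvis vector; the left
#' side mirrors the lateral axis (and with it the forward reference).
#'
#' @param frame a `skel_frame`.
#' @param side `"right"` or `"left"`.
#' @return Named numeric vector `c(x=, y=, z=)` in degrees; angles whose
#'   construction is singular for the pose (for example the twist of a
#'   straight arm) are `NA`.
#' @export
shoulder_angles <- function(frame, side = c("right", "left")) {
  side <- match.arg(side)
  out <- c(x = NA_real_, y = NA_real_, z = NA_real_)
  refs <- .upper_refs(frame, side)
  if (is.null(refs)) return(out)
  ids <- .arm_ids(side)
  if (!.obs(frame, ids[["elbow"]])) return(out)
  se <- .pos(frame, ids[["elbow"]]) - .pos(frame, ids[["shoulder"]])
  d <- .vunit(se)
  if (is.null(d)) return(out)
  out["y"] <- .y_angle(se, refs)
  out["z"] <- .z_angle(se, refs)
  if (.obs(frame, ids[["wrist"]])) {
    ew <- .pos(frame, ids[["wrist"]]) - .pos(frame, ids[["elbow"]])
    out["x"] <- .x_angle(ew, d, refs$fwd, "ref_first")
  }
  out
}

#' Hip joint angles
#'
#' Mirrors the shoulder construction on the hip chain. The lower-body
#' forward-facing vector is the cross product of the right-to-left hip vector
#' and global up (the negated camera y-axis). The x-angle (internal/external
#' thigh rotation) projects the knee-to-ankle vector onto the plane normal to
#' the hip-to-knee vector and measures it against the Backwards-Facing
#' x-Projection (the projected negative forward vector), with the sign
#' decided against the Cross-Knee reference. The y- and z-angles measure the
#' hip-to-knee vector against the lateral hip axis in the planes normal to
#' the forward vector and to global down respectively.
#'
#' @inheritParams shoulder_angles
#' @param global_up world up direction (default `c(0,-1,0)`, i.e. negative
#'   camera y).
#' @return Named numeric vector `c(x=, y=, z=)` in degrees (`NA` when
#'   singular, e.g. the twist of a straight knee).
#' @export
hip_angles <- function(frame, side = c("right", "left"),
                       global_up = c(0, -1, 0)) {
  side <- match.arg(side)
  out <- c(x = NA_real_, y = NA_real_, z = NA_real_)
  refs <- .lower_refs(frame, side, global_up)
  if (is.null(refs)) return(out)
  ids <- .leg_ids(side)
  if (!.obs(frame, ids[["knee"]])) return(out)
  hk <- .pos(frame, ids[["knee"]]) - .pos(frame, ids[["hip"]])
  t <- .vunit(hk)
  if (is.null(t)) return(out)
  out["y"] <- .y_angle(hk, refs)
  out["z"] <- .z_angle(hk, refs)
  if (.obs(frame, ids[["ankle"]])) {
    ka <- .pos(frame, ids[["ankle"]]) - .pos(frame, ids[["knee"]])
    out["x"] <- .x_angle(ka, t, -refs$fwd, "d_first")
  }
  out
}

#' Elbow flexion angle
#'
#' The revolute elbow angle is the unsigned angle between the elbow-to-
#' shoulder and elbow-to-wrist vectors: 180 degrees for a straight arm.
#'
#' @inheritParams shoulder_angles
#' @return Angle in degrees in `[0, 180]`, `NA` when a needed joint is
#'   missing or joints coincide.
#' @export
elbow_angle <- function(frame, side = c("right", "left")) {
  side <- match.arg(side)
  ids <- .arm_ids(side)
  if (!.obs(frame, ids)) return(NA_real_)
  u <- .pos(frame, ids[["shoulder"]]) - .pos(frame, ids[["elbow"]])
  v <- .pos(frame, ids[["wrist"]]) - .pos(frame, ids[["elbow"]])
  if (.vnorm(u) < 1e-8 || .vnorm(v) < 1e-8) return(NA_real_)
  angle_between(u, v)
}

#' Knee flexion angle
#'
#' The revolute knee angle: unsigned angle between the knee-to-hip and
#' knee-to-ankle vectors (180 degrees for a straight leg).
#'
#' @inheritParams shoulder_angles
#' @return Angle in degrees in `[0, 180]`, or `NA`.
#' @export
knee_angle <- function(frame, side = c("right", "left")) {
  side <- match.arg(side)
  ids <- .leg_ids(side)
  if (!.obs(frame, ids)) return(NA_real_)
  u <- .pos(frame, ids[["hip"]]) - .pos(frame, ids[["knee"]])
  v <- .pos(frame, ids[["ankle"]]) - .pos(frame, ids[["knee"]])
  if (.vnorm(u) < 1e-8 || .vnorm(v) < 1e-8) return(NA_real_)
  angle_between(u, v)
}

#' Vertebral column angles
#'
#' The x-angle (axial twist) is the signed angle, in the horizontal plane
#' (normal = global up), between the projected right-to-left shoulder vector
#' and the projected right-to-left hip vector; positive when the left
#' shoulder rotates toward the forward-facing direction. The z-angle
#' (flexion/extension) is the signed angle between the pelvis-to-chest vector
#' projected onto the plane normal to the projected hip line and global up;
#' positive for a forward bend. An upright untwisted pose gives (0, 0).
#'
#' @inheritParams hip_angles
#' @return Named numeric vector `c(x=, z=)` in degrees (`NA` when singular,
#'   e.g. shoulder or hip line parallel to global up).
#' @export
spine_angles <- function(frame, global_up = c(0, -1, 0)) {
  out <- c(x = NA_real_, z = NA_real_)
  if (!.obs(frame, c(1L, 2L, 5L, 8L, 11L))) return(out)
  gup <- .vunit(global_up)
  if (is.null(gup)) .stopf("global_up must be a nonzero 3-vector")
  r2l_sh <- .pos(frame, 5L) - .pos(frame, 2L)
  r2l_hip <- .pos(frame, 11L) - .pos(frame, 8L)
  pelvis <- (.pos(frame, 8L) + .pos(frame, 11L)) / 2
  p2c <- .pos(frame, 1L) - pelvis
  hipp <- r2l_hip - sum(r2l_hip * gup) * gup
  u <- .vunit(hipp)
  if (is.null(u)) return(out)
  ff <- .vunit(.vcross(r2l_hip, gup))
  if (is.null(ff)) return(out)
  # axial twist: projected shoulder line vs projected hip line
  shp <- r2l_sh - sum(r2l_sh * gup) * gup
  if (.vnorm(shp) >= 1e-8)
    out["x"] <- atan2(sum(shp * ff), sum(shp * u)) * .DEG
  # forward bend: torso axis vs global up in the sagittal plane
  zproj <- p2c - sum(p2c * u) * u
  if (.vnorm(zproj) >= 1e-8)
    out["z"] <- atan2(sum(zproj * ff), sum(zproj * gup)) * .DEG
  out
}

# ---- sequence-level extraction --------------------------------------------

.ANGLE_NAMES <- c("shoulder_right_x", "shoulder_right_y", "shoulder_right_z",
                  "shoulder_left_x", "shoulder_left_y", "shoulder_left_z",
                  "hip_right_x", "hip_right_y", "hip_right_z",
                  "hip_left_x", "hip_left_y", "hip_left_z",
                  "elbow_right", "elbow_left", "knee_right", "knee_left",
                  "spine_x", "spine_z")

# all 18 angles of one frame as a named vector (NA = undefined)
frame_angles <- function(frame, global_up = c(0, -1, 0)) {
  sr <- shoulder_angles(frame, "right"); sl <- shoulder_angles(frame, "left")
  hr <- hip_angles(frame, "right", global_up)
  hl <- hip_angles(frame, "left", global_up)
  sp <- spine_angles(frame, global_up)
  stats::setNames(
    c(sr, sl, hr, hl,
      elbow_angle(frame, "right"), elbow_angle(frame, "left"),
      knee_angle(frame, "right"), knee_angle(frame, "left"),
      sp),
    .ANGLE_NAMES)
}

#' Extract the anatomical joint-angle series of a sequence
#'
#' Runs the full angle extraction (shoulders, hips, elbows, knees, vertebral
#' column) over every frame of a skeleton sequence. Angles whose construction
#' needs a missing joint, or that are singular for the pose, are emitted as
#' `NA` (flagged, never silently zero).
#'
#' @param sequence a `skel_sequence` (normally the repaired output of
#'   [skeleton_repair()]).
#' @param global_up world up direction, default the negated camera y-axis.
#' @return An object of class `joint_angles`: list with `angles` (data frame
#'   with columns `frame`, `timestamp` and the 18 angle columns, degrees) and
#'   `frame_rate`.
#' @seealso [shoulder_angles()], [hip_angles()], [elbow_angle()],
#'   [knee_angle()], [spine_angles()]
#' @export
joint_angles <- function(sequence, global_up = c(0, -1, 0)) {
  if (!inherits(sequence, "skel_sequence"))
    .stopf("sequence must be a skel_sequence")
  rows <- lapply(sequence$frames, function(f)
    c(frame = f$frame_index, timestamp = f$timestamp,
      frame_angles(f, global_up)))
  df <- as.data.frame(do.call(rbind, rows))
  structure(list(angles = df, frame_rate = sequence$frame_rate,
                 global_up = global_up),
            class = "joint_angles")
}

#' @export
print.joint_angles <- function(x, ...) {
  n <- nrow(x$angles)
  nund <- sum(is.na(x$angles[, .ANGLE_NAMES]))
  cat(sprintf("joint-angle series: %d frames x %d angles (%d undefined entries)\n",
              n, length(.ANGLE_NAMES), nund))
  invisible(x)
}

#' @export
summary.joint_angles <- function(object, ...) {
  a <- object$angles[, .ANGLE_NAMES, drop = FALSE]
  s <- data.frame(angle = .ANGLE_NAMES,
                  min = suppressWarnings(apply(a, 2L, min, na.rm = TRUE)),
                  mean = colMeans(a, na.rm = TRUE),
                  max = suppressWarnings(apply(a, 2L, max, na.rm = TRUE)),
                  undefined = colSums(is.na(a)),
                  row.names = NULL)
  class(s) <- c("summary.joint_angles", "data.frame")
  s
}

#' @export
as.data.frame.joint_angles <- function(x, ...) x$angles

#' @export
plot.joint_angles <- function(x, angles = c("elbow_right", "knee_right"), ...) {
  a <- x$angles
  angles <- intersect(angles, .ANGLE_NAMES)
  if (!length(angles)) .stopf("no valid angle names to plot")
  graphics::matplot(a$timestamp, as.matrix(a[, angles, drop = FALSE]),
                    type = "l", lty = 1, xlab = "time [s]",
                    ylab = "angle [deg]", ...)
  graphics::legend("topright", legend = angles, lty = 1,
                   col = seq_along(angles), bty = "n", cex = 0.8)
  invisible(x)
}

#' Write a joint-angle series to CSV
#'
#' Long format: columns `frame`, `timestamp`, `angle_name`, `value_deg`,
#' `defined`. Undefined angles carry `defined = FALSE` and an empty value.
#'
#' @param angles a `joint_angles` object.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_angles <- function(angles, path) {
  a <- angles$angles
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("frame,timestamp,angle_name,value_deg,defined", con)
  for (i in seq_len(nrow(a))) {
    v <- unlist(a[i, .ANGLE_NAMES])
    writeLines(sprintf("%d,%s,%s,%s,%s",
                       as.integer(a$frame[i]), .fmt_num(a$timestamp[i]),
                       .ANGLE_NAMES,
                       ifelse(is.na(v), "", .fmt_num(v)),
                       ifelse(is.na(v), "false", "true")), con)
  }
  invisible(path)
}

#' Read a joint-angle series from CSV
#'
#' @param path CSV written by [write_angles()].
#' @param frame_rate frame rate to attach.
#' @return A `joint_angles` object.
#' @export
read_angles <- function(path, frame_rate = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "timestamp", "angle_name", "value_deg", "defined")
  if (!all(need %in% names(df)))
    .stopf("angle CSV %s lacks required columns", path)
  wide <- lapply(split(df, df$frame), function(d) {
    v <- stats::setNames(rep(NA_real_, length(.ANGLE_NAMES)), .ANGLE_NAMES)
    def <- d$defined %in% c("true", "TRUE", TRUE)
    v[d$angle_name[def]] <- as.numeric(d$value_deg[def])
    c(frame = d$frame[1L], timestamp = d$timestamp[1L], v)
  })
  adf <- as.data.frame(do.call(rbind, wide[order(as.integer(names(wide)))]))
  rownames(adf) <- NULL
  structure(list(angles = adf, frame_rate = frame_rate,
                 global_up = c(0, -1, 0)),
            class = "joint_angles")
}
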