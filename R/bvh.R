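#' Hierarchical kinematic model for motion export
#'
#' The avatar rig the extracted angle series is retargeted onto: a rooted
#' segment tree (pelvis root, spine to chest, head and arms off the chest,
#' legs off the pelvis) with per-joint rotation types — spherical (three
#' rotation channels: head, shoulders, hips, and the spine joint linking the
#' upper body to the pelvis) and revolute (one axis: elbows, knees). Rest-
#' pose offsets come from the body dimensions, expressed in the camera frame
#' (y down). Revolute joints are exported with a fixed-axis channel triple
#' whose off-axis channels stay zero.
#'
#' @param dims a [body_dimensions()].
#' @return Object of class `kinematic_model`: list of segments, each with
#'   `name`, `parent`, `offset`, `type` (`"root"`, `"spherical"`,
#'   `"revolute"`, `"static"`), `channels`, and the angle names feeding them.
#' @export
kinematic_model <- function(dims = body_dimensions()) {
  seg <- function(name, parent, offset, type, angles = NULL, end = NULL)
    list(name = name, parent = parent, offset = offset, type = type,
         angles = angles, end = end)
  rot3 <- c("Zrotation", "Xrotation", "Yrotation")
  segs <- list(
    seg("Hips", NA, c(0, 0, 0), "root"),
    seg("Chest", "Hips", c(0, -dims$torso, 0), "spherical",
        c(z = "spine_z", x = "spine_x", y = NA)),
    seg("Head", "Chest", c(0, -dims$neck, 0), "static",
        end = c(0, -0.10, 0)),
    seg("RightArm", "Chest", c(-dims$shoulder_width / 2, 0, 0), "spherical",
        c(z = "shoulder_right_z", x = "shoulder_right_x", y = "shoulder_right_y")),
    seg("RightForeArm", "RightArm", c(0, dims$upper_arm, 0), "revolute",
        c(z = "elbow_right", x = NA, y = NA), end = c(0, dims$forearm, 0)),
    seg("LeftArm", "Chest", c(dims$shoulder_width / 2, 0, 0), "spherical",
        c(z = "shoulder_left_z", x = "shoulder_left_x", y = "shoulder_left_y")),
    seg("LeftForeArm", "LeftArm", c(0, dims$upper_arm, 0), "revolute",
        c(z = "elbow_left", x = NA, y = NA), end = c(0, dims$forearm, 0)),
    seg("RightUpLeg", "Hips", c(-dims$hip_width / 2, 0, 0), "spherical",
        c(z = "hip_right_z", x = "hip_right_x", y = "hip_right_y")),
    seg("RightLeg", "RightUpLeg", c(0, dims$thigh, 0), "revolute",
        c(z = "knee_right", x = NA, y = NA), end = c(0, dims$shank, 0)),
    seg("LeftUpLeg", "Hips", c(dims$hip_width / 2, 0, 0), "spherical",
        c(z = "hip_left_z", x = "hip_left_x", y = "hip_left_y")),
    seg("LeftLeg", "LeftUpLeg", c(0, dims$thigh, 0), "revolute",
        c(z = "knee_left", x = NA, y = NA), end = c(0, dims$shank, 0))
  )
  names(segs) <- vapply(segs, `[[`, "", "name")
  for (i in seq_along(segs))
    segs[[i]]$channels <- if (segs[[i]]$type == "root")
      c("Xposition", "Yposition", "Zposition", rot3) else rot3
  structure(list(segments = segs, dims = dims), class = "kinematic_model")
}

#' @export
print.kinematic_model <- function(x, ...) {
  types <- vapply(x$segments, `[[`, "", "type")
  cat(sprintf("kinematic model: %d segments (%d spherical, %d revolute)\n",
              length(x$segments), sum(types == "spherical"),
              sum(types == "revolute")))
  invisible(x)
}

# channel value for one segment/frame from the angle row; flexion channels
# carry 180 - angle so that the straight-limb rest pose is the zero line
.channel_value <- function(segment, ch, arow, root_pos) {
  if (segment$type == "root") {
    k <- match(ch, c("Xposition", "Yposition", "Zposition"))
    if (!is.na(k)) return(root_pos[k])
    return(0)
  }
  axis <- c(Zrotation = "z", Xrotation = "x", Yrotation = "y")[[ch]]
  anm <- segment$angles[[axis]]
  if (is.null(anm) || is.na(anm)) return(0)
  v <- arow[[anm]]
  if (is.na(v)) return(NA_real_)
  if (segment$type == "revolute") 180 - v else v
}

#' Write an angle series as a BVH motion-capture file
#'
#' Standard Biovision Hierarchy dialect: a HIERARCHY section with rest-pose
#' offsets from the body dimensions and Z,X,Y rotation channel order (the
#' root additionally carries three position channels holding the pelvis
#' trajectory), and a MOTION section with one line per frame. Rotation
#' channels carry the anatomical angles in degrees directly; the revolute
#' elbow/knee channel carries `180 - angle` so a straight limb is zero.
#' Channel values are written with six decimals, so re-parsing recovers them
#' to better than 1e-4 degrees.
#'
#' @param angles a `joint_angles` object or its data frame.
#' @param path output file.
#' @param model a [kinematic_model()].
#' @param frame_time seconds per frame (default from the series frame rate).
#' @param root_positions n x 3 matrix of pelvis positions (default zeros).
#' @param na_action `"error"` (the series must be complete — interpolate
#'   first) or `"zero"`.
#' @return `path`, invisibly.
#' @export
write_bvh <- function(angles, path, model = kinematic_model(),
                      frame_time = NULL, root_positions = NULL,
                      na_action = c("error", "zero")) {
  na_action <- match.arg(na_action)
  adf <- if (inherits(angles, "joint_angles")) angles$angles else angles
  n <- nrow(adf)
  if (!n) .stopf("empty angle series")
  if (is.null(frame_time))
    frame_time <- if (inherits(angles, "joint_angles"))
      1 / angles$frame_rate else 1 / 30
  if (is.null(root_positions)) root_positions <- matrix(0, n, 3L)
  root_positions <- as.matrix(root_positions)
  if (nrow(root_positions) != n)
    .stopf("root_positions must have one row per frame (%d != %d)",
           nrow(root_positions), n)

  segs <- model$segments
  lines <- c("HIERARCHY")
  emit <- function(name, depth) {
    s <- segs[[name]]
    ind <- strrep("  ", depth)
    kw <- if (s$type == "root") "ROOT" else "JOINT"
    lines <<- c(lines, sprintf("%s%s %s", ind, kw, name),
                paste0(ind, "{"),
                sprintf("%s  OFFSET %.6f %.6f %.6f", ind,
                        s$offset[1L], s$offset[2L], s$offset[3L]),
                sprintf("%s  CHANNELS %d %s", ind, length(s$channels),
                        paste(s$channels, collapse = " ")))
    kids <- names(segs)[vapply(segs, function(x)
      identical(x$parent, name), TRUE)]
    for (k in kids) emit(k, depth + 1L)
    if (!is.null(s$end))
      lines <<- c(lines, sprintf("%s  End Site", ind), paste0(ind, "  {"),
                  sprintf("%s    OFFSET %.6f %.6f %.6f", ind,
                          s$end[1L], s$end[2L], s$end[3L]),
                  paste0(ind, "  }"))
    lines <<- c(lines, paste0(ind, "}"))
  }
  root <- names(segs)[vapply(segs, function(s) s$type == "root", TRUE)]
  emit(root, 0L)

  order <- .bvh_channel_order(segs)
  motion <- character(n)
  for (i in seq_len(n)) {
    vals <- vapply(seq_len(nrow(order)), function(k)
      .channel_value(segs[[order$segment[k]]], order$channel[k],
                     adf[i, , drop = FALSE], root_positions[i, ]), 0)
    if (anyNA(vals)) {
      if (na_action == "error")
        .stopf("undefined angle at frame row %d; interpolate or bridge the series first",
               i)
      vals[is.na(vals)] <- 0
    }
    motion[i] <- paste(sprintf("%.6f", vals), collapse = " ")
  }
  lines <- c(lines, "MOTION", sprintf("Frames: %d", n),
             sprintf("Frame Time: %.8f", frame_time), motion)
  writeLines(lines, path)
  invisible(path)
}

# depth-first channel order matching the hierarchy emission
.bvh_channel_order <- function(segs) {
  out <- data.frame(segment = character(0), channel = character(0))
  walk <- function(name) {
    s <- segs[[name]]
    out <<- rbind(out, data.frame(segment = name, channel = s$channels))
    kids <- names(segs)[vapply(segs, function(x)
      identical(x$parent, name), TRUE)]
    for (k in kids) walk(k)
  }
  walk(names(segs)[vapply(segs, function(s) s$type == "root", TRUE)])
  out
}

#' Parse a BVH file
#'
#' A general-purpose reader for the Biovision Hierarchy format (any joint
#' names and channel layouts): returns the joint tree with offsets and
#' channels, the frame timing, and the raw motion matrix with one column per
#' channel in file order.
#'
#' @param path BVH file.
#' @return Object of class `bvh`: list with `joints` (named list of
#'   `parent`, `offset`, `channels`, `end`), `frame_time`, `n_frames`,
#'   `motion` (matrix), `channel_index` (data frame segment/channel/column).
#' @export
read_bvh <- function(path) {
  lns <- readLines(path)
  lns <- trimws(lns)
  lns <- lns[nzchar(lns)]
  if (!length(lns) || lns[1L] != "HIERARCHY")
    .stopf("%s is not a BVH file", path)
  joints <- list()
  stack <- character(0)
  i <- 2L
  cur <- NULL
  endsite <- FALSE
  while (i <= length(lns) && lns[i] != "MOTION") {
    tok <- strsplit(lns[i], "[[:space:]]+")[[1L]]
    key <- tok[1L]
    if (key %in% c("ROOT", "JOINT")) {
      nm <- tok[2L]
      joints[[nm]] <- list(parent = if (length(stack)) stack[length(stack)]
                           else NA_character_,
                           offset = c(0, 0, 0), channels = character(0),
                           end = NULL)
      cur <- nm
    } else if (key == "End") {
      endsite <- TRUE
    } else if (key == "{") {
      if (!endsite) stack <- c(stack, cur)
    } else if (key == "}") {
      if (endsite) endsite <- FALSE
      else {
        cur <- stack[length(stack)]
        stack <- stack[-length(stack)]
      }
    } else if (key == "OFFSET") {
      v <- as.numeric(tok[2:4])
      if (endsite) joints[[cur]]$end <- v else joints[[cur]]$offset <- v
    } else if (key == "CHANNELS") {
      joints[[cur]]$channels <- tok[-(1:2)]
    }
    i <- i + 1L
  }
  if (i > length(lns)) .stopf("BVH %s has no MOTION section", path)
  nfr <- as.integer(sub("Frames:\\s*", "", lns[i + 1L]))
  ft <- as.numeric(sub("Frame Time:\\s*", "", lns[i + 2L]))
  rows <- lns[(i + 3L):(i + 2L + nfr)]
  motion <- do.call(rbind, lapply(strsplit(rows, "[[:space:]]+"), as.numeric))
  ci <- do.call(rbind, lapply(names(joints), function(nm)
    if (length(joints[[nm]]$channels))
      data.frame(segment = nm, channel = joints[[nm]]$channels)))
  ci$column <- seq_len(nrow(ci))
  if (nrow(ci) != ncol(motion))
    .stopf("BVH %s: %d channels declared but %d motion columns",
           path, nrow(ci), ncol(motion))
  structure(list(joints = joints, frame_time = ft, n_frames = nfr,
                 motion = motion, channel_index = ci), class = "bvh")
}

#' @export
print.bvh <- function(x, ...) {
  cat(sprintf("BVH: %d joints, %d frames, frame time %.6f s (%d channels)\n",
              length(x$joints), x$n_frames, x$frame_time,
              nrow(x$channel_index)))
  invisible(x)
}

#' Recover the anatomical angle series from a parsed BVH file
#'
#' Inverts the channel mapping of [write_bvh()] for files written against a
#' [kinematic_model()]: rotation channels map back to the named anatomical
#' angles (revolute channels as `180 - value`), and the root position
#' channels to the pelvis trajectory.
#'
#' @param bvh a parsed `bvh` object.
#' @param model the [kinematic_model()] the file was written with.
#' @return List with `angles` (a `joint_angles` object) and
#'   `root_positions` (n x 3 matrix).
#' @export
bvh_to_angles <- function(bvh, model = kinematic_model()) {
  segs <- model$segments
  ci <- bvh$channel_index
  n <- bvh$n_frames
  amat <- matrix(NA_real_, n, length(.ANGLE_NAMES),
                 dimnames = list(NULL, .ANGLE_NAMES))
  rootp <- matrix(0, n, 3L)
  for (k in seq_len(nrow(ci))) {
    segname <- ci$segment[k]; ch <- ci$channel[k]
    s <- segs[[segname]]
    if (is.null(s)) .stopf("BVH joint '%s' unknown to the kinematic model",
                           segname)
    col <- bvh$motion[, ci$column[k]]
    if (s$type == "root") {
      pk <- match(ch, c("Xposition", "Yposition", "Zposition"))
      if (!is.na(pk)) rootp[, pk] <- col
      next
    }
    axis <- c(Zrotation = "z", Xrotation = "x", Yrotation = "y")[[ch]]
    anm <- s$angles[[axis]]
    if (is.null(anm) || is.na(anm)) next
    amat[, anm] <- if (s$type == "revolute") 180 - col else col
  }
  ft <- bvh$frame_time
  adf <- data.frame(frame = seq_len(n) - 1L, timestamp = (seq_len(n) - 1) * ft,
                    amat)
  ang <- structure(list(angles = adf, frame_rate = 1 / ft,
                        global_up = c(0, -1, 0)), class = "joint_angles")
  list(angles = ang, root_positions = rootp)
}
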