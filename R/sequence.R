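#' Construct a single skeleton frame
#'
#' A frame holds the camera-frame coordinates (meters) of all 18 joints plus a
#' missing-joint mask. The camera frame has y pointing down and z pointing
#' outward from the sensor; x completes a right-handed frame. Body trackers
#' report unobserved joints as the exact sentinel `(0,0,0)`; those joints are
#' entered into the missing mask (their stored coordinates keep the sentinel).
#'
#' @param positions 18x3 numeric matrix of joint coordinates in joint-id order
#'   (rows 1..18 are joints 0..17), columns x, y, z.
#' @param frame_index integer frame counter, >= 0.
#' @param timestamp time in seconds.
#' @param missing optional logical vector of length 18; by default derived
#'   from the `(0,0,0)` sentinel.
#' @return An object of class `skel_frame`.
#' @export
skeleton_frame <- function(positions, frame_index = 0L, timestamp = 0,
                           missing = NULL) {
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || !identical(dim(positions), c(18L, 3L)))
    .stopf("positions must be an 18x3 numeric matrix")
  sentinel <- unname(rowSums(positions == 0) == 3L)
  if (is.null(missing)) {
    missing <- sentinel
  } else {
    missing <- unname(as.logical(missing))
    if (length(missing) != 18L) .stopf("missing mask must have length 18")
    missing <- missing | sentinel   # sentinel rows are always missing
  }
  if (any(!is.finite(positions[!missing, , drop = FALSE])))
    .stopf("non-missing joint coordinates must be finite")
  positions[missing, ] <- 0
  dimnames(positions) <- list(joint_names(), c("x", "y", "z"))
  structure(list(frame_index = as.integer(frame_index),
                 timestamp = as.numeric(timestamp),
                 positions = positions,
                 missing = missing),
            class = "skel_frame")
}

#' @export
print.skel_frame <- function(x, ...) {
  cat(sprintf("skeleton frame %d (t = %.3f s): %d/18 joints observed\n",
              x$frame_index, x$timestamp, sum(!x$missing)))
  invisible(x)
}

#' Construct a skeleton sequence
#'
#' @param frames list of `skel_frame` objects with strictly increasing
#'   `frame_index` and nondecreasing timestamps.
#' @param frame_rate capture rate in Hz.
#' @return An object of class `skel_sequence`.
#' @export
skeleton_sequence <- function(frames, frame_rate = 30) {
  if (!is.list(frames) || (length(frames) && !all(vapply(frames, inherits,
                                                         TRUE, "skel_frame"))))
    .stopf("frames must be a list of skel_frame objects")
  if (length(frames) > 1L) {
    idx <- vapply(frames, `[[`, 0L, "frame_index")
    ts <- vapply(frames, `[[`, 0, "timestamp")
    if (any(diff(idx) <= 0L)) .stopf("frame_index must be strictly increasing")
    if (any(diff(ts) < 0)) .stopf("timestamps must be nondecreasing")
  }
  structure(list(frames = frames, frame_rate = as.numeric(frame_rate)),
            class = "skel_sequence")
}

#' @export
length.skel_sequence <- function(x) length(x$frames)

#' @export
print.skel_sequence <- function(x, ...) {
  n <- length(x$frames)
  miss <- if (n) sum(vapply(x$frames, function(f) sum(f$missing), 0L)) else 0L
  cat(sprintf("skeleton sequence: %d frames at %g Hz, %d missing joint records\n",
              n, x$frame_rate, miss))
  invisible(x)
}

#' @describeIn skeleton_sequence flatten to a long data frame (one row per
#'   joint per frame) with columns frame, timestamp, joint_id, joint_name,
#'   x, y, z, missing.
#' @param x a `skel_sequence`.
#' @param ... unused.
#' @export
as.data.frame.skel_sequence <- function(x, ...) {
  nm <- joint_names()
  do.call(rbind, lapply(x$frames, function(f) {
    data.frame(frame = f$frame_index, timestamp = f$timestamp,
               joint_id = 0:17, joint_name = nm,
               x = f$positions[, 1L], y = f$positions[, 2L],
               z = f$positions[, 3L],
               missing = f$missing, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

# ---- I/O ------------------------------------------------------------------

#' Read a skeleton sequence from CSV or JSON
#'
#' CSV layout: header `frame,timestamp,joint_id,joint_name,x,y,z`, one row per
#' joint per frame. JSON layout: array of frame objects
#' `{frame, timestamp, joints: {name: [x,y,z]}}`. In both formats a joint
#' recorded as exactly `(0,0,0)` enters the frame's missing set.
#'
#' @param path file to read.
#' @param format `"csv"`, `"json"`, or `"auto"` (by file extension).
#' @param frame_rate capture rate stored on the returned sequence.
#' @return A `skel_sequence`.
#' @export
read_skeleton <- function(path, format = c("auto", "csv", "json"),
                          frame_rate = 30) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) .stopf("skeleton file not found: %s", path)
  nm <- joint_names()
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("frame", "timestamp", "joint_id", "joint_name", "x", "y", "z")
    if (!all(need %in% names(df)))
      .stopf("skeleton CSV %s lacks required columns: %s", path,
             paste(setdiff(need, names(df)), collapse = ", "))
    bad <- which(!df$joint_name %in% nm)
    if (length(bad))
      .stopf("unknown joint name '%s' at record %d of %s",
             df$joint_name[bad[1L]], bad[1L], path)
    badid <- which(df$joint_id != match(df$joint_name, nm) - 1L)
    if (length(badid))
      .stopf("joint_id/joint_name mismatch at record %d of %s", badid[1L], path)
    badnum <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))
    if (length(badnum))
      .stopf("malformed coordinates at record %d of %s", badnum[1L], path)
    frames <- lapply(split(df, df$frame), function(fd) {
      if (nrow(fd) != 18L || anyDuplicated(fd$joint_id))
        .stopf("frame %s of %s must have exactly one record per joint (18), got %d",
               fd$frame[1L], path, nrow(fd))
      fd <- fd[order(fd$joint_id), ]
      skeleton_frame(cbind(fd$x, fd$y, fd$z), fd$frame[1L], fd$timestamp[1L])
    })
    frames <- frames[order(vapply(frames, `[[`, 0L, "frame_index"))]
  } else {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    frames <- lapply(recs, function(r) {
      if (is.null(r$frame) || is.null(r$joints))
        .stopf("malformed JSON frame record in %s", path)
      unknown <- setdiff(names(r$joints), nm)
      if (length(unknown))
        .stopf("unknown joint name '%s' in %s", unknown[1L], path)
      if (length(r$joints) != 18L)
        .stopf("JSON frame %s must carry all 18 joints", r$frame)
      pos <- matrix(0, 18L, 3L)
      for (j in names(r$joints)) {
        v <- as.numeric(unlist(r$joints[[j]]))
        if (length(v) != 3L) .stopf("joint '%s' in %s is not a 3-vector", j, path)
        pos[match(j, nm), ] <- v
      }
      ts <- if (is.null(r$timestamp)) 0 else as.numeric(r$timestamp)
      skeleton_frame(pos, as.integer(r$frame), ts)
    })
  }
  skeleton_sequence(frames, frame_rate = frame_rate)
}

#' Write a skeleton sequence to CSV or JSON
#'
#' Coordinates are written with full double precision so that a read/write
#' round trip is the identity. Missing joints are written as the `(0,0,0)`
#' sentinel.
#'
#' @param sequence a `skel_sequence`.
#' @param path output file.
#' @param format `"csv"`, `"json"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_skeleton <- function(sequence, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines("frame,timestamp,joint_id,joint_name,x,y,z", con)
    nm <- joint_names()
    for (f in sequence$frames) {
      writeLines(sprintf("%d,%s,%d,%s,%s,%s,%s",
                         f$frame_index, .fmt_num(f$timestamp), 0:17, nm,
                         .fmt_num(f$positions[, 1L]),
                         .fmt_num(f$positions[, 2L]),
                         .fmt_num(f$positions[, 3L])), con)
    }
  } else {
    nm <- joint_names()
    recs <- lapply(sequence$frames, function(f) {
      joints <- stats::setNames(lapply(1:18, function(i) f$positions[i, ]), nm)
      list(frame = f$frame_index, timestamp = f$timestamp, joints = joints)
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
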