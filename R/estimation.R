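#' Parameters of the joint-estimation algorithm
#'
#' The repair algorithm accepts a joint in the current frame when (a) it is
#' observed, (b) it has not traveled more than `displacement_bound` meters
#' since the previous (corrected) frame, and (c) its distance to its
#' (already-processed) parent lies within
#' `[lower_bound_frac, upper_bound_frac]` times the reference limb distance.
#' The same fractional interval qualifies candidate cloud points as being
#' "limb distance away" from the parent. `window` is the number of initial
#' frames searched for the reference (initialization) frame.
#'
#' @param lower_bound_frac,upper_bound_frac dimensionless multipliers of the
#'   limb distance, `0 <= lower <= 1 <= upper`.
#' @param displacement_bound max per-frame joint travel, meters.
#' @param window initial frames searched for the reference frame.
#' @param drop_before_reference drop frames preceding the reference frame
#'   from the output (the algorithm chains forward from initialization).
#' @return Object of class `estimation_params`.
#' @export
estimation_params <- function(lower_bound_frac = 0.8, upper_bound_frac = 1.2,
                              displacement_bound = 0.25, window = 30L,
                              drop_before_reference = TRUE) {
  if (!(lower_bound_frac >= 0 && lower_bound_frac <= 1 &&
        upper_bound_frac >= 1))
    .stopf("bounds must satisfy 0 <= lower_bound_frac <= 1 <= upper_bound_frac")
  if (displacement_bound <= 0) .stopf("displacement_bound must be > 0")
  if (window < 1) .stopf("window must be >= 1")
  structure(list(lower_bound_frac = lower_bound_frac,
                 upper_bound_frac = upper_bound_frac,
                 displacement_bound = displacement_bound,
                 window = as.integer(window),
                 drop_before_reference = isTRUE(drop_before_reference)),
            class = "estimation_params")
}

#' Select the reference (initialization) frame
#'
#' Among the fully observed frames of the initial window, picks the frame
#' whose 18 depth (z) coordinates have the lowest standard deviation — the
#' most stable capture of the default standing pose. Ties go to the earliest
#' frame.
#'
#' @param sequence a `skel_sequence`.
#' @param window number of initial frames searched.
#' @return The `frame_index` of the selected frame.
#' @export
select_reference_frame <- function(sequence, window = 30L) {
  n <- min(length(sequence$frames), window)
  if (n < 1L) .stopf("empty sequence")
  cand <- seq_len(n)
  full <- vapply(sequence$frames[cand], function(f) !any(f$missing), TRUE)
  if (!any(full))
    .stopf(paste("no fully observed frame among the first %d frames;",
                 "capture a longer initialization of the default standing pose"),
           n)
  zsd <- vapply(sequence$frames[cand], function(f)
    stats::sd(f$positions[, 3L]), 0)
  zsd[!full] <- Inf
  sequence$frames[[which.min(zsd)]]$frame_index
}

#' Compute the reference limb-distance table
#'
#' Euclidean child-to-parent distance for each of the 17 non-root joints of a
#' fully observed frame. These distances are treated as constant (rigid
#' limbs) by the repair algorithm.
#'
#' @param frame a fully observed `skel_frame`.
#' @param topo skeleton topology.
#' @return Object of class `limb_table`: data frame with `child_id`,
#'   `parent_id`, `distance` plus attribute `reference_frame_index`.
#' @export
compute_limb_distances <- function(frame,
                                   topo = skeleton_topology(validate = FALSE)) {
  if (any(frame$missing))
    .stopf("limb distances need a fully observed frame (missing: %s)",
           paste(which(frame$missing) - 1L, collapse = ", "))
  d <- vapply(topo$limbs$child_id, function(cid) {
    .vnorm(.pos(frame, cid) - .pos(frame, .parent_of(topo, cid)))
  }, 0)
  if (any(d <= 0)) .stopf("degenerate limb of zero length in reference frame")
  out <- data.frame(child_id = topo$limbs$child_id,
                    parent_id = topo$limbs$parent_id, distance = d)
  attr(out, "reference_frame_index") <- frame$frame_index
  class(out) <- c("limb_table", "data.frame")
  out
}

#' Validate a joint observation against the displacement and limb bounds
#'
#' @param current_pos 3-vector or `NULL`/`NA` when the joint is missing.
#' @param previous_pos corrected position in the previous frame.
#' @param limb_dist reference limb distance to the parent (meters).
#' @param parent_pos corrected position of the parent in the current frame.
#' @param params an [estimation_params()].
#' @return `TRUE` (accept the observation) or `FALSE` (repair it).
#' @export
validate_joint <- function(current_pos, previous_pos, limb_dist, parent_pos,
                           params = estimation_params()) {
  if (is.null(current_pos) || any(is.na(current_pos))) return(FALSE)
  if (.vnorm(current_pos - previous_pos) > params$displacement_bound)
    return(FALSE)
  dl <- .vnorm(current_pos - parent_pos)
  dl >= params$lower_bound_frac * limb_dist &&
    dl <= params$upper_bound_frac * limb_dist
}

#' Repair one joint from its segmented point cloud
#'
#' Implements the point-cloud-assisted estimation rule: the candidate is the
#' cloud point nearest to the joint's previous-frame position among the
#' points lying limb distance away from the (already processed) parent —
#' within the fractional bound interval; for the root joint the candidate is
#' simply the nearest cloud point to the previous nose position. If the
#' current observation exists and the candidate is within the displacement
#' bound of it, the repaired position is the midpoint of candidate and
#' observation; the midpoint is also taken when it lands closer to the
#' previous-frame position than the candidate alone. When the midpoint would
#' break the limb-distance interval that the candidate satisfies, the
#' candidate alone is returned, so repaired joints always honor the limb
#' bound. If no cloud point qualifies, the previous position is carried
#' forward and the joint flagged as a fallback.
#'
#' @param previous_pos corrected position in the previous frame.
#' @param current_pos current observation, or `NULL` when missing.
#' @param parent_pos corrected parent position this frame (`NULL` for root).
#' @param limb_dist reference limb distance (`NULL` for root).
#' @param cloud a `pc_segment` (or n x 3 matrix), possibly `NULL`.
#' @param params an [estimation_params()].
#' @return List with `position` (3-vector) and `action` (`"repaired"` or
#'   `"fallback"`).
#' @export
repair_joint <- function(previous_pos, current_pos = NULL, parent_pos = NULL,
                         limb_dist = NULL, cloud = NULL,
                         params = estimation_params()) {
  pts <- if (inherits(cloud, "pc_segment")) cloud$points else cloud
  if (is.null(pts) || nrow(pts) == 0L)
    return(list(position = previous_pos, action = "fallback"))
  lo <- params$lower_bound_frac; up <- params$upper_bound_frac
  if (!is.null(parent_pos) && !is.null(limb_dist)) {
    dpar <- sqrt((pts[, 1L] - parent_pos[1L])^2 +
                 (pts[, 2L] - parent_pos[2L])^2 +
                 (pts[, 3L] - parent_pos[3L])^2)
    ok <- dpar >= lo * limb_dist & dpar <= up * limb_dist
    if (!any(ok)) return(list(position = previous_pos, action = "fallback"))
    pts <- pts[ok, , drop = FALSE]
  }
  dprev <- sqrt((pts[, 1L] - previous_pos[1L])^2 +
                (pts[, 2L] - previous_pos[2L])^2 +
                (pts[, 3L] - previous_pos[3L])^2)
  cand <- pts[which.min(dprev), ]   # ties: lowest point index
  pos <- cand
  if (!is.null(current_pos) && !any(is.na(current_pos))) {
    mid <- (cand + current_pos) / 2
    use_mid <- .vnorm(cand - current_pos) <= params$displacement_bound ||
      .vnorm(mid - previous_pos) < .vnorm(cand - previous_pos)
    if (use_mid) {
      pos <- mid
      if (!is.null(parent_pos) && !is.null(limb_dist)) {
        dl <- .vnorm(mid - parent_pos)
        if (dl < lo * limb_dist || dl > up * limb_dist) pos <- cand
      }
    }
  }
  list(position = pos, action = "repaired")
}

#' Repair a skeleton sequence using per-limb point clouds
#'
#' The full compensation pipeline for a tracked capture: select the
#' initialization frame (lowest depth standard deviation among the fully
#' observed frames of the initial window), learn the reference limb
#' distances there, then walk the remaining frames processing joints in
#' ascending id order — the nose first — validating each observation against
#' the displacement and limb-distance bounds and repairing rejected or
#' missing joints from the frame's segmented point clouds (see
#' [repair_joint()]). Children are validated against their parent's already
#' corrected position, and the previous frame is always the corrected one.
#'
#' @param sequence a `skel_sequence` (raw tracker output).
#' @param clouds list parallel to `sequence$frames`; each element a named
#'   list (by child joint id `"1"`..`"17"`) of `pc_segment`s, as produced by
#'   [sample_point_clouds()] or loaded from PLY files. The root joint uses
#'   the head/neck limb cloud (`"1"`). `NULL` clouds force fallback on
#'   joints needing repair.
#' @param params an [estimation_params()].
#' @param topo skeleton topology.
#' @return Object of class `skel_filter`: list with `sequence` (corrected
#'   `skel_sequence`), `log` (data frame: frame, joint_id, action in
#'   kept/repaired/fallback), `limb_table`, `reference_frame` and `params`.
#' @examples
#' mc <- motion_config(n_frames = 40, seed = 7)
#' gt <- generate_motion(mc)
#' corr <- corrupt_sequence(gt$clean, mc)
#' clouds <- lapply(gt$clean$frames, sample_point_clouds, config = mc)
#' fit <- skeleton_repair(corr, clouds)
#' summary(fit)
#' @export
skeleton_repair <- function(sequence, clouds = NULL,
                            params = estimation_params(),
                            topo = skeleton_topology(validate = FALSE)) {
  if (!inherits(sequence, "skel_sequence"))
    .stopf("sequence must be a skel_sequence")
  ref_fi <- select_reference_frame(sequence, params$window)
  ref_pos <- which(vapply(sequence$frames, `[[`, 0L, "frame_index") == ref_fi)
  lt <- compute_limb_distances(sequence$frames[[ref_pos]], topo)
  ldist <- stats::setNames(lt$distance, as.character(lt$child_id))

  idx <- if (params$drop_before_reference) ref_pos:length(sequence$frames)
         else seq_along(sequence$frames)  # frames before ref pass through
  out <- vector("list", length(idx))
  logs <- vector("list", length(idx))
  prev <- sequence$frames[[ref_pos]]$positions
  for (k in seq_along(idx)) {
    i <- idx[k]
    f <- sequence$frames[[i]]
    if (i <= ref_pos) {
      out[[k]] <- f
      logs[[k]] <- data.frame(frame = f$frame_index, joint_id = 0:17,
                              action = if (i == ref_pos) "kept" else "passthrough")
      next
    }
    fc <- clouds[[i]]
    newp <- matrix(NA_real_, 18L, 3L)
    act <- character(18L)
    for (j in 0:17) {
      cur <- if (f$missing[j + 1L]) NULL else f$positions[j + 1L, ]
      if (j == 0L) {
        ok <- !is.null(cur) &&
          .vnorm(cur - prev[1L, ]) <= params$displacement_bound
        cl <- if (!is.null(fc)) fc[["1"]] else NULL
        if (ok) {
          newp[1L, ] <- cur; act[1L] <- "kept"
        } else {
          r <- repair_joint(prev[1L, ], cur, NULL, NULL, cl, params)
          newp[1L, ] <- r$position; act[1L] <- r$action
        }
      } else {
        pid <- .parent_of(topo, j)
        ppos <- newp[pid + 1L, ]
        L <- ldist[[as.character(j)]]
        if (validate_joint(cur, prev[j + 1L, ], L, ppos, params)) {
          newp[j + 1L, ] <- cur; act[j + 1L] <- "kept"
        } else {
          cl <- if (!is.null(fc)) fc[[as.character(j)]] else NULL
          r <- repair_joint(prev[j + 1L, ], cur, ppos, L, cl, params)
          newp[j + 1L, ] <- r$position; act[j + 1L] <- r$action
        }
      }
    }
    out[[k]] <- skeleton_frame(newp, f$frame_index, f$timestamp,
                               missing = rep(FALSE, 18L))
    logs[[k]] <- data.frame(frame = f$frame_index, joint_id = 0:17,
                            action = act)
    prev <- newp
  }
  structure(list(sequence = skeleton_sequence(out, sequence$frame_rate),
                 log = do.call(rbind, logs),
                 limb_table = lt, reference_frame = ref_fi, params = params),
            class = "skel_filter")
}

#' @export
print.skel_filter <- function(x, ...) {
  tab <- table(factor(x$log$action,
                      c("kept", "repaired", "fallback", "passthrough")))
  cat(sprintf("skeleton repair: %d frames (reference frame %d)\n",
              length(x$sequence$frames), x$reference_frame))
  cat(sprintf("  joints kept %d, repaired %d, fallback %d\n",
              tab[["kept"]], tab[["repaired"]], tab[["fallback"]]))
  invisible(x)
}

#' @export
summary.skel_filter <- function(object, ...) {
  lg <- object$log
  per_joint <- as.data.frame.matrix(table(lg$joint_id, lg$action))
  per_joint$joint_id <- as.integer(rownames(per_joint))
  per_joint$joint_name <- joint_names()[per_joint$joint_id + 1L]
  rownames(per_joint) <- NULL
  out <- list(reference_frame = object$reference_frame,
              n_frames = length(object$sequence$frames),
              actions = table(lg$action), per_joint = per_joint,
              params = object$params)
  class(out) <- "summary.skel_filter"
  out
}

#' @export
print.summary.skel_filter <- function(x, ...) {
  cat(sprintf("skeleton repair over %d frames (reference frame %d)\n",
              x$n_frames, x$reference_frame))
  print(x$actions)
  cat("\nper joint:\n")
  print(x$per_joint[, c("joint_id", "joint_name",
                        intersect(c("kept", "repaired", "fallback"),
                                  names(x$per_joint)))])
  invisible(x)
}

#' Write the per-joint repair log to CSV
#'
#' @param fit a `skel_filter`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_repair_log <- function(fit, path) {
  utils::write.csv(fit$log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
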