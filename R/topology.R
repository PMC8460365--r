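#' The 18-joint skeleton topology
#'
#' Joint identifier table and parent links for the 18-joint stick-figure model
#' emitted by commodity RGB-D body trackers. The nose (joint 0) is the root of
#' the tree; every other joint reaches it through a chain of parent links, so
#' each of the 17 non-root joints owns exactly one limb (the segment to its
#' parent). Joints 2/3/4 are the right shoulder/elbow/wrist chain and 5/6/7
#' the left; 8/9/10 and 11/12/13 are the right and left hip/knee/ankle chains;
#' 14-17 are eyes and ears, with 15 and 16 on the left side of the head.
#'
#' @param validate logical; run internal consistency checks before returning.
#' @return An object of class `skeleton_topology`: a list with elements
#'   `joints` (data frame of `joint_id`, `name`, `parent_id`), `root` (0),
#'   and `limbs` (data frame of `child_id`, `parent_id`, one row per non-root
#'   joint).
#' @examples
#' topo <- skeleton_topology()
#' nrow(topo$joints)   # 18
#' nrow(topo$limbs)    # 17
#' @export
skeleton_topology <- function(validate = TRUE) {
  joints <- data.frame(
    joint_id = 0:17,
    name = c("nose", "chest",
             "shoulder_right", "elbow_right", "wrist_right",
             "shoulder_left", "elbow_left", "wrist_left",
             "hip_right", "knee_right", "ankle_right",
             "hip_left", "knee_left", "ankle_left",
             "eye_right", "eye_left", "ear_left", "ear_right"),
    parent_id = c(NA, 0L,
                  1L, 2L, 3L,
                  1L, 5L, 6L,
                  1L, 8L, 9L,
                  1L, 11L, 12L,
                  0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
  limbs <- data.frame(child_id = joints$joint_id[-1L],
                      parent_id = joints$parent_id[-1L])
  topo <- structure(list(joints = joints, root = 0L, limbs = limbs),
                    class = "skeleton_topology")
  if (validate) validate_topology(topo)
  topo
}

#' Validate a skeleton topology
#'
#' Checks the structural invariants of the joint tree: 18 joints, a single
#' root, no cycles, and one parent link per non-root joint.
#'
#' @param topo a `skeleton_topology`.
#' @return `topo`, invisibly; errors on violation.
#' @export
validate_topology <- function(topo) {
  j <- topo$joints
  if (nrow(j) != 18L || !identical(j$joint_id, 0:17))
    .stopf("topology must declare exactly the 18 joint ids 0-17")
  roots <- j$joint_id[is.na(j$parent_id)]
  if (length(roots) != 1L)
    .stopf("topology must have exactly one root, found %d", length(roots))
  if (roots != topo$root)
    .stopf("declared root %d does not match the parentless joint %d",
           topo$root, roots)
  if (nrow(topo$limbs) != 17L)
    .stopf("topology must have 17 limbs, found %d", nrow(topo$limbs))
  # every joint reaches the root through a finite parent chain
  parent <- j$parent_id
  for (id in j$joint_id) {
    seen <- logical(18L)
    cur <- id
    while (!is.na(parent[cur + 1L])) {
      if (seen[cur + 1L]) .stopf("parent chain of joint %d contains a cycle", id)
      seen[cur + 1L] <- TRUE
      cur <- parent[cur + 1L]
      if (!cur %in% j$joint_id) .stopf("joint %d has unknown parent %d", id, cur)
    }
    if (cur != topo$root)
      .stopf("joint %d does not reach the root", id)
  }
  invisible(topo)
}

#' @export
print.skeleton_topology <- function(x, ...) {
  cat("18-joint skeleton topology (root: nose, joint 0)\n")
  cat(sprintf("  %d joints, %d limbs (child -> parent)\n",
              nrow(x$joints), nrow(x$limbs)))
  invisible(x)
}

#' Joint names of the 18-joint model
#'
#' @param topo a `skeleton_topology` (default the packaged one).
#' @return Character vector of 18 joint names, in joint-id order (0-17).
#' @export
joint_names <- function(topo = skeleton_topology(validate = FALSE)) {
  topo$joints$name
}

# internal: parent id of joint `id` (NA for root)
.parent_of <- function(topo, id) topo$joints$parent_id[id + 1L]

#' Limb vector of a joint
#'
#' The vector from a joint's parent to the joint itself in a frame, i.e.
#' child position minus parent position.
#'
#' @param frame a `skel_frame` (see [skeleton_frame()]).
#' @param joint_id integer joint id, 1-17 (the root has no limb).
#' @param topo a `skeleton_topology`.
#' @return Numeric length-3 vector in meters.
#' @export
limb_vector <- function(frame, joint_id, topo = skeleton_topology(validate = FALSE)) {
  if (length(joint_id) != 1L || !joint_id %in% 0:17)
    .stopf("joint_id must be a single id in 0-17")
  if (joint_id == topo$root)
    .stopf("the root joint (nose) has no limb vector")
  pid <- .parent_of(topo, joint_id)
  if (frame$missing[joint_id + 1L] || frame$missing[pid + 1L])
    .stopf("limb vector of joint %d needs both endpoints observed (joint %s, parent %s)",
           joint_id,
           if (frame$missing[joint_id + 1L]) "missing" else "ok",
           if (frame$missing[pid + 1L]) "missing" else "ok")
  frame$positions[joint_id + 1L, ] - frame$positions[pid + 1L, ]
}
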