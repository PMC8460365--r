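#' Labeled point-cloud segment
#'
#' A point-cloud segment is the subset of the depth sensor's 3D points
#' attributed to the neighborhood of one limb (the segment between a joint and
#' its parent), in the same camera frame as the skeleton coordinates.
#'
#' @param points n x 3 numeric matrix of x, y, z coordinates (meters).
#' @param label joint/limb identifier (conventionally the child joint id).
#' @param allow_empty allow a segment with zero points (default `FALSE`: the
#'   estimation search assumes a non-empty cloud).
#' @return An object of class `pc_segment`.
#' @export
point_cloud_segment <- function(points, label = NA, allow_empty = FALSE) {
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), 0L, 3L)
  if (ncol(points) != 3L) .stopf("points must have 3 columns (x, y, z)")
  if (nrow(points) == 0L && !allow_empty)
    .stopf("empty point-cloud segment (label %s); pass allow_empty = TRUE to permit",
           as.character(label))
  if (nrow(points) && any(!is.finite(points)))
    .stopf("point-cloud coordinates must be finite")
  colnames(points) <- c("x", "y", "z")
  structure(list(label = label, points = points), class = "pc_segment")
}

#' @export
print.pc_segment <- function(x, ...) {
  cat(sprintf("point-cloud segment '%s': %d points\n",
              as.character(x$label), nrow(x$points)))
  invisible(x)
}

#' Read a PLY point cloud
#'
#' Supports ASCII and binary-little-endian PLY files whose vertex element
#' carries `x`, `y`, `z` properties (any float/double width; extra properties
#' are skipped). This is the standard interchange format for the segmented
#' per-limb clouds consumed by the repair algorithm.
#'
#' @param path PLY file.
#' @param label label to attach to the returned segment (default: file name).
#' @param allow_empty accept a zero-vertex file as an empty segment instead of
#'   raising an error.
#' @return A `pc_segment`.
#' @export
read_ply <- function(path, label = NULL, allow_empty = FALSE) {
  if (!file.exists(path)) .stopf("PLY file not found: %s", path)
  if (is.null(label)) label <- sub("\\.ply$", "", basename(path))
  con <- file(path, "rb")
  on.exit(close(con))
  readl <- function() {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) .stopf("unexpected end of PLY header in %s", path)
    trimws(ln)
  }
  if (readl() != "ply") .stopf("%s is not a PLY file (missing magic)", path)
  fmt <- NULL; nvert <- NULL
  props <- character(0); ptypes <- character(0)
  in_vertex <- FALSE
  repeat {
    ln <- readl()
    if (ln == "end_header") break
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (tok[1L] == "format") {
      fmt <- tok[2L]
    } else if (tok[1L] == "element") {
      in_vertex <- identical(tok[2L], "vertex")
      if (in_vertex) nvert <- as.integer(tok[3L])
    } else if (tok[1L] == "property" && in_vertex) {
      if (tok[2L] == "list") .stopf("list properties on vertices unsupported (%s)", path)
      ptypes <- c(ptypes, tok[2L])
      props <- c(props, tok[3L])
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    .stopf("unsupported PLY format '%s' in %s", fmt, path)
  if (is.null(nvert)) .stopf("PLY %s has no vertex element", path)
  if (!all(c("x", "y", "z") %in% props))
    .stopf("PLY %s lacks x/y/z vertex properties", path)
  sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
             float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  if (nvert == 0L) {
    return(point_cloud_segment(matrix(numeric(0), 0L, 3L), label,
                               allow_empty = allow_empty))
  }
  if (fmt == "ascii") {
    lns <- readLines(con, n = nvert)
    if (length(lns) < nvert) .stopf("PLY %s truncated: %d of %d vertices", path,
                                    length(lns), nvert)
    vals <- lapply(strsplit(trimws(lns), "[[:space:]]+"), as.numeric)
    if (any(lengths(vals) < length(props)))
      .stopf("malformed vertex line in %s", path)
    m <- do.call(rbind, vals)
    pts <- m[, match(c("x", "y", "z"), props), drop = FALSE]
  } else {
    unk <- setdiff(ptypes, names(sizes))
    if (length(unk)) .stopf("unsupported property type '%s' in %s", unk[1L], path)
    psz <- sizes[ptypes]
    stride <- sum(psz)
    raw <- readBin(con, "raw", n = nvert * stride)
    if (length(raw) < nvert * stride) .stopf("PLY %s truncated", path)
    off <- c(0L, cumsum(psz))
    getcol <- function(p) {
      k <- match(p, props)
      idx <- rep(off[k] + seq_len(psz[k]), nvert) +
        rep((seq_len(nvert) - 1L) * stride, each = psz[k])
      bytes <- raw[idx]
      tp <- ptypes[k]
      if (tp %in% c("float", "float32"))
        readBin(bytes, "double", n = nvert, size = 4L, endian = "little")
      else if (tp %in% c("double", "float64"))
        readBin(bytes, "double", n = nvert, size = 8L, endian = "little")
      else
        readBin(bytes, "integer", n = nvert, size = psz[k], endian = "little")
    }
    pts <- cbind(getcol("x"), getcol("y"), getcol("z"))
  }
  point_cloud_segment(pts, label, allow_empty = allow_empty)
}

#' Write a PLY point cloud
#'
#' @param segment a `pc_segment` (or n x 3 matrix).
#' @param path output file.
#' @param binary write binary-little-endian instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_ply <- function(segment, path, binary = FALSE) {
  pts <- if (inherits(segment, "pc_segment")) segment$points else as.matrix(segment)
  n <- nrow(pts)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z",
           "end_header")
  writeLines(hdr, con)
  if (n) {
    if (binary) {
      writeBin(as.vector(t(pts)), con, size = 8L, endian = "little")
    } else {
      writeLines(sprintf("%s %s %s", .fmt_num(pts[, 1L]), .fmt_num(pts[, 2L]),
                         .fmt_num(pts[, 3L])), con)
    }
  }
  invisible(path)
}
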