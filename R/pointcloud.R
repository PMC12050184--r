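#' Point cloud container
#'
#' An ordered set of 3-D surface points (in mm) for one subject's bone,
#' with optional per-point unit normals. Point order is meaningful: after
#' correspondence, index j refers to the same anatomical location across
#' subjects.
#'
#' @param points Numeric M x 3 matrix of coordinates in mm.
#' @param normals Optional M x 3 matrix of unit normals (checked to unit
#'   length within 1e-6).
#' @param subject_id Character identifier.
#' @param side One of `"left"`, `"right"`, `"unknown"`.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, normals = NULL, subject_id = "",
                        side = c("unknown", "left", "right")) {
  side <- match.arg(side)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stopf("points must be an M x 3 matrix")
  if (nrow(points) < 1L) stopf("a point cloud needs at least one point")
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stopf("all coordinates must be finite")
  dimnames(points) <- NULL
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    dimnames(normals) <- NULL
    if (!all(dim(normals) == dim(points)))
      stopf("normals must match points: %d rows expected, %d given",
            nrow(points), nrow(normals))
    if (!all(is.finite(normals))) stopf("all normals must be finite")
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6))
      stopf("normals must have unit length within 1e-6 (worst deviation %.2e)",
            max(abs(len - 1)))
  }
  structure(
    list(points = points, normals = normals, subject_id = subject_id,
         side = side),
    class = "point_cloud"
  )
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points%s%s\n", nrow(x$points),
              if (!is.null(x$normals)) " (with normals)" else "",
              if (nzchar(x$subject_id)) paste0(", subject ", x$subject_id)
              else ""))
  invisible(x)
}

n_points <- function(cloud) nrow(cloud$points)

#' Anatomical landmark set
#'
#' The four named distal radius landmarks: A (sigmoid notch volar lip),
#' B (sigmoid notch dorsal lip), C (radial styloid process vertex) and
#' D (highest point on the dorsal side of Lister's tubercle), all in mm.
#'
#' @param A,B,C,D Numeric length-3 coordinates in mm.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(A, B, C, D) {
  lm <- list(A = as.numeric(A), B = as.numeric(B),
             C = as.numeric(C), D = as.numeric(D))
  for (nm in names(lm)) {
    if (length(lm[[nm]]) != 3L || !all(is.finite(lm[[nm]])))
      stopf("landmark %s must be a finite 3-D coordinate", nm)
  }
  if (sum((lm$A - lm$B)^2) == 0)
    stopf("landmarks A and B coincide: zero-length measurement segment")
  if (sum((lm$C - lm$D)^2) == 0)
    stopf("landmarks C and D coincide: zero-length measurement segment")
  structure(lm, class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  for (nm in c("A", "B", "C", "D"))
    cat(sprintf("%s: (%.3f, %.3f, %.3f)\n", nm, x[[nm]][1], x[[nm]][2],
                x[[nm]][3]))
  invisible(x)
}

# Apply a point-wise transform function to landmarks (used by the synthetic
# generator and rigid transforms).
map_landmarks <- function(lm, f) {
  landmark_set(f(lm$A), f(lm$B), f(lm$C), f(lm$D))
}
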