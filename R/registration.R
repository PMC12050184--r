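# Pose standardization: surface-normal estimation, voxel-grid
# downsampling, principal-axis initial alignment (with optional mirroring
# for right-sided wrists), and point-to-plane ICP with an RMSE quality gate.

#' ICP parameter set
#'
#' Parameters of the point-to-plane ICP registration: absolute convergence
#' threshold on the change in mean point-to-plane error between iterations
#' (mm), iteration cap, Euclidean pair-rejection distance (mm), and the
#' RMSE quality gate (mm) a registration must meet to pass.
#'
#' @param convergence_tol Convergence threshold (default `1e-6`).
#' @param max_iters Maximum iterations (default 100).
#' @param reject_dist Pair rejection distance in mm (default 2.5).
#' @param rmse_gate RMSE acceptance gate in mm (default 0.5).
#' @return An `icp_params` list.
#' @export
icp_params <- function(convergence_tol = 1e-6, max_iters = 100L,
                       reject_dist = 2.5, rmse_gate = 0.5) {
  stopifnot(convergence_tol > 0, max_iters >= 1, reject_dist > 0,
            rmse_gate > 0)
  structure(list(convergence_tol = convergence_tol,
                 max_iters = as.integer(max_iters),
                 reject_dist = reject_dist, rmse_gate = rmse_gate),
            class = "icp_params")
}

#' Rigid transform
#'
#' A proper rotation plus translation, with mirroring recorded as a
#' separate reflection applied (about the plane through `center` with unit
#' normal `mirror_normal`) before the rotation. Application rule:
#' `q = R %*% reflect(p - center) + translation`.
#'
#' @param rotation 3 x 3 proper rotation matrix (orthonormal within 1e-9,
#'   determinant +1).
#' @param translation Length-3 translation (mm).
#' @param mirrored Logical flag.
#' @param mirror_normal Unit normal of the mirror plane (required when
#'   `mirrored`).
#' @param center Point subtracted before reflection/rotation (default
#'   origin).
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            mirrored = FALSE, mirror_normal = NULL,
                            center = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stopf("rotation is not orthonormal within 1e-9")
  if (det(rotation) < 0)
    stopf("rotation must have determinant +1; record mirroring separately")
  if (mirrored && is.null(mirror_normal))
    stopf("mirrored transforms need a mirror_normal")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 mirrored = isTRUE(mirrored),
                 mirror_normal = if (!is.null(mirror_normal))
                   unit_vector(mirror_normal),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points or a cloud
#'
#' @param x A [point_cloud] or an M x 3 matrix.
#' @param tf A [rigid_transform].
#' @return Object of the same type as `x`; normals (if present) are rotated
#'   (and reflected) with the points.
#' @export
apply_transform <- function(x, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  lin <- tf$rotation
  if (tf$mirrored) {
    w <- tf$mirror_normal
    lin <- tf$rotation %*% (diag(3) - 2 * tcrossprod(w))
  }
  tx <- function(P) {
    sweep(sweep(P, 2, tf$center) %*% t(lin), 2, tf$translation, `+`)
  }
  if (inherits(x, "point_cloud")) {
    nrm <- if (!is.null(x$normals)) x$normals %*% t(lin)
    point_cloud(tx(x$points), nrm, subject_id = x$subject_id, side = x$side)
  } else tx(as.matrix(x))
}

# Affine (A, b) form of a rigid_transform: apply(p) = A p + b.
transform_affine <- function(tf) {
  lin <- tf$rotation
  if (tf$mirrored) {
    w <- tf$mirror_normal
    lin <- tf$rotation %*% (diag(3) - 2 * tcrossprod(w))
  }
  list(A = lin, b = tf$translation - as.numeric(lin %*% tf$center))
}

#' Estimate outward surface normals
#'
#' Each point's normal is the eigenvector of the covariance of its k
#' nearest neighbours with the smallest eigenvalue, normalized to unit
#' length and oriented away from the cloud centroid. Degenerate (collinear)
#' neighbourhoods get a deterministic perpendicular.
#'
#' @param cloud A [point_cloud].
#' @param k Neighbour count (default 20); must satisfy `3 <= k < M`.
#' @return The cloud with `normals` filled in.
#' @export
estimate_normals <- function(cloud, k = 20L) {
  stopifnot(inherits(cloud, "point_cloud"))
  M <- n_points(cloud)
  if (k < 3L) stopf("k must be at least 3")
  if (k >= M) stopf("k (%d) must be smaller than the point count (%d)", k, M)
  P <- cloud$points
  if (max(apply(P, 2, function(x) diff(range(x)))) == 0)
    stopf("all points coincide; normals are undefined")
  nn <- cpp_knn(P, as.integer(k))
  centroid <- colMeans(P)
  N <- matrix(0, M, 3)
  for (i in seq_len(M)) {
    Q <- P[c(i, nn[i, ]), , drop = FALSE]
    Qc <- sweep(Q, 2, colMeans(Q))
    e <- eigen(crossprod(Qc), symmetric = TRUE)
    # eigenvalues descending; smallest is the normal direction
    if (e$values[2] <= e$values[1] * 1e-12) {
      # collinear neighbourhood: normal not unique; pick the deterministic
      # perpendicular to the dominant direction
      d <- e$vectors[, 1]
      ax <- diag(3)[, which.min(abs(d))]
      n <- unit_vector(ax - sum(ax * d) * d)
    } else {
      n <- e$vectors[, 3]
    }
    out <- P[i, ] - centroid
    dp <- sum(n * out)
    if (dp < 0) n <- -n
    else if (dp == 0 && n[which.max(abs(n))] < 0) n <- -n
    N[i, ] <- n / sqrt(sum(n^2))
  }
  point_cloud(P, N, subject_id = cloud$subject_id, side = cloud$side)
}

#' Voxel-grid downsampling
#'
#' Replaces all points falling in the same cubic voxel by their centroid.
#' The grid is anchored at the floored minimum corner of the cloud and
#' output points are ordered lexicographically by voxel index, so the
#' result is deterministic.
#'
#' @param cloud A [point_cloud].
#' @param voxel Voxel edge length in mm (default 1, the preprocessing
#'   standard for ~2000-point bone clouds).
#' @return A downsampled [point_cloud] (normals are dropped).
#' @export
voxel_downsample <- function(cloud, voxel = 1) {
  stopifnot(inherits(cloud, "point_cloud"), voxel > 0)
  P <- cloud$points
  origin <- floor(apply(P, 2, min))
  idx <- floor(sweep(P, 2, origin) / voxel)
  ord <- order(idx[, 1], idx[, 2], idx[, 3])
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  first <- !duplicated(key[ord])
  groups <- match(key, key[ord][first])
  out <- rowsum(P, groups, reorder = TRUE) /
    as.vector(table(factor(groups, levels = seq_len(max(groups)))))
  point_cloud(out, subject_id = cloud$subject_id, side = cloud$side)
}

# Principal axes with skewness-disambiguated signs. Pc: centered points.
signed_axes <- function(Pc) {
  e <- eigen(cov(Pc), symmetric = TRUE)
  vals <- e$values
  if (vals[1] <= 0 || min(abs(diff(vals))) / vals[1] < 1e-9)
    stopf(paste("cloud is isotropic (degenerate principal axes);",
                "manual pre-alignment required"))
  V <- e$vectors
  for (j in 1:3) {
    pr <- Pc %*% V[, j]
    s3 <- sum(pr^3)
    scale <- sum(pr^2)^1.5 / sqrt(nrow(Pc))
    if (abs(s3) > 1e-9 * scale) {
      if (s3 < 0) V[, j] <- -V[, j]
    } else if (V[which.max(abs(V[, j])), j] < 0) {
      V[, j] <- -V[, j]
    }
  }
  V
}

#' Initial rigid alignment by principal axes
#'
#' Matches centroids and aligns sign-disambiguated principal axes of the
#' source to the reference. When the best axis alignment requires a
#' reflection and `allow_mirror = TRUE`, the source is mirrored about its
#' first principal plane first (mapping right wrists to left) and the
#' transform records `mirrored = TRUE`.
#'
#' @param cloud Source [point_cloud].
#' @param reference Reference [point_cloud].
#' @param allow_mirror Permit a reflection (default FALSE).
#' @return List with `cloud` (aligned source) and `transform`
#'   (a [rigid_transform]).
#' @export
initial_align <- function(cloud, reference, allow_mirror = FALSE) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(reference, "point_cloud"))
  cs <- colMeans(cloud$points)
  cr <- colMeans(reference$points)
  Ps <- sweep(cloud$points, 2, cs)
  Pr <- sweep(reference$points, 2, cr)
  Vr <- signed_axes(Pr)
  Vs <- signed_axes(Ps)
  R0 <- Vr %*% t(Vs)
  mirrored <- FALSE
  mirror_normal <- NULL
  if (det(R0) < 0) {
    if (allow_mirror) {
      mirrored <- TRUE
      mirror_normal <- Vs[, 1]
      Pm <- Ps - 2 * (Ps %*% mirror_normal) %*% t(mirror_normal)
      Vs <- signed_axes(Pm)
      R0 <- Vr %*% t(Vs)
      if (det(R0) < 0) { # safeguard: flip least-variance axis
        Vs[, 3] <- -Vs[, 3]
        R0 <- Vr %*% t(Vs)
      }
    } else {
      Vs[, 3] <- -Vs[, 3]
      R0 <- Vr %*% t(Vs)
    }
  }
  # Re-orthonormalize against accumulated floating-point drift.
  sv <- svd(R0)
  R0 <- sv$u %*% t(sv$v)
  tf <- rigid_transform(rotation = R0, translation = cr, mirrored = mirrored,
                        mirror_normal = mirror_normal, center = cs)
  list(cloud = apply_transform(cloud, tf), transform = tf)
}

#' Registration quality report
#'
#' @param iterations Iterations run.
#' @param final_rmse Final point-to-plane RMSE (mm) over accepted pairs.
#' @param rejected_fraction Fraction of source points rejected in the final
#'   iteration.
#' @param converged Whether the convergence threshold was met.
#' @param passed_gate Whether `final_rmse` is at or below the RMSE gate.
#' @return A `registration_report` list.
#' @export
registration_report <- function(iterations, final_rmse, rejected_fraction,
                                converged, passed_gate) {
  stopifnot(final_rmse >= 0, rejected_fraction >= 0, rejected_fraction <= 1)
  structure(list(iterations = as.integer(iterations), final_rmse = final_rmse,
                 rejected_fraction = rejected_fraction,
                 converged = isTRUE(converged),
                 passed_gate = isTRUE(passed_gate)),
            class = "registration_report")
}

#' @export
print.registration_report <- function(x, ...) {
  cat(sprintf(
    "ICP: %d iteration(s), RMSE %.4g mm, %.1f%% rejected, %s, gate %s\n",
    x$iterations, x$final_rmse, 100 * x$rejected_fraction,
    if (x$converged) "converged" else "not converged",
    if (x$passed_gate) "passed" else "FAILED"))
  invisible(x)
}

#' Point-to-plane ICP registration
#'
#' Iteratively minimizes the sum of squared point-to-plane distances
#' between the source points and the tangent planes of their nearest
#' target points, using the standard linearized (small-angle)
#' normal-equations solve per iteration. Pairs further apart than
#' `reject_dist` (Euclidean) are excluded from each iteration's objective.
#' Iteration stops when the absolute change in mean point-to-plane error
#' drops below `convergence_tol` or `max_iters` is reached. The report's
#' `passed_gate` records whether the final RMSE meets the quality gate.
#'
#' @param source Source [point_cloud].
#' @param target Target [point_cloud] carrying normals (see
#'   [estimate_normals]).
#' @param params An [icp_params] set.
#' @return List with `transform` ([rigid_transform] mapping source to
#'   target), `report` ([registration_report]) and `cloud` (the transformed
#'   source).
#' @export
icp_point_to_plane <- function(source, target, params = icp_params()) {
  stopifnot(inherits(source, "point_cloud"), inherits(target, "point_cloud"),
            inherits(params, "icp_params"))
  if (is.null(target$normals))
    stopf("target cloud has no normals; run estimate_normals() first")
  S <- source$points
  Tp <- target$points
  Tn <- target$normals
  R_tot <- diag(3)
  t_tot <- c(0, 0, 0)
  prev_err <- Inf
  converged <- FALSE
  iterations <- 0L
  final_rmse <- NA_real_
  rejected_fraction <- NA_real_
  history <- numeric(0)
  for (it in seq_len(params$max_iters)) {
    iterations <- it
    nn <- cpp_nn1_grid(S, Tp)
    accept <- nn$dist <= params$reject_dist
    rejected_fraction <- mean(!accept)
    if (!any(accept))
      stopf("ICP failed: no accepted pairs within %.3g mm (all rejected)",
            params$reject_dist)
    src <- S[accept, , drop = FALSE]
    tgt <- Tp[nn$index[accept], , drop = FALSE]
    nrm <- Tn[nn$index[accept], , drop = FALSE]
    d <- rowSums((src - tgt) * nrm)
    cx <- src[, 2] * nrm[, 3] - src[, 3] * nrm[, 2]
    cy <- src[, 3] * nrm[, 1] - src[, 1] * nrm[, 3]
    cz <- src[, 1] * nrm[, 2] - src[, 2] * nrm[, 1]
    A <- cbind(cx, cy, cz, nrm)
    AtA <- crossprod(A)
    Atb <- crossprod(A, -d)
    # Truncated-eigenvalue pseudo-inverse: unconstrained motions (e.g. the
    # sliding modes of near-symmetric surfaces) get a zero update instead
    # of a noise-amplified one.
    ed <- eigen(AtA, symmetric = TRUE)
    keep <- ed$values > ed$values[1] * 1e-9
    if (!any(keep)) stopf("ICP solve failed: degenerate normal equations")
    Vk <- ed$vectors[, keep, drop = FALSE]
    x <- Vk %*% (crossprod(Vk, Atb) / ed$values[keep])
    if (!all(is.finite(x))) stopf("ICP produced a non-finite solve")
    R_inc <- rodrigues(x[1:3])
    t_inc <- x[4:6]
    S <- sweep(S %*% t(R_inc), 2, t_inc, `+`)
    R_tot <- R_inc %*% R_tot
    t_tot <- as.numeric(R_inc %*% t_tot) + t_inc
    res <- rowSums((S[accept, , drop = FALSE] - tgt) * nrm)
    err <- mean(abs(res))
    final_rmse <- sqrt(mean(res^2))
    history <- c(history, err)
    if (abs(prev_err - err) < params$convergence_tol) {
      converged <- TRUE
      break
    }
    prev_err <- err
  }
  report <- registration_report(iterations, final_rmse, rejected_fraction,
                                converged,
                                passed_gate = final_rmse <= params$rmse_gate)
  report$error_history <- history
  tf <- rigid_transform(rotation = R_tot, translation = t_tot)
  out_cloud <- point_cloud(S, subject_id = source$subject_id,
                           side = source$side)
  list(transform = tf, report = report, cloud = out_cloud)
}
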