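# Synthetic bone-shape cohorts. A stylized distal radius template
# (cylindrical shaft flaring into an elliptical head, styloid protrusion,
# sigmoid notch, dorsal tubercle) is deformed per group with known ground
# truth, so correspondence, shape-model recovery and classification are
# all testable without any imaging data. Conventions: shaft axis = +z,
# dorsal = +y, radial (styloid) side = +x; all coordinates in mm.

TEMPLATE_LENGTH <- 50   # shaft length, mm
TEMPLATE_RADIUS <- 7    # shaft radius, mm

# Parametric template surface: returns the (x, y, z) point for cylinder
# angle theta and axial coordinate z0 (both vectors). The shaft is an
# elliptical, gently tapering prism with an interosseous crest along the
# medial border -- real radius shafts are not surfaces of revolution, and
# that asymmetry is what makes rigid registration well-posed.
template_surface <- function(theta, z0) {
  f <- smoothstep((z0 - 38) / 12)           # head flare
  taper <- 1 + 0.004 * (z0 - 25)            # shaft widens distally
  a <- TEMPLATE_RADIUS * taper * (1.1 + 0.9 * f)  # radial (x) semi-axis
  b <- TEMPLATE_RADIUS * taper * (0.85 + 0.5 * f) # dorso-volar (y) semi-axis
  # interosseous crest: sharp medial ridge running the length of the shaft
  dth_c <- atan2(sin(theta - pi), cos(theta - pi))
  crest <- 0.3 * exp(-(dth_c / 0.45)^2) * (1 - f)
  # sigmoid notch: medial depression centred at theta = pi, z = 47
  dth_n <- atan2(sin(theta - pi), cos(theta - pi))
  notch <- 0.25 * exp(-(dth_n / 0.4)^2 - ((z0 - 47) / 2.5)^2)
  # Lister's tubercle: dorsal bump centred at theta = pi/2, z = 45
  dth_t <- atan2(sin(theta - pi / 2), cos(theta - pi / 2))
  tub <- 0.15 * exp(-(dth_t / 0.35)^2 - ((z0 - 45) / 2.5)^2)
  scale <- 1 - notch + tub + crest
  x <- a * cos(theta) * scale
  y <- b * sin(theta) * scale
  # styloid: lateral axial extension peaking at theta = 0 near the top
  dth_s <- atan2(sin(theta), cos(theta))
  z <- z0 + 6 * exp(-(dth_s / 0.5)^2) * smoothstep((z0 - 44) / 6)
  cbind(x, y, z)
}

#' Build the stylized distal radius template
#'
#' Samples `n_points` surface points of a deterministic parametric bone
#' model (per seed) and places the four landmarks and the lunate-facet
#' crest line analytically on the surface: A/B at the volar/dorsal lips of
#' the sigmoid notch, C at the styloid apex, D on the tubercle, facet line
#' across the distal articular rim.
#'
#' @param n_points Number of surface points (default 2000, at least 200).
#' @param seed RNG seed for the surface sampling.
#' @return List with `cloud` ([point_cloud]), `landmarks`
#'   ([landmark_set]) and `facet_line` (2 x 3 matrix).
#' @export
make_template <- function(n_points = 2000L, seed = 1L) {
  n_points <- as.integer(n_points)
  if (n_points < 200L) stopf("n_points must be at least 200")
  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  theta <- runif(n_points, 0, 2 * pi)
  z0 <- runif(n_points, 0, TEMPLATE_LENGTH)
  pts <- template_surface(theta, z0)
  lm <- landmark_set(
    A = template_surface(pi + 0.5, 47)[1, ],  # volar lip (y < 0 side)
    B = template_surface(pi - 0.5, 47)[1, ],  # dorsal lip (y > 0 side)
    C = template_surface(0, TEMPLATE_LENGTH)[1, ],  # styloid apex
    D = template_surface(pi / 2, 45)[1, ]     # Lister's tubercle
  )
  facet <- rbind(template_surface(-pi / 2, 49)[1, ],
                 template_surface(pi / 2, 49)[1, ])
  list(cloud = point_cloud(pts, subject_id = "template"),
       landmarks = lm, facet_line = facet)
}

#' Apply a group-specific deformation
#'
#' Colles'/Smith's: the distal segment (top 25% of the axial range) is
#' rotated dorsally/volarly about a transverse (x) axis through the
#' osteotomy plane by the given angulation, blended smoothly over a 5%
#' transition band proximal to the plane so the distal segment itself
#' moves rigidly. Barton's: the distal articular block (top 15% of the
#' axial range) is translated dorsally by the given displacement. Normal:
#' identity. Landmarks and the facet line are carried through the same
#' deformation field; ground truth (signed dorsal angulation, articular
#' displacement) is returned.
#'
#' @param template A template as returned by [make_template].
#' @param group One of `"normal"`, `"colles"`, `"smith"`, `"barton"`.
#' @param angulation_deg Angulation magnitude in degrees (Colles/Smith).
#' @param displacement_mm Articular displacement in mm (Barton).
#' @return List with `cloud`, `landmarks`, `facet_line` and `truth`
#'   (list: `group`, `angulation` signed, positive dorsal; `displacement`).
#' @export
apply_group_deformation <- function(template, group, angulation_deg = 25,
                                    displacement_mm = 3) {
  group <- match.arg(group, GROUP_LEVELS)
  P <- template$cloud$points
  zr <- range(P[, 3])
  z75 <- zr[1] + 0.75 * diff(zr)
  z85 <- zr[1] + 0.85 * diff(zr)
  band <- 0.05 * diff(zr)
  angulation <- 0
  displacement <- 0
  deform <- identity
  if (group %in% c("colles", "smith")) {
    angulation <- if (group == "colles") angulation_deg else -angulation_deg
    cxy <- colMeans(P[, 1:2, drop = FALSE])
    pivot <- c(cxy, z75)
    th <- angulation * pi / 180
    deform <- function(Q) {
      Q <- if (is.matrix(Q)) Q else matrix(Q, nrow = 1)
      # weight 1 for z >= z75 (rigid distal segment), smooth drop below
      w <- smoothstep((Q[, 3] - (z75 - band)) / band)
      y <- Q[, 2] - pivot[2]
      z <- Q[, 3] - pivot[3]
      wth <- w * th
      # +z tips toward +y (dorsal) for positive angles
      Q2 <- Q
      Q2[, 2] <- pivot[2] + cos(wth) * y + sin(wth) * z
      Q2[, 3] <- pivot[3] - sin(wth) * y + cos(wth) * z
      if (nrow(Q2) == 1L && !is.matrix(Q)) as.numeric(Q2) else Q2
    }
  } else if (group == "barton") {
    displacement <- displacement_mm
    deform <- function(Q) {
      Q <- if (is.matrix(Q)) Q else matrix(Q, nrow = 1)
      Q2 <- Q
      block <- Q[, 3] > z85
      Q2[block, 2] <- Q2[block, 2] + displacement_mm
      if (nrow(Q2) == 1L && !is.matrix(Q)) as.numeric(Q2) else Q2
    }
  }
  dnum <- function(v) as.numeric(deform(matrix(v, nrow = 1)))
  list(cloud = point_cloud(deform(P), subject_id = template$cloud$subject_id),
       landmarks = map_landmarks(template$landmarks, dnum),
       facet_line = deform(template$facet_line),
       truth = list(group = group, angulation = angulation,
                    displacement = displacement))
}

#' Synthetic population specification
#'
#' Defaults emulate a clinical case mix (43 normal, 17 Colles',
#' 12 Barton's, 8 Smith's) with deformation magnitudes just beyond the
#' diagnostic criteria (25 degrees angulation against the 20-degree rule;
#' 3 mm displacement against the 2 mm rule), 20% within-group spread,
#' 0.3 mm additive coordinate noise (below the 0.5 mm registration gate),
#' random rigid misalignment and point-order permutation.
#'
#' @param group_sizes Named counts per group.
#' @param n_points Template point count (default 2000).
#' @param colles_angulation_deg,smith_angulation_deg,barton_displacement_mm
#'   Group-mean deformation magnitudes.
#' @param spread_frac Within-group SD as a fraction of the group mean
#'   (default 0.2; per-subject magnitudes are truncated at 0).
#' @param noise_sd Isotropic coordinate noise SD in mm (default 0.3).
#' @param misalign_rot_deg,misalign_trans_mm Random rigid misalignment
#'   ranges (rotation about a random axis up to the given angle,
#'   translation per coordinate up to the given magnitude).
#' @param permute_points Randomly permute the point order of each subject
#'   (default TRUE).
#' @param seed Root RNG seed.
#' @return A `population_spec` list.
#' @export
population_spec <- function(group_sizes = c(normal = 43, colles = 17,
                                            barton = 12, smith = 8),
                            n_points = 2000L,
                            colles_angulation_deg = 25,
                            smith_angulation_deg = 25,
                            barton_displacement_mm = 3,
                            spread_frac = 0.2,
                            noise_sd = 0.3,
                            misalign_rot_deg = 15,
                            misalign_trans_mm = 5,
                            permute_points = TRUE,
                            seed = 1L) {
  stopifnot(all(group_sizes >= 2), colles_angulation_deg >= 0,
            smith_angulation_deg >= 0, barton_displacement_mm >= 0,
            spread_frac >= 0, noise_sd >= 0, misalign_rot_deg >= 0,
            misalign_trans_mm >= 0)
  bad <- setdiff(names(group_sizes), GROUP_LEVELS)
  if (length(bad)) stopf("unknown group(s): %s", paste(bad, collapse = ", "))
  structure(list(group_sizes = group_sizes, n_points = as.integer(n_points),
                 colles_angulation_deg = colles_angulation_deg,
                 smith_angulation_deg = smith_angulation_deg,
                 barton_displacement_mm = barton_displacement_mm,
                 spread_frac = spread_frac, noise_sd = noise_sd,
                 misalign_rot_deg = misalign_rot_deg,
                 misalign_trans_mm = misalign_trans_mm,
                 permute_points = isTRUE(permute_points),
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate a synthetic cohort
#'
#' Per subject: template -> group deformation with the per-subject
#' magnitude drawn from a truncated Gaussian around the group mean ->
#' isotropic coordinate noise -> optional random rigid misalignment and
#' point permutation. All ground truth (magnitudes, applied transform,
#' permutation, and the canonical cloud before misalignment/permutation)
#' is returned, and the whole draw is bit-reproducible per seed.
#'
#' @param spec A [population_spec].
#' @return A `synthetic_cohort`: lists `clouds`, `landmarks`,
#'   `facet_lines`, `canonical` (pre-misalignment clouds), character
#'   vector `labels`, data frame `truth`, plus `template` and `spec`.
#' @export
generate_population <- function(spec = population_spec()) {
  stopifnot(inherits(spec, "population_spec"))
  old <- globalenv()$.Random.seed
  set.seed(spec$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  template <- make_template(spec$n_points, seed = spec$seed)
  labels <- rep(names(spec$group_sizes), spec$group_sizes)
  n <- length(labels)
  clouds <- vector("list", n)
  canonical <- vector("list", n)
  lms <- vector("list", n)
  facets <- vector("list", n)
  truth <- data.frame(subject = paste0("S", sprintf("%03d", seq_len(n))),
                      group = labels, angulation = 0, displacement = 0,
                      stringsAsFactors = FALSE)
  transforms <- vector("list", n)
  permutations <- vector("list", n)
  mean_mag <- c(normal = 0, colles = spec$colles_angulation_deg,
                smith = spec$smith_angulation_deg,
                barton = spec$barton_displacement_mm)
  for (i in seq_len(n)) {
    g <- labels[i]
    mag <- mean_mag[[g]]
    if (g != "normal" && spec$spread_frac > 0)
      mag <- max(0, rnorm(1, mag, spec$spread_frac * mag))
    def <- apply_group_deformation(template, g,
                                   angulation_deg = mag,
                                   displacement_mm = mag)
    P <- def$cloud$points
    if (spec$noise_sd > 0)
      P <- P + matrix(rnorm(length(P), 0, spec$noise_sd), nrow(P), 3)
    canonical[[i]] <- point_cloud(P, subject_id = truth$subject[i])
    tf <- rigid_transform()
    if (spec$misalign_rot_deg > 0 || spec$misalign_trans_mm > 0) {
      R <- if (spec$misalign_rot_deg > 0) random_rotation(spec$misalign_rot_deg)
      else diag(3)
      tr <- runif(3, -spec$misalign_trans_mm, spec$misalign_trans_mm)
      tf <- rigid_transform(rotation = R, translation = tr)
    }
    P <- apply_transform(P, tf)
    lms[[i]] <- map_landmarks(def$landmarks,
                              function(v) as.numeric(apply_transform(
                                matrix(v, nrow = 1), tf)))
    facets[[i]] <- apply_transform(def$facet_line, tf)
    perm <- seq_len(nrow(P))
    if (spec$permute_points) perm <- sample.int(nrow(P))
    clouds[[i]] <- point_cloud(P[perm, , drop = FALSE],
                               subject_id = truth$subject[i])
    transforms[[i]] <- tf
    permutations[[i]] <- perm
    truth$angulation[i] <- def$truth$angulation
    truth$displacement[i] <- def$truth$displacement
  }
  structure(list(clouds = clouds, landmarks = lms, facet_lines = facets,
                 canonical = canonical, labels = labels, truth = truth,
                 transforms = transforms, permutations = permutations,
                 template = template, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects (%s), %d points each\n",
              length(x$clouds),
              paste(sprintf("%s %d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", "),
              n_points(x$clouds[[1]])))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes one PLY cloud and one landmark CSV per subject, a manifest CSV
#' and a ground-truth JSON into `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(cohort$clouds)
  cloud_files <- sprintf("%s.ply", cohort$truth$subject)
  lm_files <- sprintf("%s_landmarks.csv", cohort$truth$subject)
  for (i in seq_len(n)) {
    write_point_cloud(cohort$clouds[[i]], file.path(dir, cloud_files[i]))
    write_landmarks(cohort$landmarks[[i]], file.path(dir, lm_files[i]))
  }
  manifest <- data.frame(cloud = cloud_files, landmarks = lm_files,
                         group = cohort$labels)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}
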