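# Landmark morphometrics: the six anatomical indicators (four distances
# AB, bc, AC, CD in mm; two angles ALF, ASR in degrees), the rule-based
# fracture criteria, and group comparison with assumption checks.

#' Rule-based fracture criteria
#'
#' Quantitative thresholds for the three fracture patterns: Colles'
#' (dorsal angulation > 20 degrees), Smith's (volar angulation > 20
#' degrees) and Barton's (articular surface displacement > 2 mm).
#'
#' @param dorsal_angulation_deg,volar_angulation_deg Angulation thresholds
#'   in degrees (defaults 20).
#' @param articular_displacement_mm Displacement threshold in mm
#'   (default 2).
#' @return A `rule_criteria` list.
#' @export
rule_criteria <- function(dorsal_angulation_deg = 20,
                          volar_angulation_deg = 20,
                          articular_displacement_mm = 2) {
  stopifnot(dorsal_angulation_deg > 0, volar_angulation_deg > 0,
            articular_displacement_mm > 0)
  structure(list(dorsal_angulation_deg = dorsal_angulation_deg,
                 volar_angulation_deg = volar_angulation_deg,
                 articular_displacement_mm = articular_displacement_mm),
            class = "rule_criteria")
}

#' Radius long axis
#'
#' First principal axis of the cloud, oriented so it points from the
#' centroid toward the supplied distal hint.
#'
#' @param cloud A [point_cloud].
#' @param distal_hint A 3-D point on the distal side.
#' @return Unit length-3 vector.
#' @export
long_axis <- function(cloud, distal_hint) {
  stopifnot(inherits(cloud, "point_cloud"))
  Pc <- sweep(cloud$points, 2, colMeans(cloud$points))
  e <- eigen(cov(Pc), symmetric = TRUE)
  if (e$values[1] <= 0 ||
      (e$values[1] - e$values[2]) / e$values[1] < 1e-9)
    stopf("cloud has no well-defined long axis (isotropic)")
  ax <- e$vectors[, 1]
  d <- as.numeric(distal_hint) - colMeans(cloud$points)
  if (sum(ax * d) < 0) ax <- -ax
  unit_vector(ax)
}

#' Morphometric profile of one subject
#'
#' Computes the six indicators from the landmark set, the radius long axis
#' and the lunate-facet crest line: AB = |A - B|, bc = |B - C|,
#' AC = |A - C|, CD = |C - D| (mm); ALF = angle between the lunate-facet
#' line direction and the long axis; ASR = angle between the line from the
#' sigmoid-notch midpoint (midpoint of A and B) to the styloid vertex C and
#' the long axis (degrees, in \[0, 180\]).
#'
#' @param landmarks A [landmark_set].
#' @param axis Unit long-axis vector (see [long_axis]).
#' @param facet_line Two-point lunate-facet crest line: a 2 x 3 matrix or a
#'   list of two 3-D points.
#' @return A `morphometric_profile` (named list AB, bc, AC, CD, ALF, ASR).
#' @export
measure_profile <- function(landmarks, axis, facet_line) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (is.list(facet_line) && !is.matrix(facet_line))
    facet_line <- rbind(facet_line[[1]], facet_line[[2]])
  facet_line <- as.matrix(facet_line)
  if (!all(dim(facet_line) == c(2, 3)))
    stopf("facet_line must supply exactly two 3-D points")
  fdir <- facet_line[2, ] - facet_line[1, ]
  if (sum(fdir^2) == 0) stopf("lunate-facet line has zero length")
  mid <- (landmarks$A + landmarks$B) / 2
  asr_dir <- landmarks$C - mid
  if (sum(asr_dir^2) == 0)
    stopf("sigmoid-notch midpoint coincides with the styloid vertex")
  d <- function(p, q) sqrt(sum((p - q)^2))
  structure(list(
    AB = d(landmarks$A, landmarks$B),
    bc = d(landmarks$B, landmarks$C),
    AC = d(landmarks$A, landmarks$C),
    CD = d(landmarks$C, landmarks$D),
    ALF = angle_between(fdir, axis),
    ASR = angle_between(asr_dir, axis)
  ), class = "morphometric_profile")
}

INDICATORS <- c("AB", "bc", "AC", "CD", "ALF", "ASR")

#' Rule-based fracture classification
#'
#' Applies the quantitative criteria with Barton's checked first (articular
#' displacement is its defining feature), then Colles'/Smith's by the sign
#' of the angulation (positive = dorsal, negative = volar).
#'
#' @param dorsal_angulation Signed angulation in degrees (positive dorsal).
#' @param displacement Articular surface displacement in mm.
#' @param criteria A [rule_criteria] set.
#' @return One of `"barton"`, `"colles"`, `"smith"`, `"normal"`.
#' @export
classify_by_rule <- function(dorsal_angulation, displacement,
                             criteria = rule_criteria()) {
  stopifnot(is.finite(dorsal_angulation), is.finite(displacement),
            inherits(criteria, "rule_criteria"))
  if (displacement > criteria$articular_displacement_mm) return("barton")
  if (dorsal_angulation > criteria$dorsal_angulation_deg) return("colles")
  if (dorsal_angulation < -criteria$volar_angulation_deg) return("smith")
  "normal"
}

#' Compare indicator distributions across groups
#'
#' For each indicator: Shapiro-Wilk normality per group, Levene's test of
#' variance homogeneity (deviations from the group mean), one-way ANOVA,
#' and Tukey HSD pairwise comparisons with 95% confidence intervals.
#' Significance stars: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#' Groups with fewer than 2 subjects are excluded with a warning.
#'
#' @param profiles Data frame with one row per subject and (a subset of)
#'   the indicator columns `AB`, `bc`, `AC`, `CD`, `ALF`, `ASR`, or a list
#'   of `morphometric_profile`s.
#' @param groups Group label per subject.
#' @param indicators Indicator columns to analyze (default: all present).
#' @return A `group_comparison`: per indicator, a list with `shapiro`
#'   (data frame), `levene` (F, df, p), `anova` (F, df1, df2, p, stars) and
#'   `tukey` (data frame of pairwise differences).
#' @export
group_compare <- function(profiles, groups,
                          indicators = NULL) {
  if (is.list(profiles) && !is.data.frame(profiles) &&
      all(vapply(profiles, inherits, TRUE, "morphometric_profile")))
    profiles <- as.data.frame(do.call(rbind, lapply(profiles, unlist)))
  profiles <- as.data.frame(profiles)
  if (is.null(indicators)) indicators <- intersect(INDICATORS,
                                                   names(profiles))
  if (!length(indicators)) stopf("no indicator columns found")
  if (length(groups) != nrow(profiles))
    stopf("groups must have one entry per profile row")
  groups <- factor(groups)
  counts <- table(groups)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warnf("excluding group(s) with < 2 subjects: %s",
          paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    profiles <- profiles[keep, , drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stopf("need at least 2 groups with >= 2 subjects")
  stars <- function(p) ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  out <- lapply(indicators, function(ind) {
    y <- profiles[[ind]]
    shap <- do.call(rbind, lapply(levels(groups), function(g) {
      yy <- y[groups == g]
      if (length(yy) >= 3 && length(yy) <= 5000 && sd(yy) > 0) {
        sw <- shapiro.test(yy)
        data.frame(group = g, n = length(yy), W = unname(sw$statistic),
                   p = sw$p.value)
      } else {
        data.frame(group = g, n = length(yy), W = NA_real_, p = NA_real_)
      }
    }))
    lev <- car::leveneTest(y, groups, center = mean)
    fit <- aov(y ~ groups)
    at <- anova(fit)
    tk <- TukeyHSD(fit, conf.level = 0.95)$groups
    tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                        lwr = tk[, "lwr"], upr = tk[, "upr"],
                        p_adj = tk[, "p adj"],
                        stars = stars(tk[, "p adj"]),
                        row.names = NULL)
    list(shapiro = shap,
         levene = list(F = lev[1, "F value"], df1 = lev[1, "Df"],
                       df2 = lev[2, "Df"], p = lev[1, "Pr(>F)"]),
         anova = list(F = at["groups", "F value"],
                      df1 = at["groups", "Df"],
                      df2 = at["Residuals", "Df"],
                      p = at["groups", "Pr(>F)"],
                      stars = stars(at["groups", "Pr(>F)"])),
         tukey = tukey)
  })
  names(out) <- indicators
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  for (ind in names(x)) {
    a <- x[[ind]]$anova
    cat(sprintf("%-4s ANOVA F(%d, %d) = %.3f, p = %.3g %s\n", ind, a$df1,
                a$df2, a$F, a$p, a$stars))
  }
  invisible(x)
}
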