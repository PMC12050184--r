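# End-to-end pipeline: register -> correspond -> pooled SSM -> features ->
# cross-validated classification, with per-group shape-model variance
# reports. All randomness flows from one root seed.

#' Pipeline configuration
#'
#' One declarative object holding every stage default. Unknown keys are
#' rejected.
#'
#' @param voxel Downsampling voxel size in mm (default 1).
#' @param icp [icp_params] for registration.
#' @param allow_mirror Allow mirroring in the initial alignment (for
#'   right-sided wrists; default FALSE).
#' @param proximal_fraction Fraction of the reference's axial extent,
#'   measured from the proximal end, used as the ICP source region
#'   (default 0.7). Anchoring the fine registration on the proximal
#'   radius keeps the (possibly fractured) distal end from dragging the
#'   pose; set to 1 to register on the whole bone.
#' @param normal_k Neighbour count for reference normal estimation.
#' @param unique_correspondence One-to-one matching (default FALSE).
#' @param alpha Retained-variance target of the pooled SSM (default 0.75).
#' @param F_counts Feature counts for the cross-validation study.
#' @param k Cross-validation folds (default 4).
#' @param hidden_size,learning_rate,max_epochs Classifier hyperparameters.
#' @param leaky_thresholds See [cross_validate].
#' @param seed Root seed; per-stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(voxel = 1, icp = icp_params(),
                            allow_mirror = FALSE, proximal_fraction = 0.7,
                            normal_k = 20L,
                            unique_correspondence = FALSE, alpha = 0.75,
                            F_counts = c(5, 10, 15), k = 4L,
                            hidden_size = 10L, learning_rate = 0.01,
                            max_epochs = 2000L, leaky_thresholds = FALSE,
                            seed = 1L) {
  stopifnot(proximal_fraction > 0, proximal_fraction <= 1)
  structure(list(voxel = voxel, icp = icp, allow_mirror = allow_mirror,
                 proximal_fraction = proximal_fraction,
                 normal_k = as.integer(normal_k),
                 unique_correspondence = unique_correspondence,
                 alpha = alpha, F_counts = F_counts, k = as.integer(k),
                 hidden_size = as.integer(hidden_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 leaky_thresholds = leaky_thresholds,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' JSON file whose keys are [pipeline_config] arguments (`icp` given as an
#' object of [icp_params] arguments); unknown keys are an error.
#'
#' @param path JSON config path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(obj), known)
  if (length(bad))
    stopf("%s: unknown config key(s): %s", path, paste(bad, collapse = ", "))
  if (!is.null(obj$icp)) obj$icp <- do.call(icp_params, as.list(obj$icp))
  do.call(pipeline_config, obj)
}

#' Run the full shape-classification pipeline
#'
#' Stages: voxel downsampling of every cloud; principal-axis
#' pre-alignment and point-to-plane ICP of each subject onto the reference
#' (the first subject); nearest-neighbour correspondence to the reference
#' point order; pooled PCA shape model; projection of every subject to the
#' leading coefficients; stratified k-fold cross-validation of the
#' neural-network classifier over the requested feature counts. Per-group
#' shape models are also fitted for the cumulative-variance report.
#'
#' @param input A `synthetic_cohort` (see [generate_population]), a
#'   manifest path (see [read_manifest]), or a list of [point_cloud]s plus
#'   `labels`.
#' @param config A [pipeline_config].
#' @param labels Group labels (required when `input` is a list of clouds).
#' @param out_dir Optional report directory; when given, CSV/JSON reports
#'   are written (see [write_pipeline_reports]).
#' @return A `pipeline_result` with the registration reports,
#'   correspondence summaries, pooled `ssm`, per-group cumulative-variance
#'   table, feature matrix and the `crossval_report`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), labels = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(input, "synthetic_cohort")) {
    clouds <- input$clouds
    labels <- input$labels
  } else if (is.character(input) && length(input) == 1L) {
    manifest <- read_manifest(input)
    clouds <- lapply(seq_len(nrow(manifest)), function(i) {
      tryCatch(read_point_cloud(manifest$cloud[i],
                                subject_id = basename(manifest$cloud[i])),
               error = function(e)
                 stopf("stage shape_io, subject %d (%s): %s", i,
                       manifest$cloud[i], conditionMessage(e)))
    })
    labels <- as.character(manifest$group)
  } else if (is.list(input)) {
    clouds <- input
    if (is.null(labels)) stopf("labels are required with a list of clouds")
  } else stopf("unsupported input type")
  n <- length(clouds)
  if (n < 2L) stopf("pipeline needs at least 2 subjects")
  labels <- as.character(labels)

  # --- registration ---------------------------------------------------
  down <- lapply(clouds, voxel_downsample, voxel = config$voxel)
  reference <- estimate_normals(down[[1]], k = config$normal_k)
  # Fine registration is anchored on the proximal radius: ICP runs on the
  # source points in the proximal part of the reference's axial extent so
  # a deformed distal end cannot drag the pose.
  ax <- distal_axis(reference)
  s_ref <- as.numeric(sweep(reference$points, 2, ax$origin) %*% ax$axis)
  s_cut <- min(s_ref) + config$proximal_fraction * diff(range(s_ref))
  registered <- vector("list", n)
  reg_reports <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      ia <- initial_align(down[[i]], reference,
                          allow_mirror = config$allow_mirror)
      s <- as.numeric(sweep(ia$cloud$points, 2, ax$origin) %*% ax$axis)
      prox <- ia$cloud$points[s <= s_cut, , drop = FALSE]
      if (nrow(prox) < 10)
        stopf("fewer than 10 points in the proximal registration region")
      fit <- icp_point_to_plane(point_cloud(prox), reference, config$icp)
      list(cloud = apply_transform(ia$cloud, fit$transform),
           report = fit$report)
    }, error = function(e)
      stopf("stage registration, subject %d: %s", i, conditionMessage(e)))
    registered[[i]] <- res$cloud
    reg_reports[[i]] <- res$report
  }

  # --- correspondence -------------------------------------------------
  corresponded <- vector("list", n)
  corr_errors <- vector("list", n)
  for (i in seq_len(n)) {
    rc <- reorder_to_reference(reference, registered[[i]],
                               unique = config$unique_correspondence)
    corresponded[[i]] <- rc$cloud
    corr_errors[[i]] <- correspondence_errors(rc$map,
                                              config$icp$reject_dist)
  }

  # --- shape model ----------------------------------------------------
  dataset <- build_shape_matrix(corresponded, labels = labels)
  ssm <- fit_ssm(dataset, alpha = config$alpha)
  Fmax <- max(config$F_counts)
  if (Fmax > ssm$rank)
    stopf("stage ssm: requested %d features but model rank is only %d",
          Fmax, ssm$rank)
  features <- t(vapply(seq_len(n), function(i)
    project_shape(ssm, dataset$X[i, ], t = Fmax), numeric(Fmax)))

  group_table <- group_variance_table(dataset, config$F_counts)

  # --- cross-validated classification ---------------------------------
  cv <- cross_validate(features, labels, F_counts = config$F_counts,
                       k = config$k, seed = config$seed,
                       config = train_config(
                         learning_rate = config$learning_rate,
                         max_epochs = config$max_epochs,
                         seed = config$seed),
                       hidden_size = config$hidden_size,
                       feature_scale = sqrt(ssm$eigenvalues[seq_len(Fmax)]),
                       leaky_thresholds = config$leaky_thresholds)

  result <- structure(list(registration = reg_reports,
                           correspondence = corr_errors, ssm = ssm,
                           group_variance = group_table,
                           features = features, labels = labels,
                           cv = cv, config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_reports(result, out_dir)
  result
}

# Long axis of a reference bone with the distal direction identified as
# the end with the larger perpendicular spread (the flared articular
# head). Returns the unit axis (pointing distal), the centroid origin.
distal_axis <- function(cloud) {
  ctr <- colMeans(cloud$points)
  Pc <- sweep(cloud$points, 2, ctr)
  e <- eigen(cov(Pc), symmetric = TRUE)
  axis <- e$vectors[, 1]
  s <- as.numeric(Pc %*% axis)
  qs <- quantile(s, c(0.25, 0.75))
  perp <- Pc - outer(s, axis)
  r2 <- rowSums(perp^2)
  if (mean(r2[s >= qs[2]]) < mean(r2[s <= qs[1]])) axis <- -axis
  list(axis = axis, origin = ctr)
}

# Per-group cumulative variance contribution (percent) at the requested
# feature counts; groups with < 2 subjects are skipped.
group_variance_table <- function(dataset, F_counts) {
  groups <- unique(dataset$labels)
  rows <- lapply(groups, function(g) {
    idx <- which(dataset$labels == g)
    if (length(idx) < 2) return(NULL)
    m <- fit_ssm(dataset$X[idx, , drop = FALSE], alpha = 1)
    vals <- vapply(F_counts, function(f)
      100 * cumulative_contribution(m, f), 0)
    df <- data.frame(group = g, n = length(idx))
    for (j in seq_along(F_counts)) df[[paste0("F", F_counts[j])]] <- vals[j]
    df
  })
  do.call(rbind, rows)
}

#' @export
print.pipeline_result <- function(x, ...) {
  gates <- vapply(x$registration, `[[`, TRUE, "passed_gate")
  cat(sprintf("pipeline_result: %d subjects, %d/%d passed the RMSE gate\n",
              length(x$registration), sum(gates), length(gates)))
  cat(sprintf("pooled SSM rank %d, t = %d (alpha = %.2f)\n", x$ssm$rank,
              x$ssm$t, x$ssm$alpha))
  print(x$cv)
  invisible(x)
}

#' Write pipeline reports
#'
#' Emits `group_variance.csv` (per-group cumulative variance percentages),
#' `auc.csv`, `thresholds.csv`, `accuracy.csv` (per fold and feature
#' count) and one `confusion_F<k>.json` per feature count. Output is
#' deterministic (no timestamps).
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_pipeline_reports <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$group_variance, file.path(dir, "group_variance.csv"),
            row.names = FALSE, quote = FALSE)
  flat <- function(field) {
    do.call(rbind, lapply(result$cv$reports, function(rep) {
      m <- rep[[field]]
      data.frame(F = rep$F, fold = rownames(m), m, row.names = NULL)
    }))
  }
  write.csv(flat("auc"), file.path(dir, "auc.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(flat("thresholds"), file.path(dir, "thresholds.csv"),
            row.names = FALSE, quote = FALSE)
  acc <- do.call(rbind, lapply(result$cv$reports, function(rep)
    data.frame(F = rep$F, fold = paste0("k_", seq_along(rep$accuracy)),
               accuracy = rep$accuracy, row.names = NULL)))
  write.csv(acc, file.path(dir, "accuracy.csv"), row.names = FALSE,
            quote = FALSE)
  for (rep in result$cv$reports) {
    conf <- lapply(rep$confusion, function(m)
      as.data.frame(as.table(m)))
    jsonlite::write_json(conf, file.path(dir,
                                         sprintf("confusion_F%d.json",
                                                 rep$F)),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
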