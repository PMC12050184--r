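# Point correspondence: reorder a registered cloud so that point j matches
# point j of the reference, by the nearest-Euclidean-distance rule.

#' Correspondence map
#'
#' For each reference point j, `indices[j]` is the index of the matched
#' source point and `distances[j]` the Euclidean distance between the two.
#'
#' @param indices Integer vector of matched source indices.
#' @param distances Numeric vector of match distances (mm).
#' @param m_source Number of points in the source cloud (for range checks).
#' @return A `correspondence_map` object.
#' @export
correspondence_map <- function(indices, distances, m_source) {
  indices <- as.integer(indices)
  if (length(indices) != length(distances))
    stopf("indices and distances must have equal length")
  if (any(indices < 1L) || any(indices > m_source))
    stopf("correspondence indices out of range 1..%d", m_source)
  if (any(distances < 0)) stopf("distances must be non-negative")
  structure(list(indices = indices, distances = as.numeric(distances),
                 m_source = as.integer(m_source)),
            class = "correspondence_map")
}

#' Reorder a cloud to match a reference point order
#'
#' For every reference point the nearest source point (Euclidean distance,
#' ties to the lowest source index) becomes the corresponding output point,
#' so the output has the reference's point count and ordering. With
#' `unique = TRUE` the matching is greedy one-to-one: reference points are
#' processed in order of ascending best distance and already-used source
#' points are excluded.
#'
#' @param reference Reference [point_cloud] (both clouds must already be
#'   registered into the same frame).
#' @param source Source [point_cloud]; its point count may differ from the
#'   reference's.
#' @param unique Enforce one-to-one matching (default FALSE, matching the
#'   nearest-distance rule, which allows many-to-one matches).
#' @return List with `cloud` (reordered source) and `map`
#'   (a [correspondence_map]).
#' @export
reorder_to_reference <- function(reference, source, unique = FALSE) {
  stopifnot(inherits(reference, "point_cloud"),
            inherits(source, "point_cloud"))
  R <- reference$points
  S <- source$points
  if (nrow(S) == 0L) stopf("source cloud is empty")
  Mr <- nrow(R)
  Ms <- nrow(S)
  if (!unique) {
    nn <- cpp_nn1_grid(R, S)
    idx <- nn$index
    dist <- nn$dist
  } else {
    if (Ms < Mr)
      stopf("unique matching needs at least as many source points (%d) as reference points (%d)",
            Ms, Mr)
    # Exact greedy assignment in order of ascending current-best distance.
    D2 <- outer(rowSums(R^2), rep(1, Ms)) + outer(rep(1, Mr), rowSums(S^2)) -
      2 * R %*% t(S)
    D2[D2 < 0] <- 0
    avail <- rep(TRUE, Ms)
    idx <- integer(Mr)
    dist <- numeric(Mr)
    best_j <- max.col(-D2, ties.method = "first")
    best_d <- D2[cbind(seq_len(Mr), best_j)]
    todo <- rep(TRUE, Mr)
    for (step in seq_len(Mr)) {
      i <- which(todo)[which.min(best_d[todo])]
      j <- best_j[i]
      idx[i] <- j
      dist[i] <- sqrt(best_d[i])
      todo[i] <- FALSE
      avail[j] <- FALSE
      stale <- todo & best_j == j
      if (any(stale)) {
        for (s in which(stale)) {
          row <- D2[s, ]
          row[!avail] <- Inf
          best_j[s] <- which.min(row)
          best_d[s] <- row[best_j[s]]
        }
      }
    }
  }
  out <- point_cloud(S[idx, , drop = FALSE], subject_id = source$subject_id,
                     side = source$side)
  list(cloud = out, map = correspondence_map(idx, dist, Ms))
}

#' Summarize correspondence errors
#'
#' @param map A [correspondence_map].
#' @param threshold Flagging threshold in mm (default 2.5, reusing the ICP
#'   rejection distance).
#' @return List with `mean`, `max` and `flagged_fraction` (fraction of
#'   distances above the threshold).
#' @export
correspondence_errors <- function(map, threshold = 2.5) {
  stopifnot(inherits(map, "correspondence_map"))
  d <- map$distances
  if (length(d) == 0L) stopf("empty correspondence map")
  list(mean = mean(d), max = max(d),
       flagged_fraction = mean(d > threshold))
}
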