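#' Cluster long-term tracks by their latitude profiles
#'
#' Represents every track by its per-frame latitude over a common window
#' and clusters the profiles with k-means (deterministic Lloyd iterations
#' from initial centres picked at evenly spaced ranks of the mean
#' latitude). Reports per-cluster frame-wise mean 3D centroid trajectories
#' and which cluster reverses latitudinal direction (sign change of the
#' smoothed d(phi)/dt of its mean profile), the signature of internalising
#' cells that turn back toward the animal pole.
#'
#' Tracks must share the same frames; run [filter_tracks_region()] with
#' `completeness = "full"` first.
#'
#' @param ts a [track_set()] of complete tracks over a common window.
#' @param frame a [spherical_frame()].
#' @param k number of clusters (default 3); must not exceed the number of
#'   tracks.
#' @param smooth_frames width of the moving average applied to the cluster
#'   mean latitude before the direction test.
#' @return list of class `latitude_clusters`: `labels` (named by cell_id),
#'   `profiles` (tracks x frames latitude matrix), `centroid_latitude`
#'   (k x frames), `centroid_tracks` (list of k data.frames frame/x/y/z),
#'   `reversing_cluster` (integer or NA), `sizes`.
#' @export
cluster_latitude_profiles <- function(ts, frame = spherical_frame(), k = 3L,
                                      smooth_frames = 5L) {
  tr <- track_split(ts)
  if (k > length(tr)) stopf("k = %d exceeds the number of tracks (%d)",
                            k, length(tr))
  frames <- sort(unique(ts$data$frame))
  prof <- t(vapply(tr, function(df) {
    if (!identical(df$frame, frames)) {
      stopf("tracks do not share a common frame window; filter for complete tracks first")
    }
    to_spherical(track_positions(df), frame)$phi
  }, numeric(length(frames))))
  ctr_idx <- unique(round(seq(1L, nrow(prof), length.out = k)))
  ord <- order(rowMeans(prof))
  centers <- prof[ord[ctr_idx], , drop = FALSE]
  km <- stats::kmeans(prof, centers = centers, iter.max = 100L,
                      algorithm = "Lloyd")
  labels <- km$cluster
  names(labels) <- names(tr)
  centroid_tracks <- lapply(seq_len(k), function(cl) {
    ids <- names(labels)[labels == cl]
    sub <- ts$data[as.character(ts$data$cell_id) %in% ids, ]
    agg <- stats::aggregate(sub[, c("x_um", "y_um", "z_um")],
                            list(frame = sub$frame), mean)
    agg[order(agg$frame), ]
  })
  reversing <- NA_integer_
  for (cl in seq_len(k)) {
    dphi <- diff(moving_average(km$centers[cl, ], smooth_frames))
    s <- sign(dphi[abs(dphi) > 1e-12])
    if (length(s) && any(diff(s) != 0)) {
      # prefer the vegetal-then-animal pattern; fall back to any reversal
      if (s[1L] > 0 && any(s < 0)) {
        reversing <- cl
        break
      }
      if (is.na(reversing)) reversing <- cl
    }
  }
  structure(list(labels = labels, profiles = prof,
                 centroid_latitude = km$centers,
                 centroid_tracks = centroid_tracks,
                 reversing_cluster = reversing,
                 sizes = km$size, frames = frames),
            class = "latitude_clusters")
}

#' @export
print.latitude_clusters <- function(x, ...) {
  cat(sprintf("<latitude_clusters> k = %d, sizes %s, reversing cluster %s\n",
              nrow(x$centroid_latitude),
              paste(x$sizes, collapse = "/"),
              ifelse(is.na(x$reversing_cluster), "none",
                     x$reversing_cluster)))
  invisible(x)
}

#' Link track fragments into long-term tracks
#'
#' Stands in for statistical aggregation of short tracklets into
#' long-range trajectories: greedily links the end of one fragment to the
#' start of a later fragment when the temporal gap is at most `gap_frames`
#' and the spatial distance at most `link_radius`. Candidate links are
#' processed by increasing distance (ties by lower cell id), each fragment
#' endpoint is used at most once, and linked chains are merged under the
#' earliest fragment's id. Unlinked fragments pass through unchanged.
#'
#' @param ts a [track_set()] of (possibly fragmented) tracks.
#' @param gap_frames maximum allowed frame gap (>= 1).
#' @param link_radius maximum end-to-start distance, um (0 = never link).
#' @return a [track_set()]; attribute `links` is a data.frame of accepted
#'   `from_id` / `to_id` pairs.
#' @export
aggregate_long_tracks <- function(ts, gap_frames = 3L, link_radius = 15) {
  tr <- track_split(ts)
  ids <- names(tr)
  info <- do.call(rbind, lapply(tr, function(df) {
    data.frame(start_frame = df$frame[1L], end_frame = df$frame[nrow(df)],
               sx = df$x_um[1L], sy = df$y_um[1L], sz = df$z_um[1L],
               ex = df$x_um[nrow(df)], ey = df$y_um[nrow(df)],
               ez = df$z_um[nrow(df)])
  }))
  n <- length(tr)
  cand <- NULL
  if (link_radius > 0 && n > 1L) {
    cand_list <- list()
    for (i in seq_len(n)) {
      gap <- info$start_frame - info$end_frame[i]
      dx <- info$sx - info$ex[i]; dy <- info$sy - info$ey[i]
      dz <- info$sz - info$ez[i]
      d <- sqrt(dx^2 + dy^2 + dz^2)
      ok <- which(gap >= 1L & gap <= gap_frames & d <= link_radius)
      if (length(ok)) {
        cand_list[[length(cand_list) + 1L]] <-
          data.frame(from = i, to = ok, dist = d[ok])
      }
    }
    cand <- do.call(rbind, cand_list)
  }
  links <- data.frame(from_id = character(0), to_id = character(0))
  succ <- rep(NA_integer_, n)
  pred <- rep(NA_integer_, n)
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$dist, as.numeric(ids[cand$from]),
                       as.numeric(ids[cand$to])), ]
    for (r in seq_len(nrow(cand))) {
      f <- cand$from[r]; t2 <- cand$to[r]
      if (is.na(succ[f]) && is.na(pred[t2])) {
        succ[f] <- t2
        pred[t2] <- f
        links <- rbind(links, data.frame(from_id = ids[f], to_id = ids[t2]))
      }
    }
  }
  # walk chains from their heads and relabel
  out_rows <- list()
  heads <- which(is.na(pred))
  for (h in heads) {
    chain <- h
    while (!is.na(succ[chain[length(chain)]])) {
      chain <- c(chain, succ[chain[length(chain)]])
    }
    merged <- do.call(rbind, tr[chain])
    merged$cell_id <- tr[[h]]$cell_id[1L]
    out_rows[[length(out_rows) + 1L]] <- merged
  }
  out <- do.call(rbind, out_rows)
  res <- track_set(out, frame_interval = ts$frame_interval,
                   embryo_id = ts$embryo_id)
  attr(res, "links") <- links
  res
}
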