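#' Single-cell track container
#'
#' A `track_set` holds the per-cell tracking table the analysis consumes:
#' one row per cell per frame, in the column layout produced by external
#' trackers after layer separation. Positions are Cartesian micrometres;
#' `layer` is one of `"epiblast"`, `"mesendoderm"`, `"endoderm"` (or `NA`
#' when unknown); `mezzo`/`sox17` are normalised expression readouts in
#' [0, 1].
#'
#' @param data data.frame with columns `frame`, `time_hpf`, `cell_id`,
#'   `parent_id`, `x_um`, `y_um`, `z_um`, `layer`, `mezzo`, `sox17`.
#'   Missing optional columns (`parent_id`, `layer`, `mezzo`, `sox17`) are
#'   filled with `NA`.
#' @param frame_interval frame spacing in seconds (shared by all tracks).
#' @param embryo_id provenance tag.
#' @return An object of class `track_set`.
#' @export
track_set <- function(data, frame_interval = 120, embryo_id = "synthetic") {
  req <- c("frame", "time_hpf", "cell_id", "x_um", "y_um", "z_um")
  miss <- setdiff(req, names(data))
  if (length(miss)) stopf("track data missing columns: %s",
                          paste(miss, collapse = ", "))
  for (col in c("parent_id", "layer", "mezzo", "sox17")) {
    if (is.null(data[[col]])) data[[col]] <- NA
  }
  if (!is.finite(frame_interval) || frame_interval <= 0) {
    stopf("frame_interval must be > 0 seconds")
  }
  pos <- as.matrix(data[, c("x_um", "y_um", "z_um")])
  if (nrow(data) && !all(is.finite(pos))) stopf("positions must be finite")
  data <- data[order(data$cell_id, data$frame), , drop = FALSE]
  if (nrow(data) &&
      anyDuplicated(data[, c("cell_id", "frame")])) {
    stopf("duplicate (cell_id, frame) rows")
  }
  rownames(data) <- NULL
  structure(list(data = data,
                 frame_interval = frame_interval,
                 embryo_id = embryo_id),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  d <- x$data
  cat(sprintf("<track_set> %d tracks, %d observations, frames %s\n",
              length(unique(d$cell_id)), nrow(d),
              if (nrow(d)) paste(range(d$frame), collapse = "..") else "-"))
  cat(sprintf("  frame interval %g s, embryo '%s'\n",
              x$frame_interval, x$embryo_id))
  if (nrow(d)) {
    tab <- table(d$layer[!duplicated(d$cell_id)], useNA = "ifany")
    cat("  layers:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.track_set <- function(object, ...) {
  d <- object$data
  lens <- if (nrow(d)) as.integer(table(d$cell_id)) else integer()
  out <- list(n_tracks = length(lens), n_obs = nrow(d),
              track_length = summary(lens),
              time_range_hpf = if (nrow(d)) range(d$time_hpf) else c(NA, NA))
  class(out) <- "summary.track_set"
  out
}

#' @export
print.summary.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d tracks / %d observations, %.2f-%.2f hpf\n",
              x$n_tracks, x$n_obs, x$time_range_hpf[1], x$time_range_hpf[2]))
  print(x$track_length)
  invisible(x)
}

n_tracks <- function(ts) length(unique(ts$data$cell_id))

# list of per-track data.frames, ordered by frame
track_split <- function(ts) {
  d <- ts$data
  split(d, d$cell_id)
}

track_positions <- function(df) as.matrix(df[, c("x_um", "y_um", "z_um")])

#' Read and write track tables as CSV
#'
#' The on-disk layout is one row per (cell, frame) with columns
#' `frame, time_hpf, cell_id, parent_id, x_um, y_um, z_um, layer, mezzo,
#' sox17` -- the exchange format for tracker output after layer separation.
#'
#' @param ts a [track_set()].
#' @param path file path.
#' @param frame_interval,embryo_id metadata for `read_tracks_csv()`.
#' @return `read_tracks_csv()` returns a `track_set`; `write_tracks_csv()`
#'   returns `path` invisibly.
#' @export
write_tracks_csv <- function(ts, path) {
  utils::write.csv(ts$data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path, frame_interval = 120,
                            embryo_id = basename(path)) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  track_set(d, frame_interval = frame_interval, embryo_id = embryo_id)
}

#' Plot cell tracks in the Mercator plane
#'
#' @param x a [track_set()].
#' @param frame a [spherical_frame()].
#' @param col_by colour tracks by `"layer"` or `"none"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.track_set <- function(x, frame = spherical_frame(), col_by = "layer", ...) {
  d <- x$data
  sp <- to_spherical(track_positions(d), frame)
  mp <- mercator_project(sp$theta, sp$phi)
  cols <- c(epiblast = "#1b9e77", mesendoderm = "#d95f02", endoderm = "#7570b3")
  graphics::plot(NA, xlim = range(mp$u), ylim = range(mp$v),
                 xlab = "u (longitude)", ylab = "v (Mercator latitude)", ...)
  for (tr in split(cbind(mp, id = d$cell_id, layer = d$layer), d$cell_id)) {
    cc <- if (col_by == "layer") cols[[tr$layer[1L]]] %||% "grey40" else "grey40"
    graphics::lines(tr$u, tr$v, col = grDevices::adjustcolor(cc, 0.5))
  }
  invisible(x)
}
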