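#' Space-time export of tracks over the Mercator plane
#'
#' Converts each track to a (u, v, t) polyline -- Mercator position with
#' time as the third axis -- plus a vertical reference line marking a
#' stationary object, for space-time plots of long-term trajectories.
#'
#' @param ts a [track_set()] (aligned to `frame`).
#' @param frame a [spherical_frame()].
#' @param reference_uv length-2 (u, v) of the stationary reference line;
#'   default the mean start position.
#' @return object of class `spacetime_export`: `tracks` (data.frame
#'   `cell_id`, `layer`, `u`, `v`, `t_hpf`) and `reference` (data.frame
#'   `u`, `v`, `t_hpf` with constant u, v).
#' @export
export_spacetime <- function(ts, frame = spherical_frame(),
                             reference_uv = NULL) {
  d <- ts$data
  sp <- to_spherical(track_positions(d), frame)
  mp <- mercator_project(sp$theta, sp$phi)
  tracks <- data.frame(cell_id = d$cell_id, layer = d$layer,
                       u = mp$u, v = mp$v, t_hpf = d$time_hpf)
  tracks <- tracks[order(tracks$cell_id, tracks$t_hpf), ]
  rownames(tracks) <- NULL
  if (is.null(reference_uv)) {
    starts <- tracks[!duplicated(tracks$cell_id), ]
    reference_uv <- c(mean(starts$u), mean(starts$v))
  }
  t_ref <- sort(unique(tracks$t_hpf))
  structure(list(tracks = tracks,
                 reference = data.frame(u = reference_uv[1L],
                                        v = reference_uv[2L],
                                        t_hpf = t_ref)),
            class = "spacetime_export")
}

#' Write a space-time export as CSV
#' @param st a `spacetime_export`.
#' @param path output CSV path.
#' @export
write_spacetime_csv <- function(st, path) {
  utils::write.csv(st$tracks, path, row.names = FALSE)
  invisible(path)
}

#' Export tracks for the interactive web viewer
#'
#' Serialises trajectories in the viewer's JSON schema with vertices
#' decimated to one in `downsample` (endpoints always kept) and a
#' per-vertex normalised expression value. Expression values outside
#' [0, 1] are clipped with a warning.
#'
#' Schema: `{"format", "version", "downsample", "frame_interval_s",
#' "tracks": [{"id", "layer", "vertices": [[u, v, t_hpf, expr], ...]}]}`.
#'
#' @param ts a [track_set()].
#' @param frame a [spherical_frame()].
#' @param expression which expression column to carry (`"mezzo"` or
#'   `"sox17"`).
#' @param downsample keep every `downsample`-th vertex (default 5, i.e.
#'   one fifth of the resolution); 1 is lossless.
#' @param path optional path; when given the JSON is written there.
#' @return the export list (invisibly when `path` is given).
#' @export
export_web_json <- function(ts, frame = spherical_frame(),
                            expression = "mezzo", downsample = 5L,
                            path = NULL) {
  d <- ts$data
  expr <- d[[expression]]
  expr[is.na(expr)] <- 0
  if (any(expr < 0 | expr > 1)) {
    warnf("expression values outside [0, 1] clipped in web export")
    expr <- clamp(expr, 0, 1)
  }
  sp <- to_spherical(track_positions(d), frame)
  mp <- mercator_project(sp$theta, sp$phi)
  d$u <- mp$u; d$v <- mp$v; d$expr <- expr
  tracks <- lapply(split(d, d$cell_id), function(df) {
    df <- df[order(df$frame), ]
    n <- nrow(df)
    keep <- unique(c(seq(1L, n, by = downsample), n))
    verts <- lapply(keep, function(i) {
      c(df$u[i], df$v[i], df$time_hpf[i], df$expr[i])
    })
    list(id = df$cell_id[1L], layer = df$layer[1L], vertices = verts)
  })
  out <- list(format = "gastruflow-web-tracks", version = 1L,
              downsample = as.integer(downsample),
              frame_interval_s = ts$frame_interval,
              tracks = unname(tracks))
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}

#' Read and validate a web viewer export
#' @param path JSON path written by [export_web_json()].
#' @return the parsed export; errors on schema violations.
#' @export
read_web_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$format, "gastruflow-web-tracks")) {
    stopf("not a web track export (format field missing or wrong)")
  }
  for (tr in x$tracks) {
    if (is.null(tr$id) || is.null(tr$vertices)) {
      stopf("web export track missing id or vertices")
    }
    for (v in tr$vertices) {
      if (length(v) != 4L || !all(vapply(v, is.numeric, logical(1)))) {
        stopf("web export vertex is not [u, v, t, expr]")
      }
      if (v[[4L]] < 0 || v[[4L]] > 1) {
        stopf("web export expression value outside [0, 1]")
      }
    }
    t_seq <- vapply(tr$vertices, function(v) v[[3L]], numeric(1))
    if (is.unsorted(t_seq, strictly = FALSE)) {
      stopf("web export vertices not time-ordered")
    }
  }
  x
}
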