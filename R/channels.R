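#' Separate germ layers by channel subtraction
#'
#' The three recorded channels label nested cell populations: channel 3 all
#' nuclei (histone), channel 2 mesendoderm + endoderm (cytoplasmic mezzo),
#' channel 1 endoderm nuclei (sox17). Epiblast nuclei are isolated by
#' subtracting channel 2 from channel 3, mesendoderm by subtracting the
#' epiblast layer back out of channel 3, mesoderm by further removing the
#' endoderm signal; channel 1 is used as-is for endoderm. All outputs are
#' clamped at zero.
#'
#' Two practical steps make the subtraction meaningful across fluorophores:
#' channels are rescaled so their bright-end (99.9th percentile) intensities
#' match before subtraction, and the cytoplasmic channel 2 is first
#' grayscale-closed with a nucleus-sized structuring element so cytoplasmic
#' signal covers the nuclear footprints it must cancel.
#'
#' @param ch1,ch2,ch3 co-registered [voxel_stack()]s of identical shape.
#' @param close_radius_um radius of the closing structuring element, um;
#'   0 disables the closing.
#' @param scale_quantile quantile used to match channel intensity scales.
#' @return named list of [voxel_stack()]s: `epiblast`, `mesendoderm`,
#'   `mesoderm`, `endoderm`.
#' @export
subtract_channels <- function(ch1, ch2, ch3, close_radius_um = 4,
                              scale_quantile = 0.999) {
  shapes <- list(dim(ch1), dim(ch2), dim(ch3))
  if (!all(vapply(shapes, identical, logical(1), shapes[[1L]]))) {
    stopf("channel shapes differ: %s",
          paste(vapply(shapes, function(s) paste(s, collapse = "x"),
                       character(1)), collapse = " vs "))
  }
  a1 <- unclass(ch1); a2 <- unclass(ch2); a3 <- unclass(ch3)
  attributes(a1) <- attributes(a2) <- attributes(a3) <-
    list(dim = dim(ch3))
  if (close_radius_um > 0) {
    r_vox <- max(1L, round(close_radius_um / stack_voxel_size(ch3)))
    a2 <- gray_close_planewise(a2, r_vox)
  }
  q <- function(a) {
    v <- stats::quantile(a, scale_quantile, names = FALSE)
    if (v <= 0) 1 else v
  }
  s <- q(a3) / q(a2)
  epiblast <- pmax(a3 - s * a2, 0)
  mesendo <- pmax(a3 - epiblast, 0)
  s2 <- q(mesendo) / q(a1)
  mesoderm <- pmax(mesendo - s2 * a1, 0)
  list(epiblast = rebuild_stack(epiblast, ch3),
       mesendoderm = rebuild_stack(mesendo, ch3),
       mesoderm = rebuild_stack(mesoderm, ch3),
       endoderm = rebuild_stack(a1, ch3))
}

# plane-wise grayscale closing with a disc brush; EBImage grayscale
# morphology operates on [0, 1], so rescale around it
gray_close_planewise <- function(a, r_vox) {
  size <- 2L * r_vox + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  m <- max(a)
  if (m <= 0) return(a)
  out <- a
  for (k in seq_len(dim(a)[3L])) {
    out[, , k] <- EBImage::closing(a[, , k] / m, brush) * m
  }
  out
}

#' Classify cell positions against separated layer stacks
#'
#' Assigns each position the germ layer whose separated stack has the
#' strongest (scale-normalised) signal in a small window around it --
#' the recount used to validate the subtraction against ground truth.
#' Mesoderm wins map to `"mesendoderm"` so labels are comparable to the
#' simulator's lineage labels.
#'
#' @param layers output of [subtract_channels()].
#' @param positions n x 3 matrix of world positions, um.
#' @param window cubic window edge in voxels (odd).
#' @return character vector of layer labels.
#' @export
classify_layers <- function(layers, positions, window = 3L) {
  stacks <- layers[c("epiblast", "mesoderm", "endoderm")]
  scores <- vapply(seq_along(stacks), function(j) {
    window_means(stacks[[j]], positions, window)
  }, numeric(nrow(as_position_matrix(positions))))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  lab <- c("epiblast", "mesendoderm", "endoderm")
  lab[max.col(scores, ties.method = "first")]
}

# mean intensity in a truncated cubic window around world positions
window_means <- function(stack, positions, window = 3L) {
  v <- round(world_to_voxel(positions, stack))
  half <- (window - 1L) %/% 2L
  dims <- dim(stack)
  a <- unclass(stack)
  vapply(seq_len(nrow(v)), function(i) {
    ix <- max(1L, v[i, 1L] - half):min(dims[1L], v[i, 1L] + half)
    iy <- max(1L, v[i, 2L] - half):min(dims[2L], v[i, 2L] + half)
    iz <- max(1L, v[i, 3L] - half):min(dims[3L], v[i, 3L] + half)
    mean(a[ix, iy, iz])
  }, numeric(1))
}

#' Expression readout around tracked positions
#'
#' Means the reporter intensity in a cubic window (default 3 x 3 x 3
#' voxels, truncated at stack edges) around each position, then min-max
#' normalises to [0, 1] globally across every stack and position of the
#' run. If the global maximum equals the minimum all values are defined as
#' 0 and a warning is emitted.
#'
#' @param stacks a [voxel_stack()] or list of them (one per frame).
#' @param positions an n x 3 matrix, or a list of such matrices parallel to
#'   `stacks`.
#' @param window cubic window edge, voxels.
#' @param normalize apply the global min-max normalisation.
#' @return list of numeric vectors (one per stack) of readouts in [0, 1];
#'   a single vector when a single stack was given.
#' @export
expression_readout <- function(stacks, positions, window = 3L,
                               normalize = TRUE) {
  single <- inherits(stacks, "voxel_stack")
  if (single) {
    stacks <- list(stacks)
    positions <- list(as_position_matrix(positions))
  }
  raw <- mapply(function(s, p) window_means(s, as_position_matrix(p), window),
                stacks, positions, SIMPLIFY = FALSE)
  if (normalize) {
    all_v <- unlist(raw)
    lo <- min(all_v); hi <- max(all_v)
    if (hi - lo < .Machine$double.eps) {
      warnf("expression readout has zero dynamic range; all values set to 0")
      raw <- lapply(raw, function(v) rep(0, length(v)))
    } else {
      raw <- lapply(raw, function(v) (v - lo) / (hi - lo))
    }
  }
  if (single) raw[[1L]] else raw
}
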