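#' 3D image stack with physical metadata
#'
#' Thin wrapper around a numeric 3D array carrying the voxel spacing
#' (micrometres, isotropic), a channel tag and the world coordinate of the
#' first voxel centre, so image-space and track-space computations can be
#' mixed. The stack is centred on the world origin by default.
#'
#' @param a numeric 3D array of intensities (finite).
#' @param voxel_size voxel edge length, um.
#' @param channel free-text channel tag.
#' @param origin_um world coordinate (um) of the centre of voxel (1,1,1);
#'   default centres the box on the origin.
#' @return object of class `voxel_stack` (a 3D array with attributes).
#' @export
voxel_stack <- function(a, voxel_size = 4, channel = "",
                        origin_um = NULL) {
  if (length(dim(a)) != 3L) stopf("stack must be a 3D array")
  if (!all(is.finite(a))) stopf("stack intensities must be finite")
  if (!is.finite(voxel_size) || voxel_size <= 0) stopf("voxel_size must be > 0")
  if (is.null(origin_um)) origin_um <- -voxel_size * (dim(a) - 1) / 2
  structure(a, class = "voxel_stack", voxel_size = voxel_size,
            channel = channel, origin_um = origin_um)
}

#' @export
print.voxel_stack <- function(x, ...) {
  cat(sprintf("<voxel_stack> %s, %g um voxels, channel '%s', range [%g, %g]\n",
              paste(dim(x), collapse = "x"), attr(x, "voxel_size"),
              attr(x, "channel"), min(x), max(x)))
  invisible(x)
}

stack_voxel_size <- function(stack) attr(stack, "voxel_size")
stack_origin <- function(stack) attr(stack, "origin_um")

# continuous voxel coordinates (1-based) of world positions
world_to_voxel <- function(p, stack) {
  p <- as_position_matrix(p)
  sweep(p, 2L, stack_origin(stack)) / stack_voxel_size(stack) + 1
}

voxel_to_world <- function(v, stack) {
  v <- as_position_matrix(v)
  sweep((v - 1) * stack_voxel_size(stack), 2L, stack_origin(stack), `+`)
}

rebuild_stack <- function(a, template) {
  voxel_stack(a, voxel_size = stack_voxel_size(template),
              channel = attr(template, "channel"),
              origin_um = stack_origin(template))
}

#' Write / read a voxel stack as multi-page TIFF
#'
#' Intensities are stored as 16-bit pages scaled by the recorded maximum; a
#' JSON sidecar (`<path>.meta.json`) carries voxel size, channel, origin and
#' the intensity scale, so `read_voxel_tiff()` restores physical units.
#'
#' @param stack a [voxel_stack()].
#' @param path output TIFF path.
#' @return `write_voxel_tiff()`: `path`, invisibly. `read_voxel_tiff()`: a
#'   `voxel_stack`.
#' @export
write_voxel_tiff <- function(stack, path) {
  sc <- max(stack, 1e-12)
  planes <- lapply(seq_len(dim(stack)[3L]),
                   function(k) unclass(stack)[, , k] / sc)
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  meta <- list(voxel_size = stack_voxel_size(stack),
               channel = attr(stack, "channel"),
               origin_um = stack_origin(stack), scale = sc,
               dim = dim(stack))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_voxel_tiff
#' @export
read_voxel_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  planes <- tiff::readTIFF(path, all = TRUE)
  a <- array(0, dim = meta$dim)
  for (k in seq_along(planes)) a[, , k] <- planes[[k]] * meta$scale
  voxel_stack(a, voxel_size = meta$voxel_size, channel = meta$channel,
              origin_um = meta$origin_um)
}
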