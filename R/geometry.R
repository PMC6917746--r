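#' Embryo-centric spherical reference frame
#'
#' A `spherical_frame` fixes the coordinate system every downstream statistic
#' is computed in: the centre and radius of the best-fit embryo sphere, the
#' animal-vegetal axis and the dorsal direction (longitude zero, the shield).
#'
#' Conventions: latitude `phi` runs over \eqn{[-\pi/2, \pi/2]} with the animal
#' pole at \eqn{-\pi/2} and the vegetal pole at \eqn{+\pi/2}; longitude
#' `theta` runs over \eqn{(-\pi, \pi]} with 0 at the dorsal midline.
#'
#' @param center numeric length-3, sphere centre in micrometres.
#' @param radius positive scalar, embryo radius in micrometres.
#' @param animal_axis unit 3-vector pointing from the centre to the animal
#'   pole. Normalised internally.
#' @param dorsal_axis 3-vector toward the dorsal midline; its component along
#'   `animal_axis` is removed, then it is normalised, so only the plane it
#'   spans with the centre matters.
#' @return An object of class `spherical_frame` with fields `center`,
#'   `radius`, `animal_axis`, `dorsal_axis` and the derived right-handed
#'   third axis `bitangent_axis`.
#' @examples
#' fr <- spherical_frame(radius = 350)
#' to_spherical(rbind(fr$center + 350 * fr$animal_axis), fr)
#' @export
spherical_frame <- function(center = c(0, 0, 0), radius = 350,
                            animal_axis = c(0, 0, -1),
                            dorsal_axis = c(1, 0, 0)) {
  center <- as.numeric(center)
  if (length(center) != 3L || !all(is.finite(center))) {
    stopf("center must be a finite 3-vector")
  }
  if (!is.finite(radius) || radius <= 0) stopf("radius must be > 0")
  a <- as.numeric(animal_axis)
  if (vec_norm(a) < 1e-12) stopf("animal_axis must be non-zero")
  a <- a / vec_norm(a)
  d <- as.numeric(dorsal_axis)
  d <- d - sum(d * a) * a
  if (vec_norm(d) < 1e-9) stopf("dorsal_axis is parallel to animal_axis")
  d <- d / vec_norm(d)
  structure(list(center = center, radius = radius,
                 animal_axis = a, dorsal_axis = d,
                 bitangent_axis = cross3(a, d)),
            class = "spherical_frame")
}

#' @export
print.spherical_frame <- function(x, ...) {
  cat("<spherical_frame>\n")
  cat("  center      :", paste(signif(x$center, 5), collapse = ", "), "um\n")
  cat("  radius      :", signif(x$radius, 5), "um\n")
  cat("  animal axis :", paste(signif(x$animal_axis, 4), collapse = ", "), "\n")
  cat("  dorsal axis :", paste(signif(x$dorsal_axis, 4), collapse = ", "), "\n")
  invisible(x)
}

as_position_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  p <- as.matrix(p)
  if (ncol(p) != 3L) stopf("positions must have 3 columns (x, y, z)")
  storage.mode(p) <- "double"
  p
}

#' Convert between Cartesian and embryo-centric spherical coordinates
#'
#' `to_spherical()` maps Cartesian positions (micrometres) to
#' \eqn{(r, \theta, \phi)}: `r` the Euclidean distance to the frame centre,
#' `theta` the longitude (0 at dorsal, range \eqn{(-\pi,\pi]}) and `phi` the
#' latitude (animal pole at \eqn{-\pi/2}). `to_cartesian()` is its inverse.
#' Points at the centre (r = 0) get `theta`/`phi` of 0 and are flagged in the
#' `degenerate` column.
#'
#' @param p n x 3 matrix (or length-3 vector) of Cartesian positions, um.
#' @param frame a [spherical_frame()].
#' @return `to_spherical()`: data.frame with columns `r`, `theta`, `phi`,
#'   `degenerate`. `to_cartesian()`: n x 3 matrix of positions, um.
#' @export
to_spherical <- function(p, frame) {
  p <- as_position_matrix(p)
  u <- sweep(p, 2L, frame$center)
  r <- row_norms(u)
  degen <- r < 1e-12
  ru <- ifelse(degen, 1, r)
  ua <- (u %*% frame$animal_axis)[, 1L] / ru
  ud <- (u %*% frame$dorsal_axis)[, 1L] / ru
  ub <- (u %*% frame$bitangent_axis)[, 1L] / ru
  phi <- -asin(clamp(ua, -1, 1))
  theta <- atan2(ub, ud)
  theta[theta <= -pi] <- pi
  phi[degen] <- 0
  theta[degen] <- 0
  data.frame(r = r, theta = theta, phi = phi, degenerate = degen)
}

#' @param coords data.frame with columns `r`, `theta`, `phi` (as returned by
#'   `to_spherical()`), or a numeric length-3 vector `c(r, theta, phi)`.
#' @rdname to_spherical
#' @export
to_cartesian <- function(coords, frame) {
  if (is.numeric(coords) && is.null(dim(coords))) {
    coords <- data.frame(r = coords[1L], theta = coords[2L], phi = coords[3L])
  }
  r <- coords$r; th <- coords$theta; ph <- coords$phi
  dirs <- outer(cos(ph) * cos(th), frame$dorsal_axis) +
    outer(cos(ph) * sin(th), frame$bitangent_axis) -
    outer(sin(ph), frame$animal_axis)
  sweep(dirs * r, 2L, frame$center, `+`)
}

#' Rigidly align a track set to a reference frame
#'
#' Centers all positions on the frame centre and applies a proper rotation,
#' the programmatic stand-in for the manual orientation correction against a
#' reference embryo. Pairwise distances are preserved exactly.
#'
#' @param tracks a [track_set()].
#' @param frame a [spherical_frame()] whose centre is subtracted.
#' @param rotation 3x3 proper orthonormal matrix (checked to 1e-9; the
#'   violated property is named on failure). Applied as `p' = R (p - center)`.
#' @return The transformed `track_set`; positions are expressed in the
#'   centered, rotated frame (new frame centre at the origin).
#' @seealso [landmark_rotation()] to estimate `rotation` from landmark pairs.
#' @export
align_to_reference <- function(tracks, frame, rotation = diag(3)) {
  ok <- is_orthonormal(rotation)
  if (!isTRUE(ok)) stopf("rotation must be proper orthonormal: %s", ok)
  d <- tracks$data
  p <- as.matrix(d[, c("x_um", "y_um", "z_um")])
  p <- sweep(p, 2L, frame$center) %*% t(rotation)
  d$x_um <- p[, 1L]; d$y_um <- p[, 2L]; d$z_um <- p[, 3L]
  tracks$data <- d
  tracks
}

#' Estimate an alignment rotation from landmark pairs
#'
#' Least-squares orthogonal Procrustes: finds the proper rotation R
#' minimising ||R src_i - dst_i||^2 over (already centered) landmark pairs.
#' Three non-collinear pairs suffice.
#'
#' @param src,dst n x 3 matrices of corresponding centered landmarks (n >= 3).
#' @return 3x3 rotation matrix with det +1.
#' @export
landmark_rotation <- function(src, dst) {
  src <- as_position_matrix(src); dst <- as_position_matrix(dst)
  if (nrow(src) != nrow(dst) || nrow(src) < 3L) {
    stopf("need >= 3 corresponding landmark pairs")
  }
  H <- crossprod(src, dst)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Mercator projection with area correction
#'
#' Conformal sphere-to-plane map used for all gridded flow analyses:
#' `u = theta`, `v = ln tan(pi/4 + phi/2)`. Latitudes beyond `phi_max`
#' (default 1.4835 rad, about 85 deg) are clamped so the poles never produce
#' infinities; the number of clamped points is reported in the `clamped`
#' attribute. `area_factor()` gives the local area inflation
#' \eqn{\sec^2\phi} by which sample counts must be divided when densities
#' are compared across latitudes.
#'
#' @param theta,phi longitude and latitude in radians (vectors of equal
#'   length), or a data.frame with `theta` and `phi` columns as first arg.
#' @param phi_max clamp latitude, radians.
#' @return `mercator_project()`: data.frame with columns `u`, `v`, plus
#'   attribute `clamped` (count). `area_factor()`: numeric vector >= 1.
#' @examples
#' mercator_project(0, pi / 3)      # v = ln tan(5 pi / 12) ~ 1.3170
#' area_factor(pi / 3)              # sec^2(pi/3) = 4
#' @export
mercator_project <- function(theta, phi = NULL, phi_max = 1.4835) {
  if (is.data.frame(theta)) {
    phi <- theta$phi; theta <- theta$theta
  }
  stopifnot(length(theta) == length(phi))
  ph <- clamp(phi, -phi_max, phi_max)
  out <- data.frame(u = theta, v = log(tan(pi / 4 + ph / 2)))
  attr(out, "clamped") <- sum(abs(phi) > phi_max, na.rm = TRUE)
  out
}

#' @rdname mercator_project
#' @export
area_factor <- function(phi, phi_max = 1.4835) {
  1 / cos(clamp(phi, -phi_max, phi_max))^2
}

# inverse of the Mercator v coordinate (Gudermannian)
mercator_inv_v <- function(v) 2 * atan(exp(v)) - pi / 2

#' Reference vector fields for pure epiboly and pure convergence
#'
#' Epiboly is modelled as flow along meridians toward the vegetal pole
#' (`epi`), convergence as flow along parallels toward the dorsal midline
#' at longitude 0 (`conv`). Both fields are unit tangent fields on the
#' embryo sphere. `epi` is undefined at the poles; `conv` is undefined at
#' the poles and on the meridians theta = 0 and theta = pi (equidistant from
#' the midline on either side): there a zero vector is returned and the
#' point flagged.
#'
#' @param frame a [spherical_frame()].
#' @return A list of class `reference_fields` with functions `epi(p)` and
#'   `conv(p)` mapping an n x 3 Cartesian matrix to an n x 3 matrix of unit
#'   tangents, each with a logical `degenerate` attribute.
#' @export
reference_fields <- function(frame) {
  eval_tangents <- function(p) {
    sp <- to_spherical(p, frame)
    th <- sp$theta; ph <- sp$phi
    pole <- abs(cos(ph)) < 1e-9 | sp$degenerate
    epi <- outer(-sin(ph) * cos(th), frame$dorsal_axis) +
      outer(-sin(ph) * sin(th), frame$bitangent_axis) -
      outer(cos(ph), frame$animal_axis)
    epi[pole, ] <- 0
    dth <- outer(-sin(th), frame$dorsal_axis) +
      outer(cos(th), frame$bitangent_axis)
    seam <- abs(th) < 1e-9 | abs(abs(th) - pi) < 1e-9
    conv <- dth * -sign(th)
    conv[seam | pole, ] <- 0
    list(epi = epi, conv = conv, epi_degenerate = pole,
         conv_degenerate = seam | pole)
  }
  structure(list(
    frame = frame,
    epi = function(p) {
      t <- eval_tangents(as_position_matrix(p))
      structure(t$epi, degenerate = t$epi_degenerate)
    },
    conv = function(p) {
      t <- eval_tangents(as_position_matrix(p))
      structure(t$conv, degenerate = t$conv_degenerate)
    }
  ), class = "reference_fields")
}
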