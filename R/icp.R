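#' Rigid registration of consecutive point clouds (iterative closest point)
#'
#' Registers detected nucleus centres of one timepoint onto the next to
#' separate the embryo's global rotation inside the chorion from local cell
#' movement. Alternates nearest-neighbour correspondence with a
#' least-squares rigid solve (Kabsch SVD with det(R) = +1 enforced) until
#' the RMS residual change falls below `tol` or `max_iter` is reached.
#' With `trim` > 0 the stated fraction of worst correspondences is dropped
#' each iteration, which tolerates moderate outlier contamination.
#'
#' @param points_t,points_t1 n x 3 / m x 3 matrices of points (um) at
#'   consecutive timepoints; at least 3 non-collinear points each.
#' @param max_iter maximum ICP iterations.
#' @param tol convergence tolerance on the RMS residual change, um.
#' @param trim fraction in [0, 1) of worst-matching points to discard per
#'   iteration (0 = use all points).
#' @return list of class `rigid_transform`: rotation `R`, translation `t`
#'   (mapping `points_t` onto `points_t1` as `R p + t`), final `rms`,
#'   `iterations`, `converged`.
#' @export
rigid_register <- function(points_t, points_t1, max_iter = 50L, tol = 1e-9,
                           trim = 0) {
  P <- as_position_matrix(points_t)
  Q <- as_position_matrix(points_t1)
  if (nrow(P) < 3L || nrow(Q) < 3L) stopf("need at least 3 points per set")
  check_not_collinear(P, "points_t")
  check_not_collinear(Q, "points_t1")
  R <- diag(3)
  tr <- c(0, 0, 0)
  rms_prev <- Inf
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    Pm <- P %*% t(R) + matrix(tr, nrow(P), 3L, byrow = TRUE)
    nn <- nearest_neighbor_index(Pm, Q)
    d <- row_norms(Pm - Q[nn, , drop = FALSE])
    keep <- seq_len(nrow(P))
    if (trim > 0) {
      n_keep <- max(3L, floor((1 - trim) * nrow(P)))
      keep <- order(d)[seq_len(n_keep)]
    }
    fit <- kabsch(P[keep, , drop = FALSE], Q[nn[keep], , drop = FALSE])
    R <- fit$R; tr <- fit$t
    Pm <- P %*% t(R) + matrix(tr, nrow(P), 3L, byrow = TRUE)
    rms <- sqrt(mean(row_norms(Pm - Q[nn, , drop = FALSE])[keep]^2))
    if (abs(rms_prev - rms) < tol) {
      converged <- TRUE
      rms_prev <- rms
      break
    }
    rms_prev <- rms
  }
  structure(list(R = R, t = tr, rms = rms_prev, iterations = it,
                 converged = converged),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(clamp((sum(diag(x$R)) - 1) / 2, -1, 1))
  cat(sprintf("<rigid_transform> rotation %.4f rad, translation (%s) um, RMS %.3g um (%d iter%s)\n",
              ang, paste(sprintf("%.2f", x$t), collapse = ", "), x$rms,
              x$iterations, if (x$converged) "" else ", not converged"))
  invisible(x)
}

check_not_collinear <- function(P, what) {
  s <- svd(sweep(P, 2L, colMeans(P)))$d
  if (s[2L] < 1e-9 * max(s[1L], 1)) {
    stopf("%s is rank deficient (collinear or coincident points)", what)
  }
}

# brute-force nearest neighbours, chunked to bound memory
nearest_neighbor_index <- function(A, B, chunk = 2048L) {
  n <- nrow(A)
  out <- integer(n)
  b2 <- rowSums(B^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    Ac <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ac^2), b2, `+`) - 2 * Ac %*% t(B)
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

# least-squares rigid transform mapping P onto Q (Kabsch), det(R) = +1
kabsch <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  H <- crossprod(sweep(P, 2L, pc), sweep(Q, 2L, qc))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(qc - R %*% pc))
}

#' Rotation matrix about an axis
#'
#' Utility for constructing known rigid transforms (tests, simulations).
#' @param axis 3-vector rotation axis (normalised internally).
#' @param angle rotation angle, radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  a <- axis / vec_norm(axis)
  K <- matrix(c(0, a[3L], -a[2L], -a[3L], 0, a[1L], a[2L], -a[1L], 0), 3L, 3L)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
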