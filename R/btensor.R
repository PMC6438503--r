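#' b-tensor algebra for tensor-valued diffusion encoding
#'
#' A b-tensor is a 3x3 symmetric positive-semidefinite matrix describing the
#' diffusion encoding of one signal sample. Its trace is the b-value and its
#' normalized anisotropy is the shape parameter \eqn{b_\Delta}: 1 for linear
#' (LTE), 0 for spherical (STE) and -0.5 for planar (PTE) encoding. Units are
#' fixed package-wide: b in ms/um^2, diffusivity in um^2/ms, so b*D is
#' dimensionless.
#'
#' @param kind one of \code{"LTE"}, \code{"PTE"}, \code{"STE"}.
#' @param b b-value (trace of the tensor), ms/um^2; must be non-negative.
#' @param direction symmetry axis as a length-3 vector; normalized internally.
#'   Ignored for STE.
#' @return a \code{btensor}: a 3x3 symmetric matrix of class \code{"btensor"}.
#'
#' @details For an axisymmetric b-tensor with axial eigenvalue
#' \eqn{\lambda_{ax}} (on the symmetry axis) and radial eigenvalue
#' \eqn{\lambda_{rad}} (twice degenerate),
#' \deqn{\lambda_{ax} = b(1 + 2 b_\Delta)/3, \quad
#'       \lambda_{rad} = b(1 - b_\Delta)/3,}
#' so \eqn{b_\Delta = (\lambda_{ax} - \lambda_{rad})/b}.
#'
#' @examples
#' make_btensor("STE", 2)                 # diag(2/3, 2/3, 2/3)
#' make_btensor("LTE", 1, c(0, 0, 1))     # b z zT
#' btensor_shape(make_btensor("PTE", 1))  # b = 1, b_delta = -0.5
#' @export
make_btensor <- function(kind = c("LTE", "PTE", "STE"), b,
                         direction = c(0, 0, 1)) {
  kind <- match.arg(toupper(kind), c("LTE", "PTE", "STE"))
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b))
  if (b < 0) stop("b-value must be non-negative, got ", b)
  b_delta <- switch(kind, LTE = 1, STE = 0, PTE = -0.5)
  if (kind == "STE") {
    direction <- c(0, 0, 1)
  } else {
    stopifnot(length(direction) == 3L, all(is.finite(direction)))
    nrm <- sqrt(sum(direction^2))
    if (nrm < .Machine$double.eps^0.5)
      stop("direction must be a non-zero vector for LTE/PTE")
    direction <- direction / nrm
  }
  B <- btensor_axisym(b, b_delta, direction)
  new_btensor(B)
}

# axisymmetric tensor from (b, b_delta, axis): b/3 I + b b_delta (nn' - I/3)
btensor_axisym <- function(b, b_delta, n) {
  diag(3) * b * (1 - b_delta) / 3 + b * b_delta * tcrossprod(n)
}

new_btensor <- function(B) {
  B <- (B + t(B)) / 2
  structure(B, class = "btensor")
}

#' @export
print.btensor <- function(x, ...) {
  sh <- btensor_shape(x, strict = FALSE)
  cat(sprintf("b-tensor: b = %.4g ms/um^2, b_delta = %.4g\n", sh$b, sh$b_delta))
  print(unclass(x), ...)
  invisible(x)
}

#' Trace (b-value) and shape of a b-tensor
#'
#' Decomposes a symmetric, axisymmetric b-tensor into its b-value (trace) and
#' shape parameter \eqn{b_\Delta = (\lambda_{ax} - \lambda_{rad})/b}. The
#' axial eigenvalue is identified as the one farthest from the other two; the
#' remaining (radial) pair must agree to within \code{tol} of their mean,
#' otherwise the tensor is rejected as non-axisymmetric.
#'
#' @param B a 3x3 symmetric PSD matrix (or \code{btensor}).
#' @param tol relative tolerance on the spread of the two radial eigenvalues
#'   (default 0.01).
#' @param strict if \code{TRUE} (default) error on non-axisymmetric input;
#'   otherwise return \code{NA} for \code{b_delta}.
#' @return list with \code{b}, \code{b_delta} and \code{axis} (unit symmetry
#'   axis; arbitrary for isotropic tensors).
#' @export
btensor_shape <- function(B, tol = 0.01, strict = TRUE) {
  B <- as_btensor_matrix(B)
  b <- sum(diag(B))
  if (b <= .Machine$double.eps) {
    return(list(b = 0, b_delta = 0, axis = c(0, 0, 1)))
  }
  e <- eigen(B, symmetric = TRUE)
  lam <- e$values                       # decreasing order
  if (min(lam) < -1e-10 * b) stop("b-tensor is not positive semi-definite")
  # axial eigenvalue: the one maximizing distance to the mean of the other two
  spread <- abs(lam - (sum(lam) - lam) / 2)
  ax <- which.max(spread)
  rad <- setdiff(1:3, ax)
  rad_spread <- abs(lam[rad[1]] - lam[rad[2]])
  scale <- max(abs(lam), b / 3)
  if (rad_spread > tol * scale) {
    if (strict) stop(sprintf(
      "not axisymmetric: radial eigenvalues differ by %.3g (tolerance %.3g)",
      rad_spread, tol * scale))
    return(list(b = b, b_delta = NA_real_, axis = e$vectors[, ax]))
  }
  b_delta <- (lam[ax] - mean(lam[rad])) / b
  list(b = b, b_delta = b_delta, axis = e$vectors[, ax])
}

as_btensor_matrix <- function(B) {
  B <- unclass(B)
  stopifnot(is.matrix(B), all(dim(B) == c(3L, 3L)), all(is.finite(B)))
  rel <- max(abs(B - t(B))) / max(max(abs(B)), .Machine$double.eps)
  if (rel > 1e-12 * 100)  # forgiving: symmetrize tiny numerical asymmetry
    stop("b-tensor matrix is not symmetric")
  (B + t(B)) / 2
}

#' Rotate a b-tensor
#'
#' Conjugates the tensor by a rotation matrix: \eqn{R B R^T}. The b-value and
#' shape are invariant under rotation; only the symmetry axis moves.
#'
#' @param B a \code{btensor} or 3x3 symmetric matrix.
#' @param R a 3x3 rotation matrix.
#' @export
rotate_btensor <- function(B, R) {
  B <- as_btensor_matrix(B)
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  new_btensor(R %*% B %*% t(R))
}

#' Uniformly random rotation matrices
#'
#' Draws rotations uniformly over SO(3) via unit quaternions, using R's RNG
#' (seed with \code{set.seed} for reproducibility).
#'
#' @param n number of rotations.
#' @return a list of \code{n} 3x3 rotation matrices.
#' @export
random_rotations <- function(n) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    quat_to_rotmat(q)
  })
}

quat_to_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' Rotation taking the z-axis onto a given direction
#'
#' @param n target unit vector.
#' @return 3x3 rotation matrix \code{R} with \code{R \%*\% c(0,0,1) == n}.
#' @export
rotation_to <- function(n) {
  n <- n / sqrt(sum(n^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * n[3] - z[3] * n[2],
         z[3] * n[1] - z[1] * n[3],
         z[1] * n[2] - z[2] * n[1])
  c_ <- sum(z * n)
  if (1 + c_ < 1e-12) {               # antiparallel: rotate pi about x
    return(diag(c(1, -1, -1)))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}
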