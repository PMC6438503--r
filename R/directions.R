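#' Electrostatic-repulsion encoding direction sets
#'
#' Diffusion-encoding direction schemes are generated by minimizing the
#' electrostatic (Coulomb) energy of antipodally symmetric point pairs on the
#' unit sphere,
#' \deqn{E = \sum_{i<j} \left( \frac{1}{|u_i-u_j|} + \frac{1}{|u_i+u_j|} \right),}
#' the community-standard construction for rotation-robust sampling schemes.
#' Sets for n up to 32 are precomputed (best of 50 seeded restarts) and
#' shipped with the package; larger sets are optimized on demand.
#'
#' @param n number of directions.
#' @return an n x 3 matrix of unit row vectors.
#' @examples
#' d <- get_direction_set(6)  # icosahedral: minimal pairwise angle > 63 deg
#' @export
get_direction_set <- function(n) {
  stopifnot(length(n) == 1L, n == round(n))
  if (n < 1 || n > 120) stop("n must be between 1 and 120, got ", n)
  key <- as.character(n)
  if (!is.null(.dirset_cache[[key]])) return(.dirset_cache[[key]])
  v <- read_shipped_dirset(n)
  if (is.null(v)) v <- repulsion_directions(n, restarts = 20, seed = 1000 + n)
  .dirset_cache[[key]] <- v
  v
}

.dirset_cache <- new.env(parent = emptyenv())

read_shipped_dirset <- function(n) {
  path <- system.file("extdata", "repulsion_sets.txt", package = "dividemri")
  if (!nzchar(path)) return(NULL)
  tab <- .dirset_cache[["__table__"]]
  if (is.null(tab)) {
    tab <- utils::read.table(path, col.names = c("n", "x", "y", "z"))
    .dirset_cache[["__table__"]] <- tab
  }
  sel <- tab$n == n
  if (!any(sel)) return(NULL)
  v <- as.matrix(tab[sel, c("x", "y", "z")])
  dimnames(v) <- NULL
  v / sqrt(rowSums(v^2))
}

#' Optimize an electrostatic-repulsion direction set
#'
#' @param n number of directions (>= 1).
#' @param restarts number of seeded random restarts; the lowest-energy
#'   solution is returned.
#' @param seed RNG seed controlling the restarts (deterministic output).
#' @return an n x 3 matrix of unit row vectors.
#' @export
repulsion_directions <- function(n, restarts = 50, seed = 1) {
  stopifnot(n >= 1, restarts >= 1)
  if (n == 1) return(matrix(c(0, 0, 1), 1, 3))
  best <- NULL
  best_e <- Inf
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (r in seq_len(restarts)) {
    x0 <- matrix(stats::rnorm(3 * n), n, 3)
    fit <- stats::optim(as.vector(x0), fn = .rep_energy_flat, gr = .rep_grad_flat,
                        n = n, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (fit$value < best_e) {
      best_e <- fit$value
      best <- matrix(fit$par, n, 3)
    }
  }
  u <- best / sqrt(rowSums(best^2))
  # canonical sign: first nonzero of (z, y, x) positive, for reproducibility
  flip <- sign(u[, 3] + 1e-9 * u[, 2] + 1e-12 * u[, 1])
  u * flip
}

#' Electrostatic repulsion energy of a direction set
#'
#' @param u an n x 3 matrix of unit row vectors.
#' @return scalar energy (antipodally symmetrized Coulomb sum).
#' @export
repulsion_energy <- function(u) {
  u <- as.matrix(u)
  n <- nrow(u)
  if (n < 2) return(0)
  g <- tcrossprod(u)
  ut <- upper.tri(g)
  d2 <- pmax(2 - 2 * g[ut], .Machine$double.eps)
  s2 <- pmax(2 + 2 * g[ut], .Machine$double.eps)
  sum(1 / sqrt(d2)) + sum(1 / sqrt(s2))
}

.rep_energy_flat <- function(par, n) {
  x <- matrix(par, n, 3)
  u <- x / sqrt(rowSums(x^2))
  repulsion_energy(u)
}

.rep_grad_flat <- function(par, n) {
  x <- matrix(par, n, 3)
  nrm <- sqrt(rowSums(x^2))
  u <- x / nrm
  g <- tcrossprod(u)
  d2 <- pmax(2 - 2 * g, .Machine$double.eps)   # |u_i - u_j|^2
  s2 <- pmax(2 + 2 * g, .Machine$double.eps)   # |u_i + u_j|^2
  wd <- d2^-1.5; diag(wd) <- 0
  ws <- s2^-1.5; diag(ws) <- 0
  # dE/du_i = -sum_j (u_i - u_j) wd_ij - sum_j (u_i + u_j) ws_ij
  grad <- -(u * (rowSums(wd) + rowSums(ws)) - wd %*% u + ws %*% u)
  # chain rule through normalization: (I - u u^T)/|x|
  grad <- (grad - u * rowSums(grad * u)) / nrm
  as.vector(grad)
}

#' Minimal pairwise angle of a direction set
#'
#' Angles are taken modulo antipodal symmetry (directions and their negatives
#' are equivalent).
#'
#' @param u an n x 3 matrix of unit row vectors.
#' @return smallest pairwise angle in degrees (Inf for n = 1).
#' @export
min_pairwise_angle <- function(u) {
  u <- as.matrix(u)
  n <- nrow(u)
  if (n < 2) return(Inf)
  ct <- abs(tcrossprod(u))
  maxcos <- max(ct[upper.tri(ct)])
  acos(min(maxcos, 1)) * 180 / pi
}
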