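#' Multi-Gaussian tissue models
#'
#' A tissue model is a mixture of Gaussian diffusion-tensor compartments with
#' signal fractions summing to one. The normalized signal for a b-tensor B is
#' \deqn{S(B)/S_0 = \sum_i f_i \exp(-B : D_i),}
#' with ":" the Frobenius double contraction. Three presets reproduce
#' commonly used two-compartment toy tissues:
#' \describe{
#'   \item{\code{wm_mimic}}{white-matter-like, high anisotropic and low
#'     isotropic variance: a stick with eigenvalues (2.1, 0, 0) um^2/ms at
#'     fraction 0.8 plus an isotropic 1.4 um^2/ms ball.}
#'   \item{\code{iso_hetero}}{isotropic but heterogeneous: balls of 0.4 and
#'     1.4 um^2/ms mixed half and half (high isotropic variance).}
#'   \item{\code{mki_zero}}{a stick (2.1, 0, 0) and a ball 0.7 um^2/ms, half
#'     and half; both compartments share the same mean diffusivity so the
#'     true isotropic variance is exactly zero.}
#' }
#'
#' @param f signal fractions (non-negative, summing to 1).
#' @param eigenvalues list of length-3 diffusivity vectors, um^2/ms, one per
#'   compartment.
#' @param orientations optional list of 3x3 rotation matrices per compartment
#'   (default: eigenframe aligned with the lab axes, largest eigenvalue on x).
#' @param name optional label.
#' @return an object of class \code{tissue_model}.
#' @export
tissue_model <- function(f, eigenvalues, orientations = NULL, name = "") {
  stopifnot(is.numeric(f), all(f >= 0), abs(sum(f) - 1) < 1e-9,
            is.list(eigenvalues), length(eigenvalues) == length(f))
  for (ev in eigenvalues)
    stopifnot(length(ev) == 3L, all(ev >= 0), all(is.finite(ev)))
  if (is.null(orientations))
    orientations <- replicate(length(f), diag(3), simplify = FALSE)
  stopifnot(length(orientations) == length(f))
  comps <- lapply(seq_along(f), function(i) {
    R <- orientations[[i]]
    list(f = f[i], eigenvalues = as.numeric(eigenvalues[[i]]),
         D = R %*% diag(as.numeric(eigenvalues[[i]])) %*% t(R))
  })
  structure(list(compartments = comps, name = name), class = "tissue_model")
}

#' @rdname tissue_model
#' @param preset one of \code{"wm_mimic"}, \code{"iso_hetero"},
#'   \code{"mki_zero"}.
#' @export
tissue_preset <- function(preset = c("wm_mimic", "iso_hetero", "mki_zero")) {
  preset <- match.arg(preset)
  switch(preset,
    wm_mimic = tissue_model(
      f = c(0.8, 0.2),
      eigenvalues = list(c(2.1, 0, 0), c(1.4, 1.4, 1.4)),
      name = "wm_mimic"),
    iso_hetero = tissue_model(
      f = c(0.5, 0.5),
      eigenvalues = list(c(0.4, 0.4, 0.4), c(1.4, 1.4, 1.4)),
      name = "iso_hetero"),
    mki_zero = tissue_model(
      f = c(0.5, 0.5),
      eigenvalues = list(c(2.1, 0, 0), c(0.7, 0.7, 0.7)),
      name = "mki_zero"))
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("tissue model%s: %d compartment(s)\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              length(x$compartments)))
  for (cp in x$compartments)
    cat(sprintf("  f = %.3g, eigenvalues = (%s) um^2/ms\n", cp$f,
                paste(format(cp$eigenvalues), collapse = ", ")))
  m <- true_moments(x)
  cat(sprintf("  MD = %.4g, V_I = %.4g, V_A = %.4g, uFA = %.4g\n",
              m$MD, m$VI, m$VA, m$uFA))
  invisible(x)
}

#' Rotate every compartment of a tissue model
#'
#' @param model a \code{tissue_model}.
#' @param R a 3x3 rotation matrix.
#' @export
rotate_tissue_model <- function(model, R) {
  stopifnot(inherits(model, "tissue_model"))
  model$compartments <- lapply(model$compartments, function(cp) {
    cp$D <- R %*% cp$D %*% t(R)
    cp
  })
  model
}

#' Normalized multi-Gaussian signal for one or more b-tensors
#'
#' @param model a \code{tissue_model}.
#' @param B a \code{btensor} or a list of them.
#' @return signal fraction(s) S/S0 in (0, 1].
#' @export
dwi_signal <- function(model, B) {
  stopifnot(inherits(model, "tissue_model"))
  if (!is.list(B) || inherits(B, "btensor")) B <- list(B)
  vapply(B, function(Bi) {
    Bm <- as_btensor_matrix(Bi)
    sum(vapply(model$compartments,
               function(cp) cp$f * exp(-sum(Bm * cp$D)), 1))
  }, 1)
}

#' Closed-form diffusional moments of a tissue model
#'
#' For a multi-Gaussian mixture the powder-averaged apparent diffusivity
#' distribution has mean
#' \eqn{MD = \sum_i f_i \bar\lambda_i}, isotropic variance
#' \eqn{V_I = \sum_i f_i (\bar\lambda_i - MD)^2} (between-compartment
#' variance of mean diffusivities), and anisotropic variance
#' \eqn{V_A = \sum_i f_i \frac{2}{45}\sum_{j<k} (\lambda_{ij}-\lambda_{ik})^2}
#' (orientational variance of the directional diffusivity, closed form for a
#' Gaussian compartment). Kurtosis-style metrics are \eqn{MK_x = 3 V_x / MD^2}
#' and the microscopic fractional anisotropy follows from MD, V_I, V_A.
#'
#' @param model a \code{tissue_model}.
#' @return list with \code{MD}, \code{VI}, \code{VA}, \code{MKI},
#'   \code{MKA}, \code{uFA}.
#' @export
true_moments <- function(model) {
  stopifnot(inherits(model, "tissue_model"))
  f <- vapply(model$compartments, `[[`, 1, "f")
  md_i <- vapply(model$compartments, function(cp) mean(cp$eigenvalues), 1)
  MD <- sum(f * md_i)
  VI <- sum(f * (md_i - MD)^2)
  VA <- sum(f * vapply(model$compartments, function(cp) {
    l <- cp$eigenvalues
    (2 / 45) * ((l[1] - l[2])^2 + (l[1] - l[3])^2 + (l[2] - l[3])^2)
  }, 1))
  list(MD = MD, VI = VI, VA = VA,
       MKI = if (MD > 0) 3 * VI / MD^2 else NA_real_,
       MKA = if (MD > 0) 3 * VA / MD^2 else NA_real_,
       uFA = mufa(MD, VI, VA))
}

#' Add Rician noise to magnitude signals
#'
#' Magnitude MRI noise: the noisy signal is
#' \eqn{\sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}} with independent zero-mean
#' Gaussian \eqn{\epsilon} of standard deviation \code{S0/snr}. At high SNR
#' this is approximately Gaussian and unbiased; near the noise floor it is
#' positively biased (Rayleigh mean \eqn{\sigma\sqrt{\pi/2}} at S = 0).
#'
#' @param signal numeric vector/array of noise-free magnitudes.
#' @param snr signal-to-noise ratio defined at \code{S0}.
#' @param S0 reference signal defining the noise scale (default 1, for
#'   normalized signals).
#' @param seed optional integer seed for reproducibility; if \code{NULL} the
#'   current RNG stream is used.
#' @return array of noisy magnitudes, same shape as \code{signal}.
#' @export
add_rice_noise <- function(signal, snr, S0 = 1, seed = NULL) {
  stopifnot(snr > 0, S0 > 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  sigma <- S0 / snr
  n <- length(signal)
  out <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  attributes(out) <- attributes(signal)
  out
}

#' Load a tissue model from a YAML file
#'
#' Expected layout: a \code{name} and a \code{compartments} list, each entry
#' with \code{f} and \code{eigenvalues} (three diffusivities, um^2/ms).
#'
#' @param path YAML file path.
#' @export
read_tissue_model <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read tissue model files")
  y <- yaml::read_yaml(path)
  tissue_model(
    f = vapply(y$compartments, `[[`, 1, "f"),
    eigenvalues = lapply(y$compartments, function(cp) as.numeric(cp$eigenvalues)),
    name = if (!is.null(y$name)) y$name else "")
}
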