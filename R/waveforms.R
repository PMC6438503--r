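#' Effective gradient waveforms and b-tensor integration
#'
#' An effective gradient waveform stores the diffusion-encoding gradient with
#' the sign inversion after the refocusing pulse already applied, so that the
#' encoding integrals can ignore the RF pulse entirely. The refocusing
#' condition is then simply that the time integral of each gradient channel
#' vanishes over the full waveform.
#'
#' @name grad_waveform
#' @keywords internal
NULL

# gyromagnetic ratio of 1H, rad s^-1 T^-1
GAMMA_1H <- 2.6751e8

new_grad_waveform <- function(dt, g, delta1 = NA_real_, delta2 = NA_real_,
                              delta_P = NA_real_) {
  g <- as.matrix(g)
  stopifnot(ncol(g) == 3L, dt > 0, all(is.finite(g)))
  slew <- if (nrow(g) > 1) max(abs(diff(g))) / dt else 0  # mT/m/ms == T/m/s
  structure(list(
    dt = dt, g = g,
    delta1 = delta1, delta2 = delta2, delta_P = delta_P,
    g_max_used = max(abs(g)), slew_max_used = slew),
    class = "grad_waveform")
}

#' @export
print.grad_waveform <- function(x, ...) {
  cat(sprintf(
    "effective gradient waveform: %d samples, dt = %g ms, duration = %g ms\n",
    nrow(x$g), x$dt, (nrow(x$g) - 1) * x$dt))
  cat(sprintf("  max amplitude %.2f mT/m, max slew %.1f T/m/s\n",
              x$g_max_used, x$slew_max_used))
  invisible(x)
}

#' Integrate a b-tensor from an effective gradient waveform
#'
#' Computes the dephasing vector \eqn{q(t) = \gamma \int_0^t g(t')\,dt'} and
#' the b-tensor \eqn{B = \int q(t) q(t)^T dt} by trapezoidal quadrature on the
#' stored time grid. The waveform must satisfy the refocusing condition
#' (zero net gradient area per channel).
#'
#' @param w a \code{grad_waveform} (gradients in mT/m, dt in ms).
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1 (default 2.6751e8 for 1H).
#' @return a \code{btensor} in ms/um^2.
#' @export
btensor_from_waveform <- function(w, gamma = GAMMA_1H) {
  stopifnot(inherits(w, "grad_waveform"))
  g <- w$g
  n <- nrow(g)
  dur <- (n - 1) * w$dt
  # refocusing check: trapezoidal zeroth moment per channel
  m0 <- if (n > 1) colSums((g[-1, , drop = FALSE] + g[-n, , drop = FALSE]) / 2) * w$dt
        else c(0, 0, 0)
  gmax <- max(abs(g))
  if (gmax > 0 && max(abs(m0)) > 1e-9 * gmax * dur)
    stop(sprintf(
      "waveform is not refocused: residual zeroth moment (%.3g, %.3g, %.3g) mT/m*ms",
      m0[1], m0[2], m0[3]))
  # q(t) in SI [1/m]: gamma [rad/s/T] * g [T/m] * t [s]
  g_si <- g * 1e-3
  dt_si <- w$dt * 1e-3
  q <- apply(g_si, 2, function(gc) {
    c(0, cumsum((gc[-1] + gc[-n]) / 2)) * dt_si
  }) * gamma
  if (n == 1) q <- matrix(0, 1, 3)
  # B = int q q^T dt, trapezoidal; [s/m^2] -> ms/um^2 via 1e-9
  wts <- rep(dt_si, n)
  wts[c(1, n)] <- dt_si / 2
  B_si <- crossprod(q * sqrt(wts))
  new_btensor(B_si * 1e-9)
}

#' Synthesize a bipolar trapezoid LTE waveform
#'
#' Builds the effective gradient of a linear tensor-encoding experiment: a
#' trapezoid lobe of duration \code{delta1} before the refocusing pulse, a
#' pause of \code{delta_P}, and an opposite-polarity trapezoid lobe of
#' duration \code{delta2} after it, all along one axis. Ramps run at the slew
#' limit. The lobe amplitude is found by root finding so that the numerically
#' integrated b-value matches \code{b_target}; when \code{delta1 != delta2}
#' the second lobe's amplitude is rescaled so the waveform refocuses exactly.
#'
#' @param b_target target b-value, ms/um^2.
#' @param delta1,delta2 lobe durations before/after the refocusing pulse, ms.
#' @param delta_P pause between the lobes (the refocusing gap), ms.
#' @param G_max maximum gradient amplitude, mT/m.
#' @param S_max maximum slew rate, T/m/s.
#' @param dt time step of the stored waveform, ms.
#' @param direction encoding axis (unit vector, default z).
#' @return a \code{grad_waveform}; its integrated b-tensor has trace within
#'   0.5\% of \code{b_target} and shape \eqn{b_\Delta = 1}.
#' @export
make_bipolar_lte_waveform <- function(b_target, delta1, delta2, delta_P,
                                      G_max, S_max, dt = 0.01,
                                      direction = c(0, 0, 1)) {
  stopifnot(delta1 > 0, delta2 > 0, delta_P >= 0, G_max > 0, S_max > 0,
            dt > 0, b_target >= 0)
  direction <- direction / sqrt(sum(direction^2))
  if (b_target == 0) {
    n <- round((delta1 + delta_P + delta2) / dt) + 1
    return(new_grad_waveform(dt, matrix(0, n, 3), delta1, delta2, delta_P))
  }
  b_of_G <- function(G) {
    w <- bipolar_lte_at_amplitude(G, delta1, delta2, delta_P, S_max, dt,
                                  direction)
    btensor_shape(btensor_from_waveform(w))$b
  }
  b_max <- b_of_G(G_max)
  if (b_max < b_target)
    stop(sprintf(
      "b = %.4g ms/um^2 unreachable at G_max = %g mT/m with these timings; maximum achievable b = %.4g",
      b_target, G_max, b_max))
  G <- stats::uniroot(function(G) b_of_G(G) - b_target,
                      lower = 0, upper = G_max,
                      tol = 1e-8 * G_max)$root
  bipolar_lte_at_amplitude(G, delta1, delta2, delta_P, S_max, dt, direction)
}

# trapezoid lobe profile sampled on the grid: 0 at t<=t0, ramp to A, plateau,
# ramp down, 0 after t0+width
trapezoid_profile <- function(t, t0, width, A, ramp) {
  ramp <- min(ramp, width / 2)
  u <- t - t0
  amp <- pmin(pmax(u / ramp, 0), 1) * pmin(pmax((width - u) / ramp, 0), 1)
  A * pmin(amp, 1)
}

bipolar_lte_at_amplitude <- function(G, delta1, delta2, delta_P, S_max, dt,
                                     direction) {
  total <- delta1 + delta_P + delta2
  if (G <= 0) {
    n <- round(total / dt) + 1
    return(new_grad_waveform(dt, matrix(0, n, 3), delta1, delta2, delta_P))
  }
  ramp <- G / S_max                      # ms (mT/m over T/m/s)
  if (ramp > min(delta1, delta2) / 2)
    stop("slew limit too low: ramps do not fit inside the lobes")
  n <- round(total / dt) + 1
  t <- (seq_len(n) - 1) * dt
  # second-lobe amplitude balancing the gradient areas (trapezoid area
  # A*(width - ramp), ramp = G2/S_max): quadratic in G2, smaller root
  area1 <- G * (delta1 - ramp)
  disc <- delta2^2 - 4 * area1 / S_max
  if (disc < 0) stop("cannot refocus: second lobe cannot match the first lobe's area")
  G2 <- (delta2 - sqrt(disc)) * S_max / 2
  prof <- trapezoid_profile(t, 0, delta1, G, ramp) -
    trapezoid_profile(t, delta1 + delta_P, delta2, G2, G2 / S_max)
  # zero the *sampled* trapezoidal area exactly (grid discretisation leaves a
  # tiny residual); rescale the second lobe
  pos <- pmax(prof, 0); neg <- pmin(prof, 0)
  a_pos <- sum((pos[-1] + pos[-n]) / 2) * dt
  a_neg <- -sum((neg[-1] + neg[-n]) / 2) * dt
  if (a_neg > 0) prof <- pos + neg * (a_pos / a_neg)
  new_grad_waveform(dt, outer(prof, direction), delta1, delta2, delta_P)
}

#' Read / write effective gradient waveform text files
#'
#' Format: comment/header lines starting with \code{#}, including
#' \code{# dt_ms=<float>}; then one row per time sample with three
#' whitespace-separated effective-gradient values in mT/m.
#'
#' @param path file path.
#' @rdname waveform_io
#' @export
read_waveform <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  m <- regmatches(hdr, regexpr("dt_ms=\\s*[0-9.eE+-]+", hdr))
  m <- m[nzchar(m)]
  if (!length(m)) stop("waveform file lacks a '# dt_ms=' header: ", path)
  dt <- as.numeric(sub("dt_ms=\\s*", "", m[[1]]))
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  g <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (any(is.na(g)) || ncol(g) != 3)
    stop("waveform file rows must hold three numeric gradient values: ", path)
  new_grad_waveform(dt, g)
}

#' @param w a \code{grad_waveform}.
#' @rdname waveform_io
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "grad_waveform"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt_ms=%.10g", w$dt), con)
  writeLines("# effective gradient, three channels, mT/m", con)
  utils::write.table(format(w$g, digits = 12, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
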